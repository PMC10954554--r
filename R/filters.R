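#' Apply the dataset inclusion filters
#'
#' Partitions datasets into those admitted to an analysis and those excluded,
#' with the failed rule recorded per exclusion. Rules:
#' \describe{
#'   \item{`lifespan`}{more than 10 samples above the age at maturity AND a
#'     sampling rate (samples above maturity / maximum observed age)
#'     greater than 0.5. Requires [age_dataset] inputs and a `maturity`
#'     lookup.}
#'   \item{`corpora`}{sample size at least 20 AND sampling rate
#'     (n / maximum observed lifespan age) greater than 0.6. Requires
#'     [corpora_dataset] inputs.}
#'   \item{`juvenile`}{more than 100 records below the age at maturity.
#'     Requires [age_dataset] inputs and a `maturity` lookup.}
#' }
#'
#' @param datasets list of [age_dataset] or [corpora_dataset] objects.
#' @param kind one of `"lifespan"`, `"corpora"`, `"juvenile"`.
#' @param maturity named numeric vector of ages at maturity by species
#'   (required for `lifespan` and `juvenile`), or a single number applied to
#'   all datasets.
#' @return A list with elements `included` (list of datasets), `excluded`
#'   (list of datasets) and `log`, a data frame with columns
#'   `dataset_id, rule, value, threshold` (one row per failed rule).
#' @export
apply_inclusion_filters <- function(datasets, kind, maturity = NULL) {
  kind <- match.arg(kind, c("lifespan", "corpora", "juvenile"))
  if (inherits(datasets, "age_dataset") || inherits(datasets, "corpora_dataset")) {
    datasets <- list(datasets)
  }
  get_maturity <- function(d) {
    if (is.null(maturity)) stop("maturity lookup required for kind '",
                                kind, "'", call. = FALSE)
    if (length(maturity) == 1 && is.null(names(maturity))) return(maturity)
    m <- maturity[[d$species]]
    if (is.null(m) || is.na(m)) stop("no maturity for species ", d$species,
                                     call. = FALSE)
    m
  }
  logs <- list()
  ok <- logical(length(datasets))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    fails <- list()
    if (kind == "lifespan") {
      mat <- get_maturity(d)
      adult <- sum(d$records$count[d$records$observed_age > mat])
      rate <- adult / d$max_observed_age
      if (!(adult > 10)) fails <- c(fails, list(c("adult_samples", adult, 10)))
      if (!(rate > 0.5)) fails <- c(fails, list(c("sampling_rate", rate, 0.5)))
    } else if (kind == "corpora") {
      if (!inherits(d, "corpora_dataset")) {
        stop("corpora filter needs corpora_dataset inputs", call. = FALSE)
      }
      if (!(d$n >= 20)) fails <- c(fails, list(c("sample_size", d$n, 20)))
      if (!(d$sampling_rate > 0.6)) {
        fails <- c(fails, list(c("sampling_rate", d$sampling_rate, 0.6)))
      }
    } else { # juvenile
      mat <- get_maturity(d)
      juv <- sum(d$records$count[d$records$observed_age < mat])
      if (!(juv > 100)) fails <- c(fails, list(c("juvenile_samples", juv, 100)))
    }
    ok[i] <- length(fails) == 0
    for (f in fails) {
      logs[[length(logs) + 1]] <- data.frame(
        dataset_id = d$dataset_id, rule = f[1],
        value = as.numeric(f[2]), threshold = as.numeric(f[3]))
    }
  }
  list(included = datasets[ok],
       excluded = datasets[!ok],
       log = if (length(logs)) do.call(rbind, logs) else
         data.frame(dataset_id = character(), rule = character(),
                    value = numeric(), threshold = numeric()))
}
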