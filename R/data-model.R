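#' Construct an age-at-death dataset
#'
#' An `age_dataset` holds one published sample of ages at death for a single
#' species-sex-population, together with the metadata the mortality model
#' needs: a prior on total population change `r`, an optional age window `W`
#' over which sampling is biased, and a systematic ageing offset `B` feeding
#' the age-estimation error model.
#'
#' @param dataset_id character identifier, unique per dataset.
#' @param species species identifier.
#' @param sex `"female"` or `"male"`.
#' @param population_id population identifier; datasets sharing a
#'   `population_id` share a population-growth parameter when fitted jointly.
#' @param ages numeric vector of observed ages at death (years, >= 0).
#' @param counts non-negative integer vector, same length as `ages`; number of
#'   individuals observed at each age.
#' @param growth_prior length-2 numeric `(mean, sd)` prior on total population
#'   change `r`. Default `c(0, 0.05)`.
#' @param bias_window optional length-2 numeric closed age interval over which
#'   sampling is biased, or `NULL`.
#' @param age_bias_offset systematic under/over-ageing offset `B` in years.
#' @param source_type free-text provenance (e.g. `"bycatch"`, `"stranding"`).
#'
#' @return An object of class `age_dataset` with derived fields `n` (total
#'   count) and `max_observed_age`.
#' @export
age_dataset <- function(dataset_id, species, sex, population_id,
                        ages, counts,
                        growth_prior = c(0, 0.05),
                        bias_window = NULL,
                        age_bias_offset = 0,
                        source_type = "unknown") {
  sex <- match.arg(sex, c("female", "male"))
  stopifnot(length(ages) == length(counts))
  if (any(ages < 0)) {
    stop("negative observed age at row ", which(ages < 0)[1], call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("negative count at row ", which(counts < 0)[1], call. = FALSE)
  }
  counts <- as.integer(round(counts))
  keep <- counts > 0
  n <- sum(counts)
  if (n <= 0) stop("dataset ", dataset_id, " has no individuals", call. = FALSE)
  max_obs <- max(ages[keep])
  if (!is.null(bias_window)) {
    stopifnot(length(bias_window) == 2, bias_window[1] <= bias_window[2])
    if (bias_window[1] < 0 || bias_window[2] > max_obs) {
      stop("bias_window must lie within [0, max_observed_age]", call. = FALSE)
    }
  }
  stopifnot(length(growth_prior) == 2, growth_prior[2] >= 0)
  structure(list(
    dataset_id = as.character(dataset_id),
    species = as.character(species),
    sex = sex,
    population_id = as.character(population_id),
    records = data.frame(observed_age = ages, count = counts),
    n = n,
    max_observed_age = max_obs,
    growth_prior = as.numeric(growth_prior),
    bias_window = if (is.null(bias_window)) NULL else as.numeric(bias_window),
    age_bias_offset = as.numeric(age_bias_offset),
    source_type = as.character(source_type)
  ), class = "age_dataset")
}

#' @export
print.age_dataset <- function(x, ...) {
  cat("<age_dataset>", x$dataset_id, "-", x$species, x$sex,
      sprintf("(pop %s, n = %d, max age %.1f)\n",
              x$population_id, x$n, x$max_observed_age))
  invisible(x)
}

#' Gompertz mortality parameters
#'
#' Adult hazard `h(x) = alpha * exp(beta * x)` with `x` measured in years
#' since maturity; `alpha` is the baseline hazard and `beta` the actuarial
#' ageing rate.
#'
#' @param alpha baseline hazard (1/yr, > 0).
#' @param beta actuarial ageing rate (1/yr, >= 0; `beta = 0` is the
#'   exponential (constant-hazard) limit).
#' @return An object of class `gompertz_params`.
#' @export
gompertz_params <- function(alpha, beta) {
  stopifnot(alpha > 0, beta >= 0)
  structure(list(alpha = alpha, beta = beta), class = "gompertz_params")
}

#' Construct an ovarian corpora-count dataset
#'
#' Each record pairs a known age with the number of persistent ovarian corpora
#' (lutea + albicantia) counted post mortem; cumulative corpora index lifetime
#' ovulations.
#'
#' @param dataset_id,species identifiers.
#' @param ages numeric vector of ages (years, >= 0).
#' @param corpora non-negative integer corpora counts, same length as `ages`.
#' @param age_at_maturity age at sexual maturity (years).
#' @param max_lifespan_age maximum observed age from the lifespan database for
#'   this species, used to compute the sampling rate for inclusion filtering;
#'   defaults to `max(ages)`.
#' @return An object of class `corpora_dataset` with derived `n` and
#'   `sampling_rate = n / max_lifespan_age`.
#' @export
corpora_dataset <- function(dataset_id, species, ages, corpora,
                            age_at_maturity,
                            max_lifespan_age = max(ages)) {
  stopifnot(length(ages) == length(corpora))
  if (any(ages < 0)) stop("negative age at row ", which(ages < 0)[1], call. = FALSE)
  if (any(corpora < 0)) {
    stop("negative corpora count at row ", which(corpora < 0)[1], call. = FALSE)
  }
  n <- length(ages)
  structure(list(
    dataset_id = as.character(dataset_id),
    species = as.character(species),
    records = data.frame(age = ages, corpora_count = as.integer(round(corpora))),
    age_at_maturity = as.numeric(age_at_maturity),
    n = n,
    sampling_rate = n / max_lifespan_age
  ), class = "corpora_dataset")
}

#' Species trait record
#'
#' Mean body length and age at maturity with their uncertainties, plus the
#' menopause indicator used as the binary predictor in the comparative models.
#'
#' @param species,sex identifiers.
#' @param length_mean,length_sd body length mean and s.d. (cm).
#' @param maturity_mean,maturity_sd age at maturity mean and s.d. (years).
#' @param menopause 0/1 indicator of a prolonged postreproductive lifespan.
#' @param juvenile_sample_size number of sub-maturity records available.
#' @return An object of class `species_traits`.
#' @export
species_traits <- function(species, sex = "female",
                           length_mean, length_sd = 0,
                           maturity_mean, maturity_sd = 0,
                           menopause = 0L,
                           juvenile_sample_size = 0L) {
  stopifnot(length_sd >= 0, maturity_sd >= 0, menopause %in% c(0, 1))
  structure(list(
    species = as.character(species), sex = as.character(sex),
    length_mean = length_mean, length_sd = length_sd,
    maturity_mean = maturity_mean, maturity_sd = maturity_sd,
    menopause = as.integer(menopause),
    juvenile_sample_size = as.integer(juvenile_sample_size)
  ), class = "species_traits")
}

#' Chronogram with patristic distance matrix
#'
#' Wraps a time-calibrated phylogeny as the patristic (path-length) distance
#' matrix the Ornstein-Uhlenbeck covariance kernel consumes. Ultrametricity is
#' checked against the tree depth; departures beyond tolerance are flagged
#' with a warning, not an error, since bootstrap chronograms often carry
#' rounding slop.
#'
#' @param tree an [ape::phylo] tree with branch lengths in time units.
#' @param tree_index integer index of this tree within a bootstrap set.
#' @param tol relative ultrametricity tolerance (default `1e-6` of depth).
#' @return An object of class `chronogram` with fields `taxa`, `D`
#'   (symmetric, zero-diagonal patristic distance matrix), `tree_index`,
#'   `ultrametric` flag and the original `tree`.
#' @export
chronogram <- function(tree, tree_index = 1L, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  D <- ape::cophenetic.phylo(tree)
  taxa <- rownames(D)
  depths <- ape::node.depth.edgelength(tree)[seq_along(taxa)]
  depth <- max(depths)
  ultra <- depth == 0 || all(abs(depths - depth) <= tol * depth)
  if (!ultra) {
    warning("tree ", tree_index, " is not ultrametric within tolerance",
            call. = FALSE)
  }
  structure(list(taxa = taxa, D = D, tree_index = as.integer(tree_index),
                 ultrametric = ultra, tree = tree),
            class = "chronogram")
}
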