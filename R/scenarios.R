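## Counterfactual demographies for menopausal species. The "ancestral" case
## gives the species the lifespan predicted for its size by the non-menopause
## allometry while keeping its observed reproductive schedule; the "slow life
## history" case keeps the observed lifespan but extends reproduction to the
## end of life. Baseline fecundity is re-solved per case so every
## counterfactual population is stationary.

## Rescale the Gompertz ageing rate (holding alpha) so the ordinary maximum
## lifespan hits a target; one degree of freedom preserves the hazard shape.
## If a candidate beta already hits the target (Z lives on a 1-year grid) it
## is returned unchanged, so a degenerate target equal to the observed
## lifespan leaves the demography bitwise identical.
rescale_beta_to_z <- function(alpha, maturity, target_z, q = 0.9,
                              omega = NULL, beta_init = NULL) {
  f <- function(logb) {
    ordinary_max_lifespan(list(alpha = alpha, beta = exp(logb)), maturity,
                          q = q, omega = omega) - target_z
  }
  if (!is.null(beta_init) && f(log(beta_init)) == 0) return(beta_init)
  lo <- log(1e-4); hi <- log(3)
  if (f(lo) < 0) return(1e-4)   # target above what beta -> 0 can reach
  if (f(hi) > 0) return(3)
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-4)$root)
}

#' Build per-draw life tables and kinship metrics for a demographic scenario
#'
#' For each aligned posterior draw, constructs the case's life table and
#' computes the kinship metrics:
#' \describe{
#'   \item{observed}{fitted demography unchanged; reproduction ceases at the
#'     observed reproductive lifespan.}
#'   \item{ancestral}{adult ageing rate rescaled so the ordinary maximum
#'     lifespan equals the size-predicted non-menopause value
#'     (`target_z_draws`); reproductive cessation unchanged.}
#'   \item{slow}{observed mortality; reproduction extended so cessation age
#'     equals the draw's ordinary maximum lifespan.}
#' }
#' Draw alignment across cases is by index: call with the same draw vectors
#' per case so paired contrasts are valid.
#'
#' @param alpha_draws,beta_draws aligned adult Gompertz draws.
#' @param maturity age at maturity (years).
#' @param surv_maturity_draws aligned survival-to-maturity draws.
#' @param cessation_obs observed reproductive lifespan (years): corpora
#'   cessation age or the age of the oldest known reproductively active
#'   female.
#' @param case `"observed"`, `"ancestral"` or `"slow"`.
#' @param target_z_draws aligned size-predicted non-menopause lifespan draws
#'   (years); required for the ancestral case.
#' @param omega age cap for the life tables.
#' @param q person-year fraction defining ordinary maximum lifespan.
#' @param currency passed to [kin_expectations()].
#' @return A data frame (class `scenario_draws`, attribute `case`) with one
#'   row per draw: `draw, case, Z, cessation, GY, relGY, MY, relMY, overlap`
#'   (schedule-only), `overlap_w` (survivorship-weighted) and `f`.
#' @export
make_scenario <- function(alpha_draws, beta_draws, maturity,
                          surv_maturity_draws, cessation_obs,
                          case = c("observed", "ancestral", "slow"),
                          target_z_draws = NULL, omega = 120, q = 0.9,
                          currency = "both") {
  case <- match.arg(case)
  n <- length(alpha_draws)
  stopifnot(length(beta_draws) == n, length(surv_maturity_draws) == n)
  if (case == "ancestral") {
    if (is.null(target_z_draws)) {
      stop("ancestral case needs target_z_draws (size-predicted lifespans)",
           call. = FALSE)
    }
    stopifnot(length(target_z_draws) == n)
  }
  out <- lapply(seq_len(n), function(i) {
    a <- alpha_draws[i]; b <- beta_draws[i]
    if (case == "ancestral") {
      b <- rescale_beta_to_z(a, maturity, target_z_draws[i], q = q,
                             omega = omega, beta_init = b)
    }
    z <- ordinary_max_lifespan(list(alpha = a, beta = b), maturity, q = q,
                               omega = omega)
    cess <- if (case == "slow") z else cessation_obs
    bc <- 1 / max(cess - maturity, 1)
    tab <- life_table_from_draws(a, b, maturity, surv_maturity_draws[i], bc,
                                 omega = omega)
    traj <- kin_expectations(tab, currency = currency)
    met <- kinship_metrics(traj, tab)
    met_w <- kinship_metrics(traj, tab, survival_weight_overlap = TRUE)
    data.frame(draw = i, case = case, Z = z, cessation = cess,
               GY = met$grandmother_years,
               relGY = met$relative_grandmother_years,
               MY = met$mother_years,
               relMY = met$relative_mother_years,
               overlap = met$reproductive_overlap,
               overlap_w = met_w$reproductive_overlap,
               f = met$baseline_fecundity)
  })
  structure(do.call(rbind, out), case = case,
            class = c("scenario_draws", "data.frame"))
}

#' Contrast kinship metrics across demographic scenarios
#'
#' Paired-draw tail probabilities `P(metric_caseA > metric_caseB)` (ties
#' counted half, so identical cases give 0.5) for every ordered case pair,
#' plus draws z-scored across the pooled cases for cross-species display.
#'
#' @param metric_by_case named list: per case, an aligned numeric vector of
#'   metric draws (equal lengths required).
#' @return A list with `tail` (matrix, `tail[A, B] = P(A > B)`) and
#'   `z` (data frame `case, draw, z`; pooled mean 0, sd 1).
#' @export
scenario_contrast <- function(metric_by_case) {
  stopifnot(is.list(metric_by_case), !is.null(names(metric_by_case)))
  n <- unique(vapply(metric_by_case, length, integer(1)))
  if (length(n) != 1) stop("draw-count mismatch across cases", call. = FALSE)
  cases <- names(metric_by_case)
  tail <- matrix(NA_real_, length(cases), length(cases),
                 dimnames = list(cases, cases))
  for (a in cases) for (b in cases) {
    da <- metric_by_case[[a]]; db <- metric_by_case[[b]]
    tail[a, b] <- mean(da > db) + 0.5 * mean(da == db)
  }
  pooled <- unlist(metric_by_case, use.names = FALSE)
  z <- (pooled - mean(pooled)) / stats::sd(pooled)
  list(tail = tail,
       z = data.frame(case = rep(cases, each = n), draw = rep(seq_len(n),
                                                              length(cases)),
                      z = z))
}
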