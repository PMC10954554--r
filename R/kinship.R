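#' Build a life table on a 1-year age grid
#'
#' A `life_table` couples a survivorship schedule with a relative fecundity
#' schedule and the baseline fecundity `f` that makes the implied Leslie
#' matrix stationary (dominant eigenvalue 1). Relative fecundity follows the
#' corpora-deposition decline: `phi(x) = max(0, 1 - beta_corpora *
#' (x - maturity))` for `x >= maturity`, 0 before maturity, unless an
#' explicit `phi` is supplied.
#'
#' @param lx survivorship from birth at integer ages `0..omega`
#'   (`lx[1] = 1`, non-increasing, positive or zero).
#' @param maturity age at maturity (years).
#' @param beta_corpora linear decline rate of relative fecundity with adult
#'   age (1/yr); ignored when `phi` is given.
#' @param phi optional explicit relative fecundity schedule in `[0, 1]`,
#'   same length as `lx`.
#' @param f optional explicit baseline fecundity; when supplied the
#'   Euler-Lotka solve is skipped (used for degenerate schedules such as
#'   `phi == 0` everywhere, where no stationary `f` exists).
#' @return An object of class `life_table` with `ages`, `lx`, `px` (per-year
#'   survival), `phi`, `maturity` and solved baseline fecundity `f`.
#' @export
life_table <- function(lx, maturity, beta_corpora = NULL, phi = NULL,
                       f = NULL) {
  stopifnot(abs(lx[1] - 1) < 1e-12, all(diff(lx) <= 1e-12), all(lx >= 0))
  ages <- seq_along(lx) - 1
  if (is.null(phi)) {
    if (is.null(beta_corpora)) stop("need beta_corpora or phi", call. = FALSE)
    phi <- ifelse(ages >= maturity,
                  pmax(0, 1 - beta_corpora * (ages - maturity)), 0)
  }
  stopifnot(length(phi) == length(lx), all(phi >= 0), all(phi <= 1))
  px <- c(ifelse(lx[-length(lx)] > 0, lx[-1] / lx[-length(lx)], 0), 0)
  if (is.null(f)) f <- solve_baseline_fecundity(lx, phi)
  structure(list(ages = ages, lx = lx, px = px, phi = phi,
                 maturity = maturity, f = f),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> ages 0..%d, maturity %.1f, f = %.4f\n",
              max(x$ages), x$maturity, x$f))
  invisible(x)
}

#' Life table from fitted demographic draws
#'
#' Assembles the survivorship schedule from a juvenile survival-to-maturity
#' value (spread over the juvenile years at a constant hazard) and an adult
#' Gompertz draw, with the corpora decline rate giving relative fecundity.
#'
#' @param alpha,beta adult Gompertz parameters.
#' @param maturity age at maturity (years).
#' @param surv_maturity probability of surviving from birth to maturity.
#' @param beta_corpora corpora decline rate (1/yr); relative fecundity
#'   ceases at `maturity + 1/beta_corpora`.
#' @param omega age cap (default 120).
#' @return A [life_table].
#' @export
life_table_from_draws <- function(alpha, beta, maturity, surv_maturity,
                                  beta_corpora, omega = 120) {
  ages <- 0:omega
  mat <- maturity
  adult <- gompertz_survivorship(pmax(ages, mat),
                                 list(alpha = alpha, beta = beta),
                                 from_age = mat)
  lx <- ifelse(ages < mat, surv_maturity^(ages / mat), surv_maturity * adult)
  lx[1] <- 1
  life_table(lx, maturity, beta_corpora = beta_corpora)
}

#' Solve the baseline fecundity for a stationary population
#'
#' Finds `f` such that the Leslie matrix with daughter fecundity
#' `f * phi(age)` has dominant eigenvalue 1. At stationarity the
#' Euler-Lotka condition `sum_x lx(x) * f * phi(x) = 1` is linear in `f`,
#' so the solution is exact: `f = 1 / sum(lx * phi)`.
#'
#' @param lx survivorship from birth at integer ages.
#' @param phi relative fecundity schedule, same length.
#' @return Baseline fecundity `f` (daughters per female-year at `phi = 1`).
#' @export
solve_baseline_fecundity <- function(lx, phi) {
  tot <- sum(lx * phi)
  if (tot <= 0) stop("no reproductive age reachable: sum(lx * phi) = 0",
                     call. = FALSE)
  1 / tot
}

#' Assemble the Leslie matrix of a life table
#'
#' Top-row daughter fertilities `f * phi(age)`, subdiagonal per-year
#' survival probabilities. Its dominant eigenvalue is 1 (stationarity) by
#' construction of `f`.
#'
#' @param table a [life_table].
#' @return A square matrix of dimension `length(table$ages)`.
#' @export
leslie_matrix <- function(table) {
  n <- length(table$ages)
  A <- matrix(0, n, n)
  A[1, ] <- table$f * table$phi
  A[cbind(2:n, 1:(n - 1))] <- table$px[1:(n - 1)]
  A
}

#' Expected kin trajectories of a focal female
#'
#' Deterministic age-structured recursion, conditional on the focal female
#' being alive at each age: her expected living daughters by daughter age,
#' and her expected living matrilineal grandoffspring by grandoffspring age.
#' Newborn daughters accrue at rate `f * phi(x)`; each living daughter of
#' age `a` contributes newborn grandoffspring at rate `f * phi(a)`.
#' Counts are in the daughter line; both-sex offspring and (through
#' daughters) both-sex grandoffspring are twice these under a 0.5 birth sex
#' ratio, selected by `currency`.
#'
#' @param table a [life_table].
#' @param currency `"both"` (default): offspring of both sexes, matrilineal
#'   grandoffspring of both sexes; `"daughters"`: daughter line only.
#' @return An object of class `kin_trajectories` with matrices `offspring`
#'   and `grandoffspring` (`[focal age + 1, kin age + 1]`), the focal
#'   survivorship-from-maturity vector `lsurv`, and the currency multiplier.
#' @export
kin_expectations <- function(table, currency = c("both", "daughters")) {
  currency <- match.arg(currency)
  cm <- if (currency == "both") 2 else 1
  n <- length(table$ages)
  m <- table$f * table$phi           # daughter rate by parent age
  P <- table$px
  d <- numeric(n)
  g <- numeric(n)
  offspring <- matrix(0, n, n)
  grandoffspring <- matrix(0, n, n)
  for (x in seq_len(n - 1)) {        # focal age x (years); row x + 1
    g <- c(0, (g * P)[-n])
    d <- c(0, (d * P)[-n])
    g[1] <- sum(d * m)               # daughters' newborns (aged daughters only)
    d[1] <- m[x + 1]                 # focal's newborn at age x
    offspring[x + 1, ] <- d * cm
    grandoffspring[x + 1, ] <- g * cm
  }
  mat <- round(table$maturity)
  lsurv <- ifelse(table$ages >= mat, table$lx / table$lx[mat + 1], 0)
  structure(list(offspring = offspring, grandoffspring = grandoffspring,
                 lsurv = lsurv, currency = currency, cm = cm,
                 maturity = table$maturity),
            class = "kin_trajectories")
}

#' Intergenerational help and harm metrics
#'
#' \describe{
#'   \item{grandmother years}{`sum_x l(x | maturity) * E[grandoffspring
#'     younger than maturity at focal age x]`: expected years a female
#'     spends alive alongside sub-maturity grandoffspring.}
#'   \item{mother years}{the same with offspring in place of grandoffspring.}
#'   \item{reproductive overlap}{`sum_x E[newborn grandoffspring at x] *
#'     (remaining fraction of the focal's reproductive capacity at x)`,
#'     where remaining capacity is the schedule mass `sum(phi[y >= x]) /
#'     sum(phi)`. Not weighted by focal survivorship by default (set
#'     `survival_weight_overlap = TRUE` for the sensitivity variant).}
#' }
#' Relative metrics divide by the age at maturity.
#'
#' @param traj a `kin_trajectories`.
#' @param table the [life_table] the trajectories came from.
#' @param survival_weight_overlap logical sensitivity flag (default `FALSE`).
#' @return An object of class `kinship_metrics`: `grandmother_years`,
#'   `relative_grandmother_years`, `mother_years`, `relative_mother_years`,
#'   `reproductive_overlap`, `baseline_fecundity`.
#' @export
kinship_metrics <- function(traj, table, survival_weight_overlap = FALSE) {
  stopifnot(inherits(traj, "kin_trajectories"), inherits(table, "life_table"))
  mat <- round(table$maturity)
  n <- length(table$ages)
  sub_mat <- seq_len(max(mat, 1))    # kin ages 0..maturity-1
  gy_by_age <- rowSums(traj$grandoffspring[, sub_mat, drop = FALSE])
  my_by_age <- rowSums(traj$offspring[, sub_mat, drop = FALSE])
  gy <- sum(traj$lsurv * gy_by_age)
  my <- sum(traj$lsurv * my_by_age)
  phi_total <- sum(table$phi)
  remaining <- rev(cumsum(rev(table$phi))) / phi_total
  g0 <- traj$grandoffspring[, 1]
  w <- if (survival_weight_overlap) traj$lsurv else 1
  overlap <- sum(g0 * remaining * w)
  structure(list(grandmother_years = gy,
                 relative_grandmother_years = gy / table$maturity,
                 mother_years = my,
                 relative_mother_years = my / table$maturity,
                 reproductive_overlap = overlap,
                 baseline_fecundity = table$f),
            class = "kinship_metrics")
}

#' @export
print.kinship_metrics <- function(x, ...) {
  cat(sprintf(paste0("<kinship_metrics> GY %.3f (rel %.3f) | MY %.3f ",
                     "(rel %.3f) | overlap %.3f | f %.4f\n"),
              x$grandmother_years, x$relative_grandmother_years,
              x$mother_years, x$relative_mother_years,
              x$reproductive_overlap, x$baseline_fecundity))
  invisible(x)
}

#' Propagate posterior uncertainty through the kinship pipeline
#'
#' Takes joint draws from the mortality, juvenile-survival and corpora
#' posteriors, builds one life table per draw and computes the kinship
#' metrics, mirroring the practice of pushing a fixed number of posterior
#' draws (default 1,000) end to end rather than the full joint space.
#'
#' @param mortality a `mortality_posterior`.
#' @param surv_maturity_draws survival-to-maturity draws (recycled).
#' @param beta_corpora_draws corpora decline-rate draws (recycled).
#' @param n_draws number of joint draws (default 1000).
#' @param maturity age at maturity; defaults to the mortality fit's.
#' @param omega age cap for the life tables.
#' @param currency passed to [kin_expectations()].
#' @param seed optional integer seed for the draw subsampling.
#' @return A data frame with one row per draw: `draw, alpha, beta,
#'   surv_maturity, beta_corpora, GY, relGY, MY, relMY, overlap` (the
#'   schedule-only reproductive overlap), `overlap_w` (the
#'   survivorship-weighted variant) and `f`.
#' @export
kinship_draws <- function(mortality, surv_maturity_draws, beta_corpora_draws,
                          n_draws = 1000, maturity = NULL, omega = 120,
                          currency = "both", seed = NULL) {
  stopifnot(inherits(mortality, "mortality_posterior"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maturity)) maturity <- mortality$maturity
  pick <- function(v, n) v[sample.int(length(v), n, replace = n > length(v))]
  n <- n_draws
  rows <- sample.int(nrow(mortality$draws), n, replace = n > nrow(mortality$draws))
  a <- mortality$draws$alpha[rows]          # (alpha, beta) kept jointly
  b <- mortality$draws$beta[rows]
  sm <- pick(surv_maturity_draws, n)
  bc <- pick(beta_corpora_draws, n)
  out <- lapply(seq_len(n), function(i) {
    tab <- life_table_from_draws(a[i], b[i], maturity, sm[i], bc[i],
                                 omega = omega)
    traj <- kin_expectations(tab, currency = currency)
    met <- kinship_metrics(traj, tab)
    met_w <- kinship_metrics(traj, tab, survival_weight_overlap = TRUE)
    data.frame(draw = i, alpha = a[i], beta = b[i], surv_maturity = sm[i],
               beta_corpora = bc[i],
               GY = met$grandmother_years,
               relGY = met$relative_grandmother_years,
               MY = met$mother_years,
               relMY = met$relative_mother_years,
               overlap = met$reproductive_overlap,
               overlap_w = met_w$reproductive_overlap,
               f = met$baseline_fecundity)
  })
  do.call(rbind, out)
}
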