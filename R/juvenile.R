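#' Fit the bathtub (Siler) whole-life mortality model
#'
#' For datasets with good juvenile sampling, the whole age-at-death
#' distribution is modelled with a Siler hazard: a declining juvenile term
#' `a1 * exp(-b1 * x)`, a constant term `a2` and the Gompertz senescent term
#' `alpha * exp(beta * x)`, all from birth. The multinomial machinery matches
#' the adult model; growth discounting uses the dataset's prior-mean `r` and
#' sampling bias/age error are not applied (juvenile counts in these
#' well-sampled series are treated as unbiased). Survival to maturity per
#' draw is the fitted survivorship at the age at maturity.
#'
#' Priors: `a1 ~ half-Normal(0, 1)`, `b1 ~ half-Normal(0, 2)`,
#' `a2 ~ half-Normal(0, 0.1)`, `alpha ~ half-Normal(0, 0.1)`,
#' `beta ~ half-Normal(0, 0.2)`.
#'
#' @param dataset an [age_dataset] spanning juvenile and adult ages; must
#'   pass the juvenile inclusion filter (> 100 sub-maturity records).
#' @param maturity age at maturity (years).
#' @param n_chains,warmup,iter MCMC settings.
#' @param seed optional integer seed.
#' @param check_filter set `FALSE` to bypass the filter precondition.
#' @return An object of class `juvenile_posterior`: `draws` (data frame with
#'   `a1, b1, a2, alpha, beta` and `surv_maturity`), diagnostics, `maturity`.
#' @export
fit_juvenile_survival <- function(dataset, maturity, n_chains = 4,
                                  warmup = 3000, iter = 2500, seed = NULL,
                                  check_filter = TRUE) {
  stopifnot(inherits(dataset, "age_dataset"))
  if (check_filter) {
    flt <- apply_inclusion_filters(list(dataset), "juvenile", maturity = maturity)
    if (length(flt$excluded)) {
      stop("dataset fails the juvenile inclusion filter (needs > 100 ",
           "sub-maturity records)", call. = FALSE)
    }
  }
  omega <- max(120, 3 * dataset$max_observed_age)
  ages <- 0:omega
  bin <- floor(dataset$records$observed_age)
  counts <- numeric(length(ages))
  idx <- pmin(bin, omega) + 1
  tab <- tapply(dataset$records$count, factor(idx, levels = seq_along(ages)), sum)
  counts <- as.numeric(tab)
  counts[is.na(counts)] <- 0
  rho <- growth_discount_rate(dataset$growth_prior[1], dataset$max_observed_age)

  log_post <- function(par) {
    a1 <- exp(par[1]); b1 <- exp(par[2]); a2 <- exp(par[3])
    alpha <- exp(par[4]); beta <- exp(par[5])
    if (any(!is.finite(c(a1, b1, a2, alpha, beta))) || beta > 5 || b1 > 50) {
      return(-Inf)
    }
    lp <- stats::dnorm(a1, 0, 1, log = TRUE) + par[1] +
      stats::dnorm(b1, 0, 2, log = TRUE) + par[2] +
      stats::dnorm(a2, 0, 0.1, log = TRUE) + par[3] +
      stats::dnorm(alpha, 0, 0.1, log = TRUE) + par[4] +
      stats::dnorm(beta, 0, 0.2, log = TRUE) + par[5]
    L <- siler_survivorship(ages, a1, b1, a2, alpha, beta)
    theta <- L * (1 - rho)^ages
    theta <- theta / sum(theta)
    ll <- sum(counts * log(theta + 1e-300))
    if (!is.finite(ll)) return(-Inf)
    lp + ll
  }
  init <- function(chain) {
    c(log(0.3), log(1), log(0.02), log(0.05), log(0.1)) +
      stats::rnorm(5, 0, 0.3)
  }
  fit <- run_mh(log_post, init, n_chains = n_chains, warmup = warmup,
                iter = iter,
                par_names = c("log_a1", "log_b1", "log_a2", "log_alpha",
                              "log_beta"),
                seed = seed)
  draws <- as.data.frame(exp(fit$draws))
  names(draws) <- c("a1", "b1", "a2", "alpha", "beta")
  draws$surv_maturity <- siler_survivorship(maturity, draws$a1, draws$b1,
                                            draws$a2, draws$alpha, draws$beta)
  structure(list(dataset_id = dataset$dataset_id, species = dataset$species,
                 draws = draws, n_draws = nrow(draws), rhat = fit$rhat,
                 ess = fit$ess, converged = fit$converged,
                 maturity = maturity),
            class = "juvenile_posterior")
}

#' Regression of survival to maturity on age at maturity
#'
#' Pools the species with direct bathtub fits and regresses
#' `logit(survival to maturity)` on age at maturity, propagating the
#' per-species posterior uncertainty as response measurement error. The slope
#' sign is estimated, not assumed. Species without juvenile data get their
#' survival to maturity imputed from this regression via
#' [predict_survival_to_maturity()].
#'
#' @param surv_draws list (one element per species) of survival-to-maturity
#'   posterior draws in (0, 1].
#' @param maturities numeric vector of ages at maturity, same length.
#' @param n_chains,warmup,iter MCMC settings.
#' @param seed optional integer seed.
#' @return An object of class `juvenile_regression` with `draws`
#'   (`intercept`, `slope`, `sigma`), diagnostics and the training data.
#' @export
juvenile_survival_regression <- function(surv_draws, maturities,
                                         n_chains = 4, warmup = 3000,
                                         iter = 2500, seed = NULL) {
  stopifnot(length(surv_draws) == length(maturities))
  if (length(surv_draws) < 5) {
    stop("regression requires >= 5 species with direct fits", call. = FALSE)
  }
  y <- vapply(surv_draws, function(d) mean(stats::qlogis(pmin(pmax(d, 1e-6),
                                                              1 - 1e-6))),
              numeric(1))
  se <- vapply(surv_draws, function(d) stats::sd(stats::qlogis(pmin(pmax(d, 1e-6),
                                                                    1 - 1e-6))),
               numeric(1))
  x_center <- mean(maturities)
  x <- maturities - x_center
  ## slope is logit-survival change per year of maturity; half a logit per
  ## year is already a steep life-history gradient, so Normal(0, 0.5)
  log_post <- function(par) {
    a <- par[1]; b <- par[2]; sig <- exp(par[3])
    if (!is.finite(sig) || sig > 20) return(-Inf)
    lp <- stats::dnorm(a, 0, 5, log = TRUE) +
      stats::dnorm(b, 0, 0.5, log = TRUE) +
      stats::dexp(sig, 1, log = TRUE) + par[3]
    lp + sum(stats::dnorm(y, a + b * x, sqrt(sig^2 + se^2), log = TRUE))
  }
  init <- function(chain) c(mean(y), 0, log(0.5)) + stats::rnorm(3, 0, 0.2)
  fit <- run_mh(log_post, init, n_chains = n_chains, warmup = warmup,
                iter = iter, par_names = c("intercept", "slope", "log_sigma"),
                seed = seed)
  draws <- data.frame(intercept = fit$draws[, 1], slope = fit$draws[, 2],
                      sigma = exp(fit$draws[, 3]))
  structure(list(draws = draws, x_center = x_center, rhat = fit$rhat,
                 ess = fit$ess, converged = fit$converged,
                 training = data.frame(maturity = maturities,
                                       logit_surv = y, se = se)),
            class = "juvenile_regression")
}

#' Impute survival to maturity from the maturity regression
#'
#' Posterior-predictive draws of survival to maturity for a species with a
#' given age at maturity (full regression uncertainty plus residual spread).
#'
#' @param reg a `juvenile_regression`.
#' @param maturity scalar or vector of ages at maturity; if shorter than the
#'   number of regression draws it is recycled.
#' @param n_draws number of predictive draws (default: all regression draws).
#' @return Survival-to-maturity draws in (0, 1).
#' @export
predict_survival_to_maturity <- function(reg, maturity, n_draws = NULL) {
  stopifnot(inherits(reg, "juvenile_regression"))
  d <- reg$draws
  if (is.null(n_draws)) n_draws <- nrow(d)
  i <- sample.int(nrow(d), n_draws, replace = n_draws > nrow(d))
  mu <- d$intercept[i] + d$slope[i] * (maturity - reg$x_center)
  stats::plogis(stats::rnorm(n_draws, mu, d$sigma[i]))
}
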