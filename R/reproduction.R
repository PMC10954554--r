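#' Expected cumulative corpora count
#'
#' Cumulative mean corpora at a given adult age: yearly deposition increments
#' `dk_j = max(0, alpha * (1 - beta * AGE_j))` summed from maturity
#' (`AGE = 0`) to the focal age. The deposition rate declines linearly and is
#' clamped at zero, so the mean plateaus after `1/beta` adult years.
#'
#' @param age_since_maturity adult age(s) in years (>= 0); increments accrue
#'   in 1-year steps, so the sum runs over `AGE_j = 0, ..., floor(age)`.
#' @param params list with `alpha` (initial deposition rate, corpora/yr) and
#'   `beta` (decline rate, 1/yr).
#' @return Mean corpora count(s), same length as `age_since_maturity`.
#' @export
expected_corpora <- function(age_since_maturity, params) {
  stopifnot(all(age_since_maturity >= 0))
  a <- floor(age_since_maturity)
  maxa <- max(a)
  dk <- pmax(0, params$alpha * (1 - params$beta * (0:maxa)))
  cumsum(dk)[a + 1]
}

#' Fit the Bayesian corpora-deposition model for one species
#'
#' Corpora counts are Poisson with mean equal to the cumulative deposition
#' schedule; multiple datasets from the same species share the decline rate
#' `beta` but have independent initial rates `alpha_d`. Reproductive
#' cessation age per posterior draw is `1/beta + maturity`.
#'
#' Priors: `alpha_d ~ half-Normal(0, 2)`, `beta ~ half-Normal(0, 0.1)`.
#'
#' @param datasets list of [corpora_dataset] objects for one species; all
#'   must pass the corpora inclusion filter (n >= 20, sampling rate > 0.6).
#' @param maturity age at maturity (years).
#' @param n_chains,warmup,iter MCMC settings.
#' @param seed optional integer seed.
#' @param check_filter set `FALSE` to bypass the inclusion-filter
#'   precondition for toy fits.
#' @return An object of class `corpora_posterior`: `species`, `draws` (data
#'   frame with `beta`, one `alpha_*` column per dataset, and `cessation`),
#'   `rhat`, `ess`, `converged`, `maturity`.
#' @export
fit_corpora <- function(datasets, maturity, n_chains = 4, warmup = 3000,
                        iter = 2500, seed = NULL, check_filter = TRUE) {
  if (inherits(datasets, "corpora_dataset")) datasets <- list(datasets)
  if (length(datasets) == 0) stop("empty dataset list", call. = FALSE)
  species <- unique(vapply(datasets, `[[`, "", "species"))
  if (length(species) != 1) {
    stop("fit_corpora expects datasets from a single species", call. = FALSE)
  }
  if (check_filter) {
    flt <- apply_inclusion_filters(datasets, "corpora")
    if (length(flt$excluded)) {
      stop("dataset(s) fail the corpora inclusion filter: ",
           paste(unique(flt$log$dataset_id), collapse = ", "), call. = FALSE)
    }
  }
  if (all(unlist(lapply(datasets, function(d) d$records$corpora_count)) == 0)) {
    stop("all corpora counts are zero: alpha unidentifiable", call. = FALSE)
  }
  prep <- lapply(datasets, function(d) {
    a <- pmax(floor(d$records$age - maturity), 0)
    list(a = a, counts = d$records$corpora_count, maxa = max(a))
  })
  nd <- length(datasets)
  par_names <- c("log_beta", paste0("log_alpha_",
                 vapply(datasets, `[[`, "", "dataset_id")))
  log_post <- function(par) {
    beta <- exp(par[1])
    alphas <- exp(par[-1])
    if (!is.finite(beta) || beta > 2) return(-Inf)
    lp <- stats::dnorm(beta, 0, 0.1, log = TRUE) + par[1] +
      sum(stats::dnorm(alphas, 0, 2, log = TRUE) + par[-1])
    for (k in seq_len(nd)) {
      dk <- pmax(0, alphas[k] * (1 - beta * (0:prep[[k]]$maxa)))
      lam <- cumsum(dk)[prep[[k]]$a + 1]
      ll <- sum(stats::dpois(prep[[k]]$counts, lam + 1e-12, log = TRUE))
      if (!is.finite(ll)) return(-Inf)
      lp <- lp + ll
    }
    lp
  }
  init <- function(chain) {
    c(log(0.05) + stats::rnorm(1, 0, 0.3),
      log(pmax(vapply(prep, function(p) mean(p$counts) / max(mean(p$a), 1),
                      numeric(1)), 0.05)) + stats::rnorm(nd, 0, 0.2))
  }
  fit <- run_mh(log_post, init, n_chains = n_chains, warmup = warmup,
                iter = iter, par_names = par_names, seed = seed)
  draws <- data.frame(beta = exp(fit$draws[, 1]))
  for (k in seq_len(nd)) {
    draws[[paste0("alpha_", datasets[[k]]$dataset_id)]] <- exp(fit$draws[, k + 1])
  }
  draws$cessation <- reproductive_cessation_age(draws$beta, maturity)
  structure(list(species = species, draws = draws, n_draws = nrow(draws),
                 rhat = fit$rhat, ess = fit$ess,
                 accept_rate = fit$accept_rate, converged = fit$converged,
                 maturity = maturity),
            class = "corpora_posterior")
}

#' @export
print.corpora_posterior <- function(x, ...) {
  cat("<corpora_posterior>", x$species,
      sprintf("(%d draws, converged: %s)\n", x$n_draws, x$converged))
  cat(sprintf("  beta %.4f +/- %.4f | cessation %.1f +/- %.1f yr\n",
              mean(x$draws$beta), stats::sd(x$draws$beta),
              mean(x$draws$cessation), stats::sd(x$draws$cessation)))
  invisible(x)
}

#' Reproductive cessation age from decline-rate draws
#'
#' The age at which the modelled corpora-deposition rate reaches zero:
#' `1/beta + maturity`, elementwise over posterior draws.
#'
#' @param beta_draws positive decline-rate draws.
#' @param maturity age at maturity (years).
#' @return Cessation-age draws (years).
#' @export
reproductive_cessation_age <- function(beta_draws, maturity) {
  stopifnot(all(beta_draws > 0))
  1 / beta_draws + maturity
}
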