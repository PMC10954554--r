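#' Gompertz survivorship
#'
#' Probability of surviving from `from_age` to `age` under the Gompertz hazard
#' `h(x) = alpha * exp(beta * x)` with `x` measured from `from_age`:
#' `exp(-(alpha/beta) * (exp(beta * (age - from_age)) - 1))`. At `beta = 0`
#' the exponential limit `exp(-alpha * (age - from_age))` is used.
#'
#' @param age age(s) in years, `>= from_age`. Vectorized.
#' @param params a [gompertz_params] object (or list with `alpha`, `beta`).
#' @param from_age age survivorship is measured from (typically maturity).
#' @return Survival probabilities in (0, 1]; 1 at `age == from_age`.
#' @export
gompertz_survivorship <- function(age, params, from_age = 0) {
  stopifnot(all(age >= from_age))
  x <- age - from_age
  a <- params$alpha
  b <- params$beta
  if (b == 0) exp(-a * x) else exp(-(a / b) * (exp(b * x) - 1))
}

## Row-stochastic age-estimation error kernel over integer bins.
## Row t: distribution of the rounded observation round(Normal(t, eps_t))
## with eps_t = (t + B) / 20; eps = 0 rows are identity. Mass falling outside
## the grid is clamped to the end bins.
age_error_kernel <- function(bin_ages, B) {
  n <- length(bin_ages)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    t <- bin_ages[i]
    eps <- (t + B) / 20
    if (eps <= 0) {
      K[i, i] <- 1
    } else {
      edges <- c(-Inf, bin_ages[-n] + 0.5, Inf)
      p <- diff(stats::pnorm(edges, mean = t, sd = eps))
      K[i, ] <- p / sum(p)
    }
  }
  K
}

#' Expected adult age-at-death distribution for one dataset
#'
#' Builds the per-bin multinomial probabilities for adult ages at death as the
#' normalized product of Gompertz survivorship `L`, the population-change
#' discount `R = (1 - rho)^AGE`, and the sampling-bias multiplier `S` (`s + 1`
#' inside the bias window, 1 outside), optionally convolved with a
#' row-stochastic age-estimation error kernel built from
#' `eps = (age + B) / 20`.
#'
#' @param params [gompertz_params].
#' @param maturity age at maturity (years); bins start at
#'   `ceiling(maturity)`.
#' @param omega age cap (years); bins are the 1-year intervals
#'   `[a, a+1)` for `a = ceiling(maturity), ..., omega`.
#' @param s sampling-bias strength (>= 0); ignored without a window.
#' @param rho per-year population-change discount rate (must be < 1).
#' @param bias_window optional closed age interval, in years.
#' @param B systematic ageing offset (years) for the error kernel.
#' @param use_error_kernel logical; convolve with the error kernel?
#' @return A list of class `expected_age_distribution` with `ages` (bin left
#'   edges), `theta` (probabilities, summing to 1), components `L`, `R`, `S`,
#'   and `kernel` (or `NULL`).
#' @export
expected_age_distribution <- function(params, maturity, omega, s = 0, rho = 0,
                                      bias_window = NULL, B = 0,
                                      use_error_kernel = FALSE) {
  stopifnot(omega > maturity, s >= 0)
  if (rho >= 1) stop("rho >= 1: population cannot shrink 100%/yr or more",
                     call. = FALSE)
  ages <- seq(ceiling(maturity), floor(omega))
  AGE <- ages - ages[1]
  L <- gompertz_survivorship(ages, params, from_age = ages[1])
  L <- L / sum(L)
  R <- (1 - rho)^AGE
  S <- rep(1, length(ages))
  if (!is.null(bias_window)) {
    S[ages >= bias_window[1] & ages <= bias_window[2]] <- s + 1
  }
  theta <- L * R * S
  theta <- theta / sum(theta)
  kernel <- NULL
  if (use_error_kernel) {
    kernel <- age_error_kernel(ages, B)
    theta <- as.vector(theta %*% kernel)
  }
  structure(list(ages = ages, theta = theta, L = L, R = R, S = S,
                 kernel = kernel),
            class = "expected_age_distribution")
}

## rho_d = r / (1/2 * max observed age over same-sex datasets)
growth_discount_rate <- function(r, max_obs_age) r / (0.5 * max_obs_age)

#' Ordinary maximum lifespan
#'
#' The age by which a fraction `q` (default 90%) of a cohort's adult
#' person-years have been lived, computed by trapezoidal integration of
#' adult survivorship on a 1-year grid up to the age cap.
#'
#' @param params [gompertz_params].
#' @param maturity age at maturity (years).
#' @param q fraction of adult person-years, in (0, 1).
#' @param omega age cap (years); default `max(120, 3 * maturity)` matches the
#'   cap used by the mortality fit.
#' @return Age `Z` in years (on the 1-year grid).
#' @export
ordinary_max_lifespan <- function(params, maturity, q = 0.9, omega = NULL) {
  stopifnot(q > 0, q < 1)
  if (is.null(omega)) omega <- max(120, 3 * maturity)
  x <- seq(0, ceiling(omega - maturity))
  l <- gompertz_survivorship(x, params, from_age = 0)
  # trapezoid cumulative person-years
  py <- cumsum(c(0, (l[-1] + l[-length(l)]) / 2))
  frac <- py / py[length(py)]
  maturity + x[which(frac >= q)[1]]
}

#' Survival to, and expectancy at, a given age
#'
#' `l_M` is the probability of surviving from maturity to age `M`; `e_M` is
#' the remaining life expectancy at `M`, both under the adult Gompertz model,
#' by trapezoidal quadrature on a 1-year grid.
#'
#' @param params [gompertz_params].
#' @param M age (years), `>= maturity`.
#' @param maturity age at maturity (years).
#' @param omega age cap for the quadrature.
#' @return A list with `l_M` and `e_M`.
#' @export
survival_and_expectancy_at_age <- function(params, M, maturity, omega = NULL) {
  stopifnot(M >= maturity)
  if (is.null(omega)) omega <- max(120 + maturity, 3 * maturity, M + 120)
  l_M <- gompertz_survivorship(M, params, from_age = maturity)
  x <- seq(M, ceiling(omega))
  lx <- gompertz_survivorship(x, params, from_age = maturity) / l_M
  e_M <- sum((lx[-1] + lx[-length(lx)]) / 2)
  list(l_M = l_M, e_M = e_M)
}

#' Fit the Bayesian mortality model for one species-sex
#'
#' Joint multinomial model over all age-at-death datasets of one species-sex:
#' all datasets share the Gompertz parameters, datasets from the same
#' population share a total-population-change parameter `r` (with its
#' source-derived normal prior), and each dataset with a bias window gets an
#' independent sampling-bias strength `s_d` (exponential prior). The per-year
#' discount is `rho = r / (0.5 * max observed age)`. Age-estimation error is
#' marginalized by convolving the expected age distribution with a
#' row-stochastic kernel built from `eps = (age + B) / 20`.
#'
#' Priors: `alpha ~ half-Normal(0, 0.1)`, `beta ~ half-Normal(0, 0.2)`,
#' `s_d ~ Exponential(1)`, `r ~ Normal(growth prior)`.
#'
#' @param datasets list of [age_dataset] objects, one species-sex; all must
#'   pass the lifespan inclusion filter.
#' @param maturity age at maturity for this species-sex (years).
#' @param n_chains,warmup,iter MCMC settings (default 4 chains of 3000
#'   warmup + 2500 kept draws).
#' @param use_error_kernel marginalize age-estimation error (default `TRUE`).
#' @param q person-year fraction for ordinary maximum lifespan.
#' @param seed optional integer seed.
#' @param check_filter set `FALSE` to skip the inclusion-filter precondition
#'   (e.g. for deliberately small toy fits).
#' @return An object of class `mortality_posterior`: `species`, `sex`,
#'   `draws` (data frame with `alpha`, `beta`, any `r_*` and `s_*`, and the
#'   derived ordinary maximum lifespan `Z`), `rhat`, `ess`, `converged`,
#'   `maturity`, `omega`.
#' @export
fit_mortality <- function(datasets, maturity,
                          n_chains = 4, warmup = 3000, iter = 2500,
                          use_error_kernel = TRUE, q = 0.9, seed = NULL,
                          check_filter = TRUE) {
  if (inherits(datasets, "age_dataset")) datasets <- list(datasets)
  if (length(datasets) == 0) stop("empty dataset list", call. = FALSE)
  species <- unique(vapply(datasets, `[[`, "", "species"))
  sex <- unique(vapply(datasets, `[[`, "", "sex"))
  if (length(species) != 1 || length(sex) != 1) {
    stop("fit_mortality expects datasets from a single species-sex",
         call. = FALSE)
  }
  if (check_filter) {
    flt <- apply_inclusion_filters(datasets, "lifespan", maturity = maturity)
    if (length(flt$excluded)) {
      stop("dataset(s) fail the lifespan inclusion filter: ",
           paste(unique(flt$log$dataset_id), collapse = ", "), call. = FALSE)
    }
  }
  max_obs <- max(vapply(datasets, `[[`, 0, "max_observed_age"))
  omega <- max(120, 3 * max_obs)
  ages <- seq(ceiling(maturity), omega)
  AGE <- ages - ages[1]
  nb <- length(ages)

  ## per-dataset precomputation: binned adult counts, bias mask, error kernel
  prep <- lapply(datasets, function(d) {
    bin <- floor(d$records$observed_age)
    keep <- bin >= ages[1]
    counts <- numeric(nb)
    if (any(keep)) {
      idx <- pmin(bin[keep], omega) - ages[1] + 1
      counts <- as.numeric(tapply(d$records$count[keep], factor(idx, levels = seq_len(nb)), sum))
      counts[is.na(counts)] <- 0
    }
    in_window <- if (is.null(d$bias_window)) rep(FALSE, nb) else
      ages >= d$bias_window[1] & ages <= d$bias_window[2]
    kernel <- if (use_error_kernel) age_error_kernel(ages, d$age_bias_offset) else NULL
    list(counts = counts, in_window = in_window, kernel = kernel,
         has_window = any(in_window))
  })

  pops <- vapply(datasets, `[[`, "", "population_id")
  upops <- unique(pops)
  ## one r per population; fixed at the prior mean when the prior sd is 0
  r_prior <- t(vapply(upops, function(p) {
    datasets[[which(pops == p)[1]]]$growth_prior
  }, numeric(2)))
  free_r <- r_prior[, 2] > 0
  s_sets <- which(vapply(prep, `[[`, FALSE, "has_window"))

  par_names <- c("log_alpha", "log_beta",
                 if (any(free_r)) paste0("r_", upops[free_r]),
                 if (length(s_sets)) paste0("log_s_",
                   vapply(datasets[s_sets], `[[`, "", "dataset_id")))
  npar <- length(par_names)
  idx_r <- if (any(free_r)) 2 + seq_len(sum(free_r)) else integer()
  idx_s <- if (length(s_sets)) 2 + sum(free_r) + seq_along(s_sets) else integer()

  log_post <- function(par) {
    alpha <- exp(par[1]); beta <- exp(par[2])
    if (!is.finite(alpha) || !is.finite(beta) || beta > 5) return(-Inf)
    r_all <- r_prior[, 1]
    if (any(free_r)) r_all[free_r] <- par[idx_r]
    s_all <- rep(0, length(datasets))
    if (length(s_sets)) s_all[s_sets] <- exp(par[idx_s])
    lp <- stats::dnorm(alpha, 0, 0.1, log = TRUE) + par[1] +
          stats::dnorm(beta, 0, 0.2, log = TRUE) + par[2]
    if (any(free_r)) {
      lp <- lp + sum(stats::dnorm(par[idx_r], r_prior[free_r, 1],
                                  r_prior[free_r, 2], log = TRUE))
    }
    if (length(s_sets)) {
      lp <- lp + sum(stats::dexp(exp(par[idx_s]), 1, log = TRUE) + par[idx_s])
    }
    L <- exp(-(alpha / beta) * (exp(beta * AGE) - 1))
    for (k in seq_along(datasets)) {
      rho <- growth_discount_rate(r_all[match(pops[k], upops)], max_obs)
      if (rho >= 1) return(-Inf)
      theta <- L * (1 - rho)^AGE
      if (prep[[k]]$has_window) {
        theta[prep[[k]]$in_window] <- theta[prep[[k]]$in_window] * (s_all[k] + 1)
      }
      theta <- theta / sum(theta)
      if (!is.null(prep[[k]]$kernel)) theta <- as.vector(theta %*% prep[[k]]$kernel)
      ll <- sum(prep[[k]]$counts * log(theta + 1e-300))
      if (!is.finite(ll)) return(-Inf)
      lp <- lp + ll
    }
    lp
  }

  init <- function(chain) {
    c(log(0.05) + stats::rnorm(1, 0, 0.3), log(0.1) + stats::rnorm(1, 0, 0.3),
      if (any(free_r)) stats::rnorm(sum(free_r), r_prior[free_r, 1],
                                    pmax(r_prior[free_r, 2] / 2, 1e-3)),
      if (length(s_sets)) stats::rnorm(length(s_sets), 0, 0.3))
  }
  fit <- run_mh(log_post, init, n_chains = n_chains, warmup = warmup,
                iter = iter, par_names = par_names, seed = seed)

  draws <- data.frame(alpha = exp(fit$draws[, 1]), beta = exp(fit$draws[, 2]))
  if (any(free_r)) for (j in seq_along(idx_r)) {
    draws[[paste0("r_", upops[free_r][j])]] <- fit$draws[, idx_r[j]]
  }
  if (length(s_sets)) for (j in seq_along(idx_s)) {
    draws[[sub("^log_", "", par_names[idx_s[j]])]] <- exp(fit$draws[, idx_s[j]])
  }
  draws$Z <- vapply(seq_len(nrow(draws)), function(i) {
    ordinary_max_lifespan(list(alpha = draws$alpha[i], beta = draws$beta[i]),
                          maturity, q = q, omega = omega)
  }, numeric(1))

  structure(list(species = species, sex = sex, draws = draws,
                 n_draws = nrow(draws), rhat = fit$rhat, ess = fit$ess,
                 accept_rate = fit$accept_rate, converged = fit$converged,
                 maturity = maturity, omega = omega, q = q),
            class = "mortality_posterior")
}

#' @export
print.mortality_posterior <- function(x, ...) {
  cat("<mortality_posterior>", x$species, x$sex,
      sprintf("(%d draws, converged: %s)\n", x$n_draws, x$converged))
  cat(sprintf("  alpha %.4f +/- %.4f | beta %.4f +/- %.4f | Z %.1f +/- %.1f\n",
              mean(x$draws$alpha), stats::sd(x$draws$alpha),
              mean(x$draws$beta), stats::sd(x$draws$beta),
              mean(x$draws$Z), stats::sd(x$draws$Z)))
  invisible(x)
}
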