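## Adaptive random-walk Metropolis engine used by every model fit in the
## package. Parameters are sampled on an unconstrained scale (callers apply
## log transforms and Jacobians inside their log-posterior). During warmup the
## proposal adapts a global step-size toward the optimal random-walk
## acceptance rate (~0.234) and a proposal covariance from the accumulated
## history; both are frozen after warmup so the kept draws target the exact
## posterior.

#' Sample a log-posterior with adaptive random-walk Metropolis
#'
#' @param log_post function taking a numeric parameter vector and returning
#'   the unnormalized log posterior density (`-Inf` allowed).
#' @param init numeric vector of initial values, or a function of the chain
#'   index returning one (use this to overdisperse starts).
#' @param n_chains number of independent chains.
#' @param warmup,iter warmup (adaptation) and kept iterations per chain.
#' @param init_step initial proposal standard deviation.
#' @param par_names optional parameter names for the draw matrix.
#' @param seed optional integer seed (chains are run sequentially from it).
#' @return A list of class `mh_fit` with elements `draws` (matrix,
#'   `n_chains * iter` rows), `chain` (row chain index), `rhat`, `ess`,
#'   `accept_rate` and `converged` (all split-R-hat < 1.01).
#' @export
run_mh <- function(log_post, init, n_chains = 4, warmup = 1000, iter = 1000,
                   init_step = 0.1, par_names = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  init_fun <- if (is.function(init)) init else function(chain) {
    init + stats::rnorm(length(init), 0, 0.1 * pmax(abs(init), 0.5))
  }
  d <- length(init_fun(1L))
  all_draws <- vector("list", n_chains)
  acc_total <- 0
  for (ch in seq_len(n_chains)) {
    x <- init_fun(ch)
    lp <- log_post(x)
    tries <- 0
    while (!is.finite(lp) && tries < 50) {
      x <- init_fun(ch)
      lp <- log_post(x)
      tries <- tries + 1
    }
    if (!is.finite(lp)) stop("could not find a finite starting point", call. = FALSE)
    log_scale <- log(init_step)
    L <- diag(d)
    hist_mat <- matrix(0, warmup, d)
    draws <- matrix(0, iter, d)
    n_acc <- 0
    for (t in seq_len(warmup + iter)) {
      prop <- x + exp(log_scale) * drop(L %*% stats::rnorm(d))
      lp_prop <- log_post(prop)
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
        x <- prop; lp <- lp_prop
        if (t > warmup) n_acc <- n_acc + 1
        acc <- 1
      } else acc <- 0
      if (t <= warmup) {
        hist_mat[t, ] <- x
        # Robbins-Monro step-size adaptation toward 23.4% acceptance
        log_scale <- log_scale + (acc - 0.234) / sqrt(t)
        if (t %% 100 == 0 && t >= 200) {
          S <- stats::cov(hist_mat[seq_len(t), , drop = FALSE])
          S <- S + diag(1e-8 + 1e-6 * mean(diag(S)), d)
          Lc <- tryCatch(t(chol(S)), error = function(e) NULL)
          if (!is.null(Lc)) L <- Lc
        }
      } else {
        draws[t - warmup, ] <- x
      }
    }
    all_draws[[ch]] <- draws
    acc_total <- acc_total + n_acc
  }
  draws <- do.call(rbind, all_draws)
  if (!is.null(par_names)) colnames(draws) <- par_names
  per_chain <- lapply(all_draws, identity)
  rhat <- apply_diag(per_chain, split_rhat_one)
  ess <- apply_diag(per_chain, ess_one)
  if (!is.null(par_names)) names(rhat) <- names(ess) <- par_names
  structure(list(
    draws = draws,
    chain = rep(seq_len(n_chains), each = iter),
    rhat = rhat, ess = ess,
    accept_rate = acc_total / (n_chains * iter),
    converged = all(is.finite(rhat) & rhat < 1.01)
  ), class = "mh_fit")
}

apply_diag <- function(per_chain, fn) {
  d <- ncol(per_chain[[1]])
  vapply(seq_len(d), function(j) {
    fn(lapply(per_chain, function(m) m[, j]))
  }, numeric(1))
}

## Split R-hat (Gelman et al.): each chain halved, between/within variance.
split_rhat_one <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- floor(length(x) / 2)
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(if (B <= 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## Effective sample size via initial-positive-sequence autocorrelation sums.
ess_one <- function(chains) {
  n <- length(chains[[1]])
  m <- length(chains)
  acov <- function(x) {
    x <- x - mean(x)
    stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE,
               demean = FALSE)$acf[, 1, 1]
  }
  rhos <- rowMeans(vapply(chains, acov, numeric(min(n - 1, 200) + 1)))
  # Geyer initial positive sequence on paired sums
  tau <- 1
  k <- 1
  while (k + 1 <= length(rhos)) {
    pair <- rhos[k + 1] + if (k + 2 <= length(rhos)) rhos[k + 2] else 0
    if (pair < 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  max(1, m * n / tau)
}

#' Posterior summary table for an `mh_fit`
#'
#' @param object an `mh_fit`.
#' @param probs quantiles to report.
#' @param ... unused.
#' @return A data frame with one row per parameter: mean, sd, quantiles,
#'   R-hat and effective sample size.
#' @export
summary.mh_fit <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  qs <- t(apply(object$draws, 2, stats::quantile, probs = probs))
  out <- data.frame(
    parameter = colnames(object$draws) %||% paste0("par", seq_len(ncol(object$draws))),
    mean = colMeans(object$draws),
    sd = apply(object$draws, 2, stats::sd),
    qs,
    rhat = object$rhat,
    ess = object$ess,
    row.names = NULL, check.names = FALSE)
  names(out)[4:(3 + length(probs))] <- paste0("q", probs * 100)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
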