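## Shared fixtures and independent oracles, built in code.

## The worked 3-age toy table: survivorship (1, 0.5, 0.25), reproduction at
## ages 1 and 2 only, maturity 1. Euler-Lotka gives f = 4/3.
toy_table <- function() {
  life_table(c(1, 0.5, 0.25), maturity = 1, phi = c(0, 1, 1))
}

## Individual-based forward-simulation oracle for the kinship metrics, in the
## daughter-line currency. Replicates a focal female alive at maturity;
## daughters are born Poisson(f * phi(x)) while she is alive, survive by
## binomial thinning on the life-table survival probabilities, and themselves
## bear granddaughters Poisson(f * phi(a)). Kin aging within a step mirrors
## the package recursion (kin age before the focal's newborn arrives, and
## newborn granddaughters come from already-aged daughters).
ibs_kin_oracle <- function(tab, n_rep = 1e5, seed = 1) {
  set.seed(seed)
  n <- length(tab$ages)
  mat <- round(tab$maturity)
  m <- tab$f * tab$phi
  px <- tab$px
  alive <- matrix(FALSE, n_rep, n)
  alive[, mat + 1] <- TRUE
  d <- matrix(0L, n_rep, n)
  g <- matrix(0L, n_rep, n)
  n_daughters <- matrix(NA_real_, n, 1)  # E[living daughters | focal alive]
  g0_mean <- rep(NA_real_, n)            # E[newborn grandoffspring | alive]
  g0_se <- rep(NA_real_, n)
  g_submat <- matrix(0, n_rep, n)        # per-rep sub-maturity grandoffspring
  for (x in mat:(n - 1)) {
    xi <- x + 1
    if (x > mat) {
      alive[, xi] <- alive[, xi - 1] & (stats::runif(n_rep) < px[xi - 1])
      for (a in (n - 1):1) {             # age kin, oldest first
        g[, a + 1] <- stats::rbinom(n_rep, g[, a], px[a])
        d[, a + 1] <- stats::rbinom(n_rep, d[, a], px[a])
      }
      g[, 1] <- 0L
      d[, 1] <- 0L
    }
    g[, 1] <- stats::rpois(n_rep, as.vector(d %*% m))
    d[, 1] <- d[, 1] + stats::rpois(n_rep, m[xi]) * alive[, xi]
    ok <- alive[, xi]
    n_daughters[xi] <- mean(rowSums(d[ok, , drop = FALSE]))
    g0_mean[xi] <- mean(g[ok, 1])
    g0_se[xi] <- stats::sd(g[ok, 1]) / sqrt(sum(ok))
    sub <- seq_len(max(mat, 1))
    g_submat[, xi] <- rowSums(g[, sub, drop = FALSE])
  }
  gy_rep <- rowSums(alive * g_submat)
  phi_total <- sum(tab$phi)
  remaining <- rev(cumsum(rev(tab$phi))) / phi_total
  ov_terms <- ifelse(is.na(g0_mean), 0, g0_mean) * remaining
  overlap <- sum(ov_terms)
  overlap_se <- sqrt(sum((ifelse(is.na(g0_se), 0, g0_se) * remaining)^2))
  list(daughters_by_age = as.vector(n_daughters),
       g0_by_age = g0_mean, g0_se = g0_se,
       grandmother_years = mean(gy_rep),
       grandmother_years_se = stats::sd(gy_rep) / sqrt(n_rep),
       overlap = overlap, overlap_se = overlap_se)
}

## Generalized-least-squares oracle for the phylogenetic regression with
## known covariance (no measurement error).
gls_oracle <- function(y, X, Sigma) {
  Si <- solve(Sigma)
  solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y)
}

## tiny tree fixture: ((A:1,B:1):1,C:2);
three_taxon_tree <- function(path) {
  writeLines("((A:1,B:1):1,C:2);", path)
  path
}
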