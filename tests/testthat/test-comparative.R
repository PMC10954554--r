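test_that("OU covariance kernel evaluates and validates correctly", {
  D <- matrix(c(0, 1, 1, 0), 2)
  K <- ou_covariance(D, eta = 1, rho = 1)
  expect_equal(K[1, 1], 1)
  expect_equal(K[1, 2], exp(-1))
  Kbig <- ou_covariance(matrix(c(0, 100, 100, 0), 2), 1, 1)
  expect_lt(Kbig[1, 2], 1e-40)
  expect_error(ou_covariance(matrix(c(0, 1, 2, 0), 2), 1, 1),
               "not symmetric")
  expect_error(ou_covariance(D, -1, 1))
})

test_that("pointwise leave-one-out densities match the closed form", {
  ## 3 species, fixed parameters: condition each obs on the other two
  Sigma <- ou_covariance(matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3), 1.5, 0.6)
  diag(Sigma) <- diag(Sigma) + 0.2
  y <- c(1.2, -0.3, 0.7)
  mu <- c(0.5, 0.5, 0.5)
  got <- menokin:::mvn_loo_loglik(y, mu, Sigma)
  for (i in 1:3) {
    o <- setdiff(1:3, i)
    cm <- mu[i] + Sigma[i, o] %*% solve(Sigma[o, o], y[o] - mu[o])
    cv <- Sigma[i, i] - Sigma[i, o] %*% solve(Sigma[o, o], Sigma[o, i])
    expect_equal(got[i], dnorm(y[i], drop(cm), sqrt(drop(cv)), log = TRUE),
                 tolerance = 1e-8)
  }
})

test_that("with fixed OU parameters the fit matches the GLS/OLS oracle", {
  set.seed(88)
  n <- 5
  taxa <- paste0("t", 1:n)
  tr <- ape::rphylo(n, 1, 0)
  tr$tip.label <- taxa
  ch <- chronogram(tr)
  x <- c(-1, -0.5, 0, 0.5, 1)
  M <- c(0, 0, 1, 1, 0)
  y <- 2 + 1.5 * x + 0.8 * M + rnorm(n, 0, 0.3)
  obs <- data.frame(species = taxa, mu_z = y, sigma_z = 0, mu_s = x,
                    sigma_s = 0, menopause = M)
  ## eta fixed tiny with fast decay: K ~ eta^2 I, so the GLS oracle is OLS
  fit <- fit_phylo_regression(obs, ch, n_chains = 2, warmup = 1500,
                              iter = 2500, fix_eta = 0.05, fix_rho = 5,
                              seed = 41)
  ols <- coef(lm(y ~ x + M))
  expect_lt(abs(mean(fit$draws$beta_size) - ols[["x"]]), 0.02)
  expect_lt(abs(mean(fit$draws$beta_pr) - ols[["M"]]), 0.02)
  ## GLS oracle under a non-trivial fixed kernel
  K <- ou_covariance(ch$D[taxa, taxa], 0.6, 0.4)
  y2 <- 1 + 2 * x + t(chol(K)) %*% rnorm(n)
  obs2 <- transform(obs, mu_z = as.vector(y2))
  fit2 <- fit_phylo_regression(obs2, ch, n_chains = 2, warmup = 1500,
                               iter = 2500, fix_eta = 0.6, fix_rho = 0.4,
                               seed = 43)
  X <- cbind(1, x, M)
  gls <- gls_oracle(as.vector(y2), X, K + diag(1e-9, n))
  expect_lt(abs(mean(fit2$draws$beta_size) - gls[2]), 0.05)
  expect_lt(abs(mean(fit2$draws$beta_pr) - gls[3]), 0.05)
})

test_that("menopause lifespan offset is recovered on a synthetic clade", {
  cl <- simulate_clade(clade_sim_config(n_species = 32, n_menopause = 5,
                                        offset = 40, n_trees = 3), seed = 11)
  fit <- fit_phylo_regression(cl$observations, cl$trees, n_chains = 2,
                              warmup = 600, iter = 500, seed = 5)
  expect_lt(abs(mean(fit$draws$beta_pr) - 40), 2 * sd(fit$draws$beta_pr))
  expect_lt(abs(mean(fit$draws$beta_size) - 20), 3 * sd(fit$draws$beta_size))
  expect_gt(fit$summary$p_gt0[fit$summary$parameter == "beta_pr"], 0.95)
  ## pooling keeps equal draws per tree
  expect_equal(length(unique(table(fit$draws$tree))), 1)
})

test_that("phylo regression validates its inputs", {
  cl <- simulate_clade(clade_sim_config(n_species = 5, n_menopause = 1,
                                        n_trees = 1), seed = 2)
  obs <- cl$observations
  expect_error(fit_phylo_regression(obs[, -2], cl$trees), "mu_z")
  expect_error(fit_phylo_regression(obs[1:2, ], cl$trees), ">= 3")
  obs_bad <- obs
  obs_bad$species[1] <- "not_on_tree"
  expect_error(fit_phylo_regression(obs_bad, cl$trees), "missing taxa")
})

test_that("elpd comparison favours the menopause model when it should", {
  cl <- simulate_clade(clade_sim_config(n_species = 24, n_menopause = 5,
                                        offset = 40, n_trees = 1), seed = 31)
  f_with <- fit_phylo_regression(cl$observations, cl$trees, n_chains = 2,
                                 warmup = 500, iter = 400, seed = 8)
  obs0 <- transform(cl$observations, menopause = 0)
  f_without <- fit_phylo_regression(obs0, cl$trees, n_chains = 2,
                                    warmup = 500, iter = 400, seed = 8)
  ## self-comparison is exactly zero
  self <- compare_elpd(f_with, f_with)
  expect_identical(self$elpd_diff, 0)
  cmp <- compare_elpd(f_with, f_without)
  expect_lt(cmp$elpd_diff, -2 * cmp$se)
  f_sub <- fit_phylo_regression(cl$observations[1:10, ], cl$trees,
                                n_chains = 2, warmup = 300, iter = 200,
                                seed = 9)
  expect_error(compare_elpd(f_with, f_sub), "different species")
})

test_that("lifespan-ratio model behaves at the null and recovers effects", {
  set.seed(55)
  n <- 30
  M <- rep(c(1, 0), c(5, 25))
  ## null: identical male and female lifespans
  obs_null <- data.frame(species = paste0("s", 1:n),
                         female_mean = 40 + rnorm(n, 0, 0.1),
                         female_sd = 1, male_mean = 40, male_sd = 1,
                         menopause = M)
  obs_null$male_mean <- obs_null$female_mean
  f0 <- fit_lifespan_ratio(obs_null, n_chains = 2, warmup = 600, iter = 600,
                           seed = 3)
  s0 <- f0$summary[f0$summary$parameter == "beta_pr", ]
  expect_lt(s0$lo, 0)
  expect_gt(s0$hi, 0)
  expect_lt(abs(mean(f0$draws$alpha)), 0.05)
  ## males 20% shorter-lived only in menopause species
  obs_eff <- obs_null
  obs_eff$male_mean <- obs_eff$female_mean * ifelse(M == 1, 0.8, 1)
  f1 <- fit_lifespan_ratio(obs_eff, n_chains = 2, warmup = 600, iter = 600,
                           seed = 4)
  expect_gt(mean(f1$draws$beta_pr > 0), 0.95)
  expect_lt(abs(mean(f1$draws$beta_pr) - log(1 / 0.8)),
            3 * sd(f1$draws$beta_pr))
  ## degenerate measurement error: matches the point-value regression
  obs_pt <- transform(obs_eff, female_sd = 0, male_sd = 0)
  f2 <- fit_lifespan_ratio(obs_pt, n_chains = 2, warmup = 600, iter = 600,
                           seed = 5)
  lm_fit <- lm(log(female_mean / male_mean) ~ menopause, data = obs_pt)
  expect_lt(abs(mean(f2$draws$beta_pr) - coef(lm_fit)[["menopause"]]), 0.02)
  expect_error(fit_lifespan_ratio(transform(obs_eff, male_mean = -1)),
               "non-positive")
})

test_that("menopause contrast reduces to the regression on point masses", {
  cl <- simulate_clade(clade_sim_config(n_species = 10, n_menopause = 3,
                                        n_trees = 1), seed = 21)
  flags <- setNames(cl$observations$menopause, cl$observations$species)
  vals <- setNames(rnorm(10, 1 + 0.5 * flags, 0.1), names(flags))
  md <- lapply(vals, function(v) v)   # point masses
  c1 <- menopause_contrast(md, flags, cl$trees, n_chains = 2, warmup = 400,
                           iter = 300, seed = 6)
  obs <- data.frame(species = names(flags), mu_z = unname(vals), sigma_z = 0,
                    menopause = as.integer(flags))
  c2 <- fit_phylo_regression(obs, cl$trees, include_size = FALSE,
                             n_chains = 2, warmup = 400, iter = 300,
                             seed = 6)
  expect_equal(c1$draws$beta_pr, c2$draws$beta_pr)
  expect_error(menopause_contrast(md[-1], flags, cl$trees), "missing for")
})

test_that("metric shift between menopause classes is detected", {
  cl <- simulate_clade(clade_sim_config(n_species = 16, n_menopause = 4,
                                        n_trees = 2), seed = 13)
  flags <- setNames(cl$observations$menopause, cl$observations$species)
  set.seed(9)
  md <- lapply(seq_along(flags),
               function(i) rnorm(300, 1 + 0.7 * flags[i], 0.2))
  names(md) <- names(flags)
  fit <- menopause_contrast(md, flags, cl$trees, n_chains = 2, warmup = 500,
                            iter = 400, seed = 7)
  expect_gt(mean(fit$draws$beta_pr > 0), 0.95)
  expect_lt(abs(mean(fit$draws$beta_pr) - 0.7), 3 * sd(fit$draws$beta_pr))
  ## shared distribution: contrast centred on zero
  md0 <- lapply(seq_along(flags), function(i) rnorm(300, 1, 0.2))
  names(md0) <- names(flags)
  fit0 <- menopause_contrast(md0, flags, cl$trees, n_chains = 2,
                             warmup = 500, iter = 400, seed = 8)
  s <- fit0$summary[fit0$summary$parameter == "beta_pr", ]
  expect_lt(s$lo, 0)
  expect_gt(s$hi, 0)
})
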