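test_that("Gompertz survivorship matches its closed form and limits", {
  p <- gompertz_params(0.05, 0.1)
  expect_equal(gompertz_survivorship(10, p, from_age = 10), 1)
  expect_equal(gompertz_survivorship(20, p, from_age = 10),
               exp(-0.5 * (exp(1) - 1)), tolerance = 1e-12)
  ## beta = 0 exponential limit
  expect_equal(gompertz_survivorship(10, gompertz_params(0.1, 0)),
               exp(-1), tolerance = 1e-12)
  ## non-increasing in age
  ages <- seq(10, 60, 0.5)
  expect_true(all(diff(gompertz_survivorship(ages, p, 10)) <= 0))
})

test_that("expected age distribution reproduces hand-normalized products", {
  ## survivorship (1, 0.5, 0.25) over 3 bins via alpha = log 2, beta = 0
  p <- gompertz_params(log(2), 0)
  ed <- expected_age_distribution(p, maturity = 0, omega = 2)
  expect_equal(ed$theta, c(4, 2, 1) / 7, tolerance = 1e-12)
  ## bias window on the oldest bin with s = 1 -> S = (1, 1, 2)
  ed2 <- expected_age_distribution(p, maturity = 0, omega = 2, s = 1,
                                   bias_window = c(2, 2))
  expect_equal(ed2$theta, c(0.5, 0.25, 0.25), tolerance = 1e-12)
  ## growth discount rho = 0.5 -> theta proportional to (1, 0.25, 0.0625)
  ed3 <- expected_age_distribution(p, maturity = 0, omega = 2, rho = 0.5)
  expect_equal(ed3$theta, c(1, 0.25, 0.0625) / 1.3125, tolerance = 1e-12)
  expect_error(expected_age_distribution(p, 0, 2, rho = 1), "rho")
})

test_that("theta normalizes and the error kernel is row-stochastic", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- gompertz_params(runif(1, 0.01, 0.2), runif(1, 0.01, 0.3))
    ed <- expected_age_distribution(p, maturity = 8, omega = 90,
                                    s = runif(1, 0, 2),
                                    rho = runif(1, 0, 0.02),
                                    bias_window = c(20, 40), B = 2,
                                    use_error_kernel = TRUE)
    expect_equal(sum(ed$theta), 1, tolerance = 1e-10)
    expect_true(all(abs(rowSums(ed$kernel) - 1) < 1e-10))
    expect_true(all(diff(ed$L) <= 1e-15))
  }
})

test_that("ordinary maximum lifespan matches closed-form and oracle", {
  ## exponential limit: 90% of person-years by maturity + ln(10)/alpha
  z <- ordinary_max_lifespan(gompertz_params(0.1, 0), maturity = 10)
  expect_lt(abs(z - (10 + log(10) / 0.1)), 1.01)
  ## monotone in q
  expect_gt(ordinary_max_lifespan(gompertz_params(0.1, 0), 10, q = 0.99), z)
  ## fine-grid trapezoid oracle for a Gompertz case
  p <- list(alpha = 0.02, beta = 0.15)
  x <- seq(0, 110, 0.01)
  l <- gompertz_survivorship(x, p)
  cum <- cumsum(c(0, (l[-1] + l[-length(l)]) / 2)) * 0.01
  z_oracle <- 10 + x[which(cum / max(cum) >= 0.9)[1]]
  expect_lt(abs(ordinary_max_lifespan(p, 10) - z_oracle), 1.01)
  ## invariant to rescaling counts: Z depends only on parameters
  expect_identical(ordinary_max_lifespan(p, 10), ordinary_max_lifespan(p, 10))
})

test_that("survival and expectancy at age follow hazard structure", {
  ## memoryless constant hazard: e_M = 1/alpha at any M
  p0 <- gompertz_params(0.1, 0)
  e1 <- survival_and_expectancy_at_age(p0, 30, 10)
  e2 <- survival_and_expectancy_at_age(p0, 50, 10)
  expect_lt(abs(e1$e_M - 10), 0.5)
  expect_lt(abs(e2$e_M - 10), 0.5)
  expect_equal(survival_and_expectancy_at_age(p0, 10, 10)$l_M, 1)
  ## increasing hazard: expectancy strictly decreasing in M
  p <- gompertz_params(0.02, 0.12)
  es <- vapply(c(15, 25, 35, 45),
               function(M) survival_and_expectancy_at_age(p, M, 10)$e_M,
               numeric(1))
  expect_true(all(diff(es) < 0))
})

test_that("mortality model recovers truth on clean synthetic data", {
  sim <- simulate_age_dataset(age_sim_config(n = 1000, alpha = 0.05,
                                             beta = 0.1, maturity = 10),
                              seed = 42)
  fit <- fit_mortality(list(sim$dataset), maturity = 10, n_chains = 2,
                       warmup = 600, iter = 600, seed = 7,
                       use_error_kernel = FALSE)
  expect_lt(abs(mean(fit$draws$alpha) - 0.05), 3 * sd(fit$draws$alpha))
  expect_lt(abs(mean(fit$draws$beta) - 0.1), 3 * sd(fit$draws$beta))
  expect_equal(fit$n_draws, nrow(fit$draws))
  expect_true(all(fit$draws$Z > 10))
})

test_that("two identical datasets pool to the same posterior as one", {
  sim <- simulate_age_dataset(age_sim_config(n = 800, alpha = 0.05,
                                             beta = 0.1, maturity = 10),
                              seed = 13)
  d <- sim$dataset
  d2 <- d
  d2$dataset_id <- "copy"
  fit1 <- fit_mortality(list(d), maturity = 10, n_chains = 2, warmup = 600,
                        iter = 600, seed = 5, use_error_kernel = FALSE)
  ## doubled data: same theta, so (alpha, beta) posteriors tighten but stay
  ## centred; 95% intervals must overlap substantially
  fit2 <- fit_mortality(list(d, d2), maturity = 10, n_chains = 2,
                        warmup = 600, iter = 600, seed = 5,
                        use_error_kernel = FALSE)
  for (par in c("alpha", "beta")) {
    q1 <- quantile(fit1$draws[[par]], c(0.025, 0.975))
    q2 <- quantile(fit2$draws[[par]], c(0.025, 0.975))
    expect_lt(q2[1], q1[2])
    expect_lt(q1[1], q2[2])
    expect_lt(abs(mean(fit1$draws[[par]]) - mean(fit2$draws[[par]])),
              2 * sd(fit1$draws[[par]]))
  }
})

test_that("error kernel on error-free data barely moves the posterior", {
  sim <- simulate_age_dataset(age_sim_config(n = 1000, alpha = 0.05,
                                             beta = 0.1, maturity = 10),
                              seed = 21)
  f_plain <- fit_mortality(list(sim$dataset), maturity = 10, n_chains = 2,
                           warmup = 600, iter = 600, seed = 3,
                           use_error_kernel = FALSE)
  f_kern <- fit_mortality(list(sim$dataset), maturity = 10, n_chains = 2,
                          warmup = 600, iter = 600, seed = 3,
                          use_error_kernel = TRUE)
  for (par in c("alpha", "beta")) {
    expect_lt(abs(mean(f_plain$draws[[par]]) - mean(f_kern$draws[[par]])),
              sd(f_plain$draws[[par]]))
  }
})

test_that("mortality fit enforces its preconditions", {
  expect_error(fit_mortality(list(), maturity = 10), "empty")
  small <- age_dataset("tiny", "sp", "female", "p", ages = c(11, 12),
                       counts = c(3, 2))
  expect_error(fit_mortality(list(small), maturity = 10), "inclusion filter")
  f <- age_dataset("f", "sp", "female", "p", ages = 11:40, counts = rep(2, 30))
  m <- age_dataset("m", "sp", "male", "p", ages = 11:40, counts = rep(2, 30))
  expect_error(fit_mortality(list(f, m), maturity = 10), "single species-sex")
})

test_that("bathtub model recovers known juvenile survival", {
  juv <- list(a1 = 0.16, b1 = 1, a2 = 0.005)
  cfg <- age_sim_config(n = 1500, alpha = 0.02, beta = 0.08, maturity = 10,
                        juvenile = juv)
  sim <- simulate_age_dataset(cfg, seed = 17)
  truth <- sim$truth$survival_to_maturity
  fit <- fit_juvenile_survival(sim$dataset, maturity = 10, n_chains = 2,
                               warmup = 700, iter = 700, seed = 9)
  est <- mean(fit$draws$surv_maturity)
  expect_lt(abs(est - truth), 3 * sd(fit$draws$surv_maturity))
  expect_true(all(fit$draws$surv_maturity > 0 & fit$draws$surv_maturity <= 1))
})

test_that("zero juvenile hazard collapses to the Gompertz-only prediction", {
  cfg <- age_sim_config(n = 1500, alpha = 0.04, beta = 0.09, maturity = 10,
                        juvenile = list(a1 = 0, b1 = 1, a2 = 0))
  sim <- simulate_age_dataset(cfg, seed = 23)
  fit <- fit_juvenile_survival(sim$dataset, maturity = 10, n_chains = 2,
                               warmup = 700, iter = 700, seed = 11)
  ## per-draw Gompertz-only survival to maturity from the senescent component
  g_only <- gompertz_survivorship(10, list(alpha = mean(fit$draws$alpha),
                                           beta = mean(fit$draws$beta)))
  expect_lt(abs(mean(fit$draws$surv_maturity) - g_only), 0.15)
  expect_gt(mean(fit$draws$surv_maturity), 0.5)
})

test_that("maturity regression imputes survival within the training range", {
  set.seed(31)
  mats <- c(6, 8, 10, 12, 14, 16)
  surv_draws <- lapply(mats, function(m) {
    plogis(rnorm(400, 2 - 0.15 * m, 0.15))
  })
  reg <- juvenile_survival_regression(surv_draws, mats, n_chains = 2,
                                      warmup = 600, iter = 600, seed = 2)
  ## negative correlation between maturity and survival is recovered
  expect_gt(mean(reg$draws$slope < 0), 0.95)
  pred <- predict_survival_to_maturity(reg, mean(mats), n_draws = 2000)
  rng <- range(plogis(2 - 0.15 * mats))
  expect_gt(mean(pred), rng[1] - 0.1)
  expect_lt(mean(pred), rng[2] + 0.1)
  expect_error(juvenile_survival_regression(surv_draws[1:4], mats[1:4]),
               ">= 5 species")
})
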