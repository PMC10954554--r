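test_that("Euler-Lotka baseline fecundity is exact on the toy table", {
  tab <- toy_table()
  expect_equal(tab$f, 4 / 3, tolerance = 1e-12)
  ## single reproductive age with full survival forces f = 1
  tab1 <- life_table(c(1, 1), maturity = 0, phi = c(0, 1))
  expect_equal(tab1$f, 1, tolerance = 1e-12)
  expect_error(solve_baseline_fecundity(c(1, 0.5), c(0, 0)),
               "no reproductive age")
})

test_that("the assembled Leslie matrix is stationary", {
  for (tab in list(toy_table(),
                   life_table_from_draws(0.05, 0.1, 10, 0.6, 0.03))) {
    A <- leslie_matrix(tab)
    lambda <- max(abs(eigen(A, only.values = TRUE)$values))
    expect_equal(lambda, 1, tolerance = 1e-6)
  }
})

test_that("kin recursion reproduces the hand-computed toy values", {
  tab <- toy_table()
  traj <- kin_expectations(tab, currency = "daughters")
  ## focal age 2: expected living daughters 2/3 + 4/3 = 2
  expect_equal(sum(traj$offspring[3, ]), 2, tolerance = 1e-12)
  ## focal age 2: newborn granddaughters (4/3 * 1/2) * 4/3 = 8/9
  expect_equal(traj$grandoffspring[3, 1], 8 / 9, tolerance = 1e-12)
  met <- kinship_metrics(traj, tab)
  expect_equal(met$grandmother_years, 4 / 9, tolerance = 1e-12)
  expect_equal(met$relative_grandmother_years, 4 / 9, tolerance = 1e-12)
  expect_equal(met$reproductive_overlap, 4 / 9, tolerance = 1e-12)
  ## both-sex currency doubles the counts
  both <- kin_expectations(tab, currency = "both")
  expect_equal(sum(both$offspring[3, ]), 4, tolerance = 1e-12)
})

test_that("kin recursion agrees with the individual-based oracle", {
  tab <- toy_table()
  orc <- ibs_kin_oracle(tab, n_rep = 1e5, seed = 77)
  traj <- kin_expectations(tab, currency = "daughters")
  met <- kinship_metrics(traj, tab)
  n_eff <- 1e5
  expect_lt(abs(orc$daughters_by_age[3] - 2),
            3 * sqrt(2 / (n_eff / 2)))       # Poisson-scale se, alive ~ half
  expect_lt(abs(met$grandmother_years - orc$grandmother_years),
            3 * orc$grandmother_years_se)
  expect_lt(abs(met$reproductive_overlap - orc$overlap),
            3 * orc$overlap_se)
  expect_lt(abs(traj$grandoffspring[3, 1] - orc$g0_by_age[3]),
            3 * orc$g0_se[3])
})

test_that("degenerate schedules give forced kinship values", {
  ## no reproduction at all: all kin expectations are zero
  tab0 <- life_table(c(1, 0.5, 0.25), maturity = 1, phi = c(0, 0, 0), f = 1)
  traj0 <- kin_expectations(tab0)
  expect_true(all(traj0$offspring == 0))
  expect_true(all(traj0$grandoffspring == 0))
  ## reproduction confined to one age: grandoffspring arrive only when the
  ## focal's remaining reproductive capacity is zero, so overlap = 0
  tab1 <- life_table(c(1, 0.8, 0.6, 0.4), maturity = 1,
                     phi = c(0, 1, 0, 0))
  met1 <- kinship_metrics(kin_expectations(tab1, "daughters"), tab1)
  expect_equal(met1$reproductive_overlap, 0, tolerance = 1e-12)
})

test_that("longer life helps grandmothers; higher survival lowers fecundity", {
  base <- life_table_from_draws(0.05, 0.12, 10, 0.6, 0.04, omega = 100)
  longer <- life_table_from_draws(0.05, 0.06, 10, 0.6, 0.04, omega = 100)
  m_base <- kinship_metrics(kin_expectations(base), base)
  m_long <- kinship_metrics(kin_expectations(longer), longer)
  expect_gte(m_long$grandmother_years, m_base$grandmother_years)
  ## stationarity trade-off: better survival needs lower baseline fecundity
  expect_lt(longer$f, base$f)
})

test_that("posterior propagation yields one metric row per draw", {
  sim <- simulate_age_dataset(age_sim_config(n = 800, alpha = 0.05,
                                             beta = 0.1, maturity = 10),
                              seed = 19)
  fit <- fit_mortality(list(sim$dataset), maturity = 10, n_chains = 2,
                       warmup = 400, iter = 400, seed = 2,
                       use_error_kernel = FALSE)
  kd <- kinship_draws(fit, surv_maturity_draws = rbeta(200, 6, 4),
                      beta_corpora_draws = 1 / runif(200, 15, 30),
                      n_draws = 50, seed = 3)
  expect_equal(nrow(kd), 50)
  expect_true(all(kd$GY >= 0))
  expect_true(all(kd$f > 0))
  expect_equal(kd$relGY, kd$GY / 10)
})
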