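## Synthetic-data generators. These emulate the statistical structure the
## analysis assumes -- Gompertz deaths distorted by population growth, windowed
## sampling bias and rounding/ageing error; Poisson corpora accumulation with
## a linearly declining deposition rate; allometric lifespan-length scaling
## with a menopause lifespan offset evolving on a chronogram -- so that every
## downstream stage can be exercised and scored against known truth.

#' Configuration for simulating an age-at-death dataset
#'
#' @param n sample size (> 0).
#' @param alpha,beta true Gompertz parameters (adult hazard).
#' @param maturity age at maturity (years).
#' @param r_true true total population change (feeds the per-year discount
#'   `rho = r / (0.5 * max observed age)`).
#' @param bias_window optional closed age interval of over-sampling.
#' @param bias_strength bias multiplier `s >= 0` (sampling inside the window
#'   is inflated by `s + 1`).
#' @param age_error logical; apply rounding/ageing error
#'   (`obs = round(Normal(true, (true + B) / 20))`)?
#' @param B systematic ageing offset (years).
#' @param juvenile optional list `(a1, b1, a2)` adding a bathtub juvenile
#'   hazard component so the sample spans ages from birth.
#' @param dataset_id,species,sex,population_id identifiers for the generated
#'   dataset.
#' @param growth_prior prior to attach to the generated dataset metadata.
#' @return A list of class `age_sim_config`.
#' @export
age_sim_config <- function(n = 1000, alpha = 0.05, beta = 0.1, maturity = 10,
                           r_true = 0, bias_window = NULL, bias_strength = 0,
                           age_error = FALSE, B = 0, juvenile = NULL,
                           dataset_id = "sim1", species = "sim_species",
                           sex = "female", population_id = "pop1",
                           growth_prior = c(0, 0.05)) {
  stopifnot(n > 0, bias_strength >= 0, alpha > 0, beta >= 0)
  structure(as.list(environment()), class = "age_sim_config")
}

## Survivorship from birth under bathtub (Siler) + Gompertz hazard; closed
## form of the integrated hazard. Adult-only configs have a1 = a2 = 0 and
## measure age from maturity.
siler_survivorship <- function(x, a1, b1, a2, alpha, beta) {
  n <- max(length(x), length(a1), length(b1), length(a2), length(alpha),
           length(beta))
  x <- rep_len(x, n); a1 <- rep_len(a1, n); b1 <- rep_len(b1, n)
  a2 <- rep_len(a2, n); alpha <- rep_len(alpha, n); beta <- rep_len(beta, n)
  juv <- ifelse(b1 > 0, (a1 / pmax(b1, 1e-300)) * (1 - exp(-b1 * x)), a1 * x)
  sen <- ifelse(beta > 0, (alpha / pmax(beta, 1e-300)) * (exp(beta * x) - 1),
                alpha * x)
  exp(-(juv + a2 * x + sen))
}

#' Simulate an age-at-death dataset
#'
#' Draws binned ages from the expected age distribution
#' `theta \%prop\% L * R * S` implied by the configuration (`L` survivorship,
#' `R = (1 - rho)^AGE` growth discount, `S = s + 1` inside the bias window),
#' then applies rounding/ageing error when enabled. The discount rate uses the
#' same `rho = r / (0.5 * max observed age)` transform as the fit, with the
#' expected maximum observed age (survivorship quantile `1/n`) standing in
#' for the realized one.
#'
#' @param cfg an [age_sim_config].
#' @param seed optional integer seed; the generator is deterministic given
#'   `(cfg, seed)`.
#' @return A list with `dataset` (an [age_dataset]) and `truth` (the
#'   generating parameters, including the realized `rho`).
#' @export
simulate_age_dataset <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "age_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  if (cfg$beta < 0) stop("beta < 0 implies non-finite normalization", call. = FALSE)
  juv <- !is.null(cfg$juvenile)
  from <- if (juv) 0 else ceiling(cfg$maturity)
  omega <- max(120, ceiling(cfg$maturity) + 110)
  ages <- seq(from, omega)
  if (juv) {
    j <- cfg$juvenile
    L <- siler_survivorship(ages, j$a1, j$b1, j$a2, cfg$alpha, cfg$beta)
  } else {
    L <- gompertz_survivorship(ages, cfg, from_age = from)
  }
  # expected maximum observed age: survivorship quantile 1/n past the grid min
  exp_max <- ages[max(which(L / L[1] >= 1 / cfg$n))]
  rho <- if (cfg$r_true == 0) 0 else growth_discount_rate(cfg$r_true, exp_max)
  if (rho >= 1) stop("r_true implies rho >= 1", call. = FALSE)
  AGE <- ages - ages[1]
  theta <- L * (1 - rho)^AGE
  if (!is.null(cfg$bias_window)) {
    w <- ages >= cfg$bias_window[1] & ages <= cfg$bias_window[2]
    theta[w] <- theta[w] * (cfg$bias_strength + 1)
  }
  theta <- theta / sum(theta)
  true_age <- sample(ages, cfg$n, replace = TRUE, prob = theta)
  obs_age <- if (cfg$age_error) {
    eps <- (true_age + cfg$B) / 20
    pmin(pmax(round(stats::rnorm(cfg$n, true_age, eps)), from), omega)
  } else true_age
  tab <- table(obs_age)
  ## the stored window must lie within the realized observed ages
  bw <- cfg$bias_window
  if (!is.null(bw)) {
    bw[2] <- min(bw[2], max(obs_age))
    if (bw[1] > bw[2]) bw <- NULL
  }
  ds <- age_dataset(
    dataset_id = cfg$dataset_id, species = cfg$species, sex = cfg$sex,
    population_id = cfg$population_id,
    ages = as.numeric(names(tab)), counts = as.integer(tab),
    growth_prior = cfg$growth_prior,
    bias_window = bw,
    age_bias_offset = cfg$B,
    source_type = "synthetic")
  list(dataset = ds,
       truth = list(alpha = cfg$alpha, beta = cfg$beta, r = cfg$r_true,
                    rho = rho, s = cfg$bias_strength, maturity = cfg$maturity,
                    juvenile = cfg$juvenile,
                    survival_to_maturity = if (juv)
                      siler_survivorship(cfg$maturity, j$a1, j$b1, j$a2,
                                         cfg$alpha, cfg$beta) else NA))
}

#' Configuration for simulating an ovarian corpora dataset
#'
#' @param n number of sampled females.
#' @param alpha initial corpora deposition rate (corpora/yr, > 0).
#' @param beta linear decline rate of deposition with adult age (1/yr, > 0).
#' @param maturity age at maturity (years).
#' @param mort_alpha,mort_beta Gompertz parameters used to sample the ages of
#'   the dead females.
#' @param dataset_id,species identifiers.
#' @return A list of class `corpora_sim_config`.
#' @export
corpora_sim_config <- function(n = 200, alpha = 1.2, beta = 0.04,
                               maturity = 10, mort_alpha = 0.05,
                               mort_beta = 0.1, dataset_id = "csim1",
                               species = "sim_species") {
  stopifnot(alpha > 0, beta > 0, n > 0)
  structure(as.list(environment()), class = "corpora_sim_config")
}

#' Simulate an ovarian corpora dataset
#'
#' Ages are drawn from the adult mortality model; each female's corpora count
#' is Poisson with mean equal to the cumulative deposition
#' `sum_j max(0, alpha * (1 - beta * AGE_j))` over her adult years.
#'
#' @param cfg a [corpora_sim_config].
#' @param seed optional integer seed.
#' @return A list with `dataset` (a [corpora_dataset]) and `truth`.
#' @export
simulate_corpora_dataset <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "corpora_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  from <- ceiling(cfg$maturity)
  omega <- max(120, from + 110)
  ages <- seq(from, omega)
  L <- gompertz_survivorship(ages, list(alpha = cfg$mort_alpha,
                                        beta = cfg$mort_beta), from_age = from)
  age <- sample(ages, cfg$n, replace = TRUE, prob = L / sum(L))
  lam <- expected_corpora(age - cfg$maturity,
                          list(alpha = cfg$alpha, beta = cfg$beta))
  counts <- stats::rpois(cfg$n, lam)
  ds <- corpora_dataset(cfg$dataset_id, cfg$species, ages = age,
                        corpora = counts, age_at_maturity = cfg$maturity,
                        max_lifespan_age = max(age))
  list(dataset = ds,
       truth = list(alpha = cfg$alpha, beta = cfg$beta,
                    cessation = 1 / cfg$beta + cfg$maturity,
                    maturity = cfg$maturity))
}

#' Configuration for simulating a clade
#'
#' Defaults mirror the scale of the comparative analysis: 32 species of which
#' 5 have menopause, a ~40-year menopause lifespan offset on an allometric
#' lifespan-length scaling, and phylogenetically correlated residuals from an
#' Ornstein-Uhlenbeck kernel on a pure-birth chronogram.
#'
#' @param n_species number of species (>= 3).
#' @param n_menopause number of menopausal species (`<= n_species`).
#' @param birth_rate speciation rate of the pure-birth chronogram.
#' @param n_trees number of chronograms to generate (a bootstrap-like set of
#'   independent pure-birth trees over the same taxa; truth is generated on
#'   the first).
#' @param intercept,slope allometry of ordinary maximum lifespan (years) on
#'   log length (cm).
#' @param offset menopause lifespan offset (years) added to menopausal
#'   species' lifespans; reproductive lifespans never receive it.
#' @param loglen_mean,loglen_sd distribution of species log lengths.
#' @param ou_eta,ou_rho OU amplitude (years) and decay rate of the
#'   phylogenetic residual covariance `eta^2 * exp(-rho^2 * D)`.
#' @param obs_sd measurement s.d. attached to each species' lifespan (years).
#' @param sigma_s measurement s.d. attached to log length.
#' @param maturity_frac age at maturity as a fraction of the allometric
#'   lifespan prediction (life-history timescales covary: porpoises mature
#'   around 4 years, sperm whales past 9).
#' @param maturity_sd additive noise (years) on the age at maturity.
#' @return A list of class `clade_sim_config`.
#' @export
clade_sim_config <- function(n_species = 32, n_menopause = 5, birth_rate = 1,
                             n_trees = 10, intercept = -80, slope = 20,
                             offset = 40, loglen_mean = 6, loglen_sd = 0.5,
                             ou_eta = 3, ou_rho = 0.5, obs_sd = 2,
                             sigma_s = 0.05, maturity_frac = 0.25,
                             maturity_sd = 1) {
  if (n_species < 3) stop("n_species < 3: regression unidentifiable", call. = FALSE)
  stopifnot(n_menopause <= n_species)
  structure(as.list(environment()), class = "clade_sim_config")
}

#' Simulate a clade: chronograms, traits and true comparative parameters
#'
#' Species lifespans are the allometric prediction plus the menopause offset
#' plus OU-correlated noise on the first chronogram; reproductive lifespans
#' follow the same allometry with independent noise and no menopause offset
#' (menopausal species live longer, not reproduce shorter).
#'
#' @param cfg a [clade_sim_config].
#' @param seed optional integer seed.
#' @return A list with `trees` (list of [chronogram]), `traits` (list of
#'   [species_traits]), `observations` (data frame ready for
#'   [fit_phylo_regression()]: `species, mu_z, sigma_z, mu_s, sigma_s,
#'   menopause`), `repro_observations` (same, response = reproductive
#'   lifespan) and `truth`.
#' @export
simulate_clade <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "clade_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  taxa <- sprintf("sp%02d", seq_len(cfg$n_species))
  trees <- lapply(seq_len(cfg$n_trees), function(i) {
    tr <- ape::rphylo(cfg$n_species, birth = cfg$birth_rate, death = 0)
    tr$tip.label <- taxa
    chronogram(tr, i)
  })
  D <- trees[[1]]$D[taxa, taxa]
  K <- ou_covariance(D, cfg$ou_eta, cfg$ou_rho)
  loglen <- stats::rnorm(cfg$n_species, cfg$loglen_mean, cfg$loglen_sd)
  M <- as.integer(seq_len(cfg$n_species) %in%
                    sample.int(cfg$n_species, cfg$n_menopause))
  phylo_noise <- drop(t(chol(K + diag(1e-8, cfg$n_species))) %*%
                        stats::rnorm(cfg$n_species))
  z_true <- cfg$intercept + cfg$slope * loglen + cfg$offset * M + phylo_noise
  z_true <- pmax(z_true, 5)
  repro_noise <- drop(t(chol(K + diag(1e-8, cfg$n_species))) %*%
                        stats::rnorm(cfg$n_species))
  repro_true <- pmax(cfg$intercept + cfg$slope * loglen + repro_noise, 3)
  mu_z <- z_true + stats::rnorm(cfg$n_species, 0, cfg$obs_sd)
  mu_s <- loglen + stats::rnorm(cfg$n_species, 0, cfg$sigma_s)
  mu_r <- repro_true + stats::rnorm(cfg$n_species, 0, cfg$obs_sd)
  ## maturity tracks the (non-menopause) allometric lifespan, so life
  ## histories time-rescale across body sizes
  allometric_z <- pmax(cfg$intercept + cfg$slope * loglen, 5)
  maturity <- pmax(cfg$maturity_frac * allometric_z +
                     stats::rnorm(cfg$n_species, 0, cfg$maturity_sd), 2)
  traits <- lapply(seq_len(cfg$n_species), function(i) {
    species_traits(taxa[i], "female",
                   length_mean = exp(mu_s[i]),
                   length_sd = exp(mu_s[i]) * cfg$sigma_s,
                   maturity_mean = maturity[i], maturity_sd = 0.5,
                   menopause = M[i])
  })
  obs <- data.frame(species = taxa, mu_z = mu_z, sigma_z = cfg$obs_sd,
                    mu_s = mu_s, sigma_s = cfg$sigma_s, menopause = M)
  robs <- transform(obs, mu_z = mu_r)
  list(trees = trees, traits = traits, observations = obs,
       repro_observations = robs,
       truth = list(intercept = cfg$intercept, slope = cfg$slope,
                    offset = cfg$offset, menopause = M, loglen = loglen,
                    z_true = z_true, repro_true = repro_true,
                    maturity = maturity))
}
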