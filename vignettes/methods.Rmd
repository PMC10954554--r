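---
title: "Models and methods behind menokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind menokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`menokin` studies how menopause — a prolonged female postreproductive
lifespan — evolves in toothed whales, by chaining four Bayesian models into
a kinship-demography and comparative pipeline. This vignette explains each
model, its assumptions, the tunable parameters, the numerical choices, and
what the synthetic-data generators do and do not emulate.

## Adult mortality from ages at death

Published odontocete age data are overwhelmingly dead-recovery samples
(bycatch, strandings), so the model treats the binned ages at death in
dataset $d$ as multinomial with

$$\theta_{d,i} \propto L_i \, R_{d,i} \, S_{d,i},$$

where $L_i$ is Gompertz adult survivorship
$\exp\{-(\alpha/\beta)(e^{\beta\,\mathrm{AGE}_i}-1)\}$ normalized over the
adult age grid, $R_{d,i} = (1-\rho_d)^{\mathrm{AGE}_i}$ discounts for
population change, and $S_{d,i} = s_d + 1$ inside a source-specific bias
window (1 outside). The per-year discount is
$\rho_d = r / (\tfrac12 \max o)$, with $\max o$ the maximum observed age
across same-sex datasets; this transform is taken as given. Ages are real
numbers on input but binned to 1-year half-open intervals $[a, a+1)$ at
model time; the grid runs from $\lceil\text{maturity}\rceil$ to the cap
$\omega = \max(120, 3 \times \text{max observed age})$ years.

**Age-estimation error.** Growth-layer ageing error is modelled as the true
age being Normal around the observation with s.d.
$\varepsilon = (o + B)/20$, rounded to whole years ($B$ is a systematic
offset). Rather than sampling a latent true age per individual — discrete
latents mix poorly in any sampler — the expected age distribution is
convolved with a row-stochastic kernel whose row $t$ is the distribution of
$\lfloor \mathrm{Normal}(t, (t+B)/20) \rceil$, clamped to the grid. The
synthetic generator applies exactly the mirrored perturbation, so fits and
truth share a scale. On error-free data the kernel shifts posterior means
by well under one posterior s.d. (tested).

**Sharing.** Same-sex datasets of a species share $(\alpha, \beta)$;
same-population datasets share $r$ (fixed at its source-derived prior mean
when the prior s.d. is 0); each dataset with a window gets its own $s_d$.

**Priors.** $\alpha \sim \text{half-N}(0, 0.1)$,
$\beta \sim \text{half-N}(0, 0.2)$ (1/yr; generous for odontocete adult
hazards), $s_d \sim \text{Exp}(1)$, $r \sim$ its dataset prior (default
mean 0, s.d. 0.05).

**Ordinary maximum lifespan** $Z$ is the age by which a fraction $q = 0.9$
of adult person-years have been lived, computed by trapezoidal integration
of survivorship on the 1-year grid; it is attached to every posterior draw.
$Z$ is reported on the grid, so it is exact only to $\pm 1$ year — adequate
given posterior spreads of several years.

## Juvenile mortality

Datasets with more than 100 sub-maturity records get a Siler (bathtub)
hazard $a_1 e^{-b_1 x} + a_2 + \alpha e^{\beta x}$ from birth, with the
integrated hazard in closed form. The exact bathtub parameterization is a
documented package choice. Growth discounting uses the prior-mean $r$;
bias windows and ageing error are not applied to these well-sampled series.
Survival to maturity for species without juvenile data is imputed from a
Bayesian regression of logit survival-to-maturity on age at maturity,
with per-species posterior spread as response measurement error. The
maturity covariate is centered and the slope prior is Normal(0, 0.5)
logits/yr: half a logit per year of maturity is already a steep
life-history gradient, and looser priors let posterior-predictive
imputation wander to survival values near zero, which the stationarity
solve then converts into absurd baseline fecundities. The slope's sign is
estimated, not assumed.

## Ovarian corpora and reproductive lifespan

Corpora persist after each ovulation, so a female's count indexes lifetime
ovulations. Counts at known age are Poisson with mean equal to cumulative
deposition $\lambda_i = \sum_{j \le i} \Delta k_j$,
$\Delta k_j = \max\{0, \alpha(1 - \beta\,\mathrm{AGE}_j)\}$, accruing in
1-year steps from maturity ($\mathrm{AGE} = 0$ at maturity). The linear
rate is clamped at zero past $1/\beta$ — a valid Poisson mean requires it —
so $\lambda$ plateaus at cessation. Reproductive lifespan is
$1/\beta + \text{maturity}$ per posterior draw. Datasets of a species share
$\beta$ and differ in $\alpha_d$. Priors:
$\alpha_d \sim \text{half-N}(0, 2)$, $\beta \sim \text{half-N}(0, 0.1)$.

## Kinship demography

Per joint posterior draw (default 1,000 draws pushed end to end — the
combined posterior space is too large to enumerate), a life table couples

* survivorship: juvenile part spread at constant hazard to the fitted
  survival-to-maturity, adult part Gompertz;
* relative fecundity $\varphi(x) = \max\{0, 1 - \beta_c (x - m)\}$ for ages
  past maturity $m$, following the corpora decline;
* baseline fecundity $f$ solved so the Leslie matrix is stationary. At
  $\lambda = 1$ Euler–Lotka is linear in $f$, so
  $f = 1/\sum_x l_x \varphi_x$ is the exact solution of the eigenvalue
  bracketing problem; tests confirm the assembled matrix has dominant
  eigenvalue $1 \pm 10^{-6}$.

A deterministic recursion then tracks, conditional on the focal female
being alive at each age: her living daughters by age (newborns accrue at
$f\varphi(x)$, then survive and age) and her living matrilineal
grandoffspring (each daughter of age $a$ contributes newborns at
$f\varphi(a)$; within a step, kin age before the focal's own newborn is
added, so a daughter born this year cannot also reproduce this year).
Counts are in the daughter line; "both sexes" multiplies by 2 under a 0.5
birth sex ratio (the default currency), with grandoffspring always routed
through daughters. The recursion is validated against an individual-based
forward simulation with Poisson births and binomial survival at $10^5$
replicates.

**Metrics.**

* *Grandmother years*: $\sum_x l(x \mid m) \cdot
  E[\text{grandoffspring younger than } m \text{ at } x]$ — expected years
  spent alive alongside sub-maturity grandoffspring; *relative* divides by
  the age at maturity.
* *Mother years*: the same with offspring.
* *Reproductive overlap*: $\sum_x E[\text{newborn grandoffspring at } x]
  \cdot c(x)$ with $c(x)$ the focal's remaining fraction of reproductive
  capacity.

**The overlap weighting choice.** Two readings of "remaining capacity when
a daughter gives birth" are defensible: schedule-only
($c(x) = \sum_{y \ge x}\varphi_y / \sum_y \varphi_y$, not weighted by focal
survivorship) and survivorship-weighted (the same summand multiplied by
$l(x \mid m)$, i.e. overlap only accrues in expectation over the focal
actually being alive). `kinship_metrics()` defaults to schedule-only —
it is the literal reading and yields the hand-checkable toy values — with
`survival_weight_overlap = TRUE` as the variant. The pipeline's contrast
analyses, however, use the weighted variant as primary (both are reported
in every draws table). The reason is structural: under stationarity
$f = 1/\sum l\varphi$, so longer-lived species get systematically lower
$f$, and the schedule-only overlap — which scales with $f^2$ through the
daughter generation — then *falls* mechanically with lifespan. That makes
it a proxy for (inverse) lifespan rather than for co-reproduction, and it
manufactures a strong negative menopause effect that the weighted variant,
which credits overlap only while the focal survives, does not show. For
measuring mother–daughter co-reproduction the weighted variant is the
meaningful quantity; the schedule-only variant remains available for
sensitivity.

## Comparative regressions

The live-long/stop-early question is a regression of true lifespan on log
size and menopause status $M$ with phylogenetically structured residuals:

$$Z \sim \text{MVN}(\alpha + \beta_{SIZE}\, S + \beta_{PR}\, M,\;
K + \mathrm{diag}(\sigma_Z^2 + \beta_{SIZE}^2 \sigma_S^2)), \qquad
K_{ij} = \eta^2 e^{-\rho^2 D_{ij}},$$

with $D$ the patristic distance matrix of a time-calibrated chronogram.
The latent "true" response and predictor values of the measurement-error
formulation are marginalized analytically (flat priors on the latents make
the marginal exactly the expression above); this collapses the parameter
count from $2n + 5$ to 5 and mixes far better. The model is fitted on each
bootstrap chronogram and posteriors pooled with equal draws per tree.
Variables are standardized internally and coefficients back-transformed;
priors on the standardized scale are slopes $\sim$ N(0, 10),
$\eta, \rho \sim$ half-N(0, 2). A $10^{-9}$ diagonal jitter guards
against singular kernels. Convergence is judged on the regression
coefficients; $\eta$ and $\rho$ sit on a known weak-identifiability ridge
($\rho \to 0$ turns $K$ into a shared intercept), so their R-hats are
reported but do not gate the flag. Inference is reported the way
comparative biologists read it: posterior mean, 95% CI, and tail
probabilities such as $P(\beta_{PR} > 0)$.

Predictive comparison of models with and without the menopause term uses
leave-one-out elpd. Because the multinormal likelihood does not factorize,
the pointwise quantity is the conditional density
$p(y_i \mid y_{-i}, \theta)$ (closed form from the precision matrix),
combined across draws by importance sampling with weights
$1/p(y_i \mid y_{-i}, \theta)$ truncated at $\sqrt{S}$ times their mean.
The estimator choice (truncated IS-LOO) is the package's own; the
difference is reported as (without − with) ± s.e. over pointwise
differences.

The female:male lifespan ratio model is log-normal with mean
$\alpha + \beta_{PR} M$. The latent-lifespan measurement error enters
through the delta method: $\log(\text{ratio})$ observed with variance
$\sigma^2 + (\sigma_f/\mu_f)^2 + (\sigma_m/\mu_m)^2$. Priors
$\alpha, \beta_{PR} \sim$ N(0, 1), $\sigma \sim$ Exp(1). A
degenerate-error oracle test checks the approximation against the
point-value regression.

## Counterfactual scenarios

For each menopausal species, per aligned posterior draw:

* *observed* — fitted demography as is; reproduction ceases at the
  observed reproductive lifespan (corpora cessation, or the age of the
  oldest known reproductively active female where corpora are lacking);
* *ancestral* — the Gompertz ageing rate $\beta$ is rescaled (holding
  $\alpha$) so the ordinary maximum lifespan equals the size-predicted
  non-menopause value from the regression; rescaling one parameter
  preserves the hazard shape with a single degree of freedom, and $Z$ is
  monotone in $\beta$ so bisection on $\log\beta$ is safe. Because $Z$
  lives on a 1-year grid the objective is a step function; a candidate
  $\beta$ already on target is returned unchanged, so a degenerate target
  equal to the observed lifespan is bitwise a no-op;
* *slow life history* — observed mortality, with the fecundity schedule
  stretched so cessation equals each draw's lifespan.

Baseline fecundity is re-solved per case (a stationary counterfactual
population), which is why the slow case always has $f$ at or below the
observed case. Contrasts are paired by draw index — the cases share the
same upstream draws — and reported as tail probabilities
$P(\text{case A} > \text{case B})$ with ties counted half; draws are also
z-scored across pooled cases within species for cross-species display.

## What the synthetic generators emulate

`simulate_age_dataset` draws binned ages from exactly the
$L \cdot R \cdot S$ structure the fit assumes, then applies the rounding
error; the growth discount uses the expected maximum observed age
(survivorship quantile $1/n$) where the fit uses the realized one — the
scales agree to within the bin width. `simulate_corpora_dataset` samples
ages from the adult mortality model and counts from the Poisson deposition
model. `simulate_clade` builds pure-birth chronograms (a bootstrap-like set
of independent trees over the same taxa; the truth is generated on the
first), gives species log-lengths, lifespans on an allometry
($Z = -80 + 20 \log L_{cm}$, spanning roughly 20–80 years over lengths of
250–800 cm) plus a menopause offset (default 40 yr) and OU-correlated
residuals, and reproductive lifespans from the same allometry with
independent noise and *no* offset — menopausal species live longer, they do
not reproduce shorter. Ages at maturity scale with the allometric lifespan
(fraction 0.25): life-history timescales covary in odontocetes (porpoises
mature around 4 years, sperm whales past 9), and a size-independent
maturity would break the time-rescaling invariance that keeps
dimensionless quantities like reproductive overlap comparable across body
sizes. Defaults (32 species, 5 menopausal, measurement s.d. 2 yr on
lifespan, 0.05 on log length) mirror the scale of the comparative analysis.

The generators do not emulate: species-specific ecological covariates,
spatial structure of strandings, taxonomic error, heaping of published age
tables, or correlated sampling across datasets. Passing tests therefore
demonstrate correctness of the estimators under the assumed generative
structure, not robustness to every failure mode of literature data.

## Sampler and problem sizes

All models share an adaptive random-walk Metropolis engine: parameters on
unconstrained (log) scales with Jacobians, Robbins–Monro step-size
adaptation toward 23.4% acceptance and proposal-covariance estimation
during warmup (both frozen afterwards), split-R-hat and
initial-positive-sequence ESS diagnostics. Defaults are 4 chains × (3,000
warmup + 2,500 kept) = 10,000 draws, which brings R-hat below 1.01 on the
fits shown in the README; the simulation studies in the test suite and
`scripts/acceptance.R` use 2 chains × (400–800 warmup + 300–800 kept) per
fit with n = 1,000 ages, n = 200 corpora, 32-species clades, 10 (recovery)
or 1 (null replicate) trees, and 200 kinship draws per species — sizes
chosen so the whole validation battery runs in a few minutes on one core
while leaving recovery and calibration checks well-powered. The
null-calibration fits specifically use 800 + 800, since shorter chains
visibly narrow the 95% intervals and depress empirical coverage.

## Degenerate inputs and tie-breaks

$\beta = 0$ falls back to the exponential hazard limit everywhere. A
fecundity schedule that is zero everywhere has no stationary $f$;
`life_table()` then requires an explicit `f` (the kin recursions correctly
return all-zero expectations). All-zero corpora counts are rejected
($\alpha$ unidentifiable). Bias windows outside the realized age range are
dropped by the simulator (the stored window must lie within the observed
ages). Scenario tail probabilities count ties as half, so identical draw
sets give exactly 0.5. Filters are idempotent and every dataset lands in
exactly one partition.

## Known limitations

Only Gompertz adult hazards (no covariates, no alternative families); no
Pagel's λ or Brownian kernels alongside the OU form; paternal kin and the
sons/daughters split of offspring overlap are not implemented; "ancestral"
is a size-predicted counterfactual, not an ancestral-state reconstruction
on the tree; the lifespan-ratio model uses a delta-method approximation
rather than latent lifespans; and the pipeline's orchestration is
deliberately in-memory R — there is no shell CLI, the exported functions
and `run_pipeline()` are the interface.
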