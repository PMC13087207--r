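---
title: "Modelling reproductive senescence with senescurve: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reproductive senescence with senescurve: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`senescurve` quantifies reproductive senescence — the decline of breeding
performance at old age — from longitudinal breeding records of individually
marked animals, and compares life-history strategies within and between two
populations breeding under contrasting environmental variability. This
vignette explains the model, the derived life-history parameters, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## Data model and filters

The unit of observation is one breeding attempt: an individual, its
population (`A` or `B`), its fledge cohort, the season (labelled by the
starting calendar year, so `age = season - cohort`), a primiparity flag
(first-ever attempt) and a 0/1 success. The system modelled is a long-lived
single-egg annual breeder, so there is at most one record per individual
per season; re-lays within a season are out of scope.

Three deterministic filters precede modelling:

* **First-breeding age** (`filter_first_breeding_age()`, default 20
  years). Individuals whose earliest observed attempt is at 20 or older
  are removed entirely; such records are typically ring-reading errors or
  chronic nonbreeders, since recruitment essentially always occurs
  before 20.
* **Presumed death** (`mark_presumed_dead()`, default gap 4). An
  individual absent from the final four breeding seasons (inclusive of the
  final one, i.e. `last_seen <= final - 4`) is presumed dead. Established
  breeders are strongly site-faithful and very rarely skip more than three
  consecutive seasons, so the rule has low false-positive risk. We read
  "the last 4 years" literally as the final four seasons.
* **Robustness subset** (`subset_min_attempts()`, default 4): restricts to
  individuals with at least four recorded attempts, to check sensitivity
  to individuals observed only briefly.

For fitness analyses, `subset_fitness_cohort()` keeps individuals fledged
before a cutoff year (default 2000) *and* presumed dead, so lifetime
reproductive success (LRS, total chicks fledged) is complete rather than
right-censored.

## The hierarchical age-trajectory model

Breeding success is modelled with a binomial GLMM on standardized age
`x = (age - mean) / sd` (pooled mean and sample SD across both
populations; `standardize_age()` records the constants so everything can
be back-transformed to years):

```
logit p = b0 + b1 x + b2 x^2
        + (b3 + b4 x + b5 x^2) * 1[pop = B]
        + b6 * 1[primiparous]
        + u0_i + u1_i x + u2_i x^2    (individual)
        + v_year + w_cohort           (population-specific SDs)
```

with `(u0, u1, u2) ~ MVN(0, Sigma_pop(i))` — a *separate* 3x3 covariance
matrix per population, so the amount and structure of among-individual
heterogeneity in ageing trajectories can differ between environments —
and year and cohort random intercepts each with population-specific SDs
(cross-population year effects are independent). Population A is the
reference level, so the second population's curve is obtained by
componentwise contrast sums (`population_curve_components()`).

Priors are weakly informative: normal(0, 5) for the intercept,
normal(0, 2) for the other fixed effects, half-Student-t(df 3, scale 1)
for all group-level SDs, and LKJ(eta = 2) for the individual-effect
correlation matrices, which weakly favours near-zero correlations.
`priors = "flat"` substitutes much more diffuse versions of the same
families for sensitivity checks; no claim of exact equivalence with any
other software's flat-prior defaults is made.

### Sampler

The model is estimated by MCMC with JAGS (`rjags`), with the `glm` module
loaded: it block-updates the logistic-regression coefficients
(Holmes-Held auxiliary sampling), which improves mixing dramatically for
this model compared to one-at-a-time updates. Two implementation choices
matter:

* **Non-centered parameterization.** Individual effects are built as
  `u_i = diag(sd) L z_i` with `z ~ N(0, 1)` and `L` the Cholesky factor
  of the correlation matrix, computed in closed form for the 3x3 case.
  This keeps the posterior geometry tractable when SDs are small and
  avoids matrix inversion inside the sampler.
* **LKJ via its vine representation.** JAGS has no LKJ density; the
  LKJ(eta = 2) distribution for a 3x3 correlation matrix is realised
  exactly through its D-vine construction — level-1 correlations
  distributed as `2 Beta(2.5, 2.5) - 1`, the level-2 partial correlation
  as `2 Beta(2, 2) - 1` — which also guarantees positive definiteness by
  construction.

Default sampler settings are 8 chains of 4000 iterations including 2000
warm-up (split between adaptation and burn-in). These defaults suit a
full-scale analysis; the package's own tests and the acceptance script
use reduced settings (2 chains of 1500 with 750 warm-up, on simulated
datasets of 60-300 individuals per population), chosen as the smallest
problem sizes at which the recovery properties below are stable.

Convergence is gated on rank-normalized split R-hat <= 1.01 and bulk
effective sample size >= 400 for every fixed effect and SD (correlation
parameters are reported but not gated: with modest data they are
prior-dominated and their ESS is uninformative about the quantities
used downstream). A failed gate produces a warning and
`converged = FALSE`, never a silent pass; the pipeline aborts unless
`allow_nonconverged` is set.

## Derived life-history parameters

Per-individual curves are BLUP-style sums, per posterior draw, of the
population fixed part and the individual's random deviations. Point
estimates are posterior means, which are draw-linear and stable (posterior
modes would depend on a density estimate). From each logit-quadratic curve
`q(x) = c0 + c1 x + c2 x^2`, `derive_life_history()` computes four
parameters:

* **Onset of senescence** (years): the age at the peak,
  `x* = -c1 / (2 c2)`. Because the logistic link is monotone this is also
  the unique maximizer of the success probability.
* **Senescence rate** (probability per year): the magnitude of the tangent
  slope of `p(age)` at the *first inflection point after the peak*. For
  `p = logistic(q)`, `p'' = p (1 - p) [(1 - 2p) q'^2 + q'']`, so the
  inflection is the first root of `g(x) = (1 - 2p) q'^2 + 2 c2` beyond
  `x*`; this is, by construction, where the decline is steepest. A
  pre-peak inflection (steepest *ascent*) also exists; it is deliberately
  ignored because the parameter of interest is the fastest decline. The
  rate is reported as a positive magnitude, `-p'(x_infl) / sd` per year,
  so "higher rate" literally means "faster decline".
* **Early-life performance**: `p` at 10 years, the average age at first
  reproduction in both populations (configurable via `early_age`).
* **Peak performance**: `p` at the onset age, a proxy for maximum
  individual performance.

Curves with `c2 >= 0` (no peak) or onset beyond `max_onset = 40` years
(little-to-no senescence within an observable lifespan) are flagged
`excluded` and dropped from all downstream comparisons and fitness models.
Exclusion is a flag, not an error.

**Numerics.** The inflection root is found by a vectorized sign-change
scan outward from the peak (where `g = 2 c2 < 0`) followed by bisection to
machine precision; the scan step widens away from the peak because nearly
flat curves (`c2` close to 0) can inflect tens of SD units beyond their
peak, and the root provably exists for any `c2 < 0`. Vectorization
matters: uncertainty propagation evaluates the geometry on every posterior
draw of every individual (~10^6 curves). Tests verify the analytic peak
against a dense-grid argmax, the root against a second-difference
sign-change oracle, and the tangent rate against central finite
differences (tolerances 1e-3, 1e-3 and 1e-4 respectively). All parameters
are invariant (to ~1e-8) under reparameterizing the age axis, i.e.
computing on raw-age polynomial coefficients gives the same years and
per-year rates.

## Population comparison

Three complementary comparisons (`compare_populations()`):

* **Posterior overlap** of the *population-level* distributions of the
  four derived parameters (`population_overlap()`): for each posterior
  draw the population curves are reduced to their life-history parameters,
  and the two populations' distributions are compared with the overlapping
  coefficient `integral of min(f_A, f_B)`. Densities are Gaussian-kernel
  estimates with Silverman's bandwidth on a shared 4096-point grid
  spanning the pooled range plus three bandwidths each side; each density
  is renormalized to unit mass on the grid so identical samples give
  exactly 1. The standard error is the SD of the statistic over paired
  nonparametric bootstrap resamples (both samples resampled and bandwidths
  recomputed every iteration; the resampling scheme is pinned here because
  overlap-SE conventions differ between implementations). Draws where a
  population curve has no peak are dropped with a message.
* **Among-individual variances** of the *individual point estimates* per
  population, with the A/B ratio, plus the posterior among-year and
  among-cohort variances in success (posterior means of the squared random
  intercept SDs). Higher ratios indicate more heterogeneous life histories
  under the more variable environment.
* **Onset-rate correlation** per population (Pearson, point estimates):
  a negative correlation places individuals along a fast-slow continuum
  (early onset with fast decline through late onset with slow decline).

Overlap uses posterior distributions while variances and correlations use
individual point estimates, mirroring the distinct questions: how separated
the populations' average strategies are, versus how much individuals vary
within each.

## Fitness analysis

`fit_poisson_glm()` regresses LRS (or, as a robustness check, the number
of breeding attempts, `attempts_robustness()`) on one life-history
predictor, population, and their interaction, with a log link. Onset and
rate are never co-predictors: they are strongly negatively correlated and
jointly uninterpretable. Predictors are standardized to SD units before
fitting, so coefficients are comparable across models and runs; the
standardization constants are recorded in the fit object. The fit is the
standard IRLS maximum-likelihood fit from `stats::glm()` with a tightened
convergence tolerance, verified in tests against closed-form two-group
MLEs to 1e-8.

**Uncertainty propagation.** `propagate_uncertainty()` re-runs the GLM
(default 2000 times), each run replacing every individual's point estimate
with one joint posterior draw of its (onset, rate), restricted to draws
where *both* parameters lie inside that individual's central 95% credible
interval. Both values come from the same draw, preserving the within-draw
onset-rate dependence; independent marginal resampling would break it.
Out-of-interval draws are redrawn per individual; individuals with fewer
than 50 usable draws are dropped with a warning. Re-run summaries (mean,
SD, 2.5/97.5 percentiles) are permutation-invariant and recomputable from
the stored per-run coefficients.

## The synthetic-data generator

`simulate_population()` is the generative mirror of the trajectory model,
parameterized by `default_scenario("A")` (variable environment: lower
average success, steeper age trajectory, among-year SD 1.21, 360
individuals) and `default_scenario("B")` (stable environment: higher
success, shallower trajectory, among-year SD 0.70, 874 individuals). The
fixed effects, random-effect SDs and correlation matrices are set at the
fitted point estimates for the two study colonies the package is designed
around, so simulated data have realistic magnitudes; cohorts span
1976-2000 with the study ending in 2023.

Generator-only choices, flagged as such and configurable:

* **Lifespan** via constant annual adult survival (geometric; A 0.94,
  B 0.92, capped at 45 years). The model targets reproductive, not
  actuarial, senescence, so age-dependent mortality is deliberately
  omitted.
* **Age at first reproduction** from a discretized normal on 5-19 years
  (A: mean 10.2, SD 2.2; B: mean 9.9, SD 2.5).
* **Intermittent breeding**: each season after recruitment is attempted
  with probability 0.9 (gaps longer than three seasons are rare in the
  study system); the first realized attempt is the primiparous one.
* **Shared standardization axis**: the generator evaluates its logit on
  `x = (age - 15) / 6` and reports these constants in its truth object,
  so recovery tests can hand the model the same x-axis instead of the
  (slightly different) empirical pooled scaling.

What the generator does *not* emulate: environmental covariates driving
the year effects (they are i.i.d. normal), density dependence, pair
identity, sex differences, observation error in identity or success, and
any direct mechanistic coupling between an individual's curve parameters
and its lifespan. Consequently, passing recovery tests demonstrates that
the inference chain is self-consistent under the assumed data-generating
process — not that the model is robust to the many ways real field data
violate it (non-random missingness, terminal effects, trends in year
effects).

Determinism: every randomized function takes a seed; a two-population
study derives sub-seeds for each population from one root seed, and the
pipeline fans out stage seeds as root + 1 ... root + 4 (recorded in its
summary). Identical configuration and seed reproduce artifacts exactly.

## Degenerate inputs and edge behaviour

* Zero age variance makes standardization impossible and is an error.
* `c2 >= 0` has no peak: `onset_age()`/`senescence_inflection()` raise a
  no-peak error at curve level, while table-level derivation flags the
  row excluded.
* Overlap requires >= 50 finite values per sample and positive variance
  (a point mass has no kernel density).
* Variance comparison requires >= 2 non-excluded individuals per
  population; correlations >= 3 and positive variance in both variables.
* Poisson fitting validates non-negative integer responses and flags
  IRLS non-convergence (e.g. separation) instead of failing silently.

## Known limitations

* The quadratic-logit family forces symmetric rise and decline on the
  logit scale; threshold or piecewise senescence patterns are out of
  scope.
* With few records per individual, point-estimate life histories are
  strongly shrunk toward the population curve, compressing among-
  individual variances; the propagation machinery quantifies but does not
  remove this.
* The onset-rate correlation of *estimated* individual parameters can
  differ substantially from the correlation of the true underlying
  parameters, since both are functions of the same posterior; treat the
  sign and magnitude as descriptive, not causal.
* JAGS is markedly slower than gradient-based samplers on this model;
  full-scale default settings are an overnight-class computation, which
  is why the documented reduced settings exist.
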