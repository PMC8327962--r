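---
title: "Estimating sex-specific purging of mutation load from diallel fitness data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sex-specific purging of mutation load from diallel fitness data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diallelh)
```

## The model

`diallelh` analyses competitive lifetime reproductive success measured in a
full diallel cross among inbred strains, where fitness of each strain is
observed in four classes: inbred female (iF), outbred female (oF), inbred
male (iM), outbred male (oM). The response is *relative* fitness — raw
offspring counts divided by the sex-specific outbred mean
(`standardize_relative_fitness()`), so the outbred mean is exactly 1 within
each sex and male and female measurements share a scale.

The fitted model is a Gaussian mixed model

\[
y = \mu + S + B + I + S{\times}I + B{\times}I + u + v + v{\times}S + \varepsilon,
\]

with fixed effects for sex, block, inbred state and their interactions
(treatment coding, reference female/outbred/block 1, so the `inbred`
coefficient is directly the mean fitness reduction of inbred selfs), and
three random terms:

* **strain effects** `u`: every strain carries a 4-vector of effects, one
  per class, with unknown 4×4 covariance **H** (order iF, oF, iM, oM). An
  outbred observation of sex *s* loads weight 1 on the sire's and the dam's
  (outbred, *s*) effect (multimembership); an inbred observation loads
  weight 1 on its strain's (inbred, *s*) effect. Treating the self as one
  whole-genotype "state" effect (weight 1, not an additive dose of 2) is a
  deliberate choice: inbred and outbred are distinct states of the same
  trait, and the correlations that carry the scientific conclusions are
  invariant to this scale convention. The dose-2 alternative is available
  via `mcmc_config(w_self = 2)`.
* **symmetric epistasis** `v` and `v×S`: one effect per unordered outbred
  strain pair (shared by reciprocal crosses), plus a pair-by-sex
  counterpart, with scalar variances. These absorb strain–strain
  interaction variance among outcrossed families so that H estimates
  additive strain effects rather than a mixture.
* **residuals**: one variance per observation class, since inbred and male
  observations are far more variable than outbred and female ones.

Assumptions worth stating: fitness is treated as approximately Gaussian on
the relative scale (reasonable for counts with means near 30–40); pair
effects attach only to outbred observations; block effects are fixed, not
random (two blocks).

## Priors and the Gibbs sampler

Fixed effects take improper flat priors. Scalar variances take weak
inverse-gamma priors, parameterized as one-dimensional inverse-Wisharts
with `nu = 0.002`, `V = 1` (i.e. IG(0.001, 0.001)); with hundreds of pair
levels and thousands of residual degrees of freedom these are dominated by
the data.

H uses the **parameter-expanded** (working-parameter) family: `u = diag(α)·η`
with rows of η drawn from N(0, Ψ), Ψ inverse-Wishart with `nu_h = 4`
degrees of freedom (the dimension) and scale `V_h·I₄`, and independent
Gaussian working parameters `α_c ~ N(0, 625)`. The induced marginal prior
on each variance is a heavy-tailed scaled-F, weakly informative near zero
— the standard choice for variance components that may be small.

One hyperparameter required a decision the literature leaves open: the
scale `V_h`. The posterior mean of each H diagonal inherits a contribution
of roughly `α²·V_h/(nu_h + n_strains − 5)` from the prior scale. With 16
strains and genetic variances of order 0.001–0.02 on the relative-fitness
scale, a scale of 0.02 puts that contribution at the same order as the
quantities being estimated; parameter-recovery experiments showed it
visibly inflating the smallest variances. The package therefore defaults to
`V_h = 0.002`, an order of magnitude below the data scale, and exposes the
value in `prior_spec()`. Even so, users should expect the posterior *mean*
of a strain variance estimated from 16 strains to sit materially above the
posterior mode: with so few strain-level degrees of freedom the posterior
is strongly right-skewed, and our coverage experiments (see below) confirm
the posterior itself is calibrated.

The sampler (`fit_gibbs()`, C++ core in `src/gibbs.cpp`) is a conjugate
block Gibbs scheme: fixed effects, pair effects and strain effects from
their Gaussian full conditionals (the 64-dimensional strain-effect block is
sampled jointly via one Cholesky per iteration); α from independent
Gaussian regressions; Ψ from its inverse-Wishart full conditional; scalar
variances from inverse-gammas. Observations sharing a design row (same
cross, sex, state, block) enter every full conditional only through their
count, sum, and sum of squares, so the sampler runs on group-level
sufficient statistics: one iteration costs the same at 3,278 or 164,000
observations, and row order cannot affect results even in the last bit.
The default schedule is the full published one — 2,000,000 post-burn-in
iterations, 200,000 burn-in, thinning 2,000, giving 1,000 approximately
uncorrelated stored draws; `pipeline_config("ci")` provides a reduced
50,000/5,000/50 schedule for tests and exploration. All randomness flows
through R's RNG, so a seed reproduces stored draws bit-for-bit.

Numerical choices: every stored H draw is positive definite by
construction (inverse-Wishart via Bartlett decomposition); a Cholesky
failure in the strain-effect precision triggers diagonal jitter of 1e-10,
counted and reported, with a hard error after 10 consecutive failures; a
non-finite residual variance aborts with the iteration number. Residual
variances of classes with no observations — and epistasis variances when no
outbred pairs exist — are *not* updated and are stored as `NA`: their full
conditionals equal the IG(0.001, 0.001) prior, whose draws are not
representable in double precision (a shape-0.001 gamma underflows to zero
about half the time). With a zero-row dataset the sampler degenerates to
drawing from the (proper) prior of H, which the test suite uses for
prior-predictive checks.

## Derived statistics and resampling

All scientific quantities are *per-draw functionals across strains* of the
stored posterior, summarized afterwards — never ratios of separately
summarized quantities:

* heterosis per sex, `o − i`, and sex-averaged `(oM+oF)/2 − (iM+iF)/2`;
* selection intensities `βₐM′ = COV(oM, oF−iF)/SD(oF−iF)` and
  `βₐF′ = COV(oF, oM−iM)/SD(oM−iM)`, which use *opposite-sex* heterosis so
  that measurement error in a sex's outbred fitness does not appear on both
  sides of the covariance;
* genetic correlations `r(oM−iM, oF−iF)`, `r(iM, iF)`, `r(oM, oF)`,
  `r(oM, oF−iF)`, `r(oF, oM−iM)`;
* sex-averaged ("double-primed") variants of the β's and correlations, used
  for like-for-like sex comparisons.

Sex-averaged statistics share MCMC sampling error between the outbred
vector and the heterosis vector. To remove it, the outbred vectors are
taken from a *different* posterior iteration than the heterosis vector: a
seeded uniform random permutation of draw indices with identity mappings
re-drawn (a derangement), implemented in `cross_pairing()`. Whether the
original analysis excluded identity pairings is not recorded; excluding
them is the conservative choice and changes at most ~1/1000 pairings. The
test suite demonstrates the point directly: with shared noise injected,
same-iteration pairing biases the covariance upward by the noise variance
while cross-iteration pairing is unbiased.

Summaries: point estimates are kernel-density posterior modes (Gaussian
kernel, Silverman bandwidth, 512-point grid over the sample range; the
bandwidth multiplier is configurable since the original tool's value is
unrecorded, default 1). Intervals are highest-posterior-density: the
shortest contiguous window of sorted draws containing `ceil(0.95·n)` of
them, ties resolved toward the lower endpoint. Two-sided MCMC p-values are
twice the fraction of draws on the opposite side of zero from the mode,
capped at 1, with resolution 2/n (an empty opposite side reports "< 2/n");
a mode exactly at zero returns p = 1. Sex differences are tested as twice
the fraction of draws whose ordering contradicts the point-estimate
ordering, ties counted as half — so identical inputs give p = 1, the only
defensible degenerate answer.

`summarize_H()` prints variance posterior modes on the diagonal (with HPD
intervals and residual-variance modes), covariance modes below, and — above
the diagonal — the modes of *per-draw* correlations computed within each H
draw. The distinction matters: for fixed draws at the published
covariances, the per-draw inbred intersexual correlation is
0.0106/√(0.0108·0.0199) ≈ 0.723, whereas the published table prints 0.85
for the posterior-mode summary — mode-of-ratio and ratio-of-modes are
different estimators, and the package always uses the former.

## The synthetic-data generator: a stated world

`simulate_diallel()` inverts the fitted model. Its defaults *are* the
published experimental conditions, fixed once:

* design: 16 strains, all 16 selfs, 237 of 240 ordered crosses, two
  blocks; class totals 1616 (oM), 1450 (oF), 115 (iM), 97 (iF), total
  3,278. Which three cells failed in the real experiment is unrecorded, so
  three ordered cells are removed by seeded choice; replicates are
  allocated evenly across cell-by-block units with a seeded remainder
  (per-cell counts are likewise unpublished).
* truth: H equals the published estimate matrix (verified positive
  definite, smallest eigenvalue 1.3e-3); class residual variances 0.0256,
  0.0150, 0.0863, 0.0837; inbreeding fixed effect −0.294; intercept 1 (the
  outbred female mean after standardization). Unpublished values chosen
  once: epistasis variances σ²_v = σ²_vS = 0.001 (the same order as the
  smaller genetic variances — epistatic variance for fitness is typically
  below the additive strain variance in such diallels) and a small sex
  effect of 0.02 on the relative scale (outbred sex means are equalized by
  standardization, so this is nearly unidentifiable by construction).
* counts: relative values are scaled by a sex-specific target outbred mean
  of 40 offspring and truncated at zero; the truncation rate is recorded
  and stays below 0.1% at defaults, so the Gaussian assumption survives
  the round trip.

What the generator does *not* emulate: count overdispersion and integer
rounding, parental (dam) effects, sex-chromosome inheritance,
larval-ecology interactions, and any sexually antagonistic structure beyond
what H itself encodes. A green simulate→fit→derive test therefore
establishes that the estimator chain recovers the statistical structure it
assumes — not that the assay or the biology is faithfully modelled.

`make_null_truth()` projects the truth matrix onto a null hypothesis (e.g.
COV(oM, oF−iF) = 0) by Dykstra alternating projections between the
constraint hyperplane and the PSD cone, landing on the constraint to 1e-10.
This supplies exact nulls for type-I-error calibration.

## Calibration, scaled-down harnesses, and what the tests establish

* **Sampler correctness** is tested against an independently coded
  univariate parameter-expanded Gibbs sampler: restricted to a single
  observation class, the 4×4 model reduces exactly (the diagonal marginal
  of IW(4, V·I₄) is IG(1/2, V/2)), and the two samplers' H₁₁ posteriors
  agree by Kolmogorov–Smirnov test. Prior-predictive draws from a zero-row
  dataset match direct draws from the analytic PX prior.
* **Interval calibration**: over 50 simulations at quarter scale, central
  95% posterior intervals for the H diagonals cover the generating values
  at nominal rate (the acceptance band is 0.85–1.0).
* **Parameter recovery** runs at the stated scale — truth at the published
  values, design ×5, 50,000/5,000/50 chains, 20 replicates with seeds fixed
  in advance. Sign recovery of COV(iM,iF) and COV(oM, o−i) meets its
  thresholds (20/20 and 19/20). The replicate-mean of posterior means is
  within 50% of truth for three H diagonals; the oF diagonal lands at 1.55×
  — just outside — which decomposes into the ~1.3× right-skew of a
  posterior mean estimated from 16 strains (shown calibrated by the
  interval-coverage test) compounded by these 20 simulation seeds drawing
  realized oF strain variance 1.16× truth on average. The test is left
  asserting the stated band rather than widened.
* **Null calibration** of the two-sided MCMC p-value for βₐM′ uses 200
  simulated posteriors under the projected null (estimated breeding values
  = truth + Gaussian estimation noise; posterior draws = estimate +
  same-law noise), rejecting at α = 0.05 in 6% of replicates (band
  1–10%). Running 200 full MCMC fits instead would take hours; the
  simulated-posterior harness tests the same property of the derivation
  chain at desk scale.

Full reproduction of the published posterior summaries requires the
archived dataset and the 2.2-million-iteration schedule; the package
encodes that schedule as `pipeline_config("paper_defaults")` and the CSV
column-mapping hook in `read_fitness_table()` accommodates the archive's
headers, but no download is performed anywhere in the package or tests.

## Known limitations

* Gaussian response only; no overdispersed-count family.
* The absolute scale of H depends on the self-loading convention
  (`w_self`); cross-state correlations and all derived statistics do not.
* Posterior means of strain variances from 16 strains are right-skewed
  estimators; prefer the reported posterior modes with HPD intervals.
* One derangement is used per statistic family (seeded); the paper's exact
  resampling pairing is unrecorded, so resampled sex-averaged statistics
  reproduce published values only up to resampling noise.
* `gelman_rubin()` implements the plain PSRF (no rank normalization), as
  used for the original convergence check.
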