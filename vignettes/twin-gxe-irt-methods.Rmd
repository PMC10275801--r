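---
title: "Twin GxE models with item-level IRT measurement: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin GxE models with item-level IRT measurement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinirt)
```

## The problem

Well-being questionnaires (life-satisfaction, happiness, perceived social
support) are short Likert scales with pronounced ceiling effects: most
respondents score near the top, so sum-score distributions are strongly
left-skewed.  When such sum scores are fed into a twin variance
decomposition, measurement error is not homogeneous across the scale — two
people near the ceiling look more alike than their latent trait levels
warrant.  Because the non-shared environment component (E) absorbs
measurement error, the apparent E variance then shrinks at high trait
levels, which masquerades as gene-environment interaction: the estimated E
variance depends on the genotypic value (unmeasured, AxE) or on a measured
moderator that correlates with the trait.  `twinirt` implements both the
biased and the corrected analysis so that the artefact can be produced,
studied, and removed on synthetic data with known truth.

## Model families

All models are AE decompositions (additive genetic + non-shared
environment).  Shared-environment (C) and dominance (D) components are
deliberately out of scope: for adult well-being phenotypes their support is
weak and the AE structure keeps the interaction models identified at
realistic sample sizes.

**Unmeasured (AxE) model.**  For twin $j$ of pair $i$ with genotypic value
$A_{ij}$,

$$y_{ij} \sim N\!\big(\beta_{sex}\,sex_{ij} + \beta_{age}\,age_{ij} + A_{ij},\;
\exp(\beta_0 + \beta_1 A_{ij})\big),$$

with $A$ following the twin structure (MZ co-twins share one
$N(0,\sigma^2_A)$ value; DZ co-twins are jointly normal with correlation
one half, generated as $\sqrt{.5}(g_i + s_{ij})$ with independent
$N(0,\sigma^2_A)$ parts).  The exponential link keeps the E variance
positive; $\beta_1 = 0$ recovers the homoscedastic AE model, and the sign
of $\beta_1$ says whether environmental variance grows with the genotypic
value.

**Measured-moderator model.**  A moderator $M$ (its own phenotype, possibly
latent) enters the trait mean through zygosity-specific own- and co-twin
effects ($\beta_{1MZ}, \beta_{2MZ}, \beta_{1DZ}, \beta_{2DZ}$; singletons
keep only the own effect), which absorbs gene-environment correlation; the
*residual* variance components are then moderated log-linearly:
$\sigma^2_A = \exp(\beta_{0a} + \beta_{1a} M)$,
$\sigma^2_E = \exp(\beta_{0e} + \beta_{1e} M)$.  The genetic part is built
as $\sigma_A(M_{ij})\,\tilde A_{ij}$ from standard-normal twin-structured
latents, so MZ co-twins with different moderator values still share their
genetic core.  The log-linear parametrization (rather than moderated path
coefficients) keeps the model uniquely identified.

**Bivariate AE model.**  Two phenotypes per twin with $2\times 2$ genetic
and environmental covariance matrices (Cholesky-parametrized, so positive
semi-definiteness is structural), cross-twin cross-trait genetic covariance
$\Sigma_A$ for MZ and $\tfrac12\Sigma_A$ for DZ pairs.  Derived quantities:
per-trait heritability, genetic and environmental correlations
$r_A, r_E$, and the bivariate heritability (the share of the phenotypic
covariance due to A).

**Sum-score vs item-level forms.**  In the sum form the phenotype is the
standardized sum score, treated as directly observed.  In the item form the
phenotype is a latent trait $\theta$ measured by a graded response model
(GRM): $P(Y \ge k \mid \theta) = \text{logit}^{-1}(\alpha(\theta -
\beta_k))$, logistic link without the 1.7 constant.  The unified model is
identified by fixing the population mean at 0 and the first item
discrimination at 1, which leaves the latent variance components free — the
same data-driven scale the sum-score model gets by standardization, but
with heterogeneous measurement error modeled instead of ignored.  Because
the GRM layer carries the information function of the scale, regions where
the items discriminate poorly contribute measurement uncertainty to
$\theta$ rather than spurious E-variance structure.

## Estimation

Inference is Bayesian MCMC: an adaptive Metropolis-within-Gibbs sampler
written in C++, updating latent phenotypes, genetic latents, structural
coefficients and item parameters in turn.  Three non-obvious moves matter
for mixing and are worth documenting:

* a joint rescaling of each genetic-variance parameter with its latents
  (the centered random-walk updates alone mix a variance against thousands
  of latents extremely slowly);
* an interweaving move for the measured model that rescales the
  standard-normal genetic latents against $\beta_{0a}$;
* a joint *latent-scale* move for every item-level fit, which rescales
  $(\theta, A, \text{thresholds}, \text{covariate effects},
  \text{variances})$ while dividing the free discriminations, so that the
  only resistance comes from the first (identifying) item.  The latent
  scale is the slowest direction of these posteriors; without this move
  chains agree on scale-invariant quantities ($h^2$, $r_A$, sign of
  moderation) long before they agree on the absolute variance scale.

Item-level chains are initialized from a short phenotypic marginal
maximum-likelihood GRM fit rescaled to the $\alpha_1 = 1$ identification,
which starts the chains near the right latent scale.

Priors (all configurable in source, documented here as the defaults):
$N(0, 10^2)$ on regression coefficients, moderation slopes, log-variance
intercepts and thresholds; half-$N(0, 2.5)$ on genetic/environmental
standard deviations and Cholesky diagonals and half-$N(0, 5)$ on
discriminations — genuinely weak for phenotypes on a standardized scale,
whereas an SD prior as wide as half-$N(0,10)$ concentrates most mass on
implausibly large variances and visibly drags the weakly identified latent
scale of item-level fits upward; $N(0, 10)$ (variance 10) on imputed
missing standardized covariates and missing sum-score moderators, which are
redrawn every iteration (missing at random).  Missing item responses are
simply dropped from the likelihood.

Desk-scale defaults are 2 chains of 2,000 retained iterations after 2,000
burn-in; adaptation happens only during burn-in, so retained draws target
the exact posterior.  Production analyses of real cohort data would use the
classic tens-of-thousands of iterations; the package exposes that through
`mcmc_config()`.

Summaries follow the conventions of Bayesian twin modelling: posterior
means and SDs, 95% highest-posterior-density intervals (shortest-window
algorithm on sorted draws), split R-hat and effective sample size.  A
parameter is read as "significant" when its HPD excludes zero — except
variance components, which are bounded below by zero and must not be tested
this way.

### DIC focus

DIC in hierarchical models depends on what counts as "the likelihood".  We
use the observed-data (conditional) focus: the per-draw deviance is $-2$
times the log density of the *observed* quantities given their direct
parents — the item responses given the latent traits and item parameters in
item-level fits, the standardized scores given the genetic latents and
structural parameters in sum-score fits — and $\hat D$ plugs in posterior
means of parameters *and* latents.  This is the convention of general-
purpose Gibbs samplers, where the deviance monitor covers the observed
stochastic nodes.  An earlier variant that added the latent phenotype layer
to the item-form deviance was abandoned: that term moves with the weakly
identified latent scale, so independently run fits of the *same* model
differed by tens of deviance units of pure Monte Carlo noise.  The focus is
held fixed across every pair of compared models, so within-form comparisons
(GxE vs no-GxE) are internally consistent; DIC values are never compared
across the sum and item forms, whose data terms differ.

## The synthetic-data generator

The generator emulates the structure of adult twin-register well-being
data without reproducing any cohort's actual values:

* three bundled GRM banks: `"swls"` (5 items, 7 categories), `"shs"`
  (4 items, 7 categories, two reverse-coded) and `"fssq"` (8 items,
  5 categories).  Threshold locations were calibrated once so that sum
  scores at $\theta \sim N(0,1)$ hit the skewness regimes such scales show
  in practice (about $-1.1$, $-1.2$ and $-2.2$ with raw kurtosis near 4.3,
  4.3 and 9); the first discrimination of each bank is 1 so generating and
  fitted parameters share a scale;
* latent heritability defaults of 0.45 with unit total variance, genetic
  correlations with a social-support-like moderator of 0.5–0.75, small
  negative sex and age effects on the latent mean, pair-shared sex and age
  with age standardized within sample;
* DZ genetic values as $\sqrt{.5}\,(\text{common} + \text{specific})$,
  matching the model's own decomposition;
* completely-at-random missingness on items and covariates, with the
  pre-masking truth retained for audits;
* sum scores computed only when at most one item is missing, the missing
  item filled by person-mean imputation (keeping sums on a common scale);
  skewness as adjusted Fisher-Pearson, kurtosis raw (normal = 3) by
  default and excess by option — the convention is configurable because
  published scale descriptions rarely state it.

What the generator does *not* emulate: item-level response styles
(acquiescence, extreme responding), non-normal latent distributions,
longitudinal structure, missing-not-at-random mechanisms, and C/D variance
components.  Passing tests therefore show that the estimators behave
correctly when the model's assumptions hold and that skewed *measurement*
alone produces the spurious interaction; they do not certify behavior under
every real-data pathology.

## Numerical choices and degenerate inputs

* GRM probabilities are floored at $10^{-300}$ inside log-likelihoods;
  threshold proposals that violate the ordering are rejected rather than
  transformed.
* EAP scoring and MML fitting use a fixed 61-point grid on $[-6, 6]$;
  tests verify EAP against a 10-times-denser grid.
* MML fitting is Bock-Aitkin EM with per-item M-steps on expected count
  tables; items observed in a single category are excluded with a warning;
  ordered thresholds are maintained through a log-spacing parametrization
  with a floor on the spacings.
* Empty datasets give log-likelihood 0 (empty product); an all-missing
  response vector returns the prior in EAP scoring and is an error in
  model fitting.
* Proposal scales adapt by Robbins-Monro toward acceptance 0.44 (scalar)
  or 0.234 (blocks), clamped to a safe range, burn-in only.
* Seeding: one master seed per run; chain $c$ uses `seed + c - 1`; the
  generator derives all its sub-streams from the config seed, so datasets
  and fits are reproducible bit-for-bit.

## Open design choices, resolved

* **Moderator latent structure (item form):** the moderator gets its own
  AE decomposition (MZ share, DZ correlation one half), which is what
  induces correlated co-twin moderator latents.  A zygosity-specific free
  correlation would also identify; the AE structure was chosen because the
  moderator is itself a heritable phenotype in the motivating setting.
* **Covariates on the moderator's latent mean:** off by default; sex and
  age enter the trait mean only.  With moderator main effects regressed
  onto the trait this choice affects only the moderator's own location,
  and keeping its mean at zero matches the sum-score form, where the
  moderator is standardized.
* **Heritability reference level:** $h^2$ is reported at $A = 0$
  (unmeasured) or $M = 0$ (measured, the standardized moderator mean).
  Any other reference is available through `derive_h2(..., at = )` or the
  moderation curve.
* **Item parameters shared between phenotypic and unified fits:** the
  unified fits re-estimate item parameters rather than fixing them at
  phenotypic estimates; the phenotypic MML fit only initializes.
* **Kurtosis convention:** raw by default (see generator notes).

## Problem sizes used in validation

The packaged tests and the acceptance script run at desk scale, chosen
once: spurious-GxE reproduction at 1,500 pairs; unmeasured-GxE recovery at
1,000 pairs; measured-moderator recovery at 1,500 pairs; DIC model
selection at 300 pairs (with the longest chains of the suite, because the
DIC contrast is a few deviance units and Monte Carlo error in the mean
deviance must sit below it); bivariate recovery at 500 pairs; calibration
coverage at 300 pairs on the generator's continuous latent, where the
fitted model is exactly the generating one.  These sizes sit inside the
range of the motivating twin-register analyses (roughly 1,800–4,000
complete pairs per phenotype) while keeping a full validation run on one
desktop core within tens of minutes.

One power limit is worth stating plainly: detecting moderation of the
*E* variance of magnitude 0.15 on the log scale through an item-measured
moderator is far beyond these sample sizes.  The posterior SD of the
E-moderation slope is about 0.2 at 1,500 pairs and shrinks with the square
root of the sample, so credible intervals that exclude zero for such a
slope would require tens of thousands of pairs; at desk scale only the
sign and the direction of the heritability curve are reliably recovered.
The A-moderation slope, which is roughly twice as large in the generating
design, is usually significant at these sizes.

## Known limitations

* The sampler is a random-walk scheme; for much larger models (many
  scales, tens of items) a gradient-based backend would mix better.  The
  contracts (`fit_twin_model`, `PosteriorSummary`-style output) are
  backend-agnostic.
* DIC with the conditional focus penalizes weakly; it reliably separates
  models that differ in fit, but comparisons of nearly-equivalent models
  (e.g. GxE vs no-GxE on null item-level data) carry Monte Carlo noise of
  a few deviance units at desk-scale chain lengths.
* Absolute variance components in item-level fits are identified only
  through the first item's unit discrimination; their posteriors are
  accordingly wide at small sample sizes, while variance ratios and
  correlations are much better determined.
* No C/D components, sex-limitation, nonlinear (quadratic) moderation, or
  multidimensional IRT.
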