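---
title: "Models and methods: home-away trait shifts and the join-the-locals test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: home-away trait shifts and the join-the-locals test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointhelocals)
```

## The scientific question

When an invasive plant is compared between its native ("home") range and an
introduced ("away") range, its leaf traits often differ. Enemy-release
reasoning attributes such shifts to relaxed herbivory: with specialist
enemies left behind, invaders can reallocate resources away from defense.
The alternative this package is built to test is environmental: if the
native communities of the two regions differ in the same traits, an invader
that simply tracks the local environment will show the same shift — it
"joins the locals". Distinguishing the two requires comparing, trait by
trait, each invader's home-away shift against the difference in
native-community means between the same two regions.

The package implements the full statistical machinery of such a
three-region, multi-species comparison: a data model for population-level
trait tables, a hierarchical Bayesian model of home-away effects, the
join-the-locals bootstrap regression test, trait-syndrome PCA with mixed
models on component scores, classical regional ANOVA summaries, and a
synthetic-data generator that stands in for field data.

## Data model and transformations

The universal input is a long-format table: one row per sampled population,
with species, the region where it was sampled (France, Japan or USA), the
species' native region, growth form (woody species sampled under forest
canopies; herbaceous species in open habitats), nine leaf defense traits and
four environment covariates (soil pH, gap light index, mean annual
temperature and precipitation). Trait cells may be missing; zeros are legal
only for the two assay-floor metabolites (cyanogenic glycosides, alkaloids).

All traits are strongly right-skewed and are natural-log transformed before
analysis, with one exception: cell wall mass, for which the log makes skew
worse and which therefore stays on the raw scale. The log base is a
documented convention — downstream effects are expressed in standard
deviation (Z) units, so the base cancels. Exact zeros are replaced by half
the smallest positive observed value of that trait before logging, the
standard detection-floor convention; the offset is recorded so the
transformation is invertible (offset-adjusted zeros invert to the offset
value, not to zero).

Each trait is then Z-standardized to mean 0 and SD 1. Standardization is
performed **within growth form** for the univariate and multivariate models,
because woody and herbaceous species are modeled separately; a pooled
(`"all"`) option exists for the cross-region descriptive tables, which mix
growth forms. The per-trait `(center, scale)` pair is stored so that
standardized effects can be mapped back to raw units.

The packaged study design (`read_study_design()`) replicates a 44-species,
three-region sampling plan: 21 woody and 23 herbaceous species, 27 of them
invasive in at least one focal region, with 3–10 populations per species and
region. A home-away contrast exists for every (invasive species, region)
pair where the species was sampled outside its native range; on the packaged
design this rule yields 33 contrasts. One species is listed as native to two
regions; since observations carry a single native region, the first-listed
region is used as primary (the species is not invasive, so no contrast is
affected).

## The hierarchical home-away model

For one trait and one growth form, with standardized values $Y_i$:

$$Y_i \sim N(\alpha_{s(i)} + \beta_{r(i)} \cdot \mathrm{Home}_i,\ \sigma_Y^2)$$
$$\alpha_s \sim N(0, \sigma_S^2), \qquad \beta_r \sim N(0, \sigma_R^2)$$

where $s(i)$ is the species, $r(i)$ the species' *native* region, and
$\mathrm{Home}_i$ is 1 for populations sampled in the native region and 0
elsewhere. $\beta_r$ is thus a home-away effect that varies by native region
(a random slope over regions); positive $\beta$ means larger trait values at
home. Reports expose both sign conventions, since shift plots conventionally
use away-minus-home (`home_away_shift()` returns both). The model follows
the written equations exactly: there is no fixed region-of-sampling offset
in the univariate model; regional structure enters only through the
home-away slope and the species intercepts.

Priors on all three SDs are uniform(0, 100). The "uniform (0–100)" idiom is
read on the SD scale — the standard JAGS reading — and the bound is a
`prior_sd_bound` argument, so the variance-scale reading is one line away.

**Sampling.** All full conditionals are conjugate, so the model is fit by a
hand-written Gibbs sampler: normal updates for $\alpha$ and $\beta$,
truncated-gamma updates for the precisions (exact inverse-CDF draws under
the uniform-on-SD prior), and normal draws for missing $Y$ values, which are
carried as sampled quantities — posterior imputation falls out of the fit.
When a variance component has a single level (the collapsed one-species
check), the truncated-gamma shape is zero and a bounded slice sampler on
$\sigma$ takes over; the conditional remains proper because of the prior
bound. Defaults are three chains of 5000 iterations with a 500-iteration
burn-in. Chains are seeded deterministically from the model seed.

**Diagnostics.** The Gelman-Rubin potential scale reduction factor is
computed for every scalar parameter from the classic between/within-chain
variance formula; identical constant chains return 1 by convention. Any
value above 1.1 (a common working threshold; the diagnostic itself does not
prescribe one) attaches a convergence warning to the fit — never silently.
Goodness of fit is summarized by draw-wise Bayesian $R^2$,
$\mathrm{var}(\hat\mu) / (\mathrm{var}(\hat\mu) + \sigma_Y^2)$, in a
marginal version ($\hat\mu = \beta \cdot \mathrm{Home}$, home-away structure
only) and a conditional version ($\hat\mu = \alpha + \beta \cdot
\mathrm{Home}$, adding species effects); posterior medians are reported.

One data rule is built in: for the cyanogenic glycoside model on woody
species, *Prunus serotina* is excluded by default, because its
concentrations sit two orders of magnitude above every other species in both
ranges and would dominate the standardized scale. The exclusion is an
argument, not a hard-coded filter.

**Identifiability caveat.** For species sampled only at home (non-invasive
natives), $\alpha_s$ and $\beta_r$ are separated only through the
hierarchical priors, so $\beta_r$ carries an effective uncertainty closer to
$\sigma_S/\sqrt{S_r}$ (species native to $r$) than to
$\sigma_Y/\sqrt{n}$. Parameter-recovery errors of 0.1–0.3 Z units on single
realizations of the packaged design are genuine posterior spread, not
sampler error; the credible-interval coverage checks in the test suite
confirm the calibration.

## The join-the-locals test

For each trait, one point per invader-by-away-region contrast:

* $Y$ — invader shift: mean over the invader's home populations minus the
  mean over its populations in the away region (populations weighted
  equally);
* $X$ — native difference: mean over species native to the invader's home
  region of their species-level means, minus the same for species native to
  the away region. Only species of the same growth form qualify; only
  observations from a species' own native region contribute (away-range
  populations of other invaders never enter a native mean); and the focal
  invader is excluded from its home-region pool to avoid circularity.

Species means are averaged with equal species weights by default, matching
how community means are normally quoted; a population-pooled option is
provided because the original description is ambiguous on this point.
Contrasts are computed on the same transformed scale as the univariate
models by default, with a raw-scale option (used by the printed worked
example: a Japanese woody invader whose SLA means give a shift of −55.7
cm²/g against a native difference of −52.2 — a near-1:1 point).

Under "join the locals", points lie near the 1:1 line and the OLS slope of
$Y$ on $X$ is positive. Because contrasts share native species (the same
community means enter many $X$ values), ordinary regression inference is
invalid; the test instead builds a null distribution by breaking the
pairing: $X$ and $Y$ are each resampled with replacement, independently,
$B = 1000$ times. The one-sided p-value for a positive slope is
$(1 + \#\{b^*_{\mathrm{null}} \ge b_{\mathrm{obs}}\})/(B+1)$ — the
conventional complement with add-one smoothing, so $p \in (0, 1]$ and a
strong positive slope gives a small p. A within-margin permutation of $Y$ is
available behind a flag as a sensitivity variant. The test suite verifies
frequentist size empirically: on null-scenario synthetic data the test
rejects at the 5% level in 3–8% of 500 simulated datasets.

## Multivariate analysis

Missing trait values are replaced by the posterior means of their imputation
draws from the corresponding hierarchical fits; observed cells are never
altered. The completed matrix (per growth form, Z-scaled and re-standardized
after filling) goes into a PCA implemented as an eigendecomposition of the
covariance of the centered columns with divisor $n$ — the historical
`princomp` convention, switchable to $n-1$; the divisor scales eigenvalues
but not variance shares. Components are reported both as raw eigenvalues
and as variance *shares* (eigenvalue over total); with nine Z-scaled traits
a share of 0.27 corresponds to a raw eigenvalue near 2.4. Shares are the
natural cross-study quantity, and the headline component magnitudes in this
literature (first components near 0.27 of total variance) are shares. Signs
are fixed by making each component's largest-magnitude loading positive.

Whether PC scores differ between home and away populations is tested with a
linear mixed model: fixed effects of home-away, native region and their
interaction (treatment contrasts, alphabetical reference region, so
reported coefficients are reproducible), plus a species random intercept,
fit by REML through `lmerTest::lmer` with Satterthwaite degrees of freedom
for the Wald tests. A random-slope variant is deliberately not offered —
models of that form do not converge at these group sizes — and singular
fits are flagged in the result rather than hidden. On designs where some
native region has no away-range populations (the packaged plan has no
invasive herbs native to Japan) the interaction is rank deficient and the
affected column is dropped, which the fitting machinery reports.

## Regional descriptive statistics

Cross-region comparisons use classical one-way ANOVA with region as the
predictor, followed by Tukey HSD on all region pairs (the Tukey-Kramer
unequal-$n$ form, since region sample sizes differ) and a compact letter
display computed by insert-and-absorb, with sharing at $\alpha = 0.05$.
Traits are tested on the log scale per the global transform rule, while the
reported group means and standard errors stay in raw units, as such tables
are conventionally printed; both paths are exposed because the scale used
for the original F tests is not documented. Growth-form and single-species
contrasts use the Welch unequal-variance t test — the fractional degrees of
freedom quoted alongside such tests identify the Welch-Satterthwaite form.

## The synthetic-data generator

The generator exists so that every downstream stage is testable without the
field data. On the Z scale of each trait $j$ it draws

$$Y = m_{j,\mathrm{region\ sampled}} + \alpha_{j,s} + \beta_{j,r}\cdot
\mathrm{Home} + \varepsilon,$$

with species intercepts $\alpha_{j,s} \sim N(0, \sigma_{Sj}^2)$, realized
home-away effects $\beta_{j,r} \sim N(\bar\beta_{j,r}, \sigma_{Rj}^2)$ per
native region, residual noise $\varepsilon \sim N(0, \sigma_{Yj}^2)$, and
fixed region offsets $m$ keyed to the *sampling* region — the environment
acts on the plant where it grows. Z values are mapped to raw units through
fixed per-trait anchors (log-normal except cell wall mass) whose means sit
near the study's regional grand means; the anchors are cosmetic and cancel
under the log/Z transform. One observation is generated per population (the
analysis operates on population means; leaf-level replication is not
simulated), trait cells are masked completely at random at a configurable
rate, and environment covariates are region-level constants plus noise.

Defaults are chosen to match the study conditions: the packaged 44-species
design; $\sigma_S = 0.5$, $\sigma_Y = 0.3$ — species differences dominating
within-species residual spread, as observed for these traits — and a 5%
MCAR missingness rate, a typical assay-failure fraction, since the original
missingness pattern is not documented. Missingness is MCAR only; the
hierarchical imputation assumes ignorability either way.

Three scenario presets encode the two conceptual hypotheses plus a null:

* **`join_the_locals`** — region offsets differ across regions and invaders
  carry no intrinsic home-away effect ($\beta = 0$): each invader's shift
  then equals the native regional difference up to sampling noise, so
  shift-vs-difference points fall on the 1:1 line. (An equivalent
  formulation keys offsets to native region and sets $\beta$ to the
  between-region offset difference; offsets on the sampling region were
  chosen as the cleaner generative reading — traits follow the environment
  where the plant grows.) Offsets are nonzero for seven of the nine traits,
  zero for cyanogenic glycosides and weak for C:N, mirroring the trait
  pattern the test is expected to find: the full pipeline on this preset
  detects the positive relationship in at least 7 of 9 traits.
* **`enemy_release`** — offsets equal everywhere, $\beta = +0.6$ for all
  native regions: invaders shift but native differences are pure noise, so
  the regression slope is near zero.
* **`null`** — all offsets and effects zero; used for size/calibration
  checks.

Ground truth (realized intercepts, realized $\beta$, the pre-missingness Z
matrix, the mask) is returned with every table. Because the analysis
re-standardizes the *realized* data, generator-scale effects are converted
to the fitted model's scale through `truth_on_analysis_scale()` — an exact
slope-unit conversion via the anchor SD and the recorded standardization
scale — before any recovery comparison.

## Numerical choices and problem sizes

* Truncated-gamma precision draws use inverse-CDF sampling (`qgamma` on a
  uniform restricted above the truncation point), exact and rejection-free;
  the slice sampler used for single-level variance components is the
  shrinkage variant on the bounded support.
* The bootstrap regenerates any resample whose $X$ draw is degenerate
  (all-equal), so every null replicate is a valid slope; ties at the
  observed slope count toward the p-value.
* Compact letters are assigned in order of each letter set's first group,
  making displays order-independent and reproducible.
* Pipeline determinism: one master seed fans out to per-stage seeds through
  a fixed integer derivation (`stage_seed()`), so the whole run is
  byte-reproducible and any single stage can be re-run in isolation from
  the manifest.
* Test-suite problem sizes balance fidelity against runtime: sampler
  oracles and recovery checks run at the packaged design size (about 190
  woody observations) with full or 2500-iteration chains; the 100-dataset
  coverage study uses a reduced 12-species design with 600-iteration
  chains; bootstrap calibration uses 500 null datasets at $B = 1000$.

## What the synthetic checks do and do not show

Passing tests establish that the estimators are correct and calibrated
*under the generative model*: Gaussian effects on the log scale, MCAR
missingness, exchangeable species, independent populations. Real field data
violate several of these in known ways — phylogenetic covariance among
species, spatial autocorrelation among populations, environment-driven
trait variation within regions, non-ignorable missingness — and none of
those features are simulated. Conclusions about the field system therefore
rest on the original data; the package guarantees only that, given data of
the assumed structure, its numbers mean what they claim. Other known
limitations: no model comparison (DIC/WAIC) is provided; the univariate
model has no region-of-sampling fixed effect by construction; and the
compact-letter display is exact only for the all-pairs Tukey family it is
given.
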