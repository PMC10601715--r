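---
title: "Methods: meta-analysis of plastic residue effects on soil microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of plastic residue effects on soil microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastmeta)
```

## The problem

Plastic residues — from nanoplastics below 1 µm to macroplastic film
fragments above 25 mm — accumulate in soils and perturb the microbial
communities that drive soil biogeochemistry. Individual incubation and field
experiments report contradictory responses of microbial biomass, diversity
and function, so the question is inherently synthetic: across many published
control-versus-plastic comparisons, what is the average response of each
community parameter, what moderates it (material, dose, particle size,
exposure time, ecosystem), and are there dose or size thresholds where the
response changes direction?

`plastmeta` implements the full analysis chain for this synthesis:
observation-level effect sizes, random/mixed-effects pooling, subgroup
heterogeneity tests, a dose-response model cascade ending in broken-stick
threshold estimation, tree-ensemble moderator importance, and
publication-bias screening — plus a synthetic meta-dataset generator with
planted truths so that every estimator can be validated end to end without
any external download.

## Effect sizes

For one comparison with control mean $\bar{x}_c$ and treatment mean
$\bar{x}_t$ (both strictly positive), the effect size is the log response
ratio

$$\mathrm{lnRR} = \ln \bar{x}_t - \ln \bar{x}_c,$$

with delta-method sampling variance

$$v = \frac{s_t^2}{n_t \bar{x}_t^2} + \frac{s_c^2}{n_c \bar{x}_c^2}.$$

Observations with non-positive means are excluded with a logged reason
rather than offset-shifted: the ratio is undefined for them and silent
shifts bias the synthesis.

**Missing SDs.** Reported SDs are frequently missing. They are imputed as
(group mean) × (average coefficient of variation), where the CV pool is all
complete control/treatment groups of the same parameter; a pool smaller
than `min_pool` (default 3 CVs) falls back to the dataset-wide pool. An
observation has at most two CVs of its own, which is too few to average
stably — pooling within parameter matches the practice of CV-based
imputation in ecological meta-analysis. Imputed groups are flagged, never
silently filled.

**Ordination-derived effects.** β-diversity and community-structure shifts
are scored from the first two ordination axes of published plots. With
$D_c$, $D_t$ the mean pairwise Euclidean distances within the control and
treatment clouds and $D_b$ the mean distance over all between-group pairs,

$$\mathrm{lnRR}_b = \ln(D_t / D_c), \qquad
  \mathrm{lnRR}_s = \ln\!\big(D_b / (D_c + D_t)\big).$$

Two choices here were genuinely open. First, we use the mean of *pairwise*
distances, not centroid distances — the plain reading of "Euclidean
distances among samples", and the version our brute-force oracle tests.
Second, the structure ratio's denominator is the sum $D_c + D_t$ rather
than its average; the two differ only by the additive constant $\ln 2$, so
ordering and significance of comparisons are unaffected, and the sum is
what the definition of the denominator quantity states. Both ratios are
invariant to jointly rescaling all coordinates, so digitized plots need no
common scale.

**Functionality.** Soil functionality is synthesised by pooling the effect
sizes of the functional indicators (default list: FDA hydrolysis, soil
respiration, C-, N- and P-acquisition enzymes, oxidative decomposition
enzymes; user-overridable). Indicator directions are pooled as-is, with no
sign harmonisation — an overall functionality gain can legitimately coexist
with a C-acquisition decline, and flipping signs would presuppose which
direction is "good".

## Pooling and heterogeneity

Random-effects pooling uses inverse-variance weights $w_i = 1/(v_i +
\tau^2)$. The heterogeneity variance $\tau^2$ is estimated by REML
(default; the modern standard) or the closed-form DerSimonian–Laird moment
estimator (fast, and an independent cross-check); both are truncated at
zero. Confidence intervals use the normal quantile by default (a
$t$-option exists); an effect is significant when its 95% CI excludes
zero. With $\tau^2 = 0$ the pooling reduces *exactly* to fixed-effects
inverse-variance weighting, which the tests assert algebraically.

Subgroup (mixed-effects) analyses fit the weighted categorical moderator
model with a common residual $\tau^2$, then decompose the weighted sum of
squares about the grand mean into within-level heterogeneity and the
between-group statistic $Q_m$, referred to $\chi^2_{\,\mathrm{levels}-1}$.
The decomposition $Q_{total} = Q_m + \sum Q_{within}$ is exact for any
common weight vector and is tested to $10^{-8}$. A level enters only with
*strictly more than* `min_n = 5` observations — the printed rule is "more
than 5", and we implement it as printed (configurable). Both the $\tau^2$
estimate and $Q_m$ agree with `metafor::rma()` on the same model in the
test suite.

Per-parameter p-values are reported raw by default (the reporting
convention this synthesis follows); a Benjamini–Hochberg switch
(`p_adjust = "BH"`) is available.

## The dose-response cascade

For each response/predictor pair the cascade fits, on identical data with
identical (normalised) weights:

1. ordinary least squares (unweighted),
2. weighted least-squares meta-regression (weights $1/(v_i + \tau^2)$),
3. a penalised thin-plate spline smooth (`mgcv::gam`, GCV smoothness).

The smooth is selected only when its AIC undercuts the OLS AIC by at least
2 units; ties and smaller gaps go to the line (parsimony). Only when the
nonlinear model is selected is the broken-stick model fitted:

$$Y = \beta_0 + \beta_1 X + \beta_2 (X - c)\,\mathbb{1}[X > c] + \varepsilon,$$

two joined lines whose slope changes from $\beta_1$ to $\beta_1 + \beta_2$
at the threshold $c$, continuous at $c$ by construction. $c$ is estimated
by Muggeo's iterative linearization (start: sample median; tolerance
$10^{-8}$ on $c$; at most 50 iterations), and the estimate is always
checked against — and if necessary replaced by — a dense 500-point grid
profile of the weighted RSS, then re-polished. The grid profile is shipped
(`fit_segmented_grid()`) as both the fallback and the independent oracle
the tests compare against. The breakpoint SE comes from the final
linearization (delta method on the working covariate).

Numerical conventions worth stating:

* **Weights and AIC.** Weights are normalised to sum to $n$ before any
  fit, so weighted Gaussian log-likelihoods (hence AICs) are comparable
  across candidates on the same data.
* **AIC of the broken stick** adds one unit of 2 for the estimated
  breakpoint. With that honest counting, profiling $c$ on pure-slope null
  data still buys the segmented model an AIC advantage more often than a
  $\chi^2_2$ heuristic suggests (~13% of null simulations clear the 2-unit
  bar); this is why the cascade gates the broken stick behind the
  smooth-versus-line rule instead of comparing it to the line directly.
* **Degenerate breakpoints.** If no interior breakpoint improves on the
  straight line, the linear fit is returned with `breakpoint = NA` and a
  warning — never a boundary artefact.
* **Raw predictor scales.** Dose (g/kg), size (µm) and time (days) are
  fitted on the raw scale, because the thresholds of interest are read on
  those scales.
* **Sign-change thresholds.** `zero_crossing()` scans the fitted mean
  response on a 1000-point grid and refines the first sign change by
  bisection to $10^{-10}$; `NA` when the curve never changes sign.

## Moderator importance

Three tree-ensemble views of the same question — which moderators are most
associated with an effect-size set:

* a random forest's permutation importance (%IncMSE), with an optional
  permutation p-value per predictor from response-permuted refits;
* gradient-boosted trees' relative influence (split gain aggregated per
  predictor, normalised to sum to 100);
* a weight-aware forest in which bootstrap samples are drawn with
  probability proportional to the meta-analytic weights and importances
  averaged over replicates.

Moderators enter in both continuous and categorical form, as the source
analyses did. Rows missing a modeled predictor are dropped per model, with
counts logged, so per-model $n$ varies. Hyperparameters (forest: 1000
trees, `mtry = ceiling(p/3)`; boosting: 1000 trees, learning rate 0.01,
depth 3) are conventional defaults and configurable; because importances
are library- and seed-dependent, every test of this module is rank-based
(is the planted driver top-ranked?), never value-based. Under the null the
per-predictor permutation p-values are approximately uniform, so a
family-wise "all predictors non-significant" event has probability well
below one even with no signal; the tests therefore check per-predictor
calibration.

## Publication bias

Two conventional diagnostics with clear decision semantics: Egger
regression of the standard normal deviate on precision (the intercept
estimates small-study asymmetry and is exactly zero on a funnel symmetric
about the pooled effect — tested on an analytically constructed case), and
the Rosenthal fail-safe number (smallest count of zero-effect studies that
would render the Stouffer combined z non-significant; the closed form
$\lceil S^2/z_\alpha^2 - k\rceil$ is tested against brute-force search on
every instance up to $k = 50$). Trim-and-fill and selection models are
deliberately out of scope.

## The synthetic generator

`generate_meta_dataset()` emulates a literature-survey meta-dataset: 48
studies × 15 observations (~710 comparisons); study-level random effects
with $\tau^2 = 0.04$; lognormal control means (meanlog $\ln 10$, sdlog
0.5); within-group replicate measurements (3–6 per group) drawn lognormal
with CV 0.15, typical of enzyme and biomass assays, whose sample means and
SDs become the reported values; 10% of SD cells blanked; moderators drawn
as doses lognormal over 0.1–100 g/kg, sizes log-uniform over 0.1–30000 µm,
times uniform over 1–365 d, and categorical ecosystem/material mixes.
True effects are additive on the lnRR scale: parameter base effects
(biomass and SOC negative, most functional activities positive,
C-acquisition negative), material shifts for richness (PE negative, PP
positive), and a planted hormetic broken stick in dose for the functional
indicators (slope +0.004 per g/kg up to c = 40 g/kg, −0.001 beyond — a
positive but declining plateau).

What it does *not* emulate: correlations among moderators, within-study
covariance of observations (observations are treated as independent, as
the screening criteria of such syntheses are designed to ensure),
non-lognormal measurement error, or raw community matrices. Passing tests
therefore demonstrate estimator correctness under a clean generative
model, not robustness to every messiness of real extracted data.

**The dose-gradient recovery experiment.** The survey-style defaults are
deliberately noisy ($\tau^2 = 0.04$, CV 0.15, right-skewed doses), and
under them a threshold at 40 g/kg with slopes of a few thousandths per
g/kg is not statistically identifiable at $n = 400$ — a design-stage power
simulation put the probability of landing within ±10% of the truth below
30%. Recovery contracts are therefore tested under a designed controlled
experiment, `dose_gradient_config()`: functionality observations only,
doses uniform over 0.1–100 g/kg so both limbs of the stick are covered,
assay CV 0.05, negligible extra heterogeneity, no missing SDs. This is the
standard logic of a recovery study: the experiment is designed so that the
estimator, not the data supply, is what is being tested. Under it the
planted threshold is recovered within ±10% in ≥90 of 100 seeds.

`generate_ordination()` draws bivariate normal clouds; the expected mean
pairwise within-group distance is $\sigma\sqrt{\pi}$, so the expected
β-diversity ratio is $\ln(\sigma_t/\sigma_c)$ — the scaling law the
Monte-Carlo tests assert.

## Problem sizes used by the test suite

The suite runs entirely from code-generated data: 1000 simulated
meta-datasets of $k = 50$ for CI calibration; 500 + 200 simulations for
the $Q_m$ size and power checks; 100 seeds × 400 observations for
breakpoint recovery plus 50 random instances against the grid oracle; 20
seeds for the importance rankings; 200 replicates of $k = 100$ for Egger
calibration. These sizes keep the full suite under a minute on one CPU
while leaving Monte-Carlo margins comfortably inside the asserted bands.

## Known limitations

* Observations are modeled as independent; no multilevel (study-nested)
  variance structure is offered.
* One breakpoint only; multi-break or variance-change models are out of
  scope.
* The functional-indicator list is a configurable convention, not a claim
  about which 16 indicators any particular synthesis used.
* Egger + fail-safe N are stand-ins with the same decision semantics as
  whatever bias screen a given synthesis ran; they are not a re-derivation
  of any specific supplementary method.
* Boundary conventions (dose 10 g/kg classed "high", day 7 classed
  "short", size 5 mm classed "micro") follow the printed class
  definitions; the dose boundary itself is unassigned in the usual "<10
  low / >10 high" phrasing and we close the interval on the high side.
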