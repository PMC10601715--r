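# plastmeta

Meta-analysis of how plastic residues (nano- to macroplastics) affect soil
microbial community parameters — biomass, α/β-diversity, community
structure, and functionality — for researchers synthesising
control-versus-plastic comparisons from the literature.

## What it computes

Each observation is one control/treatment comparison with group means,
SDs and replicate counts. The package implements the full chain:

* **Effect sizes.** Log response ratio `lnRR = ln(x̄t) − ln(x̄c)` with
  variance `v = st²/(nt·x̄t²) + sc²/(nc·x̄c²)`; missing SDs imputed as
  mean × pooled CV; β-diversity and structure effects from ordination
  coordinates, `lnRRb = ln(Dt/Dc)` and `lnRRs = ln(Db/(Dc+Dt))`, where
  `Dc`, `Dt`, `Db` are mean pairwise Euclidean distances within and
  between groups.
* **Pooling.** Random-effects weights `wi = 1/(vi + τ²)` with τ² by REML
  (default) or DerSimonian–Laird; 95% CI significance rule; categorical
  mixed-effects subgroup analyses with the between-group heterogeneity
  statistic `Qm` (χ², levels − 1 df), levels admitted only with more than
  5 observations.
* **Dose-response thresholds.** Model cascade — OLS, weighted
  meta-regression, penalised spline — selected by the 2-unit AIC rule;
  when the smooth wins, the broken-stick model
  `Y = β0 + β1X + β2(X−c)·1[X>c] + ε` estimates the threshold
  ("infection point") `c` by Muggeo iterative linearization, checked
  against a dense grid-search oracle; `zero_crossing()` finds where a
  fitted response changes sign.
* **Moderator importance.** Random-forest %IncMSE (with permutation
  p-values), boosted-tree relative influence (sums to 100), and a
  weighted bootstrapped-preselection forest.
* **Publication bias.** Egger regression and the Rosenthal fail-safe
  number.
* **Synthetic data.** `generate_meta_dataset()` / `generate_ordination()`
  draw full meta-datasets and ordination clouds with planted truths
  (including a hormetic dose-response with a breakpoint at 40 g/kg), so
  every estimator is testable offline.

See the methods vignette
(`vignettes/plastic-residue-meta-analysis.Rmd`) for the model details and
design decisions.

## Worked example

```r
library(plastmeta)

gen <- generate_meta_dataset(synthetic_config(), seed = 42)
eff <- compute_effect_sizes(gen$observations)
forest <- meta_table(eff)
subset(forest, parameter %in% c("functionality", "biomass", "richness", "c_acq"))

#>        parameter   k mean_effect  ci_low ci_high significant
#> 1        biomass  77     -0.0896 -0.1457 -0.0335        TRUE
#> 2          c_acq  89     -0.0103 -0.0696  0.0489       FALSE
#> 13 functionality 385      0.0528  0.0268  0.0788        TRUE
#> 8       richness  79     -0.0319 -0.0959  0.0320       FALSE
```

Biomass is significantly depressed and pooled functionality significantly
raised — the planted truths of the generator (−0.07 and a positive
dose-dependent composite) recovered from 720 noisy comparisons; `k` is
the number of observations pooled per parameter. Subgroups and
heterogeneity:

```r
subgroup_qm(eff$lnrr, eff$variance, eff$ecosystem)
#> Subgroup heterogeneity: Qm = 2.287, df = 3, p = 0.5151 (k = 720)
#>   bare         k = 150  0.0374 [-0.0047, 0.0796]
#>   cropland     k = 342  0.0158 [-0.0122, 0.0437]
#>   forest       k =  79  0.0173 [-0.0411, 0.0756]
#>   grassland    k = 149  -0.0086 [-0.0510, 0.0338]
```

No ecosystem dependence was planted, and `Qm` finds none. Threshold
recovery from a designed dose gradient:

```r
dg  <- generate_meta_dataset(dose_gradient_config(), seed = 43)
de  <- compute_effect_sizes(dg$observations)
t2  <- estimate_tau2(de$lnrr, de$variance)
fit_segmented(de$amount_g_per_kg, de$lnrr, 1 / (de$variance + t2))
#> segmented fit (n = 400): AIC = -1569.27, r2 = 0.611, p = 3.93e-82
#>   breakpoint c = 40.3831 (se 1.3642); slopes 0.00394 -> -0.00108
```

The planted breakpoint (40 g/kg) and both planted slopes (+0.004,
−0.001) are recovered within one standard error.

`run_pipeline()` orchestrates all stages from a single config (list or
YAML/JSON file) and writes `effects.tsv`, `forest.tsv`, `subgroups.tsv`,
`dose_models.tsv`, `importance.tsv`, `bias.tsv` and a machine-readable
`report.json` into one results directory.

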