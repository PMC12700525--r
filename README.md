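# odoshift

Estimation of poleward range shifts and emergence-phenology shifts of
dragonflies and damselflies (Odonata) from opportunistic occurrence records,
between a historical (1980–2002) and a recent (2008–2018) time period — the
full analysis pipeline from raw records to driver models, for macroecologists
working with aggregated citizen-science and museum data.

## What it computes

For each species the package estimates:

* **Northern range limit** per period, as the mean distance from the equator
  of the *k* = 10 most northern occurrence points,
  `L = mean(lat_(n-9:n)) × 111.195` km/degree, and the shift
  `ΔL = L_recent − L_historical` (positive = northward).
* **Emergence onset** per 200 × 200 km equal-area quadrat and period, using
  an optimal-linear-estimation (OLE) endpoint estimator under a Weibull
  domain-of-attraction assumption: the k ≤ 10 earliest distinct days are
  mirrored, the tail shape `v` is estimated from mean log-spacing ratios, the
  extreme-order-statistic covariance `Λ_ij = Γ(2v+i)Γ(v+j)/(Γ(v+i)Γ(j))`
  (j ≤ i) is built from gamma functions, and the onset is the weighted sum
  with weights ∝ `Λ⁻¹1`. Unlike the naive first observation this is nearly
  unbiased under sparse sampling. Species-level phenology shift = unweighted
  mean of per-quadrat shifts within ±35 days, over ≥ 2 quadrats.
* **Randomization null models** that rerun both estimators on datasets with
  the observed sampling structure (same per-stratum counts, observed extreme
  values as bounds) to test whether shifts merely reflect rising sampling
  intensity.
* **ΔCV of flight-season temperature**: per-quadrat interannual coefficient
  of variation of April–October mean maximum temperature, averaged over each
  species' occupied quadrats, recent minus historical.
* **Driver models**: phenology shift ~ range shift + continent, and range
  shift ~ range geography + ΔCV + functional traits (with backward
  elimination of non-significant traits), each as a Gaussian GLM and as a
  Bayesian phylogenetic mixed model (conjugate Gibbs sampler with a
  phylogenetic random effect), plus phylogenetic signal (Pagel's λ with a
  likelihood-ratio test, Blomberg's K with a permutation test).

A synthetic-data module simulates all four input streams (occurrences,
gridded monthly temperature, trait table, phylogeny) with known ground truth,
so the whole pipeline is testable end to end without any download.

## Worked example

```r
library(odoshift)
cfg <- analysis_config(n_null_iterations = 100, seed = 42)
run <- run_pipeline(cfg)   # simulates the default 20-species scenario
print(run)
```

```
odoshift pipeline run
range shifts: 20 species; 15 expanding north (75%)
  mean shift 100.5 km overall; 153.4 km among expanders
phenology shifts: 20 species; 13 maintaining/advancing (65%)
  mean shift -2.93 days
  both 65% / range only 10% / phenology only 0% / neither 25% (n = 20)
shift-vs-shift GLM slope -0.826 (p = 8.49e-06), pseudo-R2 75.3%
null models significant at 0.05: range 9.0%, phenology 6.0%
```

The default scenario plants true range shifts spread over [−100, +300] km
with phenology shifts coupled at −0.03 days/km; the run recovers that
structure: most species expand north, emergence advances a few days on
average, and the standardized shift-vs-shift slope is strongly negative.
Per-species estimates sit in `run$range_shifts` and `run$phenology_shifts`:

```r
head(run$range_shifts[c("species", "shift_km")], 4)
#>   species   shift_km
#> 1    sp01 -101.29626
#> 2    sp02  -81.13237
#> 3    sp03  -57.97849
#> 4    sp04  -35.49406
```

(true values for these species: −100, −79, −58, −37 km). The fitted
shift-vs-shift model and the phylogenetic signal of the range-shift response:

```r
run$models$shift_vs_shift_glm
#> Gaussian GLM: mean_shift_days ~ shift_km + continent (n = 20)
#>                     term estimate    se statistic        p
#> 1            (Intercept)  -0.0982 0.181    -0.542 5.95e-01
#> 2               shift_km  -0.8262 0.132    -6.269 8.49e-06
#> 3 continentnorth_america   0.1965 0.257     0.765 4.55e-01
#> AIC 39.20 (null 59.73); pseudo-R2 75.31%

run$signal$range_shift$lambda$lambda   # 0      (traits evolve independently
run$signal$range_shift$k$k             # 0.074   of the planted shifts)
```

`write_run(run, "out/")` exports every table as CSV plus a JSON manifest
recording the configuration, seeds and projection descriptor.

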