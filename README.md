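# phycophys

Quantitative photophysiology and label-free proteomics analysis for
microalgal mutant characterization, built for studies that compare
photosynthetic mutants (e.g. diatom knockouts of chloroplast
protein-targeting components) against the wild type across light regimes.

The package implements, as tested and reusable functions, the full analysis
layer such a study needs:

* **PAM fluorescence** — Fv/Fm = (Fm − F0)/Fm, ΦPSII = (Fm′ − F′)/Fm′,
  Stern–Volmer NPQ = Fm/Fm′ − 1, NPQ induction/relaxation time courses, and
  rapid-light-curve fits of the Webb saturating exponential
  rETR(E) = rETRmax·(1 − e^(−αE/rETRmax)), reporting α, rETRmax and
  Ek = rETRmax/α.
* **Electrochromic shift (ECS)** — three-wavelength deconvolution
  (Cyt c = [554] − 0.4·[520] − 0.4·[563]; ECS_lin = [520] − 0.25·Cyt c),
  fast-phase flash amplitudes with and without PSII inhibitors
  (DCMU + hydroxylamine) giving functional PSII/PSI stoichiometry, and
  absolute electron flow from light-off slope differences normalized by the
  single-charge amplitude.
* **Phenotype** — per-cell pigments, the xanthophyll de-epoxidation index
  DES = Dtx/(Dtx + Ddx), and maximum division rates from log2-linear
  sliding-window fits to cell-count series.
* **Photoinhibition** — high-light (± lincomycin) Fv/Fm time courses
  normalized to initial, first-order photodamage rates from the
  translation-blocked arm, and repair/recovery endpoint metrics.
* **Proteomics statistics** — total-abundance normalization, missingness
  filtering, log2 mutant/WT ratios, a from-scratch
  reproducibility-optimized test statistic (bootstrap top-list
  reproducibility against a permuted null; permutation p-values and FDR),
  published-table selection rules, and log2 → fold/percent conversions.
* **Inference** — two-way fixed-effects ANOVA and Dunnett many-to-one
  comparisons against the wild type via seeded Monte Carlo.
* **Synthetic data** — a generator for every input above with known ground
  truth, including a packaged `"cpftsy_study"` scenario whose truths are
  the published growth rates, photoinhibition fractions, flow reduction and
  per-protein effects, so every estimator can be validated end to end.

## Worked example

Simulate the packaged study's high-light ± lincomycin experiment and
recover the photodamage/repair decomposition:

```r
library(phycophys)
sc <- load_scenario("cpftsy_study")
tc <- gen_hl_linc_timecourse(sc, seed = 11)
analyze_photoinhibition(tc)
#> # A tibble: 2 × 12
#>   line   decline_hl_pct decline_hl_sd decline_linc_pct decline_linc_sd
#> 1 WT               53.3          3.60             30.1            1.29
#> 2 cpftsy           38.9          2.92             29.8            1.57
#>   repair_protection recovery_pct recovery_deficit  n_hl n_linc k_damage
#> 1             23.2          98.6             1.42     3      3   0.0203
#> 2              9.16         68.6            31.4      9      9   0.0202
```

Both arms with blocked repair decline to ~30 % of the initial Fv/Fm
(identical photodamage, k ≈ 0.020 min⁻¹); with repair active the wild type
holds ~52 % at 60 min and recovers to ~96 % after 30 min of dim light,
while the mutant holds only ~40 % and recovers to ~70 % — the quantitative
signature of inefficient PSII repair plus sustained quenching.

A rapid light curve fits in one call:

```r
fit <- fit_light_curve(gen_rapid_light_curve(sc, seed = 2))
fit
#> <light_curve_fit>
#>   alpha    0.5626 rETR per (umol m^-2 s^-1)
#>   rETRmax  60.59 (raw max 61.65)
#>   Ek       107.7 umol m^-2 s^-1
#>   13 points, converged: TRUE
tidy(fit)        # broom-style coefficients
autoplot(fit)    # fitted curve with the Ek marker
```

And published log2 ratios convert directly to the quoted effect sizes:

```r
fold_conversions(c(-1.35, -1.96))
#> # A tibble: 2 × 5
#>   log2_ratio  fold percent_of_reference percent_floor fold_round
#> 1      -1.35 0.392                 39.2            39          0
#> 2      -1.96 0.257                 25.7            25          0
```

i.e. a decline to 39 % and 25 % of wild-type levels.

The whole pipeline (simulate → analyze → report for every stage) runs with
`run_scenario(run_config("cpftsy_study"))`, or from a shell via
`Rscript inst/cli/phycophys.R report --scenario cpftsy_study --out out/`.

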