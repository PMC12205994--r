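# her2strat

HER2 mRNA stratification of breast cancer into six hormone-receptor ×
HER2 subgroups, with survival comparison and immune-signature scoring.

## What it does, and for whom

Antibody–drug conjugates have made the **HER2-low** (IHC 1+/2+,
FISH-negative) and **HER2-ultralow** (IHC 0 with faint/incomplete staining
in ≤10% of cells) strata clinically actionable, but they are defined by
pathology readouts. `her2strat` is for computational researchers who want
to call these strata from microarray expression data instead:

1. **Cutoff calibration** (`derive_her2_cutoffs`) — with the HER2 probe
   `216836_s_at` as a continuous marker and IHC/FISH status as the
   reference, the empirical ROC is computed and the Youden operating point
   *J = max(sens + spec − 1)* selected; the threshold is reported as the
   midpoint of the bracketing observed scores, with its AUC and a
   two-sided Mann–Whitney rank-sum p-value as evidence. Published
   thresholds on the mean-1000-scaled MAS5 intensity scale are ≥3034 for
   positivity and <1780 for ultralow; `her2_cutoffs()` carries them as
   defaults.
2. **Stratification** (`assign_subgroups`) — HER2 class crossed with HR
   status (recorded annotation, or the ESR1 probe `205225_at` ≥ 500 rule)
   into HR±/HER2{+, low, ultralow}; HER2-zero samples excluded.
3. **Survival** (`compare_subgroup_survival`) — Kaplan–Meier curves and
   global + pairwise log-rank tests per endpoint (RFS/DMFS/OS) within each
   HR stratum.
4. **Immune scoring** (`signature_activation_matrix`) — per-gene
   one-vs-rest tests under the dual criterion *p < 0.01 and effective
   AUC > 0.6*, aggregated to percent-significant per signature per
   subgroup, plus overlap fractions between subgroups' hit sets.
5. **Synthetic cohorts** (`generate_cohort`) — log-normal trimodal HER2
   marker with planted class boundaries, imperfect IHC concordance,
   subgroup-dependent hazards and planted signature blocks, so the whole
   pipeline is testable offline with known ground truth.

`run_pipeline()` orchestrates stages 1–4 with a YAML-able configuration and
writes a deterministic JSON report. Readers for plain-TSV and GEO
series-matrix expression files, clinical TSVs, and GMT gene sets are
included (`read_expression_matrix`, `read_clinical_table`, `read_gmt`).

## Worked example

```r
library(her2strat)
co  <- generate_cohort(synthetic_config(seed = 1))   # 510-sample cohort
fit <- derive_her2_cutoffs(co$expression, co$clinical)
print(fit$cut_positive)
#> Cutoff 2965.89 (youden): AUC 0.9108, p 1.63e-30, sens 0.928, spec 0.803 (n = 125/137)
print(fit$cut_ultralow)
#> Cutoff 1796.52 (youden): AUC 0.8549, p 9.02e-31, sens 0.745, spec 0.863 (n = 137/248)
```

The derived thresholds (2966 / 1797 here) estimate the cohort's planted
class boundaries (3034 / 1780): the positivity cutoff separates IHC/FISH
positive from HER2-low samples with AUC 0.91, and both separations are
overwhelmingly non-random (rank-sum p ≈ 1e-30).

```r
report <- run_pipeline(co$expression, co$clinical,
                       co$ground_truth$signature_genes,
                       config = pipeline_config(
                         normalization = list(enabled = FALSE)))
print(report)
#> Pipeline run: ok
#>   normalize  skipped
#>   cutoffs    ok
#>   stratify   ok
#>   survival   ok
#>   immune     ok
#>   cutoffs (derived): ultralow < 1796.52, positive >= 2965.89
#>   subgroup distribution:
#>     HR+/HER2+             99   19.4%
#>     HR+/HER2-low          73   14.3%
#>     HR+/HER2-ultralow    159   31.2%
#>     HR-/HER2+             45    8.8%
#>     HR-/HER2-low          43    8.4%
#>     HR-/HER2-ultralow     91   17.8%
print(report$survival$`rfs.hr_positive`)
#> Survival comparisons (rfs, hr_positive), n = 331:
#>   global                 chi-sq    5.581  df 2  p 0.06138
#>   positive_vs_low        chi-sq    4.758  df 1  p 0.02917  (Bonferroni 0.0875)
#>   positive_vs_ultralow   chi-sq    2.231  df 1  p 0.1353  (Bonferroni 0.4059)
#>   low_vs_ultralow        chi-sq    1.766  df 1  p 0.1839  (Bonferroni 0.5516)
```

Within the HR+ stratum the planted hazard ordering (HER2-low best) shows up
as the positive-vs-low pairwise test at p = 0.029 in this 510-sample draw.
The immune stage recovers the planted signature structure — for example the
interferon block reads 100% activated in HR−/HER2-ultralow and 0–10%
elsewhere (`report$immune$activation$fraction_up`).

The generator is normalization-free by construction (it emits values on the
calibrated analysis scale), hence `normalization = list(enabled = FALSE)`
above; for raw matrices leave the stage enabled and every sample is scaled
to mean 1000 first.

See `vignettes/her2-stratification-methods.Rmd` for the model, parameter
and design rationale, and known limitations.

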