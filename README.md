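# remnantmr

Tools for asking whether triglyceride-rich-lipoprotein (TRL) **remnant
particles** are more atherogenic than **LDL particles**, from lipid-panel
and genotype data.

Both particle types carry exactly one apolipoprotein B (apoB) molecule, so
plasma apoB counts atherogenic particles. If every apoB particle carried
the same risk, the ASCVD risk gradient per unit apoB would not depend on
*which* particles drive the apoB variation. `remnantmr` implements the
full analysis strategy for testing this:

* **Lipid derivations** — non-HDL-C = TC − HDL-C; TRL/remnant-C =
  non-HDL-C − direct LDL-C; Sampson two-variable VLDL-C; per-unit ↔
  per-population-SD odds-ratio rescaling `OR_sd = OR_unit^sd` with
  reference SDs (TRL/remnant-C 0.30, LDL-C 0.82, TG 1.0 mmol/L; apoB
  0.23 g/L; VLDL-C 0.43 mmol/L).
* **GWAS-style variant selection** — per-variant scans adjusted for age,
  sex and five genetic PCs; tiered significance thresholds (1e-21 /
  1e-12 / 5e-8) on the LDL-C-and/or-TRL/remnant-C union; MAF and
  heterozygote-count filters; greedy LD pruning at r² < 0.3 keeping the
  largest combined effect `sqrt(b_LDL² + b_TRL²)`; Holm-adjusted Lp(a)
  exclusion.
* **Summary-statistics Mendelian randomisation** — multivariable
  inverse-variance-weighted (IVW), MR-Egger with pleiotropy intercept,
  and the contamination-mixture estimator, reporting per-unit and per-SD
  odds ratios.
* **SNP effect-size-ratio clustering** — the apoB:TRL/remnant-C
  effect-size ratio assigns variants to a receptor-pathway-like cluster
  (`[0.9, 3.0]`) or a lipolysis-pathway-like cluster (`[-0.75, 0.75]`);
  per-cluster MR contrasts the ASCVD risk gradient per SD apoB.
* **Risk models** — polygenic apoB-raising-allele scores with decile Cox
  hazard ratios and per-10 mg/dL apoB scaling, an apoB × cluster
  interaction test, observational Cox models, and restricted-cubic-spline
  Cox models of TG:LDL-C and TRL/remnant-C:LDL-C ratios with and without
  HDL-C adjustment.
* **A synthetic cohort generator** — block-LD genotypes, a two-pool
  (remnant/LDL particle) lipid model calibrated to the reference SDs, and
  a 12-year censored event process with a configurable per-particle
  hazard gradient, so the whole pipeline is testable without
  access-controlled data.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()` for the result types.

## Worked example

Simulate a 20,000-subject cohort with 150 variants, derive the lipid
exposures, select instruments, and run the multivariable MR plus the
cluster analysis:

```r
library(remnantmr)
library(dplyr)

co <- simulate_cohort(cohort_params(n_subjects = 20000,
                                    n_variants = 150, seed = 42))
subjects <- derive_lipids(co$subjects)
subjects$ascvd <- as.integer(subjects$prevalent_ascvd |
                             subjects$incident_event)

assoc <- assoc_scan_traits(subjects, co$genotypes,
  c("ldl_c_direct", "trl_remnant_c", "apob", "lpa"))
outcome <- assoc_scan(subjects, co$genotypes, "ascvd")
sel <- select_variants(assoc, co$genotypes, tier = 3)   # 60 variants

sel_assoc <- filter(assoc, variant_id %in% sel$variant_id)
wide <- sel_assoc |>
  select(variant_id, trait, beta, se) |>
  tidyr::pivot_wider(names_from = trait, values_from = c(beta, se))
out <- outcome[match(wide$variant_id, outcome$variant_id), ]

fit <- ivw_fit(mr_input(
  cbind(trl_remnant_c = wide$beta_trl_remnant_c,
        ldl_c = wide$beta_ldl_c_direct),
  cbind(wide$se_trl_remnant_c, wide$se_ldl_c_direct),
  out$beta, out$se, snps = wide$variant_id))
report_estimates(fit, sd_table())
#> # A tibble: 2 x 10
#>   exposure      method n_snps or_unit ci_low ci_high or_sd or_sd_low or_sd_high
#>   <chr>         <chr>   <int>   <dbl>  <dbl>   <dbl> <dbl>     <dbl>      <dbl>
#> 1 trl_remnant_c ivw        60    1.64   1.23    2.17  1.16      1.06       1.26
#> 2 ldl_c         ivw        60    1.23   1.11    1.36  1.19      1.09       1.29
#>           p
#>       <dbl>
#> 1 0.000647
#> 2 0.0000463
```

Per 1.0 mmol/L of genetically-determined cholesterol, the odds ratio for
TRL/remnant-C (1.64) exceeds LDL-C's (1.23): a mmol of remnant cholesterol
carries more risk than a mmol of LDL cholesterol. The per-SD column
rescales each by its population SD.

```r
clusters <- cluster_assignments(orient_effects(sel_assoc, "minor_vs_major"))
table(clusters$cluster)
#>          1          2 unassigned
#>         33         24          3

oar <- orient_effects(sel_assoc, "apob_raising")
cluster_mr(oar, outcome, clusters)
#> <cluster_mr>
#>   cluster method n_snps  theta     se or_sd or_sd_low or_sd_high         p
#> 1       2    ivw     24 2.2589 0.5802 1.681     1.294      2.184 9.883e-05
#> 2       2 conmix     24 2.2561 0.5802 1.680     1.297      2.181 1.008e-04
#> 3       1    ivw     33 0.9809 0.1602 1.253     1.166      1.347 9.272e-10
#> 4       1 conmix     33 1.5713 0.2026 1.435     1.280      1.607 8.908e-15
#> cluster 2 vs 1: z = 2.12, p = 0.0337
```

The risk gradient per SD of apoB is steeper when the apoB variation comes
from lipolysis-pathway variants (cluster 2, OR 1.68) than from
receptor-pathway variants (cluster 1, OR 1.25) — the same apoB increment
carries more risk when it sits on remnant particles. The observational
side agrees:

```r
observational_cox(subjects)
#> # A tibble: 2 x 7
#>   exposure      log_hr     se    hr ci_low ci_high          p
#>   <chr>          <dbl>  <dbl> <dbl>  <dbl>   <dbl>      <dbl>
#> 1 ldl_c_direct   0.154 0.0361  1.17   1.09    1.25 0.0000206
#> 2 trl_remnant_c  0.400 0.0896  1.49   1.25    1.78 0.00000820
```

`run_pipeline(run_config(...), out_dir)` executes the whole chain —
simulate → derive → scan → select → MR → cluster → score → observational
models — writing every stage artifact as TSV plus an MD5 manifest;
`pipeline_report(out_dir)` summarises a run. The methods vignette
(`vignettes/remnant-mr-methods.Rmd`) documents the models, the generator's
assumptions and every numerical design choice.

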