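---
title: "Remnant versus LDL atherogenicity: models, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Remnant versus LDL atherogenicity: models, generator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(remnantmr)
```

## The scientific question

Triglyceride-rich lipoproteins (TRL) and their partially lipolysed
"remnants" carry cholesterol into the artery wall, as LDL particles do.
Whether a remnant particle is *more* atherogenic than an LDL particle is a
live question: both particle types carry exactly one apolipoprotein B
(apoB) molecule, so plasma apoB counts atherogenic particles, and one school
of thought holds that risk is purely a function of particle number.
`remnantmr` implements an analysis strategy that addresses the question
three ways:

1. **Multivariable Mendelian randomisation (MR)** of ASCVD on
   genetically-determined TRL/remnant cholesterol (TRL/remnant-C) and LDL
   cholesterol jointly, using GWAS-selected variants as instruments.
2. **Effect-size-ratio clustering of variants.** For each variant the ratio
   of its apoB effect (g/L) to its TRL/remnant-C effect (mmol/L) separates
   receptor-pathway-like variants (concordant remnant + LDL + apoB effects,
   ratios in `[0.9, 3.0]`, "cluster 1") from lipolysis-pathway-like
   variants (remnant/TG effects with little apoB change, ratios in
   `[-0.75, 0.75]`, "cluster 2"). If remnants and LDL were equally
   atherogenic per particle, the ASCVD risk gradient per SD of apoB would
   be the same in both clusters; a steeper cluster-2 gradient indicates
   higher per-particle remnant atherogenicity.
3. **Individual-level survival analyses**: polygenic apoB-raising-allele
   scores per cluster with decile Cox hazard ratios scaled per 10 mg/dL
   apoB, observational Cox models per mmol/L of TRL/remnant-C versus LDL-C,
   and restricted-cubic-spline Cox models of the TG:LDL-C and
   TRL/remnant-C:LDL-C ratios controlling for apoB, with and without HDL-C.

The exposures are derived from a standard lipid panel: non-HDL-C = TC −
HDL-C; TRL/remnant-C = non-HDL-C − directly measured LDL-C; VLDL-C from the
two-variable Sampson equation in TG and non-HDL-C (constants table in
`?vldl_c_sampson`; transcribed working in mg/dL and converted with 38.67
mg/dL per mmol/L cholesterol and 88.57 mg/dL per mmol/L TG). Records whose
derived concentrations come out negative under assay noise are flagged and
excluded from analyses of that trait, never silently clamped.

Per-unit odds ratios are rescaled to per-population-SD via
`OR_sd = OR_unit^sd`; the fixed reference SDs are TRL/remnant-C 0.30
mmol/L, LDL-C 0.82 mmol/L, TG 1.0 mmol/L, apoB 0.23 g/L and VLDL-C 0.43
mmol/L (`sd_table()`), with a cohort-estimated mode available.

## The synthetic cohort generator

Real biobank-scale data are access-controlled, so the package carries a
first-class generator (`simulate_cohort()` and friends) that emulates the
data structure the analyses assume. It is the substrate of the test suite;
its defaults are the package's reference study conditions and are not
adjusted per analysis.

**Latent pools.** Two latent particle pools drive everything: `R`
(TRL/remnant particles) and `L` (LDL particles), in arbitrary particle
units chosen so that 1 unit of `R` carries 1.0 mmol/L cholesterol
(`chol_per_remnant`), 1 unit of `L` carries 0.88 mmol/L
(`chol_per_ldl`), and either particle carries 0.22 g/L apoB
(`apob_per_particle`). Remnants therefore carry ~14% more cholesterol per
apoB than LDL, the qualitative fact that makes per-cholesterol and
per-particle comparisons differ. Cohort means are 0.6 `R`-units and 4.0
`L`-units, giving mean TRL/remnant-C ≈ 0.6 mmol/L, LDL-C ≈ 3.5 mmol/L,
apoB ≈ 1.01 g/L and TC ≈ 5.6 mmol/L — an untreated middle-aged European
population.

**Variant classes.** A mechanism is a property of a locus, so each LD
block (default 5 variants, shared MAF drawn from U(0.05, 0.5)) gets one
mechanism: *receptor* blocks affect `R` and `L` concordantly with
`effect_ldl/effect_remnant ~ U(5.5, 8.5)`, which pins the implied
apoB:TRL/remnant-C effect-size ratio inside `[1.43, 2.09] ⊂ [0.9, 3.0]`;
*lipolysis* blocks act mainly on `R` (`U(-0.3, 0.5)`, implied ratios in
`[0.15, 0.33] ⊂ [-0.75, 0.75]`); *Lp(a)* blocks raise Lp(a) mass, part of
which (30%) the direct LDL-C assay counts as cholesterol — this is what
gives Lp(a) variants a genuine LDL-C association for the Holm exclusion
filter to catch; *null* blocks do nothing. Effect magnitudes are a floor
plus a mild gamma tail, rescaled so the panel explains 30% of each pool's
variance (`h2_remnant`, `h2_ldl`); the floor keeps every causal variant
detectable at cohort scale, so realised (estimated) effect-size ratios stay
close to their implied values — a few strong PCSK9/LPL-like variants arise
from the tail.

**Genotypes.** Haplotypes within a block follow a Markov copy-with-refresh
chain: each allele is copied from its left neighbour with probability
`ld_rho` (default 0.4) or redrawn at the block MAF. This makes the
allele-level (and dosage) correlation between adjacent variants *exactly*
`ld_rho` while preserving marginal frequencies — a thresholded-Gaussian
construction was rejected because dichotomisation attenuates the realised
correlation below the nominal one, which would make the `r^2 < 0.3`
pruning threshold mean something different from what is configured.

**Lipids.** The remnant pool and TG take multiplicative log-normal
residuals (mean-one), keeping both positive and right-skewed as in real
panels; LDL takes an additive Gaussian residual. Residual variances are
solved so the derived TRL/remnant-C, LDL-C, TG and apoB SDs equal the
reference SDs above (±10% is the tested tolerance); `noise_scale = 0`
switches every residual off, making the generative equations exact for
closed-form checks. TC is assembled as LDL-C + remnant cholesterol + HDL-C
+ assay noise, so the non-HDL-C − LDL-C derivation recovers the latent
remnant cholesterol up to a 0.05 mmol/L assay SD. HDL-C is coupled
directly to the remnant pool (−0.7 mmol/L per mmol/L remnant-C), emulating
cholesteryl-ester transfer from HDL to TRL during remnant formation; this
yields corr(HDL-C, TG) ≈ −0.5 and makes HDL-C an informative remnant
proxy, which is what the HDL-adjusted spline models probe. Negative lipid
values are floored at 0.01 mmol/L and counted; more than 1% floored is an
error.

**Outcomes.** Incident events are exponential with log-hazard
`log(0.004) + 0.41·(R − R̄) + 0.16·(L − L̄) + 0.06·(age − 56) +
0.4·[male]`, censored administratively at 12 years (~5% incident events);
prevalent disease is an independent logistic draw with the same linear
predictor (~6.5%). The per-particle gradients 0.41 vs 0.16 encode the
"remnants more atherogenic" truth: per mmol/L they imply hazard ratios
~1.51 (TRL/remnant-C) vs ~1.20 (LDL-C), and per g/L of apoB the
cluster-level log-hazard gradients are ~1.8 (lipolysis-driven) vs ~0.9
(receptor-driven), a 2:1 contrast. The baseline hazard is a free
parameter; 0.004/year was chosen to give a realistic combined event
fraction (~11-12%) for a 40-70-year-old cohort.

**What the generator does not emulate**: real LD beyond within-block AR
structure, population stratification with lipid-correlated PCs (PCs are
null by default), statin initiation during follow-up, left truncation of
prevalent disease, assay batch effects, or non-European architectures.
Passing tests therefore demonstrate correctness of the *machinery* under a
faithful but idealised data-generating process, not robustness to every
artefact of real cohort data.

## Statistical design choices

* **Association scans** (`assoc_scan()`): exact OLS via covariate
  projection for quantitative traits; for binary traits the null-model
  score-test one-step estimator (standard large-cohort GWAS practice),
  with exact per-variant `glm` behind `method = "glm"` (the two agree to
  well within sampling error; tested). Covariates: age, sex, PCs 1-5.
* **Selection pipeline** (`select_variants()`): tier filter (union of
  LDL-C and TRL/remnant-C p-values below 1e-21 / 1e-12 / 5e-8) → MAF >
  0.01 and heterozygote count (the full-scale ≥1000 rule rescaled by
  n/354,104 so it binds at desk scale) → greedy LD pruning in decreasing
  order of `sqrt(beta_ldl² + beta_trl²)`, ties broken lexicographically →
  Holm-adjusted Lp(a) exclusion at 0.05, with the multiplicity family
  being the pruned candidate list. Pruning precedes the Lp(a) filter so
  the Holm family is the final candidate set.
* **IVW** is weighted least squares of outcome on exposure effects with
  weights `1/se_out²`, no intercept, multiplicative random-effects SE
  inflation floored at 1 (fixed-effects by flag). **Egger** adds a free
  intercept after orienting each variant so its first-exposure effect is
  positive (Egger is orientation-dependent; this convention makes it
  deterministic, and the fit is invariant to allele flips of the input).
  **Contamination mixture** profiles a 500-point theta grid spanning ±4
  pooled SEs around the IVW point, each variant classified valid
  (Normal(θ, se)) or invalid (Normal(0, ψ)); ψ defaults to 1.5 × SD of the
  ratio estimates; the CI is likelihood-based.
* **Clustering**: ratios are computed in minor-vs-major orientation (the
  quotient is invariant to allele flips); the denominator is guarded at
  one SE of the TRL/remnant-C effect — a ratio over a noise-level
  denominator is treated as undefined and the variant stays unassigned.
  Interval endpoints are closed. Re-orientation to the apoB-raising
  allele happens only for MR, scores and per-cluster analyses.
* **Survival models**: Cox proportional hazards with Breslow ties (Efron
  by flag); decile hazard models adjust for age and sex; the per-10 mg/dL
  apoB hazard ratio is an inverse-variance-weighted regression of decile
  log-HRs on decile mean apoB *with an intercept*, so it is invariant to
  the choice of reference decile. Spline models use a natural cubic
  spline with 4 knots at the 5/35/65/95% ratio quantiles, ratios
  winsorised at the 0.1/99.9 percentiles, and the curve normalised to
  HR = 1 at the cohort-median ratio (the model being linear in
  covariates, the curve does not depend on the covariate profile).
* **Gene scores** are `Σ w_j · d_ij` with `d` counting apoB-raising
  alleles and `w` the apoB effect in g/L, so the score is a predicted
  apoB and regressing measured apoB on it gives slope ≈ 1 — exactly so
  for uncorrelated variants; residual within-block LD (r² < 0.3 survives
  pruning) double-counts tagged effects and shrinks the calibration
  slope, a known property of marginal-beta scores.

## Reference problem sizes for the statistical checks

The stochastic end-to-end checks in `tests/testthat/test-acceptance.R` run
at these desk-scale reference sizes (the package's own choices, recorded
here so results are interpretable):

* *IVW recovery*: 200 replicates of a two-sample design — selection and
  exposure weights from one 20,000-subject cohort, outcome associations
  from an independent 20,000-subject cohort on the same 60-variant panel.
  The outcome is the prevalent flag, whose generative law is exactly
  logistic with per-mmol/L gradients 0.41 (TRL/remnant-C) and 0.182
  (LDL-C); the check asks for estimates within 2 SE of these in ≥95% of
  replicates. Two design notes. First, a one-sample design under-covers
  badly (scan errors correlated between exposure and outcome), which is
  itself informative about one-sample MR. Second — and this the check
  deliberately leaves exposed — pruning at r² < 0.3 leaves residual
  correlation among retained instruments, and the IVW variance formula
  assumes independence; the model-based SEs are therefore anticonservative
  by roughly 10–15% under these study conditions and 2-SE coverage sits a
  few points below its nominal 95.4% despite essentially unbiased point
  estimates. (Diagnostic experiments: with an LD-free panel, or pruning at
  r² < 0.05, coverage is nominal.) Correlated-instrument IVW with an LD
  matrix is deliberately out of scope, so this check documents a real
  property of the r² < 0.3 convention rather than an implementation
  defect.
* *Ordering recovery*: 60 one-sample replicates at n = 50,000 with 150
  variants, generator defaults (cluster-2 per-apoB gradient 2× cluster
  1's). Two assertions: cluster-2 OR per SD apoB > cluster-1's (IVW), and
  per-10 mg/dL HR ordering from the decile analysis. The second is
  intrinsically marginal at this scale: published full-scale confidence
  intervals for the corresponding per-10 mg/dL hazard ratios imply an
  ordering z-statistic of only ≈2.7 at ~400,000 subjects, so at 50,000
  subjects the ordering reproduces in roughly 85–90% of replicates rather
  than 95% — a power limit of the design at desk scale, not an estimator
  defect; the MR-based ordering is comfortably powered.
* *Null calibration*: tier-3 false selection across 10 null-outcome
  cohorts (≥200 null-mechanism variants); Egger intercept rejection over
  200 null summary-stat replicates; spline-term rejection over 100 null
  cohorts of 2,500 subjects — each within a 3-sigma binomial band of the
  nominal 5%.
* *HDL blunting*: 40 replicates at n = 70,000; the TRL/remnant-C:LDL-C
  spline must be significant without HDL-C and its significance
  attenuated with HDL-C in ≥80%. Attenuation is measured on the spline
  p-value: conditioning on a strong remnant proxy inflates the spline
  term's variance and drains significance, which is how the blunting
  phenomenon presents; the fitted-curve log-HR range barely changes in
  truth (ratio + apoB jointly pin the remnant pool), so a range
  comparison is near chance even when blunting is real.

## Known limitations

Instrument sets at desk scale number tens of variants rather than
hundreds, so contamination-mixture valid-set estimates are coarser than at
biobank scale. The score-test binary scan is a one-step approximation
(excellent for the small per-allele effects relevant here; exact `glm`
available). The decile-based per-10 mg/dL hazard scaling discards
within-decile information by construction; a continuous-score alternative
is available via the combined Cox model in `interaction_test()`. The
generator's LD is block-local and stationary; pruning behaviour on real,
long-range LD (e.g. the extended LPA region) is untested.
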