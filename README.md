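# petdwi

Quantification and statistics for preclinical PET / diffusion-MRI therapy
response studies.

Targeted cancer therapies change tumor physiology before they change tumor
size, so trials in xenograft models read response from functional imaging:
tumor glucose uptake by ^18^F-FDG-PET and tumor cellularity by
diffusion-weighted MRI, validated against terminal immunohistochemistry.
`petdwi` implements that analysis stack for R users — the people running
small-animal imaging studies who need reproducible semiquantification and
defensible small-sample statistics:

* **PET semiquantification** — tumor-to-liver ratio
  `TTL = VOImax_tumor / VOImean_liver` (normalization-free: dose and body
  weight cancel), metabolic tumor volume by percentage-of-maximum
  threshold segmentation (default 30%), and spherical liver background
  VOIs of a target volume (default 9 mm³).
* **ADC mapping** — voxel-wise least-squares fit of the mono-exponential
  model `S(b) = S0 · exp(−b · ADC)` across b-values (default 0/200/800
  s/mm²), log-linear or Levenberg-Marquardt, with a validity mask and the
  VOI median as the per-tumor statistic.
* **Delta-response metrics and cohort analysis** — per-animal follow-up −
  baseline deltas, mean ± sample-SD group summaries.
* **Exact nonparametric inference** — Mann-Whitney U and Wilcoxon
  signed-rank tests with exact enumeration null distributions (mid-rank
  ties, two-sided doubling convention), tie-aware Spearman correlation
  with exact permutation p for small n, Bonferroni adjustment.
* **Digital phantoms** — seeded PET, DWI, and cohort generators with known
  ground truth, and an end-to-end pipeline that images a synthetic cohort
  and pushes it through the full quantification + statistics stack.
* **A packaged study** — the complete per-animal tables of a 21-animal
  BRAF + CDK4/6 inhibitor melanoma xenograft study (12 therapy / 9
  control, imaged at day 0 and day 7) as plain-text fixtures, so every
  published group summary, test, and correlation can be regenerated from
  scratch.

Volumes and masks read/write NIfTI-1 (via RNifti); cohorts are plain CSV.

## Worked example

Reproduce the packaged study's headline analysis:

```r
library(petdwi)

cohort <- load_cohort()          # 21 animals, 12 therapy / 9 control
report <- run_study(cohort)      # summaries, exact tests, correlations

d <- compute_deltas(cohort)
mean(d$d_ttl[d$group == "therapy"])   # -1.00
mean(d$d_ttl[d$group == "control"])   #  0.85

subset(report$tests, comparison == "intergroup_delta" &
         biomarker %in% c("d_ttl", "d_adc_mm2s"))
```

Running `Rscript analysis/03_reproduce_study.R` prints:

```
delta TTL: therapy -1.00 +- 0.53 vs control 0.85 +- 1.21
delta ADC (e-3 mm^2/s): therapy 0.12 vs control -0.12
exact intergroup p: delta TTL 0.00066, delta ADC 0.00033
               pair        rho      p_value          method  n
1 ttl_followup~cd31  0.7846704 2.536955e-05 t-approximation 21
2 ttl_followup~ki67  0.3337662 1.392367e-01 t-approximation 21
3 adc_followup~cd31 -0.8035140 1.150522e-05 t-approximation 21
4 adc_followup~ki67 -0.4149599 6.141432e-02 t-approximation 21
5       d_ttl~d_adc -0.7446395 1.080669e-04 t-approximation 21
77/80 published statistics match at printed precision; 3 whitelisted one-digit gaps
consistent with the published record: TRUE
```

Reading: therapy suppressed glucose uptake (ΔTTL −1.00 vs +0.85, exact
two-sided p = 0.00066) and raised diffusivity (ΔADC +0.12 vs −0.12 ×10⁻³
mm²/s, p = 0.00033), and the follow-up imaging readouts correlate strongly
with microvascular density at explant (TTL–CD31 ρ = 0.78, ADC–CD31
ρ = −0.80). The "whitelisted gaps" are three published correlation
coefficients that differ from the mid-rank recomputation by one unit in
the last printed digit; the comparison report lists them explicitly
instead of hiding them.

The other drivers exercise the synthetic side: `analysis/01…` writes
seeded PET/DWI phantoms as NIfTI with JSON truth sidecars, `analysis/02…`
quantifies them back (TTL 4.009 recovered vs 3.922 truth under noise;
median ADC 0.8020 vs 0.8000 ×10⁻³ mm²/s), and `analysis/04…` runs the
end-to-end pipeline at the study's effect sizes plus a 500-replicate
type-I calibration of the exact U test.

A worked methods discussion — model assumptions, tie conventions,
threshold semantics, what the phantoms do and do not emulate — is in
`vignettes/petdwi-methods.Rmd`.

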