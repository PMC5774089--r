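Package: petdwi
Title: PET and Diffusion-Weighted MRI Biomarkers of Targeted Tumor
    Therapy Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification and statistical analysis of preclinical
    therapy-response imaging biomarkers. Implements PET semiquantification
    (tumor-to-liver ratio, percentage-of-maximum metabolic tumor volume
    segmentation, spherical liver background VOIs), voxel-wise apparent
    diffusion coefficient mapping from multi-b-value diffusion-weighted MRI
    by mono-exponential least-squares fitting, delta-response metrics over
    baseline/follow-up cohorts, and exact small-sample nonparametric
    inference (enumeration-based Mann-Whitney U and Wilcoxon signed-rank
    tests, tie-aware Spearman correlation, Bonferroni adjustment). Ships
    seeded digital phantom generators (PET, DWI, two-group cohorts) with
    known ground truth, the per-animal data tables of a BRAF plus CDK4/6
    inhibitor melanoma xenograft study as plain-text fixtures, and an
    orchestration layer that reproduces every published group summary,
    test, and correlation from those tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
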