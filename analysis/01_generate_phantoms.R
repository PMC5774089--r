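#!/usr/bin/env Rscript
# Generate the digital phantoms used throughout the analysis: a two-
# compartment PET phantom (tumor + liver in background) and a two-
# compartment DWI phantom, both with known ground truth. Images go to
# results/phantoms/ as NIfTI-1 with the truth recorded as JSON sidecars.

library(petdwi)

out <- "results/phantoms"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

pet_cfg <- pet_phantom_config(tumor_profile = "radial-falloff",
                              noise_sd = 0.1, seed = seed)
pet <- generate_pet_phantom(pet_cfg)
write_volume_nifti(pet$volume, file.path(out, "pet_activity.nii.gz"))
write_volume_nifti(pet$truth$tumor_mask, file.path(out, "pet_tumor_voi.nii.gz"))
write_volume_nifti(pet$truth$liver_mask, file.path(out, "pet_liver_voi.nii.gz"))
jsonlite::write_json(
  list(tumor_peak = pet$truth$tumor_peak, liver_mean = pet$truth$liver_mean,
       expected_ttl = pet$truth$tumor_peak / pet$truth$liver_mean,
       noise_sd = pet_cfg$noise_sd, seed = seed),
  file.path(out, "pet_truth.json"), auto_unbox = TRUE, digits = NA)

dwi_cfg <- dwi_phantom_config(
  grid_shape = c(24, 24, 6),
  adc = list(tumor = 0.8e-3, background = 1.6e-3,
             center = c(3.6, 3.6, 6), radii = c(2.5, 2.5, 5)),
  s0 = 100, noise_sd = 2, seed = seed)
dwi <- generate_dwi_phantom(dwi_cfg)
for (i in seq_along(dwi$series$bvalues)) {
  write_volume_nifti(dwi$series$volumes[[i]],
                     file.path(out, sprintf("dwi_b%04d.nii.gz",
                                            dwi$series$bvalues[i])))
}
write_volume_nifti(dwi$truth$tumor_mask, file.path(out, "dwi_tumor_voi.nii.gz"))
jsonlite::write_json(
  list(bvalues = dwi$series$bvalues, adc_tumor = 0.8e-3,
       adc_background = 1.6e-3, s0 = 100, noise_sd = dwi_cfg$noise_sd,
       seed = seed),
  file.path(out, "dwi_truth.json"), auto_unbox = TRUE, digits = NA)

cat("PET phantom: expected TTL",
    round(pet$truth$tumor_peak / pet$truth$liver_mean, 3),
    "| tumor", sum(pet$truth$tumor_mask$data), "voxels | noise SD",
    pet_cfg$noise_sd, "\n")
cat("DWI phantom: tumor ADC 0.8e-3, background 1.6e-3 mm^2/s, b =",
    paste(dwi$series$bvalues, collapse = "/"), "s/mm^2\n")
cat("wrote phantom images and truth sidecars to", out, "\n")
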