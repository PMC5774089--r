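test_that("PET phantom: noiseless ratio, determinism, and config errors", {
  cfg <- pet_phantom_config(noise_sd = 0, tumor_peak_activity = 8,
                            liver_mean_activity = 2)
  ph <- generate_pet_phantom(cfg)
  liver_voi <- ph$truth$liver_mask
  res <- compute_ttl(ph$volume, ph$truth$tumor_mask, liver_voi)
  expect_identical(res$ttl, 4.0)

  # same config + seed -> bit-identical volumes (with noise on)
  cfg_n <- pet_phantom_config(noise_sd = 0.2, seed = 42)
  expect_identical(generate_pet_phantom(cfg_n)$volume$data,
                   generate_pet_phantom(cfg_n)$volume$data)
  expect_false(identical(generate_pet_phantom(cfg_n, seed = 43)$volume$data,
                         generate_pet_phantom(cfg_n)$volume$data))

  expect_error(pet_phantom_config(tumor_center = c(30, 10, 10)), "grid too small")
  expect_error(generate_pet_phantom(
    pet_phantom_config(tumor_center = c(9, 10, 10), tumor_radii = c(4, 3, 3))),
    "overlap")
  expect_error(pet_phantom_config(liver_mean_activity = -1), ">= 0")
})

test_that("PET phantom noise is unbiased around the configured liver mean", {
  cfg <- pet_phantom_config(noise_sd = 0.1, liver_mean_activity = 2)
  means <- vapply(1:50, function(s) {
    ph <- generate_pet_phantom(cfg, seed = s)
    mean(ph$volume$data[ph$truth$liver_mask$data])
  }, numeric(1))
  n_vox <- sum(generate_pet_phantom(cfg)$truth$liver_mask$data)
  se <- 0.1 / sqrt(n_vox * 50)
  expect_lt(abs(mean(means) - 2), 3 * se)
})

test_that("radial-falloff tumor peaks at the center and stays above background", {
  cfg <- pet_phantom_config(noise_sd = 0, tumor_profile = "radial-falloff",
                            background_activity = 0.5, tumor_peak_activity = 8)
  ph <- generate_pet_phantom(cfg)
  tum <- ph$volume$data[ph$truth$tumor_mask$data]
  expect_true(all(tum >= 0.5))
  expect_lte(max(tum), 8)
  expect_identical(ph$truth$tumor_peak, max(tum))
})

test_that("DWI phantom signals follow the mono-exponential closed form", {
  cfg <- dwi_phantom_config(adc = 0.8e-3, s0 = 100, noise_sd = 0)
  ph <- generate_dwi_phantom(cfg)
  expect_true(all(ph$series$volumes[[1]]$data == 100))          # b = 0
  expect_equal(unique(as.numeric(ph$series$volumes[[3]]$data)),
               100 * exp(-0.64), tolerance = 1e-12)             # b = 800

  # noiseless two-compartment map round-trips through the fitter exactly
  cfg2 <- dwi_phantom_config(
    grid_shape = c(12, 12, 4), voxel_dims = c(0.5, 0.5, 2),
    adc = list(tumor = 0.7e-3, background = 1.8e-3,
               center = c(3, 3, 4), radii = c(2, 2, 3)),
    s0 = 100, noise_sd = 0)
  ph2 <- generate_dwi_phantom(cfg2)
  fitted <- fit_adc_map(ph2$series)
  expect_equal(fitted$adc$data, ph2$truth$adc_map$data, tolerance = 1e-12)

  expect_error(dwi_phantom_config(bvalues = 0), "2 distinct")
  expect_error(dwi_phantom_config(adc = 5e-3), "mm\\^2/s")
})

test_that("DWI noise models are seed-deterministic and Rician is non-negative", {
  for (nm in c("gaussian", "rician")) {
    cfg <- dwi_phantom_config(noise_sd = 3, noise_model = nm, seed = 9)
    a <- generate_dwi_phantom(cfg)
    b <- generate_dwi_phantom(cfg)
    expect_identical(a$series$volumes[[2]]$data, b$series$volumes[[2]]$data)
  }
  ric <- generate_dwi_phantom(dwi_phantom_config(noise_sd = 50,
                                                 noise_model = "rician",
                                                 seed = 2))
  expect_true(all(ric$series$volumes[[3]]$data >= 0))
})

test_that("cohort generator hits configured sizes, labels, and degenerate means", {
  zero_sd <- default_biomarker_sim()
  for (nm in names(zero_sd)) {
    zero_sd[[nm]]$baseline_sd <- 0
    zero_sd[[nm]]$delta_sd_therapy <- 0
    zero_sd[[nm]]$delta_sd_control <- 0
  }
  ihc0 <- default_ihc_sim()
  for (nm in names(ihc0)) ihc0[[nm]]$sd_therapy <- ihc0[[nm]]$sd_control <- 0
  coh <- generate_cohort(cohort_sim_config(biomarkers = zero_sd, ihc = ihc0))
  expect_equal(as.vector(table(coh$group)[c("therapy", "control")]), c(12L, 9L))
  expect_equal(coh$ttl_baseline, rep(4.0, 21))
  d <- compute_deltas(coh)
  expect_equal(d$d_ttl[d$group == "therapy"], rep(-1.00, 12))
  expect_equal(d$d_ttl[d$group == "control"], rep(0.85, 9))
  expect_equal(coh$cd31[coh$group == "therapy"], rep(147, 12))

  expect_error(cohort_sim_config(n_therapy = 1), "n >= 2")
  bad <- default_biomarker_sim(); bad$ttl$baseline_sd <- NULL
  expect_error(cohort_sim_config(biomarkers = bad), "missing fields")
})

test_that("cohort generator recovers configured group delta means over seeds", {
  cfg <- cohort_sim_config()
  reps <- 100
  d_ther <- d_ctrl <- numeric(reps)
  for (s in seq_len(reps)) {
    d <- compute_deltas(generate_cohort(cfg, seed = s))
    d_ther[s] <- mean(d$d_adc_mm2s[d$group == "therapy"])
    d_ctrl[s] <- mean(d$d_adc_mm2s[d$group == "control"])
  }
  se_t <- 0.14e-3 / sqrt(12 * reps)
  se_c <- 0.06e-3 / sqrt(9 * reps)
  expect_lt(abs(mean(d_ther) - 0.12e-3), 3 * se_t)
  expect_lt(abs(mean(d_ctrl) + 0.12e-3), 3 * se_c)
})

test_that("paper-sized delta-TTL effect is detected by the exact U test", {
  # configured effect: therapy -1.0 (SD 0.53) vs control +0.85 (SD 1.21)
  cfg <- cohort_sim_config()
  hits <- 0L
  reps <- 200
  for (s in seq_len(reps)) {
    d <- compute_deltas(generate_cohort(cfg, seed = 10000 + s))
    p <- mann_whitney_exact(d$d_ttl[d$group == "therapy"],
                            d$d_ttl[d$group == "control"])$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gt(hits / reps, 0.90)
})
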