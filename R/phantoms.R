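#' PET phantom configuration
#'
#' Describes a two-compartment digital PET phantom: a tumor ellipsoid and a
#' disjoint liver ellipsoid embedded in a uniform background, with optional
#' additive Gaussian noise (truncated at zero, since reconstructed activity
#' is non-negative). Geometry is in mm; activities are in arbitrary units —
#' the tumor-to-liver ratio is scale-free, so no calibration is modeled.
#'
#' @param grid_shape integer length-3, grid size in voxels.
#' @param voxel_dims voxel edge lengths in mm; default 0.5 mm isotropic,
#'   typical of reconstructed small-animal PET.
#' @param tumor_center,tumor_radii mm; ellipsoid center and semi-axes.
#' @param liver_center,liver_radii mm; must be disjoint from the tumor.
#' @param background_activity,liver_mean_activity,tumor_peak_activity
#'   non-negative activities (arbitrary units).
#' @param tumor_profile `"uniform"` (tumor voxels all at peak) or
#'   `"radial-falloff"` (parabolic decline from peak at the center to the
#'   background level at the ellipsoid surface — a stand-in heterogeneity
#'   profile, not a biological claim).
#' @param noise_sd additive Gaussian noise SD (activity units).
#' @param seed integer RNG seed; every random draw in the generator flows
#'   from it.
#' @return A `pet_phantom_config` list.
#' @export
pet_phantom_config <- function(grid_shape = c(40, 40, 40),
                               voxel_dims = c(0.5, 0.5, 0.5),
                               tumor_center = c(6, 10, 10),
                               tumor_radii = c(3, 3, 3),
                               liver_center = c(14.5, 10, 10),
                               liver_radii = c(3.5, 3, 3),
                               background_activity = 0.5,
                               liver_mean_activity = 2,
                               tumor_peak_activity = 8,
                               tumor_profile = c("uniform", "radial-falloff"),
                               noise_sd = 0,
                               seed = 1L) {
  tumor_profile <- match.arg(tumor_profile)
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_dims = check_voxel_dims(voxel_dims),
              tumor_center = as.numeric(tumor_center),
              tumor_radii = as.numeric(tumor_radii),
              liver_center = as.numeric(liver_center),
              liver_radii = as.numeric(liver_radii),
              background_activity = background_activity,
              liver_mean_activity = liver_mean_activity,
              tumor_peak_activity = tumor_peak_activity,
              tumor_profile = tumor_profile,
              noise_sd = noise_sd, seed = seed)
  acts <- c(background_activity, liver_mean_activity, tumor_peak_activity)
  if (any(!is.finite(acts)) || any(acts < 0)) {
    stop("activities must be finite and >= 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  extent <- cfg$grid_shape * cfg$voxel_dims
  for (who in c("tumor", "liver")) {
    ctr <- cfg[[paste0(who, "_center")]]; rad <- cfg[[paste0(who, "_radii")]]
    if (length(ctr) != 3L || length(rad) != 3L || any(rad <= 0)) {
      stop(who, " ellipsoid needs a 3-D center and positive radii", call. = FALSE)
    }
    if (any(ctr - rad < 0) || any(ctr + rad > extent)) {
      stop("grid too small: ", who, " ellipsoid extends outside the ",
           paste(signif(extent, 4), collapse = " x "), " mm grid", call. = FALSE)
    }
  }
  structure(cfg, class = "pet_phantom_config")
}

#' Generate a PET phantom with ground truth
#'
#' Rasterizes the configured tumor and liver ellipsoids (voxel-center-inside
#' rule), paints activities, adds truncated Gaussian noise, and returns both
#' the noisy volume and the generating truth (masks, noiseless hottest tumor
#' voxel, configured liver mean).
#'
#' @param config a [pet_phantom_config()].
#' @param seed optional override of `config$seed`.
#' @return A list with elements `volume` ([image_volume()]) and `truth`
#'   (list: `tumor_mask`, `liver_mask` ([voi_mask()]), `tumor_peak`,
#'   `liver_mean`, `config`).
#' @examples
#' ph <- generate_pet_phantom(pet_phantom_config(noise_sd = 0))
#' compute_ttl(ph$volume, ph$truth$tumor_mask, ph$truth$liver_mask)$ttl
#' @export
generate_pet_phantom <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "pet_phantom_config"))
  gs <- config$grid_shape; vd <- config$voxel_dims
  tumor <- ellipsoid_mask_array(gs, vd, config$tumor_center, config$tumor_radii)
  liver <- ellipsoid_mask_array(gs, vd, config$liver_center, config$liver_radii)
  if (any(tumor & liver)) {
    stop("tumor and liver ellipsoids overlap (", sum(tumor & liver),
         " shared voxels); configure disjoint compartments", call. = FALSE)
  }
  if (!any(tumor) || !any(liver)) {
    stop("a configured ellipsoid rasterizes to zero voxels; ",
         "enlarge it relative to the voxel size", call. = FALSE)
  }
  act <- array(config$background_activity, dim = gs)
  act[liver] <- config$liver_mean_activity
  if (config$tumor_profile == "uniform") {
    act[tumor] <- config$tumor_peak_activity
  } else {
    rho2 <- ellipsoid_rho2(gs, vd, config$tumor_center, config$tumor_radii)
    act[tumor] <- config$background_activity +
      (config$tumor_peak_activity - config$background_activity) * (1 - rho2[tumor])
  }
  true_peak <- max(act[tumor])
  noisy <- if (config$noise_sd > 0) {
    with_seed(seed, pmax(act + stats::rnorm(length(act), 0, config$noise_sd), 0))
  } else act
  noisy <- array(noisy, dim = gs)
  list(volume = image_volume(noisy, vd),
       truth = list(tumor_mask = voi_mask(tumor, vd),
                    liver_mask = voi_mask(liver, vd),
                    tumor_peak = true_peak,
                    liver_mean = config$liver_mean_activity,
                    config = config))
}

#' DWI phantom configuration
#'
#' Describes a multi-b-value diffusion phantom whose noiseless per-voxel
#' signal follows the mono-exponential model `S(b) = S0 * exp(-b * ADC)`.
#' The true ADC field is either constant or two-compartment (a tumor
#' ellipsoid over a background). Noise is added per frame, either additive
#' Gaussian or Rician (magnitude of a complex Gaussian perturbation, the
#' distribution of magnitude MR images).
#'
#' @param grid_shape integer length-3 grid size in voxels.
#' @param voxel_dims mm; default 0.3 x 0.3 mm in-plane, 2 mm slices, a
#'   typical small-animal EPI geometry.
#' @param bvalues s/mm^2, non-negative strictly increasing, >= 2 values.
#' @param adc either a single true ADC (mm^2/s) for a constant field, or a
#'   list `list(tumor = , background = , center = , radii = )` for a
#'   two-compartment field (center/radii in mm).
#' @param s0 true signal at b = 0 (arbitrary units).
#' @param noise_sd noise scale in signal units.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param seed integer RNG seed.
#' @return A `dwi_phantom_config` list.
#' @export
dwi_phantom_config <- function(grid_shape = c(24, 24, 6),
                               voxel_dims = c(0.3, 0.3, 2),
                               bvalues = c(0, 200, 800),
                               adc = 0.8e-3,
                               s0 = 100,
                               noise_sd = 0,
                               noise_model = c("gaussian", "rician"),
                               seed = 1L) {
  noise_model <- match.arg(noise_model)
  check_bvalues(bvalues)
  adc_vals <- if (is.list(adc)) c(adc$tumor, adc$background) else adc
  if (any(!is.finite(adc_vals)) || any(adc_vals <= 0) || any(adc_vals >= 4e-3)) {
    stop("true ADC values must lie in (0, 4e-3) mm^2/s", call. = FALSE)
  }
  if (is.list(adc) && (is.null(adc$center) || is.null(adc$radii))) {
    stop("two-compartment `adc` needs `center` and `radii` (mm)", call. = FALSE)
  }
  if (!is.finite(s0) || s0 <= 0) stop("`s0` must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_dims = check_voxel_dims(voxel_dims),
                 bvalues = as.numeric(bvalues), adc = adc, s0 = s0,
                 noise_sd = noise_sd, noise_model = noise_model, seed = seed),
            class = "dwi_phantom_config")
}

#' Generate a DWI phantom with ground truth
#'
#' @param config a [dwi_phantom_config()].
#' @param seed optional override of `config$seed`.
#' @return A list with `series` ([dwi_series()]) and `truth` (list:
#'   `adc_map` ([image_volume()], mm^2/s), `s0`, `tumor_mask` (`NULL` for a
#'   constant field), `config`).
#' @examples
#' ph <- generate_dwi_phantom(dwi_phantom_config(noise_sd = 0))
#' range(ph$series$volumes[[1]]$data)  # all s0 at b = 0
#' @export
generate_dwi_phantom <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "dwi_phantom_config"))
  gs <- config$grid_shape; vd <- config$voxel_dims
  if (is.list(config$adc)) {
    tumor <- ellipsoid_mask_array(gs, vd, config$adc$center, config$adc$radii)
    if (!any(tumor)) stop("tumor compartment rasterizes to zero voxels", call. = FALSE)
    adc_arr <- array(config$adc$background, dim = gs)
    adc_arr[tumor] <- config$adc$tumor
    tumor_mask <- voi_mask(tumor, vd)
  } else {
    adc_arr <- array(config$adc, dim = gs)
    tumor_mask <- NULL
  }
  frames <- with_seed(seed, {
    lapply(config$bvalues, function(b) {
      s <- config$s0 * exp(-b * adc_arr)
      if (config$noise_sd > 0) {
        if (config$noise_model == "gaussian") {
          s <- s + stats::rnorm(length(s), 0, config$noise_sd)
        } else {
          s <- sqrt((s + stats::rnorm(length(s), 0, config$noise_sd))^2 +
                      stats::rnorm(length(s), 0, config$noise_sd)^2)
        }
      }
      image_volume(array(s, dim = gs), vd)
    })
  })
  list(series = dwi_series(frames, config$bvalues),
       truth = list(adc_map = image_volume(adc_arr, vd), s0 = config$s0,
                    tumor_mask = tumor_mask, config = config))
}

#' Two-group cohort simulation configuration
#'
#' Defines a synthetic baseline/follow-up two-group animal cohort. Each
#' imaging biomarker draws a baseline value from a common Gaussian (groups
#' are randomized, so baselines share a distribution) and a follow-up value
#' as baseline plus a group-specific Gaussian treatment effect. Terminal
#' immunohistochemistry counts are drawn per group and rounded to
#' non-negative integers. The defaults reproduce the observed study
#' conditions: 12 therapy vs 9 control animals with group means/SDs taken
#' from the published per-animal tables.
#'
#' @param n_therapy,n_control group sizes (>= 2 each).
#' @param biomarkers named list; each element is a list with
#'   `baseline_mean`, `baseline_sd`, and per-group delta distributions
#'   `delta_mean_therapy`, `delta_sd_therapy`, `delta_mean_control`,
#'   `delta_sd_control`. Units: `ttl` dimensionless, `mtv_mm3` and
#'   `vol_mm3` mm^3, `adc_mm2s` mm^2/s.
#' @param ihc named list (`cd31`, `ki67`) of per-group count distributions
#'   (`mean_therapy`, `sd_therapy`, `mean_control`, `sd_control`).
#' @param seed integer RNG seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_therapy = 12L, n_control = 9L,
                              biomarkers = default_biomarker_sim(),
                              ihc = default_ihc_sim(),
                              seed = 1L) {
  if (n_therapy < 2L || n_control < 2L) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  need <- c("baseline_mean", "baseline_sd", "delta_mean_therapy",
            "delta_sd_therapy", "delta_mean_control", "delta_sd_control")
  for (nm in names(biomarkers)) {
    b <- biomarkers[[nm]]
    if (!all(need %in% names(b))) {
      stop("biomarker `", nm, "` is missing fields: ",
           paste(setdiff(need, names(b)), collapse = ", "), call. = FALSE)
    }
    sds <- unlist(b[grepl("_sd", names(b))], use.names = FALSE)
    if (any(sds < 0)) stop("biomarker `", nm, "`: SDs must be >= 0", call. = FALSE)
  }
  structure(list(n_therapy = as.integer(n_therapy),
                 n_control = as.integer(n_control),
                 biomarkers = biomarkers, ihc = ihc, seed = seed),
            class = "cohort_sim_config")
}

#' @rdname cohort_sim_config
#' @export
default_biomarker_sim <- function() {
  list(
    ttl = list(baseline_mean = 4.0, baseline_sd = 0.95,
               delta_mean_therapy = -1.00, delta_sd_therapy = 0.53,
               delta_mean_control = 0.85, delta_sd_control = 1.21),
    mtv_mm3 = list(baseline_mean = 185, baseline_sd = 115,
                   delta_mean_therapy = 50.5, delta_sd_therapy = 117.9,
                   delta_mean_control = 355.6, delta_sd_control = 153.3),
    adc_mm2s = list(baseline_mean = 0.785e-3, baseline_sd = 0.10e-3,
                    delta_mean_therapy = 0.12e-3, delta_sd_therapy = 0.14e-3,
                    delta_mean_control = -0.12e-3, delta_sd_control = 0.06e-3),
    vol_mm3 = list(baseline_mean = 112, baseline_sd = 80,
                   delta_mean_therapy = 36.2, delta_sd_therapy = 63.2,
                   delta_mean_control = 247.6, delta_sd_control = 95.1)
  )
}

#' @rdname cohort_sim_config
#' @export
default_ihc_sim <- function() {
  list(cd31 = list(mean_therapy = 147, sd_therapy = 48,
                   mean_control = 287, sd_control = 92),
       ki67 = list(mean_therapy = 3718, sd_therapy = 998,
                   mean_control = 5389, sd_control = 1332))
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-animal baseline and follow-up biomarker values and terminal
#' IHC counts under a [cohort_sim_config()]. Values are truncated to their
#' physical domains (volumes >= 0, ADC in (0, 4e-3) mm^2/s, TTL >= 0.05 as
#' a ratio of positive activities); truncation is negligible at the default
#' settings.
#'
#' @param config a [cohort_sim_config()].
#' @param seed optional override of `config$seed`.
#' @return A `cohort_table` data frame, one row per animal (wide layout),
#'   with the truth attached as attribute `"sim_config"`.
#' @examples
#' coh <- generate_cohort(cohort_sim_config(seed = 7))
#' table(coh$group)
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_sim_config"))
  nT <- config$n_therapy; nC <- config$n_control; n <- nT + nC
  group <- c(rep("therapy", nT), rep("control", nC))
  out <- data.frame(animal_id = seq_len(n), group = group,
                    stringsAsFactors = FALSE)
  with_seed(seed, {
    for (nm in names(config$biomarkers)) {
      b <- config$biomarkers[[nm]]
      base <- stats::rnorm(n, b$baseline_mean, b$baseline_sd)
      dmean <- ifelse(group == "therapy", b$delta_mean_therapy, b$delta_mean_control)
      dsd <- ifelse(group == "therapy", b$delta_sd_therapy, b$delta_sd_control)
      fu <- base + stats::rnorm(n, dmean, dsd)
      if (nm == "adc_mm2s") {
        base <- pmin(pmax(base, 1e-5), 4e-3 - 1e-5)
        fu <- pmin(pmax(fu, 1e-5), 4e-3 - 1e-5)
      } else if (grepl("mm3$", nm)) {
        base <- pmax(base, 0); fu <- pmax(fu, 0)
      } else if (nm == "ttl") {
        # TTL is a ratio of positive activities: floor at a small positive value
        base <- pmax(base, 0.05); fu <- pmax(fu, 0.05)
      }
      out[[paste0(nm_stub(nm), "_baseline", nm_unit(nm))]] <- base
      out[[paste0(nm_stub(nm), "_followup", nm_unit(nm))]] <- fu
    }
    for (nm in names(config$ihc)) {
      h <- config$ihc[[nm]]
      m <- ifelse(group == "therapy", h$mean_therapy, h$mean_control)
      s <- ifelse(group == "therapy", h$sd_therapy, h$sd_control)
      out[[nm]] <- pmax(0, round(stats::rnorm(n, m, s)))
    }
  })
  attr(out, "sim_config") <- config
  class(out) <- c("cohort_table", "data.frame")
  out
}

# Column naming: biomarker config keys carry their unit suffix
# (mtv_mm3, adc_mm2s, vol_mm3); timepoint goes between stub and unit so the
# cohort schema reads ttl_baseline, mtv_baseline_mm3, adc_followup_mm2s, ...
nm_stub <- function(nm) sub("_(mm3|mm2s)$", "", nm)
nm_unit <- function(nm) {
  m <- regmatches(nm, regexpr("_(mm3|mm2s)$", nm))
  if (length(m)) m else ""
}
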