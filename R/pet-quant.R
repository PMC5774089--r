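#' Segment the metabolic tumor volume by percentage-of-maximum threshold
#'
#' Inside a manually drawn guidance VOI, keeps the voxels whose activity is
#' at least `fraction` of the hottest voxel in that VOI (default 30%), the
#' conventional fixed-percentage MTV definition. Ties at exactly the
#' threshold are kept (`>=`), so the maximum voxel is always in its own
#' mask and the result is non-empty. No connected-component filtering is
#' applied. An alternative reading — keep the top `fraction` of voxels by
#' rank — is available as `mode = "top-count"` but is not the default.
#'
#' @param volume an [image_volume()] of PET activity.
#' @param guide_voi a non-empty [voi_mask()] on the same grid.
#' @param fraction threshold fraction in (0, 1); default 0.30.
#' @param mode `"percent-max"` (default) or `"top-count"`.
#' @return A [voi_mask()], subset of `guide_voi`.
#' @examples
#' vol <- image_volume(array(1, c(4, 4, 4)))
#' voi <- voi_mask(array(TRUE, c(4, 4, 4)))
#' sum(segment_mtv(vol, voi)$data)  # uniform volume: whole VOI kept
#' @export
segment_mtv <- function(volume, guide_voi, fraction = 0.30,
                        mode = c("percent-max", "top-count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "image_volume"), inherits(guide_voi, "voi_mask"))
  if (!same_grid(volume, guide_voi)) {
    stop("segment_mtv: volume and guidance VOI are on different grids", call. = FALSE)
  }
  if (!any(guide_voi$data)) stop("segment_mtv: guidance VOI is empty", call. = FALSE)
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    stop("segment_mtv: `fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  vals <- volume$data[guide_voi$data]
  keep <- array(FALSE, dim = dim(volume$data))
  if (mode == "percent-max") {
    keep[guide_voi$data] <- vals >= fraction * max(vals)
  } else {
    # top `fraction` of VOI voxels by activity rank; ties at the cutoff all
    # kept, so the mask can slightly exceed the nominal count
    k <- max(1L, ceiling(fraction * length(vals)))
    cut <- sort(vals, decreasing = TRUE)[k]
    keep[guide_voi$data] <- vals >= cut
  }
  voi_mask(keep, volume$voxel_dims)
}

#' Volume of a VOI mask in mm^3
#'
#' @param mask a [voi_mask()].
#' @param voxel_dims optional override of the mask's voxel dimensions (mm).
#' @return Voxel count times voxel volume; 0 for an empty mask.
#' @export
mtv_volume <- function(mask, voxel_dims = NULL) {
  stopifnot(inherits(mask, "voi_mask"))
  vd <- if (is.null(voxel_dims)) mask$voxel_dims else check_voxel_dims(voxel_dims)
  sum(mask$data) * prod(vd)
}

#' Place a spherical liver background VOI of a target volume
#'
#' Builds an approximately spherical voxel set around `center`: the voxel
#' count is the integer whose total volume is closest to `target_mm3`
#' (default 9 mm^3, the liver background used for TTL normalization), and
#' the voxels selected are those nearest the center, with ties broken by
#' array order for determinism.
#'
#' @param volume an [image_volume()] providing the grid.
#' @param center mm coordinates of the VOI center; must lie inside the grid.
#' @param target_mm3 target VOI volume (mm^3).
#' @return A [voi_mask()].
#' @examples
#' vol <- image_volume(array(0, c(30, 30, 30)), c(0.5, 0.5, 0.5))
#' sum(make_liver_voi(vol, center = c(7.5, 7.5, 7.5))$data)  # 72 voxels = 9 mm^3
#' @export
make_liver_voi <- function(volume, center, target_mm3 = 9) {
  stopifnot(inherits(volume, "image_volume"))
  gs <- dim(volume$data); vd <- volume$voxel_dims
  extent <- gs * vd
  center <- as.numeric(center)
  if (length(center) != 3L || any(center < 0) || any(center > extent)) {
    stop("make_liver_voi: `center` must lie inside the grid (0..",
         paste(signif(extent, 4), collapse = " x "), " mm)", call. = FALSE)
  }
  if (!is.finite(target_mm3) || target_mm3 <= 0) {
    stop("make_liver_voi: `target_mm3` must be > 0", call. = FALSE)
  }
  vv <- prod(vd)
  n_lo <- max(1, floor(target_mm3 / vv)); n_hi <- n_lo + 1
  count <- if (abs(n_lo * vv - target_mm3) <= abs(n_hi * vv - target_mm3)) n_lo else n_hi
  ctr <- voxel_centers(gs, vd)
  d2 <- outer(outer((ctr[[1]] - center[1])^2, (ctr[[2]] - center[2])^2, `+`),
              (ctr[[3]] - center[3])^2, `+`)
  ord <- order(d2)  # stable: ties broken by array index
  sel <- ord[seq_len(count)]
  # reject placements where the nominal sphere is truncated by the grid edge
  r_max <- sqrt(d2[sel[count]])
  if (any(center - r_max < 0) || any(center + r_max > extent)) {
    stop("make_liver_voi: VOI of ", signif(target_mm3, 4),
         " mm^3 would extend outside the grid at this center", call. = FALSE)
  }
  keep <- array(FALSE, dim = gs)
  keep[sel] <- TRUE
  voi_mask(keep, vd)
}

#' Tumor-to-liver ratio and metabolic tumor volume
#'
#' The semiquantitative PET readout: TTL is the hottest voxel inside the
#' tumor VOI divided by the mean activity in the liver background VOI
#' (`VOImax_tumor / VOImean_liver`), a normalization-free uptake measure
#' (injected dose and body weight cancel). The MTV is segmented alongside
#' at the configured threshold fraction.
#'
#' @param volume an [image_volume()] of PET activity.
#' @param tumor_voi,liver_voi non-empty [voi_mask()]s on the volume's grid.
#' @param fraction MTV threshold fraction, see [segment_mtv()].
#' @return A `pet_quant_result` list: `ttl`, `tumor_max`, `liver_mean`,
#'   `mtv_mm3`, `mtv_mask`, `threshold_fraction`.
#' @export
compute_ttl <- function(volume, tumor_voi, liver_voi, fraction = 0.30) {
  stopifnot(inherits(volume, "image_volume"),
            inherits(tumor_voi, "voi_mask"), inherits(liver_voi, "voi_mask"))
  if (!same_grid(volume, tumor_voi) || !same_grid(volume, liver_voi)) {
    stop("compute_ttl: VOIs must be on the volume's grid", call. = FALSE)
  }
  if (!any(tumor_voi$data)) stop("compute_ttl: tumor VOI is empty", call. = FALSE)
  if (!any(liver_voi$data)) stop("compute_ttl: liver VOI is empty", call. = FALSE)
  tumor_max <- max(volume$data[tumor_voi$data])
  liver_mean <- mean(volume$data[liver_voi$data])
  if (!is.finite(liver_mean) || liver_mean <= 0) {
    stop("compute_ttl: liver mean is ", signif(liver_mean, 4),
         "; non-positive background signals a corrupt liver VOI", call. = FALSE)
  }
  mtv_mask <- segment_mtv(volume, tumor_voi, fraction)
  structure(list(ttl = tumor_max / liver_mean,
                 tumor_max = tumor_max,
                 liver_mean = liver_mean,
                 mtv_mm3 = mtv_volume(mtv_mask),
                 mtv_mask = mtv_mask,
                 threshold_fraction = fraction),
            class = "pet_quant_result")
}

#' @export
print.pet_quant_result <- function(x, ...) {
  cat("<pet_quant_result> TTL = ", signif(x$ttl, 4),
      " (tumor max ", signif(x$tumor_max, 4), " / liver mean ",
      signif(x$liver_mean, 4), "); MTV = ", signif(x$mtv_mm3, 5),
      " mm^3 at ", 100 * x$threshold_fraction, "% of max\n", sep = "")
  invisible(x)
}
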