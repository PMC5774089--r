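#' 3-D image volume with voxel geometry
#'
#' Lightweight carrier for a scalar 3-D image grid: PET activity, a single
#' diffusion-weighted frame, or an ADC map. The array is stored as-is; the
#' only geometry retained is the voxel edge length along each axis, which is
#' all the downstream semiquantification needs (volumes in mm^3, VOI
#' placement in mm).
#'
#' @param data numeric 3-D array.
#' @param voxel_dims numeric length-3, voxel edge lengths in mm (x, y, z).
#' @return An `image_volume` object.
#' @examples
#' vol <- image_volume(array(1, c(4, 4, 4)), voxel_dims = c(0.5, 0.5, 0.5))
#' voxel_volume(vol)
#' @export
image_volume <- function(data, voxel_dims = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    stop("image_volume: `data` must be a 3-D array, got ",
         length(dim(data)), " dimensions", call. = FALSE)
  }
  if (!is.numeric(data)) stop("image_volume: `data` must be numeric", call. = FALSE)
  voxel_dims <- check_voxel_dims(voxel_dims)
  structure(list(data = data, voxel_dims = voxel_dims), class = "image_volume")
}

#' Binary volume-of-interest mask
#'
#' A logical 3-D array on the same grid as an [image_volume()]: a manually
#' drawn tumor guidance VOI, a segmented metabolic tumor volume, or a liver
#' background VOI.
#'
#' @param data logical (or coercible) 3-D array; `TRUE` marks voxels inside
#'   the VOI.
#' @param voxel_dims numeric length-3, voxel edge lengths in mm.
#' @return A `voi_mask` object.
#' @export
voi_mask <- function(data, voxel_dims = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    stop("voi_mask: `data` must be a 3-D array", call. = FALSE)
  }
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("voi_mask: mask contains NA", call. = FALSE)
  voxel_dims <- check_voxel_dims(voxel_dims)
  structure(list(data = data, voxel_dims = voxel_dims), class = "voi_mask")
}

#' Multi-b-value diffusion-weighted series
#'
#' An ordered set of co-registered [image_volume()] frames, one per
#' diffusion weighting, with their b-values in s/mm^2.
#'
#' @param volumes list of `image_volume` objects on a common grid.
#' @param bvalues numeric vector of b-values (s/mm^2), one per frame,
#'   non-negative and strictly increasing.
#' @return A `dwi_series` object.
#' @export
dwi_series <- function(volumes, bvalues) {
  if (!is.list(volumes) || !all(vapply(volumes, inherits, logical(1), "image_volume"))) {
    stop("dwi_series: `volumes` must be a list of image_volume objects", call. = FALSE)
  }
  if (length(volumes) != length(bvalues)) {
    stop("dwi_series: one b-value per frame required", call. = FALSE)
  }
  check_bvalues(bvalues)
  for (i in seq_along(volumes)[-1L]) {
    if (!same_grid(volumes[[1L]], volumes[[i]])) {
      stop("dwi_series: frame ", i, " is not on the same grid as frame 1", call. = FALSE)
    }
  }
  structure(list(volumes = volumes, bvalues = as.numeric(bvalues)),
            class = "dwi_series")
}

check_bvalues <- function(bvalues) {
  if (length(bvalues) < 2L) {
    stop("at least 2 distinct b-values are required", call. = FALSE)
  }
  if (any(!is.finite(bvalues)) || any(bvalues < 0)) {
    stop("b-values must be finite and non-negative", call. = FALSE)
  }
  if (any(diff(bvalues) <= 0)) {
    stop("b-values must be strictly increasing", call. = FALSE)
  }
  invisible(bvalues)
}

check_voxel_dims <- function(voxel_dims) {
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(!is.finite(voxel_dims)) || any(voxel_dims <= 0)) {
    stop("`voxel_dims` must be 3 positive finite lengths (mm)", call. = FALSE)
  }
  voxel_dims
}

#' Voxel volume in mm^3
#' @param x an `image_volume` or `voi_mask`.
#' @return Scalar voxel volume (mm^3).
#' @export
voxel_volume <- function(x) prod(x$voxel_dims)

#' Do two volumes/masks share a grid?
#' @param a,b `image_volume` or `voi_mask` objects.
#' @return `TRUE` if dimensions and voxel sizes agree.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$voxel_dims, b$voxel_dims, tolerance = 1e-8))
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$voxel_dims, 4), collapse = " x "), " mm\n",
      "  range: [", signif(min(x$data), 5), ", ", signif(max(x$data), 5), "]\n",
      sep = "")
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  cat("<voi_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$voxel_dims, 4), collapse = " x "), " mm; ",
      sum(x$data), " voxels in mask (",
      signif(sum(x$data) * voxel_volume(x), 5), " mm^3)\n", sep = "")
  invisible(x)
}

#' @export
print.dwi_series <- function(x, ...) {
  cat("<dwi_series> ", length(x$volumes), " frames, b = ",
      paste(x$bvalues, collapse = ", "), " s/mm^2; grid ",
      paste(dim(x$volumes[[1L]]$data), collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' Read / write volumes as NIfTI-1
#'
#' Voxel dimensions are carried in the NIfTI header (`pixdim`). Masks are
#' written as 0/1 integer volumes and re-binarized (`> 0.5`) on read.
#'
#' @param x an `image_volume` or `voi_mask`.
#' @param path file path, conventionally `.nii` or `.nii.gz`.
#' @return `write_volume_nifti()` returns `path` invisibly;
#'   `read_volume_nifti()` returns an `image_volume`; `read_mask_nifti()`
#'   returns a `voi_mask`.
#' @export
write_volume_nifti <- function(x, path) {
  stopifnot(inherits(x, c("image_volume", "voi_mask")))
  img <- RNifti::asNifti(x$data * 1, reference = NULL)
  RNifti::pixdim(img) <- x$voxel_dims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim = dim(img)[1:3]),
               voxel_dims = RNifti::pixdim(img)[1:3])
}

#' @rdname write_volume_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  voi_mask(array(as.numeric(img) > 0.5, dim = dim(img)[1:3]),
           voxel_dims = RNifti::pixdim(img)[1:3])
}
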