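#' Fit the mono-exponential diffusion model at one voxel
#'
#' Least-squares fit of `S(b) = S0 * exp(-b * ADC)` to one voxel's signals
#' across b-values. The default `"loglinear"` method is ordinary least
#' squares of `log(S)` on `b` (slope `-ADC`, intercept `log(S0)`), the
#' standard deterministic choice for a 3-point acquisition; `"nonlinear"`
#' refines it by Levenberg-Marquardt least squares on the exponential model
#' ([minpack.lm::nlsLM()]), initialized from the log-linear solution. Both
#' are exact on noiseless data.
#'
#' A voxel with any non-positive signal cannot enter the log fit and is
#' returned as invalid rather than raising an error (the map-level fitter
#' relies on this). Fits with ADC outside the physiological window
#' (0, 4e-3) mm^2/s — the free-water ceiling — are also flagged invalid;
#' the fitted value is still reported.
#'
#' @param signals numeric vector of signal intensities, one per b-value.
#' @param bvalues numeric vector of b-values (s/mm^2), >= 2 distinct.
#' @param method `"loglinear"` (default) or `"nonlinear"`.
#' @return An `adc_fit` list: `adc` (mm^2/s), `s0`, `r_squared` (of the fit
#'   in its own domain; `NA` with 2 points), `valid`.
#' @examples
#' fit_adc_voxel(100 * exp(-c(0, 200, 800) * 0.8e-3), c(0, 200, 800))
#' @export
fit_adc_voxel <- function(signals, bvalues, method = c("loglinear", "nonlinear")) {
  method <- match.arg(method)
  signals <- as.numeric(signals)
  if (length(signals) != length(bvalues)) {
    stop("fit_adc_voxel: `signals` and `bvalues` lengths differ", call. = FALSE)
  }
  check_bvalues(sort(unique(bvalues)))
  if (any(!is.finite(signals)) || any(signals <= 0)) {
    return(structure(list(adc = NA_real_, s0 = NA_real_,
                          r_squared = NA_real_, valid = FALSE),
                     class = "adc_fit"))
  }
  b <- as.numeric(bvalues)
  y <- log(signals)
  bbar <- mean(b); ybar <- mean(y)
  slope <- sum((b - bbar) * (y - ybar)) / sum((b - bbar)^2)
  adc <- -slope
  s0 <- exp(ybar - slope * bbar)
  if (method == "nonlinear") {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        signals ~ A * exp(-b * D), start = list(A = s0, D = adc),
        control = minpack.lm::nls.lm.control(maxiter = 100))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      s0 <- unname(cf["A"]); adc <- unname(cf["D"])
    }
    resid <- signals - s0 * exp(-b * adc)
    ss_tot <- sum((signals - mean(signals))^2)
  } else {
    resid <- y - (log(s0) - adc * b)
    ss_tot <- sum((y - ybar)^2)
  }
  r2 <- if (length(b) > 2L && ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  valid <- is.finite(adc) && is.finite(s0) && s0 > 0 && adc > 0 && adc < 4e-3
  structure(list(adc = adc, s0 = s0, r_squared = r2, valid = valid),
            class = "adc_fit")
}

#' @export
print.adc_fit <- function(x, ...) {
  cat("<adc_fit> ADC = ", signif(x$adc * 1e3, 4), " x10^-3 mm^2/s, S0 = ",
      signif(x$s0, 4), if (!x$valid) " [invalid]", "\n", sep = "")
  invisible(x)
}

#' Voxel-wise ADC map from a multi-b-value series
#'
#' Applies [fit_adc_voxel()] at every voxel. The log-linear path is solved
#' in closed form for all voxels at once (one OLS slope per voxel); the
#' nonlinear path loops over voxels and is intended for small volumes or
#' masked regions. The validity mask flags voxels with non-positive
#' signals or fits outside (0, 4e-3) mm^2/s; flagged ADC values are kept in
#' the map but excluded from VOI summaries.
#'
#' @param series a [dwi_series()].
#' @param method `"loglinear"` (default) or `"nonlinear"`.
#' @return An `adc_map` list: `adc` ([image_volume()], mm^2/s; `NA` where a
#'   voxel could not be fit at all), `valid` ([voi_mask()]), `bvalues`,
#'   `method`.
#' @export
fit_adc_map <- function(series, method = c("loglinear", "nonlinear")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "dwi_series"))
  gs <- dim(series$volumes[[1L]]$data)
  vd <- series$volumes[[1L]]$voxel_dims
  b <- series$bvalues
  sig <- vapply(series$volumes, function(v) as.numeric(v$data),
                numeric(prod(gs)))  # voxels x frames
  if (method == "loglinear") {
    ok <- rowSums(!is.finite(sig) | sig <= 0) == 0L
    adc <- rep(NA_real_, nrow(sig))
    if (any(ok)) {
      y <- log(sig[ok, , drop = FALSE])
      bc <- b - mean(b)
      slope <- (y %*% bc) / sum(bc^2)
      adc[ok] <- -as.numeric(slope)
    }
    valid <- ok & is.finite(adc) & adc > 0 & adc < 4e-3
  } else {
    fits <- apply(sig, 1L, fit_adc_voxel, bvalues = b, method = "nonlinear")
    adc <- vapply(fits, `[[`, numeric(1), "adc")
    valid <- vapply(fits, `[[`, logical(1), "valid")
  }
  structure(list(adc = image_volume(array(adc, gs), vd),
                 valid = voi_mask(array(valid, gs), vd),
                 bvalues = b, method = method),
            class = "adc_map")
}

#' @export
print.adc_map <- function(x, ...) {
  cat("<adc_map> ", paste(dim(x$adc$data), collapse = " x "), " voxels, b = ",
      paste(x$bvalues, collapse = ", "), " s/mm^2 (", x$method, "); ",
      sum(x$valid$data), " valid voxels\n", sep = "")
  invisible(x)
}

#' Representative VOI ADC: the median over valid voxels
#'
#' The per-tumor summary used for statistical analysis: the median ADC over
#' the valid voxels of a multi-slice VOI (midpoint convention for even
#' counts, as in [stats::median()]).
#'
#' @param map an `adc_map` from [fit_adc_map()].
#' @param voi a [voi_mask()] on the map's grid.
#' @return Median ADC in mm^2/s.
#' @export
median_adc <- function(map, voi) {
  stopifnot(inherits(map, "adc_map"), inherits(voi, "voi_mask"))
  if (!same_grid(map$adc, voi)) {
    stop("median_adc: VOI is not on the map's grid", call. = FALSE)
  }
  use <- voi$data & map$valid$data
  if (!any(use)) {
    stop("median_adc: no valid voxels inside the VOI", call. = FALSE)
  }
  stats::median(map$adc$data[use])
}
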