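# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All generator randomness flows through this: a generator call is a
# pure function of (config, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Round half away from zero at `digits` decimals -- the convention used by
# the published tables (base round() rounds half to even).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Voxel-center coordinates (mm) along each axis of a grid.
voxel_centers <- function(grid_shape, voxel_dims) {
  lapply(1:3, function(a) (seq_len(grid_shape[a]) - 0.5) * voxel_dims[a])
}

# Squared normalized ellipsoid radius at every voxel center:
# value <= 1 inside the ellipsoid. Returns an array of grid_shape.
ellipsoid_rho2 <- function(grid_shape, voxel_dims, center, radii) {
  ctr <- voxel_centers(grid_shape, voxel_dims)
  u <- (ctr[[1]] - center[1]) / radii[1]
  v <- (ctr[[2]] - center[2]) / radii[2]
  w <- (ctr[[3]] - center[3]) / radii[3]
  outer(outer(u^2, v^2, `+`), w^2, `+`)
}

# Rasterize an ellipsoid with the voxel-center-inside rule.
ellipsoid_mask_array <- function(grid_shape, voxel_dims, center, radii) {
  ellipsoid_rho2(grid_shape, voxel_dims, center, radii) <= 1
}
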