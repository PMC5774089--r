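# Independent brute-force oracles. These deliberately recompute statistics
# by a different route than the package (pair counting instead of rank
# sums, literal enumeration instead of convolution/caching) so that
# agreement is informative.

# MTV threshold segmentation by a literal scan over every voxel.
oracle_mtv_mask <- function(volume, guide_voi, fraction) {
  vmax <- -Inf
  idx <- which(guide_voi$data)
  for (i in idx) vmax <- max(vmax, volume$data[i])
  keep <- array(FALSE, dim = dim(volume$data))
  for (i in idx) keep[i] <- volume$data[i] >= fraction * vmax
  keep
}

# Log-linear ADC fit via explicit normal equations on (1, -b).
oracle_loglinear <- function(signals, bvalues) {
  X <- cbind(1, -bvalues)
  beta <- solve(t(X) %*% X, t(X) %*% log(signals))
  list(s0 = exp(beta[1L]), adc = beta[2L])
}

# Exact two-sided Mann-Whitney p by enumerating every group assignment of
# the pooled values; U computed by pair counting (greater = 1, tie = 1/2).
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x); N <- length(pooled)
  u_of <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b) u <- u + (ai > bi) + 0.5 * (ai == bi)
    u
  }
  u_obs <- u_of(x, y)
  sets <- utils::combn(N, m)
  us <- apply(sets, 2L, function(s) u_of(pooled[s], pooled[-s]))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# Exact two-sided Wilcoxon signed-rank p by literal enumeration of all
# 2^n sign assignments of the midranks of |d| (zeros already removed).
oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- signs %*% r
  eps <- 1e-9
  min(1, 2 * min(mean(ws <= w_obs + eps), mean(ws >= w_obs - eps)))
}

# Exact two-sided Spearman permutation p by literal enumeration of all n!
# permutations (kept to n <= 6 so the R loop stays cheap).
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- sum(rx * ry)
  perms <- all_permutations(n)
  s <- apply(perms, 1L, function(p) sum(rx * ry[p]))
  eps <- 1e-9
  min(1, 2 * min(mean(s <= obs + eps), mean(s >= obs - eps)))
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow(sub), n - 1L))
  }))
}

# Small random PET-like volume on its own grid.
random_volume <- function(shape = c(8, 8, 8), seed = 1, vd = c(1, 1, 1)) {
  set.seed(seed)
  image_volume(array(runif(prod(shape), 0.5, 10), dim = shape), vd)
}

# Cohort simulation config with all treatment effects removed (both groups
# share each biomarker's delta distribution): the null for type-I checks.
null_cohort_config <- function(seed = 1) {
  bio <- default_biomarker_sim()
  for (nm in names(bio)) {
    bio[[nm]]$delta_mean_therapy <- bio[[nm]]$delta_mean_control <- 0
    sd_pool <- mean(c(bio[[nm]]$delta_sd_therapy, bio[[nm]]$delta_sd_control))
    bio[[nm]]$delta_sd_therapy <- bio[[nm]]$delta_sd_control <- sd_pool
  }
  cohort_sim_config(biomarkers = bio, seed = seed)
}
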