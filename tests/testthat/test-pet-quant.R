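test_that("MTV threshold segmentation matches its definition and oracle", {
  vd <- c(0.5, 0.5, 0.5)
  uni <- image_volume(array(3, c(4, 4, 4)), vd)
  voi <- voi_mask(array(TRUE, c(4, 4, 4)), vd)
  expect_identical(segment_mtv(uni, voi)$data, voi$data)  # uniform: all kept

  spike <- array(1, c(4, 4, 4)); spike[2, 3, 1] <- 10
  m <- segment_mtv(image_volume(spike, vd), voi, fraction = 0.30)
  expect_equal(sum(m$data), 1L)
  expect_true(m$data[2, 3, 1])

  # seeded random volumes vs exhaustive voxel-scan oracle
  for (seed in 1:5) {
    vol <- random_volume(c(8, 8, 8), seed = seed, vd = vd)
    set.seed(seed + 100)
    guide <- voi_mask(array(runif(512) < 0.4, c(8, 8, 8)), vd)
    if (!any(guide$data)) next
    got <- segment_mtv(vol, guide, fraction = 0.30)
    expect_identical(got$data, oracle_mtv_mask(vol, guide, 0.30))
  }

  expect_error(segment_mtv(uni, voi_mask(array(FALSE, c(4, 4, 4)), vd)), "empty")
  expect_error(segment_mtv(uni, voi, fraction = 1), "between 0 and 1")
  expect_error(segment_mtv(uni, voi_mask(array(TRUE, c(4, 4, 4)), c(1, 1, 1))),
               "different grids")
})

test_that("MTV is monotone in the threshold and scale-invariant", {
  vol <- random_volume(c(8, 8, 8), seed = 7)
  voi <- voi_mask(array(TRUE, c(8, 8, 8)))
  prev <- NULL
  for (f in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    m <- segment_mtv(vol, voi, f)
    if (!is.null(prev)) expect_true(all(prev$data | !m$data))  # nested masks
    prev <- m
  }
  scaled <- image_volume(vol$data * 17.3, vol$voxel_dims)
  expect_identical(segment_mtv(scaled, voi, 0.3)$data,
                   segment_mtv(vol, voi, 0.3)$data)
})

test_that("top-count segmentation mode keeps the requested share of voxels", {
  set.seed(3)
  vol <- image_volume(array(sample(1:1000, 512), c(8, 8, 8)))  # no ties
  voi <- voi_mask(array(TRUE, c(8, 8, 8)))
  m <- segment_mtv(vol, voi, fraction = 0.30, mode = "top-count")
  expect_equal(sum(m$data), ceiling(0.30 * 512))
  expect_gte(min(vol$data[m$data]), max(vol$data[!m$data]))
})

test_that("mask volume is count times voxel volume", {
  vd <- c(0.5, 0.5, 0.5)
  arr <- array(FALSE, c(10, 10, 10)); arr[1:10, 1:10, 1:10] <- TRUE
  expect_equal(mtv_volume(voi_mask(arr, vd)), 1000 * 0.125)
  expect_equal(mtv_volume(voi_mask(array(FALSE, c(4, 4, 4)), vd)), 0)

  # voxelized sphere r = 3 mm at 0.5 mm voxels approximates 4/3 pi r^3
  sphere <- ellipsoid_mask_array(c(16, 16, 16), vd, c(4, 4, 4), c(3, 3, 3))
  expect_equal(mtv_volume(voi_mask(sphere, vd)), 4 / 3 * pi * 27,
               tolerance = 0.05)
})

test_that("liver VOI hits the achievable volume closest to the target", {
  mk <- function(vd) image_volume(array(0, c(40, 40, 40)), vd)
  expect_equal(sum(make_liver_voi(mk(c(1, 1, 1)), c(20, 20, 20))$data), 9L)
  expect_equal(sum(make_liver_voi(mk(c(0.5, 0.5, 0.5)), c(10, 10, 10))$data), 72L)
  # 0.4 mm voxels: 141 x 0.064 = 9.024 is the closest achievable volume
  voi <- make_liver_voi(mk(c(0.4, 0.4, 0.4)), c(8, 8, 8))
  expect_equal(sum(voi$data), 141L)
  expect_equal(mtv_volume(voi), 9.024)
  # roughly spherical: all selected voxels within the bounding radius
  expect_error(make_liver_voi(mk(c(0.5, 0.5, 0.5)), c(0.5, 10, 10)), "outside")
  expect_error(make_liver_voi(mk(c(1, 1, 1)), c(100, 20, 20)), "inside the grid")
})

test_that("TTL equals max-over-tumor divided by mean-over-liver", {
  vd <- c(1, 1, 1)
  arr <- array(1, c(6, 6, 6)); arr[2, 2, 2] <- 4
  tumor <- array(FALSE, c(6, 6, 6)); tumor[1:3, 1:3, 1:3] <- TRUE
  liver <- array(FALSE, c(6, 6, 6)); liver[5:6, 5:6, 5:6] <- TRUE
  vol <- image_volume(arr, vd)
  res <- compute_ttl(vol, voi_mask(tumor, vd), voi_mask(liver, vd))
  expect_equal(res$ttl, 4.0)
  expect_equal(res$mtv_mm3, mtv_volume(res$mtv_mask))

  # ratio is invariant under positive rescaling
  res2 <- compute_ttl(image_volume(arr * 3.7, vd),
                      voi_mask(tumor, vd), voi_mask(liver, vd))
  expect_equal(res2$ttl, res$ttl, tolerance = 1e-12)

  # seeded random volume vs direct max/mean
  vol3 <- random_volume(c(6, 6, 6), seed = 5)
  res3 <- compute_ttl(vol3, voi_mask(tumor, vd), voi_mask(liver, vd))
  expect_equal(res3$ttl, max(vol3$data[tumor]) / mean(vol3$data[liver]),
               tolerance = 1e-12)

  neg <- image_volume(array(-1, c(6, 6, 6)), vd)
  expect_error(compute_ttl(neg, voi_mask(tumor, vd), voi_mask(liver, vd)),
               "liver mean")
})
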