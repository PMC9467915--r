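test_that("section equalization recovers a flat intensity profile", {
  set.seed(1)
  # strictly positive, well away from 0, so the clip at zero never fires
  st <- array(runif(20 * 30 * 30, 1, 2), c(20, 30, 30))
  gains <- runif(20, 0.5, 2)
  eq <- equalize_sections(st * gains)
  means <- apply(eq, 1, mean)
  sds <- apply(eq, 1, sd)
  expect_lt(diff(range(means)), 1e-6)
  expect_lt(diff(range(sds)), 1e-6)
  expect_true(all(eq >= 0))
  # an already-equalized stack passes through unchanged
  eq2 <- equalize_sections(eq)
  expect_equal(as.numeric(eq2), as.numeric(eq), tolerance = 1e-6)
})

test_that("zero-variance slices are left unscaled and flagged", {
  st <- array(runif(6 * 8 * 8), c(6, 8, 8))
  st[3, , ] <- 0.7
  eq <- equalize_sections(st)
  expect_equal(attr(eq, "unscaled_slices"), 2L)
  expect_equal(eq[3, , ], st[3, , ])
})

test_that("periodic artifact smoothing halves z and damps the oscillation", {
  # shape contract on an 8-slice stack
  st8 <- array(runif(8 * 6 * 6), c(8, 6, 6))
  expect_equal(dim(smooth_periodic_artifact(st8))[1], 4)
  # constant stacks stay constant
  cst <- smooth_periodic_artifact(array(2, c(12, 5, 5)))
  expect_equal(diff(range(cst)), 0)
  expect_true(all(cst >= 0))
  # odd slice counts drop the trailing slice, flagged
  odd <- smooth_periodic_artifact(array(1, c(9, 5, 5)))
  expect_equal(attr(odd, "dropped_slices"), 8L)
  # pure period-2 oscillation: Nyquist amplitude reduced at least 10x
  nz <- 40
  osc <- array(0.5, c(nz, 20, 20)) * (1 + 0.4 * rep_len(c(1, -1), nz))
  out <- smooth_periodic_artifact(osc)
  nyq <- function(m) abs(sum(m * (-1)^(seq_along(m)))) / length(m)
  expect_gt(nyq(apply(osc, 1, mean)) / nyq(apply(out, 1, mean)), 10)
})

test_that("shading correction flattens a multiplicative vignette", {
  spec <- volume_spec(c(8, 256, 256), seed = 2,
                      noise = list(gaussian_sd = 0, poisson_scale = 0))
  flat <- array(0.5, c(8, 256, 256))
  sh <- add_acquisition_artifacts(flat, spec, shading_scale = 0.4)
  corr <- shading_correction(sh[1:4, , ], 37, 2)
  cv <- function(m) sd(m) / mean(m)
  expect_gt(cv(sh[2, , ]) / cv(corr[2, , ]), 5)
  # uniform input passes through (reference is identically 1)
  u <- array(0.7, c(2, 48, 48))
  expect_equal(shading_correction(u, 37, 2), u, tolerance = 1e-9)
  # global scalars commute with the correction
  set.seed(3)
  st <- array(runif(2 * 48 * 48, 0.2, 1), c(2, 48, 48))
  expect_equal(shading_correction(st * 3, 37, 2),
               3 * shading_correction(st, 37, 2), tolerance = 1e-9)
})

test_that("structure tensor recovers fiber orientations", {
  fs <- synthetic_fiber_scene(seed = 5, orientation = c(0, 0, 1))
  of <- orientation_field(fs$volume)
  idx <- which(fs$truth$fiber_mask & of$mask)
  expect_gt(length(idx), 1000)
  errs <- vapply(idx, function(i) {
    angular_error_deg(c(of$vz[i], of$vy[i], of$vx[i]), c(0, 0, 1))
  }, numeric(1))
  expect_lte(median(errs), 5)
  # masked orientations are unit vectors, canonical sign
  n2 <- of$vz[idx]^2 + of$vy[idx]^2 + of$vx[idx]^2
  expect_lt(max(abs(n2 - 1)), 1e-9)
})

test_that("noise and constant volumes yield (almost) no oriented voxels", {
  spec <- volume_spec(c(32, 32, 32), seed = 11,
                      noise = list(gaussian_sd = 0.05, poisson_scale = 0))
  noisy <- deepstain:::apply_noise(array(0.3, c(32, 32, 32)), spec)
  expect_lt(mean(orientation_field(noisy)$mask), 0.1)
  expect_equal(sum(orientation_field(array(0.5, c(32, 32, 32)))$mask), 0)
})

test_that("orientation estimation is equivariant under axis permutation", {
  fs <- synthetic_fiber_scene(seed = 6, orientation = c(0, 0.6, 0.8))
  of <- orientation_field(fs$volume)
  perm <- c(3, 1, 2)   # (z, y, x) -> (x, z, y)
  ofp <- orientation_field(aperm(fs$volume, perm))
  idx <- which(of$mask & aperm(ofp$mask, order(perm)))
  idx <- sample(idx, min(500, length(idx)))
  vperm <- list(ofp$vz, ofp$vy, ofp$vx)
  back <- lapply(vperm, function(a) aperm(a, order(perm)))
  errs <- vapply(idx, function(i) {
    v1 <- c(of$vz[i], of$vy[i], of$vx[i])
    # components of the permuted field, re-ordered to original axes
    v2 <- c(back[[which(perm == 1)]][i], back[[which(perm == 2)]][i],
            back[[which(perm == 3)]][i])
    angular_error_deg(v1, v2)
  }, numeric(1))
  expect_lt(median(errs), 1)
})

test_that("streamlines follow straight fibers and stop at sharp turns", {
  fs <- synthetic_fiber_scene(seed = 5, orientation = c(0, 0, 1))
  of <- orientation_field(fs$volume)
  idx <- which(fs$truth$fiber_mask & of$mask)[200]
  seed_pt <- (arrayInd(idx, dim(of$mask)) - 1) * of$voxel_size
  sl <- track_streamlines(of, matrix(seed_pt, ncol = 3), step_um = 1,
                          max_length_um = 200)
  pts <- sl[[1]]$points
  expect_gt(nrow(pts), 20)
  seg <- diff(pts)
  seg <- seg / sqrt(rowSums(seg^2))
  expect_true(all(abs(seg[, 3]) > cos(25 * pi / 180)))
  # consecutive turning angles respect the threshold
  turn <- acos(pmin(1, rowSums(seg[-1, , drop = FALSE] *
                                 seg[-nrow(seg), , drop = FALSE])))
  expect_true(all(turn <= 25 * pi / 180 + 1e-9))

  # two orthogonal blocks: tracking terminates at the interface
  d <- c(16, 16, 32)
  f2 <- structure(list(vz = array(0, d), vy = array(0, d),
                       vx = array(0, d), coherence = array(1, d),
                       mask = array(TRUE, d), voxel_size = c(1, 1, 1)),
                  class = "orientation_field")
  f2$vx[, , 1:16] <- 1
  f2$vy[, , 17:32] <- 1
  sl2 <- track_streamlines(f2, matrix(c(8, 8, 4), ncol = 3), step_um = 1,
                           max_length_um = 100)
  expect_true("angle" %in% sl2[[1]]$termination)
  expect_true(all(sl2[[1]]$points[, 3] <= 16.5))
  expect_equal(track_streamlines(of, NULL), list())
})

test_that("block-average downscaling preserves means", {
  v <- array(seq_len(8 * 20 * 30), c(8, 20, 30))
  dv <- downscale_volume(v, c(2, 10, 10))
  expect_equal(dim(dv), c(4, 2, 3))
  expect_equal(dv[1, 1, 1], mean(v[1:2, 1:10, 1:10]))
  expect_equal(mean(dv), mean(v))
})
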