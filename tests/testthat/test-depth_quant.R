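test_that("distance transform is exact on canonical geometries", {
  # one-voxel-thick sheet: every tissue voxel adjacent to background
  m <- array(FALSE, c(5, 8, 8))
  m[3, , ] <- TRUE
  dm <- distance_from_surface(m, c(1, 1, 1))
  expect_equal(unique(dm$values[m]), 1)
  expect_equal(unique(dm$values[!m]), 0)
  # solid 11^3 cube: center voxel 6 um from the nearest outside center
  cube <- array(FALSE, c(21, 21, 21))
  cube[6:16, 6:16, 6:16] <- TRUE
  dmc <- distance_from_surface(cube, c(1, 1, 1))
  expect_equal(dmc$values[11, 11, 11], 6)
})

test_that("distance transform matches the brute-force all-pairs oracle", {
  set.seed(7)
  for (i in 1:20) {
    d <- sample(5:16, 3, replace = TRUE)
    w <- runif(3, 0.5, 3)
    m <- array(runif(prod(d)) < 0.6, d)
    if (!any(m) || all(m)) next
    dm <- distance_from_surface(m, w)
    expect_lt(max(abs(dm$values - brute_force_edt(m, w))), 1e-9)
  }
})

test_that("distance transform obeys the Lipschitz bound across neighbors", {
  set.seed(8)
  w <- c(2, 1, 1.5)
  m <- array(runif(12 * 12 * 12) < 0.7, c(12, 12, 12))
  dm <- distance_from_surface(m, w)
  for (ax in 1:3) {
    dv <- apply(dm$values, setdiff(1:3, ax), diff)
    expect_lte(max(abs(dv)), w[ax] + 1e-12)
  }
})

test_that("distance transform validates masks and supports open boundaries", {
  expect_error(distance_from_surface(array(FALSE, c(4, 4, 4))), "no tissue")
  expect_error(distance_from_surface(array(TRUE, c(4, 4, 4))),
               "open_boundary")
  dm <- distance_from_surface(array(TRUE, c(5, 5, 5)), c(1, 1, 1),
                              open_boundary = TRUE)
  expect_equal(dm$values[3, 3, 3], 3)  # center to just outside the border
  expect_equal(dm$values[1, 3, 3], 1)
})

test_that("snr_db matches its closed forms and is scale-invariant", {
  roi <- c(1, 2, 3, 4.5)
  expect_equal(snr_db(roi, roi), 0)
  expect_equal(snr_db(10 * roi, roi), 20)
  set.seed(1)
  s <- runif(40)
  b <- runif(25)
  expect_equal(snr_db(s, b), 10 * log10(sum(s^2) / sum(b^2)), tolerance = 1e-12)
  expect_equal(snr_db(3.7 * s, 3.7 * b), snr_db(s, b), tolerance = 1e-12)
  expect_error(snr_db(s, numeric(0)), "background")
  expect_error(snr_db(s, c(0, 0)), "background")
})

test_that("depth profiles report per-slice statistics and omitted slices", {
  v <- array(2, c(6, 10, 10))
  sig <- array(FALSE, dim(v))
  bg <- array(FALSE, dim(v))
  sig[2:5, 3:5, 3:5] <- TRUE
  bg[2:5, 7:9, 7:9] <- TRUE
  dp <- depth_profile(v, sig, bg)
  expect_equal(dp$z_index, 1:4)
  expect_equal(dp$roi_sd, rep(0, 4))
  expect_equal(dp$snr_db, rep(0, 4))  # identical constant ROIs
  expect_equal(attr(dp, "omitted_slices"), c(0L, 5L))
  expect_error(depth_profile(v, array(FALSE, dim(v)), bg), "no slice")
})

test_that("slice means are flat for depth-independent staining and decay otherwise", {
  sc <- cell_scene(1)
  mk_rois <- function(scene) {
    w <- scene$spec$voxel_size
    tab <- scene$truth$cell_table
    sig <- array(FALSE, scene$spec$shape)
    for (i in seq_len(nrow(tab))) {
      iz <- round(tab$z[i] / w[1]) + 1
      iy <- round(tab$y[i] / w[2]) + 1
      ix <- round(tab$x[i] / w[3]) + 1
      sig[iz + (-1:1), iy + (-1:1), ix + (-1:1)] <- TRUE
    }
    bg <- scene$truth$tissue_mask & !sig
    list(sig = sig, bg = bg)
  }
  r <- mk_rois(sc)
  dp <- depth_profile(sc$volume, r$sig, r$bg)
  fit <- lm(roi_mean ~ z_index, data = as.data.frame(dp))
  ci <- confint(fit)["z_index", ]
  expect_true(ci[1] < 0 && ci[2] > 0)   # slope CI contains 0
  # exponentially decaying depth profile: smoothed slice means decrease
  scd <- synthetic_cell_scene(seed = 2,
                              depth_profile = function(d) exp(-d / 60))
  rd <- mk_rois(scd)
  dpd <- depth_profile(scd$volume, rd$sig, rd$bg)
  sm <- stats::filter(dpd$roi_mean, rep(1 / 5, 5), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
  expect_true(mean(diff(sm) <= 1e-9) > 0.8)
})

test_that("LoG segmentation handles empty and single-object volumes", {
  bgv <- array(0.05, c(32, 32, 32))
  seg <- segment_cells_log(bgv, sigma_L = 3, sigma_G = 1.5)
  expect_equal(nrow(seg$cells), 0)
  v <- array(0.05, c(40, 40, 40))
  ctr <- c(20, 20, 20)
  co <- lapply(1:3, function(a) seq_len(40) - 1)
  d2 <- outer((co[[1]] - ctr[1])^2,
              outer((co[[2]] - ctr[2])^2, (co[[3]] - ctr[3])^2, "+"), "+")
  v[d2 <= 36] <- v[d2 <= 36] + 0.6 * exp(-d2[d2 <= 36] / (2 * 9))
  seg1 <- segment_cells_log(v, sigma_L = 4, sigma_G = 2, min_volume = 10)
  expect_equal(nrow(seg1$cells), 1)
  expect_lt(max(abs(c(seg1$cells$z, seg1$cells$y, seg1$cells$x) - 20)), 1)
  expect_gt(seg1$cells$sphericity, 0.8)
  expect_lte(seg1$cells$sphericity, 1.1)
})

test_that("segmentation recovers seeded cells with their depths", {
  sc <- cell_scene(1)
  seg <- segment_scene(sc)
  m <- match_cells(sc$truth$cell_table, seg$cells)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
  diag_um <- sqrt(sum(sc$spec$voxel_size^2))
  derr <- abs(seg$cells$depth_um[m$match_idx] -
                sc$truth$cell_table$depth_um)[m$matched]
  expect_lte(max(derr), diag_um)
})

test_that("assign_depths averages the distance map per labeled object", {
  labels <- array(0L, c(6, 6, 6))
  labels[2, 3, 3] <- 1L
  labels[4:5, 4, 4] <- 2L
  seg <- list(cells = data.frame(label = c(1L, 2L), z = 0, y = 0, x = 0,
                                 n_voxels = c(1L, 2L), volume_um3 = 1,
                                 sphericity = 1, mean_intensity = 1,
                                 depth_um = NA_real_),
              labels = labels)
  mask <- array(TRUE, c(6, 6, 6))
  mask[1, , ] <- FALSE
  dm <- distance_from_surface(mask, c(1, 1, 1))
  out <- assign_depths(seg, dm)
  expect_equal(out$cells$depth_um, c(1, mean(c(3, 4))))
  dm2 <- distance_from_surface(mask[1:5, , ], c(1, 1, 1))
  expect_error(assign_depths(seg, dm2), "geometries")
})

test_that("surface cells adjacent to background sit at one voxel depth", {
  labels <- array(0L, c(4, 6, 6))
  labels[2, 2:4, 2:4] <- 1L
  mask <- array(TRUE, c(4, 6, 6))
  mask[1, , ] <- FALSE
  seg <- list(cells = data.frame(label = 1L, z = 0, y = 0, x = 0,
                                 n_voxels = 9L, volume_um3 = 9,
                                 sphericity = 1, mean_intensity = 1,
                                 depth_um = NA_real_),
              labels = labels)
  out <- assign_depths(seg, distance_from_surface(mask, c(1, 1, 1)))
  expect_equal(out$cells$depth_um, 1)
})

test_that("moment statistics recover analytic skewness and kurtosis", {
  set.seed(123)
  e <- rexp(1e5)
  s <- depth_stats(e)
  # 3 Monte-Carlo SEs at n = 1e5 (SEs estimated by replication)
  expect_lt(abs(s$skewness - 2), 0.084)
  expect_lt(abs(s$excess_kurtosis - 6), 0.83)
  u <- depth_stats(runif(1e5))
  expect_lt(abs(u$excess_kurtosis - (-1.2)), 0.011)
  nrm <- depth_stats(rnorm(1e5))
  expect_lt(abs(nrm$skewness), 3 * sqrt(6 / 1e5))
})

test_that("moment statistics match an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(4)
  x <- rgamma(2000, shape = 2)
  s <- depth_stats(x)
  expect_equal(s$skewness, e1071::skewness(x, type = 1))
  expect_equal(s$excess_kurtosis, e1071::kurtosis(x, type = 1))
  sa <- depth_stats(x, adjusted = TRUE)
  expect_equal(sa$skewness, e1071::skewness(x, type = 2))
  expect_equal(sa$excess_kurtosis, e1071::kurtosis(x, type = 2))
})

test_that("degenerate depth samples yield undefined higher moments", {
  s <- depth_stats(rep(3, 10))
  expect_equal(s$mean, 3)
  expect_equal(s$iqr, 0)
  expect_true(is.na(s$skewness) && is.na(s$excess_kurtosis))
  s3 <- depth_stats(c(1, 2, 5))
  expect_true(is.na(s3$skewness))
  expect_equal(s3$n, 3)
})

test_that("KS comparison matches a brute-force ECDF sweep", {
  x <- c(1, 2, 3)
  expect_equal(compare_depth_distributions(x, x)$ks_statistic, 0)
  expect_equal(compare_depth_distributions(1:5, 11:15)$ks_statistic, 1)
  set.seed(2)
  a <- rnorm(200)
  b <- rnorm(300, 0.4)
  k <- compare_depth_distributions(a, b)
  xs <- sort(c(a, b))
  sweep_stat <- max(abs(ecdf(a)(xs) - ecdf(b)(xs)))
  expect_equal(k$ks_statistic, sweep_stat, tolerance = 1e-12)
  expect_true(k$p_value >= 0 && k$p_value <= 1)
  expect_error(compare_depth_distributions(numeric(0), 1:3), "non-empty")
})

test_that("intensity versus depth reports correlations with degeneracy flags", {
  cells <- data.frame(depth_um = c(1, 2, 3, 4), mean_intensity = c(4, 3, 2, 1))
  r <- intensity_vs_depth(cells)
  expect_equal(r$pearson, -1)
  expect_equal(r$spearman, -1)
  expect_false(r$degenerate)
  const <- data.frame(depth_um = 1:4, mean_intensity = rep(2, 4))
  rc <- intensity_vs_depth(const)
  expect_equal(rc$pearson, 0)
  expect_true(rc$degenerate)
  r1 <- intensity_vs_depth(data.frame(depth_um = 1, mean_intensity = 1))
  expect_true(is.na(r1$pearson) && r1$degenerate)
})

test_that("decaying staining gives a negative depth-intensity correlation", {
  scd <- synthetic_cell_scene(seed = 3,
                              depth_profile = function(d) exp(-d / 60))
  seg <- segment_cells_log(scd$volume, 10, 5, sigma_units = "um",
                           voxel_size = scd$spec$voxel_size,
                           min_volume = 100, min_sphericity = 0.5)
  dm <- distance_from_surface(scd$truth$tissue_mask, scd$spec$voxel_size)
  seg <- assign_depths(seg, dm)
  r <- intensity_vs_depth(seg$cells)
  expect_lt(r$spearman, 0)
})
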