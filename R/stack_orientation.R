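# Serial-stack normalization and artifact smoothing, shading correction,
# structure-tensor fiber orientation estimation, and a simple
# deterministic streamline tracker.

#' Equalize per-section intensity statistics
#'
#' Affinely rescales every z-slice so its mean and standard deviation
#' match the stack-wide reference (the median of the slice means and of
#' the slice sds); negative results are clipped at 0. Zero-sd slices
#' are left untouched and listed in the `unscaled_slices` attribute.
#'
#' @param stack (z, y, x) array with at least 2 slices.
#' @return equalized stack.
#' @export
equalize_sections <- function(stack) {
  stopifnot(length(dim(stack)) == 3, dim(stack)[1] >= 2)
  nz <- dim(stack)[1]
  means <- apply(stack, 1, mean)
  sds <- apply(stack, 1, sd)
  ref_m <- median(means)
  ref_s <- median(sds)
  out <- stack
  flat <- which(sds == 0)
  for (iz in setdiff(seq_len(nz), flat)) {
    out[iz, , ] <- pmax((stack[iz, , ] - means[iz]) / sds[iz] * ref_s +
                          ref_m, 0)
  }
  attr(out, "unscaled_slices") <- flat - 1L
  out
}

# 1D Gaussian filtering along z with replicate boundaries.
z_gaussian <- function(stack, sigma) conv_axis(stack, gaussian_kernel(sigma), 1)

#' Smooth periodic per-plane acquisition artifacts
#'
#' De-interleaves the stack into odd- and even-numbered slices,
#' Gaussian-filters each half along z (sigma 1 pixel), mean-projects
#' consecutive slice pairs within each half, re-interleaves, and
#' applies a final z Gaussian (sigma 1 pixel). Pair projection halves
#' the z extent; a trailing unpaired slice (odd counts) is dropped and
#' flagged.
#'
#' @param stack (z, y, x) array with at least 4 slices.
#' @param projection `"mean"` (smoothing-consistent default) or
#'   `"max"` for the pair grouping.
#' @return smoothed stack with `floor(n_z / 2)` slices (after an even
#'   trim); attribute `dropped_slices` lists dropped trailing slices.
#' @export
smooth_periodic_artifact <- function(stack, projection = c("mean", "max")) {
  projection <- match.arg(projection)
  stopifnot(length(dim(stack)) == 3, dim(stack)[1] >= 4)
  nz <- dim(stack)[1]
  dropped <- integer(0)
  if (nz %% 2 == 1) {
    dropped <- nz - 1L   # 0-based index of the dropped slice
    stack <- stack[seq_len(nz - 1), , , drop = FALSE]
    nz <- nz - 1L
  }
  halves <- list(odd = stack[seq(1, nz, by = 2), , , drop = FALSE],
                 even = stack[seq(2, nz, by = 2), , , drop = FALSE])
  proj <- function(a, b) if (projection == "mean") (a + b) / 2 else pmax(a, b)
  halves <- lapply(halves, function(h) {
    h <- z_gaussian(h, 1)
    nh <- dim(h)[1]
    if (nh %% 2 == 1) h <- h[seq_len(nh - 1), , , drop = FALSE]
    np <- dim(h)[1] / 2
    out <- array(0, c(np, dim(h)[2], dim(h)[3]))
    for (i in seq_len(np)) {
      out[i, , ] <- proj(h[2 * i - 1, , ], h[2 * i, , ])
    }
    out
  })
  np <- dim(halves$odd)[1]
  inter <- array(0, c(2 * np, dim(stack)[2], dim(stack)[3]))
  inter[seq(1, 2 * np, by = 2), , ] <- halves$odd
  inter[seq(2, 2 * np, by = 2), , ] <- halves$even
  out <- z_gaussian(inter, 1)
  attr(out, "dropped_slices") <- dropped
  out
}

#' Multiplicative shading correction
#'
#' Builds a per-slice shading reference by 2D median filtering (square
#' kernel) followed by 2D Gaussian blurring, normalizes it to unit
#' mean, and divides the slice by the (floored) reference.
#'
#' @param stack (z, y, x) array; in-plane dims must exceed the kernel.
#' @param median_kernel odd median kernel size in pixels.
#' @param gaussian_sigma 2D Gaussian sigma in pixels.
#' @param reference_floor lower bound on the unit-mean reference, to
#'   avoid division blow-up in dark regions.
#' @return corrected stack.
#' @export
shading_correction <- function(stack, median_kernel = 37,
                               gaussian_sigma = 2.0,
                               reference_floor = 0.05) {
  stopifnot(length(dim(stack)) == 3,
            dim(stack)[2] > median_kernel, dim(stack)[3] > median_kernel,
            median_kernel %% 2 == 1)
  g <- gaussian_kernel(gaussian_sigma)
  out <- stack
  for (iz in seq_len(dim(stack)[1])) {
    ref <- median_filter2d_cpp(stack[iz, , ], (median_kernel - 1L) / 2L)
    ref <- conv_operator(nrow(ref), g) %*% ref %*%
      t(conv_operator(ncol(ref), g))
    ref <- ref / mean(ref)
    out[iz, , ] <- stack[iz, , ] / pmax(ref, reference_floor)
  }
  out
}

#' Block-average downscaling
#'
#' @param volume (z, y, x) array.
#' @param factors integer downscaling factors (z, y, x); e.g.
#'   `c(2, 10, 10)` turns an anisotropic whole-brain stack into an
#'   isotropic volume. Trailing voxels that do not fill a block are
#'   cropped.
#' @return downscaled array.
#' @export
downscale_volume <- function(volume, factors) {
  d <- dim(volume)
  factors <- as.integer(rep_len(factors, 3))
  nd <- d %/% factors
  stopifnot(all(nd >= 1))
  v <- volume[seq_len(nd[1] * factors[1]), seq_len(nd[2] * factors[2]),
              seq_len(nd[3] * factors[3]), drop = FALSE]
  dim(v) <- c(factors[1], nd[1], factors[2], nd[2], factors[3], nd[3])
  apply(v, c(2, 4, 6), mean)
}

#' Structure-tensor fiber orientation field
#'
#' Image gradients are taken with derivative-of-Gaussian filters at
#' `derivative_sigma`; the outer-product tensor is smoothed at
#' `tensor_sigma`; per voxel, the eigenvector of the smallest
#' eigenvalue gives the local fiber direction (gradients are
#' perpendicular to fibers). Coherence is
#' `(lambda_mid - lambda_min) / (lambda_max + lambda_mid + lambda_min)`;
#' voxels below `coherence_threshold` or with degenerate tensors are
#' unmasked. Orientations are sign-canonicalized (first nonzero of
#' (z, y, x) components non-negative).
#'
#' @param volume (z, y, x) array.
#' @param derivative_sigma,tensor_sigma filter scales in voxels.
#' @param coherence_threshold minimum coherence for a defined
#'   orientation.
#' @return object of class `orientation_field`: arrays `vz`, `vy`,
#'   `vx`, `coherence`, logical `mask`, and `voxel_size`.
#' @param voxel_size (z, y, x) voxel size (used by the tracker).
#' @export
orientation_field <- function(volume, derivative_sigma = 0.6,
                              tensor_sigma = 2.3,
                              coherence_threshold = 0.2,
                              voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(volume)) == 3,
            all(dim(volume) > 2 * ceiling(3.5 * tensor_sigma) + 1))
  gz <- gaussian_gradient_axis(volume, derivative_sigma, 1)
  gy <- gaussian_gradient_axis(volume, derivative_sigma, 2)
  gx <- gaussian_gradient_axis(volume, derivative_sigma, 3)
  sm <- function(a) gaussian_smooth(a, tensor_sigma)
  eg <- tensor_eigen_cpp(sm(gz * gz), sm(gz * gy), sm(gz * gx),
                         sm(gy * gy), sm(gy * gx), sm(gx * gx),
                         degenerate_tol = 1e-9)
  d <- dim(volume)
  vz <- array(eg$vz, d); vy <- array(eg$vy, d); vx <- array(eg$vx, d)
  coh <- array(eg$coherence, d)
  mask <- array(!eg$degenerate, d) & coh >= coherence_threshold
  # sign canonicalization
  s <- sign(vz)
  s[s == 0] <- sign(vy)[s == 0]
  s[s == 0] <- sign(vx)[s == 0]
  s[s == 0] <- 1
  vz <- vz * s; vy <- vy * s; vx <- vx * s
  vz[!mask] <- NA_real_; vy[!mask] <- NA_real_; vx[!mask] <- NA_real_
  structure(list(vz = vz, vy = vy, vx = vx, coherence = coh, mask = mask,
                 voxel_size = as.numeric(voxel_size)),
            class = "orientation_field")
}

# Nearest voxel (1-based index triple) of a physical point; NULL if
# outside the volume bounds.
nearest_voxel <- function(point, dims, voxel_size) {
  idx <- round(point / voxel_size) + 1
  if (any(idx < 1) || any(idx > dims)) return(NULL)
  as.integer(idx)
}

#' Deterministic streamline tracking
#'
#' Bidirectional fixed-step integration following the nearest voxel's
#' orientation, with the sign at each step chosen to minimize turning.
#' A streamline terminates when the turning angle exceeds the
#' threshold, when it leaves the orientation mask or the volume, or at
#' the maximum length. This is a deliberately simple tracker intended
#' for testing orientation fields, not a replacement for a full
#' tractography engine.
#'
#' @param field an [orientation_field()].
#' @param seeds matrix of seed points (rows; (z, y, x) um).
#' @param step_um integration step.
#' @param angle_threshold maximum turning angle per step, degrees.
#' @param max_length_um maximum streamline length.
#' @return list of streamlines, each a list with `points` (matrix of
#'   (z, y, x) um) and `termination` (reasons at the two ends).
#' @export
track_streamlines <- function(field, seeds, step_um = 1,
                              angle_threshold = 25, max_length_um = 500) {
  stopifnot(inherits(field, "orientation_field"))
  if (is.null(seeds) || NROW(seeds) == 0) return(list())
  seeds <- matrix(seeds, ncol = 3)
  dims <- dim(field$mask)
  cos_thr <- cos(angle_threshold * pi / 180)
  orient_at <- function(p) {
    v <- nearest_voxel(p, dims, field$voxel_size)
    if (is.null(v) || !field$mask[v[1], v[2], v[3]]) return(NULL)
    c(field$vz[v[1], v[2], v[3]], field$vy[v[1], v[2], v[3]],
      field$vx[v[1], v[2], v[3]])
  }
  march <- function(p0, dir0) {
    pts <- list()
    reason <- "max_length"
    p <- p0
    dir <- dir0
    n_steps <- floor(max_length_um / step_um)
    for (i in seq_len(n_steps)) {
      p_new <- p + step_um * dir
      o <- orient_at(p_new)
      if (is.null(o)) {
        v <- nearest_voxel(p_new, dims, field$voxel_size)
        reason <- if (is.null(v)) "bounds" else "mask"
        break
      }
      if (sum(o * dir) < 0) o <- -o
      if (sum(o * dir) < cos_thr) {
        reason <- "angle"
        break
      }
      pts[[i]] <- p_new
      p <- p_new
      dir <- o
    }
    list(points = do.call(rbind, pts), reason = reason)
  }
  lapply(seq_len(nrow(seeds)), function(i) {
    s <- seeds[i, ]
    o <- orient_at(s)
    if (is.null(o)) {
      return(list(points = matrix(s, ncol = 3), termination = "seed_unmasked"))
    }
    fwd <- march(s, o)
    bwd <- march(s, -o)
    pts <- rbind(if (!is.null(bwd$points))
      bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE],
      matrix(s, ncol = 3), fwd$points)
    colnames(pts) <- c("z", "y", "x")
    list(points = pts, termination = c(backward = bwd$reason,
                                       forward = fwd$reason))
  })
}
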