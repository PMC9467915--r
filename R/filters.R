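# Separable filtering on (z, y, x) volumes. Each 1D pass is expressed as a
# dense banded operator matrix applied to the unfolded volume, which keeps
# the inner loop in BLAS. Boundaries are replicate-padded.

#' Sampled Gaussian kernel
#'
#' @param sigma standard deviation in samples (voxels).
#' @param radius kernel half-width; defaults to `ceiling(3.5 * sigma)`.
#' @return numeric vector of odd length summing to 1.
#' @keywords internal
#' @noRd
gaussian_kernel <- function(sigma, radius = NULL) {
  if (sigma <= 0) return(1)
  if (is.null(radius)) radius <- max(1L, ceiling(3.5 * sigma))
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# First-derivative-of-Gaussian kernel, normalized so a unit ramp maps to 1.
gaussian_deriv_kernel <- function(sigma, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(3.5 * sigma))
  x <- seq(-radius, radius)
  k <- x * exp(-x^2 / (2 * sigma^2))
  k / sum(k * x)
}

# Second-derivative-of-Gaussian kernel: zero DC response and unit response
# on the quadratic x^2 / 2.
gaussian_deriv2_kernel <- function(sigma, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(3.5 * sigma))
  x <- seq(-radius, radius)
  k <- (x^2 - sigma^2) * exp(-x^2 / (2 * sigma^2))
  k <- k - mean(k)
  k / sum(k * x^2 / 2)
}

# n x n operator matrix realizing correlation with `kernel` under
# replicate (clamped-index) boundary handling.
conv_operator <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  m <- matrix(0, n, n)
  idx <- seq_len(n)
  for (j in seq_along(kernel)) {
    src <- pmin(pmax(idx + (j - 1L - r), 1L), n)
    m[cbind(idx, src)] <- m[cbind(idx, src)] + kernel[j]
  }
  m
}

# Apply a 1D kernel along one axis of a 3D array.
conv_axis <- function(vol, kernel, axis) {
  if (length(kernel) == 1L) return(vol * kernel)
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  dp <- dim(v)
  m <- conv_operator(dp[1], kernel) %*% matrix(v, nrow = dp[1])
  dim(m) <- dp
  aperm(m, order(perm))
}

#' Separable Gaussian smoothing of a volume
#'
#' @param vol 3D numeric array in (z, y, x) order.
#' @param sigma standard deviation(s) in voxels; scalar or length 3
#'   (per axis, (z, y, x)). Zero skips the axis.
#' @return smoothed array of the same shape.
#' @export
gaussian_smooth <- function(vol, sigma) {
  stopifnot(length(dim(vol)) == 3)
  sigma <- rep_len(sigma, 3)
  for (ax in 1:3) {
    if (sigma[ax] > 0) vol <- conv_axis(vol, gaussian_kernel(sigma[ax]), ax)
  }
  vol
}

# Gradient along `axis` via derivative-of-Gaussian at sigma (voxels),
# Gaussian-smoothed at the same sigma along the other two axes.
gaussian_gradient_axis <- function(vol, sigma, axis) {
  g <- gaussian_kernel(sigma)
  d <- gaussian_deriv_kernel(sigma)
  for (ax in 1:3) {
    vol <- conv_axis(vol, if (ax == axis) d else g, ax)
  }
  vol
}

# Laplacian-of-Gaussian response at scale sigma (voxels): sum over axes of
# the second Gaussian derivative along that axis times Gaussian smoothing
# along the others.
log_response <- function(vol, sigma) {
  g <- gaussian_kernel(sigma)
  d2 <- gaussian_deriv2_kernel(sigma)
  out <- 0
  for (axis in 1:3) {
    part <- vol
    for (ax in 1:3) {
      part <- conv_axis(part, if (ax == axis) d2 else g, ax)
    }
    out <- out + part
  }
  out
}

# Grayscale erosion/dilation with an axis-aligned box of half-width
# k (voxels, per axis), built from running extremes along each axis.
box_extreme <- function(vol, k, maximum) {
  k <- rep_len(as.integer(k), 3)
  d <- dim(vol)
  for (ax in 1:3) {
    if (k[ax] < 1) next
    perm <- c(ax, setdiff(1:3, ax))
    v <- aperm(vol, perm)
    dp <- dim(v)
    m <- roll_extreme_cols_cpp(matrix(v, nrow = dp[1]), k[ax], maximum)
    dim(m) <- dp
    vol <- aperm(m, order(perm))
  }
  vol
}

# White top-hat: original minus its morphological opening (erosion then
# dilation) with a box of half-width k voxels. Removes background
# structures wider than the box.
white_tophat <- function(vol, k) {
  opened <- box_extreme(box_extreme(vol, k, maximum = FALSE), k, maximum = TRUE)
  vol - opened
}

# Per-slice 2D median filter (square kernel, odd size) over the (y, x)
# planes of a (z, y, x) stack.
median_filter_slices <- function(vol, kernel_size) {
  stopifnot(kernel_size %% 2 == 1)
  k <- (kernel_size - 1L) / 2L
  out <- vol
  for (iz in seq_len(dim(vol)[1])) {
    out[iz, , ] <- median_filter2d_cpp(vol[iz, , ], k)
  }
  out
}

# Otsu threshold from a histogram of the data (maximizes between-class
# variance).
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  w <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}
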