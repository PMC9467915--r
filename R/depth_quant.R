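# Staining depth and homogeneity quantification: distance-from-surface
# maps, per-slice intensity/SNR profiles, Laplacian-of-Gaussian cell
# segmentation with per-cell depth assignment, and depth-distribution
# statistics.

#' Euclidean distance from the nearest tissue surface
#'
#' Exact anisotropic-spacing Euclidean distance transform: every tissue
#' voxel gets its distance (in micrometers) to the nearest non-tissue
#' voxel center; non-tissue voxels are exactly 0. Internal cavities
#' (e.g. ventricles) marked non-tissue count as surface.
#'
#' @param tissue_mask logical (z, y, x) array, TRUE on tissue.
#' @param voxel_size physical voxel size (z, y, x) in micrometers.
#' @param open_boundary if TRUE, the array border is treated as
#'   adjacent to non-tissue (the volume is a crop of a larger sample).
#' @return object of class `distance_map`: list with `values` (um),
#'   `tissue_mask`, `voxel_size`.
#' @export
distance_from_surface <- function(tissue_mask, voxel_size = c(1, 1, 1),
                                  open_boundary = FALSE) {
  stopifnot(length(dim(tissue_mask)) == 3, all(voxel_size > 0))
  if (!any(tissue_mask)) stop("mask contains no tissue voxels")
  if (all(tissue_mask) && !open_boundary) {
    stop("mask is all tissue; use open_boundary = TRUE to treat the ",
         "array border as non-tissue")
  }
  d <- dim(tissue_mask)
  if (open_boundary) {
    padded <- array(FALSE, d + 2L)
    padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- tissue_mask
    sq <- edt_squared_cpp(as.integer(padded), dim(padded),
                          as.numeric(voxel_size))
    dim(sq) <- d + 2L
    sq <- sq[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  } else {
    sq <- edt_squared_cpp(as.integer(tissue_mask), d,
                          as.numeric(voxel_size))
    dim(sq) <- d
  }
  structure(list(values = sqrt(sq), tissue_mask = tissue_mask,
                 voxel_size = as.numeric(voxel_size)),
            class = "distance_map")
}

#' Signal-to-noise ratio in decibels
#'
#' The ratio r of the summed squared pixel intensities of the
#' positive-staining ROI to that of the background ROI, expressed as
#' `10 * log10(r)`.
#'
#' @param signal_roi_values,background_roi_values numeric vectors of
#'   pixel intensities.
#' @return SNR in dB.
#' @export
snr_db <- function(signal_roi_values, background_roi_values) {
  bg <- sum(background_roi_values^2)
  if (length(background_roi_values) == 0 || bg <= 0) {
    stop("background ROI has zero summed squared intensity")
  }
  10 * log10(sum(signal_roi_values^2) / bg)
}

#' Per-slice intensity and SNR depth profile
#'
#' Profiles the pixel intensities of per-slice signal and background
#' ROIs through z: per-slice mean, standard deviation, and SNR (dB).
#' Slices lacking a signal or background ROI are omitted and listed in
#' the `omitted_slices` attribute.
#'
#' @param volume (z, y, x) intensity array.
#' @param signal_rois,background_rois logical arrays of the same shape
#'   marking the ROIs.
#' @return data.frame with `z_index` (0-based slice), `roi_mean`,
#'   `roi_sd`, `snr_db`.
#' @export
depth_profile <- function(volume, signal_rois, background_rois) {
  stopifnot(identical(dim(volume), dim(signal_rois)),
            identical(dim(volume), dim(background_rois)))
  nz <- dim(volume)[1]
  rows <- lapply(seq_len(nz), function(iz) {
    s <- volume[iz, , ][signal_rois[iz, , ]]
    b <- volume[iz, , ][background_rois[iz, , ]]
    if (length(s) == 0 || length(b) == 0 || sum(b^2) == 0) return(NULL)
    data.frame(z_index = iz - 1L, roi_mean = mean(s),
               roi_sd = if (length(s) > 1) sd(s) else 0,
               snr_db = snr_db(s, b))
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("no slice has both a signal and a background ROI")
  out <- do.call(rbind, rows[keep])
  attr(out, "omitted_slices") <- which(!keep) - 1L
  out
}

# Surface area of each label, from exposed voxel faces. Face counting
# overestimates smooth surfaces by a factor 3/2 (the average of
# |n_z|+|n_y|+|n_x| over orientations), so the raw face area is
# multiplied by 2/3.
label_surface_areas <- function(labels, voxel_size, n_labels) {
  d <- dim(labels)
  face_area <- c(voxel_size[2] * voxel_size[3],   # z-normal faces
                 voxel_size[1] * voxel_size[3],   # y-normal
                 voxel_size[1] * voxel_size[2])   # x-normal
  areas <- numeric(n_labels)
  add <- function(lab_vals, a) {
    t <- tabulate(lab_vals, nbins = n_labels)
    areas <<- areas + t * a
  }
  for (ax in 1:3) {
    n <- d[ax]
    idx_lo <- lapply(d, seq_len); idx_lo[[ax]] <- 1:(n - 1)
    idx_hi <- lapply(d, seq_len); idx_hi[[ax]] <- 2:n
    a <- do.call(`[`, c(list(labels), idx_lo))
    b <- do.call(`[`, c(list(labels), idx_hi))
    diff <- a != b
    add(a[diff & a > 0], face_area[ax])
    add(b[diff & b > 0], face_area[ax])
    # faces on the array border
    first <- lapply(d, seq_len); first[[ax]] <- 1L
    last <- lapply(d, seq_len); last[[ax]] <- n
    add(do.call(`[`, c(list(labels), first)), face_area[ax])
    add(do.call(`[`, c(list(labels), last)), face_area[ax])
  }
  areas * 2 / 3
}

# Exposed-surface voxel coordinates of one label (um), for Feret
# computation: voxels with at least one 6-neighbor outside the label.
label_surface_coords <- function(labels, label, voxel_size) {
  idx <- which(labels == label)
  co <- arrayInd(idx, dim(labels))
  d <- dim(labels)
  on_surface <- rep(FALSE, nrow(co))
  flat <- function(z, y, x) z + dim(labels)[1] * ((y - 1) +
                                                    dim(labels)[2] * (x - 1))
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- co
      nb[, ax] <- nb[, ax] + s
      out <- nb[, ax] < 1 | nb[, ax] > d[ax]
      inb <- !out
      nb_idx <- flat(nb[inb, 1], nb[inb, 2], nb[inb, 3])
      hit <- rep(TRUE, nrow(co))
      hit[inb] <- labels[nb_idx] != label
      on_surface <- on_surface | hit
    }
  }
  sweep(co[on_surface, , drop = FALSE] - 1, 2, voxel_size, `*`)
}

# Local-background-contrast mask refinement: replace each seed
# component by the connected region of the smoothed image, within a
# padded bounding box, that exceeds background + fraction * (local peak
# - background) and overlaps the seed. Emulates contrast-based object
# delineation: extents track cells rather than response level sets.
refine_labels_local_contrast <- function(labels, n_lab, smoothed, pad,
                                         fraction) {
  d <- dim(labels)
  bg <- median(smoothed)
  out <- array(0L, d)
  idx_all <- which(labels > 0)
  co_all <- arrayInd(idx_all, d)
  lab_all <- labels[idx_all]
  for (l in seq_len(n_lab)) {
    co <- co_all[lab_all == l, , drop = FALSE]
    if (nrow(co) == 0) next
    rng <- lapply(1:3, function(a) {
      max(1L, min(co[, a]) - pad):min(d[a], max(co[, a]) + pad)
    })
    sub <- smoothed[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    seed_sub <- labels[rng[[1]], rng[[2]], rng[[3]], drop = FALSE] == l
    peak <- max(sub[seed_sub])
    level <- bg + fraction * (peak - bg)
    m <- sub > level
    if (!any(m & seed_sub)) m <- seed_sub
    cl <- label_components_cpp(as.integer(m), dim(sub))
    dim(cl) <- dim(sub)
    hit <- unique(cl[cl > 0 & seed_sub])
    sel <- array(cl %in% hit, dim(sub))
    target <- out[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    target[sel & target == 0L] <- l
    out[rng[[1]], rng[[2]], rng[[3]]] <- target
  }
  out
}

#' Laplacian-of-Gaussian 3D cell segmentation
#'
#' Smooths the volume at `sigma_G`, computes the (negated)
#' Laplacian-of-Gaussian response at `sigma_L`, thresholds it, labels
#' 26-connected components, and filters them by volume and sphericity.
#' Sphericity is `pi^(1/3) (6V)^(2/3) / A` with A the digitization-
#' corrected exposed-face surface area.
#'
#' @param volume (z, y, x) intensity array.
#' @param sigma_L,sigma_G LoG and pre-smoothing Gaussian scales. By
#'   default interpreted in voxels of the analyzed image (as in the
#'   original macro); set `sigma_units = "um"` to interpret them in
#'   micrometers via `voxel_size`.
#' @param sigma_units `"voxel"` or `"um"`.
#' @param voxel_size (z, y, x) voxel size in micrometers.
#' @param threshold_policy `"ksd"` (mean + k * sd of the response;
#'   deterministic stand-in for interactive local-background-contrast
#'   thresholding) or `"absolute"`.
#' @param k multiplier for the `"ksd"` policy.
#' @param absolute_threshold response threshold for `"absolute"`.
#' @param min_volume minimum object volume in cubic micrometers.
#' @param min_sphericity minimum sphericity (0 disables).
#' @param refine_mask if `TRUE` (default), each detected component is
#'   re-delineated by local background contrast: its extent becomes the
#'   connected region, around the LoG seed, where the smoothed image
#'   exceeds background plus `local_contrast_fraction` of the local
#'   peak contrast. This makes the object extent track the cell, not
#'   the response superlevel set, so per-object volumes and mean
#'   intensities are meaningful across brightness levels.
#' @param local_contrast_fraction contrast fraction for the
#'   refinement.
#' @return list with `cells` (data.frame: label, centroid `z`, `y`, `x`
#'   in um, `n_voxels`, `volume_um3`, `sphericity`, `mean_intensity`,
#'   `depth_um` = NA until [assign_depths()]) and `labels` (integer
#'   array; only surviving labels are nonzero).
#' @export
segment_cells_log <- function(volume, sigma_L = 10, sigma_G = 5,
                              sigma_units = c("voxel", "um"),
                              voxel_size = c(1, 1, 1),
                              threshold_policy = c("ksd", "absolute"),
                              k = 3, absolute_threshold = NULL,
                              min_volume = 0, min_sphericity = 0,
                              refine_mask = TRUE,
                              local_contrast_fraction = 0.5) {
  sigma_units <- match.arg(sigma_units)
  threshold_policy <- match.arg(threshold_policy)
  stopifnot(sigma_L > 0, sigma_G > 0, length(dim(volume)) == 3)
  sL <- if (sigma_units == "um") sigma_L / voxel_size else rep(sigma_L, 3)
  sG <- if (sigma_units == "um") sigma_G / voxel_size else rep(sigma_G, 3)
  if (any(dim(volume) < 2 * ceiling(3.5 * pmax(sL, sG)) + 1)) {
    stop("volume smaller than the filter support")
  }
  empty <- data.frame(label = integer(0), z = numeric(0), y = numeric(0),
                      x = numeric(0), n_voxels = integer(0),
                      volume_um3 = numeric(0), sphericity = numeric(0),
                      mean_intensity = numeric(0), depth_um = numeric(0))
  if (diff(range(volume)) == 0) {   # featureless volume
    return(list(cells = empty, labels = array(0L, dim(volume)),
                threshold = NA_real_))
  }
  smoothed <- gaussian_smooth(volume, sG)
  # negated LoG: bright blobs give positive response
  resp <- 0
  for (axis in 1:3) {
    part <- smoothed
    for (ax in 1:3) {
      kern <- if (ax == axis) gaussian_deriv2_kernel(sL[ax])
              else gaussian_kernel(sL[ax])
      part <- conv_axis(part, kern, ax)
    }
    resp <- resp - part
  }
  thr <- if (threshold_policy == "ksd") mean(resp) + k * sd(resp)
         else absolute_threshold
  mask <- resp > thr
  if (!any(mask)) {
    return(list(cells = empty, labels = array(0L, dim(volume)),
                threshold = thr))
  }
  labels <- label_components_cpp(as.integer(mask), dim(volume))
  n_lab <- attr(labels, "n_labels")
  dim(labels) <- dim(volume)
  if (refine_mask) {
    labels <- refine_labels_local_contrast(labels, n_lab, smoothed,
                                           pad = ceiling(2 * max(sL)),
                                           fraction = local_contrast_fraction)
  }
  counts <- tabulate(labels[labels > 0], nbins = n_lab)
  voxel_vol <- prod(voxel_size)
  areas <- label_surface_areas(labels, voxel_size, n_lab)
  vol_um3 <- counts * voxel_vol
  spher <- pi^(1 / 3) * (6 * vol_um3)^(2 / 3) / areas
  idx <- which(labels > 0)
  co <- arrayInd(idx, dim(volume))
  lab_v <- labels[idx]
  cz <- tapply((co[, 1] - 1) * voxel_size[1], lab_v, mean)
  cy <- tapply((co[, 2] - 1) * voxel_size[2], lab_v, mean)
  cx <- tapply((co[, 3] - 1) * voxel_size[3], lab_v, mean)
  mi <- tapply(volume[idx], lab_v, mean)
  ids <- as.integer(names(cz))
  tab <- data.frame(label = ids, z = as.numeric(cz), y = as.numeric(cy),
                    x = as.numeric(cx), n_voxels = counts[ids],
                    volume_um3 = vol_um3[ids], sphericity = spher[ids],
                    mean_intensity = as.numeric(mi),
                    depth_um = NA_real_)
  keep <- tab$volume_um3 >= min_volume & tab$sphericity >= min_sphericity
  dropped <- tab$label[!keep]
  if (length(dropped)) labels[labels %in% dropped] <- 0L
  tab <- tab[keep, , drop = FALSE]
  rownames(tab) <- NULL
  list(cells = tab, labels = labels, threshold = thr)
}

#' Assign per-cell depths from a distance map
#'
#' Each cell's depth is the mean of the distance-from-surface map over
#' its labeled voxels, mirroring the use of a distance-transformation
#' channel's mean intensity per segmented object.
#'
#' @param segmentation a [segment_cells_log()] result.
#' @param dmap a [distance_from_surface()] result on the same geometry.
#' @return the segmentation with `cells$depth_um` populated.
#' @export
assign_depths <- function(segmentation, dmap) {
  stopifnot(inherits(dmap, "distance_map"))
  labels <- segmentation$labels
  if (!identical(dim(labels), dim(dmap$values))) {
    stop("segmentation and distance map geometries differ")
  }
  if (nrow(segmentation$cells) == 0) return(segmentation)
  idx <- which(labels > 0)
  depth_by <- tapply(dmap$values[idx], labels[idx], mean)
  segmentation$cells$depth_um <-
    as.numeric(depth_by[as.character(segmentation$cells$label)])
  segmentation
}

#' Depth-distribution statistics
#'
#' Moment-based skewness and excess kurtosis (Fisher convention: a
#' normal distribution scores 0), along with n, mean, median, and IQR.
#' Population-moment (n-denominator) formulas by default; set
#' `adjusted = TRUE` for the sample-corrected versions.
#'
#' @param depths numeric vector (n >= 4 for the higher moments).
#' @param adjusted use sample-size-corrected skewness/kurtosis.
#' @return list with `n`, `mean`, `median`, `iqr`, `skewness`,
#'   `excess_kurtosis`. Zero-variance input yields `NA` for the
#'   standardized moments.
#' @export
depth_stats <- function(depths, adjusted = FALSE) {
  depths <- depths[!is.na(depths)]
  n <- length(depths)
  stopifnot(n >= 1)
  m <- mean(depths)
  out <- list(n = n, mean = m, median = median(depths),
              iqr = unname(diff(quantile(depths, c(0.25, 0.75)))),
              skewness = NA_real_, excess_kurtosis = NA_real_)
  if (n < 4) return(out)
  m2 <- mean((depths - m)^2)
  if (m2 == 0) return(out)
  g1 <- mean((depths - m)^3) / m2^1.5
  g2 <- mean((depths - m)^4) / m2^2 - 3
  if (adjusted) {
    g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
    g2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  }
  out$skewness <- g1
  out$excess_kurtosis <- g2
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of depth distributions
#'
#' @param depths_a,depths_b numeric samples (non-empty).
#' @return list with `ks_statistic` (sup of the absolute ECDF
#'   difference) and `p_value` (asymptotic).
#' @export
compare_depth_distributions <- function(depths_a, depths_b) {
  if (length(depths_a) == 0 || length(depths_b) == 0) {
    stop("both samples must be non-empty")
  }
  kt <- suppressWarnings(ks.test(depths_a, depths_b, exact = FALSE))
  list(ks_statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Cell intensity versus depth
#'
#' Pairs each segmented cell's mean intensity with its depth and
#' reports Pearson and Spearman correlations; degenerate inputs (fewer
#' than 3 cells, or zero variance in either column) give `NA`
#' correlations with `degenerate = TRUE`.
#'
#' @param cells the `cells` data.frame of a depth-assigned
#'   [segment_cells_log()] result.
#' @return list with `table` (depth, mean_intensity), `pearson`,
#'   `spearman`, `degenerate`.
#' @export
intensity_vs_depth <- function(cells) {
  stopifnot(nrow(cells) >= 1)
  tab <- data.frame(depth_um = cells$depth_um,
                    mean_intensity = cells$mean_intensity)
  if (nrow(tab) < 2) {
    return(list(table = tab, pearson = NA_real_, spearman = NA_real_,
                degenerate = TRUE))
  }
  if (sd(tab$depth_um) == 0 || sd(tab$mean_intensity) == 0) {
    return(list(table = tab, pearson = 0, spearman = 0, degenerate = TRUE))
  }
  list(table = tab,
       pearson = cor(tab$depth_um, tab$mean_intensity),
       spearman = cor(tab$depth_um, tab$mean_intensity,
                      method = "spearman"),
       degenerate = FALSE)
}
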