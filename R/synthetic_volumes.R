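# Seeded generators of ground-truthed 3D image stacks that emulate the
# statistical structure of cleared-tissue fluorescence volumes: spherical
# cells with depth-dependent brightness, dim vessels carrying bright
# punctate precipitates, oriented fiber bundles, periodic per-plane gain
# artifacts, multiplicative shading, and Poisson-Gaussian noise.
#
# Conventions: arrays are (z, y, x); voxel indices are 0-based in the
# ground truth; the physical coordinate of voxel index i along an axis
# with spacing w is i * w (voxel-center coordinates).

#' Specification of a synthetic volume
#'
#' @param shape integer vector `(n_z, n_y, n_x)`, all >= 8.
#' @param voxel_size physical voxel size `(z, y, x)` in micrometers.
#' @param background_level baseline intensity of unlabeled tissue
#'   voxels (autofluorescence).
#' @param outside_level intensity of non-tissue voxels (mounting
#'   medium / empty space); defaults to `background_level / 5`.
#' @param noise list with `gaussian_sd` (additive read noise) and
#'   `poisson_scale` (photon-noise granularity; 0 disables the Poisson
#'   component).
#' @param seed integer seed; a fixed seed makes every generator
#'   deterministic.
#' @param tissue_margin thickness, in voxels, of the non-tissue rim.
#' @param geometry `"box"` (non-tissue rim on all six faces) or
#'   `"slab"` (single cut surface at low z, as in a sectioned block).
#' @return object of class `volume_spec`.
#' @export
volume_spec <- function(shape, voxel_size = c(1, 1, 1),
                        background_level = 0.05,
                        outside_level = background_level / 5,
                        noise = list(gaussian_sd = 0.02, poisson_scale = 0),
                        seed = 1L, tissue_margin = 2L,
                        geometry = c("box", "slab")) {
  geometry <- match.arg(geometry)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 8), all(voxel_size > 0),
            noise$gaussian_sd >= 0, noise$poisson_scale >= 0,
            outside_level >= 0, outside_level <= background_level,
            tissue_margin >= 1)
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 background_level = background_level,
                 outside_level = outside_level, noise = noise,
                 seed = as.integer(seed),
                 tissue_margin = as.integer(tissue_margin),
                 geometry = geometry),
            class = "volume_spec")
}

#' @rdname volume_spec
#' @param spec a `volume_spec`.
#' @return `tissue_mask_of()`: logical (z, y, x) array, TRUE on tissue.
#' @export
tissue_mask_of <- function(spec) {
  d <- spec$shape
  m <- spec$tissue_margin
  idx <- function(n) seq_len(n) - 1L
  z_in <- idx(d[1]) >= m & (if (spec$geometry == "box") idx(d[1]) < d[1] - m
                            else TRUE)
  if (spec$geometry == "box") {
    y_in <- idx(d[2]) >= m & idx(d[2]) < d[2] - m
    x_in <- idx(d[3]) >= m & idx(d[3]) < d[3] - m
  } else {
    y_in <- rep(TRUE, d[2])
    x_in <- rep(TRUE, d[3])
  }
  outer(z_in, outer(y_in, x_in, "&"), "&")
}

# Physical coordinate arrays of voxel centers, one per axis.
voxel_coords <- function(spec) {
  lapply(1:3, function(a) (seq_len(spec$shape[a]) - 1) * spec$voxel_size[a])
}

# Analytic depth (um) of a point from the nearest non-tissue voxel
# center, for the box/slab tissue geometries. Independent of the
# distance-transform code, so it can serve as ground truth against it.
analytic_depth <- function(spec, point) {
  m <- spec$tissue_margin
  w <- spec$voxel_size
  d <- spec$shape
  lows <- point - (m - 1) * w               # distance to low-side rim
  highs <- ((d - m) * w) - point            # distance to high-side rim
  if (spec$geometry == "slab") min(lows[1]) else min(lows, highs)
}

blank_volume <- function(spec) {
  vol <- array(spec$background_level, dim = spec$shape)
  vol[!tissue_mask_of(spec)] <- spec$outside_level
  vol
}

# Squared physical distance of every voxel center to a point, as an array.
dist2_to_point <- function(spec, point) {
  co <- voxel_coords(spec)
  dz2 <- (co[[1]] - point[1])^2
  dy2 <- (co[[2]] - point[2])^2
  dx2 <- (co[[3]] - point[3])^2
  outer(dz2, outer(dy2, dx2, "+"), "+")
}

#' Specification of the synthetic cell population
#'
#' @param n_cells number of cells.
#' @param radius_range min/max cell radius in micrometers.
#' @param intensity_range min/max nominal peak intensity.
#' @param depth_profile function mapping depth (um) to relative staining
#'   intensity (vectorized, values >= 0); e.g. a constant 1 for uniform
#'   staining, or a decaying curve for penetration-limited staining. A
#'   bound-complex radial profile from the reaction-diffusion module can
#'   be wrapped with [depth_profile_from_rd()].
#' @param min_gap minimum surface-to-surface gap between cells (um);
#'   placement uses rejection sampling.
#' @return object of class `cell_spec`.
#' @export
cell_spec <- function(n_cells = 50, radius_range = c(8, 12),
                      intensity_range = c(0.5, 0.9),
                      depth_profile = function(d) rep(1, length(d)),
                      min_gap = 12) {
  stopifnot(n_cells >= 0, all(radius_range > 0),
            diff(radius_range) >= 0, diff(intensity_range) >= 0,
            is.function(depth_profile), min_gap >= 0)
  structure(list(n_cells = as.integer(n_cells), radius_range = radius_range,
                 intensity_range = intensity_range,
                 depth_profile = depth_profile, min_gap = min_gap),
            class = "cell_spec")
}

#' Turn a bound-complex radial profile into a depth profile
#'
#' Maps depth below the cylinder surface (um, via `length_scale`) to the
#' bound-complex concentration at the corresponding radius, normalized
#' to the profile maximum. Lets the reaction-diffusion solution drive
#' the depth dependence of the synthetic cell brightness.
#'
#' @param profile a [profile_at()] result.
#' @param length_scale physical length (um) corresponding to one
#'   dimensionless radius unit.
#' @return function depth_um -> relative intensity in `[0, 1]`.
#' @export
depth_profile_from_rd <- function(profile, length_scale = 100) {
  r_in <- profile$r[profile$inside]
  v_in <- profile$value[profile$inside]
  top <- max(v_in)
  if (top <= 0) return(function(d) rep(0, length(d)))
  r_surface <- max(r_in)
  function(d) {
    r_eq <- pmax(r_surface - d / length_scale, min(r_in))
    approx(r_in, v_in, xout = r_eq, rule = 2)$y / top
  }
}

#' Generate spherical cells with depth-dependent brightness
#'
#' Cells are isotropic Gaussians (sigma = radius / 2) truncated at 3
#' sigma, placed by rejection sampling so that spheres lie fully inside
#' the tissue mask and centers respect the pairwise separation
#' constraint. Each cell's rendered peak intensity is its sampled
#' nominal intensity times `depth_profile(true depth)`, where the true
#' depth is the distance of the center from the nearest non-tissue
#' voxel.
#'
#' @param spec a [volume_spec()].
#' @param cells a [cell_spec()].
#' @param max_attempts rejection-sampling budget.
#' @return list with `volume` (noise-free intensity array) and `truth`,
#'   a list holding `cell_table` (data.frame: center coordinates in um,
#'   radius, nominal intensity, rendered peak, true depth) and
#'   `tissue_mask`.
#' @export
generate_cells <- function(spec, cells = cell_spec(), max_attempts = 10000) {
  stopifnot(inherits(spec, "volume_spec"), inherits(cells, "cell_spec"))
  set.seed(spec$seed)
  vol <- blank_volume(spec)
  tissue <- tissue_mask_of(spec)
  tab <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                    radius_um = numeric(0), intensity = numeric(0),
                    peak = numeric(0), depth_um = numeric(0))
  if (cells$n_cells == 0) {
    return(list(volume = vol,
                truth = list(cell_table = tab, tissue_mask = tissue)))
  }
  w <- spec$voxel_size
  m <- spec$tissue_margin
  d <- spec$shape
  placed <- matrix(numeric(0), ncol = 4) # z, y, x, radius
  attempts <- 0
  while (nrow(placed) < cells$n_cells) {
    attempts <- attempts + 1
    if (attempts > max_attempts) {
      stop("cell placement failed: placed ", nrow(placed), " of ",
           cells$n_cells, " cells in ", max_attempts, " attempts")
    }
    r_um <- runif(1, cells$radius_range[1], cells$radius_range[2])
    # whole sphere inside tissue: center depth >= radius + one voxel
    lo <- (m - 1) * w + r_um + w
    hi <- (d - m) * w - r_um - w
    if (spec$geometry == "slab") {
      hi_slab <- (d - 1) * w - r_um - w
      hi <- c(hi[1], hi_slab[2:3])
      lo <- c(lo[1], r_um + w[2], r_um + w[3])
    }
    if (any(hi <= lo)) stop("cells do not fit inside the tissue mask")
    p <- runif(3, lo, hi)
    if (nrow(placed) > 0) {
      dd <- sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - p)^2))
      if (any(dd < placed[, 4] + r_um + cells$min_gap)) next
    }
    placed <- rbind(placed, c(p, r_um))
  }
  co <- voxel_coords(spec)
  for (i in seq_len(nrow(placed))) {
    p <- placed[i, 1:3]
    r_um <- placed[i, 4]
    inten <- runif(1, cells$intensity_range[1], cells$intensity_range[2])
    depth <- analytic_depth(spec, p)
    peak <- inten * cells$depth_profile(depth)
    sig <- r_um / 2
    # render only inside the 3 sigma bounding box
    rng <- lapply(1:3, function(a) {
      lo <- max(1L, floor((p[a] - 3 * sig) / w[a]) + 1L)
      hi <- min(d[a], ceiling((p[a] + 3 * sig) / w[a]) + 1L)
      lo:hi
    })
    d2 <- outer((co[[1]][rng[[1]]] - p[1])^2,
                outer((co[[2]][rng[[2]]] - p[2])^2,
                      (co[[3]][rng[[3]]] - p[3])^2, "+"), "+")
    sub <- vol[rng[[1]], rng[[2]], rng[[3]]]
    sel <- d2 <= (3 * sig)^2
    sub[sel] <- sub[sel] + peak * exp(-d2[sel] / (2 * sig^2))
    vol[rng[[1]], rng[[2]], rng[[3]]] <- sub
    tab[i, ] <- c(p, r_um, inten, peak, depth)
  }
  list(volume = vol, truth = list(cell_table = tab, tissue_mask = tissue))
}

#' Generate straight vessels with intravascular precipitates
#'
#' Vessels are randomly oriented straight tubes of dim signal; bright
#' ellipsoidal precipitates (max diameter capped) are seeded inside the
#' tubes as a Poisson process over the vessel volume and clipped to the
#' lumen, so the precipitate mask is always a subset of the vessel mask.
#'
#' @param spec a [volume_spec()].
#' @param n_vessels number of tubes.
#' @param radius_um tube radius in micrometers.
#' @param precipitate_density expected precipitates per cubic micrometer
#'   of vessel volume.
#' @param vessel_intensity,precipitate_intensity rendered intensities.
#' @param precipitate_diameter_range min/max precipitate max-diameter
#'   (um); the max must not exceed 10.
#' @return list with `volume` and `truth` (`vessel_mask`,
#'   `precipitate_mask`, `precipitate_table`, `tissue_mask`).
#' @export
generate_vessels <- function(spec, n_vessels = 6, radius_um = 4,
                             precipitate_density = 7e-4,
                             vessel_intensity = 0.12,
                             precipitate_intensity = 0.9,
                             precipitate_diameter_range = c(4, 8)) {
  stopifnot(inherits(spec, "volume_spec"),
            radius_um >= min(spec$voxel_size),
            max(precipitate_diameter_range) <= 10)
  set.seed(spec$seed + 1L)
  vol <- blank_volume(spec)
  tissue <- tissue_mask_of(spec)
  vessel <- array(FALSE, spec$shape)
  co <- voxel_coords(spec)
  extent <- (spec$shape - 1) * spec$voxel_size
  cz <- array(co[[1]], spec$shape)
  cy <- aperm(array(co[[2]], spec$shape[c(2, 1, 3)]), c(2, 1, 3))
  cx <- aperm(array(co[[3]], spec$shape[c(3, 2, 1)]), c(3, 2, 1))
  for (i in seq_len(n_vessels)) {
    p0 <- runif(3, 0.2, 0.8) * extent
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    # squared distance of voxel centers to the line p0 + s*u
    rz <- cz - p0[1]; ry <- cy - p0[2]; rx <- cx - p0[3]
    s <- rz * u[1] + ry * u[2] + rx * u[3]
    d2 <- (rz - s * u[1])^2 + (ry - s * u[2])^2 + (rx - s * u[3])^2
    vessel <- vessel | (d2 <= radius_um^2 & tissue)
  }
  vol[vessel] <- pmax(vol[vessel], spec$background_level + vessel_intensity)
  voxel_vol <- prod(spec$voxel_size)
  vessel_volume_um3 <- sum(vessel) * voxel_vol
  n_prec <- rpois(1, precipitate_density * vessel_volume_um3)
  precip <- array(FALSE, spec$shape)
  ptab <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                     max_diameter_um = numeric(0))
  if (n_prec > 0) {
    vessel_idx <- which(vessel)
    placed <- matrix(numeric(0), ncol = 4)  # z, y, x, dmax
    for (i in seq_len(n_prec)) {
      dmax <- runif(1, precipitate_diameter_range[1],
                    precipitate_diameter_range[2])
      # separate aggregates so they stay individually resolvable (and
      # within the diameter scale): centers at least the sum of the
      # semi-diameters plus a 2 um margin apart
      for (attempt in 1:100) {
        ctr <- arrayInd(sample(vessel_idx, 1), spec$shape)
        p <- (ctr - 1) * spec$voxel_size
        if (nrow(placed) == 0 ||
            all(sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - c(p))^2)) >=
                  (placed[, 4] + dmax) / 2 + 2)) {
          placed <- rbind(placed, c(p, dmax))
          break
        }
      }
    }
    for (i in seq_len(nrow(placed))) {
      p <- placed[i, 1:3]
      dmax <- placed[i, 4]
      semi <- c(dmax / 2,
                runif(2, 0.6, 1) * dmax / 2) # a >= b, c
      q2 <- ((cz - p[1]) / semi[1])^2 + ((cy - p[2]) / semi[2])^2 +
        ((cx - p[3]) / semi[3])^2
      precip <- precip | (q2 <= 1 & vessel)
      ptab[i, ] <- c(p, dmax)
    }
    vol[precip] <- precipitate_intensity
  }
  list(volume = vol,
       truth = list(vessel_mask = vessel, precipitate_mask = precip,
                    precipitate_table = ptab,
                    tissue_mask = tissue_mask_of(spec)))
}

#' Generate a bundle of parallel fibers
#'
#' Straight cylinders along a common orientation with small per-fiber
#' angular jitter; the true unit orientation of every fiber voxel is
#' recorded.
#'
#' @param spec a [volume_spec()].
#' @param orientation unit direction vector in (z, y, x) component
#'   order (normalized internally; the zero vector is an error).
#' @param n_fibers number of fibers.
#' @param radius_um fiber radius in micrometers.
#' @param fiber_intensity rendered intensity above background.
#' @param jitter_sd standard deviation of per-fiber direction jitter.
#' @return list with `volume` and `truth` (`fiber_mask`, `orientation`
#'   as an (n_voxel x 3) matrix aligned with `which(fiber_mask)`, plus
#'   the per-fiber direction table).
#' @export
generate_fibers <- function(spec, orientation = c(0, 0, 1), n_fibers = 8,
                            radius_um = 2, fiber_intensity = 0.6,
                            jitter_sd = 0.02) {
  stopifnot(inherits(spec, "volume_spec"),
            radius_um >= min(spec$voxel_size))
  nrm <- sqrt(sum(orientation^2))
  if (nrm == 0) stop("orientation must be a nonzero vector")
  orientation <- orientation / nrm
  set.seed(spec$seed + 2L)
  vol <- blank_volume(spec)
  tissue <- tissue_mask_of(spec)
  fiber <- array(FALSE, spec$shape)
  vz <- array(0, spec$shape); vy <- vz; vx <- vz
  co <- voxel_coords(spec)
  extent <- (spec$shape - 1) * spec$voxel_size
  cz <- array(co[[1]], spec$shape)
  cy <- aperm(array(co[[2]], spec$shape[c(2, 1, 3)]), c(2, 1, 3))
  cx <- aperm(array(co[[3]], spec$shape[c(3, 2, 1)]), c(3, 2, 1))
  dirs <- matrix(NA_real_, n_fibers, 3)
  for (i in seq_len(n_fibers)) {
    u <- orientation + rnorm(3, sd = jitter_sd)
    u <- u / sqrt(sum(u^2))
    dirs[i, ] <- u
    p0 <- runif(3, 0.15, 0.85) * extent
    rz <- cz - p0[1]; ry <- cy - p0[2]; rx <- cx - p0[3]
    s <- rz * u[1] + ry * u[2] + rx * u[3]
    d2 <- (rz - s * u[1])^2 + (ry - s * u[2])^2 + (rx - s * u[3])^2
    sel <- d2 <= radius_um^2 & tissue
    fiber <- fiber | sel
    vz[sel] <- u[1]; vy[sel] <- u[2]; vx[sel] <- u[3]
    vol[sel] <- spec$background_level + fiber_intensity
  }
  idx <- which(fiber)
  list(volume = vol,
       truth = list(fiber_mask = fiber,
                    orientation = cbind(z = vz[idx], y = vy[idx],
                                        x = vx[idx]),
                    fiber_directions = dirs,
                    tissue_mask = tissue_mask_of(spec)))
}

#' Apply acquisition artifacts and noise
#'
#' Multiplies each z-plane by a periodic gain (emulating the per-N-plane
#' intensity artifact of serial acquisition), applies a smooth
#' multiplicative in-plane shading field (vignette), then adds
#' Poisson-Gaussian noise. With zero amplitude, zero shading scale and
#' zero noise the volume is returned unchanged.
#'
#' @param volume (z, y, x) array.
#' @param spec the [volume_spec()] (supplies seed and noise defaults).
#' @param period artifact period in planes (>= 2).
#' @param modulation_amplitude relative amplitude of the periodic gain.
#' @param shading_scale strength of the parabolic vignette (0..1).
#' @param noise noise parameters; defaults to `spec$noise`.
#' @return distorted volume.
#' @export
add_acquisition_artifacts <- function(volume, spec, period = 10,
                                      modulation_amplitude = 0,
                                      shading_scale = 0,
                                      noise = spec$noise) {
  stopifnot(period >= 2)
  d <- dim(volume)
  gain <- 1 + modulation_amplitude * sin(2 * pi * (seq_len(d[1]) - 1) / period)
  volume <- volume * gain   # gain recycles down the first (z) extent
  if (shading_scale > 0) {
    yy <- (seq_len(d[2]) - 1) / (d[2] - 1) - 0.5
    xx <- (seq_len(d[3]) - 1) / (d[3] - 1) - 0.5
    field <- 1 - shading_scale * outer(yy^2 + 0.25, xx^2, "+") * 2
    field <- field / mean(field)
    volume <- volume * rep(aperm(array(field, c(d[2], d[3], d[1])),
                                 c(3, 1, 2)), 1)
  }
  apply_noise(volume, spec, noise)
}

# Poisson-Gaussian camera noise: scaled Poisson shot noise plus additive
# Gaussian read noise, seeded from the spec.
apply_noise <- function(volume, spec, noise = spec$noise) {
  if (noise$poisson_scale == 0 && noise$gaussian_sd == 0) return(volume)
  set.seed(spec$seed + 3L)
  d <- dim(volume)
  if (noise$poisson_scale > 0) {
    volume <- noise$poisson_scale *
      array(rpois(length(volume), pmax(volume, 0) / noise$poisson_scale), d)
  }
  if (noise$gaussian_sd > 0) {
    volume <- volume + array(rnorm(length(volume), sd = noise$gaussian_sd), d)
  }
  volume
}

#' Combine component volumes over a shared background
#'
#' Signals are additive above the common background level, so summing
#' cell, vessel and fiber renderings preserves each component's masks
#' and tables unchanged.
#'
#' @param volumes list of (z, y, x) arrays rendered on the same
#'   [volume_spec()] baseline.
#' @param spec the shared `volume_spec`.
#' @return combined array.
#' @export
combine_volumes <- function(volumes, spec) {
  base <- blank_volume(spec)
  Reduce(`+`, lapply(volumes, function(v) v - base)) + base
}

#' Canonical synthetic scenes
#'
#' Fixed default scenes used throughout the test-bed analyses:
#' `synthetic_cell_scene()` — 50 non-overlapping cells (radius 8-12 um)
#' in a 64 x 160 x 160 voxel box at 2 um isotropic sampling;
#' `synthetic_vessel_scene()` — 6 tubes (radius 4 um) with bright
#' precipitates at 1 um sampling; `synthetic_fiber_scene()` — a jittered
#' parallel fiber bundle at 1 um sampling.
#'
#' @param seed integer seed.
#' @param depth_profile depth-to-intensity mapping for the cells.
#' @param noise noise settings override.
#' @return as the underlying generator, with noise applied to `volume`
#'   (the noise-free rendering is kept as `clean`).
#' @export
synthetic_cell_scene <- function(seed = 1L,
                                 depth_profile = function(d)
                                   rep(1, length(d)),
                                 noise = list(gaussian_sd = 0.02,
                                              poisson_scale = 0.002)) {
  spec <- volume_spec(shape = c(64, 160, 160), voxel_size = c(2, 2, 2),
                      background_level = 0.05, noise = noise, seed = seed,
                      tissue_margin = 4L, geometry = "slab")
  g <- generate_cells(spec, cell_spec(n_cells = 50,
                                      depth_profile = depth_profile))
  list(spec = spec, clean = g$volume,
       volume = apply_noise(g$volume, spec), truth = g$truth)
}

#' @rdname synthetic_cell_scene
#' @param precipitate_density expected precipitates per um^3 of vessel.
#' @export
synthetic_vessel_scene <- function(seed = 1L, precipitate_density = 7e-4,
                                   noise = list(gaussian_sd = 0.01,
                                                poisson_scale = 0)) {
  spec <- volume_spec(shape = c(64, 128, 128), voxel_size = c(1, 1, 1),
                      background_level = 0.05, noise = noise, seed = seed)
  g <- generate_vessels(spec, precipitate_density = precipitate_density)
  list(spec = spec, clean = g$volume,
       volume = apply_noise(g$volume, spec), truth = g$truth)
}

#' @rdname synthetic_cell_scene
#' @param orientation common fiber direction, (z, y, x) components.
#' @export
synthetic_fiber_scene <- function(seed = 1L, orientation = c(0, 0, 1),
                                  noise = list(gaussian_sd = 0.01,
                                               poisson_scale = 0)) {
  spec <- volume_spec(shape = c(48, 64, 64), voxel_size = c(1, 1, 1),
                      background_level = 0.05, noise = noise, seed = seed)
  g <- generate_fibers(spec, orientation = orientation)
  list(spec = spec, clean = g$volume,
       volume = apply_noise(g$volume, spec), truth = g$truth)
}
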