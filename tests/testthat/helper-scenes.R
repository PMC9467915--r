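# Shared fixtures: canonical synthetic scenes are expensive enough to
# build once per test run and reuse across files.
.scene_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.scene_cache[[key]])) .scene_cache[[key]] <- builder()
  .scene_cache[[key]]
}

cell_scene <- function(seed = 1L) {
  cached(paste0("cells", seed), function() synthetic_cell_scene(seed = seed))
}

vessel_scene <- function(seed = 1L) {
  cached(paste0("vessels", seed),
         function() synthetic_vessel_scene(seed = seed))
}

# Segment + depth-assign a cell scene with the canonical settings
# (physical-unit LoG sigmas 10 / 5 um).
segment_scene <- function(scene) {
  seg <- segment_cells_log(scene$volume, sigma_L = 10, sigma_G = 5,
                           sigma_units = "um",
                           voxel_size = scene$spec$voxel_size,
                           min_volume = 100, min_sphericity = 0.5)
  dmap <- distance_from_surface(scene$truth$tissue_mask,
                                scene$spec$voxel_size)
  assign_depths(seg, dmap)
}

# Match ground-truth cells to segmented objects by nearest centroid;
# a truth cell counts as recalled when the nearest object centroid lies
# within that cell's radius.
match_cells <- function(truth_table, cells) {
  if (nrow(cells) == 0) {
    return(list(recall = 0, precision = NA_real_,
                matched = logical(nrow(truth_table)),
                match_idx = integer(nrow(truth_table))))
  }
  d2 <- outer(truth_table$z, cells$z, `-`)^2 +
    outer(truth_table$y, cells$y, `-`)^2 +
    outer(truth_table$x, cells$x, `-`)^2
  d <- sqrt(d2)
  mi <- apply(d, 1, which.min)
  matched <- d[cbind(seq_len(nrow(truth_table)), mi)] <= truth_table$radius_um
  det_matched <- apply(d, 2, min) <= max(truth_table$radius_um)
  list(recall = mean(matched), precision = mean(det_matched),
       matched = matched, match_idx = mi)
}

# Brute-force all-pairs distance-to-background oracle (physical units).
brute_force_edt <- function(mask, w) {
  d <- dim(mask)
  bg <- which(!mask)
  tis <- which(mask)
  cob <- (arrayInd(bg, d) - 1) %*% diag(w)
  cot <- (arrayInd(tis, d) - 1) %*% diag(w)
  g <- outer(rowSums(cot^2), rowSums(cob^2), "+") - 2 * cot %*% t(cob)
  out <- array(0, d)
  out[tis] <- sqrt(pmax(apply(g, 1, min), 0))
  out
}

angular_error_deg <- function(u, v) {
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  acos(min(1, abs(sum(u * v)))) * 180 / pi
}
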