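# Surface segmentation (threshold -> 26-connected labelling -> size filter),
# vessel mask construction (closing + lumen filling), and LoG nucleus spot
# detection.

resolve_threshold <- function(channel, threshold, check_range = TRUE) {
  method <- threshold$method %||% "otsu"
  if (method == "otsu") {
    otsu_threshold(channel)
  } else {
    value <- threshold$value
    if (check_range) {
      rng <- range(channel, finite = TRUE)
      if (value < rng[1] || value > rng[2]) {
        abort(sprintf("manual threshold %g lies outside the intensity range [%g, %g]",
                      value, rng[1], rng[2]))
      }
    }
    value
  }
}

#' Segment a channel into labelled 3D surface objects
#'
#' Absolute-intensity thresholding (Otsu by default, a manual value when
#' provided), 26-connected component labelling, and a minimum-size filter.
#' Per-object volumes are voxel counts times the physical voxel volume.
#'
#' @param channel 3D numeric array (typically smoothed and
#'   background-corrected).
#' @param voxel_size_um Voxel size (z, y, x), micrometers.
#' @param threshold `list(method = "otsu")` or
#'   `list(method = "manual", value = ...)`.
#' @param min_object_voxels Smallest connected component kept.
#' @param channel_name Recorded as the object source.
#' @return A `surface_set`: label array (`labels`), per-object tibble
#'   (`objects` with label, voxel_count, volume_um3, centroid), the threshold
#'   used, and the source channel name.
#' @export
segment_surfaces <- function(channel, voxel_size_um,
                             threshold = list(method = "otsu"),
                             min_object_voxels = 5L,
                             channel_name = NULL) {
  check_volume(channel, "channel")
  voxel_size_um <- check_voxel_size(voxel_size_um)
  thr <- resolve_threshold(channel, threshold)
  segment_surfaces_absolute(channel, voxel_size_um, thr, min_object_voxels, channel_name)
}

# Core segmentation at a resolved absolute threshold; shared with the masked
# re-segmentation of the extravasation analysis, where the threshold may
# legitimately exceed the (masked) channel range.
segment_surfaces_absolute <- function(channel, voxel_size_um, thr,
                                      min_object_voxels = 5L, channel_name = NULL) {
  d <- dim(channel)
  fg <- channel > thr
  labels <- cpp_label26(as.logical(fg), d)
  n_raw <- max(labels, 0L)
  objects <- tibble::tibble(label = integer(0), voxel_count = integer(0),
                            volume_um3 = numeric(0), centroid_z_um = numeric(0),
                            centroid_y_um = numeric(0), centroid_x_um = numeric(0))
  if (n_raw > 0) {
    counts <- tabulate(labels, nbins = n_raw)
    keep <- which(counts >= min_object_voxels)
    relabel <- integer(n_raw)
    relabel[keep] <- seq_along(keep)
    nz <- labels != 0L
    labels[nz] <- relabel[labels[nz]]
    if (length(keep) > 0) {
      idx1 <- which(labels != 0L)
      lab <- labels[idx1]
      vox <- linear_to_index(idx1, d)
      um <- index_to_um(vox, voxel_size_um)
      cen <- rowsum(um, lab) / as.vector(table(lab))
      cnt <- counts[keep]
      objects <- tibble::tibble(
        label = seq_along(keep),
        voxel_count = cnt,
        volume_um3 = cnt * voxel_volume_um3(voxel_size_um),
        centroid_z_um = cen[, 1],
        centroid_y_um = cen[, 2],
        centroid_x_um = cen[, 3]
      )
    }
  }
  structure(list(
    labels = array(labels, dim = d),
    objects = objects,
    threshold = thr,
    voxel_size_um = voxel_size_um,
    source_channel = channel_name
  ), class = "surface_set")
}

#' @export
print.surface_set <- function(x, ...) {
  cat(sprintf("<surface_set> %d object(s) from '%s', threshold %.4g, total %.0f um^3\n",
              nrow(x$objects), x$source_channel %||% "?", x$threshold,
              sum(x$objects$volume_um3)))
  invisible(x)
}

#' Build a filled vessel mask from vessel surfaces
#'
#' Takes the binary union of the segmented vessel objects, applies a 3D
#' morphological closing (radius = the surface smoothing detail) to bridge
#' small gaps, then fills interior cavities so the lumen of shell-like vessel
#' staining counts as intravascular.
#'
#' @param vessel_surfaces A `surface_set` from the vessel channel.
#' @param closing_radius_um Closing radius, micrometers.
#' @return A `vessel_mask`: logical `mask`, `total_volume_um3`,
#'   `voxel_size_um`.
#' @export
build_vessel_mask <- function(vessel_surfaces, closing_radius_um = 2) {
  stopifnot(inherits(vessel_surfaces, "surface_set"))
  d <- dim(vessel_surfaces$labels)
  vs <- vessel_surfaces$voxel_size_um
  bin <- as.numeric(vessel_surfaces$labels != 0L)
  offs <- ellipsoid_offsets(closing_radius_um, vs)
  if (nrow(offs) > 1) {
    bin <- cpp_morph(cpp_morph(bin, d, offs, TRUE), d, offs, FALSE)
  }
  filled <- cpp_fill_holes(bin > 0.5, d)
  mask <- array(filled, dim = d)
  structure(list(
    mask = mask,
    total_volume_um3 = sum(mask) * voxel_volume_um3(vs),
    voxel_size_um = vs
  ), class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %.0f um^3 vascular volume (%.1f%% of the field)\n",
              x$total_volume_um3, 100 * mean(x$mask)))
  invisible(x)
}

#' Detect nucleus spots with a scale-matched Laplacian of Gaussian
#'
#' Blurs the channel at sigma = `spot_diameter_um / (2 sqrt(3))` per axis
#' (anisotropy-corrected; axes coarser than the blob are skipped), takes the
#' negated scale-normalized Laplacian as the detector response, finds 26-
#' neighbourhood local maxima, greedily enforces a minimum physical separation
#' of one spot diameter, and keeps maxima whose response ("quality") reaches
#' `spot_quality_min`.
#'
#' The retained-quality floor is `spot_quality_min` raised, when necessary, to
#' `noise_sigma_mult` times a robust estimate (scaled MAD) of the response
#' noise over the volume. This automates the interactive practice of raising
#' the quality cutoff above its nominal floor until background noise is
#' excluded; on noise-free data the floor stays at `spot_quality_min`.
#'
#' @param channel Nucleus channel, 3D numeric array.
#' @param voxel_size_um Voxel size (z, y, x), micrometers.
#' @param spot_diameter_um Estimated blob diameter, micrometers.
#' @param spot_quality_min Minimum detector response retained.
#' @param noise_sigma_mult Noise-floor multiplier for the automatic quality
#'   cutoff (classic 5-sigma detection by default); 0 disables the automatic
#'   raise.
#' @return A tibble (`spot_set`) with `center_z_um`, `center_y_um`,
#'   `center_x_um`, `diameter_um`, `quality`, ordered by decreasing quality.
#' @export
detect_spots <- function(channel, voxel_size_um, spot_diameter_um = 5,
                         spot_quality_min = 10, noise_sigma_mult = 5) {
  check_volume(channel, "channel")
  voxel_size_um <- check_voxel_size(voxel_size_um)
  if (spot_diameter_um <= 0) abort("`spot_diameter_um` must be positive")
  d <- dim(channel)
  sigma_um <- spot_diameter_um / (2 * sqrt(3))
  sigma_vox <- sigma_um / voxel_size_um
  sigma_vox[sigma_vox < 0.3] <- 0
  blurred <- array(cpp_gauss_blur(as.numeric(channel), d, sigma_vox), dim = d)
  resp <- -sigma_um^2 * laplacian_physical(blurred, voxel_size_um)

  if (noise_sigma_mult > 0) {
    sigma_noise <- stats::mad(resp, center = stats::median(resp))
    spot_quality_min <- max(spot_quality_min, noise_sigma_mult * sigma_noise)
  }
  floor_val <- spot_quality_min * (1 - 1e-9) - 1e-12
  cand <- cpp_local_max26(as.numeric(resp), d, floor_val)
  empty <- tibble::tibble(center_z_um = numeric(0), center_y_um = numeric(0),
                          center_x_um = numeric(0), diameter_um = numeric(0),
                          quality = numeric(0))
  if (length(cand) == 0) return(empty)
  q <- resp[cand]
  ord <- order(q, decreasing = TRUE)
  cand <- cand[ord]
  q <- q[ord]
  um <- index_to_um(linear_to_index(cand, d), voxel_size_um)

  keep <- logical(length(cand))
  kept_um <- matrix(numeric(0), ncol = 3)
  min_sep2 <- spot_diameter_um^2
  for (i in seq_along(cand)) {
    if (nrow(kept_um) > 0) {
      d2 <- (kept_um[, 1] - um[i, 1])^2 + (kept_um[, 2] - um[i, 2])^2 +
        (kept_um[, 3] - um[i, 3])^2
      if (any(d2 < min_sep2)) next
    }
    keep[i] <- TRUE
    kept_um <- rbind(kept_um, um[i, , drop = FALSE])
  }
  sel <- which(keep & q >= spot_quality_min)
  if (length(sel) == 0) return(empty)
  tibble::tibble(
    center_z_um = um[sel, 1],
    center_y_um = um[sel, 2],
    center_x_um = um[sel, 3],
    diameter_um = spot_diameter_um,
    quality = q[sel]
  )
}

# 3D Laplacian by second central differences scaled by the physical spacing;
# boundary planes replicate their neighbours (zero second derivative).
laplacian_physical <- function(x, voxel_size_um) {
  d <- dim(x)
  out <- array(0, dim = d)
  for (axis in 1:3) {
    if (d[axis] < 3) next
    n <- d[axis]
    idx_m <- c(1L, seq_len(n - 1L))
    idx_p <- c(seq_len(n - 1L) + 1L, n)
    if (axis == 1) {
      second <- x[idx_p, , , drop = FALSE] + x[idx_m, , , drop = FALSE] - 2 * x
    } else if (axis == 2) {
      second <- x[, idx_p, , drop = FALSE] + x[, idx_m, , drop = FALSE] - 2 * x
    } else {
      second <- x[, , idx_p, drop = FALSE] + x[, , idx_m, drop = FALSE] - 2 * x
    }
    out <- out + second / voxel_size_um[axis]^2
  }
  out
}
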