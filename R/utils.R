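# Internal helpers shared across modules. Conventions: volumes are numeric or
# logical arrays dim = c(nz, ny, nx); voxel sizes are length-3 (z, y, x) in
# micrometers; physical coordinates use the 0-based voxel-center convention.

check_volume <- function(x, name = "volume") {
  if (!is.array(x) || length(dim(x)) != 3L) {
    abort(sprintf("`%s` must be a 3D array (z, y, x)", name))
  }
  invisible(x)
}

check_voxel_size <- function(voxel_size_um) {
  if (length(voxel_size_um) != 3L || !is.numeric(voxel_size_um) ||
      any(!is.finite(voxel_size_um)) || any(voxel_size_um <= 0)) {
    abort("`voxel_size_um` must be three strictly positive numbers (z, y, x)")
  }
  invisible(as.numeric(voxel_size_um))
}

voxel_volume_um3 <- function(voxel_size_um) prod(voxel_size_um)

# Physical (z, y, x) micrometers of 1-based voxel indices (matrix n x 3).
index_to_um <- function(idx, voxel_size_um) {
  sweep(idx - 1, 2, voxel_size_um, `*`)
}

# Nearest voxel (1-based, n x 3) for physical coordinates; no bounds clamping.
um_to_index <- function(coords_um, voxel_size_um) {
  round(sweep(coords_um, 2, voxel_size_um, `/`)) + 1
}

# Decompose 1-based linear indices of a (nz, ny, nx) array into voxel indices.
linear_to_index <- function(i, dim) {
  i0 <- i - 1L
  z <- i0 %% dim[1]
  rest <- i0 %/% dim[1]
  y <- rest %% dim[2]
  x <- rest %/% dim[2]
  cbind(z, y, x) + 1L
}

index_in_bounds <- function(idx, dim) {
  idx[, 1] >= 1 & idx[, 1] <= dim[1] &
    idx[, 2] >= 1 & idx[, 2] <= dim[2] &
    idx[, 3] >= 1 & idx[, 3] <= dim[3]
}

# Voxel offsets (n x 3 integer, z/y/x) of an ellipsoid with a common physical
# radius; axes whose voxel pitch exceeds the radius contribute offset 0 only.
ellipsoid_offsets <- function(radius_um, voxel_size_um) {
  r_vox <- pmax(floor(radius_um / voxel_size_um), 0)
  g <- expand.grid(z = -r_vox[1]:r_vox[1], y = -r_vox[2]:r_vox[2], x = -r_vox[3]:r_vox[3])
  d2 <- (g$z * voxel_size_um[1])^2 + (g$y * voxel_size_um[2])^2 + (g$x * voxel_size_um[3])^2
  m <- as.matrix(g[d2 <= radius_um^2 + 1e-9, , drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Otsu threshold of an intensity volume
#'
#' Histogram-based threshold maximizing between-class variance, the default
#' automatic substitute for the manually tuned absolute thresholds used in
#' interactive surface segmentation.
#'
#' @param x Numeric vector or array of intensities.
#' @param levels Number of histogram bins.
#' @return Threshold value on the intensity scale; voxels strictly above it
#'   are foreground. `Inf` for a constant input (empty foreground).
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (!is.finite(rng[1]) || rng[2] <= rng[1]) {
    return(Inf)
  }
  h <- tabulate(pmin(pmax(floor((x - rng[1]) / (rng[2] - rng[1]) * levels) + 1, 1), levels),
                nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(levels) - 0.5) * (rng[2] - rng[1]) / levels
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  denom <- omega * (1 - omega)
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b2)
  # threshold at the upper edge of the chosen bin
  rng[1] + k * (rng[2] - rng[1]) / levels
}

seed_offset <- function(seed, k) {
  (as.integer(seed) + k) %% .Machine$integer.max
}
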