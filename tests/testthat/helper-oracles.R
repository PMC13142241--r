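# Independent oracles and shared fixtures. Oracles are deliberately naive
# (brute force / direct enumeration) and never call the code paths they check.

# Brute-force anisotropic distance map: per voxel, minimum physical distance
# over all mask voxels.
bf_distance_map <- function(mask, voxel_size_um) {
  d <- dim(mask)
  idx <- which(mask)
  stopifnot(length(idx) > 0)
  mv <- arrayInd(idx, d)
  mu <- sweep(mv - 1, 2, voxel_size_um, `*`)
  all_idx <- arrayInd(seq_len(prod(d)), d)
  au <- sweep(all_idx - 1, 2, voxel_size_um, `*`)
  out <- numeric(prod(d))
  for (i in seq_len(nrow(au))) {
    out[i] <- sqrt(min((mu[, 1] - au[i, 1])^2 + (mu[, 2] - au[i, 2])^2 +
                         (mu[, 3] - au[i, 3])^2))
  }
  array(out, dim = d)
}

# Greedy nearest-center matching of detections to truth within a radius;
# returns the number of true positives.
match_centers <- function(truth_um, det_um, radius_um) {
  used <- rep(FALSE, nrow(truth_um))
  tp <- 0L
  for (i in seq_len(nrow(det_um))) {
    d2 <- (truth_um[, 1] - det_um[i, 1])^2 + (truth_um[, 2] - det_um[i, 2])^2 +
      (truth_um[, 3] - det_um[i, 3])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= radius_um^2) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  tp
}

cells_to_matrix <- function(cells) {
  as.matrix(cells[, c("center_z_um", "center_y_um", "center_x_um")])
}

# Small, fast simulation used across unit tests; any argument can be
# overridden.
small_sim_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(
    shape_voxels = c(14L, 96L, 96L),
    voxel_size_um = c(8, 1.14, 1.14),
    n_vessels = 2L,
    vessel_radius_um = c(mean = 9, sd = 1),
    n_cells = 120L,
    seed = seed
  ), list(...))
  do.call(simulation_config, args)
}

# gaussian_sd that realizes a nominal SNR = (peak - background)/sd with shot
# noise disabled, on the generator's amplitude scale.
noise_for_snr <- function(config, snr) {
  list(poisson_gain = 0, gaussian_sd = config$channel_amplitude / snr)
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
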