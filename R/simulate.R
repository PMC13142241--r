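# Synthetic cleared-tumor volume generator. The three stages -- vessel
# network, cell placement, optical rendering -- are separately callable and
# individually seeded from `config$seed`, so the full chain is reproducible
# voxel-for-voxel while each stage can be re-run in isolation.

# Effective rendering semi-axes of a sphere of radius r: the axial semi-axis
# is clamped to half the z-step so structures smaller than the sampling slab
# still intersect their nearest plane, as they do under the thick optical
# section of a low-NA confocal acquisition. Ground-truth volumes use the same
# semi-axes so truth and pipeline measure the same rendered quantity.
render_radii <- function(radius_um, voxel_size_um) {
  c(max(radius_um, voxel_size_um[1] / 2), radius_um, radius_um)
}

#' Generate a tube-like vascular network
#'
#' Grows `n_vessels` piecewise-linear random-walk centerlines through the
#' field of view and sweeps each with its own radius to produce a solid binary
#' vessel mask, emulating lectin-labelled tumor vasculature. The returned
#' intensity channel is the mask rendered at `vessel_amplitude`, before optics
#' and noise.
#'
#' @param config A [simulation_config()].
#' @return List with `vessel_mask_true` (logical array) and `vessel_channel`
#'   (numeric array).
#' @export
generate_vessel_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  dim3 <- config$shape_voxels
  vs <- config$voxel_size_um
  extent <- dim3 * vs
  r_mean <- config$vessel_radius_um[["mean"]]
  if (2 * r_mean >= min(extent)) {
    abort(sprintf("vessel radius (%.1f um) is too large for the field of view (min extent %.1f um)",
                  r_mean, min(extent)))
  }
  mask <- array(FALSE, dim = dim3)
  if (config$n_vessels > 0) {
    withr::with_seed(seed_offset(config$seed, 0L), {
      flat <- as.logical(mask)
      for (v in seq_len(config$n_vessels)) {
        radius <- max(2, rnorm(1, r_mean, config$vessel_radius_um[["sd"]]))
        pts <- vessel_centerline(extent, config$step_length_um, config$tortuosity,
                                 pad = radius)
        flat <- cpp_tube_mask(dim3, vs, pts, radius, flat)
      }
      mask <- array(flat, dim = dim3)
    })
  }
  occ <- mean(mask)
  if (occ >= 0.5) {
    abort(sprintf("degenerate geometry: vessels occupy %.0f%% of the volume", 100 * occ))
  }
  list(vessel_mask_true = mask,
       vessel_channel = array(config$vessel_amplitude * as.numeric(mask), dim = dim3))
}

# Random-walk polyline through the (0, extent) box: starts at a uniform
# interior point and walks in both directions until leaving the box padded by
# the tube radius, so vessels cross the field rather than dead-ending at their
# seed point.
vessel_centerline <- function(extent, step_um, tortuosity, pad) {
  start <- runif(3) * extent
  dir0 <- rnorm(3)
  dir0 <- dir0 / sqrt(sum(dir0^2))
  walk <- function(p, d) {
    pts <- list()
    for (i in seq_len(1000L)) {
      p <- p + d * step_um
      pts[[i]] <- p
      if (any(p < -pad) || any(p > extent + pad)) break
      d <- d + tortuosity * rnorm(3)
      d <- d / sqrt(sum(d^2))
    }
    do.call(rbind, pts)
  }
  fwd <- walk(start, dir0)
  bwd <- walk(start, -dir0)
  rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE], matrix(start, 1), fwd)
}

#' Rasterize tubes swept along explicit centerlines
#'
#' Low-level helper behind [generate_vessel_network()], exposed so that
#' analytically known geometries (straight cylinders) can be built directly.
#'
#' @param centerlines List of n x 3 matrices of (z, y, x) points, micrometers.
#' @param radius_um Tube radius (single value or one per centerline).
#' @param shape_voxels Volume shape (z, y, x).
#' @param voxel_size_um Voxel size (z, y, x), micrometers.
#' @return Logical mask array.
#' @export
rasterize_tubes <- function(centerlines, radius_um, shape_voxels, voxel_size_um) {
  if (is.matrix(centerlines)) centerlines <- list(centerlines)
  voxel_size_um <- check_voxel_size(voxel_size_um)
  radius_um <- rep_len(radius_um, length(centerlines))
  flat <- rep(FALSE, prod(shape_voxels))
  for (i in seq_along(centerlines)) {
    flat <- cpp_tube_mask(as.integer(shape_voxels), voxel_size_um,
                          centerlines[[i]], radius_um[i], flat)
  }
  array(flat, dim = shape_voxels)
}

#' Place effector cells inside and outside the vasculature
#'
#' `floor(n_cells * (1 - f))` cells are placed uniformly on intravascular
#' voxels; the remainder are placed on extravascular voxels at distances drawn
#' from an Exponential(`decay_length_um`) law by rejection against the
#' anisotropic distance map of the true mask, reproducing the distance-decay
#' of perivascular effector-cell density. Cell centers are jittered by less
#' than half a voxel so every center keeps its generating voxel as nearest
#' voxel, making the recorded compartment and distance exact ground truth.
#'
#' Ground-truth population volumes are measured on the noiseless union of
#' whole-cell spheres clipped by the vessel mask, i.e. on exactly the quantity
#' the masking analysis later estimates.
#'
#' @param config A [simulation_config()].
#' @param vessel_mask_true Logical vessel mask from [generate_vessel_network()].
#' @return A `ground_truth` list: `cells` tibble (centers, compartment, true
#'   distance), the mask, true in/out volumes and `fraction_true_pct`.
#' @export
place_cells <- function(config, vessel_mask_true) {
  stopifnot(inherits(config, "simulation_config"))
  check_volume(vessel_mask_true, "vessel_mask_true")
  dim3 <- dim(vessel_mask_true)
  vs <- config$voxel_size_um
  f <- config$extravascular_fraction_true
  n_in <- as.integer(floor(config$n_cells * (1 - f)))
  n_out <- config$n_cells - n_in
  inside_idx <- which(vessel_mask_true)
  if (n_in > 0 && length(inside_idx) == 0) {
    abort("intravascular cells requested but the vessel mask is empty")
  }

  dmap <- NULL
  if (n_out > 0) {
    if (length(inside_idx) == 0) {
      abort("extravascular placement needs a non-empty vessel mask as distance reference")
    }
    dmap <- cpp_edt(as.logical(vessel_mask_true), dim3, vs)
  }

  if ((config$cell_placement %||% "perivascular") == "uniform") {
    return(place_cells_uniform(config, vessel_mask_true))
  }

  withr::with_seed(seed_offset(config$seed, 1L), {
    centers <- matrix(numeric(0), ncol = 3)
    compartment <- character(0)
    dist_true <- numeric(0)

    if (n_in > 0) {
      pick <- sample(inside_idx, n_in, replace = length(inside_idx) < n_in)
      idx <- linear_to_index(pick, dim3)
      centers <- rbind(centers, index_to_um(idx, vs))
      compartment <- c(compartment, rep("intravascular", n_in))
      dist_true <- c(dist_true, rep(0, n_in))
    }

    if (n_out > 0) {
      outside_idx <- which(!as.logical(vessel_mask_true) & dmap > 0 & is.finite(dmap))
      if (length(outside_idx) == 0) {
        abort("no extravascular voxels available for placement")
      }
      dvals <- dmap[outside_idx]
      ord <- order(dvals)
      sorted_d <- dvals[ord]
      sorted_idx <- outside_idx[ord]
      tol <- max(vs)
      picks <- integer(n_out)
      for (i in seq_len(n_out)) {
        placed <- FALSE
        for (try in seq_len(200L)) {
          d <- rexp(1, rate = 1 / config$decay_length_um)
          j <- findInterval(d, sorted_d, all.inside = TRUE)
          j <- if (j < length(sorted_d) &&
                   abs(sorted_d[j + 1] - d) < abs(sorted_d[j] - d)) j + 1L else j
          if (abs(sorted_d[j] - d) > tol) next
          # sample among voxels whose distance is indistinguishable from the hit
          win <- 0.5
          lo <- j; while (lo > 1L && sorted_d[lo - 1L] >= sorted_d[j] - win) lo <- lo - 1L
          hi <- j; while (hi < length(sorted_d) && sorted_d[hi + 1L] <= sorted_d[j] + win) hi <- hi + 1L
          picks[i] <- sorted_idx[if (hi > lo) sample(lo:hi, 1) else lo]
          placed <- TRUE
          break
        }
        if (!placed) {
          abort("infeasible extravascular placement: no voxel matches the drawn distance after bounded retries")
        }
      }
      idx <- linear_to_index(picks, dim3)
      centers <- rbind(centers, index_to_um(idx, vs))
      compartment <- c(compartment, rep("extravascular", n_out))
      dist_true <- c(dist_true, dmap[picks])
    }

    if (nrow(centers) > 0) {
      jitter <- matrix(runif(3 * nrow(centers), -0.45, 0.45), ncol = 3)
      centers <- centers + sweep(jitter, 2, vs, `*`)
    }
  })

  cells <- tibble::tibble(
    cell_id = seq_len(nrow(centers)),
    center_z_um = centers[, 1],
    center_y_um = centers[, 2],
    center_x_um = centers[, 3],
    compartment = compartment,
    distance_true_um = dist_true
  )

  vox_vol <- voxel_volume_um3(vs)
  if (nrow(cells) > 0) {
    body <- array(cpp_sphere_union(dim3, vs, centers,
                                   render_radii(config$cell_radius_um, vs)), dim = dim3)
    v_in <- sum(body & vessel_mask_true) * vox_vol
    v_out <- sum(body & !vessel_mask_true) * vox_vol
  } else {
    v_in <- 0
    v_out <- 0
  }

  structure(list(
    vessel_mask_true = vessel_mask_true,
    cells = cells,
    volume_in_true_um3 = v_in,
    volume_out_true_um3 = v_out,
    fraction_true_pct = if (v_in + v_out > 0) 100 * v_out / (v_in + v_out) else NA_real_,
    config = config
  ), class = "ground_truth")
}

# Uniform layout for detector benchmarks: voxels sampled uniformly over the
# whole volume; compartments and distances still come from the mask.
place_cells_uniform <- function(config, vessel_mask_true) {
  dim3 <- dim(vessel_mask_true)
  vs <- config$voxel_size_um
  if (!any(vessel_mask_true)) {
    abort("uniform placement still needs a non-empty vessel mask as distance reference")
  }
  dmap <- cpp_edt(as.logical(vessel_mask_true), dim3, vs)
  withr::with_seed(seed_offset(config$seed, 1L), {
    picks <- sample.int(prod(dim3), config$n_cells, replace = TRUE)
    idx <- linear_to_index(picks, dim3)
    centers <- index_to_um(idx, vs)
    if (nrow(centers) > 0) {
      jitter <- matrix(runif(3 * nrow(centers), -0.45, 0.45), ncol = 3)
      centers <- centers + sweep(jitter, 2, vs, `*`)
    }
  })
  inside <- vessel_mask_true[picks]
  cells <- tibble::tibble(
    cell_id = seq_len(nrow(centers)),
    center_z_um = centers[, 1],
    center_y_um = centers[, 2],
    center_x_um = centers[, 3],
    compartment = ifelse(inside, "intravascular", "extravascular"),
    distance_true_um = ifelse(inside, 0, dmap[picks])
  )
  vox_vol <- voxel_volume_um3(vs)
  body <- array(cpp_sphere_union(dim3, vs, centers,
                                 render_radii(config$cell_radius_um, vs)), dim = dim3)
  v_in <- sum(body & vessel_mask_true) * vox_vol
  v_out <- sum(body & !vessel_mask_true) * vox_vol
  structure(list(
    vessel_mask_true = vessel_mask_true,
    cells = cells,
    volume_in_true_um3 = v_in,
    volume_out_true_um3 = v_out,
    fraction_true_pct = if (v_in + v_out > 0) 100 * v_out / (v_in + v_out) else NA_real_,
    config = config
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat(sprintf("  %d cells (%d intravascular, %d extravascular)\n",
              nrow(x$cells), sum(x$cells$compartment == "intravascular"),
              sum(x$cells$compartment == "extravascular")))
  cat(sprintf("  true volumes: in %.0f um^3, out %.0f um^3 (fraction %.1f%%)\n",
              x$volume_in_true_um3, x$volume_out_true_um3, x$fraction_true_pct))
  invisible(x)
}

#' Render a ground-truth scene into a multi-channel stack
#'
#' Channels are rendered as solid uniform spheres (nuclei at every cell
#' center, whole cells on the effector channel) plus the solid vessel tube,
#' convolved with the anisotropic Gaussian PSF, offset by the background
#' level, and degraded with Poisson then additive Gaussian noise. Intensities
#' are non-negative doubles on the `channel_amplitude` scale.
#'
#' @param truth A `ground_truth` from [place_cells()].
#' @param config The matching [simulation_config()].
#' @return A [volume_stack()] with channels `nucleus`, `effector`, `vessel`.
#' @export
render_volume <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "simulation_config"))
  dim3 <- dim(truth$vessel_mask_true)
  vs <- config$voxel_size_um
  centers <- as.matrix(truth$cells[, c("center_z_um", "center_y_um", "center_x_um")])

  render_sphere_channel <- function(radius) {
    if (nrow(centers) == 0) return(array(0, dim = dim3))
    array(config$channel_amplitude *
            as.numeric(cpp_sphere_union(dim3, vs, centers, render_radii(radius, vs))),
          dim = dim3)
  }

  chans <- list(
    nucleus = render_sphere_channel(config$nucleus_radius_um),
    effector = render_sphere_channel(config$cell_radius_um),
    vessel = array(config$vessel_amplitude * as.numeric(truth$vessel_mask_true), dim = dim3)
  )

  sigma_vox <- config$psf_sigma_um / vs
  sigma_vox[sigma_vox < 0.05] <- 0
  chans <- lapply(chans, function(ch) {
    array(cpp_gauss_blur(as.numeric(ch), dim3, sigma_vox), dim = dim3)
  })

  gain <- config$noise_model$poisson_gain %||% 0
  gsd <- config$noise_model$gaussian_sd %||% 0
  withr::with_seed(seed_offset(config$seed, 2L), {
    chans <- lapply(chans, function(ch) {
      ch <- ch + config$background_level
      if (gain > 0) ch <- array(rpois(length(ch), pmax(ch, 0) * gain) / gain, dim = dim3)
      if (gsd > 0) ch <- ch + array(rnorm(length(ch), 0, gsd), dim = dim3)
      array(pmax(ch, 0), dim = dim3)
    })
  })
  volume_stack(chans, vs)
}

#' Simulate a complete cleared-tumor acquisition with ground truth
#'
#' Runs [generate_vessel_network()], [place_cells()] and [render_volume()] in
#' sequence under `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with `stack` (a [volume_stack()]) and `truth` (a
#'   `ground_truth`).
#' @export
simulate_tumor_volume <- function(config = simulation_config()) {
  net <- generate_vessel_network(config)
  truth <- place_cells(config, net$vessel_mask_true)
  stack <- render_volume(truth, config)
  list(stack = stack, truth = truth)
}

#' Write simulator output: stack, truth sidecar and mask TIFF
#'
#' @param sim Result of [simulate_tumor_volume()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(sim$stack, dir)
  write_mask_tiff(sim$truth$vessel_mask_true, file.path(dir, "vessel_mask_true.tif"))
  truth <- sim$truth
  meta <- list(
    schema_version = 1L,
    cells = truth$cells,
    volume_in_true_um3 = truth$volume_in_true_um3,
    volume_out_true_um3 = truth$volume_out_true_um3,
    fraction_true_pct = truth$fraction_true_pct
  )
  jsonlite::write_json(meta, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
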