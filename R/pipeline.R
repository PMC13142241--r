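# End-to-end orchestration: segmentation -> spot detection -> association ->
# distance mapping -> voxel masking -> endpoints, for every quantified
# population of a stack against one shared vessel mask.

#' Run the full extravasation quantification pipeline on a stack
#'
#' Reconstructs the vessel mask from the vessel channel (smoothing,
#' background subtraction, thresholding, closing, lumen filling), computes the
#' anisotropic distance-to-vessel map, detects nucleus spots, and then for
#' each quantified channel: segments cell surfaces, associates nuclei within
#' the proximity threshold, assigns distances and compartments, builds the
#' penetration profile and escape distance, computes the CPD/CPA metrics, and
#' measures intravascular/extravascular volumes by voxel masking and
#' re-segmentation. Deterministic for a fixed configuration; every threshold
#' actually used is recorded in the report.
#'
#' @param stack A [volume_stack()] with at least the vessel, nucleus and one
#'   quantified channel.
#' @param config A [pipeline_config()].
#' @return An `extrav_report`; see [glance.extrav_report()] for the endpoint
#'   table and [tidy.extrav_report()] for per-cell rows.
#' @export
run_pipeline <- function(stack, config = pipeline_config()) {
  stopifnot(inherits(stack, "volume_stack"), inherits(config, "pipeline_config"))
  ch_names <- names(stack$channels)
  for (needed in c(config$vessel_channel, config$nucleus_channel)) {
    if (!needed %in% ch_names) {
      abort(sprintf("stack has no '%s' channel (channels: %s)", needed,
                    paste(ch_names, collapse = ", ")))
    }
  }
  quantified <- config$quantified_channels %||%
    setdiff(ch_names, c(config$vessel_channel, config$nucleus_channel))
  if (length(quantified) == 0) abort("no quantified channels in the stack")
  vs <- stack$voxel_size_um

  preprocess <- function(ch) {
    sm <- smooth_channel(stack$channels[[ch]], config$smoothing_detail_um, vs)
    subtract_background(sm, config$background_sphere_um, vs)
  }

  # stage: vessel mask
  vessel_proc <- preprocess(config$vessel_channel)
  vessel_surf <- segment_surfaces(vessel_proc, vs, config$vessel_threshold,
                                  config$min_object_voxels, config$vessel_channel)
  if (nrow(vessel_surf$objects) == 0) {
    abort("vessel segmentation produced no objects; cannot build a vessel mask")
  }
  vmask <- build_vessel_mask(vessel_surf, config$smoothing_detail_um)
  dmap <- distance_map_outside(vmask)

  # stage: nucleus spots
  nuc_proc <- preprocess(config$nucleus_channel)
  spots <- detect_spots(nuc_proc, vs, config$spot_diameter_um, config$spot_quality_min)

  populations <- lapply(quantified, function(pop) {
    proc <- preprocess(pop)
    surf <- segment_surfaces(proc, vs, config$population_threshold,
                             config$min_object_voxels, pop)
    cells <- spots_near_surfaces(spots, surf, config$proximity_um, pop)
    cells <- assign_distances(cells, dmap, vmask)
    counts <- count_extravasated(cells)
    profile <- bin_distances(cells, config$bin_width_um, pop)
    escape <- if (counts[["n_extravasated"]] > 0) {
      escape_distance(cells, config$cumulative_quantile)
    } else {
      NA_real_
    }
    metrics <- if (counts[["n_extravasated"]] > 0) {
      penetration_metrics(cells, pop)
    } else {
      tibble::tibble(population = pop, n_extravascular = 0L,
                     cpd_max_um = NA_real_, cpd50_um = NA_real_, cpa50 = NA_integer_)
    }
    masked <- mask_population_channel(proc, vmask)
    vols <- population_volumes(masked, vs, surf$threshold, config$min_object_voxels)
    frac <- if (sum(vols) > 0) extravasation_fraction(vols[["V_in_um3"]], vols[["V_out_um3"]]) else NA_real_
    list(
      name = pop,
      threshold = surf$threshold,
      n_objects = nrow(surf$objects),
      cells = cells,
      profile = profile,
      escape_um = escape,
      metrics = metrics,
      extravasation = tibble::tibble(
        population = pop,
        V_in_um3 = vols[["V_in_um3"]],
        V_out_um3 = vols[["V_out_um3"]],
        fraction_pct = frac,
        n_extravasated = counts[["n_extravasated"]],
        n_intravascular = counts[["n_intravascular"]]
      )
    )
  })
  names(populations) <- quantified

  structure(list(
    config = config,
    voxel_size_um = vs,
    shape_voxels = dim(stack),
    vessel = list(threshold = vessel_surf$threshold,
                  n_objects = nrow(vessel_surf$objects),
                  volume_um3 = vmask$total_volume_um3),
    vessel_mask = vmask,
    distance_map = dmap,
    n_spots = nrow(spots),
    populations = populations
  ), class = "extrav_report")
}

#' @export
print.extrav_report <- function(x, ...) {
  cat("<extrav_report>\n")
  cat(sprintf("  vessel volume %.0f um^3 (threshold %.4g), %d nucleus spots\n",
              x$vessel$volume_um3, x$vessel$threshold, x$n_spots))
  print(glance(x))
  invisible(x)
}

#' Endpoint summary of a pipeline report
#'
#' One row per quantified population with every scalar endpoint: counts,
#' in/out volumes, the extravasation fraction, the escape distance at the
#' configured quantile, and the penetration metrics.
#'
#' @param x An `extrav_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.extrav_report <- function(x, ...) {
  purrr::map_dfr(x$populations, function(p) {
    dplyr::bind_cols(
      p$extravasation,
      tibble::tibble(
        escape_um = p$escape_um,
        cpd_max_um = p$metrics$cpd_max_um,
        cpd50_um = p$metrics$cpd50_um,
        cpa50 = p$metrics$cpa50,
        threshold = p$threshold
      )
    )
  })
}

#' Per-cell rows of a pipeline report
#'
#' @param x An `extrav_report`.
#' @param ... Unused.
#' @return Tibble of all cells across populations with centers, distances and
#'   compartments.
#' @export
tidy.extrav_report <- function(x, ...) {
  purrr::map_dfr(x$populations, function(p) p$cells)
}
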