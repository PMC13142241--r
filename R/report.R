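# Persisted result reports: per-cell CSV, penetration-profile CSV, and a
# versioned metrics JSON; multiple region reports aggregate to a mean +/- SD
# record per endpoint.

report_schema_version <- 1L

population_metrics_record <- function(p, quantile) {
  list(
    population = p$name,
    threshold = p$threshold,
    n_objects = p$n_objects,
    n_cells = nrow(p$cells),
    n_extravasated = p$extravasation$n_extravasated,
    n_intravascular = p$extravasation$n_intravascular,
    V_in_um3 = p$extravasation$V_in_um3,
    V_out_um3 = p$extravasation$V_out_um3,
    extravasation_fraction_pct = p$extravasation$fraction_pct,
    escape_um = p$escape_um,
    escape_quantile = quantile,
    cpd_max_um = p$metrics$cpd_max_um,
    cpd50_um = p$metrics$cpd50_um,
    cpa50 = p$metrics$cpa50,
    units = list(distance = "um", volume = "um3")
  )
}

#' Write pipeline results to disk
#'
#' Emits `cells.csv` (per-cell centers in micrometers, compartment and
#' distance), `profiles.csv` (distance bins with counts, percent, cumulative
#' percent), and `metrics.json` (every endpoint with units, schema
#' versioned). `results` may be one `extrav_report` or a list of them (one
#' per region); with several regions the JSON gains per-region records plus a
#' mean +/- SD aggregate per endpoint.
#'
#' @param results An `extrav_report` or list of them.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, `out_dir`.
#' @export
write_report <- function(results, out_dir) {
  if (inherits(results, "extrav_report")) results <- list(results)
  stopifnot(all(vapply(results, inherits, logical(1), "extrav_report")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  region_ids <- names(results) %||% paste0("region_", seq_along(results))
  if (is.null(names(results))) names(results) <- region_ids

  cells <- purrr::imap_dfr(results, function(rep, id) {
    cc <- tidy(rep)
    if (nrow(cc) == 0) return(cc)
    dplyr::mutate(cc, region_id = id, .before = 1)
  })
  write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)

  profiles <- purrr::imap_dfr(results, function(rep, id) {
    purrr::map_dfr(rep$populations, function(p) {
      pr <- tibble::as_tibble(p$profile)
      if (nrow(pr) == 0) return(pr)
      dplyr::mutate(pr, region_id = id, population = p$name,
                    n_intravascular = attr(p$profile, "n_intravascular"),
                    .before = 1)
    })
  })
  write.csv(profiles, file.path(out_dir, "profiles.csv"), row.names = FALSE)

  regions <- purrr::imap(results, function(rep, id) {
    list(
      region_id = id,
      voxel_size_um = rep$voxel_size_um,
      shape_voxels = rep$shape_voxels,
      vessel = rep$vessel,
      populations = purrr::map(rep$populations, population_metrics_record,
                               quantile = rep$config$cumulative_quantile)
    )
  })

  aggregate <- NULL
  if (length(results) > 1) {
    gl <- purrr::imap_dfr(results, function(rep, id) {
      dplyr::mutate(glance(rep), region_id = id, .before = 1)
    })
    metric_cols <- c("fraction_pct", "n_extravasated", "escape_um",
                     "cpd_max_um", "cpd50_um", "cpa50")
    aggregate <- lapply(split(gl, gl$population), function(g) {
      recs <- lapply(metric_cols, function(mc) {
        as.list(aggregate_regions(g[[mc]], mc))
      })
      setNames(recs, metric_cols)
    })
  }

  meta <- list(
    format = "extravas-report",
    schema_version = report_schema_version,
    n_regions = length(results),
    regions = unname(regions),
    aggregate = aggregate
  )
  jsonlite::write_json(meta, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(out_dir)
}

#' Re-read a written report
#'
#' @param dir Directory written by [write_report()].
#' @return List with `cells` and `profiles` tibbles plus the parsed
#'   `metrics` JSON.
#' @export
read_report <- function(dir) {
  metrics <- jsonlite::read_json(file.path(dir, "metrics.json"), simplifyVector = FALSE)
  cells <- tibble::as_tibble(read.csv(file.path(dir, "cells.csv")))
  profiles <- tibble::as_tibble(read.csv(file.path(dir, "profiles.csv")))
  list(cells = cells, profiles = profiles, metrics = metrics)
}
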