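# Linking nucleus spots to segmented cell surfaces and marker-positivity
# arithmetic.

#' Associate nucleus spots with nearby surfaces
#'
#' A spot belongs to a population when the minimum physical distance from its
#' center to any foreground voxel of the population's surface set is at most
#' `proximity_um` (closed bound; distance 0 when the center lies inside an
#' object). Distances come from the anisotropic Euclidean distance transform
#' of the surface foreground; each associated spot becomes one cell, tied to
#' its nearest surface object for provenance.
#'
#' @param spots Spot tibble from [detect_spots()].
#' @param surfaces A `surface_set` for the population channel.
#' @param proximity_um Association threshold, micrometers.
#' @param population_name Label recorded on the resulting cells.
#' @return A `cell_population` tibble: `cell_id`, centers, `surface_label`,
#'   `surface_distance_um`, `population`.
#' @export
spots_near_surfaces <- function(spots, surfaces, proximity_um = 5,
                                population_name = surfaces$source_channel %||% "population") {
  stopifnot(inherits(surfaces, "surface_set"))
  if (proximity_um < 0) abort("`proximity_um` must be >= 0")
  d <- dim(surfaces$labels)
  vs <- surfaces$voxel_size_um
  empty <- tibble::tibble(cell_id = integer(0), center_z_um = numeric(0),
                          center_y_um = numeric(0), center_x_um = numeric(0),
                          surface_label = integer(0), surface_distance_um = numeric(0),
                          population = character(0))
  if (nrow(spots) == 0 || nrow(surfaces$objects) == 0) return(empty)

  fg <- surfaces$labels != 0L
  dmap <- array(cpp_edt(as.logical(fg), d, vs), dim = d)
  centers <- as.matrix(spots[, c("center_z_um", "center_y_um", "center_x_um")])
  vox <- um_to_index(centers, vs)
  inb <- index_in_bounds(vox, d)
  vox[, 1] <- pmin(pmax(vox[, 1], 1L), d[1])
  vox[, 2] <- pmin(pmax(vox[, 2], 1L), d[2])
  vox[, 3] <- pmin(pmax(vox[, 3], 1L), d[3])
  lin <- vox[, 1] + d[1] * (vox[, 2] - 1) + d[1] * d[2] * (vox[, 3] - 1)
  dist_surface <- dmap[lin]
  assoc <- inb & dist_surface <= proximity_um

  if (!any(assoc)) return(empty)
  sel <- which(assoc)

  # provenance: nearest object label, via a bounding-box search around each
  # associated spot (the nearest foreground voxel is within dist + one voxel)
  fg_idx <- which(fg)
  fg_vox <- linear_to_index(fg_idx, d)
  fg_um <- index_to_um(fg_vox, vs)
  fg_lab <- surfaces$labels[fg_idx]
  nearest_label <- integer(length(sel))
  for (k in seq_along(sel)) {
    i <- sel[k]
    if (surfaces$labels[lin[i]] != 0L) {
      nearest_label[k] <- surfaces$labels[lin[i]]
      next
    }
    r <- dist_surface[i] + max(vs)
    cand <- abs(fg_um[, 1] - centers[i, 1]) <= r &
      abs(fg_um[, 2] - centers[i, 2]) <= r &
      abs(fg_um[, 3] - centers[i, 3]) <= r
    ci <- which(cand)
    d2 <- (fg_um[ci, 1] - centers[i, 1])^2 + (fg_um[ci, 2] - centers[i, 2])^2 +
      (fg_um[ci, 3] - centers[i, 3])^2
    nearest_label[k] <- fg_lab[ci[which.min(d2)]]
  }

  tibble::tibble(
    cell_id = seq_along(sel),
    center_z_um = centers[sel, 1],
    center_y_um = centers[sel, 2],
    center_x_um = centers[sel, 3],
    surface_label = nearest_label,
    surface_distance_um = dist_surface[sel],
    population = population_name
  )
}

#' Marker-positivity percentage
#'
#' The percentage of marker-positive cells among all counted cells, reported
#' to one decimal (e.g. 273 positive of 711 total gives 38.4).
#'
#' @param n_positive,n_total Non-negative counts with
#'   `n_positive <= n_total`, `n_total > 0`.
#' @return Percentage, rounded to one decimal.
#' @export
marker_positive_fraction <- function(n_positive, n_total) {
  if (any(n_total <= 0)) abort("`n_total` must be positive; positivity is undefined for empty counts")
  if (any(n_positive < 0) || any(n_positive > n_total)) {
    abort("`n_positive` must lie between 0 and `n_total`")
  }
  round(100 * n_positive / n_total, 1)
}
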