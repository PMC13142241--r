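#' Multi-channel 3D volume with physical voxel geometry
#'
#' The raw input container of the pipeline: one 3D intensity array per channel
#' (identical shapes, `(z, y, x)` order) plus the physical voxel size. The
#' physical coordinate of voxel `(i, j, k)` (1-based) is
#' `((i-1)*sz, (j-1)*sy, (k-1)*sx)` micrometers (voxel-center convention).
#'
#' @param channels Named list of 3D numeric arrays, e.g. `nucleus`,
#'   `effector`, `vessel`, `apoptosis`.
#' @param voxel_size_um Physical voxel size (z, y, x), micrometers.
#' @return A `volume_stack` object.
#' @export
volume_stack <- function(channels, voxel_size_um) {
  if (!is.list(channels) || length(channels) == 0) {
    abort("`channels` must be a non-empty named list of 3D arrays")
  }
  nm <- names(channels)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    abort("channel names must be present and unique")
  }
  voxel_size_um <- check_voxel_size(voxel_size_um)
  dims <- lapply(channels, function(ch) {
    check_volume(ch, "channel")
    dim(ch)
  })
  ref <- dims[[1]]
  same <- vapply(dims, function(d) identical(d, ref), logical(1))
  if (!all(same)) {
    abort(sprintf("all channels must share one shape; mismatch in: %s",
                  paste(nm[!same], collapse = ", ")))
  }
  structure(list(channels = channels, voxel_size_um = voxel_size_um),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<volume_stack>\n")
  cat(sprintf("  %d channel(s): %s\n", length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  %d x %d x %d voxels (z, y, x) at (%.2f, %.2f, %.2f) um\n",
              d[1], d[2], d[3],
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  invisible(x)
}

#' @export
dim.volume_stack <- function(x) dim(x$channels[[1]])

# Intensities are persisted as 32-bit float TIFF pages scaled into [0, 1] by a
# per-channel power of two, so the scaling itself is exact in binary and the
# only loss is the double -> float32 rounding of each voxel.
channel_scale <- function(x) {
  m <- max(x, 0)
  if (m <= 0) 1 else 2^ceiling(log2(m))
}

write_channel_tiff <- function(x, path, scale) {
  pages <- lapply(seq_len(dim(x)[1]), function(z) x[z, , , drop = TRUE] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
}

read_channel_tiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  arr * scale
}

#' Write a volume stack as multi-page TIFF files plus a JSON sidecar
#'
#' One float32 multi-page TIFF per channel (`<channel>.tif`, pages = z-planes)
#' and a `stack.json` sidecar carrying the channel names, voxel size in
#' micrometers, array shape, and the per-channel intensity scale. Voxel data
#' round-trip to within one part in 2^31 of the channel's full scale (the
#' TIFF writer's float conversion), i.e. exactly for practical purposes.
#'
#' @param stack A [volume_stack()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the sidecar path.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "volume_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scales <- vapply(stack$channels, channel_scale, numeric(1))
  for (nm in names(stack$channels)) {
    if (any(stack$channels[[nm]] < 0)) {
      abort(sprintf("channel '%s' has negative intensities; stacks store non-negative data", nm))
    }
    write_channel_tiff(stack$channels[[nm]], file.path(dir, paste0(nm, ".tif")), scales[[nm]])
  }
  meta <- list(
    format = "extravas-stack",
    schema_version = 1L,
    channel_names = names(stack$channels),
    voxel_size_um = stack$voxel_size_um,
    shape_voxels = dim(stack$channels[[1]]),
    intensity_scale = as.list(scales),
    axis_order = "zyx",
    coordinate_convention = "0-based voxel-center"
  )
  sidecar <- file.path(dir, "stack.json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}

#' Read a volume stack written by [write_stack()] or from plain TIFF files
#'
#' With `dir` pointing at a directory containing `stack.json`, geometry and
#' channel naming come from the sidecar. Plain multi-page TIFFs are read by
#' passing `channel_map` (named character vector of file paths) and an
#' explicit `voxel_size_um`. An explicit `voxel_size_um` always wins over the
#' sidecar, with a warning when the two disagree.
#'
#' @param dir Directory containing `stack.json`, or `NULL` when reading from
#'   `channel_map` alone.
#' @param channel_map Named character vector mapping channel names to TIFF
#'   paths; overrides the sidecar file list.
#' @param voxel_size_um Physical voxel size (z, y, x), micrometers; required
#'   when no sidecar is present.
#' @return A [volume_stack()].
#' @export
read_stack <- function(dir = NULL, channel_map = NULL, voxel_size_um = NULL) {
  meta <- NULL
  if (!is.null(dir)) {
    sidecar <- file.path(dir, "stack.json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    }
  }
  if (is.null(channel_map)) {
    if (is.null(meta)) {
      abort("no `stack.json` sidecar found; supply `channel_map` and `voxel_size_um`")
    }
    channel_map <- setNames(file.path(dir, paste0(meta$channel_names, ".tif")),
                            meta$channel_names)
  }
  missing <- !file.exists(channel_map)
  if (any(missing)) {
    abort(sprintf("missing file for channel(s): %s",
                  paste(names(channel_map)[missing], collapse = ", ")))
  }
  if (!is.null(meta) && !is.null(voxel_size_um)) {
    if (any(abs(as.numeric(meta$voxel_size_um) - as.numeric(voxel_size_um)) > 1e-9)) {
      warn("`voxel_size_um` disagrees with the stack.json sidecar; the explicit argument wins")
    }
  }
  vs <- voxel_size_um %||% meta$voxel_size_um
  if (is.null(vs)) abort("`voxel_size_um` is required when no sidecar is present")
  channels <- lapply(names(channel_map), function(nm) {
    scale <- 1
    if (!is.null(meta) && !is.null(meta$intensity_scale[[nm]])) {
      scale <- meta$intensity_scale[[nm]]
    }
    read_channel_tiff(channel_map[[nm]], scale)
  })
  names(channels) <- names(channel_map)
  volume_stack(channels, vs)
}

#' Persist a binary mask as an 8-bit multi-page TIFF
#'
#' @param mask Logical 3D array.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_mask_tiff <- function(mask, path) {
  check_volume(mask, "mask")
  pages <- lapply(seq_len(dim(mask)[1]), function(z) {
    matrix(as.numeric(mask[z, , , drop = TRUE]), nrow = dim(mask)[2])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  read_channel_tiff(path) > 0.5
}
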