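# ggplot2 views of penetration profiles and pipeline reports.

#' @export
#' @rdname plot_penetration_profile
autoplot.penetration_profile <- function(object, ...) {
  plot_penetration_profile(object, ...)
}

#' Plot a distance-binned penetration profile
#'
#' Per-bin percentage of extravascular cells as bars with the cumulative
#' percentage overlaid, as a function of distance from the nearest vessel
#' surface.
#'
#' @param object A `penetration_profile` from [bin_distances()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_penetration_profile <- function(object, ...) {
  stopifnot(inherits(object, "penetration_profile"))
  df <- tibble::as_tibble(object)
  df$mid <- (df$bin_lo_um + df$bin_hi_um) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$percent), fill = "grey35", width = attr(object, "bin_width_um") * 0.9) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_percent), colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative_percent), colour = "firebrick", size = 1) +
    ggplot2::labs(
      x = "distance from vessel surface (µm)",
      y = "cells (%)",
      title = attr(object, "population_name"),
      subtitle = sprintf("%d intravascular cells not binned", attr(object, "n_intravascular"))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.extrav_report <- function(object, ...) {
  profs <- purrr::map_dfr(object$populations, function(p) {
    pr <- tibble::as_tibble(p$profile)
    if (nrow(pr) == 0) return(pr)
    pr$population <- p$name
    pr$mid <- (pr$bin_lo_um + pr$bin_hi_um) / 2
    pr
  })
  if (nrow(profs) == 0) {
    abort("report has no extravascular cells to plot")
  }
  ggplot2::ggplot(profs, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$percent), fill = "grey35") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_percent), colour = "firebrick") +
    ggplot2::facet_wrap(~population) +
    ggplot2::labs(x = "distance from vessel surface (µm)", y = "cells (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
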