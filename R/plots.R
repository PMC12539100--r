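#' Maximum-intensity z-projection plot
#'
#' The standard quick-look for a z-stack: maximum over z rendered as a
#' raster, with physical axes in micrometres.
#'
#' @param x A [vn_volume()], [vn_binary()] or `vn_skeleton`.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_projection <- function(x, title = NULL) {
  if (inherits(x, c("vn_binary", "vn_skeleton"))) {
    vol <- x$mask * 1
  } else {
    vol <- x$voxels
  }
  vs <- x$voxel_size
  proj <- apply(vol, c(2, 3), max)
  df <- expand.grid(y = seq_len(nrow(proj)), x = seq_len(ncol(proj)))
  df$intensity <- as.vector(proj)
  df$x_um <- df$x * vs[3]
  df$y_um <- df$y * vs[2]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [µm]", y = "y [µm]", title = title,
                  fill = "max I") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot

#' Plot batch measurements
#'
#' One panel per measurement, one point per image — the quick overview of
#' a batch run.
#'
#' @param object A `vn_batch` from [run_batch()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vn_batch <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tidy(object),
    cols = c("volume_fraction", "network_length_voxels", "n_skeletons",
             "n_segments", "n_junctions", "n_endpoints"),
    names_to = "measurement", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$image_id, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measurement, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an overlap evaluation table
#'
#' Overlap percentage against ground-truth dilation rounds.
#'
#' @param object A tibble from [evaluate_overlap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_overlap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dilation_rounds,
                                       y = .data$overlap_percent)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$dilation_rounds) +
    ggplot2::labs(x = "ground-truth dilation rounds",
                  y = "skeleton overlap [%]") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
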