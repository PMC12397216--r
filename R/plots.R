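#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar plot of a concordance report
#'
#' One bar per subject (raters, average rater, transform) showing the mean
#' landmark distance in micrometres, facetted by age — the standard way to
#' eyeball whether the transform sits within the inter-rater band.
#'
#' @param object A [concordance_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot concordance_report
#' @export
autoplot.concordance_report <- function(object, ...) {
  df <- object$errors
  df$subject <- factor(df$subject, levels = unique(df$subject))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject, y = .data$mean_um,
                                   fill = .data$subject)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~age, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "mean landmark distance (µm)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Line plot of region loads
#'
#' @param object A `region_load_table` (or a row-bound tibble of several
#'   with an added `age` column, giving one line per region across ages).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot region_load_table
#' @export
autoplot.region_load_table <- function(object, ...) {
  if ("age" %in% names(object)) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$load,
                                         colour = .data$region_name)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "postnatal day", y = "load (area fraction)",
                    colour = "region") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$region_name,
                                         y = .data$load)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = NULL, y = "load (area fraction)") +
      ggplot2::theme_minimal()
  }
}

#' Plot one orthogonal slice of a volume
#'
#' @param vol An [intensity_volume()] or [label_volume()].
#' @param axis Slicing axis (1 = AP, 2 = SI, 3 = LR).
#' @param index 0-based slice index; default the middle slice.
#' @return A ggplot raster of the slice.
#' @export
plot_slice <- function(vol, axis = 1L, index = NULL) {
  arr <- if (is_label_volume(vol)) vol$labels else vol$values
  sh <- dim(arr)
  if (is.null(index)) index <- (sh[axis] - 1L) %/% 2L
  sl <- switch(axis, arr[index + 1L, , ], arr[, index + 1L, ],
               arr[, , index + 1L])
  df <- expand.grid(row = seq_len(nrow(sl)) - 1L,
                    col = seq_len(ncol(sl)) - 1L)
  df$value <- as.vector(sl)
  axes <- setdiff(1:3, axis)
  lab <- c("AP", "SI", "LR")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = lab[axes[2]], y = lab[axes[1]],
                  title = sprintf("%s slice %d (P%g)", lab[axis], index,
                                  vol$space$age)) +
    ggplot2::theme_minimal()
  if (is_label_volume(vol)) {
    p + ggplot2::scale_fill_viridis_c(option = "turbo")
  } else {
    p + ggplot2::scale_fill_viridis_c()
  }
}
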