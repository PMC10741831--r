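# ggplot2 displays for phantom cases, ventilation maps, metrics and
# training histories.

raster_df <- function(m, value_name = "value") {
  tibble::tibble(
    row = as.vector(row(m)), col = as.vector(col(m)),
    value = as.vector(m)
  )
}

#' Plot the ten phases of a phantom case
#'
#' @param object a `phantom_case`.
#' @param ... unused.
#' @return A ggplot (phase images as facetted rasters, radiographic
#'   orientation).
#' @export
autoplot.phantom_case <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(0:9, function(t) {
    d <- raster_df(object$images[[t + 1]])
    d$phase <- paste0("p", t)
    d
  }))
  df$phase <- factor(df$phase, levels = paste0("p", 0:9))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::facet_wrap(~phase, nrow = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity")
}

#' Plot a ventilation map
#'
#' @param object a `ventilation_map` from [ventilation_map()].
#' @param ... unused.
#' @return A ggplot raster of `v = det J - 1` on a diverging scale
#'   (negative = compression, positive = expansion).
#' @export
autoplot.ventilation_map <- function(object, ...) {
  df <- raster_df(object$v)
  lim <- max(abs(df$value), 1e-6)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-lim, lim)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "v")
}

#' Plot per-phase evaluation metrics
#'
#' @param object an `rms_metrics` object.
#' @param ... unused.
#' @return A ggplot of the per-phase Dice distribution with the cohort
#'   mean overlaid.
#' @export
autoplot.rms_metrics <- function(object, ...) {
  ggplot2::ggplot(object$per_case,
                  ggplot2::aes(x = factor(.data$phase), y = .data$dice)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey90") +
    ggplot2::geom_point(
      data = object$per_phase,
      ggplot2::aes(x = factor(.data$phase), y = .data$dice_mean),
      colour = "#b2182b", size = 2
    ) +
    ggplot2::labs(x = "phase", y = "Dice")
}

#' Plot a training history
#'
#' @param object an `rms_checkpoint`.
#' @param ... unused.
#' @return A ggplot of loss components against epoch.
#' @export
autoplot.rms_checkpoint <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            c("smooth", "mse", "ncc", "total"),
                            names_to = "component", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss component")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
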