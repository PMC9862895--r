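#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_histogram
#'   facet_wrap labs theme_minimal coord_equal scale_color_viridis_c
NULL

#' Plot surface points colored by prediction or label
#'
#' A 2D projection (x against y) of the dot surface; point color shows
#' the prediction when present, otherwise the ligandability label.
#'
#' @param object A `surface_points` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot surface_points
#' @export
autoplot.surface_points <- function(object, ...) {
  if (!all(is.na(object$prediction))) {
    ggplot(object, aes(x = .data$x, y = .data$y, color = .data$prediction)) +
      geom_point(size = 0.8) +
      scale_color_viridis_c(limits = c(0, 1)) +
      coord_equal() +
      labs(title = "Surface points by predicted ligandability") +
      theme_minimal()
  } else {
    ggplot(object, aes(x = .data$x, y = .data$y, color = .data$ligandable)) +
      geom_point(size = 0.8) +
      coord_equal() +
      labs(title = "Surface points by ligandability label") +
      theme_minimal()
  }
}

#' Plot training and validation loss traces
#'
#' @param object A trained `ligandability_cnn`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ligandability_cnn
#' @export
autoplot.ligandability_cnn <- function(object, ...) {
  df <- tidyr::pivot_longer(object$losses, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  df <- df[!is.na(df$loss), ]
  ggplot(df, aes(x = .data$epoch, y = .data$loss, color = .data$set)) +
    geom_line() +
    labs(title = "Cross-entropy loss by epoch") +
    theme_minimal()
}

#' Histograms of binding-site shape properties
#'
#' @param object A `binding_sites` tibble.
#' @param ... Unused.
#' @return A ggplot object faceted over the three properties.
#' @method autoplot binding_sites
#' @export
autoplot.binding_sites <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("size", "avg_dist", "std_dist")],
    dplyr::everything(), names_to = "property", values_to = "value"
  )
  ggplot(df, aes(x = .data$value)) +
    geom_histogram(bins = 20) +
    facet_wrap(~property, scales = "free") +
    labs(title = "Binding-site shape properties") +
    theme_minimal()
}
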