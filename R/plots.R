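#' Plot training history
#'
#' Loss curves (position MSE and state cross-entropy) over parameter
#' updates, on a log scale.
#'
#' @param object An `rnn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rnn_fit
#' @export
autoplot.rnn_fit <- function(object, ...) {
  object$history |>
    tidyr::pivot_longer(c("position_mse", "state_xent"),
                        names_to = "term", values_to = "loss") |>
    ggplot2::ggplot(ggplot2::aes(.data$update, .data$loss, colour = .data$term)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "parameter update", y = "loss (log scale)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot tuning curves as per-map heatmaps
#'
#' @param object A [compute_tuning_curves()] object.
#' @param units Optional subset of units to show.
#' @param ... Unused.
#' @return A ggplot object (position x unit heatmap, one facet per map).
#' @method autoplot tuning_curves
#' @export
autoplot.tuning_curves <- function(object, units = NULL, ...) {
  df <- as_tibble.tuning_curves(object)
  if (!is.null(units)) df <- dplyr::filter(df, .data$unit %in% units)
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$unit,
                                   fill = .data$activity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~map) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "track position (rad)", y = "unit") +
    ggplot2::theme_minimal()
}

#' Project per-map manifolds into their top principal components
#'
#' Stacks the maps' tuning curves, projects onto the top principal axes of
#' the stacked activity, and draws each map's ring colored by track
#' position — the standard visualization of aligned ring manifolds.
#'
#' @param curves A [compute_tuning_curves()] object.
#' @param dims Which two principal components to plot.
#' @return A ggplot object.
#' @export
plot_manifolds <- function(curves, dims = c(1, 2)) {
  labels <- attr(curves, "maps")
  stacked <- do.call(rbind, lapply(labels, function(m) map_curves(curves, m)))
  pc <- prcomp(stacked, center = TRUE, scale. = FALSE)
  P <- dim(curves)[1]
  df <- tibble::tibble(
    map = factor(rep(labels, each = P)),
    position = rep(attr(curves, "bin_centers"), length(labels)),
    pc1 = pc$x[, dims[1]],
    pc2 = pc$x[, dims[2]]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2,
                                   colour = .data$position,
                                   group = .data$map)) +
    ggplot2::geom_path(ggplot2::aes(linetype = .data$map)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_gradientn(colours = c("#d73027", "#4575b4", "#d73027")) +
    ggplot2::labs(
      x = sprintf("PC %d", dims[1]), y = sprintf("PC %d", dims[2]),
      colour = "position (rad)"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a fixed-point census
#'
#' Leading Jacobian eigenvalue modulus against the coordinate along the
#' remapping dimension, colored by stability class — marginal points trace
#' the two ring attractors at coordinates near -1 and +1 with
#' `|lambda| ~ 1`; unstable saddles sit between the rings.
#'
#' @param object A classified, located [find_fixed_points()] tibble (see
#'   [classify_fixed_points()], [locate_fixed_points()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fixed_points
#' @export
autoplot.fixed_points <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (is.null(df$remap_coord)) {
    stop("run `locate_fixed_points()` before plotting.", call. = FALSE)
  }
  if (is.null(df$class)) df$class <- "unclassified"
  ggplot2::ggplot(df, ggplot2::aes(.data$remap_coord, .data$lambda_max,
                                   colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(
      marginal = "#1b9e77", unstable = "#d8a200", discarded = "grey70",
      unclassified = "grey40"
    )) +
    ggplot2::labs(x = "remapping coordinate (-1 = map 1, +1 = map 2)",
                  y = "largest |eigenvalue|", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the trial-by-trial correlation matrix
#'
#' @param object A [trial_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trial_matrix
#' @export
autoplot.trial_matrix <- function(object, ...) {
  cm <- object$cor
  df <- tidyr::expand_grid(i = seq_len(nrow(cm)), j = seq_len(ncol(cm)))
  df$correlation <- cm[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$correlation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(-1, 1)) +
    ggplot2::labs(x = "traversal", y = "traversal") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
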