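# ggplot2 visualizations for each result type.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot nuclear dimer time courses of a trajectory
#'
#' @param object An `nfkb_trajectory`.
#' @param species Species to show (default the three nuclear dimers).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nfkb_trajectory
#' @export
autoplot.nfkb_trajectory <- function(object,
                                     species = c("A_nuc", "C_nuc", "B_nuc"),
                                     ...) {
  df <- tidy_trajectory(object) |>
    dplyr::filter(.data$species %in% !!species)
  ggplot2::ggplot(df, ggplot2::aes(.data$time / 60, .data$value,
                                   color = .data$species)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (h)", y = "abundance (a.u.)",
                  color = "species",
                  title = unique(df$scenario)[1]) +
    ggplot2::theme_minimal()
}

#' Plot ensemble mean and standard-deviation ribbons
#'
#' @param object An `nfkb_ensemble`.
#' @param species Species to show (default nuclear dimers).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nfkb_ensemble
#' @export
autoplot.nfkb_ensemble <- function(object,
                                   species = c("A_nuc", "C_nuc", "B_nuc"),
                                   ...) {
  df <- summarize_ensemble(object) |>
    dplyr::filter(.data$species %in% !!species)
  ggplot2::ggplot(df, ggplot2::aes(.data$time / 60, .data$mean,
                                   color = .data$species,
                                   fill = .data$species)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (h)", y = "nuclear abundance (a.u.)",
                  title = object$label) +
    ggplot2::theme_minimal()
}

#' Plot a z-score fingerprint as contoured density
#'
#' @param object An `nfkb_fingerprint`.
#' @param show_medians Overlay per-sample median markers (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nfkb_fingerprint
#' @export
autoplot.nfkb_fingerprint <- function(object, show_medians = TRUE, ...) {
  med <- object$medians |>
    tidyr::pivot_wider(names_from = "marker", values_from = "median_z") |>
    rlang::set_names(c("sample", "zx", "zy"))
  p <- ggplot2::ggplot(object$density,
                       ggplot2::aes(.data$x, .data$y, z = .data$density)) +
    ggplot2::geom_contour(breaks = unname(object$contour_levels),
                          color = "steelblue") +
    ggplot2::labs(x = paste0("z(", object$markers[1], ")"),
                  y = paste0("z(", object$markers[2], ")")) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (show_medians) {
    p <- p + ggplot2::geom_point(
      data = med, ggplot2::aes(.data$zx, .data$zy), inherit.aes = FALSE,
      shape = 21, size = 3, fill = "tomato")
  }
  p
}

#' Plot a fitted dose-response curve
#'
#' @param object A `fourpl_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fourpl_fit
#' @export
autoplot.fourpl_fit <- function(object, ...) {
  df <- object$data
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$dose, .data$viability)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (uM)", y = "viability") +
    ggplot2::theme_minimal()
  if (!object$degenerate && object$converged) {
    grid <- 10^seq(log10(min(df$dose)), log10(max(df$dose)),
                   length.out = 200)
    pred <- object$bottom + (object$top - object$bottom) /
      (1 + (grid / object$lc50)^object$slope)
    p <- p +
      ggplot2::geom_line(data = tibble::tibble(dose = grid,
                                               viability = pred),
                         color = "steelblue") +
      ggplot2::geom_vline(xintercept = object$lc50, linetype = "dashed",
                          color = "tomato")
  }
  p
}
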