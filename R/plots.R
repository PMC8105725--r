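#' Plot track trajectories
#'
#' Trajectories in physical coordinates, coloured by track id (or by size
#' class when a classification table is supplied).
#'
#' @param tracks a track tibble.
#' @param classification optional tibble from [classify_tracks()].
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks, classification = NULL) {
  d <- tracks
  if (!is.null(classification))
    d <- dplyr::left_join(d, classification, by = "track_id")
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x_um, .data$y_um,
                                       group = .data$track_id))
  p <- if (!is.null(classification)) {
    p + ggplot2::geom_path(ggplot2::aes(colour = .data$size_class))
  } else {
    p + ggplot2::geom_path(ggplot2::aes(colour = factor(.data$track_id)),
                           show.legend = FALSE)
  }
  p + ggplot2::coord_fixed() + ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  colour = "size class") +
    ggplot2::theme_minimal()
}

#' Maximum-intensity size distribution against the N-mer model
#'
#' Density of maximum normalized punctum sizes with the single-GFP and
#' 6x-GFP model densities and the classification threshold overlaid.
#'
#' @param classification tibble from [classify_tracks()].
#' @param model a [calibration_model()].
#' @param k threshold to mark (default 4.5).
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(classification, model, k = 4.5) {
  cv <- model$sigma_gfp / model$mu_gfp
  xs <- seq(0, max(classification$max_norm_size, 8) * 1.05,
            length.out = 400)
  ref <- dplyr::bind_rows(
    tibble::tibble(x = xs, density = stats::dnorm(xs, 1, cv),
                   which = "1x GFP"),
    tibble::tibble(x = xs, density = stats::dnorm(xs, 6, sqrt(6) * cv),
                   which = "6x GFP"))
  ggplot2::ggplot(classification, ggplot2::aes(.data$max_norm_size)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(data = ref,
                       ggplot2::aes(.data$x, .data$density,
                                    colour = .data$which)) +
    ggplot2::geom_vline(xintercept = k, linetype = "dashed") +
    ggplot2::labs(x = "maximum intensity (GFP units)", y = "density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Lifetime versus intensity growth
#'
#' 2-D binned histogram of track lifetime against normalized growth for
#' growth-eligible tracks.
#'
#' @param metrics tibble from [track_metrics()].
#' @return A ggplot object.
#' @export
plot_lifetime_growth <- function(metrics) {
  d <- metrics[is.finite(metrics$delta_norm), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$lifetime_s, .data$delta_norm)) +
    ggplot2::geom_bin2d(bins = 40) +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "lifetime (s)",
                  y = expression(Delta * " intensity (GFP units)")) +
    ggplot2::theme_minimal()
}

#' Mean FRAP recovery with SD ribbon
#'
#' @param avg tibble from [frap_average()].
#' @return A ggplot object.
#' @export
plot_frap <- function(avg) {
  ggplot2::ggplot(avg, ggplot2::aes(.data$time_s, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after bleach (s)",
                  y = "normalized intensity") +
    ggplot2::theme_minimal()
}

#' @rdname plot_size_distribution
#' @param object a [calibration_model()].
#' @param ... unused.
#' @export
autoplot.calibration_model <- function(object, ...) {
  xs <- seq(max(0, object$mu_gfp - 4 * object$sigma_gfp),
            object$mu_gfp + 4 * object$sigma_gfp, length.out = 400)
  tibble::tibble(x = xs,
                 density = stats::dnorm(xs, object$mu_gfp,
                                        object$sigma_gfp)) |>
    ggplot2::ggplot(ggplot2::aes(.data$x, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$mu_gfp, linetype = "dashed") +
    ggplot2::labs(x = "single-GFP intensity (ADU)", y = "density") +
    ggplot2::theme_minimal()
}
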