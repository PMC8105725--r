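#' Single-fluorophore calibration model
#'
#' Holds the unit-intensity distribution of a single GFP measured with the
#' same corrected-frame 3 x 3 procedure as cellular puncta: mean `mu_gfp`,
#' SD `sigma_gfp` and the retained sample count. Copy numbers are estimated
#' as intensity / `mu_gfp`.
#'
#' @param mu_gfp mean single-GFP intensity, ADU (> 0).
#' @param sigma_gfp SD of the single-GFP intensity, ADU (>= 0).
#' @param n_samples number of samples behind the estimates (>= 30 for a
#'   valid model).
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(mu_gfp, sigma_gfp, n_samples) {
  if (mu_gfp <= 0) stop("mu_gfp must be positive")
  if (sigma_gfp < 0) stop("sigma_gfp must be >= 0")
  if (n_samples < 30) stop("a valid calibration needs >= 30 samples")
  structure(list(mu_gfp = mu_gfp, sigma_gfp = sigma_gfp,
                 n_samples = as.integer(n_samples)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> mu = %.2f ADU, sigma = %.2f (CV %.3f), n = %d\n",
    x$mu_gfp, x$sigma_gfp, x$sigma_gfp / x$mu_gfp, x$n_samples))
  invisible(x)
}

#' Calibrate the single-GFP unit intensity
#'
#' Estimates the unit intensity from single-emitter 3 x 3 intensities as
#' the sample mean and SD after a robust outlier screen: samples outside
#' median +/- 5 x MAD (scaled MAD, consistent with a Gaussian SD) are
#' discarded, which removes rare aggregates and cosmic-ray events without
#' biasing a Gaussian sample.
#'
#' @param intensities numeric vector of single-emitter intensities, or a
#'   data frame with an `intensity` column (e.g. a calibration track
#'   table).
#' @return A [calibration_model()].
#' @export
calibrate <- function(intensities) {
  if (is.data.frame(intensities)) intensities <- intensities$intensity
  x <- intensities[is.finite(intensities)]
  if (length(x) < 30) stop("calibration needs >= 30 intensity samples")
  med <- median(x)
  scr <- mad(x)
  keep <- if (scr > 0) abs(x - med) <= 5 * scr else rep(TRUE, length(x))
  x <- x[keep]
  if (length(x) < 30) stop("fewer than 30 samples retained after screening")
  if (mean(x) <= 0) stop("non-positive mean calibration intensity")
  calibration_model(mean(x), sd(x), length(x))
}

#' Intensity distribution of an N-mer
#'
#' Models the integrated intensity of a punctum containing `n` independent
#' fluorophores as Gaussian with mean and variance both scaled n-fold from
#' the single-GFP distribution: mean `n * mu_gfp`, SD `sqrt(n) * sigma_gfp`.
#'
#' @param model a [calibration_model()].
#' @param n copy number(s), >= 1.
#' @return A tibble with `n`, `mean`, `sd`.
#' @export
nmer_distribution <- function(model, n) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(n < 1)) stop("n must be >= 1")
  tibble::tibble(n = n, mean = n * model$mu_gfp,
                 sd = sqrt(n) * model$sigma_gfp)
}

#' Fraction of N-mers at or above a copy-number threshold
#'
#' Closed-form Gaussian tail P(X >= k * mu_gfp) for X ~ Normal(n * mu_gfp,
#' n * sigma_gfp^2): the fraction of n-mer puncta that a maximum-intensity
#' threshold of `k` unit intensities captures. With `sigma_gfp = 0` the
#' distribution is degenerate and the result is a step function.
#'
#' @inheritParams nmer_distribution
#' @param k threshold in single-GFP units (default 4.5).
#' @return Probability vector (one per element of `n`).
#' @export
fraction_above_threshold <- function(model, n, k = 4.5) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(n < 1)) stop("n must be >= 1")
  if (any(k < 0)) stop("k must be >= 0")
  if (model$sigma_gfp == 0) return(as.numeric(n >= k))
  1 - pnorm((k - n) * model$mu_gfp / (sqrt(n) * model$sigma_gfp))
}

#' Classify tracked puncta by oligomer size
#'
#' Normalizes each track's maximum per-frame intensity by the single-GFP
#' unit intensity and classifies it as a large oligomer when the maximum
#' reaches `k` units (default 4.5, boundary inclusive), which excludes
#' monomers, dimers and trimers while capturing essentially all hexamers.
#' No temporal smoothing is applied before taking the maximum.
#'
#' @param tracks track tibble with `track_id` and `intensity`.
#' @param model a [calibration_model()].
#' @param k classification threshold in single-GFP units (default 4.5).
#' @return A tibble with `track_id`, `max_norm_size`, `size_class`
#'   (`"small"`/`"large"`) and `threshold_used`.
#' @export
classify_tracks <- function(tracks, model, k = 4.5) {
  stopifnot(inherits(model, "calibration_model"))
  stopifnot(all(c("track_id", "intensity") %in% names(tracks)))
  dplyr::group_by(tracks, .data$track_id) |>
    dplyr::summarise(
      max_norm_size = max(.data$intensity, na.rm = TRUE) / model$mu_gfp) |>
    dplyr::mutate(
      size_class = ifelse(.data$max_norm_size >= k, "large", "small"),
      threshold_used = k)
}

#' Calibrate directly from a calibration stack
#'
#' Runs the full measurement path on a single-fluorophore stack —
#' identical preprocessing, detection, linking and 3 x 3 intensity
#' measurement as cellular data — and fits the calibration model on the
#' per-detection intensities.
#'
#' @param movie raw calibration [tirf_movie()].
#' @param dark optional dark-frame matrix.
#' @param psf_sigma_px PSF scale.
#' @param quality_threshold LoG threshold; `NULL` = noise-scaled default.
#' @param min_frames minimum emitter track length (default 2; immobile
#'   emitters are seen repeatedly).
#' @return A [calibration_model()].
#' @export
calibrate_stack <- function(movie, dark = NULL, psf_sigma_px = 1.1,
                            quality_threshold = NULL, min_frames = 2) {
  tracks <- track_movie(movie, dark, psf_sigma_px, quality_threshold,
                        min_frames = min_frames, channel = "calibration")
  calibrate(tracks$intensity)
}
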