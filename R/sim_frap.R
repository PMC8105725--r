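#' Construct a FRAP trace
#'
#' A FRAP trace is a tibble with columns `time_s` and `intensity`
#' (integrated, background-subtracted intensity of the bleached region) and
#' a `bleach_index` attribute marking the first post-bleach sample.
#'
#' @param time_s strictly increasing sample times, seconds.
#' @param intensity intensity values, ADU.
#' @param bleach_index 1-based index of the first post-bleach sample; at
#'   least one sample must precede it.
#'
#' @return A tibble of class `frap_trace`.
#' @export
frap_trace <- function(time_s, intensity, bleach_index) {
  stopifnot(length(time_s) == length(intensity),
            all(diff(time_s) > 0),
            bleach_index >= 2, bleach_index <= length(time_s))
  structure(
    tibble::tibble(time_s = time_s, intensity = intensity),
    bleach_index = as.integer(bleach_index),
    class = c("frap_trace", class(tibble::tibble()))
  )
}

#' @export
#' @rdname frap_trace
#' @param x object to query.
bleach_index <- function(x) attr(x, "bleach_index")

#' Simulate a FRAP recovery trace
#'
#' Generates a prebleach plateau at `prebleach_level`, an instantaneous drop
#' at the bleach frame to `prebleach_level * (1 - bleach_depth)`, and a
#' single-exponential recovery with time constant `tau_s` toward
#' `recovery_fraction` of the bleached amplitude (so the normalized trace
#' approaches `recovery_fraction` as t grows).
#'
#' @param prebleach_level plateau intensity, ADU.
#' @param bleach_depth fraction of intensity removed by the bleach, in
#'   `[0, 1]`.
#' @param recovery_fraction asymptotic recovered fraction of the bleached
#'   amplitude, in `[0, 1]` (the mobile fraction).
#' @param tau_s recovery time constant, seconds.
#' @param n_prebleach number of prebleach samples.
#' @param n_frames total number of samples.
#' @param frame_interval_s sampling interval, seconds.
#' @param noise_sd Gaussian noise SD added to every sample, ADU.
#' @param seed seed.
#'
#' @return A [frap_trace()].
#' @export
simulate_frap_trace <- function(prebleach_level = 1000,
                                bleach_depth = 0.8,
                                recovery_fraction = 0.57,
                                tau_s = 30,
                                n_prebleach = 10,
                                n_frames = 130,
                                frame_interval_s = 1,
                                noise_sd = 0,
                                seed = 1L) {
  stopifnot(bleach_depth >= 0, bleach_depth <= 1,
            recovery_fraction >= 0, recovery_fraction <= 1,
            tau_s > 0, n_prebleach >= 1, n_frames > n_prebleach)
  time_s <- (seq_len(n_frames) - 1) * frame_interval_s
  bleach_idx <- n_prebleach + 1L
  floor_level <- prebleach_level * (1 - bleach_depth)
  amp <- (prebleach_level - floor_level) * recovery_fraction
  t_rel <- time_s - time_s[bleach_idx]
  intensity <- ifelse(
    t_rel < 0, prebleach_level,
    floor_level + amp * (1 - exp(-t_rel / tau_s)))
  if (noise_sd > 0) {
    intensity <- withr::with_seed(
      seed, intensity + rnorm(n_frames, 0, noise_sd))
  }
  frap_trace(time_s, intensity, bleach_idx)
}
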