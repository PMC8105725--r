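#' Read and write track tables, ground truth and calibration models
#'
#' Track tables and colocalization records are plain CSV; calibration
#' models are JSON objects with fields `mu_gfp`, `sigma_gfp`, `n_samples`.
#'
#' @param tracks a track tibble.
#' @param path file path.
#' @return The written path (invisibly) for writers; a tibble or
#'   [calibration_model()] for readers.
#' @export
write_tracks_csv <- function(tracks, path) {
  readr::write_csv(tracks, path)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname write_tracks_csv
#' @param model a [calibration_model()].
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(
    list(mu_gfp = model$mu_gfp, sigma_gfp = model$sigma_gfp,
         n_samples = model$n_samples),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(x$mu_gfp, x$sigma_gfp, x$n_samples)
}

#' Write simulation ground truth as CSV
#'
#' Writes the per-punctum, per-frame ground-truth table of
#' [simulate_puncta_movie()] in a stable column order.
#'
#' @param truth ground-truth tibble.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}
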