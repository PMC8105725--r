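#' Tidy a calibration model
#'
#' @param x a [calibration_model()].
#' @param ... unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble::tibble(term = c("mu_gfp", "sigma_gfp"),
                 estimate = c(x$mu_gfp, x$sigma_gfp))
}

#' One-row summary of a calibration model
#'
#' @param x a [calibration_model()].
#' @param ... unused.
#' @return A one-row tibble: `mu_gfp`, `sigma_gfp`, `cv`, `n_samples`.
#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(mu_gfp = x$mu_gfp, sigma_gfp = x$sigma_gfp,
                 cv = x$sigma_gfp / x$mu_gfp, n_samples = x$n_samples)
}

#' Tidy a cell segmentation
#'
#' @param x a [segment_cells()] result.
#' @param ... unused.
#' @return The per-cell feature tibble.
#' @export
tidy.cell_segmentation <- function(x, ...) x$cells
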