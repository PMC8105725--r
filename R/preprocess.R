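#' Disk-footprint median filter
#'
#' Median filter with a disk-shaped structuring element of the given pixel
#' radius and reflect border padding. With `stride > 1` the median is
#' evaluated on a strided grid and bilinearly interpolated, which is
#' appropriate only for surfaces that vary slowly relative to the stride
#' (e.g. illumination profiles).
#'
#' @param img numeric matrix.
#' @param radius_px footprint radius in pixels (>= 1).
#' @param stride evaluation stride (default 1 = exact everywhere).
#' @return A numeric matrix of the same size.
#' @export
disk_median <- function(img, radius_px, stride = 1L) {
  stopifnot(is.matrix(img), radius_px >= 1)
  .disk_median_cpp(img, as.integer(radius_px), as.integer(stride))
}

with_frames <- function(movie, fun, step) {
  movie <- as_movie_like(movie)
  out <- movie
  for (t in seq_len(n_frames(movie)))
    out$frames[, , t] <- fun(movie$frames[, , t])
  out$provenance <- c(movie$provenance, step)
  out
}

#' Subtract a camera dark frame
#'
#' Removes the camera's fixed-pattern offset by subtracting a dark frame
#' (the average of many images captured without light exposure) from every
#' frame. Output stays signed; values are never clipped at zero, since
#' clipping would bias dim-punctum intensities used for stoichiometry.
#'
#' @param movie a [tirf_movie()], matrix or `H x W x T` array.
#' @param dark dark-frame matrix of the same spatial size.
#' @return A corrected [tirf_movie()] with `"dark"` appended to provenance.
#' @export
subtract_dark <- function(movie, dark) {
  movie <- as_movie_like(movie)
  stopifnot(is.matrix(dark))
  if (!all(dim(dark) == dim(movie$frames)[1:2]))
    stop("dark frame shape does not match movie frames")
  with_frames(movie, function(f) f - dark, "dark")
}

#' Subtract the cytosolic background
#'
#' Estimates the diffuse background of each frame as a disk-footprint median
#' filter (default radius 25 px) — robust to the sparse bright puncta — and
#' subtracts it, leaving puncta on a zero-mean background.
#'
#' @inheritParams subtract_dark
#' @param radius_px median-filter radius, pixels (default 25).
#' @return A corrected [tirf_movie()] with `"background"` appended.
#' @export
subtract_background <- function(movie, radius_px = 25) {
  movie <- as_movie_like(movie)
  d <- dim(movie$frames)
  if (radius_px < 1) stop("radius_px must be >= 1")
  if (radius_px > min(d[1:2]) / 2)
    stop("radius_px larger than half the smallest image dimension")
  with_frames(movie,
              function(f) f - disk_median(f, radius_px),
              "background")
}

#' Correct uneven illumination
#'
#' Estimates the microscope's illumination function as a large-radius
#' (default 100 px) disk median blur of the mean of all frames, rescales it
#' to unit mean, and divides every frame by it, so corrected intensities
#' stay on the camera scale. The median surface is evaluated on a strided
#' grid (default every 4 px) and bilinearly interpolated; the illumination
#' profile varies over ~100 px scales, so the interpolation error is
#' negligible.
#'
#' @inheritParams subtract_dark
#' @param radius_px median-blur radius, pixels (default 100).
#' @param stride evaluation stride for the median surface (default 4).
#' @return A corrected [tirf_movie()] with `"illumination"` appended.
#' @export
correct_illumination <- function(movie, radius_px = 100, stride = 4L) {
  movie <- as_movie_like(movie)
  d <- dim(movie$frames)
  mean_img <- apply(movie$frames, c(1, 2), mean)
  illum <- disk_median(mean_img, radius_px, stride = stride)
  illum <- illum / mean(illum)
  if (any(illum <= 0))
    stop("illumination image has non-positive values after rescaling")
  with_frames(movie, function(f) f / illum, "illumination")
}

#' Standard live-cell correction: dark frame then rolling-median background
#'
#' @inheritParams subtract_dark
#' @inheritParams subtract_background
#' @return A corrected [tirf_movie()].
#' @export
preprocess_live <- function(movie, dark = NULL, radius_px = 25) {
  movie <- as_movie_like(movie)
  if (!is.null(dark)) movie <- subtract_dark(movie, dark)
  subtract_background(movie, radius_px)
}

#' Standard fixed-cell correction: dark, illumination, then background
#'
#' @inheritParams subtract_dark
#' @param illumination_radius_px,background_radius_px filter radii.
#' @param stride stride for the illumination median surface.
#' @return A corrected [tirf_movie()].
#' @export
preprocess_fixed <- function(movie, dark = NULL,
                             illumination_radius_px = 100,
                             background_radius_px = 25,
                             stride = 4L) {
  movie <- as_movie_like(movie)
  if (!is.null(dark)) movie <- subtract_dark(movie, dark)
  movie <- correct_illumination(movie, illumination_radius_px, stride)
  subtract_background(movie, background_radius_px)
}
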