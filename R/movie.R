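#' TIRF movie container
#'
#' A light container for a time-ordered single-channel image stack together
#' with its physical calibration. Frames are stored as an `H x W x T` numeric
#' array (rows = y, columns = x); pixel values are camera counts (ADU) and may
#' be negative after correction steps. The `provenance` field records, in
#' order, the correction steps already applied.
#'
#' @param frames numeric matrix (single frame) or `H x W x T` array.
#' @param pixel_size_um pixel size in micrometres (default 0.15, i.e. 150 nm).
#' @param frame_interval_s time between frames in seconds.
#' @param provenance character vector of applied corrections.
#'
#' @return An object of class `tirf_movie`.
#' @export
tirf_movie <- function(frames, pixel_size_um = 0.15, frame_interval_s = 1,
                       provenance = character()) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            pixel_size_um > 0, frame_interval_s > 0)
  structure(
    list(frames = frames, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s, provenance = provenance),
    class = "tirf_movie"
  )
}

#' @export
print.tirf_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<tirf_movie> %d x %d px, %d frame(s), %.0f nm/px, dt = %g s\n",
              d[1], d[2], d[3], 1000 * x$pixel_size_um, x$frame_interval_s))
  if (length(x$provenance))
    cat("  corrections:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.tirf_movie <- function(x) dim(x$frames)

n_frames <- function(movie) dim(movie$frames)[3]

#' Extract one frame of a movie as a matrix
#'
#' @param movie a [tirf_movie()].
#' @param frame 1-based frame index.
#' @return A numeric matrix.
#' @export
movie_frame <- function(movie, frame) {
  stopifnot(inherits(movie, "tirf_movie"),
            frame >= 1, frame <= n_frames(movie))
  movie$frames[, , frame]
}

as_movie_like <- function(x) {
  if (inherits(x, "tirf_movie")) return(x)
  tirf_movie(x)
}

#' Read and write movies as multi-page 16-bit TIFF
#'
#' Movies are written one page per frame as unsigned 16-bit TIFF; values are
#' clamped to `[0, 65535]` and rounded. Physical calibration is not stored in
#' the file and must be supplied again when reading.
#'
#' @param movie a [tirf_movie()].
#' @param path file path.
#' @return `write_movie_tiff()` returns `path` invisibly; `read_movie_tiff()`
#'   returns a [tirf_movie()].
#' @export
write_movie_tiff <- function(movie, path) {
  movie <- as_movie_like(movie)
  pages <- lapply(seq_len(n_frames(movie)), function(t) {
    f <- round(movie$frames[, , t])
    f[f < 0] <- 0
    f[f > 65535] <- 65535
    f / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_movie_tiff
#' @inheritParams tirf_movie
#' @export
read_movie_tiff <- function(path, pixel_size_um = 0.15, frame_interval_s = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]] * 65535
  tirf_movie(frames, pixel_size_um, frame_interval_s)
}
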