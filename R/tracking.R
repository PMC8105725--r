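#' @noRd
#' Scale-normalized Laplacian-of-Gaussian kernel, sign-flipped so bright
#' blobs of scale ~ sigma give a positive peak response. Zero-DC so a
#' constant background contributes nothing.
log_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  x <- -r:r
  X <- matrix(x, 2 * r + 1, 2 * r + 1, byrow = TRUE)
  Y <- t(X)
  g <- exp(-(X^2 + Y^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
  k <- -sigma^2 * ((X^2 + Y^2 - 2 * sigma^2) / sigma^4) * g
  k - mean(k)
}

#' Detect diffraction-limited spots in one frame
#'
#' Laplacian-of-Gaussian blob detection at the PSF scale: the frame is
#' convolved with a scale-normalized LoG kernel, local maxima of the
#' response above `quality_threshold` are kept, and centres are refined to
#' sub-pixel precision by a quadratic fit of the response peak.
#'
#' The response of the zero-DC kernel is invariant to constant offsets; a
#' sensible `quality_threshold` is a small multiple of the background noise
#' level propagated through the kernel, see [log_quality_threshold()].
#'
#' @param frame corrected image matrix (rows = y, columns = x).
#' @param psf_sigma_px PSF standard deviation in pixels (> 0).
#' @param quality_threshold minimum LoG response.
#' @return A tibble with `x_px`, `y_px` (0-based sub-pixel centres) and
#'   `quality` (LoG response at the peak).
#' @export
detect_spots <- function(frame, psf_sigma_px, quality_threshold) {
  stopifnot(is.matrix(frame))
  if (psf_sigma_px <= 0) stop("psf_sigma_px must be positive")
  k <- log_kernel(psf_sigma_px)
  resp <- EBImage::filter2(frame, k, boundary = "replicate")
  H <- nrow(resp); W <- ncol(resp)
  if (H < 3 || W < 3)
    return(tibble::tibble(x_px = numeric(), y_px = numeric(),
                          quality = numeric()))
  ci <- 2:(H - 1); cj <- 2:(W - 1)
  C <- resp[ci, cj]
  # strictly greater than N/W/NW/NE, >= S/E/SW/SE: one peak per plateau
  ismax <- C > resp[ci - 1, cj] & C >= resp[ci + 1, cj] &
    C > resp[ci, cj - 1] & C >= resp[ci, cj + 1] &
    C > resp[ci - 1, cj - 1] & C >= resp[ci + 1, cj + 1] &
    C > resp[ci - 1, cj + 1] & C >= resp[ci + 1, cj - 1] &
    C >= quality_threshold
  idx <- which(ismax, arr.ind = TRUE)
  if (!nrow(idx))
    return(tibble::tibble(x_px = numeric(), y_px = numeric(),
                          quality = numeric()))
  iy <- idx[, 1] + 1L  # back to full-image 1-based indices
  ix <- idx[, 2] + 1L
  # parabolic fit of log-response (exact for a Gaussian-shaped peak);
  # falls back to a plain quadratic fit when a neighbour is non-positive
  quad_offset <- function(l, c, r) {
    pos <- l > 0 & c > 0 & r > 0
    ll <- l; lc <- c; lr <- r
    ll[pos] <- log(l[pos]); lc[pos] <- log(c[pos]); lr[pos] <- log(r[pos])
    den <- ll + lr - 2 * lc
    off <- ifelse(den < 0, 0.5 * (ll - lr) / den, 0)
    pmin(pmax(off, -0.5), 0.5)
  }
  dy <- quad_offset(resp[cbind(iy - 1L, ix)], resp[cbind(iy, ix)],
                    resp[cbind(iy + 1L, ix)])
  dx <- quad_offset(resp[cbind(iy, ix - 1L)], resp[cbind(iy, ix)],
                    resp[cbind(iy, ix + 1L)])
  out <- tibble::tibble(
    x_px = (ix - 1L) + dx, y_px = (iy - 1L) + dy,
    quality = resp[cbind(iy, ix)])
  dplyr::arrange(out, .data$x_px, .data$y_px)
}

#' Noise-scaled LoG quality threshold
#'
#' Expresses the detection threshold in units of the background noise
#' propagated through the LoG kernel: Gaussian noise of SD `noise_sd`
#' produces a response of SD `noise_sd * sqrt(sum(kernel^2))`, and the
#' threshold is `k` times that (default 4, i.e. a four-sigma detection).
#' The relevant noise is the *total* background noise — shot noise on the
#' cytosolic background plus camera read noise — so by default (`noise_sd
#' = NULL`) it is estimated from a background-subtracted frame as the MAD
#' about zero, which is robust to the sparse bright puncta. A small floor
#' keeps the threshold positive on noise-free synthetic data.
#'
#' @param psf_sigma_px PSF scale of the kernel.
#' @param noise_sd background noise SD, ADU; `NULL` (default) estimates it
#'   from `frame`.
#' @param frame corrected frame for the MAD estimate.
#' @param k multiple of the propagated noise SD (default 4).
#' @return A numeric threshold for [detect_spots()].
#' @export
log_quality_threshold <- function(psf_sigma_px, noise_sd = NULL,
                                  frame = NULL, k = 4) {
  if (is.null(noise_sd)) {
    if (is.null(frame)) stop("supply either noise_sd or a frame")
    noise_sd <- mad(as.vector(frame), center = 0)
  }
  noise_sd <- max(noise_sd, 1e-3)
  k * noise_sd * sqrt(sum(log_kernel(psf_sigma_px)^2))
}

#' Detect spots in every frame of a movie
#'
#' @param movie a corrected [tirf_movie()].
#' @inheritParams detect_spots
#' @param quality_threshold minimum LoG response; `NULL` uses the
#'   noise-scaled threshold of [log_quality_threshold()] estimated from
#'   the first corrected frame.
#' @return A tibble with `frame`, `x_px`, `y_px`, `x_um`, `y_um`,
#'   `quality`. Physical coordinates use the pixel-centre convention
#'   `x_um = (x_px + 0.5) * pixel_size_um`.
#' @export
detect_movie <- function(movie, psf_sigma_px, quality_threshold = NULL) {
  movie <- as_movie_like(movie)
  if (is.null(quality_threshold))
    quality_threshold <- log_quality_threshold(
      psf_sigma_px, frame = movie$frames[, , 1])
  px <- movie$pixel_size_um
  dplyr::bind_rows(lapply(seq_len(n_frames(movie)), function(t) {
    d <- detect_spots(movie$frames[, , t], psf_sigma_px, quality_threshold)
    if (nrow(d)) d$frame <- t
    d
  })) |>
    (\(d) if (nrow(d)) dplyr::mutate(
      d, x_um = (.data$x_px + 0.5) * px, y_um = (.data$y_px + 0.5) * px,
      .after = "y_px")
      else tibble::tibble(x_px = numeric(), y_px = numeric(),
                          x_um = numeric(), y_um = numeric(),
                          quality = numeric(), frame = integer()))() |>
    dplyr::relocate("frame")
}

#' Link per-frame detections into tracks
#'
#' Frame-to-frame greedy mutual-nearest-neighbour linking: for each frame,
#' candidate pairs between open track heads (last seen within `max_gap`
#' frames) and new detections are assigned in order of increasing distance,
#' one-to-one, while the distance is at most `max_disp_um`. Unmatched
#' detections start new tracks; a track ends after `max_gap` consecutive
#' missing frames. Detections within a frame are processed in a canonical
#' coordinate order, so the result is invariant to their input order.
#'
#' @param detections tibble from [detect_movie()] (needs `frame`, `x_um`,
#'   `y_um`; extra columns are carried through).
#' @param max_disp_um maximum frame-to-frame displacement, micrometres.
#' @param max_gap maximum number of consecutive missing frames bridged
#'   (default 1).
#' @return A tibble of tracks: `track_id`, `frame`, positions and carried
#'   columns, ordered by track and frame. Track ids are assigned by first
#'   appearance (frame, then x, then y).
#' @export
link_tracks <- function(detections, max_disp_um = 0.5, max_gap = 1L) {
  if (max_disp_um < 0) stop("max_disp_um must be >= 0")
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(detections)))
  det <- dplyr::arrange(detections, .data$frame, .data$x_um, .data$y_um)
  if (!nrow(det)) return(dplyr::mutate(det, track_id = integer()))
  det$track_id <- NA_integer_
  frames <- sort(unique(det$frame))
  heads <- data.frame(track_id = integer(), x = numeric(), y = numeric(),
                      last_frame = integer())
  next_id <- 1L
  for (f in frames) {
    rows <- which(det$frame == f)
    open <- heads$last_frame >= f - 1L - max_gap & heads$last_frame < f
    cand <- which(open)
    if (length(cand) && length(rows)) {
      dmat <- outer(heads$x[cand], det$x_um[rows], `-`)^2 +
        outer(heads$y[cand], det$y_um[rows], `-`)^2
      dmat <- sqrt(dmat)
      dmat[dmat > max_disp_um] <- NA
      while (any(!is.na(dmat))) {
        best <- which(dmat == min(dmat, na.rm = TRUE), arr.ind = TRUE)
        bi <- best[1, 1]; bj <- best[1, 2]
        tr <- cand[bi]; rw <- rows[bj]
        det$track_id[rw] <- heads$track_id[tr]
        heads$x[tr] <- det$x_um[rw]; heads$y[tr] <- det$y_um[rw]
        heads$last_frame[tr] <- f
        dmat[bi, ] <- NA; dmat[, bj] <- NA
      }
    }
    new_rows <- rows[is.na(det$track_id[rows])]
    for (rw in new_rows) {
      det$track_id[rw] <- next_id
      heads <- rbind(heads, data.frame(
        track_id = next_id, x = det$x_um[rw], y = det$y_um[rw],
        last_frame = f))
      next_id <- next_id + 1L
    }
  }
  dplyr::arrange(det, .data$track_id, .data$frame) |>
    dplyr::relocate("track_id")
}

#' Measure per-frame track intensities from a corrected stack
#'
#' For every track point, sums the 3 x 3 pixel block centred on the rounded
#' spot centre of the corrected frame (a sum, not a mean, so the same
#' window applied to single-fluorophore calibration emitters makes the
#' unit cancel). Centres within 1 px of the border get a missing intensity.
#'
#' @param tracks tibble with `frame`, `x_px`, `y_px`.
#' @param movie the corrected [tirf_movie()] the tracks were detected on.
#' @return `tracks` with `intensity` (ADU) and `time_s` columns added.
#' @export
measure_intensity <- function(tracks, movie) {
  movie <- as_movie_like(movie)
  stopifnot(all(c("frame", "x_px", "y_px") %in% names(tracks)))
  H <- dim(movie$frames)[1]; W <- dim(movie$frames)[2]
  intensity <- vapply(seq_len(nrow(tracks)), function(i) {
    cx <- round(tracks$x_px[i]) + 1L  # 1-based centre pixel
    cy <- round(tracks$y_px[i]) + 1L
    if (cx < 2 || cx > W - 1 || cy < 2 || cy > H - 1) return(NA_real_)
    sum(movie$frames[(cy - 1L):(cy + 1L), (cx - 1L):(cx + 1L),
                     tracks$frame[i]])
  }, numeric(1))
  dplyr::mutate(tracks, intensity = intensity,
                time_s = (.data$frame - 1) * movie$frame_interval_s)
}

#' Drop tracks observed in fewer than `min_frames` frames
#'
#' Restricts analysis to puncta tracked for three or more frames (the
#' default), excluding one- and two-frame detections that cannot be
#' distinguished from noise or transient binding.
#'
#' @param tracks tibble with `track_id` and `frame`.
#' @param min_frames minimum number of observed frames (default 3,
#'   inclusive).
#' @return The filtered tibble.
#' @export
filter_min_length <- function(tracks, min_frames = 3) {
  dplyr::group_by(tracks, .data$track_id) |>
    dplyr::filter(dplyr::n_distinct(.data$frame) >= min_frames) |>
    dplyr::ungroup()
}

#' Assign tracks to segmented cells
#'
#' Each track gets the cell label covering the majority of its positions;
#' tracks mostly outside all cells (modal label 0) stay unassigned (`NA`)
#' and are excluded from per-cell summaries.
#'
#' @param tracks tibble with `track_id`, `x_px`, `y_px`.
#' @param cell_labels labelled image matrix (0 = background).
#' @return `tracks` with a `cell_id` column.
#' @export
assign_to_cells <- function(tracks, cell_labels) {
  stopifnot(is.matrix(cell_labels))
  H <- nrow(cell_labels); W <- ncol(cell_labels)
  lab <- vapply(seq_len(nrow(tracks)), function(i) {
    cx <- round(tracks$x_px[i]) + 1L
    cy <- round(tracks$y_px[i]) + 1L
    if (cx < 1 || cx > W || cy < 1 || cy > H) return(0)
    as.numeric(cell_labels[cy, cx])
  }, numeric(1))
  tracks$.lab <- lab
  modal <- dplyr::group_by(tracks, .data$track_id) |>
    dplyr::summarise(cell_id = {
      tb <- sort(table(.data$.lab), decreasing = TRUE)
      m <- as.integer(names(tb)[1])
      if (m == 0L) NA_integer_ else m
    })
  dplyr::select(tracks, -".lab") |>
    dplyr::left_join(modal, by = "track_id")
}

#' Full live-cell tracking pipeline
#'
#' Convenience wrapper: dark-frame and background correction, LoG spot
#' detection, nearest-neighbour linking, 3 x 3 intensity measurement and
#' the minimum-length filter, returning an analysis-ready track table.
#'
#' @param movie raw [tirf_movie()].
#' @param dark optional dark-frame matrix.
#' @param psf_sigma_px PSF scale for detection.
#' @param quality_threshold LoG threshold; `NULL` = noise-scaled default.
#' @param background_radius_px rolling-median background radius.
#' @param max_disp_um,max_gap linking parameters.
#' @param min_frames minimum track length.
#' @param channel label stored in the `channel` column.
#' @return A track tibble (`track_id`, `channel`, `frame`, `time_s`,
#'   coordinates, `intensity`).
#' @export
track_movie <- function(movie, dark = NULL, psf_sigma_px = 1.1,
                        quality_threshold = NULL,
                        background_radius_px = 25,
                        max_disp_um = 0.5, max_gap = 1L,
                        min_frames = 3, channel = "C0") {
  corrected <- preprocess_live(movie, dark, background_radius_px)
  det <- detect_movie(corrected, psf_sigma_px, quality_threshold)
  tracks <- link_tracks(det, max_disp_um, max_gap)
  tracks <- measure_intensity(tracks, corrected)
  tracks <- filter_min_length(tracks, min_frames)
  dplyr::mutate(tracks, channel = channel, .after = "track_id")
}
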