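#' Per-track lifetime and growth metrics
#'
#' Computes, for every classified track: its lifetime (number of observed
#' frames times the frame interval — with the 3-frame minimum at 1 s
#' intervals the shortest observable lifetime is 3 s), its lifetime class
#' (short `< 50 s`, long `>= 50 s`, boundary inclusive), and its normalized
#' intensity growth `delta_norm = (max - initial) / mu_gfp`. Growth is
#' reported only for tracks whose initial normalized intensity is strictly
#' below `initial_max_norm` (default 2.5): brighter starts are likely buds
#' or splits from pre-existing assemblies whose nucleation time is unknown,
#' and are excluded (`delta_norm = NA`).
#'
#' @param tracks track tibble with `track_id`, `frame`, `intensity` (and
#'   optionally `cell_id`, carried through).
#' @param model a [calibration_model()].
#' @param frame_interval_s frame interval, seconds.
#' @param lifetime_cutoff_s short/long lifetime boundary (default 50 s).
#' @param initial_max_norm growth-eligibility cutoff on the initial
#'   normalized intensity (default 2.5, strict).
#' @param k size-classification threshold passed to [classify_tracks()].
#' @param movie_end_frame if given, tracks still present in this frame are
#'   flagged right-censored (lifetime is a lower bound).
#' @return A tibble with one row per track: `track_id`, optional `cell_id`,
#'   `n_frames_obs`, `lifetime_s`, `lifetime_class`, `initial_norm`,
#'   `delta_norm`, `max_norm_size`, `size_class`, `right_censored`.
#' @export
track_metrics <- function(tracks, model, frame_interval_s = 1,
                          lifetime_cutoff_s = 50,
                          initial_max_norm = 2.5,
                          k = 4.5,
                          movie_end_frame = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  stopifnot(all(c("track_id", "frame", "intensity") %in% names(tracks)))
  cls <- classify_tracks(tracks, model, k)
  per <- dplyr::arrange(tracks, .data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      cell_id = if ("cell_id" %in% names(tracks))
        dplyr::first(.data$cell_id) else NA_integer_,
      n_frames_obs = dplyr::n_distinct(.data$frame),
      last_frame = max(.data$frame),
      initial_norm = dplyr::first(
        .data$intensity[is.finite(.data$intensity)]) / model$mu_gfp)
  out <- dplyr::left_join(per, cls, by = "track_id") |>
    dplyr::mutate(
      lifetime_s = .data$n_frames_obs * frame_interval_s,
      lifetime_class = ifelse(.data$lifetime_s >= lifetime_cutoff_s,
                              "long", "short"),
      delta_norm = ifelse(.data$initial_norm < initial_max_norm,
                          .data$max_norm_size - .data$initial_norm,
                          NA_real_),
      right_censored = if (is.null(movie_end_frame)) NA else
        .data$last_frame >= movie_end_frame) |>
    dplyr::select("track_id", "cell_id", "n_frames_obs", "lifetime_s",
                  "lifetime_class", "initial_norm", "delta_norm",
                  "max_norm_size", "size_class", "threshold_used",
                  "right_censored")
  out
}

#' Lifetime-growth correlation
#'
#' Spearman rank correlation between track lifetime and normalized
#' intensity growth over growth-eligible tracks (those with `delta_norm`
#' present). Ties are handled by average ranks; the p-value uses the
#' large-sample t approximation, appropriate for the thousands of tracks a
#' typical experiment yields.
#'
#' @param metrics tibble from [track_metrics()].
#' @return A one-row tibble: `spearman_r`, `p_value`, `n_tracks`.
#' @export
lifetime_growth_correlation <- function(metrics) {
  d <- metrics[is.finite(metrics$delta_norm) &
                 is.finite(metrics$lifetime_s), ]
  n <- nrow(d)
  if (n < 10) stop("need >= 10 growth-eligible tracks, have ", n)
  r <- cor(rank(d$lifetime_s), rank(d$delta_norm))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  tibble::tibble(spearman_r = r, p_value = p, n_tracks = n)
}

#' Per-cell summary of puncta size and lifetime classes
#'
#' For each cell: the percentage of tracks classified small / large, the
#' percentage large within each lifetime class (absent — `NA`, not zero —
#' when a cell has no tracks in that class, so cross-cell averages are not
#' biased by structural zeros), the count of tracks that are both large and
#' long-lived, and the per-cell lifetime-growth Spearman correlation when
#' at least 10 growth-eligible tracks exist.
#'
#' @param metrics tibble from [track_metrics()]. Tracks with `cell_id` `NA`
#'   are dropped unless every track is unassigned, in which case all tracks
#'   are summarised as one pseudo-cell (id 0).
#' @return A tibble with one row per cell: `cell_id`, `n_tracks`,
#'   `pct_large`, `pct_small`, `pct_large_short`, `pct_large_long`,
#'   `n_large_long`, `spearman_r`.
#' @export
summarize_cells <- function(metrics) {
  m <- metrics
  if (all(is.na(m$cell_id))) m$cell_id <- 0L
  m <- m[!is.na(m$cell_id), ]
  if (!nrow(m)) stop("no tracks assigned to cells")
  pct <- function(x) 100 * mean(x)
  dplyr::group_by(m, .data$cell_id) |>
    dplyr::summarise(
      n_tracks = dplyr::n(),
      pct_large = pct(.data$size_class == "large"),
      pct_small = pct(.data$size_class == "small"),
      pct_large_short = {
        s <- .data$size_class[.data$lifetime_class == "short"]
        if (length(s)) pct(s == "large") else NA_real_
      },
      pct_large_long = {
        s <- .data$size_class[.data$lifetime_class == "long"]
        if (length(s)) pct(s == "large") else NA_real_
      },
      n_large_long = sum(.data$size_class == "large" &
                           .data$lifetime_class == "long"),
      spearman_r = {
        ok <- is.finite(.data$delta_norm)
        if (sum(ok) >= 10)
          cor(rank(.data$lifetime_s[ok]), rank(.data$delta_norm[ok]))
        else NA_real_
      })
}
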