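#' Normalize a FRAP trace to the prebleach intensity
#'
#' Applies the standard double-point normalization
#' `(I(t) - I(0)) / (I(prebleach) - I(0))`, where `I(prebleach)` is the
#' average of the prebleach samples and `I(0)` is the single first
#' post-bleach sample (the intensity immediately after photobleaching).
#' The normalized trace is 1 at the prebleach level and 0 at the
#' post-bleach floor; negative values are permitted (no clipping), so an
#' immobile structure can legitimately report a slightly negative recovery.
#'
#' @param trace a [frap_trace()] (background-subtracted intensities).
#' @param prebleach_window number of samples immediately before the bleach
#'   to average; `NULL` (default) averages all prebleach samples.
#' @return The trace with a `normalized` column added.
#' @export
frap_normalize <- function(trace, prebleach_window = NULL) {
  bi <- bleach_index(trace)
  if (is.null(bi)) stop("trace must be a frap_trace with a bleach_index")
  pre_idx <- seq_len(bi - 1L)
  if (!is.null(prebleach_window))
    pre_idx <- utils::tail(pre_idx, prebleach_window)
  i_pre <- mean(trace$intensity[pre_idx])
  i0 <- trace$intensity[bi]
  if (isTRUE(all.equal(i_pre, i0)) || i_pre == i0)
    stop("zero bleach depth: prebleach and post-bleach intensities equal")
  trace$normalized <- (trace$intensity - i0) / (i_pre - i0)
  trace
}

#' Recovery statistics of a normalized FRAP trace
#'
#' Reports the maximal recovery over the post-bleach window and the
#' recovery at the sample closest to `horizon_s` after the bleach, both as
#' percentages of the prebleach intensity.
#'
#' @param trace a normalized [frap_trace()] (see [frap_normalize()]).
#' @param horizon_s horizon after the bleach, seconds; must lie within the
#'   trace.
#' @return A one-row tibble: `max_recovery_pct`, `recovery_at_horizon_pct`.
#' @export
frap_recovery_stats <- function(trace, horizon_s) {
  if (!"normalized" %in% names(trace))
    stop("trace is not normalized; call frap_normalize() first")
  bi <- bleach_index(trace)
  t_rel <- trace$time_s - trace$time_s[bi]
  post <- which(t_rel >= 0)
  if (horizon_s > max(t_rel)) stop("horizon_s beyond the end of the trace")
  at <- post[which.min(abs(t_rel[post] - horizon_s))]
  tibble::tibble(
    max_recovery_pct = 100 * max(trace$normalized[post]),
    recovery_at_horizon_pct = 100 * trace$normalized[at])
}

#' Average normalized FRAP traces
#'
#' Aligns traces on the bleach (t = 0 at the first post-bleach sample) and
#' returns the pointwise mean and SD on the first trace's time grid;
#' traces sampled on other grids are linearly interpolated onto it.
#'
#' @param traces list of normalized [frap_trace()] objects (>= 2).
#' @return A tibble with `time_s` (relative to the bleach), `mean`, `sd`,
#'   `n`.
#' @export
frap_average <- function(traces) {
  if (length(traces) < 2) stop("need >= 2 traces to average")
  if (!all(vapply(traces, function(x) "normalized" %in% names(x),
                  logical(1))))
    stop("all traces must be normalized")
  rel <- lapply(traces, function(tr) {
    t0 <- tr$time_s[bleach_index(tr)]
    data.frame(t = tr$time_s - t0, v = tr$normalized)
  })
  grid <- rel[[1]]$t
  mat <- vapply(rel, function(d) {
    if (length(d$t) == length(grid) && all(d$t == grid)) return(d$v)
    approx(d$t, d$v, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  tibble::tibble(
    time_s = grid,
    mean = rowMeans(mat),
    sd = apply(mat, 1, sd),
    n = length(traces))
}
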