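#' @noRd
#' Longest run of consecutive frames observed in both tracks with pairwise
#' distance <= max_dist. A missing frame in either channel breaks the run.
longest_overlap_run <- function(fa, xa, ya, fb, xb, yb, max_dist) {
  common <- sort(intersect(fa, fb))
  if (!length(common)) return(0L)
  ia <- match(common, fa); ib <- match(common, fb)
  ok <- sqrt((xa[ia] - xb[ib])^2 + (ya[ia] - yb[ib])^2) <= max_dist
  best <- 0L; cur <- 0L
  for (i in seq_along(common)) {
    if (!ok[i]) {
      cur <- 0L
    } else if (i > 1 && ok[i - 1] && common[i] == common[i - 1] + 1L) {
      cur <- cur + 1L
    } else {
      cur <- 1L
    }
    if (cur > best) best <- cur
  }
  best
}

#' Two-channel track colocalization and recruitment timing
#'
#' Pairs each reference-channel track (channel A, e.g. MyD88) with at most
#' one partner-channel track (channel B, e.g. IRAK4/1). A pair qualifies
#' when the two tracks are within `max_dist_um` (default 0.25 um, boundary
#' inclusive) for at least `min_consecutive` (default 2) consecutive frames
#' observed in both channels; a gap in either channel breaks the run.
#' Each A-track takes the B-track giving the longest qualifying run, each
#' B-track is assigned to at most one A-track (longest run wins; ties go to
#' the A-track that nucleated earlier).
#'
#' For colocalized pairs the recruitment time is the delay from
#' A nucleation to B appearance, `(first frame of B - first frame of A) *
#' frame_interval_s`. A partner that nucleated before its reference track
#' yields a negative value and is flagged (`flag_negative_delay`), to be
#' excluded from recruitment-time distributions.
#'
#' Distances are computed on the sub-pixel physical coordinates (`x_um`,
#' `y_um`); both channels must share the corrected coordinate system and
#' frame clock.
#'
#' @param tracks_a,tracks_b track tibbles with `track_id`, `frame`,
#'   `x_um`, `y_um`.
#' @param max_dist_um colocalization distance threshold, micrometres.
#' @param min_consecutive minimum qualifying run length, frames.
#' @param frame_interval_s frame interval, seconds.
#' @return A tibble with one row per A-track: `trackA_id`, `trackB_id`
#'   (`NA` when not colocalized), `colocalized`, `n_consecutive_overlap`,
#'   `recruitment_time_s` (`NA` unless colocalized), `flag_negative_delay`.
#' @export
colocalize <- function(tracks_a, tracks_b, max_dist_um = 0.25,
                       min_consecutive = 2L, frame_interval_s = 1) {
  need <- c("track_id", "frame", "x_um", "y_um")
  stopifnot(all(need %in% names(tracks_a)), all(need %in% names(tracks_b)))
  if (max_dist_um < 0) stop("max_dist_um must be >= 0")

  split_tr <- function(tr) {
    tr <- dplyr::arrange(tr, .data$track_id, .data$frame)
    split(tr[, c("frame", "x_um", "y_um")], tr$track_id)
  }
  A <- split_tr(tracks_a); B <- split_tr(tracks_b)
  a_ids <- names(A); b_ids <- names(B)
  a_first <- vapply(A, function(d) min(d$frame), numeric(1))
  b_first <- vapply(B, function(d) min(d$frame), numeric(1))

  # candidate qualifying pairs (bounding-box prefilter keeps the pair scan
  # near-linear on sparse fields)
  bbox <- function(tr) vapply(tr, function(d)
    c(min(d$x_um), max(d$x_um), min(d$y_um), max(d$y_um)), numeric(4))
  ba <- bbox(A); bb <- bbox(B)
  cand <- list()
  for (i in seq_along(A)) {
    da <- A[[i]]
    fa_min <- min(da$frame); fa_max <- max(da$frame)
    for (j in seq_along(B)) {
      db <- B[[j]]
      if (min(db$frame) > fa_max || max(db$frame) < fa_min) next
      if (bb[1, j] - ba[2, i] > max_dist_um ||
          ba[1, i] - bb[2, j] > max_dist_um ||
          bb[3, j] - ba[4, i] > max_dist_um ||
          ba[3, i] - bb[4, j] > max_dist_um) next
      run <- longest_overlap_run(da$frame, da$x_um, da$y_um,
                                 db$frame, db$x_um, db$y_um, max_dist_um)
      if (run >= min_consecutive)
        cand[[length(cand) + 1L]] <- c(i = i, j = j, run = run)
    }
  }

  assigned_b <- logical(length(B))
  best_for_a <- rep(NA_integer_, length(A))
  best_run <- rep(0L, length(A))
  if (length(cand)) {
    cd <- do.call(rbind, cand)
    ord <- order(-cd[, "run"], a_first[cd[, "i"]], cd[, "i"], cd[, "j"])
    cd <- cd[ord, , drop = FALSE]
    for (r in seq_len(nrow(cd))) {
      i <- cd[r, "i"]; j <- cd[r, "j"]
      if (!is.na(best_for_a[i]) || assigned_b[j]) next
      best_for_a[i] <- j
      best_run[i] <- cd[r, "run"]
      assigned_b[j] <- TRUE
    }
  }

  coloc <- !is.na(best_for_a)
  rec <- ifelse(coloc,
                (b_first[ifelse(coloc, best_for_a, 1L)] - a_first) *
                  frame_interval_s,
                NA_real_)
  tibble::tibble(
    trackA_id = as.integer(a_ids),
    trackB_id = ifelse(coloc, as.integer(b_ids[best_for_a]), NA_integer_),
    colocalized = coloc,
    n_consecutive_overlap = best_run,
    recruitment_time_s = rec,
    flag_negative_delay = !is.na(rec) & rec < 0)
}

#' Recruitment-time distribution from colocalization records
#'
#' Returns the recruitment delays of colocalized pairs, excluding flagged
#' negative delays (partner nucleated before the reference track).
#'
#' @param records tibble from [colocalize()].
#' @return Numeric vector of recruitment times, seconds.
#' @export
recruitment_times <- function(records) {
  records$recruitment_time_s[records$colocalized &
                               !records$flag_negative_delay]
}

#' Compare partner-positive and partner-negative puncta
#'
#' Summarises, over reference-channel tracks, the mean maximum normalized
#' size of partner-positive vs partner-negative puncta and the percentage
#' colocalized overall and within each lifetime class.
#'
#' @param records tibble from [colocalize()].
#' @param metrics tibble from [track_metrics()] for the reference channel
#'   (needs `track_id`, `max_norm_size`; `lifetime_class` enables the
#'   per-class percentages).
#' @return A one-row tibble: `n_positive`, `n_negative`,
#'   `mean_size_positive` (`NA` when no positives), `mean_size_negative`,
#'   `pct_colocalized`, `pct_colocalized_short`, `pct_colocalized_long`.
#' @export
compare_partner_classes <- function(records, metrics) {
  stopifnot(all(c("track_id", "max_norm_size") %in% names(metrics)))
  d <- dplyr::inner_join(records, metrics,
                         by = c(trackA_id = "track_id"))
  pos <- d[d$colocalized, ]; neg <- d[!d$colocalized, ]
  pct_in <- function(cls) {
    if (!"lifetime_class" %in% names(d)) return(NA_real_)
    s <- d[d$lifetime_class == cls, ]
    if (nrow(s)) 100 * mean(s$colocalized) else NA_real_
  }
  tibble::tibble(
    n_positive = nrow(pos), n_negative = nrow(neg),
    mean_size_positive = if (nrow(pos)) mean(pos$max_norm_size) else NA_real_,
    mean_size_negative = if (nrow(neg)) mean(neg$max_norm_size) else NA_real_,
    pct_colocalized = 100 * mean(d$colocalized),
    pct_colocalized_short = pct_in("short"),
    pct_colocalized_long = pct_in("long"))
}
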