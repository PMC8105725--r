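mk_track <- function(frames, x, y = 1) {
  tibble::tibble(track_id = 1L, frame = frames,
                 x_um = rep_len(x, length(frames)),
                 y_um = rep_len(y, length(frames)))
}

test_that("identical coordinates over 5 frames colocalize with overlap 5", {
  a <- mk_track(1:5, 2)
  b <- dplyr::mutate(mk_track(1:5, 2), track_id = 10L)
  rec <- colocalize(a, b)
  expect_true(rec$colocalized)
  expect_equal(rec$n_consecutive_overlap, 5L)
  expect_equal(rec$trackB_id, 10L)
  expect_equal(rec$recruitment_time_s, 0)
})

test_that("a single-frame overlap does not colocalize; two frames do", {
  a <- mk_track(1:5, 2)
  b1 <- dplyr::mutate(mk_track(5:8, 2), track_id = 2L)
  expect_false(colocalize(a, b1)$colocalized)
  b2 <- dplyr::mutate(mk_track(4:8, 2), track_id = 2L)
  expect_true(colocalize(a, b2)$colocalized)
})

test_that("the 0.25 um distance boundary is inclusive", {
  a <- mk_track(1:3, 1, 1)
  b <- dplyr::mutate(mk_track(1:3, 1.25, 1), track_id = 2L)  # exactly 0.25
  rec <- colocalize(a, b, max_dist_um = 0.25)
  expect_true(rec$colocalized)
  expect_equal(rec$n_consecutive_overlap, 3L)
  b_far <- dplyr::mutate(mk_track(1:3, 1.2500001, 1), track_id = 2L)
  expect_false(colocalize(a, b_far, max_dist_um = 0.25)$colocalized)
})

test_that("a gap in either channel breaks the consecutive run", {
  a <- mk_track(c(1:3, 5:7), 2)          # gap at frame 4 in A
  b <- dplyr::mutate(mk_track(1:7, 2), track_id = 2L)
  rec <- colocalize(a, b, min_consecutive = 2)
  expect_equal(rec$n_consecutive_overlap, 3L)
})

test_that("recruitment time is the nucleation delay; negatives are flagged", {
  a <- mk_track(10:30, 2)
  b <- dplyr::mutate(mk_track(24:30, 2), track_id = 2L)
  rec <- colocalize(a, b, frame_interval_s = 1)
  expect_equal(rec$recruitment_time_s, 14)
  expect_false(rec$flag_negative_delay)
  b_early <- dplyr::mutate(mk_track(5:30, 2), track_id = 2L)
  rec2 <- colocalize(a, b_early)
  expect_equal(rec2$recruitment_time_s, -5)
  expect_true(rec2$flag_negative_delay)
  expect_length(recruitment_times(rec2), 0)
})

test_that("each partner track is assigned to one reference track only", {
  a <- dplyr::bind_rows(mk_track(1:6, 2),
                        dplyr::mutate(mk_track(3:8, 2.1), track_id = 2L))
  b <- dplyr::mutate(mk_track(1:8, 2), track_id = 7L)
  rec <- colocalize(a, b)
  expect_equal(sum(rec$trackB_id == 7L, na.rm = TRUE), 1)
  # longest run wins: track 1 overlaps 6 frames, track 2 at distance 0.1
  expect_equal(rec$trackA_id[rec$colocalized], 1L)
})

test_that("colocalization is invariant to common translation and id permutation", {
  set.seed(8)
  pairs <- replicate(20, random_track_pair(), simplify = FALSE)
  a <- dplyr::bind_rows(lapply(seq_along(pairs), function(i)
    dplyr::mutate(pairs[[i]]$a, track_id = i)))
  b <- dplyr::bind_rows(lapply(seq_along(pairs), function(i)
    dplyr::mutate(pairs[[i]]$b, track_id = 100L + i)))
  base <- colocalize(a, b)
  shifted <- colocalize(
    dplyr::mutate(a, x_um = x_um + 5, y_um = y_um - 2),
    dplyr::mutate(b, x_um = x_um + 5, y_um = y_um - 2))
  expect_equal(base, shifted)
  perm <- colocalize(a[sample.int(nrow(a)), ], b[sample.int(nrow(b)), ])
  expect_equal(base, dplyr::arrange(perm, trackA_id))
})

test_that("with unlimited distance and run 1, any temporal overlap colocalizes", {
  set.seed(9)
  pairs <- replicate(30, random_track_pair(), simplify = FALSE)
  for (p in pairs) {
    rec <- colocalize(p$a, dplyr::mutate(p$b, track_id = 2L),
                      max_dist_um = Inf, min_consecutive = 1)
    has_overlap <- length(intersect(p$a$frame, p$b$frame)) > 0
    expect_equal(rec$colocalized, has_overlap)
  }
})

test_that("run lengths agree exactly with the brute-force oracle", {
  set.seed(123)
  for (i in 1:200) {
    p <- random_track_pair()
    rec <- colocalize(p$a, dplyr::mutate(p$b, track_id = 2L),
                      max_dist_um = 0.25, min_consecutive = 2)
    run <- oracle_coloc_run(p$a, p$b, 0.25)
    expect_equal(rec$colocalized, run >= 2)
    if (rec$colocalized) expect_equal(rec$n_consecutive_overlap, run)
  }
})

test_that("partner-positive puncta are larger in a gated simulation", {
  cfg <- sim_config(n_frames = 200, nucleation_rate = 3, seed = 55)
  tt <- simulate_puncta_movie(cfg, render = FALSE)$truth
  a <- filter_min_length(truth_tracks(tt), 3)
  b <- partner_truth_tracks(tt)
  rec <- colocalize(a, b)
  m <- track_metrics(a, calibration_model(100, 25, 100))
  cmp <- compare_partner_classes(rec, m)
  expect_gt(cmp$n_positive, 5)
  expect_gt(cmp$mean_size_positive, cmp$mean_size_negative)
  expect_gt(cmp$pct_colocalized_long, cmp$pct_colocalized_short)
  # constructed arithmetic: positives (10, 12, 11), negatives (3, 3.4)
  recs <- tibble::tibble(trackA_id = 1:5,
                         colocalized = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  mets <- tibble::tibble(track_id = 1:5,
                         max_norm_size = c(10, 12, 11, 3, 3.4))
  out <- compare_partner_classes(recs, mets)
  expect_equal(out$mean_size_positive, 11.0)
  expect_equal(out$mean_size_negative, 3.2)
  # all-negative: positive-class mean absent
  recs0 <- dplyr::mutate(recs, colocalized = FALSE)
  expect_true(is.na(compare_partner_classes(recs0, mets)$mean_size_positive))
})
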