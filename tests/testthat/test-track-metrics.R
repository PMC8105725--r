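cal100 <- calibration_model(100, 25, 100)

test_that("lifetime is observed frames times the frame interval", {
  mk <- function(n, dt) {
    tr <- tibble::tibble(track_id = 1L, frame = seq_len(n),
                         intensity = 100)
    track_metrics(tr, cal100, frame_interval_s = dt)
  }
  expect_equal(mk(3, 1)$lifetime_s, 3)      # minimum observable: 3 s
  m50 <- mk(50, 1)
  expect_equal(m50$lifetime_s, 50)
  expect_equal(m50$lifetime_class, "long")  # >= 50 s inclusive
  expect_equal(mk(10, 5)$lifetime_s, 50)
  expect_equal(mk(49, 1)$lifetime_class, "short")
})

test_that("growth is measured only for dim starts and as (max - initial)/mu", {
  tr <- tibble::tibble(
    track_id = rep(1:3, each = 3),
    frame = rep(1:3, 3),
    intensity = c(250, 400, 300,    # initial exactly 2.5x -> excluded
                  150, 480, 620,    # delta (620 - 150)/100 = 4.7
                  100, 100, 100))   # constant -> delta 0
  m <- track_metrics(tr, cal100)
  expect_true(is.na(m$delta_norm[1]))
  expect_equal(m$delta_norm[2], 4.7)
  expect_equal(m$delta_norm[3], 0)
})

test_that("Spearman correlation matches the hand-ranked oracle", {
  life <- c(3, 5, 8, 60, 120)
  delta <- c(0.1, 0.4, 0.2, 3.0, 6.0)
  expect_equal(oracle_spearman_d2(life, delta), 0.9)
  m <- tibble::tibble(track_id = 1:10,
                      lifetime_s = rep(life, 2),
                      delta_norm = rep(delta, 2))
  r <- lifetime_growth_correlation(m)
  expect_equal(r$spearman_r, cor(rep(life, 2), rep(delta, 2),
                                 method = "spearman"))
  # perfectly monotone -> R = 1
  m2 <- tibble::tibble(track_id = 1:10, lifetime_s = 1:10,
                       delta_norm = (1:10)^2)
  expect_equal(lifetime_growth_correlation(m2)$spearman_r, 1)
  expect_error(lifetime_growth_correlation(m2[1:5, ]), ">= 10")
})

test_that("independent deltas give a null correlation", {
  set.seed(77)
  m <- tibble::tibble(track_id = 1:10000,
                      lifetime_s = rgeom(10000, 0.2) + 3,
                      delta_norm = abs(rnorm(10000)))
  expect_lt(abs(lifetime_growth_correlation(m)$spearman_r), 0.03)
})

test_that("per-cell summaries count classes and handle empty classes", {
  m <- tibble::tibble(
    track_id = 1:10, cell_id = 1L,
    lifetime_s = c(rep(10, 8), 60, 70),
    lifetime_class = c(rep("short", 8), "long", "long"),
    delta_norm = NA_real_,
    max_norm_size = c(rep(2, 8), 6, 7),
    size_class = c(rep("small", 8), "large", "large"))
  s <- summarize_cells(m)
  expect_equal(s$n_tracks, 10)
  expect_equal(s$pct_large, 20)
  expect_equal(s$pct_large + s$pct_small, 100)
  expect_equal(s$pct_large_long, 100)
  expect_equal(s$pct_large_short, 0)
  expect_equal(s$n_large_long, 2)
  # all short-lived: long-class percentage is absent, not zero
  m_short <- dplyr::mutate(m, lifetime_class = "short")
  expect_true(is.na(summarize_cells(m_short)$pct_large_long))
})

test_that("summaries are invariant to track relabeling and time rescaling", {
  cfg <- sim_config(n_frames = 120, nucleation_rate = 2, seed = 19)
  tt <- simulate_puncta_movie(cfg, render = FALSE)$truth
  tr <- filter_min_length(truth_tracks(tt), 3)
  m1 <- track_metrics(tr, cal100, frame_interval_s = 1)
  # relabel track ids
  ids <- unique(tr$track_id)
  remap <- setNames(sample(ids), ids)
  tr2 <- dplyr::mutate(tr, track_id = unname(remap[as.character(track_id)]))
  m2 <- track_metrics(tr2, cal100, frame_interval_s = 1)
  expect_equal(summarize_cells(m1)[, -1], summarize_cells(m2)[, -1])
  # halve the frame interval while doubling observed frames per track
  tr3 <- dplyr::bind_rows(tr, dplyr::mutate(tr, frame = frame + 0.5))
  m3 <- track_metrics(tr3, cal100, frame_interval_s = 0.5)
  expect_equal(m3$lifetime_s, m1$lifetime_s[match(m3$track_id,
                                                  m1$track_id)])
})

test_that("coupled growth simulations show the lifetime-growth correlation", {
  cfg <- sim_config(n_frames = 300, nucleation_rate = 7, seed = 31)
  tt <- simulate_puncta_movie(cfg, render = FALSE)$truth
  tr <- filter_min_length(truth_tracks(tt), 3)
  m <- track_metrics(tr, cal100)
  r <- lifetime_growth_correlation(m)
  expect_gte(r$n_tracks, 1000)
  expect_gt(r$spearman_r, 0.4)
  # permutation null: same marginals, coupling destroyed
  set.seed(99)
  ok <- is.finite(m$delta_norm)
  m_null <- m[ok, ]
  m_null$delta_norm <- sample(m_null$delta_norm)
  expect_lt(abs(lifetime_growth_correlation(m_null)$spearman_r), 0.05)
})
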