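test_that("spot detection handles empty and dominated-threshold frames", {
  expect_equal(nrow(detect_spots(matrix(0, 32, 32), 1.1, 1)), 0)
  img <- myddoquant:::render_spot(matrix(0, 32, 32), 15, 15, 1.1, 100)
  resp_max <- max(EBImage::filter2(img, myddoquant:::log_kernel(1.1),
                                   boundary = "replicate"))
  expect_equal(nrow(detect_spots(img, 1.1, resp_max * 1.01)), 0)
  expect_error(detect_spots(img, -1, 1), "psf_sigma")
})

test_that("two noiseless spots are found with sub-pixel accuracy", {
  # continuous index-unit u maps to pixel coordinate x_px = u - 0.5
  # (a spot at the centre of pixel j, u = j + 0.5, has x_px = j)
  img <- matrix(0, 48, 48)
  img <- myddoquant:::render_spot(img, 14.3, 20.7, 1.1, 100)
  img <- myddoquant:::render_spot(img, 24.3, 20.7, 1.1, 100)
  d <- detect_spots(img, 1.1, 1)
  expect_equal(nrow(d), 2)
  d <- d[order(d$x_px), ]
  expect_lt(abs(d$x_px[1] - 13.8), 0.25)
  expect_lt(abs(d$y_px[1] - 20.2), 0.25)
  expect_lt(abs(d$x_px[2] - 23.8), 0.25)
})

test_that("linking keeps stationary spots as single, unswapped tracks", {
  # one spot over 10 frames -> one track of length 10
  det1 <- tibble::tibble(frame = 1:10, x_um = 3, y_um = 3)
  tr1 <- link_tracks(det1, max_disp_um = 0.5)
  expect_equal(length(unique(tr1$track_id)), 1)
  expect_equal(nrow(tr1), 10)
  # two spots 3 um apart with 0.5 um max displacement: never swapped
  det2 <- dplyr::bind_rows(
    tibble::tibble(frame = rep(1:8, each = 1), x_um = 1, y_um = 1),
    tibble::tibble(frame = 1:8, x_um = 4, y_um = 1))
  tr2 <- link_tracks(det2, max_disp_um = 0.5)
  expect_equal(length(unique(tr2$track_id)), 2)
  pos_by_track <- tapply(tr2$x_um, tr2$track_id,
                         function(x) length(unique(x)))
  expect_true(all(pos_by_track == 1))
})

test_that("gap closing follows max_gap exactly", {
  det <- tibble::tibble(frame = c(1, 2, 4, 5), x_um = 2, y_um = 2)
  with_gap <- link_tracks(det, max_disp_um = 0.5, max_gap = 1)
  expect_equal(length(unique(with_gap$track_id)), 1)
  no_gap <- link_tracks(det, max_disp_um = 0.5, max_gap = 0)
  expect_equal(length(unique(no_gap$track_id)), 2)
  expect_error(link_tracks(det, max_disp_um = -1), "max_disp")
})

test_that("linking is invariant to detection order within frames", {
  set.seed(11)
  det <- dplyr::bind_rows(lapply(1:6, function(f)
    tibble::tibble(frame = f,
                   x_um = c(1, 2.5, 4) + rnorm(3, 0, 0.05),
                   y_um = c(1, 1.2, 0.8) + rnorm(3, 0, 0.05))))
  shuffled <- det[sample.int(nrow(det)), ]
  canon <- function(tr) {
    s <- split(paste(tr$frame, round(tr$x_um, 9), round(tr$y_um, 9)),
               tr$track_id)
    unname(s[order(vapply(s, `[`, "", 1))])
  }
  expect_identical(canon(link_tracks(det, 0.5)),
                   canon(link_tracks(shuffled, 0.5)))
})

test_that("3x3 intensity measurement matches the Gaussian-window oracle", {
  # uniform frame: 3x3 sum is 9v
  mv <- tirf_movie(matrix(5, 32, 32))
  tr <- tibble::tibble(frame = 1L, x_px = 15, y_px = 12)
  expect_equal(measure_intensity(tr, mv)$intensity, 45)
  # spot at a pixel centre: captured fraction equals the closed-form
  # Gaussian integral over the 3x3 window (~0.684 at sigma 1.1, a constant
  # that cancels in GFP-normalized units)
  img <- myddoquant:::render_spot(matrix(0, 41, 41), 20.5, 20.5, 1.1, 1000)
  got <- measure_intensity(tibble::tibble(frame = 1L, x_px = 20.5,
                                          y_px = 20.5),
                           tirf_movie(img))$intensity
  expect_equal(got / 1000, oracle_capture_fraction(1.1), tolerance = 1e-6)
  # centres within 1 px of the border are flagged missing
  brd <- measure_intensity(tibble::tibble(frame = 1L, x_px = 0, y_px = 20),
                           tirf_movie(img))
  expect_true(is.na(brd$intensity))
})

test_that("minimum track length filter is inclusive at the boundary", {
  tr <- tibble::tibble(track_id = rep(1:3, times = c(2, 3, 5)),
                       frame = c(1:2, 1:3, 1:5))
  kept <- filter_min_length(tr, 3)
  expect_setequal(unique(kept$track_id), c(2, 3))
  expect_equal(nrow(filter_min_length(tr[0, ], 3)), 0)
})

test_that("tracks take the majority cell label; outsiders stay unassigned", {
  lab <- matrix(0L, 20, 20)
  lab[1:10, 1:10] <- 1L
  lab[11:20, 1:10] <- 2L
  inside <- tibble::tibble(track_id = 1L, frame = 1:4,
                           x_px = 4, y_px = c(2, 4, 6, 8))
  expect_equal(unique(assign_to_cells(inside, lab)$cell_id), 1L)
  # 60% in label 1, 40% in label 2 -> majority 1
  split60 <- tibble::tibble(track_id = 1L, frame = 1:5,
                            x_px = 4, y_px = c(2, 4, 6, 12, 14))
  expect_equal(unique(assign_to_cells(split60, lab)$cell_id), 1L)
  outside <- tibble::tibble(track_id = 1L, frame = 1:3,
                            x_px = 15, y_px = 15)
  expect_true(all(is.na(assign_to_cells(outside, lab)$cell_id)))
})

test_that("noise-free well-separated movies are recovered exactly", {
  cfg <- noise_free_config(image_shape = c(128, 128), n_frames = 40,
                           nucleation_rate = 0.15, min_spacing_um = 2,
                           seed = 21)
  sim <- simulate_puncta_movie(cfg)
  tr <- track_movie(sim$movie, min_frames = 1)
  truth_sum <- dplyr::summarise(
    dplyr::group_by(sim$truth, .data$punctum_id),
    birth = min(frame), death = max(frame), len = dplyr::n())
  trk_sum <- dplyr::summarise(
    dplyr::group_by(tr, .data$track_id),
    birth = min(frame), death = max(frame), len = dplyr::n())
  expect_equal(nrow(trk_sum), nrow(truth_sum))
  a <- as.data.frame(dplyr::arrange(truth_sum, birth, death, len))[, -1]
  b <- as.data.frame(dplyr::arrange(trk_sum, birth, death, len))[, -1]
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("default-noise tracking has high recall and sub-pixel accuracy", {
  hits <- 0L; total <- 0L; sq_err <- numeric()
  px <- 0.15
  for (seed in c(33, 35)) {
    cfg <- sim_config(image_shape = c(128, 128), n_frames = 50,
                      nucleation_rate = 0.6, min_spacing_um = 1.5,
                      seed = seed)
    sim <- simulate_puncta_movie(cfg)
    tr <- track_movie(sim$movie, min_frames = 3)
    # qualifying puncta present >= 2 monomers for a trackable span
    # (>= 3 frames); pure monomer frames sit below the detection limit
    qual <- dplyr::filter(
      dplyr::summarise(dplyr::group_by(sim$truth, .data$punctum_id),
                       frames_ge2 = sum(n >= 2),
                       x = mean(x_um), y = mean(y_um)),
      frames_ge2 >= 3)
    hit <- vapply(seq_len(nrow(qual)), function(i) {
      any(abs(tr$x_um - qual$x[i]) < 0.5 & abs(tr$y_um - qual$y[i]) < 0.5)
    }, logical(1))
    hits <- hits + sum(hit); total <- total + nrow(qual)
    m <- dplyr::inner_join(tr, sim$truth, by = "frame",
                           relationship = "many-to-many")
    m <- dplyr::filter(m, sqrt((x_um.x - x_um.y)^2 +
                                 (y_um.x - y_um.y)^2) < 0.3)
    sq_err <- c(sq_err, (m$x_um.x - m$x_um.y)^2 / 2 +
                  (m$y_um.x - m$y_um.y)^2 / 2)
  }
  expect_gte(hits / total, 0.95)
  expect_lte(sqrt(mean(sq_err)) / px, 0.5)
})
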