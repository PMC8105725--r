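test_that("an isolated disk cell is segmented with faithful geometry", {
  fx <- simulate_fixedcell_field(n_cells = 1, nuclear_ratio = 2, seed = 1,
                                 image_shape = c(200, 200))
  seg <- segment_cells(fx$dapi, fx$marker, fx$pixel_size_um)
  expect_equal(nrow(seg$cells), 1)
  # equivalent-circle radius within one pixel of the constructed radius
  expect_lt(abs(seg$cells$nucleus_radius_um - fx$truth$nucleus_r_um),
            fx$pixel_size_um)
  expect_lt(abs(seg$cells$nucleus_ecc - 1), 0.05)
  expect_lt(sqrt((seg$cells$x_um - fx$truth$x_um)^2 +
                   (seg$cells$y_um - fx$truth$y_um)^2), 1)
})

test_that("touching nuclei are split into separate labels", {
  px <- 0.283
  H <- 160
  img <- matrix(0, H, H)
  xs <- ((seq_len(H) - 0.5) * px)
  X <- matrix(xs, H, H, byrow = TRUE); Y <- t(X)
  r <- 6
  c1 <- c(18, 22); c2 <- c(18 + 2 * r - 0.3, 22)  # slightly overlapping
  img[(X - c1[1])^2 + (Y - c1[2])^2 <= r^2] <- 500
  img[(X - c2[1])^2 + (Y - c2[2])^2 <= r^2] <- 500
  marker <- img
  seg <- segment_cells(img, marker, px)
  expect_equal(nrow(seg$cells), 2)
})

test_that("a blank field yields an empty segmentation", {
  blank <- matrix(0, 64, 64)
  seg <- segment_cells(blank, blank, 0.283)
  expect_equal(nrow(seg$cells), 0)
})

test_that("each morphological filter rule fires on its constructed violation", {
  fx <- simulate_fixedcell_field(
    n_cells = 4, nuclear_ratio = 2, image_shape = c(480, 480),
    n_crowded = 1, n_edge = 1, n_debris = 1, seed = 3)
  seg <- apply_cell_filters(
    segment_cells(fx$dapi, fx$marker, fx$pixel_size_um))
  cells <- seg$cells
  # map segmented cells to ground truth by nuclear centroid
  idx <- vapply(seq_len(nrow(cells)), function(i)
    which.min((fx$truth$x_um - cells$x_um[i])^2 +
                (fx$truth$y_um - cells$y_um[i])^2), integer(1))
  type <- fx$truth$type[idx]
  expect_setequal(unique(type), unique(fx$truth$type))
  # exact confusion matrix: all constructed passes accepted, all
  # constructed violations rejected for the constructed reason
  expect_true(all(cells$pass_filters[type == "normal"]))
  expect_true(all(!cells$pass_crowding[type == "crowded"]))
  expect_true(all(!cells$pass_border[type == "edge"]))
  expect_true(all(!cells$pass_nucleus_ecc[type == "elongated"]))
  expect_true(all(!cells$pass_filters[type != "normal"]))
  # crowding: 6 nuclei within 16 um means 6 neighbours (self included)
  expect_true(all(cells$n_neighbors_16um[type == "crowded"] == 6))
})

test_that("explicit filter bounds work on a constructed feature table", {
  fx <- simulate_fixedcell_field(n_cells = 1, nuclear_ratio = 1, seed = 5,
                                 image_shape = c(200, 200))
  seg <- segment_cells(fx$dapi, fx$marker, fx$pixel_size_um)
  # nucleus radius 7 um, isolated, interior: passes
  expect_true(apply_cell_filters(seg)$cells$pass_filters)
  # tighten the size window so radius 7 fails (too small)
  expect_false(
    apply_cell_filters(seg, nucleus_radius_um = c(8, 10))$cells$pass_filters)
  # disabling the rule restores the pass
  expect_true(
    apply_cell_filters(seg, nucleus_radius_um = NULL)$cells$pass_filters)
})

test_that("nuclear to cytoplasmic stain ratios are recovered", {
  for (ratio in c(1, 3)) {
    fx <- simulate_fixedcell_field(n_cells = 4, nuclear_ratio = ratio,
                                   image_shape = c(300, 300), seed = 7)
    seg <- apply_cell_filters(
      segment_cells(fx$dapi, fx$marker, fx$pixel_size_um))
    st <- measure_stain(seg, fx$stain, mode = "ratio")
    expect_equal(mean(st$ratio), ratio, tolerance = 0.02)
  }
  # zero stain channel: nuclear mean 0
  fx <- simulate_fixedcell_field(n_cells = 2, nuclear_ratio = 1, seed = 8)
  seg <- segment_cells(fx$dapi, fx$marker, fx$pixel_size_um)
  st0 <- measure_stain(seg, matrix(0, nrow(fx$dapi), ncol(fx$dapi)))
  expect_true(all(st0$nuclear_mean == 0))
})

test_that("normalization to the unstimulated median is plain division", {
  m <- 7
  unstim <- c(5, m, 11)  # median 7
  expect_equal(normalize_to_unstimulated(m, unstim), 1)
  expect_equal(normalize_to_unstimulated(c(2 * m, 4 * m), unstim), c(2, 4))
  expect_equal(normalize_to_unstimulated(10, 5), 2)  # single-value median
  expect_error(normalize_to_unstimulated(1, c(-2, 0)), "positive")
})

test_that("overlapping nuclei configurations are refused", {
  expect_error(
    simulate_fixedcell_field(n_cells = 60, image_shape = c(200, 200),
                             seed = 1),
    "packing")
})

test_that("maximum projection and condition comparison helpers work", {
  st <- array(c(1, 5, 2), c(1, 1, 3))
  expect_equal(max_project(st)[1, 1], 5)
  expect_equal(max_project(st, planes = c(1, 3))[1, 1], 2)
  set.seed(2)
  out <- compare_conditions(rnorm(6, 10), rnorm(6, 10))
  expect_gt(out$p_value, 0.001)
  expect_equal(out$df, 10)
})
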