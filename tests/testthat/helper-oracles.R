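# Independent oracles used to freeze expected values.

# Brute-force longest qualifying colocalization run: rle-based, written
# independently of the package implementation (which scans with a counter).
oracle_coloc_run <- function(ta, tb, dmax) {
  f <- sort(intersect(ta$frame, tb$frame))
  if (!length(f)) return(0L)
  ia <- match(f, ta$frame); ib <- match(f, tb$frame)
  ok <- sqrt((ta$x_um[ia] - tb$x_um[ib])^2 +
               (ta$y_um[ia] - tb$y_um[ib])^2) <= dmax
  grp <- cumsum(c(1L, diff(f) != 1L))
  best <- 0L
  for (g in unique(grp)) {
    r <- rle(ok[grp == g])
    runs <- r$lengths[r$values]
    if (length(runs)) best <- max(best, max(runs))
  }
  as.integer(best)
}

# Expected fraction of a pixel-integrated Gaussian spot captured by the
# 3 x 3 window centred on the spot (closed-form Gaussian integral).
oracle_capture_fraction <- function(sigma, dx = 0, dy = 0) {
  capt <- function(off) {
    pnorm((1.5 - off) / sigma) - pnorm((-1.5 - off) / sigma)
  }
  capt(dx) * capt(dy)
}

# Hand-rank Spearman coefficient (no ties), from the d^2 formula.
oracle_spearman_d2 <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Random toy track pair generator for colocalization oracle comparisons.
random_track_pair <- function(rng_dummy = NULL) {
  fa0 <- sample.int(10, 1); la <- sample(3:12, 1)
  fb0 <- fa0 + sample(-3:6, 1); lb <- sample(3:12, 1)
  mk <- function(f0, l) {
    tibble::tibble(
      track_id = 1L,
      frame = seq(f0, f0 + l - 1L),
      x_um = cumsum(c(runif(1, 0, 3), rnorm(l - 1, 0, 0.08))),
      y_um = cumsum(c(runif(1, 0, 3), rnorm(l - 1, 0, 0.08))))
  }
  ta <- mk(fa0, la); tb <- mk(fb0, lb)
  # occasionally drop a frame to create gaps
  if (runif(1) < 0.3 && nrow(ta) > 4) ta <- ta[-sample(2:(nrow(ta) - 1), 1), ]
  if (runif(1) < 0.3 && nrow(tb) > 4) tb <- tb[-sample(2:(nrow(tb) - 1), 1), ]
  list(a = ta, b = tb)
}
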