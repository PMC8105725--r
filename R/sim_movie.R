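#' @noRd
#' Add one pixel-integrated Gaussian spot to an image matrix.
#' `cx`, `cy` are 0-based continuous centres in pixel-index units (columns =
#' x, rows = y; pixel j spans [j, j+1)); `intensity` is the infinite-plane
#' integral of the spot, so the rendered sum over the support equals
#' `intensity` up to Gaussian truncation (support is +/- 5 sigma).
render_spot <- function(img, cx, cy, sigma, intensity) {
  H <- nrow(img); W <- ncol(img)
  s <- ceiling(5 * sigma)
  j0 <- max(0, floor(cx) - s); j1 <- min(W - 1, floor(cx) + s)
  i0 <- max(0, floor(cy) - s); i1 <- min(H - 1, floor(cy) + s)
  if (j0 > j1 || i0 > i1) return(img)
  xs <- j0:j1; ys <- i0:i1
  fx <- pnorm((xs + 1 - cx) / sigma) - pnorm((xs - cx) / sigma)
  fy <- pnorm((ys + 1 - cy) / sigma) - pnorm((ys - cy) / sigma)
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + intensity * (fy %o% fx)
  img
}

#' @noRd
#' Camera model: Poisson shot noise on the (non-negative) signal, plus
#' offset and Gaussian read noise.
apply_camera <- function(img, cfg) {
  if (cfg$shot_noise) {
    img <- matrix(rpois(length(img), pmax(img, 0)), nrow(img), ncol(img))
  }
  img <- img + cfg$camera_offset
  if (cfg$read_noise_sd > 0) {
    img <- img + matrix(rnorm(length(img), 0, cfg$read_noise_sd),
                        nrow(img), ncol(img))
  }
  img
}

#' @noRd
#' Birth-death size walk of one punctum; consumes draws from the current RNG
#' stream. Returns per-frame monomer counts, summed fluorophore brightness
#' and stability flags, plus whether the punctum died (vs. reached
#' `max_steps` still alive).
walk_one_punctum <- function(cfg, max_steps) {
  unit <- cfg$gfp_unit_mean; usd <- cfg$gfp_unit_cv * cfg$gfp_unit_mean
  n <- sample.int(cfg$start_size_max, 1L)
  b <- rnorm(n, unit, usd)
  stable <- n >= cfg$stable_size_threshold
  ns <- integer(max_steps); Bs <- numeric(max_steps); st <- logical(max_steps)
  died <- FALSE
  t <- 0L
  while (t < max_steps) {
    t <- t + 1L
    ns[t] <- n; Bs[t] <- sum(b); st[t] <- stable
    if (stable) {
      if (n < cfg$max_size && runif(1) < cfg$stable_p_grow) {
        n <- n + 1L
        b <- c(b, rnorm(1, unit, usd))
      }
    } else {
      u <- runif(1)
      if (u < cfg$p_grow) {
        n <- n + 1L
        b <- c(b, rnorm(1, unit, usd))
        if (n >= cfg$stable_size_threshold) stable <- TRUE
      } else if (u < cfg$p_grow + cfg$p_shrink) {
        drop <- sample.int(n, 1L)
        b <- b[-drop]
        n <- n - 1L
        if (n == 0L) { died <- TRUE; break }
      }
    }
  }
  keep <- seq_len(t)  # all recorded frames have n > 0 (death breaks first)
  list(n = ns[keep], intensity = Bs[keep], stable = st[keep], died = died)
}

#' Simulate the oligomer size kinetics alone
#'
#' Runs the two-population birth-death size walk of [sim_config()] for
#' `n_puncta` puncta without rendering any pixels. Useful for validating the
#' kinetic model (lifetime laws, growth-lifetime coupling) at large n.
#'
#' @param n_puncta number of puncta to simulate.
#' @param config a [sim_config()]; kinetic and photometry fields are used.
#' @param max_frames walk horizon per punctum (default `config$n_frames`);
#'   puncta still alive at the horizon are right-censored.
#' @param seed seed (default `config$seed`).
#'
#' @return A tibble with one row per punctum per frame: `punctum_id`,
#'   `frame` (1-based, relative to nucleation), `n` (monomers), `intensity`
#'   (summed fluorophore brightness, ADU), `stable`, `censored`.
#' @export
simulate_size_walk <- function(n_puncta, config = sim_config(),
                               max_frames = config$n_frames,
                               seed = config$seed) {
  validate_sim_config(config)
  withr::with_seed(seed, {
    walks <- lapply(seq_len(n_puncta), function(i)
      walk_one_punctum(config, max_frames))
  })
  dplyr::bind_rows(lapply(seq_len(n_puncta), function(i) {
    w <- walks[[i]]
    tibble::tibble(
      punctum_id = i, frame = seq_along(w$n), n = w$n,
      intensity = w$intensity, stable = w$stable, censored = !w$died)
  }))
}

#' Simulate a TIRF movie of assembling oligomer puncta
#'
#' Puncta nucleate at uniform random positions at rate
#' `config$nucleation_rate` per frame, perform the birth-death monomer walk
#' of [sim_config()], and are rendered each frame as pixel-integrated 2-D
#' Gaussians whose integrated intensity is the summed brightness of their
#' fluorophores; the camera model then adds offset, shot noise and read
#' noise. Ground truth is exhaustive: every punctum's per-frame position,
#' monomer count and rendered intensity is returned.
#'
#' Random draws descend from `config$seed` in documented order: per-frame
#' birth counts; then punctum-by-punctum (in nucleation order) the position,
#' start size, fluorophore brightnesses, walk transitions, diffusion steps
#' and partner delay; then per-frame camera noise.
#'
#' @param config a [sim_config()].
#' @param partner_channel logical; also render the partner (e.g. IRAK)
#'   channel, recruited to puncta whose monomer count ever reaches
#'   `config$partner_size_threshold` after a truncated-normal delay from
#'   nucleation.
#' @param render logical; `FALSE` skips pixel rendering (`movie` is
#'   `NULL`) and returns the kinetic ground truth only — useful for
#'   large-n studies of the assembly kinetics. Camera noise is drawn after
#'   all kinetic draws, so the truth is bit-identical either way.
#'
#' @return A list with `movie` (a [tirf_movie()]), `truth` (tibble:
#'   `punctum_id`, `frame`, `x_um`, `y_um`, `n`, `intensity`, `stable`,
#'   `birth_frame`, `death_frame`, `censored`, `partner_frame`), and, when
#'   `partner_channel`, `movie_partner`.
#' @export
simulate_puncta_movie <- function(config = sim_config(),
                                  partner_channel = FALSE,
                                  render = TRUE) {
  cfg <- validate_sim_config(config)
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]
  m <- cfg$margin_px
  if (2 * m >= min(H, W)) stop("margin_px too large for image_shape")
  px <- cfg$pixel_size_um; dt <- cfg$frame_interval_s

  withr::with_seed(cfg$seed, {
    births_per_frame <- rpois(cfg$n_frames, cfg$nucleation_rate)
    birth_frames <- rep(seq_len(cfg$n_frames), births_per_frame)
    np <- length(birth_frames)
    puncta <- vector("list", np)
    for (i in seq_len(np)) {
      bf <- birth_frames[i]
      # position (rejection against live puncta when min_spacing_um > 0)
      pos <- NULL
      for (attempt in seq_len(50L)) {
        cx <- runif(1, m, W - m); cy <- runif(1, m, H - m)
        if (cfg$min_spacing_um <= 0) { pos <- c(cx, cy); break }
        ok <- TRUE
        for (j in seq_len(i - 1L)) {
          pj <- puncta[[j]]
          if (is.null(pj)) next
          alive <- bf >= pj$birth_frame & bf <= pj$death_frame
          if (!alive) next
          d <- sqrt((cx - pj$cx[1])^2 + (cy - pj$cy[1])^2) * px
          if (d < cfg$min_spacing_um) { ok <- FALSE; break }
        }
        if (ok) { pos <- c(cx, cy); break }
      }
      if (is.null(pos)) { puncta[i] <- list(NULL); next }
      w <- walk_one_punctum(cfg, cfg$n_frames - bf + 1L)
      L <- length(w$n)
      cx <- rep(pos[1], L); cy <- rep(pos[2], L)
      if (cfg$diffusion_step_um > 0 && L > 1) {
        step_px <- cfg$diffusion_step_um / px
        cx <- cx + c(0, cumsum(rnorm(L - 1, 0, step_px)))
        cy <- cy + c(0, cumsum(rnorm(L - 1, 0, step_px)))
      }
      partner_frame <- NA_integer_
      if (max(w$n) >= cfg$partner_size_threshold) {
        delay <- max(0, rnorm(1, cfg$partner_delay_mean_s,
                              cfg$partner_delay_sd_s))
        pf <- bf + as.integer(round(delay / dt))
        if (pf <= bf + L - 1L) partner_frame <- pf
      }
      puncta[[i]] <- list(
        id = i, birth_frame = bf, death_frame = bf + L - 1L,
        cx = cx, cy = cy, n = w$n, intensity = w$intensity,
        stable = w$stable, censored = !w$died, partner_frame = partner_frame)
    }
    puncta <- Filter(Negate(is.null), puncta)

    partner_intensity <- vapply(puncta, function(p) {
      if (is.na(p$partner_frame)) return(NA_real_)
      sum(rnorm(cfg$partner_copies, cfg$gfp_unit_mean,
                cfg$gfp_unit_cv * cfg$gfp_unit_mean))
    }, numeric(1))

    frames <- if (render) array(0, c(H, W, cfg$n_frames))
    frames_b <- if (render && partner_channel)
      array(0, c(H, W, cfg$n_frames))
    for (t in if (render) seq_len(cfg$n_frames) else integer()) {
      img <- matrix(cfg$background_level, H, W)
      img_b <- matrix(cfg$background_level, H, W)
      for (pi in seq_along(puncta)) {
        p <- puncta[[pi]]
        if (t < p$birth_frame || t > p$death_frame) next
        k <- t - p$birth_frame + 1L
        img <- render_spot(img, p$cx[k], p$cy[k], cfg$psf_sigma_px,
                           p$intensity[k])
        if (partner_channel && !is.na(p$partner_frame) &&
            t >= p$partner_frame) {
          img_b <- render_spot(img_b, p$cx[k], p$cy[k], cfg$psf_sigma_px,
                               partner_intensity[pi])
        }
      }
      frames[, , t] <- apply_camera(img, cfg)
      if (partner_channel) frames_b[, , t] <- apply_camera(img_b, cfg)
    }
  })

  truth <- dplyr::bind_rows(lapply(puncta, function(p) {
    k <- seq_along(p$n)
    tibble::tibble(
      punctum_id = p$id, frame = p$birth_frame + k - 1L,
      x_um = p$cx * px, y_um = p$cy * px,
      n = p$n, intensity = p$intensity, stable = p$stable,
      birth_frame = p$birth_frame, death_frame = p$death_frame,
      censored = p$censored, partner_frame = p$partner_frame)
  }))
  if (nrow(truth) == 0) {
    truth <- tibble::tibble(
      punctum_id = integer(), frame = integer(), x_um = numeric(),
      y_um = numeric(), n = integer(), intensity = numeric(),
      stable = logical(), birth_frame = integer(), death_frame = integer(),
      censored = logical(), partner_frame = integer())
  }
  out <- list(movie = if (render) tirf_movie(frames, px, dt), truth = truth)
  if (render && partner_channel)
    out$movie_partner <- tirf_movie(frames_b, px, dt)
  out
}

#' Simulate a calibration stack of immobile single fluorophores
#'
#' Emulates purified monomeric GFP adsorbed sparsely to glass: `n_emitters`
#' immobile single-fluorophore spots with static brightnesses drawn from
#' Normal(`gfp_unit_mean`, (`gfp_unit_cv` * `gfp_unit_mean`)^2), rendered
#' with the same PSF and camera model as live movies. Each emitter bleaches
#' in a single step with rate `bleach_rate` per frame (survival to frame t is
#' exp(-bleach_rate * (t - 1)); all emitters are visible at frame 1).
#'
#' Emitter positions are drawn with a minimum pairwise spacing of
#' `4 * psf_sigma_px`; configurations too dense for that spacing (expected
#' mean nearest-neighbour distance below it) are refused.
#'
#' @param config a [sim_config()].
#' @param n_emitters number of emitters.
#' @param bleach_rate single-step photobleach rate per frame (0 = none).
#' @param background_level background on clean glass, ADU (default 2,
#'   overriding the cellular default of `config`: adsorbed fluorophores in
#'   buffer see far less background than the cytosol).
#' @param seed seed (default `config$seed`).
#'
#' @return List with `movie` (a [tirf_movie()]) and `truth` (tibble:
#'   `emitter_id`, `x_um`, `y_um`, `brightness`, `last_frame`).
#' @export
simulate_calibration_stack <- function(config = sim_config(),
                                       n_emitters = 100,
                                       bleach_rate = 0,
                                       background_level = 2,
                                       seed = config$seed) {
  config$background_level <- background_level
  cfg <- validate_sim_config(config)
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]
  m <- cfg$margin_px; px <- cfg$pixel_size_um
  min_sp <- 4 * cfg$psf_sigma_px
  # expected mean nearest-neighbour spacing for a Poisson point field
  if (0.5 * sqrt(H * W / n_emitters) < min_sp)
    stop("emitter density too high: mean nearest-neighbour spacing would be ",
         "< 4 * psf_sigma_px")

  withr::with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    for (i in seq_len(n_emitters)) {
      placed <- FALSE
      for (attempt in seq_len(200L)) {
        cx <- runif(1, m, W - m); cy <- runif(1, m, H - m)
        if (!length(xs) || min(sqrt((xs - cx)^2 + (ys - cy)^2)) >= min_sp) {
          xs <- c(xs, cx); ys <- c(ys, cy); placed <- TRUE; break
        }
      }
      if (!placed)
        stop("could not place emitters with 4-sigma spacing; reduce density")
    }
    brightness <- rnorm(n_emitters, cfg$gfp_unit_mean,
                        cfg$gfp_unit_cv * cfg$gfp_unit_mean)
    last_frame <- rep(cfg$n_frames, n_emitters)
    if (bleach_rate > 0) {
      L <- 1L + stats::rgeom(n_emitters, 1 - exp(-bleach_rate))
      last_frame <- pmin(L, cfg$n_frames)
    }
    frames <- array(0, c(H, W, cfg$n_frames))
    for (t in seq_len(cfg$n_frames)) {
      img <- matrix(cfg$background_level, H, W)
      for (i in seq_len(n_emitters)) {
        if (t > last_frame[i]) next
        img <- render_spot(img, xs[i], ys[i], cfg$psf_sigma_px, brightness[i])
      }
      frames[, , t] <- apply_camera(img, cfg)
    }
  })
  list(
    movie = tirf_movie(frames, px, cfg$frame_interval_s),
    truth = tibble::tibble(
      emitter_id = seq_len(n_emitters), x_um = xs * px,
      y_um = ys * px, brightness = brightness,
      last_frame = as.integer(last_frame))
  )
}

#' Simulate a field of immobile N-mer puncta of known copy number
#'
#' Renders `n_puncta` static puncta, each a sum of `copies` fluorophores,
#' placed on a jittered grid with generous spacing. Used to validate
#' stoichiometry recovery through the full detection / tracking /
#' classification pipeline against known copy numbers.
#'
#' @param copies monomer copy number of every punctum.
#' @param n_puncta number of puncta.
#' @param config a [sim_config()]; `n_frames` controls the movie length.
#' @param spacing_px grid spacing (default `max(8 * psf_sigma_px, 12)`).
#' @param seed seed (default `config$seed`).
#'
#' @return List with `movie` and `truth` (tibble: `punctum_id`, `x_um`,
#'   `y_um`, `n`, `intensity`).
#' @export
simulate_nmer_field <- function(copies, n_puncta, config = sim_config(),
                                spacing_px = NULL, seed = config$seed) {
  cfg <- validate_sim_config(config)
  stopifnot(copies >= 1, n_puncta >= 1)
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]; m <- cfg$margin_px
  if (is.null(spacing_px)) spacing_px <- max(8 * cfg$psf_sigma_px, 12)
  gx <- seq(m, W - m, by = spacing_px)
  gy <- seq(m, H - m, by = spacing_px)
  if (length(gx) * length(gy) < n_puncta)
    stop("image too small for ", n_puncta, " puncta at spacing ", spacing_px)
  centers <- expand.grid(cx = gx, cy = gy)[seq_len(n_puncta), ]

  withr::with_seed(seed, {
    cx <- centers$cx + runif(n_puncta, -0.5, 0.5)
    cy <- centers$cy + runif(n_puncta, -0.5, 0.5)
    brightness <- vapply(seq_len(n_puncta), function(i)
      sum(rnorm(copies, cfg$gfp_unit_mean,
                cfg$gfp_unit_cv * cfg$gfp_unit_mean)), numeric(1))
    frames <- array(0, c(H, W, cfg$n_frames))
    base <- matrix(cfg$background_level, H, W)
    for (i in seq_len(n_puncta))
      base <- render_spot(base, cx[i], cy[i], cfg$psf_sigma_px, brightness[i])
    for (t in seq_len(cfg$n_frames)) frames[, , t] <- apply_camera(base, cfg)
  })
  list(
    movie = tirf_movie(frames, cfg$pixel_size_um, cfg$frame_interval_s),
    truth = tibble::tibble(
      punctum_id = seq_len(n_puncta),
      x_um = cx * cfg$pixel_size_um,
      y_um = cy * cfg$pixel_size_um,
      n = copies, intensity = brightness)
  )
}
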