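#' Simulation configuration for synthetic TIRF movies
#'
#' Defines the imaging geometry, camera model, single-fluorophore photometry
#' and oligomer assembly kinetics used by [simulate_puncta_movie()] and the
#' other generators. Defaults emulate the imaging regime the pipeline is
#' designed for: 150 nm pixels, 1 s frame interval, a diffraction-limited
#' Gaussian PSF, and a two-population kinetic model in which most nascent
#' oligomers are transient (death-biased birth-death walk over monomer
#' counts) while the minority that reach `stable_size_threshold` monomers
#' persist and keep growing.
#'
#' Assembly kinetics: a punctum nucleates with 1..`start_size_max` monomers;
#' each frame it gains a monomer with probability `p_grow` or loses one with
#' probability `p_shrink` (else unchanged) and dies when the count reaches 0.
#' Once the count reaches `stable_size_threshold` the punctum becomes stable:
#' it no longer shrinks and instead gains a monomer with probability
#' `stable_p_grow`, capped at `max_size` (`Inf` allowed, emulating the
#' unbounded growth regime seen when downstream kinases are absent).
#'
#' Photometry: each fluorophore carries a fixed brightness drawn once from
#' Normal(`gfp_unit_mean`, (`gfp_unit_cv` * `gfp_unit_mean`)^2); a punctum's
#' integrated intensity is the running sum of its fluorophores' brightnesses,
#' so an n-mer's intensity is Normal with mean `n * gfp_unit_mean` and SD
#' `sqrt(n) * gfp_unit_cv * gfp_unit_mean` (relative noise shrinking as
#' 1/sqrt(n)), and a given punctum's brightness is stable over frames as a
#' sum of fluorophores is. The camera adds `camera_offset`, Poisson shot
#' noise (when `shot_noise`) and Gaussian read noise.
#'
#' Partner channel: puncta whose monomer count ever reaches
#' `partner_size_threshold` recruit a partner-channel punctum at the same
#' position after a delay from nucleation drawn from
#' Normal(`partner_delay_mean_s`, `partner_delay_sd_s`^2) truncated at 0.
#'
#' @param image_shape integer vector `c(H, W)` in pixels.
#' @param pixel_size_um pixel size, micrometres (default 0.15).
#' @param frame_interval_s frame interval, seconds (default 1).
#' @param n_frames number of frames.
#' @param psf_sigma_px Gaussian PSF standard deviation, pixels.
#' @param gfp_unit_mean mean single-GFP integrated intensity, ADU.
#' @param gfp_unit_cv coefficient of variation of the single-GFP intensity.
#' @param camera_offset camera offset, ADU.
#' @param read_noise_sd Gaussian read noise SD, ADU.
#' @param shot_noise logical; add Poisson shot noise on the signal.
#' @param background_level uniform cytosolic background level, ADU.
#' @param nucleation_rate expected new puncta per frame.
#' @param start_size_max nucleating puncta start with 1..`start_size_max`
#'   monomers (uniform).
#' @param p_grow,p_shrink per-frame monomer gain/loss probabilities while
#'   unstable.
#' @param stable_size_threshold monomer count at which a punctum stabilises.
#' @param stable_p_grow per-frame growth probability once stable.
#' @param max_size monomer cap once stable (`Inf` = no cap).
#' @param partner_size_threshold monomer count gating partner recruitment.
#' @param partner_delay_mean_s,partner_delay_sd_s partner recruitment delay
#'   distribution, seconds.
#' @param partner_copies partner punctum copy number (rendered intensity is
#'   `partner_copies` fluorophore units of the partner channel).
#' @param diffusion_step_um per-frame Gaussian random-walk step of punctum
#'   position, micrometres (0 = stationary).
#' @param min_spacing_um minimum allowed distance between a nucleating
#'   punctum and any live punctum (0 disables; used to build well-separated
#'   validation movies).
#' @param margin_px puncta nucleate at least this many pixels from the image
#'   border.
#' @param seed integer seed; every random draw of a simulation call descends
#'   from it.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(image_shape = c(128, 128),
                       pixel_size_um = 0.15,
                       frame_interval_s = 1,
                       n_frames = 100,
                       psf_sigma_px = 1.1,
                       gfp_unit_mean = 100,
                       gfp_unit_cv = 0.25,
                       camera_offset = 100,
                       read_noise_sd = 2,
                       shot_noise = TRUE,
                       background_level = 20,
                       nucleation_rate = 0.2,
                       start_size_max = 3,
                       p_grow = 0.10,
                       p_shrink = 0.25,
                       stable_size_threshold = 4,
                       stable_p_grow = 0.15,
                       max_size = 12,
                       partner_size_threshold = 6,
                       partner_delay_mean_s = 15,
                       partner_delay_sd_s = 5,
                       partner_copies = 6,
                       diffusion_step_um = 0,
                       min_spacing_um = 0,
                       margin_px = 6,
                       seed = 1L) {
  cfg <- list(
    image_shape = as.integer(image_shape), pixel_size_um = pixel_size_um,
    frame_interval_s = frame_interval_s, n_frames = as.integer(n_frames),
    psf_sigma_px = psf_sigma_px, gfp_unit_mean = gfp_unit_mean,
    gfp_unit_cv = gfp_unit_cv, camera_offset = camera_offset,
    read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise),
    background_level = background_level, nucleation_rate = nucleation_rate,
    start_size_max = as.integer(start_size_max),
    p_grow = p_grow, p_shrink = p_shrink,
    stable_size_threshold = stable_size_threshold,
    stable_p_grow = stable_p_grow, max_size = max_size,
    partner_size_threshold = partner_size_threshold,
    partner_delay_mean_s = partner_delay_mean_s,
    partner_delay_sd_s = partner_delay_sd_s,
    partner_copies = partner_copies,
    diffusion_step_um = diffusion_step_um,
    min_spacing_um = min_spacing_um, margin_px = margin_px,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(image_shape) != 2L || any(image_shape <= 0))
      stop("image_shape must be two positive integers (H, W)")
    if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
    if (frame_interval_s <= 0) stop("frame_interval_s must be positive")
    if (psf_sigma_px <= 0) stop("psf_sigma_px must be positive")
    if (psf_sigma_px >= min(image_shape) / 4)
      stop("psf_sigma_px must be < min(H, W) / 4")
    probs <- c(p_grow, p_shrink, stable_p_grow)
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
    if (p_grow + p_shrink > 1)
      stop("p_grow + p_shrink must not exceed 1")
    if (gfp_unit_cv < 0) stop("gfp_unit_cv must be >= 0")
    if (gfp_unit_mean <= 0) stop("gfp_unit_mean must be positive")
    if (nucleation_rate < 0) stop("nucleation_rate must be >= 0")
    if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %d x %d px, %d frames @ %g s, %g nm/px\n",
           "  PSF sigma %g px | GFP unit %g ADU (CV %g) | offset %g, read ",
           "noise %g\n  nucleation %g/frame | p_grow %g, p_shrink %g | ",
           "stable at >= %g (p_grow %g, cap %s)\n"),
    x$image_shape[1], x$image_shape[2], x$n_frames, x$frame_interval_s,
    1000 * x$pixel_size_um, x$psf_sigma_px, x$gfp_unit_mean, x$gfp_unit_cv,
    x$camera_offset, x$read_noise_sd, x$nucleation_rate, x$p_grow,
    x$p_shrink, x$stable_size_threshold, x$stable_p_grow,
    ifelse(is.finite(x$max_size), format(x$max_size), "none")))
  invisible(x)
}
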