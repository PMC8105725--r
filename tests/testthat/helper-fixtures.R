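# Shared fixtures, computed once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# A noise-free config: no camera noise, no brightness heterogeneity.
noise_free_config <- function(...) {
  sim_config(gfp_unit_cv = 0, read_noise_sd = 0, shot_noise = FALSE,
             camera_offset = 0, background_level = 0, ...)
}

# Calibration model measured through the full pipeline on a simulated
# single-GFP stack (glass background).
fixture_pipeline_calibration <- function() {
  fixture("pipeline_cal", {
    cal <- simulate_calibration_stack(
      sim_config(image_shape = c(128, 128), n_frames = 10, seed = 3),
      n_emitters = 60)
    calibrate_stack(cal$movie)
  })
}

# Track tables built directly from simulation ground truth (positions and
# true summed-fluorophore intensities, no rendering).
truth_tracks <- function(truth) {
  tibble::tibble(track_id = truth$punctum_id, frame = truth$frame,
                 x_um = truth$x_um, y_um = truth$y_um,
                 intensity = truth$intensity)
}

partner_truth_tracks <- function(truth) {
  keep <- !is.na(truth$partner_frame) & truth$frame >= truth$partner_frame
  tibble::tibble(track_id = truth$punctum_id[keep],
                 frame = truth$frame[keep],
                 x_um = truth$x_um[keep], y_um = truth$y_um[keep])
}
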