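# Shared fixtures: everything is generated in code at test time.

# small quiet movie with one centered landing event, zero noise
tiny_event_movie <- function(n_frames = 80L, field_px = 48L,
                             contrast = 2.2e-3, frame = 40L,
                             row = 24, col = 24, noise_sigma = 0,
                             seed = 1L) {
  p <- simulation_params(n_frames = n_frames, n_events = 0L,
                         field_px = field_px, noise_sigma = noise_sigma,
                         speckle_amp = 0, seed = seed)
  sim <- simulate_movie(p)
  truth <- tibble::tibble(frame = frame, row = row, col = col,
                          contrast = contrast)
  list(movie = inject_events(sim$movie, truth, psf_model()), truth = truth)
}

# representative operating noise: the scale at which the monomer anchor
# calibration lands (single-frame std on a background of 1)
op_noise_sigma <- 2.4e-3

# the study calibration constants
study_cal <- calibration_model()

expect_tibble_cols <- function(x, cols) {
  expect_true(all(cols %in% names(x)))
}
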