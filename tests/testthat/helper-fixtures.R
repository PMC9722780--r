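# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# moderate all-valid-cue session with the shipped valid profile
valid_session <- function() {
  fixture("valid_session", function() {
    sp <- stim_params(cue_probability = 1, cue_validity = 1)
    simulate_session(1500, sp, model_params("valid"), seed = 420L,
                     observer_id = "fix_valid")
  })
}

# a zero-noise, zero-internal-noise single-trial movie (deterministic path)
quiet_movie <- function(seed = 5L, onset_frame = 1L, side = "left") {
  sp <- stim_params()
  mv <- make_noise_movie(sp, seed)
  mv$noise[] <- 0
  mv$contrast <- mv$noise
  mv <- add_target(mv, side, onset_frame, sp)
  mv$eps_std <- rep(0, sp$n_frames)
  mv
}
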