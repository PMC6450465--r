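# Small synthesis helpers shared across test files.

# Compact protocol config for fast tests: 16x16 grid, single-second record.
test_config <- function(noise_sd = 0, seed = 1, grid = c(16, 16)) {
  cfg <- synth_protocol_config(noise_sd = noise_sd, seed = seed)
  cfg$grid <- as.integer(grid)
  cfg
}

# Template whose transient fully recovers before the next beat at the bcls
# used in tests, so noiseless amplitude recovery is exact.
test_template <- function(decay_tau = 20) {
  transient_template(time_to_peak = 12, decay_tau = decay_tau,
                     amplitude = 100, baseline = 100,
                     support = 12 + decay_tau * 4.7)
}

# Random per-beat amplitude series and the matching single-pixel trace
# (window-truncated transients, stimulus-aligned sampling), used by the
# oracle-equivalence tests.
random_beat_trace <- function(n_beats, bcl, template = test_template(),
                              frame_rate = 1000) {
  amps <- stats::runif(n_beats, 20, 200)
  total <- n_beats * bcl
  t <- seq(0, total - 1e-9, by = 1000 / frame_rate)
  trace <- rep(template$baseline, length(t))
  for (k in seq_len(n_beats)) {
    tk <- t - (k - 1) * bcl
    win <- tk >= 0 & tk < bcl
    trace[win] <- template$baseline +
      amps[k] * alternansim:::.transient_shape(template, tk[win])
  }
  list(trace = trace, amps = amps,
       pacing_times = (seq_len(n_beats) - 1) * bcl)
}
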