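test_that("alternans fields validate magnitudes and grids", {
  expect_error(alternans_field(matrix(1.2, 4, 4)), "within")
  expect_error(alternans_field(matrix(0.5, 4, 4),
                               bz_mask = matrix(FALSE, 3, 3)), "match")
  expect_error(make_discordant_field(c(8, 8), peak_magnitude = 0), "peak")
  expect_error(make_discordant_field(c(8, 8), peak_magnitude = 1.5), "peak")
  expect_error(make_discordant_field(c(8, 8), nodal_line = 20), "grid")
})

test_that("discordant field changes sign only across the nodal curve", {
  f <- make_discordant_field(c(16, 16), nodal_line = 8.5,
                             peak_magnitude = 0.3)
  expect_true(all(f$signed[, 1:8] < 0))
  expect_true(all(f$signed[, 9:16] > 0))
  expect_lt(max(abs(f$signed)), 0.3 + 1e-12)
  # taper: magnitude grows monotonically away from the curve on each row
  expect_true(all(diff(f$signed[1, 9:16]) > 0))
})

test_that("default BZ mask is one connected left-edge region", {
  m <- default_bz_mask(c(32, 32), fraction = 0.4)
  expect_true(all(m[, 1:12]))
  expect_false(any(m[, 14:32]))
  expect_error(default_bz_mask(c(8, 8), fraction = 0), "fraction")
})

test_that("protocol config enforces its invariants", {
  expect_error(synth_protocol_config(recorded_duration = 11), "exceed")
  expect_error(synth_protocol_config(frame_rate = 333,
                                     recorded_duration = 0.5), "integer")
  expect_silent(synth_protocol_config())
})

test_that("default-protocol movies carry 1000 frames per second on the full grid", {
  cfg <- synth_protocol_config(noise_sd = 0)
  sm <- synthesize_movie(cfg, make_uniform_field(c(32, 32), 0.1),
                         transient_template(), bcl = 100)
  expect_equal(dim(sm$movie$calcium), c(32, 32, 1000))
  expect_equal(dim(sm$movie$voltage), c(32, 32, 1000))
  expect_equal(sm$movie$frame_rate, 1000)
  expect_equal(diff(sm$movie$pacing_times), rep(100, 9))
})

test_that("noiseless uniform movies have exactly alternating beat amplitudes", {
  cfg <- test_config()
  sm <- synthesize_movie(cfg, make_uniform_field(c(16, 16), 0.2),
                         test_template(), bcl = 120, voltage = FALSE)
  tr <- sm$movie$calcium[4, 7, ]
  w <- segment_beats(tr, sm$movie$pacing_times, 1000)
  amps <- alternansim:::.trace_amplitudes(tr, w)
  # even beats (1st, 3rd, ...) carry a(1+s), odd a(1-s)
  expect_equal(amps[c(1, 3, 5)] / amps[c(2, 4, 6)],
               rep(1.2 / 0.8, 3), tolerance = 1e-9)
  # direct evaluation: |A-B|/(A+B) = 0.2
  expect_equal(unname(nam_pixel(amps)["signed"]), 0.2, tolerance = 1e-9)
})

test_that("zero-alternans noiseless movies give identical beats and zero NAM", {
  cfg <- test_config()
  sm <- synthesize_movie(cfg, make_uniform_field(c(16, 16), 0),
                         test_template(), bcl = 120, voltage = FALSE)
  map <- alternans_map(sm$movie, detrend = FALSE)
  expect_lt(max(map$nam, na.rm = TRUE), 1e-12)
  expect_equal(nrow(map$nodal_lines), 0)
})

test_that("regeneration is seed-deterministic and seeds change only the noise", {
  cfg <- test_config(noise_sd = 0.05, seed = 5)
  f <- make_uniform_field(c(16, 16), 0.15)
  m1 <- synthesize_movie(cfg, f, test_template(), bcl = 100)
  m2 <- synthesize_movie(cfg, f, test_template(), bcl = 100)
  expect_identical(m1$movie$calcium, m2$movie$calcium)
  m3 <- synthesize_movie(cfg, f, test_template(), bcl = 100, seed = 6)
  expect_false(identical(m1$movie$calcium, m3$movie$calcium))
  # the underlying clean signal is the same: differences are noise-scale
  expect_lt(max(abs(m1$movie$calcium - m3$movie$calcium)),
            10 * 0.05 * 100)
})

test_that("voltage channel durations alternate in phase with calcium", {
  cfg <- test_config()
  sm <- synthesize_movie(cfg, make_uniform_field(c(16, 16), 0.2),
                         test_template(), bcl = 140, apd0 = 60)
  tr <- sm$movie$voltage[8, 8, ]
  w <- segment_beats(tr, sm$movie$pacing_times, 1000)
  durs <- vapply(w[1:4], function(idx) {
    transient_duration(tr[idx], 0.9, 1000)
  }, numeric(1))
  res <- apd_alternans_pixel(durs)
  expect_gt(res[["signed"]], 0.1)  # even beats longer, same phase as Ca
})

test_that("synthesize_protocol produces the full condition x bcl x repeat grid", {
  cfg <- test_config(seed = 2)
  cfg$bcl_list <- c(140, 100)
  prot <- synthesize_protocol(cfg, make_uniform_field(c(16, 16), 0.3),
                              test_template(),
                              conditions = c("control", "NE"),
                              n_repeats = 2, voltage = FALSE)
  expect_named(prot, c("control", "NE"))
  expect_named(prot$control, c("140", "100"))
  expect_length(prot$control[["140"]], 2)
  # the NE condition attenuates the programmed alternans field
  expect_lt(max(abs(prot$NE[["100"]][[1]]$truth$signed)),
            0.5 * max(abs(prot$control[["100"]][[1]]$truth$signed)))
})
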