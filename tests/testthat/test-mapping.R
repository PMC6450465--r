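test_that("beat segmentation yields one window per complete pacing interval", {
  tr <- rep(0, 1000)  # 1000 ms at 1 kHz
  w100 <- segment_beats(tr, seq(0, 900, by = 100), 1000)
  expect_length(w100, 10)
  w140 <- segment_beats(tr, seq(0, 980, by = 140), 1000)
  expect_length(w140, 7)  # floor(1000/140)
  expect_error(segment_beats(tr, 0, 1000), "insufficient")
})

test_that("beat amplitude is peak minus pre-upstroke baseline", {
  expect_equal(beat_amplitude(c(100, 130, 160, 120, 105)), 60)
  w <- c(100, 130, 160, 120, 105)
  expect_equal(beat_amplitude(2 * w), 2 * beat_amplitude(w))  # gain
  expect_equal(beat_amplitude(rep(7, 10)), 0)                 # flat
  expect_equal(beat_amplitude(c(50, 80), pre_window = c(20, 10)), 70)
  expect_error(beat_amplitude(numeric(0)), "empty")
})

test_that("normalized alternans magnitude follows |A-B|/(A+B)", {
  expect_equal(nam_pixel(c(1.2, 0.8, 1.2, 0.8)),
               c(nam = 0.2, signed = 0.2))
  expect_equal(nam_pixel(c(1.5, 0.5)), c(nam = 0.5, signed = 0.5))
  expect_equal(unname(nam_pixel(rep(3, 8))["nam"]), 0)
  # odd beat count: last beat dropped so the series have equal length
  expect_equal(nam_pixel(c(1.2, 0.8, 99)), nam_pixel(c(1.2, 0.8)))
  # undefined when A + B is zero
  expect_true(all(is.na(nam_pixel(c(0, 0, 0, 0)))))
  expect_error(nam_pixel(1), "2 beats")
})

test_that("duration alternans mirrors the amplitude statistic", {
  expect_equal(unname(apd_alternans_pixel(c(60, 40, 60, 40))["nam"]), 0.2)
  expect_equal(unname(apd_alternans_pixel(c(55, 45))["nam"]), 0.1)
  expect_equal(unname(apd_alternans_pixel(rep(80, 6))["nam"]), 0)
})

test_that("alternans statistic is invariant to gain and offset and flips with parity", {
  set.seed(42)
  for (i in 1:20) {
    amps <- runif(8, 0.5, 2)
    base <- nam_pixel(amps)
    gain <- runif(1, 0.1, 10)
    expect_equal(nam_pixel(gain * amps), base, tolerance = 1e-12)
    # parity swap -> signed negates, nam unchanged
    swapped <- nam_pixel(amps[c(2, 1, 4, 3, 6, 5, 8, 7)])
    expect_equal(swapped[["nam"]], base[["nam"]], tolerance = 1e-12)
    expect_equal(swapped[["signed"]], -base[["signed"]], tolerance = 1e-12)
  }
  # offset invariance happens upstream: amplitudes are baseline-subtracted
  tr <- make_transient(test_template(), 50, 100)
  expect_equal(beat_amplitude(tr + 1000), beat_amplitude(tr))
})

test_that("transient duration interpolates, censors and handles level 0", {
  tr <- make_transient(transient_template(time_to_peak = 10,
                                          decay_tau = 25),
                       beat_amplitude = 1, duration = 300)
  expect_equal(transient_duration(tr, 0, 1000), 10)  # time of peak
  d <- transient_duration(tr, 0.9, 1000)
  expect_equal(d, 10 + 25 * log(10), tolerance = 0.2)
  # window too short to recover: right-censored
  short <- tr[1:30]
  res <- transient_duration(short, 0.9, 1000)
  expect_true(is.na(res))
  expect_true(attr(res, "censored"))
  expect_error(transient_duration(rep(1, 10), 0.9), "peak")
})

test_that("pipeline masks weak pixels and errors when nothing is valid", {
  cfg <- test_config(noise_sd = 0.05, seed = 9)
  # half the field has zero-amplitude beats (scar-like), half real signal
  f <- make_uniform_field(c(16, 16), 0.1)
  sm <- synthesize_movie(cfg, f, test_template(), bcl = 100,
                         voltage = FALSE)
  scar <- sm$movie
  scar$calcium[, 1:8, ] <- matrix(rnorm(16 * 8 * 1000, 100, 5),
                                  nrow = 16 * 8)
  dim(scar$calcium) <- c(16, 16, 1000)
  map <- alternans_map(scar)
  # the 3x3 spatial filter blurs real signal into the scar boundary, so
  # only pixels beyond the blur range must fail
  expect_false(any(map$valid_mask[, 1:6]))
  expect_true(mean(map$valid_mask[, 10:16]) > 0.9)
  expect_true(all(is.na(map$nam[!map$valid_mask])))
  # a pure-noise movie has no valid pixel at all
  noise <- sm$movie
  noise$calcium <- array(rnorm(16 * 16 * 1000, 100, 5), c(16, 16, 1000))
  expect_error(alternans_map(noise), "valid")
})

test_that("recording summary computes zone means and their ratio", {
  mk_map <- function(nam) {
    structure(list(nam = nam, signed = nam,
                   valid_mask = matrix(TRUE, nrow(nam), ncol(nam)),
                   condition = "control", bcl = 100),
              class = "alternans_map")
  }
  bz <- matrix(FALSE, 4, 4); bz[, 1:2] <- TRUE
  nam <- matrix(0.1, 4, 4); nam[bz] <- 0.3
  s <- summarize_recording(mk_map(nam), bz_mask = bz)
  expect_equal(s$bz_nz_ratio, 3)
  expect_equal(s$mean_nam_bz, 0.3)
  # identical zones: the ratio reference line
  s1 <- summarize_recording(mk_map(matrix(0.2, 4, 4)), bz_mask = bz)
  expect_equal(s1$bz_nz_ratio, 1)
  # degenerate: no alternans in the non-infarcted zone
  zero_nz <- matrix(0, 4, 4); zero_nz[bz] <- 0.2
  expect_error(summarize_recording(mk_map(zero_nz), bz_mask = bz),
               "ratio")
  # empty zone
  expect_error(summarize_recording(mk_map(nam),
                                   bz_mask = matrix(TRUE, 4, 4)), "zone")
})

test_that("repeat averaging is an element-wise mean with label checking", {
  mk <- function(x, cond = "control", bcl = 100) {
    structure(list(mean_nam_total = x, mean_nam_bz = 2 * x,
                   mean_nam_nz = x, bz_nz_ratio = 2, catd90_bz = 70,
                   catd90_nz = 60, condition = cond, bcl = bcl),
              class = "recording_summary")
  }
  avg <- average_repeats(list(mk(0.1), mk(0.2), mk(0.3)))
  expect_equal(avg$mean_nam_total, 0.2)
  expect_equal(avg$mean_nam_bz, 0.4)
  # idempotence on identical repeats
  same <- average_repeats(list(mk(0.2), mk(0.2), mk(0.2)))
  expect_equal(same$mean_nam_total, 0.2)
  # two repeats: mean of available, with a warning
  expect_warning(two <- average_repeats(list(mk(0.1), mk(0.3))), "2")
  expect_equal(two$mean_nam_total, 0.2)
  expect_error(average_repeats(list(mk(0.1), mk(0.2, cond = "NE"))),
               "share")
})

test_that("nodal line extraction interpolates zero crossings and applies the floor", {
  signed <- matrix(rep(seq(-0.3, 0.3, length.out = 8), each = 8), 8, 8)
  nl <- extract_nodal_lines(signed)
  expect_gt(nrow(nl), 0)
  expect_true(all(abs(nl$col - 4.5) < 0.6))
  # a sign flip deep inside a no-alternans region is suppressed
  quiet <- matrix(c(-0.01, 0.01), 8, 8)
  expect_equal(nrow(extract_nodal_lines(quiet)), 0)
})

test_that("regression on collinear pairs is exact and errors are caught", {
  catd <- c(60, 80, 100, 120)
  # suppress R's note about an essentially perfect fit
  ct <- suppressWarnings(correlate_catd_nam(catd, 0.001 * catd + 0.05))
  expect_equal(ct$r_squared, 1, tolerance = 1e-12)
  expect_equal(ct$slope, 0.001, tolerance = 1e-12)
  expect_error(correlate_catd_nam(c(60, 80), c(0.1, 0.2)), "3 pairs")
  expect_error(correlate_catd_nam(rep(60, 5), runif(5)), "variance")
})

test_that("shuffled pairs give the null R-squared expectation", {
  # permutation oracle: for independent pairs E[R^2] = 1/(n-1)
  set.seed(7)
  pairs <- synthesize_catd_nam_pairs(24, slope = 0.004, seed = 21)
  r2 <- replicate(300, {
    correlate_catd_nam(pairs$catd90_ms, sample(pairs$nam))$r_squared
  })
  expect_equal(mean(r2), 1 / (24 - 1), tolerance = 0.35)
})

test_that("pixel table flattens the map with zone labels", {
  cfg <- test_config()
  sm <- synthesize_movie(cfg, make_uniform_field(c(16, 16), 0.2,
                                                 bz_mask = default_bz_mask(c(16, 16))),
                         test_template(), bcl = 100, voltage = FALSE)
  map <- alternans_map(sm$movie)
  px <- pixel_table(map, catd_map(sm$movie), sm$movie$bz_mask)
  expect_equal(nrow(px), 256)
  expect_setequal(unique(px$zone), c("BZ", "NZ"))
  expect_true(all(c("row", "col", "zone", "nam", "signed", "catd90_ms",
                    "valid") %in% names(px)))
})
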