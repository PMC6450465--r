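#' Synthetic alternans-mapping protocol configuration
#'
#' Acquisition parameters of the synthetic dual-channel movies, mirroring an
#' epicardial alternans-mapping protocol: the heart is paced for
#' `paced_duration_per_bcl` seconds at each basic cycle length of `bcl_list`
#' (a ladder from 140 down to 80 ms) and the last `recorded_duration` second
#' is recorded on a `grid` of pixels at `frame_rate`.
#'
#' @param bcl_list basic cycle lengths, ms.
#' @param paced_duration_per_bcl pacing duration per cycle length, s.
#' @param recorded_duration recorded duration (the end of each pacing
#'   epoch), s.
#' @param frame_rate acquisition rate, Hz.
#' @param grid two-element integer vector `(rows, cols)`.
#' @param fov field of view, mm.
#' @param noise_sd additive Gaussian noise SD as a fraction of the mean beat
#'   amplitude.
#' @param seed integer seed for the noise generator.
#' @return An object of class `synth_protocol_config`.
#' @export
synth_protocol_config <- function(bcl_list = c(140, 130, 120, 110, 100, 95,
                                               90, 85, 80),
                                  paced_duration_per_bcl = 10,
                                  recorded_duration = 1, frame_rate = 1000,
                                  grid = c(32, 32), fov = c(7, 7),
                                  noise_sd = 0.05, seed = 1L) {
  if (recorded_duration > paced_duration_per_bcl) {
    stop("recorded_duration cannot exceed paced_duration_per_bcl")
  }
  n_frames <- frame_rate * recorded_duration
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    stop("frame_rate x recorded_duration must be an integer frame count")
  }
  if (any(grid <= 0) || any(fov <= 0)) stop("grid and fov must be positive")
  structure(list(bcl_list = bcl_list,
                 paced_duration_per_bcl = paced_duration_per_bcl,
                 recorded_duration = recorded_duration,
                 frame_rate = frame_rate, grid = as.integer(grid),
                 fov = fov, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_protocol_config")
}

#' @export
print.synth_protocol_config <- function(x, ...) {
  cat(sprintf(
    "<synth_protocol_config> %dx%d @ %g Hz, %g s recorded, bcl ladder %s ms, noise %g%%\n",
    x$grid[1], x$grid[2], x$frame_rate, x$recorded_duration,
    paste(x$bcl_list, collapse = ","), 100 * x$noise_sd))
  invisible(x)
}

# Evaluate with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  force(expr)
}

#' Synthesize one dual-channel mapping movie
#'
#' Generates the recorded second of a pacing epoch on each pixel of the grid.
#' Per pixel, even-indexed beats (counted from the first recorded stimulus)
#' have calcium amplitude `a (1 + s)` and odd-indexed beats `a (1 - s)`,
#' where `s` is the pixel's signed alternans magnitude, so the true
#' normalized alternans magnitude is exactly `|s|`. Border-zone pixels use a
#' longer calcium decay (factor `bz_catd_factor`), emulating the prolonged
#' calcium transient duration of border-zone tissue. An optional voltage
#' channel carries square-wave-like action potentials whose duration
#' alternates in phase with the calcium amplitude. Zero-mean Gaussian noise
#' (SD = `config$noise_sd` times the amplitude) is added per pixel and frame
#' under the configured seed.
#'
#' @param config a [synth_protocol_config()].
#' @param field an [alternans_field()] whose grid matches the config.
#' @param template a [transient_template()] for the calcium channel.
#' @param bcl basic cycle length of this movie, ms.
#' @param condition condition label (`"control"`, `"NE"`, `"NE+Meto"`).
#' @param bz_catd_factor multiplier on `decay_tau` for border-zone pixels.
#' @param voltage generate the companion voltage channel?
#' @param apd0 voltage-channel action potential duration at zero alternans,
#'   ms (default: half the cycle length, capped at 60 ms).
#' @param seed noise seed; defaults to the config seed.
#' @return A list with `movie` (a `mapping_movie`) and `truth` (the
#'   ground-truth record: signed field, per-pixel true calcium transient
#'   duration at 90% recovery, template and parity convention).
#' @export
synthesize_movie <- function(config, field, template = transient_template(),
                             bcl, condition = "control",
                             bz_catd_factor = 1.25, voltage = TRUE,
                             apd0 = min(60, bcl / 2), seed = config$seed) {
  stopifnot(inherits(config, "synth_protocol_config"),
            inherits(field, "alternans_field"),
            inherits(template, "transient_template"))
  if (!all(dim(field$signed) == config$grid)) {
    stop("field grid does not match config grid")
  }
  if (any(abs(field$signed) > 1)) stop("|signed magnitude| > 1")
  total_ms <- config$recorded_duration * 1000
  dt <- 1000 / config$frame_rate
  t <- seq(0, total_ms - 1e-9, by = dt)
  n_t <- length(t)
  nr <- config$grid[1]; nc <- config$grid[2]

  # stimulus times in the recorded window: pacing started
  # paced_duration_per_bcl - recorded_duration seconds before recording
  pre_ms <- (config$paced_duration_per_bcl - config$recorded_duration) * 1000
  offset <- (bcl - pre_ms %% bcl) %% bcl
  n_beats <- floor((total_ms - offset - 1e-6) / bcl) + 1
  pacing_times <- offset + bcl * (seq_len(n_beats) - 1)

  # per-beat unit waveforms, NZ and BZ transient shapes
  tpl_bz <- template
  tpl_bz$decay_tau <- template$decay_tau * bz_catd_factor
  shape_nz <- matrix(0, n_t, n_beats)
  shape_bz <- matrix(0, n_t, n_beats)
  for (k in seq_len(n_beats)) {
    tk <- t - pacing_times[k]
    # each beat occupies its own pacing interval
    win <- tk >= 0 & tk < bcl
    shape_nz[win, k] <- .transient_shape(template, tk[win])
    shape_bz[win, k] <- .transient_shape(tpl_bz, tk[win])
  }
  parity <- rep_len(c(1, -1), n_beats)  # +1 on even-indexed beats (0, 2, ..)

  amp <- template$amplitude
  s_vec <- as.vector(field$signed)                  # pixel-major
  bz_vec <- as.vector(field$bz_mask)
  # beat amplitudes per pixel x beat
  beat_amp <- amp * (1 + outer(s_vec, parity))       # n_px x n_beats
  ca <- matrix(template$baseline, nr * nc, n_t)
  ca[!bz_vec, ] <- ca[!bz_vec, , drop = FALSE] +
    beat_amp[!bz_vec, , drop = FALSE] %*% t(shape_nz)
  if (any(bz_vec)) {
    ca[bz_vec, ] <- ca[bz_vec, , drop = FALSE] +
      beat_amp[bz_vec, , drop = FALSE] %*% t(shape_bz)
  }

  vm <- NULL
  if (voltage) {
    # square-ish AP: 2 ms rise, sigmoidal repolarization shoulder at the
    # alternating duration apd0 * (1 + s * parity)
    vm <- matrix(template$baseline, nr * nc, n_t)
    for (k in seq_len(n_beats)) {
      tk <- t - pacing_times[k]
      win <- which(tk >= 0 & tk < bcl)
      tkw <- tk[win]
      apd_px <- apd0 * (1 + s_vec * parity[k])       # n_px
      rise <- pmin(tkw / 2, 1)
      # outer over pixels x window samples
      rep_m <- 1 / (1 + exp(outer(-apd_px, tkw, "+") / 3))
      vm[, win] <- vm[, win] + amp * rep_m *
        matrix(rise, nr * nc, length(win), byrow = TRUE)
    }
  }

  if (config$noise_sd > 0) {
    .with_seed(seed, {
      ca <- ca + matrix(rnorm(length(ca), 0, config$noise_sd * amp),
                        nrow(ca))
      if (!is.null(vm)) {
        vm <- vm + matrix(rnorm(length(vm), 0, config$noise_sd * amp),
                          nrow(vm))
      }
    })
  }

  to_stack <- function(m) {
    a <- array(0, c(nr, nc, n_t))
    a[] <- m  # pixel-major rows fill (row, col) in column-major order
    a
  }
  movie <- structure(list(
    calcium = to_stack(ca),
    voltage = if (is.null(vm)) NULL else to_stack(vm),
    frame_rate = config$frame_rate, pacing_times = pacing_times,
    bcl = bcl, condition = condition, bz_mask = field$bz_mask,
    fov = config$fov), class = "mapping_movie")
  catd_true <- matrix(template$time_to_peak +
                        template$decay_tau * log(10), nr, nc)
  catd_true[field$bz_mask] <- tpl_bz$time_to_peak +
    tpl_bz$decay_tau * log(10)
  truth <- list(signed = field$signed, nam = abs(field$signed),
                catd90_ms = catd_true,
                nodal_geometry = field$nodal_geometry,
                parity = "even beats (0-based, from first recorded stimulus) carry amplitude a(1+s)",
                template = template, bz_catd_factor = bz_catd_factor,
                apd0 = apd0, seed = seed)
  list(movie = movie, truth = truth)
}

#' @export
print.mapping_movie <- function(x, ...) {
  d <- dim(x$calcium)
  cat(sprintf(
    "<mapping_movie> %dx%d px, %d frames @ %g Hz, bcl %g ms, %s%s, %d beats\n",
    d[1], d[2], d[3], x$frame_rate, x$bcl, x$condition,
    if (is.null(x$voltage)) " (calcium only)" else " (dual channel)",
    length(x$pacing_times)))
  invisible(x)
}

#' Synthesize a full mapping protocol
#'
#' Generates movies for every basic cycle length of the protocol ladder and
#' `n_repeats` repeats per condition, emulating the experimental design of
#' repeated alternans-mapping episodes under control, norepinephrine and
#' norepinephrine + metoprolol conditions. Condition effects are applied as
#' multiplicative factors on the alternans field and on the calcium decay
#' time (beta-adrenergic stimulation attenuates alternans and shortens the
#' calcium transient; adding the beta-blocker restores both).
#'
#' @param config a [synth_protocol_config()].
#' @param field baseline [alternans_field()].
#' @param template a [transient_template()].
#' @param conditions character vector of condition labels to generate.
#' @param condition_alternans named multipliers on the signed field.
#' @param condition_catd named multipliers on `decay_tau`.
#' @param n_repeats repeats per condition and bcl.
#' @param rate_scale function mapping bcl to a multiplier on the field
#'   (alternans grows as bcl shortens); the default leaves 140-120 ms nearly
#'   alternans-free and saturates by 80 ms.
#' @param ... passed to [synthesize_movie()].
#' @return A nested list `out[[condition]][[as.character(bcl)]][[repeat]]`,
#'   each element as returned by [synthesize_movie()].
#' @export
synthesize_protocol <- function(config, field, template = transient_template(),
                                conditions = c("control", "NE", "NE+Meto"),
                                condition_alternans = c(control = 1, NE = 0.4,
                                                        `NE+Meto` = 1),
                                condition_catd = c(control = 1, NE = 0.85,
                                                   `NE+Meto` = 1),
                                n_repeats = 3,
                                rate_scale = function(bcl) {
                                  stats::plogis((115 - bcl) / 8)
                                },
                                ...) {
  stopifnot(inherits(config, "synth_protocol_config"))
  out <- list()
  run <- 0L
  for (cond in conditions) {
    ca <- condition_alternans[[cond]]
    cc <- condition_catd[[cond]]
    tpl <- template
    tpl$decay_tau <- template$decay_tau * cc
    out[[cond]] <- list()
    for (bcl in config$bcl_list) {
      reps <- vector("list", n_repeats)
      for (r in seq_len(n_repeats)) {
        run <- run + 1L
        f <- alternans_field(field$signed * ca * rate_scale(bcl),
                             bz_mask = field$bz_mask,
                             nodal_geometry = field$nodal_geometry)
        reps[[r]] <- synthesize_movie(config, f, tpl, bcl = bcl,
                                      condition = cond,
                                      seed = config$seed + run, ...)
      }
      out[[cond]][[as.character(bcl)]] <- reps
    }
  }
  out
}

#' Synthetic hearts with a programmed calcium-duration/alternans link
#'
#' Draws per-heart calcium transient durations (CaTD90 at slow pacing) and
#' generates the matched fast-pacing alternans magnitude through a linear
#' relationship plus Gaussian noise — the construction used to validate the
#' CaTD90-to-alternans regression.
#'
#' @param n number of heart-condition pairs.
#' @param slope,intercept programmed linear relationship (NAM per ms).
#' @param catd_range range of CaTD90 values to draw from, ms.
#' @param noise_sd SD of the noise added to NAM.
#' @param seed integer seed.
#' @return data.frame with columns `catd90_ms` and `nam`.
#' @export
synthesize_catd_nam_pairs <- function(n = 24, slope = 0.004,
                                      intercept = -0.15,
                                      catd_range = c(60, 120),
                                      noise_sd = 0.02, seed = 1L) {
  if (n < 3) stop("need at least 3 pairs")
  .with_seed(seed, {
    catd <- runif(n, catd_range[1], catd_range[2])
    nam <- pmin(1, pmax(0, intercept + slope * catd + rnorm(n, 0, noise_sd)))
    data.frame(catd90_ms = catd, nam = nam)
  })
}
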