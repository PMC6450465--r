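#' Segment a fluorescence trace into beats
#'
#' Splits a single-pixel time series into one window per pacing interval,
#' aligned to the stimulus onsets. The final window is kept only when the
#' full pacing interval fits inside the recording (the last partial beat is
#' dropped).
#'
#' @param trace numeric vector of fluorescence samples.
#' @param pacing_times stimulus onsets, ms (within the recording).
#' @param frame_rate sampling rate, Hz.
#' @return A list of integer sample-index vectors, one per complete beat,
#'   with attribute `pacing_times` giving the matching onsets.
#' @export
segment_beats <- function(trace, pacing_times, frame_rate = 1000) {
  if (length(pacing_times) < 2) {
    stop("insufficient data: need at least 2 pacing times in the recording")
  }
  dt <- 1000 / frame_rate
  total_ms <- length(trace) * dt
  spacing <- diff(pacing_times)
  bounds <- c(pacing_times, pacing_times[length(pacing_times)] +
                stats::median(spacing))
  windows <- list()
  kept <- numeric(0)
  for (k in seq_along(pacing_times)) {
    if (bounds[k + 1] > total_ms + 1e-9) break  # partial beat: drop
    idx <- which(seq_along(trace) * dt - dt >= bounds[k] - 1e-9 &
                   seq_along(trace) * dt - dt < bounds[k + 1] - 1e-9)
    if (!length(idx)) break
    windows[[length(windows) + 1]] <- idx
    kept <- c(kept, pacing_times[k])
  }
  if (length(windows) < 2) {
    stop("insufficient data: fewer than 2 complete beats in the recording")
  }
  attr(windows, "pacing_times") <- kept
  windows
}

#' Amplitude of one beat
#'
#' Peak fluorescence minus the pre-upstroke baseline. The baseline is the
#' minimum over the `baseline_ms` preceding the stimulus onset (robust to
#' slow drift); when no pre-stimulus samples are available the first sample
#' of the window is used.
#'
#' @param window numeric vector, the beat's samples (starting at the
#'   stimulus onset).
#' @param pre_window numeric vector of samples preceding the stimulus
#'   (optional).
#' @return Amplitude in the units of the trace (0 for a flat window).
#' @export
beat_amplitude <- function(window, pre_window = NULL) {
  if (!length(window)) stop("empty beat window")
  baseline <- if (length(pre_window)) min(pre_window) else window[1]
  max(window) - baseline
}

# Per-beat amplitudes of a full trace given its beat windows.
.trace_amplitudes <- function(trace, windows, frame_rate = 1000,
                              baseline_ms = 10) {
  n_pre <- max(1, round(baseline_ms * frame_rate / 1000))
  vapply(windows, function(idx) {
    pre <- trace[max(1, idx[1] - n_pre):max(1, idx[1] - 1)]
    if (idx[1] == 1) pre <- trace[1]
    beat_amplitude(trace[idx], pre)
  }, numeric(1))
}

#' Normalized alternans magnitude of one pixel
#'
#' The alternans statistic `|A - B| / (A + B)`, where `A` is the mean
#' amplitude of even-indexed beats and `B` of odd-indexed beats (0-based,
#' anchored to the first recorded stimulus). With an odd number of beats the
#' last beat is dropped so both series have equal length. The signed variant
#' `(A - B) / (A + B)` carries the alternans phase relative to even beats.
#' The statistic is independent of multiplicative gain and, because
#' amplitudes are baseline-subtracted, of additive offset.
#'
#' @param amplitudes numeric vector of per-beat amplitudes (or durations for
#'   the duration-alternans variant).
#' @return Named vector `c(nam, signed)`; both `NA` when `A + B` is not
#'   positive (pixel undefined, to be masked invalid).
#' @export
nam_pixel <- function(amplitudes) {
  if (length(amplitudes) < 2) stop("need at least 2 beats")
  n <- length(amplitudes)
  if (n %% 2 == 1) amplitudes <- amplitudes[-n]
  a <- mean(amplitudes[seq(1, length(amplitudes), by = 2)])
  b <- mean(amplitudes[seq(2, length(amplitudes), by = 2)])
  if (!is.finite(a + b) || a + b <= 0) {
    return(c(nam = NA_real_, signed = NA_real_))
  }
  signed <- (a - b) / (a + b)
  c(nam = abs(signed), signed = signed)
}

#' Duration (APD/CaTD) alternans of one pixel
#'
#' The alternans statistic applied to per-beat durations instead of
#' amplitudes: `A` and `B` are the mean durations of even- and odd-indexed
#' beats.
#'
#' @param durations numeric vector of per-beat durations, ms.
#' @return Named vector `c(nam, signed)` as in [nam_pixel()].
#' @export
apd_alternans_pixel <- function(durations) nam_pixel(durations)

#' Transient duration at a recovery level
#'
#' Duration from the transient onset (the stimulus time, i.e. the start of
#' the window) to the time the trace has recovered `recovery_level` of the
#' way from peak back to baseline, with linear interpolation between samples.
#' `recovery_level = 0.9` gives CaTD90 (or APD90 on a voltage trace);
#' `recovery_level = 0` gives the time of the peak.
#'
#' @param window numeric vector, the beat's samples starting at the stimulus.
#' @param recovery_level fraction of the peak-to-baseline drop, in `[0, 1]`.
#' @param frame_rate sampling rate, Hz.
#' @param baseline baseline fluorescence; defaults to the first sample.
#' @return Duration in ms, or `NA` with attribute `censored = TRUE` when the
#'   trace does not recover to the level within the window.
#' @export
transient_duration <- function(window, recovery_level = 0.9,
                               frame_rate = 1000, baseline = window[1]) {
  if (!length(window)) stop("empty beat window")
  if (recovery_level < 0 || recovery_level > 1) {
    stop("recovery_level must be in [0, 1]")
  }
  dt <- 1000 / frame_rate
  ipk <- which.max(window)
  peak <- window[ipk]
  if (peak <= baseline) stop("window contains no peak above baseline")
  if (recovery_level == 0) return((ipk - 1) * dt)
  level <- peak - recovery_level * (peak - baseline)
  v <- window
  dn <- which(v[-1] <= level & v[-length(v)] > level)
  dn <- dn[dn >= ipk]
  if (!length(dn)) {
    return(structure(NA_real_, censored = TRUE))
  }
  j <- dn[1]
  frac <- (v[j] - level) / (v[j] - v[j + 1])
  ((j - 1) + frac) * dt
}

# --- preprocessing -------------------------------------------------------

# 3x3 (or k x k) spatial mean filter per frame, replicate padding.
.spatial_mean <- function(stack, k = 3) {
  if (k <= 1) return(stack)
  d <- dim(stack)
  pad <- (k - 1) %/% 2
  ri <- pmin(pmax(seq_len(d[1] + 2 * pad) - pad, 1), d[1])
  ci <- pmin(pmax(seq_len(d[2] + 2 * pad) - pad, 1), d[2])
  padded <- stack[ri, ci, , drop = FALSE]
  out <- array(0, d)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out <- out + padded[i:(i + d[1] - 1), j:(j + d[2] - 1), , drop = FALSE]
    }
  }
  out / (k * k)
}

# temporal moving average over w frames (centered, replicate ends)
.temporal_mean <- function(stack, w = 3) {
  if (w <= 1) return(stack)
  d <- dim(stack)
  half <- (w - 1) %/% 2
  ti <- pmin(pmax(seq_len(d[3] + 2 * half) - half, 1), d[3])
  padded <- stack[, , ti, drop = FALSE]
  out <- array(0, d)
  for (i in seq_len(w)) {
    out <- out + padded[, , i:(i + d[3] - 1), drop = FALSE]
  }
  out / w
}

# per-pixel linear detrend (least squares on time); returns stack plus the
# removed trend's mean level so absolute units are preserved
.detrend <- function(stack) {
  d <- dim(stack)
  n <- d[3]
  tt <- seq_len(n) - (n + 1) / 2           # centered time
  m <- matrix(stack, d[1] * d[2], n)
  slope <- (m %*% tt) / sum(tt * tt)
  m <- m - slope %*% t(tt)
  array(m, d)
}

# robust per-pixel noise SD from first differences (transient slopes are
# sparse in time, so the median absolute first difference tracks the noise)
.noise_sd_map <- function(stack) {
  d <- dim(stack)
  m <- matrix(stack, d[1] * d[2], d[3])
  dm <- abs(m[, -1, drop = FALSE] - m[, -d[3], drop = FALSE])
  matrix(apply(dm, 1, stats::median) * 1.4826 / sqrt(2), d[1], d[2])
}

#' Nodal lines of a signed alternans map
#'
#' Zero-level points of the signed alternans field: for every pair of
#' 4-adjacent valid pixels with opposite sign, the zero crossing is located
#' by linear interpolation along the edge. An edge qualifies only when some
#' pixel in the 3x3 neighborhood of either endpoint has alternans magnitude
#' of at least `nam_floor`: a true nodal line separates regions that do
#' alternate, while in regions of no alternans sign flips are noise and the
#' floor suppresses spurious contours there.
#'
#' @param signed numeric matrix of signed alternans (NA on invalid pixels).
#' @param valid logical matrix of valid pixels.
#' @param nam_floor minimum alternans magnitude next to a crossing.
#' @return data.frame with sub-pixel `row`, `col` coordinates of the
#'   crossing points (0 rows when there is no nodal line).
#' @export
extract_nodal_lines <- function(signed, valid = is.finite(signed),
                                nam_floor = 0.05) {
  nr <- nrow(signed); nc <- ncol(signed)
  pts <- list()
  # 3x3 dilation of the |signed| >= floor region
  hot <- is.finite(signed) & abs(signed) >= nam_floor
  near <- hot
  if (nr > 1) {
    near[-1, ] <- near[-1, ] | hot[-nr, ]
    near[-nr, ] <- near[-nr, ] | hot[-1, ]
  }
  if (nc > 1) {
    h2 <- near
    near[, -1] <- near[, -1] | h2[, -nc]
    near[, -nc] <- near[, -nc] | h2[, -1]
  }
  cross <- function(s1, s2) is.finite(s1) & is.finite(s2) & (s1 * s2 < 0)
  # horizontal edges
  s1 <- signed[, -nc, drop = FALSE]; s2 <- signed[, -1, drop = FALSE]
  ok <- cross(s1, s2) & valid[, -nc, drop = FALSE] & valid[, -1, drop = FALSE] &
    (near[, -nc, drop = FALSE] | near[, -1, drop = FALSE])
  if (any(ok)) {
    idx <- which(ok, arr.ind = TRUE)
    f <- s1[ok] / (s1[ok] - s2[ok])
    pts[[length(pts) + 1]] <- data.frame(row = idx[, 1],
                                         col = idx[, 2] + f)
  }
  # vertical edges
  s1 <- signed[-nr, , drop = FALSE]; s2 <- signed[-1, , drop = FALSE]
  ok <- cross(s1, s2) & valid[-nr, , drop = FALSE] & valid[-1, , drop = FALSE] &
    (near[-nr, , drop = FALSE] | near[-1, , drop = FALSE])
  if (any(ok)) {
    idx <- which(ok, arr.ind = TRUE)
    f <- s1[ok] / (s1[ok] - s2[ok])
    pts[[length(pts) + 1]] <- data.frame(row = idx[, 1] + f,
                                         col = idx[, 2])
  }
  if (!length(pts)) {
    return(data.frame(row = numeric(0), col = numeric(0)))
  }
  do.call(rbind, pts)
}

#' Per-pixel alternans map of a mapping movie
#'
#' The full image-processing pipeline: preprocessing (per-pixel linear
#' detrend, spatial mean filter, temporal smoothing — all configurable),
#' beat segmentation on the recorded pacing times, per-beat amplitude
#' measurement (peak minus pre-stimulus baseline), the normalized alternans
#' magnitude per pixel, an SNR validity mask (mean beat amplitude must
#' exceed `valid_k` times the per-pixel noise SD estimate; weak-signal
#' pixels such as scar are masked), and nodal-line extraction on the signed
#' map.
#'
#' @param movie a `mapping_movie` (see [synthesize_movie()]).
#' @param channel `"calcium"` or `"voltage"`.
#' @param spatial_k spatial mean-filter kernel size (pixels; 1 disables).
#' @param temporal_w temporal moving-average length (frames; 1 disables).
#' @param detrend apply per-pixel linear detrending?
#' @param valid_k SNR factor of the validity rule.
#' @param nam_floor nodal-line alternans floor (see
#'   [extract_nodal_lines()]).
#' @param baseline_ms pre-stimulus window for the amplitude baseline, ms.
#' @return An object of class `alternans_map`: matrices `nam`, `signed`
#'   (NA on invalid pixels), `valid_mask`, `mean_amplitude`, `noise_sd`,
#'   the `nodal_lines` data.frame and the per-pixel beat amplitude matrix
#'   (`amplitudes`, pixels x beats) used upstream.
#' @export
alternans_map <- function(movie, channel = c("calcium", "voltage"),
                          spatial_k = 3, temporal_w = 3, detrend = TRUE,
                          valid_k = 5, nam_floor = 0.05, baseline_ms = 10) {
  stopifnot(inherits(movie, "mapping_movie"))
  channel <- match.arg(channel)
  stack <- movie[[channel]]
  if (is.null(stack)) stop(sprintf("movie has no %s channel", channel))
  d <- dim(stack)
  noise <- .noise_sd_map(stack)
  if (detrend) stack <- .detrend(stack)
  stack <- .spatial_mean(stack, spatial_k)
  stack <- .temporal_mean(stack, temporal_w)

  windows <- segment_beats(stack[1, 1, ], movie$pacing_times,
                           movie$frame_rate)
  nr <- d[1]; nc <- d[2]
  m <- matrix(stack, nr * nc, d[3])
  n_pre <- max(1, round(baseline_ms * movie$frame_rate / 1000))
  # a beat enters the alternans statistic only with a full pre-stimulus
  # baseline window; a first beat starting at (or within baseline_ms of)
  # the recording onset is measured against smoothed upstroke samples and
  # would bias the parity means
  windows <- Filter(function(idx) idx[1] > n_pre, windows)
  n_beats <- length(windows)
  if (n_beats < 2) stop("insufficient data: fewer than 2 measurable beats")
  amps <- matrix(NA_real_, nr * nc, n_beats)
  for (k in seq_len(n_beats)) {
    idx <- windows[[k]]
    pre_idx <- (idx[1] - n_pre):(idx[1] - 1)
    base <- apply(m[, pre_idx, drop = FALSE], 1, min)
    amps[, k] <- apply(m[, idx, drop = FALSE], 1, max) - base
  }
  res <- t(apply(amps, 1, nam_pixel))
  nam <- matrix(res[, 1], nr, nc)
  signed <- matrix(res[, 2], nr, nc)
  mean_amp <- matrix(rowMeans(amps), nr, nc)
  valid <- is.finite(nam) & (mean_amp > valid_k * noise)
  if (!any(valid)) stop("empty map: all pixels fail the validity rule")
  nam[!valid] <- NA
  signed[!valid] <- NA
  structure(list(nam = nam, signed = signed, valid_mask = valid,
                 mean_amplitude = mean_amp, noise_sd = noise,
                 nodal_lines = extract_nodal_lines(signed, valid, nam_floor),
                 amplitudes = amps, n_beats = n_beats,
                 channel = channel, bcl = movie$bcl,
                 condition = movie$condition),
            class = "alternans_map")
}

#' @export
print.alternans_map <- function(x, ...) {
  cat(sprintf(
    "<alternans_map> %dx%d (%s, bcl %g ms), %d/%d valid px, mean NAM %.3f, %d nodal points\n",
    nrow(x$nam), ncol(x$nam), x$condition, x$bcl, sum(x$valid_mask),
    length(x$nam), mean(x$nam[x$valid_mask]), nrow(x$nodal_lines)))
  invisible(x)
}

#' Per-pixel transient-duration map
#'
#' Mean CaTD (or APD) at the given recovery level across the recorded beats
#' of every pixel, after the same preprocessing as [alternans_map()].
#' Right-censored beats (no recovery within the window) are excluded;
#' pixels with no measurable beat are NA.
#'
#' @inheritParams alternans_map
#' @param recovery_level recovery fraction (0.9 for CaTD90).
#' @return Numeric matrix of durations, ms.
#' @export
catd_map <- function(movie, channel = c("calcium", "voltage"),
                     recovery_level = 0.9, spatial_k = 3, temporal_w = 3,
                     detrend = TRUE) {
  stopifnot(inherits(movie, "mapping_movie"))
  channel <- match.arg(channel)
  stack <- movie[[channel]]
  if (is.null(stack)) stop(sprintf("movie has no %s channel", channel))
  d <- dim(stack)
  if (detrend) stack <- .detrend(stack)
  stack <- .spatial_mean(stack, spatial_k)
  stack <- .temporal_mean(stack, temporal_w)
  windows <- segment_beats(stack[1, 1, ], movie$pacing_times,
                           movie$frame_rate)
  m <- matrix(stack, d[1] * d[2], d[3])
  out <- matrix(NA_real_, d[1], d[2])
  for (p in seq_len(nrow(m))) {
    ds <- vapply(windows, function(idx) {
      w <- m[p, idx]
      if (max(w) <= w[1]) return(NA_real_)
      as.numeric(transient_duration(w, recovery_level, movie$frame_rate))
    }, numeric(1))
    if (any(is.finite(ds))) out[p] <- mean(ds[is.finite(ds)])
  }
  out
}

#' Summarize one recording
#'
#' Zone-wise summary of an alternans map: mean normalized alternans
#' magnitude over all valid pixels, over border-zone and non-infarcted-zone
#' pixels, their ratio (the border-zone vulnerability statistic; 1 means
#' both zones alternate equally), and zone-mean transient durations.
#'
#' @param map an [alternans_map()].
#' @param catd matrix of per-pixel transient durations (optional).
#' @param bz_mask logical matrix of border-zone pixels.
#' @return An object of class `recording_summary` with fields
#'   `mean_nam_total`, `mean_nam_bz`, `mean_nam_nz`, `bz_nz_ratio`,
#'   `catd90_bz`, `catd90_nz`, plus the condition/bcl labels.
#' @export
summarize_recording <- function(map, catd = NULL, bz_mask) {
  stopifnot(inherits(map, "alternans_map"))
  valid <- map$valid_mask
  bz <- bz_mask & valid
  nz <- !bz_mask & valid
  if (!any(bz) || !any(nz)) {
    stop("empty zone: need at least one valid pixel in each zone")
  }
  mean_bz <- mean(map$nam[bz])
  mean_nz <- mean(map$nam[nz])
  if (mean_nz <= 0) stop("undefined ratio: non-infarcted zone mean is zero")
  structure(list(
    mean_nam_total = mean(map$nam[valid]),
    mean_nam_bz = mean_bz, mean_nam_nz = mean_nz,
    bz_nz_ratio = mean_bz / mean_nz,
    catd90_bz = if (is.null(catd)) NA_real_ else
      mean(catd[bz][is.finite(catd[bz])]),
    catd90_nz = if (is.null(catd)) NA_real_ else
      mean(catd[nz][is.finite(catd[nz])]),
    condition = map$condition, bcl = map$bcl),
    class = "recording_summary")
}

#' @export
print.recording_summary <- function(x, ...) {
  cat(sprintf(
    "<recording_summary> %s bcl %g ms: NAM total %.3f (BZ %.3f / NZ %.3f, ratio %.2f); CaTD90 BZ %.1f / NZ %.1f ms\n",
    x$condition, x$bcl, x$mean_nam_total, x$mean_nam_bz, x$mean_nam_nz,
    x$bz_nz_ratio, x$catd90_bz, x$catd90_nz))
  invisible(x)
}

#' Average repeated recordings
#'
#' Element-wise arithmetic mean of repeat summaries taken under the same
#' condition and basic cycle length (the protocol takes three repeats per
#' condition; the final score is their average). With fewer repeats than
#' `expected` the mean of the available ones is returned with a warning.
#'
#' @param summaries list of `recording_summary` objects.
#' @param expected expected number of repeats.
#' @return A `recording_summary` of the means.
#' @export
average_repeats <- function(summaries, expected = 3) {
  stopifnot(length(summaries) >= 1,
            all(vapply(summaries, inherits, logical(1), "recording_summary")))
  conds <- vapply(summaries, `[[`, character(1), "condition")
  bcls <- vapply(summaries, `[[`, numeric(1), "bcl")
  if (length(unique(conds)) != 1 || length(unique(bcls)) != 1) {
    stop("summaries must share one condition and one bcl")
  }
  if (length(summaries) < expected) {
    warning(sprintf("averaging %d repeats (expected %d)",
                    length(summaries), expected))
  }
  fields <- c("mean_nam_total", "mean_nam_bz", "mean_nam_nz", "bz_nz_ratio",
              "catd90_bz", "catd90_nz")
  out <- lapply(fields, function(f) {
    mean(vapply(summaries, `[[`, numeric(1), f))
  })
  names(out) <- fields
  structure(c(out, list(condition = conds[1], bcl = bcls[1])),
            class = "recording_summary")
}

#' Regression of alternans magnitude on calcium transient duration
#'
#' Ordinary least-squares regression of fast-pacing alternans magnitude on
#' slow-pacing CaTD90 across hearts and conditions, with the standard
#' two-sided t-test on the slope (the regression slope test) and the squared
#' correlation.
#'
#' @param catd90 numeric vector of CaTD90 values, ms (or a data.frame with
#'   columns `catd90_ms` and `nam`).
#' @param nam numeric vector of matched alternans magnitudes.
#' @return List with `slope` (NAM per ms), `slope_se`, `intercept`,
#'   `r_squared`, `p_value` and `n`.
#' @export
correlate_catd_nam <- function(catd90, nam = NULL) {
  if (is.data.frame(catd90)) {
    nam <- catd90$nam
    catd90 <- catd90$catd90_ms
  }
  ok <- is.finite(catd90) & is.finite(nam)
  catd90 <- catd90[ok]; nam <- nam[ok]
  if (length(catd90) < 3) stop("need at least 3 pairs")
  if (stats::sd(catd90) == 0) stop("undefined: predictor has zero variance")
  fit <- stats::lm(nam ~ catd90)
  sm <- summary(fit)
  co <- sm$coefficients
  list(slope = co["catd90", "Estimate"],
       slope_se = co["catd90", "Std. Error"],
       intercept = co["(Intercept)", "Estimate"],
       r_squared = sm$r.squared,
       p_value = co["catd90", "Pr(>|t|)"],
       n = length(catd90))
}

#' Per-pixel results table
#'
#' One row per pixel of the imaging grid with its zone, alternans measures,
#' transient duration and validity — the flat export of a recording.
#'
#' @param map an [alternans_map()].
#' @param catd optional matrix of per-pixel transient durations, ms.
#' @param bz_mask logical matrix of border-zone pixels.
#' @return data.frame with columns `row`, `col`, `zone`, `nam`, `signed`,
#'   `catd90_ms`, `valid`.
#' @export
pixel_table <- function(map, catd = NULL, bz_mask = NULL) {
  stopifnot(inherits(map, "alternans_map"))
  nr <- nrow(map$nam); nc <- ncol(map$nam)
  if (is.null(bz_mask)) bz_mask <- matrix(FALSE, nr, nc)
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  data.frame(grid,
             zone = ifelse(as.vector(bz_mask), "BZ", "NZ"),
             nam = as.vector(map$nam),
             signed = as.vector(map$signed),
             catd90_ms = if (is.null(catd)) NA_real_ else as.vector(catd),
             valid = as.vector(map$valid_mask))
}
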