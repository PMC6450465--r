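#' Configure a 1D myocardial fiber
#'
#' Builds the configuration for a monodomain cable of myocytes. The
#' composition is either a homogeneous non-infarcted fiber (`"NZ only"`) or a
#' fiber with a central border-zone segment flanked by non-infarcted tissue
#' (`"NZ-BZ-NZ"`). Beta-adrenergic stimulation, when present, applies to the
#' whole fiber (it models receptor agonist perfusion, not local innervation).
#'
#' @param n_cells number of cells in the cable.
#' @param composition `"NZ-BZ-NZ"` or `"NZ only"`.
#' @param bz_range two-element integer vector, first and last BZ cell
#'   (1-based), strictly inside the fiber; ignored for `"NZ only"`.
#' @param bcl S1 basic cycle length, ms.
#' @param n_prepace number of pre-pacing S1 beats.
#' @param bar_level beta-adrenergic stimulation level in `[0, 1]`.
#' @param diffusion voltage diffusion coefficient, cm^2/ms.
#' @param dx cell spacing, cm.
#' @param dt integration step, ms.
#' @param s1_segment integer vector of stimulated cells (1-based).
#' @param stim_amp,stim_dur stimulus strength (1/ms) and duration (ms).
#' @return An object of class `fiber_config`.
#' @export
fiber_config <- function(n_cells = 240,
                         composition = c("NZ-BZ-NZ", "NZ only"),
                         bz_range = NULL, bcl = 300, n_prepace = 500,
                         bar_level = 0, diffusion = 3.3e-3, dx = 0.0125,
                         dt = 0.02, s1_segment = 1:8, stim_amp = 0.8,
                         stim_dur = 2) {
  composition <- match.arg(composition)
  if (n_cells < 20) stop("n_cells too small for a fiber")
  if (diffusion <= 0 || dx <= 0 || dt <= 0) {
    stop("diffusion, dx and dt must be positive")
  }
  if (any(s1_segment < 1) || any(s1_segment > n_cells)) {
    stop("s1_segment out of bounds")
  }
  if (composition == "NZ-BZ-NZ") {
    if (is.null(bz_range)) {
      # default geometry: central third of the cable
      bz_range <- c(floor(n_cells / 3) + 1, floor(2 * n_cells / 3))
    }
    if (bz_range[1] <= 1 || bz_range[2] >= n_cells ||
        bz_range[1] >= bz_range[2]) {
      stop("bz_range must lie strictly inside the fiber")
    }
  } else {
    bz_range <- NULL
  }
  zones <- rep("NZ", n_cells)
  if (!is.null(bz_range)) zones[bz_range[1]:bz_range[2]] <- "BZ"
  structure(list(n_cells = n_cells, composition = composition,
                 bz_range = bz_range, zones = zones, bcl = bcl,
                 n_prepace = n_prepace, bar_level = bar_level,
                 diffusion = diffusion, dx = dx, dt = dt,
                 s1_segment = sort(s1_segment), stim_amp = stim_amp,
                 stim_dur = stim_dur),
            class = "fiber_config")
}

#' @export
print.fiber_config <- function(x, ...) {
  cat(sprintf(
    "<fiber_config> %d cells, %s%s, bcl=%g ms, %d pre-pace beats, bar=%.2f\n",
    x$n_cells, x$composition,
    if (!is.null(x$bz_range)) sprintf(" (BZ %d-%d)", x$bz_range[1],
                                      x$bz_range[2]) else "",
    x$bcl, x$n_prepace, x$bar_level))
  invisible(x)
}

# Per-cell parameter matrix for a fiber config.
.fiber_params <- function(config) {
  pn <- cell_params(phenotype("NZ", config$bar_level))
  pb <- cell_params(phenotype("BZ", config$bar_level))
  m <- matrix(rep(pn, each = config$n_cells), nrow = config$n_cells,
              dimnames = list(NULL, .par_names))
  bz <- config$zones == "BZ"
  if (any(bz)) m[bz, ] <- matrix(rep(pb, each = sum(bz)), nrow = sum(bz))
  m
}

.fiber_rest <- function(config) {
  st <- matrix(0, config$n_cells, 8)
  st[, 2] <- .h_init
  st[, 3] <- .nz_base[["c_base"]]
  st[, 4] <- .sr_init
  st[, 5] <- .sr_init
  st[, 7] <- .nz_base[["c_base"]]
  st[, 8] <- -1e6
  st
}

# stim matrix rows: t_on, dur, amp, cell_lo, cell_hi (0-based inclusive)
.seg_stim <- function(times, segment, amp, dur) {
  cbind(times, dur, amp, min(segment) - 1, max(segment) - 1)
}

# Build a fiber_recording object from an integrator result.
.fiber_recording <- function(run, config, s1_times, s2 = NULL) {
  ref_cell <- if (!is.null(config$bz_range)) {
    round(mean(config$bz_range))
  } else round(config$n_cells / 2)
  rec_s1 <- s1_times[s1_times >= run$times[1]]
  apd <- act <- NULL
  if (length(rec_s1)) {
    apd <- matrix(NA_real_, config$n_cells, length(rec_s1))
    act <- matrix(NA_real_, config$n_cells, length(rec_s1))
    for (i in seq_len(config$n_cells)) {
      m <- .measure_beats(run$times, run$vm[i, ], rec_s1)
      apd[i, ] <- m$apd90
      act[i, ] <- m$t_act
    }
  }
  structure(list(times = run$times, vm = run$vm, cai = run$cai,
                 final_state = run$state, config = config,
                 s1_times = s1_times, recorded_s1 = rec_s1,
                 apd90 = apd, activation = act, ref_cell = ref_cell,
                 s2 = s2),
            class = "fiber_recording")
}

#' @export
print.fiber_recording <- function(x, ...) {
  cat(sprintf(
    "<fiber_recording> %d cells x %d samples (%.0f-%.0f ms), %d recorded beats\n",
    nrow(x$vm), ncol(x$vm), min(x$times), max(x$times),
    length(x$recorded_s1)))
  invisible(x)
}

#' Pre-pace a fiber
#'
#' Integrates the cable under repeated S1 stimulation at the configured basic
#' cycle length, with no-flux boundaries, and returns the spatio-temporal
#' membrane potential record of the last `record_beats` beats together with
#' the final model state (the starting point for S2 protocols) and per-cell
#' APD90/activation annotations of the recorded beats.
#'
#' @param config a [fiber_config()].
#' @param record_beats number of final beats to record in full.
#' @param record_every trace sampling interval, ms.
#' @return An object of class `fiber_recording`.
#' @export
run_prepace <- function(config, record_beats = 2, record_every = 1) {
  stopifnot(inherits(config, "fiber_config"))
  par <- .fiber_params(config)
  s1_times <- (seq_len(config$n_prepace) - 1) * config$bcl
  stim <- .seg_stim(s1_times, config$s1_segment, config$stim_amp,
                    config$stim_dur)
  t_end <- config$n_prepace * config$bcl
  rec_start <- max(0, t_end - record_beats * config$bcl)
  run <- cpp_run_cable(par, .fiber_rest(config), 0, t_end, config$dt, stim,
                       config$diffusion, config$dx, rec_start, record_every)
  .fiber_recording(run, config, s1_times)
}

#' Deliver a premature S2 stimulus to a pre-paced fiber
#'
#' Resumes integration from the stored end-of-pre-pacing state, continues the
#' S1 rhythm for one or two more beats, and delivers a single S2 stimulus to
#' `s2_segment` at coupling interval `ci`, measured from the S1 stimulus time
#' of the beat the S2 follows. During alternans consecutive beats differ;
#' `after` selects whether the S2 follows the beat with the longer or the
#' shorter APD90 at the reference cell (the BZ center, or the fiber center
#' for a homogeneous fiber). One continuation beat is delivered when its
#' parity matches the request (alternation persists from the recorded final
#' beat pair), two otherwise.
#'
#' @param prepace a `fiber_recording` from [run_prepace()].
#' @param s2_segment integer vector of stimulated cells (1-based).
#' @param ci coupling interval from the preceding S1 stimulus, ms.
#' @param after `"last"`, `"long"` or `"short"`: which beat the S2 follows.
#' @param s2_amp,s2_dur S2 stimulus strength (1/ms) and duration (ms);
#'   premature stimuli are conventionally stronger than the S1 drive, so the
#'   default doubles the S1 amplitude.
#' @param tail_ms how long to integrate past the S2, ms; long enough for all
#'   wavefronts to resolve at the default.
#' @param record_every trace sampling interval, ms.
#' @return A `fiber_recording` covering the pre-S2 beat and the S2 response;
#'   its `s2` field holds the S2 time, segment and coupling interval.
#' @export
apply_s2 <- function(prepace, s2_segment, ci, after = c("last", "long",
                                                        "short"),
                     s2_amp = 1.75 * prepace$config$stim_amp,
                     s2_dur = prepace$config$stim_dur,
                     tail_ms = 500, record_every = 1) {
  stopifnot(inherits(prepace, "fiber_recording"))
  after <- match.arg(after)
  config <- prepace$config
  if (any(s2_segment < 1) || any(s2_segment > config$n_cells)) {
    stop("s2_segment out of bounds")
  }
  if (ci <= 0) stop("ci must be positive")
  par <- .fiber_params(config)
  t0 <- config$n_prepace * config$bcl

  n_extra <- 1L
  if (after != "last") {
    nb <- length(prepace$recorded_s1)
    if (nb < 2) stop("need at least two recorded beats to select parity")
    apds <- prepace$apd90[prepace$ref_cell, (nb - 1):nb]
    if (any(!is.finite(apds))) stop("reference-cell APD90 unavailable")
    last_is_long <- apds[2] >= apds[1]
    # the first continuation beat has the opposite parity of the final
    # recorded beat; add a second one if that is not the requested type
    first_extra_is_long <- !last_is_long
    if ((after == "long") != first_extra_is_long) n_extra <- 2L
  }
  extra_times <- t0 + (seq_len(n_extra) - 1) * config$bcl
  last_s1 <- extra_times[n_extra]
  stim <- .seg_stim(extra_times, config$s1_segment, config$stim_amp,
                    config$stim_dur)
  t_s2 <- last_s1 + ci
  stim <- rbind(stim, .seg_stim(t_s2, s2_segment, s2_amp, s2_dur))
  t_end <- t_s2 + tail_ms
  run <- cpp_run_cable(par, prepace$final_state, t0, t_end, config$dt, stim,
                       config$diffusion, config$dx, 0, record_every)
  s1_times <- c(prepace$s1_times, extra_times)
  rec <- .fiber_recording(run, config, s1_times,
                          s2 = list(time = t_s2, ci = ci,
                                    segment = sort(s2_segment),
                                    after = after))
  rec
}

#' S2 activation times along the fiber
#'
#' Per-cell activation time after the S2 stimulus, `NA` where the cell never
#' re-activates. A cell counts as activated only by a regenerative upstroke:
#' it must first be (or become) diastolic (below `rest_mv`) at or after the S2
#' time and subsequently exceed `peak_mv`. This excludes both the
#' repolarizing tail of the preceding beat and the passive electrotonic bump
#' around a stimulated-but-refractory segment. The activation time is the
#' first upcross of `act_mv` between those two events.
#'
#' @param recording a `fiber_recording` from [apply_s2()].
#' @param act_mv activation time threshold, mV.
#' @param rest_mv diastolic level the cell must reach first, mV.
#' @param peak_mv level the upstroke must exceed to count as an AP, mV; set
#'   just above the release-triggering voltage so that passive electrotonic
#'   depolarization next to a stimulated segment never qualifies.
#' @return Numeric vector, one element per cell.
#' @export
s2_activation_times <- function(recording, act_mv = -40, rest_mv = -60,
                                peak_mv = -10) {
  stopifnot(inherits(recording, "fiber_recording"),
            !is.null(recording$s2))
  t_s2 <- recording$s2$time
  sel <- recording$times >= t_s2
  tt <- recording$times[sel]
  vapply(seq_len(nrow(recording$vm)), function(i) {
    v <- recording$vm[i, sel]
    i0 <- which(v < rest_mv)
    if (!length(i0)) return(NA_real_)
    i0 <- i0[1]
    ipk <- which(v > peak_mv)
    ipk <- ipk[ipk > i0]
    if (!length(ipk)) return(NA_real_)
    ipk <- ipk[1]
    up <- which(v[-1] >= act_mv & v[-length(v)] < act_mv)
    up <- up[up >= i0 & up < ipk]
    if (!length(up)) return(tt[ipk])
    j <- up[1]
    tt[j] + (act_mv - v[j]) / (v[j + 1] - v[j]) * (tt[j + 1] - tt[j])
  }, numeric(1))
}

#' Conduction velocity over a fiber segment
#'
#' Fits activation time against position over `cells` for the given recorded
#' beat and returns the conduction velocity in cm/ms. Intended for
#' uniform-phenotype segments with clean propagation.
#'
#' @param recording a `fiber_recording`.
#' @param cells integer vector of cell indices to fit over.
#' @param beat which recorded beat to use (default: last).
#' @return Conduction velocity, cm/ms.
#' @export
conduction_velocity <- function(recording, cells,
                                beat = length(recording$recorded_s1)) {
  stopifnot(inherits(recording, "fiber_recording"))
  act <- recording$activation[cells, beat]
  if (any(!is.finite(act))) {
    stop("conduction velocity undefined: activation failure in range")
  }
  x <- (cells - 1) * recording$config$dx
  fit <- stats::lm(act ~ x)
  slope <- stats::coef(fit)[["x"]]
  if (!is.finite(slope) || abs(slope) < 1e-12) {
    stop("conduction velocity undefined: flat activation profile")
  }
  1 / abs(slope)
}
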