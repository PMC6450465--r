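#' Myocyte phenotype
#'
#' A phenotype selects the parameterization of the ventricular myocyte model:
#' a non-infarcted zone (NZ) or infarct border-zone (BZ) cell, together with a
#' graded beta-adrenergic stimulation level.
#'
#' The shipped model is a phenomenological action-potential model (a
#' Mitchell-Schaeffer-type excitable membrane in a normalized voltage
#' variable, mapped to millivolts as `vm = -85 + 125 u`) coupled to a
#' two-variable calcium-cycling subsystem: a cytosolic pool and an SR load
#' whose beat-wise release fraction is a steep sigmoid of the load. Slow SR
#' reuptake combined with steep release restitution produces calcium-driven
#' alternans; cytosolic calcium feeds back on repolarization so calcium
#' alternans drives APD alternans. The BZ phenotype has slower calcium
#' reuptake (prolonged calcium transient), steeper release restitution and
#' slower recovery of excitability than NZ. `bar_level` scales the
#' beta-adrenergic effect continuously: it accelerates SR reuptake and
#' release kinetics, shortens the action potential and speeds recovery of
#' excitability.
#'
#' @param zone `"NZ"` or `"BZ"`.
#' @param bar_level beta-adrenergic stimulation level in `[0, 1]` (0 = off,
#'   1 = full stimulation).
#' @return An object of class `phenotype`.
#' @export
phenotype <- function(zone = c("NZ", "BZ"), bar_level = 0) {
  zone <- match.arg(zone)
  if (!is.numeric(bar_level) || length(bar_level) != 1 ||
      is.na(bar_level) || bar_level < 0 || bar_level > 1) {
    stop("bar_level must be a single number in [0, 1]")
  }
  structure(list(zone = zone, bar_level = bar_level), class = "phenotype")
}

#' @export
print.phenotype <- function(x, ...) {
  cat(sprintf("<phenotype> zone=%s, beta-adrenergic level=%.2f\n",
              x$zone, x$bar_level))
  invisible(x)
}

# Parameter names, in the column order the integrator expects.
.par_names <- c("tau_in", "tau_out", "tau_open", "tau_close", "u_gate",
                "g_cv", "c_base", "v_up", "K_up", "tau_ca_out", "g_in",
                "tau_rel", "rel_fmax", "rel_K", "rel_gamma", "u_rel_gate",
                "rel_refrac", "tau_tr", "tau_cv")

# NZ baseline. Time constants in ms, calcium in uM (cytosol-equivalent).
.nz_base <- c(
  tau_in = 0.15,      # upstroke time constant (sharp threshold)
  tau_out = 6,        # repolarizing leak
  tau_open = 120,     # recovery of excitability
  tau_close = 78,     # inactivation during the plateau; sets APD scale
  u_gate = 0.13,      # excitation threshold (normalized voltage)
  g_cv = 3.5,         # calcium -> voltage coupling (APD prolongation per uM)
  c_base = 0.1,       # diastolic calcium, uM
  v_up = 0.020,       # max SERCA reuptake rate, uM/ms
  K_up = 0.25,        # SERCA half-saturation, uM
  tau_ca_out = 50,    # sarcolemmal calcium extrusion, ms
  g_in = 0.0008,      # depolarization-gated calcium influx, uM/ms
  tau_rel = 10,       # SR release time constant, ms
  rel_fmax = 0.75,    # max releasable fraction of SR load
  rel_K = 1.6,        # half-max SR load for release, uM
  rel_gamma = 20,     # steepness of release-load relation
  u_rel_gate = 0.6,   # voltage threshold for triggering SR release
  rel_refrac = 60,    # minimum interval between releases, ms
  tau_tr = 120,       # refill of the release pool from the uptake pool, ms
  tau_cv = 120        # low-pass of cytosolic calcium seen by the membrane, ms
)

.sr_init <- 1.0  # initial SR load, uM (well below rel_K: gentle initial beats)

#' Model parameter set for a phenotype
#'
#' Expands a [phenotype()] into the full named parameter vector of the myocyte
#' model. BZ remodeling and beta-adrenergic stimulation are applied as
#' multiplicative factors on the NZ baseline.
#'
#' @param pheno a [phenotype()].
#' @return Named numeric vector of model parameters.
#' @export
cell_params <- function(pheno) {
  stopifnot(inherits(pheno, "phenotype"))
  p <- .nz_base
  b <- pheno$bar_level
  if (pheno$zone == "BZ") {
    # Border-zone remodeling is dominated by depressed calcium handling and
    # its downstream effects on repolarization and recovery. Beta-adrenergic
    # stimulation (PKA phosphorylation of phospholamban, RyR and ICaL)
    # compensates exactly this axis, so each remodeling factor is scaled by
    # (1 - bar_level): at full stimulation a BZ cell behaves functionally
    # like an NZ cell, consistent with the near-identical premature-complex
    # vulnerability of fully stimulated BZ fibers and plain NZ fibers.
    p["v_up"] <- p["v_up"] * (0.50 + 0.50 * b)   # impaired reuptake
    p["rel_gamma"] <- 20 + 10 * (1 - b)          # steeper release restitution
    p["tau_tr"] <- 120 + 80 * (1 - b)            # slower release-pool refill
    p["tau_close"] <- p["tau_close"] * (1 + 0.02 * (1 - b))
    p["tau_open"] <- p["tau_open"] * (1 + 0.20 * (1 - b))  # longer ERP
  }
  if (b > 0) {
    p["v_up"] <- p["v_up"] * (1 + 1.0 * b)       # SERCA stimulation
    p["tau_tr"] <- p["tau_tr"] * (1 - 0.5 * b)   # faster release-pool refill
    p["tau_close"] <- p["tau_close"] * (1 - 0.03 * b)   # APD shortening
    p["tau_open"] <- p["tau_open"] * (1 - 0.04 * b)    # faster recovery
    p["tau_rel"] <- p["tau_rel"] * (1 - 0.25 * b)      # faster release
    p["g_in"] <- p["g_in"] * (1 + 0.25 * b)
  }
  p
}

# Initial diastolic state for one cell. h starts at a typical end-diastolic
# value under pacing (not full rest): a pristine h = 1 makes the very first
# action potential abnormally long, which can push the first cycle of a
# paced fiber into a persistent 2:1 rhythm before any steady state is
# reached.
.h_init <- 0.6
.rest_state <- function(p) {
  c(u = 0, h = .h_init, c = unname(p["c_base"]), nsr = .sr_init,
    jsr = .sr_init, rrem = 0, cw = unname(p["c_base"]), last_rel = -1e6)
}

#' Time derivative of the myocyte state
#'
#' The continuous right-hand side of the model (SR release triggering is an
#' upstroke-crossing event handled by the integrator; here its effect appears
#' through the releasing store `rrem`). Useful for inspection and for
#' verifying the compiled integrator.
#'
#' @param state named vector `(u, h, c, nsr, jsr, rrem, cw)` (a trailing
#'   `last_rel` element is ignored).
#' @param pheno a [phenotype()].
#' @param i_stim stimulus current in normalized-voltage units per ms.
#' @return Named vector of derivatives
#'   `(du, dh, dc, dnsr, djsr, drrem, dcw)` per ms.
#' @export
cell_derivatives <- function(state, pheno, i_stim = 0) {
  if (!all(is.finite(state))) stop("integration failure: non-finite state")
  p <- cell_params(pheno)
  u <- state[["u"]]; h <- state[["h"]]; cc <- state[["c"]]
  rrem <- state[["rrem"]]
  du <- h * u^2 * (1 - u) / p[["tau_in"]] - u / p[["tau_out"]] +
    p[["g_cv"]] * (state[["cw"]] - p[["c_base"]]) * u^2 * (1 - u) + i_stim
  dh <- if (u < p[["u_gate"]]) (1 - h) / p[["tau_open"]] else -h / p[["tau_close"]]
  jrel <- rrem / p[["tau_rel"]]
  jup <- p[["v_up"]] * cc^2 / (cc^2 + p[["K_up"]]^2)
  jefx <- (cc - p[["c_base"]]) / p[["tau_ca_out"]]
  jlcc <- if (u > p[["u_gate"]]) p[["g_in"]] else 0
  jtr <- (state[["nsr"]] - state[["jsr"]]) / p[["tau_tr"]]
  c(du = unname(du), dh = unname(dh),
    dc = unname(jrel - jup - jefx + jlcc),
    dnsr = unname(jup - jtr), djsr = unname(jtr), drrem = unname(-jrel),
    dcw = unname((cc - state[["cw"]]) / p[["tau_cv"]]))
}

# Low-level run of a single cell. stim is a matrix with columns
# (t_on, dur, amp); record_every = 0 disables trace recording.
.run_cell <- function(p, state, t0, t_end, stim, dt = 0.02,
                      record_start = 0, record_every = 1) {
  par <- matrix(p, nrow = 1, dimnames = list(NULL, .par_names))
  st <- matrix(state, nrow = 1)
  stim_m <- cbind(stim, 0, 0) # cell range: the single cell (0-based)
  cpp_run_cable(par, st, t0, t_end, dt, stim_m, 0, 1,
                record_start, record_every)
}

# Per-beat AP measures from a sampled vm trace.
# Returns a data.frame with one row per stimulus: activation time (upcross of
# `act_mv`), peak vm, amplitude (peak minus vm at stimulus onset), apd90 and a
# capture flag (amplitude >= 40 mV above rest and an upstroke present).
.measure_beats <- function(times, vm, stim_times, act_mv = -40,
                           repol_frac = 0.9) {
  nb <- length(stim_times)
  out <- data.frame(beat = seq_len(nb), t_stim = stim_times,
                    t_act = NA_real_, peak = NA_real_, rest = NA_real_,
                    amplitude = NA_real_, apd90 = NA_real_,
                    captured = FALSE)
  bounds <- c(stim_times, max(times) + 1)
  for (k in seq_len(nb)) {
    sel <- times >= bounds[k] & times < bounds[k + 1]
    if (sum(sel) < 5) next
    tt <- times[sel]; v <- vm[sel]
    rest <- v[1]
    peak_i <- which.max(v)
    peak <- v[peak_i]
    amp <- peak - rest
    out$rest[k] <- rest; out$peak[k] <- peak; out$amplitude[k] <- amp
    if (amp < 40) next
    # activation: first upcross of act_mv
    up <- which(v[-1] >= act_mv & v[-length(v)] < act_mv)
    if (!length(up)) next
    i <- up[1]
    frac <- (act_mv - v[i]) / (v[i + 1] - v[i])
    t_act <- tt[i] + frac * (tt[i + 1] - tt[i])
    # repolarization level: rest + (1 - repol_frac) * amplitude
    lev <- rest + (1 - repol_frac) * amp
    dn <- which(v[-1] <= lev & v[-length(v)] > lev)
    dn <- dn[dn >= peak_i]
    out$t_act[k] <- t_act
    out$captured[k] <- TRUE
    if (length(dn)) {
      j <- dn[1]
      fr <- (v[j] - lev) / (v[j] - v[j + 1])
      t90 <- tt[j] + fr * (tt[j + 1] - tt[j])
      out$apd90[k] <- t90 - t_act
    }
  }
  out
}

#' Pace a single myocyte at a fixed cycle length
#'
#' Delivers `n_beats` stimuli at the basic cycle length `bcl` to a resting
#' cell and measures per-beat APD90 and calcium transient amplitude. APD90 is
#' measured from the activation upstroke to 90% repolarization of the
#' peak-to-rest amplitude, with linear interpolation between samples.
#'
#' @param pheno a [phenotype()].
#' @param bcl basic cycle length, ms.
#' @param n_beats number of stimuli (>= 2).
#' @param dt integration step, ms.
#' @param record_every trace sampling interval, ms.
#' @param stim_amp,stim_dur stimulus strength (1/ms, normalized voltage) and
#'   duration (ms).
#' @return An object of class `pacing_result`: a list with per-beat measures
#'   (`beats`), `apd90_per_beat`, `cat_amplitude_per_beat`, the final beat
#'   pair APD difference `apd_alternans` (ms), sampled traces and the final
#'   model state.
#' @export
pace_single_cell <- function(pheno, bcl, n_beats, dt = 0.02,
                             record_every = 1, stim_amp = 0.4,
                             stim_dur = 1) {
  stopifnot(inherits(pheno, "phenotype"))
  if (bcl <= 0) stop("bcl must be positive")
  if (n_beats < 2) stop("n_beats must be >= 2")
  p <- cell_params(pheno)
  stim_times <- (seq_len(n_beats) - 1) * bcl
  stim <- cbind(stim_times, stim_dur, stim_amp)
  run <- .run_cell(p, .rest_state(p), 0, n_beats * bcl, stim, dt = dt,
                   record_start = 0, record_every = record_every)
  vm <- run$vm[1, ]
  cai <- run$cai[1, ]
  beats <- .measure_beats(run$times, vm, stim_times)
  # calcium transient amplitude per beat: peak minus value at stimulus onset
  bounds <- c(stim_times, n_beats * bcl + 1)
  cat_amp <- vapply(seq_len(n_beats), function(k) {
    sel <- run$times >= bounds[k] & run$times < bounds[k + 1]
    if (!any(sel)) return(NA_real_)
    max(cai[sel]) - cai[sel][1]
  }, numeric(1))
  apds <- beats$apd90
  alt <- if (n_beats >= 2 && all(is.finite(apds[n_beats - 1:0]))) {
    abs(apds[n_beats] - apds[n_beats - 1])
  } else NA_real_
  structure(list(
    phenotype = pheno, bcl = bcl, n_beats = n_beats,
    beats = beats, apd90_per_beat = apds,
    cat_amplitude_per_beat = cat_amp, apd_alternans = alt,
    times = run$times, vm = vm, cai = cai, final_state = run$state,
    stim = list(amp = stim_amp, dur = stim_dur, times = stim_times)
  ), class = "pacing_result")
}

#' @export
print.pacing_result <- function(x, ...) {
  cat(sprintf(
    "<pacing_result> %s bar=%.2f, bcl=%g ms, %d beats; last APD90 = %.1f ms, APD alternans = %.2f ms\n",
    x$phenotype$zone, x$phenotype$bar_level, x$bcl, x$n_beats,
    x$apd90_per_beat[x$n_beats], x$apd_alternans))
  invisible(x)
}

#' Effective refractory period of a single myocyte
#'
#' After steady S1 pacing, scans the S1-S2 coupling interval upward at 1 ms
#' resolution and returns the shortest interval at which the S2 elicits a
#' propagation-competent action potential, operationalized for a single cell
#' as an AP whose amplitude reaches at least `amp_frac` of the steady S1
#' amplitude.
#'
#' @param pheno a [phenotype()].
#' @param bcl S1 basic cycle length, ms.
#' @param n_s1 number of S1 beats before the scan.
#' @param ci_range two-element vector of scan bounds, ms.
#' @param step scan resolution, ms.
#' @param amp_frac capture criterion as a fraction of the S1 amplitude.
#' @param dt integration step, ms.
#' @return The ERP in ms, or `Inf` (sentinel) if no coupling interval in the
#'   scan range captures.
#' @export
measure_erp <- function(pheno, bcl, n_s1 = 50, ci_range = c(100, 400),
                        step = 1, amp_frac = 0.8, dt = 0.02,
                        stim_amp = 0.4, stim_dur = 1) {
  stopifnot(inherits(pheno, "phenotype"))
  p <- cell_params(pheno)
  t_last <- (n_s1 - 1) * bcl
  # integrate the S1 train up to just before the earliest possible S2
  s1_times <- (seq_len(n_s1) - 1) * bcl
  s1_stim <- cbind(s1_times, stim_dur, stim_amp)
  base <- .run_cell(p, .rest_state(p), 0, t_last + ci_range[1], s1_stim,
                    dt = dt, record_start = 0, record_every = 1)
  m1 <- .measure_beats(base$times, base$vm[1, ], s1_times)
  s1_amp <- m1$amplitude[n_s1 - 1]  # last fully contained S1 beat
  if (!isTRUE(m1$captured[n_s1 - 1])) stop("loss of capture during S1 pacing")
  t0 <- t_last + ci_range[1]
  for (ci in seq(ci_range[1], ci_range[2], by = step)) {
    t_s2 <- t_last + ci
    stim <- cbind(t_s2, stim_dur, stim_amp)
    run <- .run_cell(p, base$state[1, ], t0, t_s2 + 400, stim, dt = dt,
                     record_start = max(0, t_s2 - t0 - 5), record_every = 1)
    m <- .measure_beats(run$times, run$vm[1, ], t_s2)
    if (isTRUE(m$captured[1]) && is.finite(m$amplitude[1]) &&
        m$amplitude[1] >= amp_frac * s1_amp) {
      return(ci)
    }
  }
  Inf
}
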