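#' Calcium transient template
#'
#' Parametric single-beat fluorescence waveform used by the synthetic movie
#' generator: a smooth monotone rise (raised-cosine, shape exponent
#' `upstroke_shape`) from `baseline` to `baseline + amplitude` at
#' `time_to_peak`, followed by an exponential decay with time constant
#' `decay_tau`. With `support` set, the waveform is truncated to zero beyond
#' that time, guaranteeing full recovery before the next beat; by default the
#' decay is untruncated, so at short cycle lengths consecutive transients
#' overlap (diastolic fluorescence stays elevated), as in rapidly paced
#' myocardium.
#'
#' @param time_to_peak rise time from stimulus to peak, ms.
#' @param decay_tau decay time constant, ms. The transient duration at 90%
#'   recovery of an instantaneous-upstroke transient is `decay_tau * log(10)`.
#' @param amplitude peak amplitude above baseline, arbitrary fluorescence
#'   units.
#' @param baseline resting fluorescence, arbitrary units.
#' @param upstroke_shape exponent applied to the raised-cosine rise
#'   (1 = half-cosine; larger values sharpen the foot).
#' @param support optional truncation time, ms: the waveform is exactly zero
#'   above baseline for `t > support`.
#' @return An object of class `transient_template`.
#' @export
transient_template <- function(time_to_peak = 12, decay_tau = 25,
                               amplitude = 100, baseline = 100,
                               upstroke_shape = 1, support = NULL) {
  if (time_to_peak <= 0) stop("time_to_peak must be positive")
  if (decay_tau <= 0) stop("decay_tau must be positive")
  if (amplitude <= 0) stop("amplitude must be positive")
  if (!is.null(support) && support <= time_to_peak) {
    stop("support must exceed time_to_peak")
  }
  structure(list(time_to_peak = time_to_peak, decay_tau = decay_tau,
                 amplitude = amplitude, baseline = baseline,
                 upstroke_shape = upstroke_shape, support = support),
            class = "transient_template")
}

#' @export
print.transient_template <- function(x, ...) {
  cat(sprintf(
    "<transient_template> rise %g ms, decay tau %g ms, amplitude %g on baseline %g\n",
    x$time_to_peak, x$decay_tau, x$amplitude, x$baseline))
  invisible(x)
}

# Unit-amplitude waveform of a template at times t (ms since stimulus);
# 0 before the stimulus and at the stimulus instant, 1 at the peak.
.transient_shape <- function(template, t) {
  ttp <- template$time_to_peak
  y <- numeric(length(t))
  rising <- t > 0 & t <= ttp
  y[rising] <- ((1 - cos(pi * t[rising] / ttp)) / 2)^template$upstroke_shape
  decaying <- t > ttp
  y[decaying] <- exp(-(t[decaying] - ttp) / template$decay_tau)
  if (!is.null(template$support)) y[t > template$support] <- 0
  y
}

#' Sample a single-beat transient
#'
#' Evaluates the template waveform on a regular sampling grid, as recorded by
#' a camera running at `frame_rate`.
#'
#' @param template a [transient_template()].
#' @param beat_amplitude amplitude of this beat, arbitrary units (overrides
#'   the template amplitude; 0 gives a flat trace at baseline).
#' @param duration trace length, ms.
#' @param frame_rate sampling rate, Hz.
#' @return Numeric vector of fluorescence samples at times
#'   `0, 1/frame_rate, ...` (in seconds), starting at the stimulus.
#' @export
make_transient <- function(template, beat_amplitude = template$amplitude,
                           duration = 200, frame_rate = 1000) {
  stopifnot(inherits(template, "transient_template"))
  if (beat_amplitude < 0) stop("beat_amplitude must be non-negative")
  if (duration < template$time_to_peak) {
    stop("duration must be at least time_to_peak")
  }
  if (frame_rate <= 0) stop("frame_rate must be positive")
  t <- seq(0, duration - 1e-9, by = 1000 / frame_rate)
  template$baseline + beat_amplitude * .transient_shape(template, t)
}
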