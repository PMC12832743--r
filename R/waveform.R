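#' Parametric pupillary-light-reflex waveform
#'
#' Defines the diameter-time course of a pupil responding to a light
#' stimulus: a pre-stimulus baseline, a latency period after light onset,
#' a constriction phase down to the minimum diameter, a partial redilation
#' (recovery) phase, and a terminal plateau. The waveform is the ground
#' truth of the synthetic cine generator: all six PLR metrics are available
#' from it in closed form via [true_metrics()].
#'
#' @param baseline_diameter Pre-stimulus pupil diameter in mm (the true
#'   INIT).
#' @param min_diameter Diameter at maximal constriction in mm (the true
#'   END); must be strictly smaller than `baseline_diameter`.
#' @param latency Time from light onset to onset of constriction, in s
#'   (the true LAT); non-negative.
#' @param constriction_duration Duration of the constriction phase in s;
#'   positive.
#' @param recovery_fraction Fraction of the constriction amplitude regained
#'   by the end of the recovery phase, in `[0, 1]`.
#' @param recovery_duration Duration of the recovery phase in s; positive.
#' @param shape `"piecewise_linear"` (default) or `"exponential"`. The
#'   exponential mode uses normalised exponential segments so that
#'   `min_diameter` is attained exactly at the end of the constriction
#'   phase and the recovery endpoint exactly at the end of the recovery
#'   phase, keeping the closed-form metrics exact.
#' @param tau_constrict,tau_dilate Time constants in s for the exponential
#'   segments (ignored in piecewise-linear mode).
#'
#' @return An object of class `plr_waveform`.
#' @seealso [waveform_diameter()], [true_metrics()], [render_cine()]
#' @examples
#' w <- plr_waveform(4.0, 3.0, latency = 0.3, constriction_duration = 1.0)
#' waveform_diameter(w, t = c(0, 1.3, 1.8), stimulus_onset = 0.5)
#' true_metrics(w)
#' @export
plr_waveform <- function(baseline_diameter, min_diameter,
                         latency = 0.25,
                         constriction_duration = 0.8,
                         recovery_fraction = 0.6,
                         recovery_duration = 1.2,
                         shape = c("piecewise_linear", "exponential"),
                         tau_constrict = 0.3, tau_dilate = 0.5) {
  shape <- match.arg(shape)
  stopifnot(
    is.numeric(baseline_diameter), length(baseline_diameter) == 1L,
    is.numeric(min_diameter), length(min_diameter) == 1L,
    is.finite(baseline_diameter), is.finite(min_diameter)
  )
  if (!(min_diameter < baseline_diameter))
    stop("'min_diameter' must be strictly less than 'baseline_diameter'")
  if (min_diameter <= 0)
    stop("'min_diameter' must be positive")
  if (latency < 0)
    stop("'latency' must be non-negative")
  if (constriction_duration <= 0)
    stop("'constriction_duration' must be positive")
  if (recovery_fraction < 0 || recovery_fraction > 1)
    stop("'recovery_fraction' must lie in [0, 1]")
  if (recovery_duration <= 0)
    stop("'recovery_duration' must be positive")
  if (shape == "exponential" && (tau_constrict <= 0 || tau_dilate <= 0))
    stop("time constants must be positive in exponential mode")
  structure(
    list(
      baseline_diameter = baseline_diameter,
      min_diameter = min_diameter,
      latency = latency,
      constriction_duration = constriction_duration,
      recovery_fraction = recovery_fraction,
      recovery_duration = recovery_duration,
      shape = shape,
      tau_constrict = tau_constrict,
      tau_dilate = tau_dilate
    ),
    class = "plr_waveform"
  )
}

#' @export
print.plr_waveform <- function(x, ...) {
  cat("PLR waveform (", x$shape, ")\n", sep = "")
  cat(sprintf("  baseline %.3f mm -> min %.3f mm (delta %.3f)\n",
              x$baseline_diameter, x$min_diameter,
              (x$baseline_diameter - x$min_diameter) / x$baseline_diameter))
  cat(sprintf("  latency %.3f s, constriction %.3f s, recovery %.0f%% over %.3f s\n",
              x$latency, x$constriction_duration,
              100 * x$recovery_fraction, x$recovery_duration))
  invisible(x)
}

#' Evaluate the PLR waveform diameter at given times
#'
#' Returns the analytic pupil diameter at times `t` (seconds from the start
#' of the recording) for a stimulus delivered at `stimulus_onset`.
#'
#' Phase boundaries are `t0 = stimulus_onset + latency` (onset of
#' constriction), `t1 = t0 + constriction_duration` (maximal constriction)
#' and `t2 = t1 + recovery_duration` (end of recovery); the diameter is
#' constant at the recovered level afterwards.
#'
#' @param waveform A [plr_waveform()].
#' @param t Numeric vector of times in s (non-negative).
#' @param stimulus_onset Light-stimulus onset time in s.
#' @return Numeric vector of diameters in mm, same length as `t`.
#' @export
waveform_diameter <- function(waveform, t, stimulus_onset) {
  stopifnot(inherits(waveform, "plr_waveform"), all(t >= 0))
  w <- waveform
  A <- w$baseline_diameter - w$min_diameter
  t0 <- stimulus_onset + w$latency
  t1 <- t0 + w$constriction_duration
  t2 <- t1 + w$recovery_duration
  plateau <- w$min_diameter + w$recovery_fraction * A

  d <- rep(w$baseline_diameter, length(t))
  con <- t >= t0 & t < t1
  rec <- t >= t1 & t < t2
  d[t >= t2] <- plateau

  if (w$shape == "piecewise_linear") {
    d[con] <- w$baseline_diameter - A * (t[con] - t0) / w$constriction_duration
    d[rec] <- w$min_diameter +
      w$recovery_fraction * A * (t[rec] - t1) / w$recovery_duration
  } else {
    # normalised exponentials: endpoints are attained exactly
    Ec <- exp(-w$constriction_duration / w$tau_constrict)
    d[con] <- w$min_diameter +
      A * (exp(-(t[con] - t0) / w$tau_constrict) - Ec) / (1 - Ec)
    Ed <- exp(-w$recovery_duration / w$tau_dilate)
    d[rec] <- w$min_diameter + w$recovery_fraction * A *
      (1 - exp(-(t[rec] - t1) / w$tau_dilate)) / (1 - Ed)
  }
  d
}

#' Closed-form ground-truth PLR metrics of a waveform
#'
#' Derives the six PLR metrics analytically from the waveform parameters,
#' with no simulation: INIT is the baseline diameter, END the minimum
#' diameter, DELTA the constriction ratio `(INIT - END)/INIT`, LAT the
#' latency, ACV the endpoint secant `(INIT - END)/constriction_duration`,
#' and ADV the recovery secant
#' `recovery_fraction * (INIT - END)/recovery_duration`. The same
#' endpoint-secant definitions apply to both waveform shapes, since the
#' exponential mode attains the phase endpoints exactly.
#'
#' @param waveform A [plr_waveform()].
#' @return A [plr_metrics()] object.
#' @export
true_metrics <- function(waveform) {
  stopifnot(inherits(waveform, "plr_waveform"))
  w <- waveform
  A <- w$baseline_diameter - w$min_diameter
  plr_metrics(
    init = w$baseline_diameter,
    end = w$min_diameter,
    delta = A / w$baseline_diameter,
    lat = w$latency,
    acv = A / w$constriction_duration,
    adv = w$recovery_fraction * A / w$recovery_duration
  )
}
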