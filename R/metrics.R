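#' The six scalar PLR metrics
#'
#' Container for one acquisition's (or one averaged session's) pupillary
#' light reflex metrics: initial diameter INIT (mm), end-constriction
#' diameter END (mm), constriction ratio DELTA = (INIT - END)/INIT,
#' latency LAT (s, light onset to onset of constriction), average
#' constriction velocity ACV (mm/s) and average dilation velocity ADV
#' (mm/s). `lat`, `acv` and `adv` may be `NA` when not measurable.
#'
#' @param init,end Diameters in mm; `end <= init`.
#' @param delta Constriction ratio in `[0, 1]`; must equal
#'   `(init - end)/init` to 1e-9 when all three are present.
#' @param lat Latency in s, or `NA`.
#' @param acv,adv Velocities in mm/s (non-negative), or `NA`.
#' @return An object of class `plr_metrics`.
#' @export
plr_metrics <- function(init, end, delta, lat = NA_real_,
                        acv = NA_real_, adv = NA_real_) {
  if (!is.na(init) && !is.na(end) && end > init + 1e-12)
    stop("'end' must not exceed 'init'")
  if (!is.na(init) && !is.na(end) && !is.na(delta) &&
      abs(delta - (init - end) / init) > 1e-9)
    stop("'delta' inconsistent with (init - end)/init")
  if (!is.na(acv) && acv < 0) stop("'acv' must be non-negative")
  if (!is.na(adv) && adv < 0) stop("'adv' must be non-negative")
  structure(
    list(init = init, end = end, delta = delta, lat = lat,
         acv = acv, adv = adv),
    class = "plr_metrics"
  )
}

#' @export
print.plr_metrics <- function(x, ...) {
  fmt <- function(v, u) if (is.na(v)) "NA" else sprintf("%.3f %s", v, u)
  cat("PLR metrics:\n")
  cat("  INIT ", fmt(x$init, "mm"), "  END ", fmt(x$end, "mm"),
      "  DELTA ", if (is.na(x$delta)) "NA" else sprintf("%.3f", x$delta), "\n",
      sep = "")
  cat("  LAT ", fmt(x$lat, "s"), "  ACV ", fmt(x$acv, "mm/s"),
      "  ADV ", fmt(x$adv, "mm/s"), "\n", sep = "")
  invisible(x)
}

#' Metric-extraction configuration
#'
#' @param baseline_window Pre-stimulus span in s used for INIT and the
#'   baseline noise estimate.
#' @param smoothing_window Odd moving-median window (frames) applied to
#'   the valid-frame trace before all metric extraction.
#' @param onset_k_sigma Multiple of the baseline SD that the smoothed
#'   diameter must drop below baseline to call constriction onset.
#' @param onset_min_drop Minimum absolute drop in mm (floor of the onset
#'   criterion, guarding against near-zero baseline noise).
#' @param onset_persistence Number of consecutive non-increasing frames
#'   required after the candidate onset.
#' @param recovery_fraction_for_adv Fraction of the constriction amplitude
#'   whose recovery defines the ADV secant endpoint (in `(0, 1]`).
#' @return An object of class `metrics_config`.
#' @export
metrics_config <- function(baseline_window = 0.8,
                           smoothing_window = 5L,
                           onset_k_sigma = 3,
                           onset_min_drop = 0.05,
                           onset_persistence = 3L,
                           recovery_fraction_for_adv = 0.5) {
  if (baseline_window <= 0) stop("'baseline_window' must be positive")
  if (smoothing_window < 1 || smoothing_window %% 2 == 0)
    stop("'smoothing_window' must be odd and >= 1")
  if (onset_persistence < 1) stop("'onset_persistence' must be >= 1")
  if (recovery_fraction_for_adv <= 0 || recovery_fraction_for_adv > 1)
    stop("'recovery_fraction_for_adv' must lie in (0, 1]")
  structure(
    list(baseline_window = baseline_window,
         smoothing_window = as.integer(smoothing_window),
         onset_k_sigma = onset_k_sigma,
         onset_min_drop = onset_min_drop,
         onset_persistence = as.integer(onset_persistence),
         recovery_fraction_for_adv = recovery_fraction_for_adv),
    class = "metrics_config"
  )
}

# moving median over the valid-frame sequence, window shrunk near the ends
smooth_trace <- function(d, window) {
  n <- length(d)
  if (window <= 1L || n < 3L) return(d)
  k <- min(window, if (n %% 2L == 1L) n else n - 1L)
  if (k < 3L) return(d)
  stats::runmed(d, k, endrule = "median")
}

#' Derive PLR metrics from a diameter-time trace
#'
#' The valid-frame trace is smoothed with a moving median; INIT is the
#' mean smoothed diameter over the pre-stimulus baseline window. Onset of
#' constriction is the first post-stimulus sample whose smoothed diameter
#' falls below `INIT - max(onset_k_sigma * baseline SD, onset_min_drop)`
#' and keeps non-increasing for `onset_persistence` frames; the onset
#' time is refined to the continuous-time threshold crossing by linear
#' interpolation between the bracketing samples (halving the
#' frame-quantisation delay in LAT and in the ACV window). LAT is onset
#' minus the stimulus onset. END is the minimum smoothed diameter after
#' onset (earliest minimum on ties), DELTA the constriction ratio, ACV the
#' secant `(INIT - END)/(t_min - onset)`, and ADV the secant from the
#' minimum to the earliest time the diameter regains
#' `recovery_fraction_for_adv` of the constriction amplitude (or to the
#' last valid frame if never regained).
#'
#' If no onset is found, `lat` and `acv` are `NA` and `end`/`delta` come
#' from the global post-stimulus minimum. Fewer than 3 valid baseline
#' frames or no valid post-stimulus frame raises a classed error
#' (`sonopupil_qc_error`).
#'
#' @param trace A [diameter_trace()].
#' @param config A [metrics_config()].
#' @return A [plr_metrics()] object.
#' @export
compute_metrics <- function(trace, config = metrics_config()) {
  stopifnot(inherits(trace, "diameter_trace"))
  t <- trace$times[trace$valid]
  d <- trace$diameters[trace$valid]
  on <- trace$stimulus_onset
  qc_stop <- function(msg)
    stop(structure(class = c("sonopupil_qc_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1L))))
  if (length(d) == 0L) qc_stop("trace has no valid frames")

  sm <- smooth_trace(d, config$smoothing_window)
  base_idx <- which(t >= on - config$baseline_window & t < on)
  if (length(base_idx) < 3L)
    qc_stop("fewer than 3 valid baseline frames")
  post <- which(t >= on)
  if (length(post) == 0L)
    qc_stop("no valid post-stimulus frames")

  init <- mean(sm[base_idx])
  sd_b <- stats::sd(sm[base_idx])
  drop <- max(config$onset_k_sigma * sd_b, config$onset_min_drop)

  onset_i <- NA_integer_
  thr <- init - drop
  for (i in post) {
    if (sm[i] < thr) {
      j <- i:min(i + config$onset_persistence, length(sm))
      if (length(j) >= 2L && all(diff(sm[j]) <= 0)) {
        onset_i <- i
        break
      }
    }
  }
  # continuous-time crossing: interpolate between the last sample at or
  # above the threshold and the first below it
  interp_onset <- function(i) {
    if (i <= 1L || sm[i - 1L] < thr || sm[i - 1L] <= sm[i]) return(t[i])
    t[i - 1L] + (sm[i - 1L] - thr) / (sm[i - 1L] - sm[i]) *
      (t[i] - t[i - 1L])
  }

  if (is.na(onset_i)) {
    end_i <- post[which.min(sm[post])]
    end <- min(sm[post])
    return(plr_metrics(init = init, end = min(end, init),
                       delta = max(0, (init - min(end, init)) / init),
                       lat = NA_real_, acv = NA_real_, adv = NA_real_))
  }

  after <- onset_i:length(sm)
  end_i <- after[which.min(sm[after])]     # which.min: earliest on ties
  end <- sm[end_i]
  t_onset <- interp_onset(onset_i)
  t_min <- t[end_i]
  lat <- t_onset - on
  acv <- if (t_min > t_onset) (init - end) / (t_min - t_onset) else NA_real_

  adv <- NA_real_
  if (end_i < length(sm)) {
    target <- end + config$recovery_fraction_for_adv * (init - end)
    rec <- (end_i + 1L):length(sm)
    hit <- rec[sm[rec] >= target]
    rec_i <- if (length(hit) > 0L) hit[1L] else length(sm)
    if (t[rec_i] > t_min)
      adv <- max(0, (sm[rec_i] - end) / (t[rec_i] - t_min))
  }

  plr_metrics(init = init, end = min(end, init),
              delta = (init - min(end, init)) / init,
              lat = lat, acv = max(0, acv), adv = adv)
}

#' Arithmetic session average of repeated acquisitions
#'
#' Field-wise arithmetic mean over the acquisitions in which the field is
#' defined; a field is `NA` in the average only if it is `NA` in every
#' acquisition. `delta` of the average is recomputed from the averaged
#' `init` and `end` so the constriction-ratio identity is preserved
#' exactly.
#'
#' @param per_acquisition List of [plr_metrics()] (at least one).
#' @return A [plr_metrics()] object.
#' @export
average_session <- function(per_acquisition) {
  if (length(per_acquisition) == 0L)
    stop("at least one acquisition is required")
  stopifnot(all(vapply(per_acquisition, inherits, logical(1L),
                       "plr_metrics")))
  avg <- function(field) {
    v <- vapply(per_acquisition, function(m) m[[field]], numeric(1L))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  init <- avg("init"); end <- avg("end")
  delta <- if (!is.na(init) && !is.na(end) && init > 0)
    (init - end) / init else avg("delta")
  plr_metrics(init = init, end = end, delta = delta,
              lat = avg("lat"), acv = avg("acv"), adv = avg("adv"))
}

#' Trace-level quality control
#'
#' Mirrors on-screen acquisition checks: the trace must extend at least
#' 1 s beyond the stimulus onset (`"too_short"`), at least 80% of frames
#' must be valid (`"valid_fraction"`), at least 3 valid baseline frames
#' must exist (`"insufficient_baseline"`), and the baseline coefficient
#' of variation must not exceed 0.05 (`"baseline_cv"`).
#'
#' @param trace A [diameter_trace()].
#' @param config A [metrics_config()].
#' @return A list with `qc_pass` (logical) and `reasons` (character).
#' @export
quality_control <- function(trace, config = metrics_config()) {
  reasons <- character(0)
  n <- length(trace$times)
  if (n == 0L || max(trace$times) < trace$stimulus_onset + 1) {
    reasons <- c(reasons, "too_short")
  }
  if (n > 0L && mean(trace$valid) < 0.8)
    reasons <- c(reasons, "valid_fraction")
  t <- trace$times[trace$valid]
  d <- trace$diameters[trace$valid]
  base <- d[t >= trace$stimulus_onset - config$baseline_window &
              t < trace$stimulus_onset]
  if (length(base) < 3L) {
    reasons <- c(reasons, "insufficient_baseline")
  } else if (stats::sd(base) / mean(base) > 0.05) {
    reasons <- c(reasons, "baseline_cv")
  }
  list(qc_pass = length(reasons) == 0L, reasons = reasons)
}

#' Convert metrics to a one-row data frame
#'
#' @param x A [plr_metrics()].
#' @param ... Unused.
#' @return One-row data frame with columns
#'   `init_mm, end_mm, delta, lat_s, acv_mm_s, adv_mm_s`.
#' @export
as.data.frame.plr_metrics <- function(x, ...) {
  data.frame(init_mm = x$init, end_mm = x$end, delta = x$delta,
             lat_s = x$lat, acv_mm_s = x$acv, adv_mm_s = x$adv)
}
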