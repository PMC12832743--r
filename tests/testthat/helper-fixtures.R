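# Shared fixtures: all built in code at test time.

# canonical unit-test waveform: 4.0 -> 3.0 mm, latency 0.3 s, 1 s
# constriction, 50% recovery over 1 s (ACV 1.0, ADV 0.5 mm/s)
ref_waveform <- function(recovery_fraction = 0.5) {
  plr_waveform(4.0, 3.0, latency = 0.3, constriction_duration = 1.0,
               recovery_fraction = recovery_fraction,
               recovery_duration = 1.0)
}

# analytic (device-free) trace sampled from a waveform
analytic_trace <- function(waveform, frame_rate = 30, duration = 5,
                           stimulus_onset = 1.0, loop_id = "analytic") {
  t <- (seq_len(round(duration * frame_rate)) - 1) / frame_rate
  d <- waveform_diameter(waveform, t, stimulus_onset)
  diameter_trace(t, d, rep(TRUE, length(t)), stimulus_onset, loop_id)
}

# pupil_mask wrapper around a hand-built logical matrix
make_mask <- function(mask) {
  idx <- which(mask)
  rr <- (idx - 1L) %% nrow(mask) + 1L
  cc <- (idx - 1L) %/% nrow(mask) + 1L
  structure(list(mask = mask, centroid_row_px = mean(rr),
                 centroid_col_px = mean(cc), area_px = length(idx),
                 valid = TRUE),
            class = "pupil_mask")
}

# study-conditions parameter grid: population mean +/- 1 SD per axis;
# phase durations from the population mean velocities
recovery_grid <- function() {
  g <- expand.grid(baseline = c(3.48, 4.05, 4.62),
                   delta = c(0.200, 0.252, 0.304),
                   latency = c(0.251, 0.278, 0.305))
  g$amplitude <- g$baseline * g$delta
  g$cd <- pmin(pmax(g$amplitude / 1.461, 0.35), 1.8)
  g$rd <- pmin(pmax(0.6 * g$amplitude / 0.776, 0.4), 1.7)
  g
}

grid_waveform <- function(row) {
  plr_waveform(row$baseline, row$baseline - row$amplitude,
               latency = row$latency, constriction_duration = row$cd,
               recovery_fraction = 0.6, recovery_duration = row$rd)
}

# independent ICC oracle: mean squares from stats::aov on the long table
icc_aov_oracle <- function(values, form) {
  n <- nrow(values); k <- ncol(values)
  long <- data.frame(y = as.vector(values),
                     subject = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = long))[[1L]][, "Mean Sq"]
  msr <- ms[1L]; msc <- ms[2L]; mse <- ms[3L]
  if (form == "icc_2_1")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (k - 1) * mse)
}
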