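#' Default PLR waveform population for the study emulator
#'
#' Eye-level distributions (mean, SD, truncation bounds) of baseline
#' diameter, constriction ratio, latency and the two velocities from
#' which per-eye waveforms are drawn. Defaults follow the infrared
#' reference summary shipped in
#' `system.file("extdata", "icu_agreement_summary.csv", package =
#' "sonopupil")`: baseline 4.05 +/- 0.57 mm, constriction ratio 0.252 +/-
#' 0.052, latency 0.278 +/- 0.027 s, constriction velocity 1.461 +/-
#' 0.297 mm/s, dilation velocity 0.776 +/- 0.173 mm/s.
#'
#' @param baseline,delta,latency,acv,adv Numeric `c(mean, sd, lower,
#'   upper)` vectors.
#' @param recovery_fraction Fraction of the constriction amplitude
#'   regained by every generated waveform.
#' @return A list of class `waveform_population`.
#' @export
waveform_population <- function(
    baseline = c(4.05, 0.57, 2.5, 6.0),
    delta = c(0.252, 0.052, 0.10, 0.45),
    latency = c(0.278, 0.027, 0.15, 0.45),
    acv = c(1.461, 0.297, 0.60, 2.60),
    adv = c(0.776, 0.173, 0.30, 1.40),
    recovery_fraction = 0.6) {
  structure(
    list(baseline = baseline, delta = delta, latency = latency,
         acv = acv, adv = adv, recovery_fraction = recovery_fraction),
    class = "waveform_population"
  )
}

rnorm_trunc <- function(n, spec) {
  x <- stats::rnorm(n, spec[1L], spec[2L])
  pmin(pmax(x, spec[3L]), spec[4L])
}

# Draw one eye's waveform; constriction/recovery durations are derived
# from the drawn velocities and clamped so the response completes within
# the recording.
draw_waveform <- function(population) {
  p <- population
  base <- rnorm_trunc(1L, p$baseline)
  delta <- rnorm_trunc(1L, p$delta)
  lat <- rnorm_trunc(1L, p$latency)
  acv <- rnorm_trunc(1L, p$acv)
  adv <- rnorm_trunc(1L, p$adv)
  A <- base * delta
  cd <- min(max(A / acv, 0.35), 1.8)
  rd <- min(max(p$recovery_fraction * A / adv, 0.4), 1.7)
  plr_waveform(baseline_diameter = base, min_diameter = base - A,
               latency = lat, constriction_duration = cd,
               recovery_fraction = p$recovery_fraction,
               recovery_duration = rd)
}

#' Study configuration for the end-to-end emulator
#'
#' Describes a paired two-modality eye-level study: per-patient eyes,
#' triplicate acquisitions, an emulated second modality (infrared
#' pupillometry) with configurable per-metric calibration offsets and
#' measurement noise, and a waveform population. Defaults emulate a
#' 20-patient, 40-eye, 3-acquisition design.
#'
#' @param n_patients Number of patients.
#' @param eyes_per_patient Eyes per patient (default 2).
#' @param acquisitions_per_eye Consecutive acquisitions per eye per
#'   modality (default 3, averaged arithmetically).
#' @param modality_b_offsets Named list of additive calibration offsets
#'   applied to the emulated modality B (`init`, `end`, `delta`, `lat`,
#'   `acv`, `adv`; metric units). Positive values make modality B larger,
#'   i.e. push the reported `a - b` bias negative.
#' @param modality_b_noise_sd Named list of Gaussian measurement noise
#'   SDs for modality B (same names/units).
#' @param population A [waveform_population()].
#' @param scene A [scene_config()] used for all rendered acquisitions
#'   (its seed is superseded by per-loop seeds drawn from `rng_seed`).
#' @param observer_shift_px Maximum probe-placement jitter (pupil-centre
#'   shift, px) applied per observer in the reliability emulation.
#' @param rng_seed Master seed; the whole study is reproducible from it.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_patients = 20L, eyes_per_patient = 2L,
                         acquisitions_per_eye = 3L,
                         modality_b_offsets = list(),
                         modality_b_noise_sd = list(),
                         population = waveform_population(),
                         scene = scene_config(),
                         observer_shift_px = 2L,
                         rng_seed = 1L) {
  if (n_patients < 1L || eyes_per_patient < 1L || acquisitions_per_eye < 1L)
    stop("counts must be at least 1")
  off <- list(init = 0, end = 0, delta = 0, lat = 0, acv = 0, adv = 0)
  off[names(modality_b_offsets)] <- modality_b_offsets
  if (!all(vapply(off, is.finite, logical(1L))))
    stop("modality offsets must be finite")
  nsd <- list(init = 0.02, end = 0.02, delta = 0, lat = 0.008,
              acv = 0.03, adv = 0.03)
  nsd[names(modality_b_noise_sd)] <- modality_b_noise_sd
  structure(
    list(n_patients = as.integer(n_patients),
         eyes_per_patient = as.integer(eyes_per_patient),
         acquisitions_per_eye = as.integer(acquisitions_per_eye),
         modality_b_offsets = off,
         modality_b_noise_sd = nsd,
         population = population,
         scene = scene,
         observer_shift_px = as.integer(observer_shift_px),
         rng_seed = as.integer(rng_seed)),
    class = "study_config"
  )
}

# Modality-B (infrared) emulation: the same metric-extraction operator is
# applied to a noise-free analytic trace sampled at the device frame
# rate, so that both modalities share the onset-detection convention;
# calibration offsets and per-metric measurement noise are then added.
emulate_modality_b <- function(waveform, scene, offsets, noise_sd,
                               mconfig = metrics_config()) {
  t <- (seq_len(round(scene$duration * scene$frame_rate)) - 1) /
    scene$frame_rate
  d <- waveform_diameter(waveform, t, scene$stimulus_onset)
  tr <- diameter_trace(t, d, rep(TRUE, length(t)), scene$stimulus_onset,
                       loop_id = "ipa_ideal")
  m <- compute_metrics(tr, mconfig)
  init <- m$init + offsets$init + stats::rnorm(1L, 0, noise_sd$init)
  end <- m$end + offsets$end + stats::rnorm(1L, 0, noise_sd$end)
  end <- min(end, init)
  delta <- (init - end) / init + offsets$delta +
    if (noise_sd$delta > 0) stats::rnorm(1L, 0, noise_sd$delta) else 0
  data.frame(
    init_mm = init, end_mm = end, delta = delta,
    lat_s = m$lat + offsets$lat + stats::rnorm(1L, 0, noise_sd$lat),
    acv_mm_s = m$acv + offsets$acv + stats::rnorm(1L, 0, noise_sd$acv),
    adv_mm_s = m$adv + offsets$adv + stats::rnorm(1L, 0, noise_sd$adv)
  )
}

# One observer's session on one eye: render, segment, QC, derive, average.
measure_session <- function(waveform, scene, seeds, center_shift,
                            sconfig, mconfig, eye_id, log) {
  per_acq <- list()
  qc_all <- TRUE
  qc_reasons <- character(0)
  for (k in seq_along(seeds)) {
    sc <- scene
    sc$rng_seed <- seeds[k]
    sc$pupil_center_row_px <- sc$pupil_center_row_px + center_shift[1L]
    sc$pupil_center_col_px <- sc$pupil_center_col_px + center_shift[2L]
    loop <- render_cine(waveform, sc,
                        loop_id = sprintf("%s_acq%d", eye_id, k))$loop
    tr <- extract_trace(loop, sconfig)
    qc <- quality_control(tr, mconfig)
    if (!qc$qc_pass) {
      qc_all <- FALSE
      qc_reasons <- union(qc_reasons, qc$reasons)
      log("WARN", sprintf("QC failed for %s acquisition %d: %s", eye_id, k,
                          paste(qc$reasons, collapse = ",")))
    }
    m <- tryCatch(compute_metrics(tr, mconfig),
                  sonopupil_qc_error = function(e) {
                    log("WARN", sprintf("metrics failed for %s acq %d: %s",
                                        eye_id, k, conditionMessage(e)))
                    NULL
                  })
    if (!is.null(m)) per_acq[[length(per_acq) + 1L]] <- m
  }
  if (length(per_acq) == 0L)
    stop("all acquisitions failed for eye ", eye_id)
  list(per_acquisition = per_acq, averaged = average_session(per_acq),
       qc_pass = qc_all, qc_reasons = qc_reasons)
}

#' Run the end-to-end paired-modality study emulator
#'
#' Draws one PLR waveform per eye from the configured population, renders
#' triplicate B-mode cine loops per eye, extracts and quality-controls
#' diameter traces, derives and averages PLR metrics (modality
#' `auto_upa`), emulates the paired infrared modality (`ipa`) with the
#' configured calibration offsets and noise, and emits the agreement
#' report (one row per metric: means +/- SD, bias, limits of agreement,
#' regression, correlation, proportional bias) plus, optionally, the
#' two-observer reliability report (inter-observer ICC(2,1) on
#' session-averaged values; intra-observer ICC(3,1) on the first
#' observer's three repetitions). A manifest JSON records the seed and a
#' config hash. Identical config and seed give byte-identical CSV
#' reports.
#'
#' @param config A [study_config()].
#' @param outdir Output directory (created if needed); receives
#'   `metrics.csv` (per-acquisition rows plus a session-averaged
#'   `acquisition = "avg"` row per eye and modality), `agreement.csv`,
#'   `reliability.csv`, `manifest.json` and `study.log`.
#' @param do_reliability Emulate the second observer and write the
#'   reliability report (doubles the rendering work).
#' @param seg_config A [segmentation_config()].
#' @param met_config A [metrics_config()].
#' @param quiet Suppress per-stage console messages.
#' @return Invisibly, a list with `metrics_table`, `agreement`,
#'   `reliability` (or `NULL`), and the output paths.
#' @export
run_study <- function(config, outdir, do_reliability = TRUE,
                      seg_config = segmentation_config(),
                      met_config = metrics_config(), quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "study.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  log <- function(level, msg) {
    line <- sprintf("%s [%s] %s",
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), level, msg)
    writeLines(line, log_con)
    if (!quiet) message(line)
  }

  n_eyes <- config$n_patients * config$eyes_per_patient
  eye_side <- c("R", "L")
  log("INFO", sprintf("study start: %d patients, %d eyes, %d acquisitions/eye, seed %d",
                      config$n_patients, n_eyes,
                      config$acquisitions_per_eye, config$rng_seed))

  res <- with_seed(config$rng_seed, {
    rows <- list()
    intra <- list()
    inter_o1 <- list()
    inter_o2 <- list()
    for (p in seq_len(config$n_patients)) {
      for (e in seq_len(config$eyes_per_patient)) {
        eye_id <- sprintf("P%02d_%s", p,
                          if (config$eyes_per_patient == 2L) eye_side[e]
                          else sprintf("E%d", e))
        wf <- draw_waveform(config$population)
        seeds1 <- sample.int(2147483646L, config$acquisitions_per_eye)
        shift1 <- sample(-config$observer_shift_px:config$observer_shift_px,
                         2L, replace = TRUE)
        s1 <- measure_session(wf, config$scene, seeds1, shift1,
                              seg_config, met_config, eye_id, log)
        acq_rows <- do.call(rbind, lapply(seq_along(s1$per_acquisition),
          function(k) cbind(
            data.frame(eye_id = eye_id, modality = "auto_upa",
                       acquisition = as.character(k)),
            as.data.frame(s1$per_acquisition[[k]]),
            data.frame(qc_pass = s1$qc_pass))))
        a_row <- cbind(data.frame(eye_id = eye_id, modality = "auto_upa",
                                  acquisition = "avg"),
                       as.data.frame(s1$averaged),
                       data.frame(qc_pass = s1$qc_pass))
        b_vals <- emulate_modality_b(wf, config$scene,
                                     config$modality_b_offsets,
                                     config$modality_b_noise_sd,
                                     met_config)
        b_row <- cbind(data.frame(eye_id = eye_id, modality = "ipa",
                                  acquisition = "avg"),
                       b_vals, data.frame(qc_pass = TRUE))
        rows[[length(rows) + 1L]] <- rbind(acq_rows, a_row, b_row)

        if (do_reliability) {
          intra[[eye_id]] <- vapply(
            s1$per_acquisition,
            function(m) c(m$init, m$end, m$delta, m$lat, m$acv, m$adv),
            numeric(6L))
          seeds2 <- sample.int(2147483646L, config$acquisitions_per_eye)
          shift2 <- sample(-config$observer_shift_px:config$observer_shift_px,
                           2L, replace = TRUE)
          s2 <- measure_session(wf, config$scene, seeds2, shift2,
                                seg_config, met_config,
                                paste0(eye_id, "_obs2"), log)
          inter_o1[[eye_id]] <- s1$averaged
          inter_o2[[eye_id]] <- s2$averaged
        }
      }
      log("INFO", sprintf("patient %d/%d done", p, config$n_patients))
    }
    list(rows = rows, intra = intra, inter_o1 = inter_o1,
         inter_o2 = inter_o2)
  })

  metrics_table <- do.call(rbind, res$rows)
  metrics_path <- file.path(outdir, "metrics.csv")
  utils::write.csv(format_num_df(metrics_table), metrics_path,
                   row.names = FALSE, quote = FALSE)
  log("INFO", paste("metrics written:", metrics_path))

  metric_names <- c("init", "end", "delta", "lat", "acv", "adv")
  agreement <- do.call(rbind, lapply(metric_names, function(m)
    compare_modalities(metrics_table, m)))
  agreement_path <- file.path(outdir, "agreement.csv")
  utils::write.csv(format_num_df(agreement), agreement_path,
                   row.names = FALSE, quote = FALSE)
  log("INFO", paste("agreement report written:", agreement_path))

  reliability <- NULL
  if (do_reliability) {
    fields <- c("init", "end", "delta", "lat", "acv", "adv")
    rel_rows <- list()
    for (i in seq_along(fields)) {
      f <- fields[i]
      o1 <- vapply(res$inter_o1, function(m) m[[f]], numeric(1L))
      o2 <- vapply(res$inter_o2, function(m) m[[f]], numeric(1L))
      ok <- is.finite(o1) & is.finite(o2)
      r2 <- icc(cbind(o1[ok], o2[ok]), "icc_2_1")
      rel_rows[[length(rel_rows) + 1L]] <- data.frame(
        metric = f, design = "inter_observer", form = "icc_2_1",
        n_subjects = sum(ok), icc = r2$icc,
        ms_rows = r2$ms_rows, ms_cols = r2$ms_cols, ms_error = r2$ms_error)
      reps <- t(vapply(res$intra, function(m) m[i, ],
                       numeric(ncol(res$intra[[1L]]))))
      ok3 <- apply(is.finite(reps), 1L, all)
      if (sum(ok3) >= 2L && ncol(reps) >= 2L) {
        r3 <- icc(reps[ok3, , drop = FALSE], "icc_3_1")
        rel_rows[[length(rel_rows) + 1L]] <- data.frame(
          metric = f, design = "intra_observer", form = "icc_3_1",
          n_subjects = sum(ok3), icc = r3$icc,
          ms_rows = r3$ms_rows, ms_cols = r3$ms_cols,
          ms_error = r3$ms_error)
      }
    }
    reliability <- do.call(rbind, rel_rows)
    reliability_path <- file.path(outdir, "reliability.csv")
    utils::write.csv(format_num_df(reliability), reliability_path,
                     row.names = FALSE, quote = FALSE)
    log("INFO", paste("reliability report written:", reliability_path))
  }

  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(serialize_config(config), cfg_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "sonopupil",
    version = as.character(utils::packageVersion("sonopupil")),
    rng_seed = config$rng_seed,
    n_eyes = n_eyes,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = c("metrics.csv", "agreement.csv",
                if (do_reliability) "reliability.csv")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("INFO", "study complete")

  invisible(list(metrics_table = metrics_table, agreement = agreement,
                 reliability = reliability, outdir = outdir))
}

# Fixed-notation numeric formatting so reports are locale- and
# platform-stable (byte-identical reruns).
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 10, format = "g")
  }
  df
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$population <- unclass(out$population)
  out$scene <- unclass(out$scene)
  out
}
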