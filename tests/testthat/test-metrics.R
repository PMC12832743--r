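test_that("ideal noise-free trace recovers the generator ground truth", {
  w <- ref_waveform(recovery_fraction = 0.6)   # INIT 4, END 3, LAT 0.3
  tr <- analytic_trace(w, frame_rate = 30, duration = 5,
                       stimulus_onset = 1.0)
  m <- compute_metrics(tr)
  expect_equal(m$init, 4.0, tolerance = 0.01)
  expect_lt(abs(m$end - 3.0), 0.1)
  # the window-5 median smoother clips the constriction vertex by about
  # ACV/frame_rate mm, bounding the delta error at ~0.008 here
  expect_lt(abs(m$delta - 0.25), 0.01)
  expect_lt(abs(m$lat - 0.3), 2 / 30)
  expect_lt(abs(m$acv - 1.0), 0.1)
  expect_lt(abs(m$adv - 0.6), 0.1)
})

test_that("ADV falls back to the last-frame secant when the recovery target is never regained", {
  # 50% recovery waveform: the vertex-clipped END puts the 50%-amplitude
  # target just above the attained plateau, so the secant runs to the
  # last frame and underestimates the true dilation velocity
  w <- ref_waveform(recovery_fraction = 0.5)
  m <- compute_metrics(analytic_trace(w))
  expect_false(is.na(m$adv))
  expect_lt(m$adv, 0.3)
  # with a lower recovery target the same trace recovers ADV well
  m2 <- compute_metrics(analytic_trace(w),
                        metrics_config(recovery_fraction_for_adv = 0.4))
  expect_lt(abs(m2$adv - 0.5), 0.1)
})

test_that("a flat trace yields no onset and near-zero constriction", {
  t <- (0:89) / 30
  tr <- diameter_trace(t, rep(4, 90), rep(TRUE, 90), 1.0, "flat")
  m <- compute_metrics(tr)
  expect_true(is.na(m$lat))
  expect_true(is.na(m$acv))
  expect_equal(m$delta, 0)
})

test_that("the constriction-ratio identity holds for every extracted record", {
  w <- plr_waveform(4.3, 3.2, latency = 0.28, constriction_duration = 0.7)
  for (s in 1:3) {
    sc <- scene_config(rng_seed = s)
    m <- compute_metrics(extract_trace(render_cine(w, sc)$loop))
    expect_lt(abs(m$delta - (m$init - m$end) / m$init), 1e-9)
  }
  # constructor enforces the identity
  expect_equal(plr_metrics(4, 3, 0.25)$delta, 0.25)
  expect_error(plr_metrics(4, 3, 0.3), "inconsistent")
})

test_that("insufficient baseline raises a quality-control error", {
  t <- (0:89) / 30
  v <- rep(TRUE, 90); v[t < 1.0] <- FALSE; v[1:2] <- TRUE
  d <- rep(4, 90); d[!v] <- NA
  tr <- diameter_trace(t, d, v, 1.0, "sparse")
  expect_error(compute_metrics(tr), class = "sonopupil_qc_error")
})

test_that("session averaging is field-wise over defined values", {
  m <- plr_metrics(4, 3, 0.25, lat = 0.3, acv = 1, adv = 0.5)
  expect_equal(unclass(average_session(list(m, m, m))), unclass(m))
  m1 <- plr_metrics(4.0, 3.0, 0.25, lat = 0.3)
  m2 <- plr_metrics(4.1, 3.0, (4.1 - 3) / 4.1, lat = NA)
  m3 <- plr_metrics(4.2, 3.0, (4.2 - 3) / 4.2, lat = 0.4)
  avg <- average_session(list(m1, m2, m3))
  expect_equal(avg$init, 4.1)
  expect_equal(avg$lat, 0.35)          # mean over the two defined values
  expect_true(is.na(avg$acv))          # undefined everywhere stays undefined
  expect_error(average_session(list()), "at least one")
})

test_that("averaging commutes with scaling for the linear fields", {
  set.seed(7)
  base <- lapply(1:3, function(i) {
    init <- runif(1, 3.5, 4.5); end <- runif(1, 2.5, 3.4)
    plr_metrics(init, end, (init - end) / init, lat = runif(1, 0.2, 0.4),
                acv = runif(1, 0.8, 1.6), adv = runif(1, 0.4, 0.9))
  })
  c0 <- 1.7
  scaled <- lapply(base, function(m)
    plr_metrics(c0 * m$init, c0 * m$end,
                (c0 * m$init - c0 * m$end) / (c0 * m$init),
                lat = m$lat, acv = c0 * m$acv, adv = c0 * m$adv))
  a1 <- average_session(base); a2 <- average_session(scaled)
  for (f in c("init", "end", "acv", "adv"))
    expect_equal(a2[[f]], c0 * a1[[f]])
  expect_equal(a2$delta, a1$delta)
})

test_that("quality control names its failure reasons", {
  w <- ref_waveform()
  ideal <- analytic_trace(w)
  expect_true(quality_control(ideal)$qc_pass)
  # 40% of frames blanked
  blk <- ideal
  idx <- seq(1L, length(blk$times), length.out = 60L)
  blk$valid[idx] <- FALSE; blk$diameters[idx] <- NA
  qc <- quality_control(blk)
  expect_false(qc$qc_pass)
  expect_true("valid_fraction" %in% qc$reasons)
  # empty trace
  empty <- diameter_trace(numeric(0), numeric(0), logical(0), 1.0, "e")
  expect_true("too_short" %in% quality_control(empty)$reasons)
  # noisy baseline trips the coefficient-of-variation check
  set.seed(1)
  noisy <- ideal
  noisy$diameters <- noisy$diameters + rnorm(length(noisy$diameters), 0, 0.4)
  noisy$diameters <- pmax(noisy$diameters, 0.5)
  expect_true("baseline_cv" %in% quality_control(noisy)$reasons)
})
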