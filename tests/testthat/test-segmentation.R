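test_that("chord through the centroid measures run length inclusively", {
  # full-row rectangle, 30 px wide at 0.1 mm/px
  rect <- matrix(FALSE, 40, 60)
  rect[10:20, 11:40] <- TRUE
  expect_equal(chord_diameter(make_mask(rect), 0.1), 3.0)
  # single pixel
  single <- matrix(FALSE, 40, 60); single[5, 7] <- TRUE
  expect_equal(chord_diameter(make_mask(single), 0.1), 0.1)
  # rasterised disc r = 10 px centred on a pixel: 21 pixels on the centre row
  disc <- matrix(FALSE, 41, 41)
  for (i in 1:41) for (j in 1:41)
    disc[i, j] <- (i - 21)^2 + (j - 21)^2 <= 100
  expect_equal(chord_diameter(make_mask(disc), 0.1), 2.1)
  # invalid mask yields the undefined marker
  expect_true(is.na(chord_diameter(
    structure(list(valid = FALSE), class = "pupil_mask"), 0.1)))
})

test_that("tracking prior selects the nearer of two dark components", {
  f <- matrix(1, 96, 128)
  f[10:39, 10:39] <- 0.05      # large blob, centroid (24.5, 24.5)
  f[70:77, 100:107] <- 0.05    # small blob, centroid (73.5, 103.5)
  cfg <- segmentation_config(threshold_method = "fixed",
                             fixed_threshold = 0.2)
  m_large <- segment_frame(f, cfg)               # no prior: largest wins
  expect_equal(m_large$area_px, 900L)
  m_small <- segment_frame(f, cfg, prior_centroid = c(73, 103))
  expect_true(m_small$valid)
  expect_equal(m_small$area_px, 64L)
  expect_equal(m_small$centroid_row_px, 73.5)
  # prior farther than the search radius rejects the frame
  cfg2 <- segmentation_config(threshold_method = "fixed",
                              fixed_threshold = 0.2,
                              tracking_search_radius_px = 3L)
  expect_false(segment_frame(f, cfg2, prior_centroid = c(50, 70))$valid)
})

test_that("degenerate frames give invalid masks, never errors", {
  expect_false(segment_frame(matrix(0.9, 96, 128))$valid)  # all bright
  expect_false(segment_frame(NULL)$valid)
  expect_false(segment_frame(matrix(numeric(0), 0, 0))$valid)
  # components below the area floor are discarded
  f <- matrix(1, 50, 50); f[10:11, 10:11] <- 0
  cfg <- segmentation_config(threshold_method = "fixed",
                             fixed_threshold = 0.5,
                             opening_radius_px = 0L,
                             min_component_area_px = 20L)
  expect_false(segment_frame(f, cfg)$valid)
})

test_that("noise-free segmentation reproduces the rendered gap and the waveform", {
  w <- ref_waveform()
  sc <- scene_config(speckle_shape = Inf, blur_sigma_px = 0, rng_seed = 2)
  r <- render_cine(w, sc)
  # with morphology disabled the mask equals the rendered gap pixel set
  cfg0 <- segmentation_config(opening_radius_px = 0L, closing_radius_px = 0L)
  f10 <- r$loop$frames[[10L]]
  m <- segment_frame(f10, cfg0)
  expect_identical(m$mask, f10 == sc$pupil_intensity)
  # trace oracle at default config
  tr <- extract_trace(r$loop)
  expect_true(all(tr$valid))
  d_true <- waveform_diameter(w, tr$times, sc$stimulus_onset)
  expect_true(max(abs(tr$diameters - d_true)) <= sc$pixel_spacing)
})

test_that("speckled loops track the waveform within twice the pixel spacing (RMS)", {
  w <- ref_waveform()
  rms <- vapply(1:5, function(s) {
    sc <- scene_config(rng_seed = s)
    tr <- extract_trace(render_cine(w, sc)$loop)
    d_true <- waveform_diameter(w, tr$times, sc$stimulus_onset)
    sqrt(mean((tr$diameters[tr$valid] - d_true[tr$valid])^2))
  }, numeric(1L))
  expect_true(all(rms <= 2 * 0.1))
})

test_that("blanked frames are flagged invalid exactly where blanked", {
  w <- ref_waveform()
  sc <- scene_config(speckle_shape = Inf, rng_seed = 4)
  loop <- render_cine(w, sc)$loop
  for (i in 5:7) loop$frames[[i]] <- matrix(0.9, 96, 128)
  tr <- extract_trace(loop)
  expect_false(any(tr$valid[5:7]))
  expect_true(all(tr$valid[-(5:7)]))
  expect_true(all(is.na(tr$diameters[5:7])))
})

test_that("a static loop yields a constant trace", {
  w <- ref_waveform()
  sc <- scene_config(speckle_shape = Inf, rng_seed = 6, duration = 1, stimulus_onset = 0.2,
                     frame_rate = 15)
  frame <- render_cine(w, sc)$loop$frames[[1L]]
  loop <- cine_loop(rep(list(frame), 12L), 15, 0.1, 0.2, "static")
  tr <- extract_trace(loop)
  expect_true(all(tr$valid))
  expect_equal(length(unique(tr$diameters)), 1L)
})

test_that("boundary smoothing regularises ragged run extents without moving the chord", {
  w <- ref_waveform()
  sc <- scene_config(rng_seed = 31)
  f <- render_cine(w, sc)$loop$frames[[5L]]
  plain <- segment_frame(f, segmentation_config())
  smooth <- segment_frame(f, segmentation_config(boundary_smoothing_window = 5L))
  expect_true(smooth$valid)
  d1 <- chord_diameter(plain, 0.1)
  d2 <- chord_diameter(smooth, 0.1)
  expect_lt(abs(d1 - d2), 0.3)
  # per-row width variation shrinks (or stays equal) after smoothing
  spread <- function(m) {
    rows <- which(rowSums(m$mask) > 0)
    stats::sd(rowSums(m$mask[rows, , drop = FALSE]))
  }
  expect_lte(spread(smooth), spread(plain) + 1e-9)
  expect_error(segmentation_config(boundary_smoothing_window = 4L), "odd")
})

test_that("tabulated Otsu agrees with the reference implementation on bimodal samples", {
  set.seed(42)
  for (i in 1:10) {
    f <- matrix(pmin(pmax(c(rnorm(5000, 0.3, 0.08),
                            rnorm(7288, 0.7, 0.08)), 0), 1), 96, 128)
    t_own <- sonopupil:::otsu_threshold(f)
    t_ref <- EBImage::otsu(EBImage::Image(f))
    expect_lt(abs(t_own - t_ref), 1 / 256 + 1e-12)
  }
})

test_that("trace CSV round trip preserves the data and onset", {
  tr <- analytic_trace(ref_waveform(), frame_rate = 10, duration = 2)
  tr$valid[3L] <- FALSE
  tr$diameters[3L] <- NA_real_
  path <- file.path(withr::local_tempdir(), "trace.csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$times, tr$times)
  expect_equal(back$diameters, tr$diameters)
  expect_equal(back$valid, tr$valid)
  expect_equal(back$stimulus_onset, tr$stimulus_onset)
})
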