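#' Scene configuration for the synthetic B-mode cine generator
#'
#' Describes the imaging geometry and echo texture of a tangential
#' transpalpebral ocular view: a bright eyelid band at the top of the
#' frame, a bright iris echo band across the frame, and an anechoic pupil
#' gap inside the iris band whose width follows the PLR waveform. Speckle
#' is modelled as multiplicative gamma noise of mean 1, followed by a
#' Gaussian point-spread blur, emulating fixed depth and gain settings.
#'
#' @param frame_height_px,frame_width_px Frame size in pixels.
#' @param pixel_spacing Spatial calibration in mm/px.
#' @param frame_rate Temporal calibration in Hz.
#' @param duration Recording length in s; `duration * frame_rate` must be
#'   at least 10 frames.
#' @param stimulus_onset Light-stimulus onset in s, within `[0, duration)`.
#' @param eyelid_band_thickness_px Thickness of the eyelid echo band (rows
#'   from the top of the frame).
#' @param iris_band_thickness_px Thickness of the iris echo band, centred
#'   on the pupil centre row.
#' @param iris_intensity,eyelid_intensity,background_intensity,pupil_intensity
#'   Mean grayscale levels in `[0, 1]` of the four tissue classes; the
#'   pupil must be darker than the iris.
#' @param speckle_shape Shape parameter of the mean-1 gamma speckle;
#'   smaller is noisier. `Inf` disables speckle (noise-free rendering).
#' @param blur_sigma_px Gaussian blur standard deviation in px; 0 disables.
#' @param pupil_center_row_px,pupil_center_col_px Pupil centre (1-based
#'   pixel indices; row 1 is the top of the frame).
#' @param rng_seed Integer seed; rendering is bit-reproducible per seed.
#'
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(frame_height_px = 96L, frame_width_px = 128L,
                         pixel_spacing = 0.1, frame_rate = 30,
                         duration = 5, stimulus_onset = 1.0,
                         eyelid_band_thickness_px = 10L,
                         iris_band_thickness_px = 24L,
                         iris_intensity = 0.75, eyelid_intensity = 0.9,
                         background_intensity = 0.35,
                         pupil_intensity = 0.03,
                         speckle_shape = 4, blur_sigma_px = 1,
                         pupil_center_row_px = NULL,
                         pupil_center_col_px = NULL,
                         rng_seed = 1L) {
  if (pixel_spacing <= 0) stop("'pixel_spacing' must be positive")
  if (frame_rate <= 0) stop("'frame_rate' must be positive")
  if (duration * frame_rate < 10)
    stop("recording must span at least 10 frames")
  if (stimulus_onset < 0 || stimulus_onset >= duration)
    stop("'stimulus_onset' must lie in [0, duration)")
  if (!(pupil_intensity < iris_intensity))
    stop("'pupil_intensity' must be less than 'iris_intensity'")
  if (speckle_shape <= 0) stop("'speckle_shape' must be positive")
  if (blur_sigma_px < 0) stop("'blur_sigma_px' must be non-negative")
  if (is.null(pupil_center_row_px))
    pupil_center_row_px <- as.integer(round(frame_height_px * 0.55))
  if (is.null(pupil_center_col_px))
    pupil_center_col_px <- as.integer(round(frame_width_px / 2))
  structure(
    list(
      frame_height_px = as.integer(frame_height_px),
      frame_width_px = as.integer(frame_width_px),
      pixel_spacing = pixel_spacing,
      frame_rate = frame_rate,
      duration = duration,
      stimulus_onset = stimulus_onset,
      eyelid_band_thickness_px = as.integer(eyelid_band_thickness_px),
      iris_band_thickness_px = as.integer(iris_band_thickness_px),
      iris_intensity = iris_intensity,
      eyelid_intensity = eyelid_intensity,
      background_intensity = background_intensity,
      pupil_intensity = pupil_intensity,
      speckle_shape = speckle_shape,
      blur_sigma_px = blur_sigma_px,
      pupil_center_row_px = as.integer(pupil_center_row_px),
      pupil_center_col_px = as.integer(pupil_center_col_px),
      rng_seed = as.integer(rng_seed)
    ),
    class = "scene_config"
  )
}

#' Construct a cine loop container
#'
#' A cine loop is an ordered stack of grayscale frames (values in
#' `[0, 1]`) with spatial and temporal calibration and the stimulus onset
#' carried as metadata.
#'
#' @param frames List of numeric H x W matrices, all the same size.
#' @param frame_rate Frames per second.
#' @param pixel_spacing mm per pixel.
#' @param stimulus_onset Stimulus onset in s.
#' @param loop_id Identifier string.
#' @return An object of class `cine_loop`.
#' @export
cine_loop <- function(frames, frame_rate, pixel_spacing, stimulus_onset,
                      loop_id = "loop") {
  stopifnot(is.list(frames), length(frames) >= 1L)
  d <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1L))))
    stop("all frames must have identical dimensions")
  structure(
    list(frames = frames, frame_rate = frame_rate,
         pixel_spacing = pixel_spacing, stimulus_onset = stimulus_onset,
         loop_id = loop_id),
    class = "cine_loop"
  )
}

#' @export
print.cine_loop <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("Cine loop '%s': %d frames of %dx%d px, %.4g Hz, %.4g mm/px, stimulus at %.3g s\n",
              x$loop_id, length(x$frames), d[1L], d[2L], x$frame_rate,
              x$pixel_spacing, x$stimulus_onset))
  invisible(x)
}

#' Frame times of a cine loop
#' @param loop A [cine_loop()].
#' @return Numeric vector of frame times in s (frame i at `(i-1)/rate`).
#' @export
frame_times <- function(loop) {
  (seq_along(loop$frames) - 1) / loop$frame_rate
}

# Evaluate with a private RNG stream; caller's .Random.seed is untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Banded separable Gaussian kernel matrix (rows renormalised at the edges,
# i.e. reflect-free boundary handling identical to truncated normalisation).
gauss_band <- function(n, sigma) {
  if (sigma <= 0) return(NULL)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - r):(j + r)
    ok <- idx >= 1L & idx <= n
    w <- k[ok]
    M[idx[ok], j] <- w / sum(w)
  }
  M
}

# Noise-free tissue template for one diameter value.
scene_template <- function(scene, diameter_mm) {
  H <- scene$frame_height_px; W <- scene$frame_width_px
  f <- matrix(scene$background_intensity, H, W)
  if (scene$eyelid_band_thickness_px > 0L)
    f[seq_len(min(H, scene$eyelid_band_thickness_px)), ] <-
      scene$eyelid_intensity
  half <- scene$iris_band_thickness_px %/% 2L
  band <- max(1L, scene$pupil_center_row_px - half):
    min(H, scene$pupil_center_row_px - half + scene$iris_band_thickness_px - 1L)
  f[band, ] <- scene$iris_intensity
  n_px <- as.integer(round(diameter_mm / scene$pixel_spacing))
  if (n_px >= W)
    stop("pupil gap wider than the frame; enlarge the scene or shrink the pupil")
  if (n_px > 0L) {
    c0 <- scene$pupil_center_col_px - (n_px - 1L) %/% 2L
    cols <- c0:(c0 + n_px - 1L)
    cols <- cols[cols >= 1L & cols <= W]
    f[band, cols] <- scene$pupil_intensity
  }
  f
}

#' Render a synthetic B-mode cine loop from a PLR waveform
#'
#' Each frame is built as a deterministic tissue template (eyelid band,
#' iris band, anechoic pupil gap of width `waveform_diameter(t)` centred at
#' the pupil centre), multiplied by mean-1 gamma speckle, convolved with a
#' Gaussian point-spread function, and clipped to `[0, 1]`. Rendering with
#' the same `rng_seed` is bit-identical.
#'
#' @param waveform A [plr_waveform()].
#' @param scene A [scene_config()].
#' @param loop_id Identifier carried into the loop metadata.
#' @return A list with components `loop` (a [cine_loop()]) and
#'   `ground_truth` (waveform, closed-form [true_metrics()], and pupil
#'   centre in px).
#' @export
render_cine <- function(waveform, scene, loop_id = "synthetic") {
  stopifnot(inherits(waveform, "plr_waveform"),
            inherits(scene, "scene_config"))
  n_frames <- as.integer(round(scene$duration * scene$frame_rate))
  t <- (seq_len(n_frames) - 1) / scene$frame_rate
  d <- waveform_diameter(waveform, t, scene$stimulus_onset)
  H <- scene$frame_height_px; W <- scene$frame_width_px
  Kr <- gauss_band(H, scene$blur_sigma_px)
  Kc <- gauss_band(W, scene$blur_sigma_px)
  noisy <- is.finite(scene$speckle_shape)
  frames <- with_seed(scene$rng_seed, {
    lapply(seq_len(n_frames), function(i) {
      f <- scene_template(scene, d[i])
      if (noisy)
        f <- f * matrix(stats::rgamma(H * W, shape = scene$speckle_shape,
                                      rate = scene$speckle_shape), H, W)
      if (!is.null(Kr)) f <- Kr %*% f %*% Kc
      f[f < 0] <- 0; f[f > 1] <- 1
      f
    })
  })
  loop <- cine_loop(frames, scene$frame_rate, scene$pixel_spacing,
                    scene$stimulus_onset, loop_id = loop_id)
  gt <- structure(
    list(waveform = waveform,
         true_metrics = true_metrics(waveform),
         pupil_center_row_px = scene$pupil_center_row_px,
         pupil_center_col_px = scene$pupil_center_col_px),
    class = "ground_truth"
  )
  list(loop = loop, ground_truth = gt)
}

#' Write a cine loop as multi-page TIFF with a JSON sidecar
#'
#' The TIFF stores one 16-bit grayscale page per frame; the sidecar JSON
#' (same path with extension `.json`) records frame rate, pixel spacing,
#' stimulus onset and, when supplied, the generator seed, waveform
#' parameters and ground-truth metrics.
#'
#' @param loop A [cine_loop()].
#' @param path Output TIFF path.
#' @param ground_truth Optional ground-truth list from [render_cine()].
#' @param scene Optional [scene_config()]; its seed is recorded.
#' @return Invisibly, the sidecar path.
#' @export
write_cine <- function(loop, path, ground_truth = NULL, scene = NULL) {
  tiff::writeTIFF(loop$frames, path, bits.per.sample = 16L)
  meta <- list(
    loop_id = loop$loop_id,
    frame_rate = loop$frame_rate,
    pixel_spacing = loop$pixel_spacing,
    stimulus_onset = loop$stimulus_onset,
    n_frames = length(loop$frames)
  )
  if (!is.null(scene)) meta$rng_seed <- scene$rng_seed
  if (!is.null(ground_truth)) {
    meta$waveform <- unclass(ground_truth$waveform)
    meta$true_metrics <- unclass(ground_truth$true_metrics)
    meta$pupil_center_px <- c(ground_truth$pupil_center_row_px,
                              ground_truth$pupil_center_col_px)
  }
  sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar)
}

#' Read a cine loop from multi-page TIFF plus JSON sidecar
#'
#' @param path TIFF path; the sidecar is looked up next to it unless given.
#' @param sidecar Optional explicit sidecar JSON path.
#' @return A [cine_loop()].
#' @export
read_cine <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) {
    sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
    if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  }
  if (!file.exists(sidecar))
    stop("sidecar metadata not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1L]   # collapse any channel dim
    f
  })
  cine_loop(frames, meta$frame_rate, meta$pixel_spacing,
            meta$stimulus_onset,
            loop_id = if (is.null(meta$loop_id)) "loop" else meta$loop_id)
}
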