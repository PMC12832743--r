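#' Segmentation configuration
#'
#' Parameters of the four-stage pupil segmentation pipeline: intensity
#' thresholding of dark (anechoic) pixels, morphological opening and
#' closing, small-component rejection, and centroid-tracked component
#' selection across frames.
#'
#' @param threshold_method `"otsu"` (default; adaptive, restricted to the
#'   iris-band region of interest) or `"fixed"` (whole-frame fixed cut,
#'   deterministic — useful for constructed fixtures).
#' @param fixed_threshold Grayscale cut in `[0, 1]` for the fixed method.
#' @param opening_radius_px,closing_radius_px Radii of binary opening and
#'   closing with a 3x3 box structuring element applied radius times; 0
#'   disables the step.
#' @param min_component_area_px Components smaller than this are
#'   discarded.
#' @param boundary_smoothing_window Odd window (rows) for running-median
#'   smoothing of the per-row left/right boundary extents of the selected
#'   component; 1 disables.
#' @param tracking_search_radius_px Maximum centroid displacement from the
#'   previous frame for a component to be accepted during tracking.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = 0.2,
                                opening_radius_px = 1L,
                                closing_radius_px = 1L,
                                min_component_area_px = 20L,
                                boundary_smoothing_window = 1L,
                                tracking_search_radius_px = 20L) {
  threshold_method <- match.arg(threshold_method)
  if (opening_radius_px < 0 || closing_radius_px < 0)
    stop("morphological radii must be non-negative")
  if (min_component_area_px < 1)
    stop("'min_component_area_px' must be at least 1")
  if (boundary_smoothing_window < 1 || boundary_smoothing_window %% 2 == 0)
    stop("'boundary_smoothing_window' must be odd and >= 1")
  structure(
    list(threshold_method = threshold_method,
         fixed_threshold = fixed_threshold,
         opening_radius_px = as.integer(opening_radius_px),
         closing_radius_px = as.integer(closing_radius_px),
         min_component_area_px = as.integer(min_component_area_px),
         boundary_smoothing_window = as.integer(boundary_smoothing_window),
         tracking_search_radius_px = as.integer(tracking_search_radius_px)),
    class = "segmentation_config"
  )
}

# Binary erosion/dilation by a 3x3 box, applied `r` times (vectorised
# shift-and/shift-or; equivalent to a (2r+1)-box structuring element).
erode_box <- function(m, r = 1L) {
  H <- nrow(m); W <- ncol(m)
  for (i in seq_len(r)) {
    v <- m & rbind(m[-1L, , drop = FALSE], FALSE) &
      rbind(FALSE, m[-H, , drop = FALSE])
    m <- v & cbind(v[, -1L, drop = FALSE], FALSE) &
      cbind(FALSE, v[, -W, drop = FALSE])
  }
  m
}

dilate_box <- function(m, r = 1L) {
  H <- nrow(m); W <- ncol(m)
  for (i in seq_len(r)) {
    v <- m | rbind(m[-1L, , drop = FALSE], FALSE) |
      rbind(FALSE, m[-H, , drop = FALSE])
    m <- v | cbind(v[, -1L, drop = FALSE], FALSE) |
      cbind(FALSE, v[, -W, drop = FALSE])
  }
  m
}

# Otsu threshold on a [0,1] sample, 256-level histogram (vectorised
# between-class variance maximisation; agrees with EBImage::otsu to one
# grey level but avoids its per-call hist() overhead on cine loops).
otsu_threshold <- function(x, levels = 256L) {
  b <- pmin.int(pmax.int(floor(x * levels), 0), levels - 1L)
  h <- tabulate(b + 1L, nbins = levels)
  n <- length(x)
  w1 <- cumsum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  m1 <- cumsum(h * mids)
  w2 <- n - w1
  mu1 <- m1 / w1
  mu2 <- (m1[levels] - m1) / w2
  between <- w1 * w2 * (mu1 - mu2)^2
  between[!is.finite(between)] <- -Inf
  k <- which.max(between[-levels])
  k / levels
}

# Otsu threshold restricted to the iris-band region of interest.
# Stage 1: a whole-frame Otsu cut separates echogenic tissue from dark
# pixels; band rows are those dominated by bright tissue. Stage 2: Otsu
# over band pixels splits iris echo from the anechoic pupil gap.
otsu_band_threshold <- function(frame) {
  t1 <- otsu_threshold(frame)
  bright_frac <- rowMeans(frame > t1)
  band <- which(bright_frac > 0.4)
  if (length(band) < 2L) band <- seq_len(nrow(frame))
  t2 <- otsu_threshold(frame[band, , drop = FALSE])
  list(threshold = min(t2, t1), rows = band)
}

#' Segment the pupil in a single B-mode frame
#'
#' Binarises dark pixels, applies morphological opening then closing,
#' discards small components, and selects one component: the one with
#' centroid nearest `prior_centroid` when tracking, otherwise the largest.
#' Ties are broken by larger area, then smaller centroid row. A component
#' farther than the tracking search radius from the prior centroid is
#' rejected. Degenerate frames yield an invalid mask, never an error.
#'
#' @param frame Numeric H x W matrix with values in `[0, 1]` (row 1 = top).
#' @param config A [segmentation_config()].
#' @param prior_centroid Optional `c(row, col)` centroid of the previous
#'   frame's pupil, in px.
#' @return An object of class `pupil_mask`: logical mask, centroid
#'   (`centroid_row_px`, `centroid_col_px`), `area_px`, `valid`.
#' @export
segment_frame <- function(frame, config = segmentation_config(),
                          prior_centroid = NULL) {
  invalid <- structure(
    list(mask = NULL, centroid_row_px = NA_real_, centroid_col_px = NA_real_,
         area_px = 0L, valid = FALSE),
    class = "pupil_mask"
  )
  if (is.null(frame) || length(frame) == 0L || !is.matrix(frame))
    return(invalid)
  H <- nrow(frame); W <- ncol(frame)

  if (config$threshold_method == "fixed") {
    mask <- frame < config$fixed_threshold
  } else {
    ob <- otsu_band_threshold(frame)
    mask <- matrix(FALSE, H, W)
    mask[ob$rows, ] <- frame[ob$rows, , drop = FALSE] < ob$threshold
  }
  if (!any(mask)) return(invalid)

  if (config$opening_radius_px > 0L)
    mask <- dilate_box(erode_box(mask, config$opening_radius_px),
                       config$opening_radius_px)
  if (config$closing_radius_px > 0L)
    mask <- erode_box(dilate_box(mask, config$closing_radius_px),
                      config$closing_radius_px)
  if (!any(mask)) return(invalid)

  lab <- EBImage::bwlabel(mask * 1L)
  idx <- which(lab > 0L)
  l <- lab[idx]
  area <- tabulate(l)
  keep <- which(area >= config$min_component_area_px)
  if (length(keep) == 0L) return(invalid)

  rr <- (idx - 1L) %% H + 1L
  cc <- (idx - 1L) %/% H + 1L
  cr <- rowsum(rr, l)[, 1L] / area
  ccol <- rowsum(cc, l)[, 1L] / area

  if (!is.null(prior_centroid)) {
    dist <- sqrt((cr[keep] - prior_centroid[1L])^2 +
                   (ccol[keep] - prior_centroid[2L])^2)
    best <- dist - 1e-9 <= min(dist)
    cand <- keep[best]
    if (length(cand) > 1L) {               # tie: larger area, then top-most
      cand <- cand[order(-area[cand], cr[cand])]
    }
    chosen <- cand[1L]
    if (min(dist) > config$tracking_search_radius_px) return(invalid)
  } else {
    cand <- keep[order(-area[keep], cr[keep])]
    chosen <- cand[1L]
  }

  sel <- matrix(FALSE, H, W)
  sel[idx[l == chosen]] <- TRUE
  if (config$boundary_smoothing_window > 1L)
    sel <- smooth_boundary(sel, config$boundary_smoothing_window)

  csel <- which(sel)
  rr <- (csel - 1L) %% H + 1L
  cc <- (csel - 1L) %/% H + 1L
  structure(
    list(mask = sel, centroid_row_px = mean(rr), centroid_col_px = mean(cc),
         area_px = length(csel), valid = TRUE),
    class = "pupil_mask"
  )
}

# Running-median smoothing of the per-row left/right extents of a single
# component; rows are refilled between the smoothed extents.
smooth_boundary <- function(mask, window) {
  rows <- which(rowSums(mask) > 0L)
  if (length(rows) < 3L) return(mask)
  lo <- hi <- integer(length(rows))
  for (i in seq_along(rows)) {
    w <- which(mask[rows[i], ])
    lo[i] <- min(w); hi[i] <- max(w)
  }
  k <- min(window, if (length(rows) %% 2L == 1L) length(rows)
           else length(rows) - 1L)
  if (k >= 3L) {
    lo <- as.integer(round(stats::runmed(lo, k)))
    hi <- as.integer(round(stats::runmed(hi, k)))
  }
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_along(rows))
    out[rows[i], lo[i]:hi[i]] <- TRUE
  out
}

#' Maximal horizontal chord through the pupil centroid
#'
#' On the mask row nearest the component centroid, measures the contiguous
#' run of pupil pixels containing (or nearest to) the centroid column.
#' Run length is inclusive (`max_col - min_col + 1` pixels).
#'
#' @param mask A `pupil_mask` from [segment_frame()].
#' @param pixel_spacing mm per pixel.
#' @return Chord length in mm, or `NA` for an invalid mask.
#' @export
chord_diameter <- function(mask, pixel_spacing) {
  if (!isTRUE(mask$valid)) return(NA_real_)
  row <- min(max(1L, as.integer(round(mask$centroid_row_px))),
             nrow(mask$mask))
  v <- mask$mask[row, ]
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (length(on) == 0L) return(NA_real_)
  col <- mask$centroid_col_px
  # distance from centroid column to each run interval (0 if inside)
  d <- pmax(starts[on] - col, col - ends[on], 0)
  run <- on[which.min(d)]
  r$lengths[run] * pixel_spacing
}

#' Diameter-time trace container
#'
#' @param times Frame times in s, strictly increasing.
#' @param diameters Per-frame diameters in mm (`NA` where invalid).
#' @param valid Logical per-frame validity flags.
#' @param stimulus_onset Stimulus onset in s.
#' @param loop_id Identifier string.
#' @return An object of class `diameter_trace`.
#' @export
diameter_trace <- function(times, diameters, valid, stimulus_onset,
                           loop_id = "loop") {
  stopifnot(length(times) == length(diameters),
            length(times) == length(valid))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  if (any(valid & (is.na(diameters) | diameters <= 0)))
    stop("valid frames must carry positive diameters")
  structure(
    list(times = as.numeric(times), diameters = as.numeric(diameters),
         valid = as.logical(valid), stimulus_onset = stimulus_onset,
         loop_id = loop_id),
    class = "diameter_trace"
  )
}

#' @export
print.diameter_trace <- function(x, ...) {
  cat(sprintf("Diameter trace '%s': %d frames, %.0f%% valid, stimulus at %.3g s\n",
              x$loop_id, length(x$times),
              100 * mean(x$valid), x$stimulus_onset))
  invisible(x)
}

#' @export
as.data.frame.diameter_trace <- function(x, ...) {
  data.frame(loop_id = x$loop_id,
             frame_index = seq_along(x$times),
             time_s = x$times,
             diameter_mm = x$diameters,
             valid = x$valid)
}

#' Extract the diameter-time trace from a cine loop
#'
#' Segments frames sequentially, threading each frame's centroid into the
#' next frame as tracking prior, and measures the maximal horizontal chord
#' per frame. Per-frame segmentation failures become `valid = FALSE`
#' entries, never errors. Times are `(frame_index - 1)/frame_rate`;
#' the stimulus onset is carried through from the loop metadata.
#'
#' @param loop A [cine_loop()].
#' @param config A [segmentation_config()].
#' @return A [diameter_trace()].
#' @export
extract_trace <- function(loop, config = segmentation_config()) {
  stopifnot(inherits(loop, "cine_loop"))
  n <- length(loop$frames)
  diam <- rep(NA_real_, n)
  ok <- logical(n)
  prior <- NULL
  for (i in seq_len(n)) {
    m <- segment_frame(loop$frames[[i]], config, prior_centroid = prior)
    if (m$valid) {
      d <- chord_diameter(m, loop$pixel_spacing)
      if (!is.na(d) && d > 0) {
        diam[i] <- d
        ok[i] <- TRUE
        prior <- c(m$centroid_row_px, m$centroid_col_px)
      }
    }
  }
  diameter_trace(frame_times(loop), diam, ok, loop$stimulus_onset,
                 loop_id = loop$loop_id)
}

#' Write / read a diameter trace as CSV
#'
#' Columns: `loop_id, frame_index, time_s, diameter_mm, valid`.
#'
#' @param trace A [diameter_trace()].
#' @param path CSV path.
#' @param stimulus_onset Onset override when reading a CSV that lacks loop
#'   metadata (the onset is stored in a commented header line).
#' @return `write_trace` invisibly returns `path`; `read_trace` returns a
#'   [diameter_trace()].
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stimulus_onset_s=%.17g", trace$stimulus_onset), con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, stimulus_onset = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(stimulus_onset)) {
    if (!grepl("^# stimulus_onset_s=", first))
      stop("no stimulus onset in header; supply 'stimulus_onset'")
    stimulus_onset <- as.numeric(sub("^# stimulus_onset_s=", "", first))
  }
  df <- utils::read.csv(path, comment.char = "#")
  diameter_trace(df$time_s, df$diameter_mm, df$valid, stimulus_onset,
                 loop_id = as.character(df$loop_id[1L]))
}
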