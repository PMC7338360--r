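# Region-of-activity (ROA) detection: from a motion-corrected fluorescence
# movie to a table of spatiotemporal Ca2+ events.
#
# Processing chain (all stages exported individually):
#   A. spatial Gaussian smoothing of each frame            -> F
#   B. temporal moving average (width w) -> F_LP;
#      per-pixel mode of F_LP            -> baseline image F0;
#      S = (F - F0) / F0                 -> dF/F0 series
#   C. S_LP = moving average of S (width w); S_HP = S - S_LP;
#      sigma[p] = SD_t(S_HP[p, ]) / sqrt(L_filt)  (noise of S_LP);
#      S_BP = S_LP - 10 s moving average of S_LP  (drift removal);
#      active voxels: S_BP > k * sigma, outside the ignore mask;
#      3D connected components -> one ROA per component.

#' ROA detection parameters
#'
#' @param smooth_sigma_px Spatial Gaussian sigma in pixels (default 2).
#' @param baseline_window_s Temporal moving-average width `w` in seconds used
#'   for the baseline/lowpass series (default 1.0); the filter length is
#'   `L_filt = round(w * frame_rate)` frames.
#' @param drift_window_s Moving-average width in seconds subtracted from the
#'   lowpass series to remove slow fluorescence drift (default 10).
#' @param k Threshold factor: a voxel is active when the bandpassed dF/F0
#'   exceeds `k` times the per-pixel noise SD (default 5).
#' @param connectivity Voxel adjacency for component labeling: 26
#'   (face+edge+corner, default) or 6 (face only).
#' @param mode_bins Histogram bins for the per-pixel mode estimator.
#' @param footprint Either `"union"` (default: spatial footprint is the union
#'   of active pixels over the event's lifetime) or `"max_frame"` (largest
#'   instantaneous active area across the event's frames).
#' @return A list of class `roa_params`.
#' @export
roa_params <- function(smooth_sigma_px = 2, baseline_window_s = 1.0,
                       drift_window_s = 10, k = 5, connectivity = 26L,
                       mode_bins = 100L, footprint = c("union", "max_frame")) {
  footprint <- match.arg(footprint)
  if (smooth_sigma_px < 0) stop("`smooth_sigma_px` must be >= 0", call. = FALSE)
  if (baseline_window_s <= 0) stop("`baseline_window_s` must be > 0", call. = FALSE)
  if (drift_window_s <= baseline_window_s) {
    stop("`drift_window_s` must exceed `baseline_window_s`", call. = FALSE)
  }
  if (k <= 0) stop("`k` must be > 0", call. = FALSE)
  if (!connectivity %in% c(6L, 26L)) {
    stop("`connectivity` must be 6 or 26", call. = FALSE)
  }
  structure(list(smooth_sigma_px = smooth_sigma_px,
                 baseline_window_s = baseline_window_s,
                 drift_window_s = drift_window_s, k = k,
                 connectivity = as.integer(connectivity),
                 mode_bins = as.integer(mode_bins), footprint = footprint),
            class = "roa_params")
}

window_frames <- function(window_s, frame_rate, n_frames, name) {
  L <- as.integer(round(window_s * frame_rate))
  if (L < 1L) {
    stop("`", name, "` (", window_s, " s) is shorter than one frame period",
         call. = FALSE)
  }
  if (L > n_frames) {
    stop("`", name, "` (", window_s, " s) exceeds the recording length",
         call. = FALSE)
  }
  L
}

#' Spatial Gaussian smoothing of a movie
#'
#' Filters each frame with a normalized 2D Gaussian kernel (FFT-based,
#' replicated edges, so signal near a border is not wrapped to the opposite
#' side of the field). `sigma = 0` is the identity.
#'
#' @param movie A [movie_stack()].
#' @param smooth_sigma_px Gaussian sigma in pixels.
#' @return A smoothed [movie_stack()].
#' @export
spatial_smooth <- function(movie, smooth_sigma_px = 2) {
  stopifnot(inherits(movie, "movie_stack"))
  if (smooth_sigma_px < 0) stop("`smooth_sigma_px` must be >= 0", call. = FALSE)
  if (smooth_sigma_px == 0) return(movie)
  k <- gaussian_kernel_2d(smooth_sigma_px,
                          max_half = (min(dim(movie$data)[1:2]) - 1L) %/% 2L)
  sm <- EBImage::filter2(movie$data, k, boundary = "replicate")
  movie_stack(sm, movie$pixel_size, movie$frame_rate)
}

#' Per-pixel baseline image F0 and lowpass series F_LP
#'
#' Smooths each pixel trace with a centered moving average of width
#' `baseline_window_s` and takes the per-pixel histogram mode over time as
#' the baseline image.
#'
#' @param movie A (spatially smoothed) [movie_stack()].
#' @param baseline_window_s Moving-average width in seconds.
#' @param mode_bins Histogram bins for the mode estimator.
#' @param return_f_lp Keep the lowpass series in the result (set `FALSE` to
#'   save memory when only the baseline image is needed).
#' @return List with `f0` (x-by-y baseline matrix), `f_lp` (lowpass
#'   [movie_stack()], or `NULL`), `L_filt` (filter length in frames) and
#'   `edge` (logical per-frame flag where the moving-average window was
#'   truncated).
#' @export
compute_baseline <- function(movie, baseline_window_s = 1.0,
                             mode_bins = 100L, return_f_lp = TRUE) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$data)
  L <- window_frames(baseline_window_s, movie$frame_rate, d[3L],
                     "baseline_window_s")
  m <- array_to_tp(movie$data)
  f_lp <- moving_average(m, L)
  rm(m)
  edge <- attr(f_lp, "edge")
  f0 <- matrix(mode_estimate_cols(f_lp, mode_bins), d[1L], d[2L])
  list(f0 = f0,
       f_lp = if (return_f_lp) {
         movie_stack(tp_to_array(f_lp, d), movie$pixel_size,
                     movie$frame_rate)
       },
       L_filt = L, edge = edge)
}

#' Relative fluorescence change dF/F0
#'
#' `S = (F - F0) / F0` per pixel. Non-positive baseline pixels are floored at
#' the 1st percentile of the positive baseline values; the flooring count is
#' reported so pathological baselines are visible.
#'
#' @param movie A [movie_stack()] (the series `F`).
#' @param f0 Baseline image from [compute_baseline()].
#' @param floor_quantile Quantile of positive `f0` values used as the floor.
#' @return A [movie_stack()] in dF/F0 units with attribute `"n_floored"`.
#' @export
compute_dff <- function(movie, f0, floor_quantile = 0.01) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$data)
  stopifnot(all(dim(f0) == d[1:2]))
  pos <- f0[f0 > 0]
  if (length(pos) == 0L) {
    stop("baseline image has no positive pixels; cannot form dF/F0",
         call. = FALSE)
  }
  floor_val <- quantile(pos, floor_quantile, names = FALSE)
  n_floored <- sum(f0 < floor_val)
  f0c <- pmax(f0, floor_val)
  s <- sweep(sweep(movie$data, 1:2, f0c, "-"), 1:2, f0c, "/")
  out <- movie_stack(s, movie$pixel_size, movie$frame_rate)
  attr(out, "n_floored") <- n_floored
  out
}

#' Per-pixel noise map of the lowpass dF/F0 series
#'
#' Splits `S` into a lowpass part `S_LP` (moving average, width
#' `baseline_window_s`) and a highpass remainder `S_HP = S - S_LP`. The SD
#' over time of `S_HP` approximates the noise SD of `S`; dividing by
#' `sqrt(L_filt)` gives the noise SD of the moving-average-filtered `S_LP`,
#' which is the series that gets thresholded.
#'
#' @param s dF/F0 [movie_stack()] from [compute_dff()].
#' @param baseline_window_s Moving-average width in seconds.
#' @return List with `sigma` (x-by-y noise SD map of `S_LP`), `s_lp`
#'   (lowpass [movie_stack()]), `L_filt`, and `n_degenerate` (count of
#'   constant pixels whose sigma is 0).
#' @export
estimate_noise <- function(s, baseline_window_s = 1.0) {
  stopifnot(inherits(s, "movie_stack"))
  d <- dim(s$data)
  L <- window_frames(baseline_window_s, s$frame_rate, d[3L],
                     "baseline_window_s")
  m <- array_to_tp(s$data)
  s_lp <- moving_average(m, L)
  m <- m - s_lp  # highpass remainder S_HP (reuses the buffer)
  nt <- d[3L]
  mu <- colMeans(m)
  v <- (colSums(m * m) - nt * mu^2) / (nt - 1L)
  rm(m)
  v[v < 0] <- 0
  sigma <- sqrt(v) / sqrt(L)
  list(sigma = matrix(sigma, d[1L], d[2L]),
       s_lp = movie_stack(tp_to_array(s_lp, d), s$pixel_size, s$frame_rate),
       L_filt = L, n_degenerate = sum(sigma == 0))
}

#' Drift removal by subtracting a slow moving average
#'
#' `S_BP = S_LP - movingaverage(S_LP, drift_window_s)`, removing slow
#' fluorescence drift while leaving transient events intact.
#'
#' @param s_lp Lowpass dF/F0 [movie_stack()] from [estimate_noise()].
#' @param drift_window_s Moving-average width in seconds (default 10).
#' @return A bandpassed [movie_stack()].
#' @export
detrend <- function(s_lp, drift_window_s = 10) {
  stopifnot(inherits(s_lp, "movie_stack"))
  d <- dim(s_lp$data)
  L <- window_frames(drift_window_s, s_lp$frame_rate, d[3L], "drift_window_s")
  m <- array_to_tp(s_lp$data)
  bp <- m - moving_average(m, L)
  movie_stack(tp_to_array(bp, d), s_lp$pixel_size, s_lp$frame_rate)
}

#' Noise-calibrated activity thresholding
#'
#' A voxel is active when the bandpassed dF/F0 strictly exceeds `k` times the
#' per-pixel noise SD (one-sided: Ca2+ transients are fluorescence
#' increases). Pixels inside the ignore mask (vessels, artifacts) are never
#' active.
#'
#' @param s_bp Bandpassed [movie_stack()] from [detrend()].
#' @param sigma Per-pixel noise SD map from [estimate_noise()].
#' @param k Threshold factor (default 5).
#' @param ignore_mask Optional logical x-by-y matrix; `TRUE` marks pixels to
#'   exclude.
#' @return Logical x-y-t array of active voxels with attribute
#'   `"ignore_mask"`.
#' @export
threshold_activity <- function(s_bp, sigma, k = 5, ignore_mask = NULL) {
  stopifnot(inherits(s_bp, "movie_stack"))
  if (k <= 0) stop("`k` must be > 0", call. = FALSE)
  d <- dim(s_bp$data)
  stopifnot(all(dim(sigma) == d[1:2]))
  # per-pixel threshold recycles along t (column-major: x, y fastest)
  active <- s_bp$data > as.vector(k * sigma)
  dim(active) <- d
  if (!is.null(ignore_mask)) {
    stopifnot(all(dim(ignore_mask) == d[1:2]))
    active <- active & as.vector(!as.logical(ignore_mask))
    dim(active) <- d
  }
  attr(active, "ignore_mask") <- ignore_mask
  active
}

#' Extract ROAs from an activity mask
#'
#' Labels connected components of the active-voxel volume (adjacent in space
#' and time under the chosen connectivity) and records one event per
#' component with its start time, duration, spatial footprint, and volume.
#'
#' @param active Logical x-y-t array (e.g. from [threshold_activity()]).
#' @param pixel_size Pixel size in um/px.
#' @param frame_rate Frame rate in Hz.
#' @param connectivity 26 (default) or 6.
#' @param footprint `"union"` or `"max_frame"`; see [roa_params()].
#' @return A `data.frame` with one row per event: `event_id`, `start_frame`
#'   (0-based), `start_time_s`, `duration_s`, `footprint_area_um2`,
#'   `volume_um2s`, `n_voxels`, and bounding box columns `x0,x1,y0,y1,t0,t1`
#'   (0-based, inclusive). The label volume is attached as attribute
#'   `"labels"`.
#' @export
extract_roas <- function(active, pixel_size, frame_rate, connectivity = 26L,
                         footprint = c("union", "max_frame")) {
  footprint <- match.arg(footprint)
  stopifnot(is.logical(active), length(dim(active)) == 3L)
  d <- dim(active)
  labels <- .label_components_3d(as.logical(active), as.integer(d),
                                 as.integer(connectivity))
  n_comp <- attr(labels, "n_components")
  empty <- data.frame(event_id = integer(), start_frame = integer(),
                      start_time_s = numeric(), duration_s = numeric(),
                      footprint_area_um2 = numeric(), volume_um2s = numeric(),
                      n_voxels = integer(), x0 = integer(), x1 = integer(),
                      y0 = integer(), y1 = integer(), t0 = integer(),
                      t1 = integer())
  if (n_comp == 0L) {
    attr(empty, "labels") <- array(labels, dim = d)
    return(empty)
  }
  st <- .component_stats(labels, as.integer(d), n_comp)
  act_idx <- which(labels > 0L)
  lab <- labels[act_idx]
  col <- (act_idx - 1L) %% (d[1L] * d[2L])  # x-y column index, 0-based
  if (footprint == "union") {
    key <- as.numeric(lab) * (d[1L] * d[2L]) + col
    fp_px <- tabulate(lab[!duplicated(key)], n_comp)
  } else {
    frame <- (act_idx - 1L) %/% (d[1L] * d[2L])
    per_frame <- stats::aggregate(
      list(n = col), list(lab = lab, frame = frame), FUN = length)
    fp_px <- as.integer(tapply(per_frame$n, factor(per_frame$lab,
                                                   levels = seq_len(n_comp)),
                               max))
  }
  px_area <- pixel_size^2
  frame_period <- 1 / frame_rate
  out <- data.frame(
    event_id = seq_len(n_comp),
    start_frame = st$t0,
    start_time_s = st$t0 * frame_period,
    duration_s = (st$t1 - st$t0 + 1L) * frame_period,
    footprint_area_um2 = fp_px * px_area,
    volume_um2s = st$n_voxels * px_area * frame_period,
    n_voxels = st$n_voxels,
    x0 = st$x0, x1 = st$x1, y0 = st$y0, y1 = st$y1, t0 = st$t0, t1 = st$t1)
  out <- out[order(out$start_frame, out$x0, out$y0), , drop = FALSE]
  out$event_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "labels") <- array(labels, dim = d)
  out
}

#' Full ROA detection pipeline
#'
#' Runs spatial smoothing, baseline estimation, dF/F0 conversion, noise
#' estimation, drift removal, noise-calibrated thresholding and connected
#' component extraction in sequence. Deterministic: the same movie and
#' parameters always yield the same event table.
#'
#' @param movie A motion-corrected [movie_stack()].
#' @param params A [roa_params()].
#' @param ignore_mask Optional logical x-by-y matrix of pixels to exclude
#'   (vessels, artifacts).
#' @param keep_labels Keep the voxel label volume on the event table
#'   (memory-heavy for large movies; default `TRUE`).
#' @return List of class `roa_detection` with `events` (see
#'   [extract_roas()]), `active` (logical x-y-t array), `sigma` (noise map),
#'   `f0` (baseline image), `n_floored`, `L_filt`, and the `params` used.
#' @export
roa_detect <- function(movie, params = roa_params(), ignore_mask = NULL,
                       keep_labels = TRUE) {
  stopifnot(inherits(movie, "movie_stack"), inherits(params, "roa_params"))
  f <- spatial_smooth(movie, params$smooth_sigma_px)
  bl <- compute_baseline(f, params$baseline_window_s, params$mode_bins,
                         return_f_lp = FALSE)
  f0 <- bl$f0
  L_filt <- bl$L_filt
  rm(bl)
  s <- compute_dff(f, f0)
  n_floored <- attr(s, "n_floored")
  rm(f)
  gc(FALSE)
  nz <- estimate_noise(s, params$baseline_window_s)
  rm(s)
  gc(FALSE)
  s_bp <- detrend(nz$s_lp, params$drift_window_s)
  nz$s_lp <- NULL
  gc(FALSE)
  active <- threshold_activity(s_bp, nz$sigma, params$k, ignore_mask)
  rm(s_bp)
  gc(FALSE)
  events <- extract_roas(active, movie$pixel_size, movie$frame_rate,
                         params$connectivity, params$footprint)
  if (!keep_labels) attr(events, "labels") <- NULL
  structure(list(events = events, active = active, sigma = nz$sigma,
                 f0 = f0, n_floored = n_floored, L_filt = L_filt,
                 params = params),
            class = "roa_detection")
}

#' @export
print.roa_detection <- function(x, ...) {
  d <- dim(x$active)
  cat(sprintf(paste0("roa_detection: %d events in %d x %d x %d volume ",
                     "(k = %g, L_filt = %d, %d floored baseline px)\n"),
              nrow(x$events), d[1L], d[2L], d[3L], x$params$k, x$L_filt,
              x$n_floored))
  invisible(x)
}
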