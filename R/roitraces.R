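# Conventional hand-drawn ROI analysis: mean fluorescence traces, dF/F0
# with a mode baseline, neuropil (doughnut) correction for the neuronal
# channel, noise-thresholded event detection, and onset-difference
# histograms.

#' ROI definitions
#'
#' Circle or polygon regions of interest on the imaging field. Kinds follow
#' the analysis roles: astrocyte somata and neuropil circles on the
#' astrocyte channel, neuron somata and their 5 um doughnut annuli on the
#' neuronal channel.
#'
#' @param id Identifier.
#' @param kind One of `"astro_soma"`, `"astro_neuropil"`, `"neuron_soma"`,
#'   `"neuron_doughnut"`.
#' @param cx,cy Circle center in pixels (1-based), for circles.
#' @param r Circle radius in pixels; for `roi_annulus`, `r_in` and `r_out`.
#' @param xs,ys Polygon vertex coordinates in pixels, for polygons.
#' @param channel `"astro"` or `"neuron"`; defaults from `kind`.
#' @return A list of class `roi`.
#' @name roi
NULL

roi_kinds <- function() c("astro_soma", "astro_neuropil", "neuron_soma",
                          "neuron_doughnut")

roi_new <- function(id, kind, geometry, channel = NULL) {
  kind <- match.arg(kind, roi_kinds())
  channel <- channel %||%
    if (startsWith(kind, "astro")) "astro" else "neuron"
  structure(c(list(id = id, kind = kind, channel = channel), geometry),
            class = "roi")
}

#' @rdname roi
#' @export
roi_circle <- function(id, kind, cx, cy, r) {
  stopifnot(r > 0)
  roi_new(id, kind, list(shape = "circle", cx = cx, cy = cy, r = r))
}

#' @rdname roi
#' @export
roi_annulus <- function(id, kind, cx, cy, r_in, r_out) {
  stopifnot(r_out > r_in, r_in >= 0)
  roi_new(id, kind, list(shape = "annulus", cx = cx, cy = cy, r_in = r_in,
                         r_out = r_out))
}

#' @rdname roi
#' @export
roi_polygon <- function(id, kind, xs, ys) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3L)
  roi_new(id, kind, list(shape = "polygon", xs = xs, ys = ys))
}

# Even-odd ray-casting point-in-polygon test.
point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (ys[i] > py) != (ys[j] > py)
    xint <- (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i]
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

#' Rasterize an ROI to a pixel mask
#'
#' @param roi A [roi_circle()], [roi_annulus()] or [roi_polygon()].
#' @param shape Image size in pixels, length 2.
#' @return Logical matrix with `TRUE` inside the ROI.
#' @export
roi_mask <- function(roi, shape) {
  stopifnot(inherits(roi, "roi"))
  px <- rep(seq_len(shape[1L]), shape[2L])
  py <- rep(seq_len(shape[2L]), each = shape[1L])
  inside <- switch(roi$shape,
    circle = (px - roi$cx)^2 + (py - roi$cy)^2 <= roi$r^2,
    annulus = {
      dd <- (px - roi$cx)^2 + (py - roi$cy)^2
      dd <= roi$r_out^2 & dd > roi$r_in^2
    },
    polygon = point_in_polygon(px, py, roi$xs, roi$ys))
  matrix(inside, shape[1L], shape[2L])
}

#' Read / write ROI definitions as JSON
#'
#' @param rois List of `roi` objects.
#' @param path JSON file path.
#' @return `read_rois` returns a list of `roi` objects.
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(lapply(rois, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(raw, function(r) {
    geometry <- r[setdiff(names(r), c("id", "kind", "channel"))]
    geometry <- lapply(geometry, unlist)
    roi_new(r$id, r$kind, geometry, r$channel)
  })
}

#' Auto-place neuropil circles
#'
#' Places circles of 5 um radius at least 5 um away from every soma ROI
#' perimeter (centers sampled on a grid, deterministic). Manual ROI files
#' remain authoritative; this is a convenience for synthetic studies.
#'
#' @param soma_rois List of soma `roi` circles.
#' @param shape Field size in pixels.
#' @param pixel_size Pixel size in um/px.
#' @param n Number of circles to place.
#' @return List of `astro_neuropil` [roi_circle()]s.
#' @export
auto_neuropil_rois <- function(soma_rois, shape, pixel_size, n = 10L) {
  r_px <- 5 / pixel_size
  clearance <- 5 / pixel_size
  step <- max(2 * r_px, 4)
  cand_x <- seq(r_px + 1, shape[1L] - r_px, by = step)
  cand_y <- seq(r_px + 1, shape[2L] - r_px, by = step)
  out <- list()
  for (cy in cand_y) {
    for (cx in cand_x) {
      ok <- TRUE
      for (s in soma_rois) {
        gap <- sqrt((cx - s$cx)^2 + (cy - s$cy)^2) - s$r - r_px
        if (gap < clearance) { ok <- FALSE; break }
      }
      if (ok) {
        out[[length(out) + 1L]] <- roi_circle(
          paste0("neuropil_", length(out) + 1L), "astro_neuropil", cx, cy,
          r_px)
        if (length(out) >= n) return(out)
      }
    }
  }
  out
}

#' Mean fluorescence trace inside an ROI
#'
#' @param movie A [movie_stack()].
#' @param roi A `roi` object or a logical pixel mask.
#' @return Numeric per-frame mean trace.
#' @export
extract_trace <- function(movie, roi) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$data)
  mask <- if (inherits(roi, "roi")) roi_mask(roi, d[1:2]) else roi
  stopifnot(all(dim(mask) == d[1:2]))
  n_px <- sum(mask)
  if (n_px == 0L) stop("ROI contains no pixels", call. = FALSE)
  m <- matrix(movie$data, prod(d[1:2]), d[3L])
  colSums(m[which(mask), , drop = FALSE]) / n_px
}

#' dF/F0 trace with a mode baseline
#'
#' `F0` is the histogram mode of the trace; the result is
#' `(F - F0) / F0`. A constant trace returns all zeros.
#'
#' @param f Fluorescence trace.
#' @param nbins Histogram bins for the mode estimator.
#' @param floor_value Minimum admissible baseline; non-positive modes are
#'   floored here (with a warning).
#' @return dF/F0 trace with attribute `"f0"`.
#' @export
dff_trace <- function(f, nbins = 100L, floor_value = NULL) {
  f0 <- mode_estimate(f, nbins)
  if (f0 <= 0) {
    pos <- f[f > 0]
    if (is.null(floor_value) && length(pos) == 0L) {
      stop("trace has no positive values; dF/F0 is undefined", call. = FALSE)
    }
    floor_value <- floor_value %||% min(pos)
    warning("non-positive baseline mode (", signif(f0, 3), "); floored at ",
            signif(floor_value, 3))
    f0 <- floor_value
  }
  out <- (f - f0) / f0
  attr(out, "f0") <- f0
  out
}

#' Neuropil-corrected neuronal dF/F0
#'
#' `(F_neuron - F_doughnut) / F0`: the doughnut (5 um annulus around the
#' soma) signal approximates the neuropil contamination and is subtracted
#' before normalizing by the soma baseline.
#'
#' @param f_neuron,f_doughnut Time-aligned traces.
#' @param f0 Baseline (scalar), typically the mode of `f_neuron`.
#' @return Corrected dF/F0 trace.
#' @export
neuropil_correct <- function(f_neuron, f_doughnut, f0) {
  stopifnot(length(f_neuron) == length(f_doughnut), f0 > 0)
  (f_neuron - f_doughnut) / f0
}

#' Event detection on a dF/F0 trace
#'
#' Smooths the trace (Gaussian, sigma 0.25 s for the astrocytic GCaMP6f
#' channel, 0.1 s for the neuronal jRGECO1a channel), removes drift by
#' subtracting a heavily smoothed copy (sigma 120 s), and detects events
#' where the drift-free smoothed trace exceeds a noise-scaled threshold
#' (2.5x the noise SD for astro, 2x for neuron; the noise trace is the raw
#' minus the smoothed trace). Event onset is the threshold crossing,
#' duration runs between the surrounding zero crossings, amplitude is the
#' peak within the event.
#'
#' @param dff dF/F0 trace.
#' @param fs Sampling rate in Hz.
#' @param sensor `"astro"` or `"neuron"`.
#' @param smooth_sigma_s,threshold_mult Override the per-sensor defaults.
#' @param drift_sigma_s Drift-removal smoothing sigma in seconds
#'   (default 120).
#' @return `data.frame`: `onset_s`, `duration_s`, `amplitude`, `start_s`,
#'   `end_s` (the zero-crossing bounds); noise SD and threshold as
#'   attributes.
#' @export
detect_trace_events <- function(dff, fs, sensor = c("astro", "neuron"),
                                smooth_sigma_s = NULL, threshold_mult = NULL,
                                drift_sigma_s = 120) {
  sensor <- match.arg(sensor)
  smooth_sigma_s <- smooth_sigma_s %||%
    switch(sensor, astro = 0.25, neuron = 0.1)
  threshold_mult <- threshold_mult %||% switch(sensor, astro = 2.5,
                                               neuron = 2)
  if (length(dff) < 10 * smooth_sigma_s * fs) {
    stop("trace shorter than 10x the smoothing width", call. = FALSE)
  }
  sm <- gauss_smooth(dff, smooth_sigma_s * fs)
  noise <- dff - sm
  drift <- gauss_smooth(sm, drift_sigma_s * fs)
  y <- sm - drift
  noise_sd <- sd(noise)
  thr <- threshold_mult * noise_sd

  above <- y > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- data.frame(onset_s = numeric(), duration_s = numeric(),
                    amplitude = numeric(), start_s = numeric(),
                    end_s = numeric())
  neg <- which(y <= 0)
  for (j in which(r$values)) {
    i0 <- starts[j]
    # surrounding zero crossings
    before <- neg[neg < i0]
    z0 <- if (length(before) > 0L) max(before) + 1L else 1L
    after <- neg[neg > ends[j]]
    z1 <- if (length(after) > 0L) min(after) - 1L else length(y)
    # merge candidates sharing the same zero-bounded hump into one event
    if (nrow(out) > 0L && tail(out$start_s, 1L) == (z0 - 1L) / fs) next
    out <- rbind(out, data.frame(
      onset_s = (i0 - 1L) / fs,
      duration_s = (z1 - z0 + 1L) / fs,
      amplitude = max(y[z0:z1]),
      start_s = (z0 - 1L) / fs, end_s = z1 / fs))
  }
  attr(out, "noise_sd") <- noise_sd
  attr(out, "threshold") <- thr
  out
}

#' Histogram of astrocyte-event onsets around neuron-event onsets
#'
#' For every neuronal soma event, collects astrocytic event onsets within
#' `window_s` seconds and histograms the onset differences
#' (astro minus neuron) in 1 s bins.
#'
#' @param astro_onsets,neuron_onsets Event onset times (seconds, common
#'   clock).
#' @param bin_s Bin width in seconds (default 1).
#' @param window_s Half-window in seconds (default 10).
#' @return `data.frame`: `bin_center_s`, `count`; the raw differences as
#'   attribute `"differences"`.
#' @export
onset_difference_histogram <- function(astro_onsets, neuron_onsets,
                                       bin_s = 1, window_s = 10) {
  edges <- seq(-window_s, window_s, by = bin_s)
  diffs <- numeric()
  for (tn in neuron_onsets) {
    dd <- astro_onsets - tn
    diffs <- c(diffs, dd[dd >= -window_s & dd <= window_s])
  }
  counts <- if (length(diffs) > 0L) {
    idx <- pmin(findInterval(diffs, edges, rightmost.closed = TRUE),
                length(edges) - 1L)
    tabulate(idx, length(edges) - 1L)
  } else {
    integer(length(edges) - 1L)
  }
  structure(data.frame(bin_center_s = edges[-length(edges)] + bin_s / 2,
                       count = counts),
            differences = diffs)
}
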