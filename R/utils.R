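# Shared numeric helpers: moving averages with shrinking edge windows,
# histogram-mode estimation, Gaussian smoothing of traces, analytic signal.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centered moving average with shrinking edge windows
#'
#' Averages over a centered window of `width` samples. At the boundaries the
#' window shrinks so the output has the same length as the input; the
#' `"edge"` attribute flags the positions where the full window did not fit.
#'
#' @param x Numeric vector, or a matrix with time along rows (each column is
#'   averaged independently).
#' @param width Window width in samples (integer, >= 1).
#' @return Object of the same shape as `x` with attribute `"edge"` (logical
#'   vector over time).
#' @export
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (is.na(width) || width < 1L) {
    stop("moving average `width` must be at least 1 sample", call. = FALSE)
  }
  mat <- is.matrix(x)
  if (!mat) x <- matrix(x, ncol = 1L)
  nt <- nrow(x)
  if (width > nt) {
    stop("moving average `width` (", width, ") exceeds the number of samples (",
         nt, ")", call. = FALSE)
  }
  lo <- pmax(seq_len(nt) - (width - 1L) %/% 2L, 1L)
  hi <- pmin(seq_len(nt) + width %/% 2L, nt)
  n_win <- hi - lo + 1L
  lo1 <- lo > 1L
  out <- matrix(0, nt, ncol(x))
  # blockwise over pixels to bound the cumulative-sum temporaries
  block <- max(1L, min(ncol(x), as.integer(2^22 %/% nt)))
  for (j0 in seq(1L, ncol(x), by = block)) {
    j <- j0:min(ncol(x), j0 + block - 1L)
    cs <- apply(x[, j, drop = FALSE], 2L, cumsum)
    if (!is.matrix(cs)) cs <- matrix(cs, nrow = nt)
    o <- cs[hi, , drop = FALSE]
    o[lo1, ] <- o[lo1, , drop = FALSE] - cs[lo[lo1] - 1L, , drop = FALSE]
    out[, j] <- o / n_win
  }
  if (!mat) out <- drop(out)
  attr(out, "edge") <- n_win < width
  out
}

#' Histogram mode of a numeric vector
#'
#' Bins the values into `nbins` equal-width bins spanning the 0.1-99.9
#' percentile range and returns the center of the most populated bin. Used
#' as the baseline (F0) estimator for pixel and ROI fluorescence traces:
#' with sparse transients most samples sit at baseline, so the mode is
#' robust to activity that would bias a mean or even a median.
#'
#' @param x Numeric vector.
#' @param nbins Number of histogram bins (default 100).
#' @return Scalar mode estimate. Degenerate (constant) input returns that
#'   constant.
#' @export
mode_estimate <- function(x, nbins = 100L) {
  rng <- quantile(x, c(0.001, 0.999), names = FALSE, type = 7)
  if (diff(rng) <= 0) return(rng[1L])
  idx <- findInterval(x, seq(rng[1L], rng[2L], length.out = nbins + 1L),
                      rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nbins)
  counts <- tabulate(idx, nbins)
  b <- which.max(counts)
  rng[1L] + (b - 0.5) * diff(rng) / nbins
}

# Column-wise histogram mode for a time-by-pixel matrix; vectorized over
# pixels (one tabulate over pixel*bin codes instead of a per-pixel loop).
mode_estimate_cols <- function(m, nbins = 100L) {
  nt <- nrow(m)
  np <- ncol(m)
  qs <- apply(m, 2L, quantile, probs = c(0.001, 0.999), names = FALSE, type = 7)
  lo <- qs[1L, ]
  hi <- qs[2L, ]
  span <- hi - lo
  flat <- span <= 0
  span[flat] <- 1
  idx <- floor((sweep(m, 2L, lo, "-")) / rep(span, each = nt) * nbins) + 1L
  idx[idx < 1L] <- 1L
  idx[idx > nbins] <- nbins
  code <- idx + rep((seq_len(np) - 1L) * nbins, each = nt)
  counts <- tabulate(code, nbins * np)
  counts <- matrix(counts, nrow = nbins)
  b <- max.col(t(counts), ties.method = "first")
  out <- lo + (b - 0.5) * span / nbins
  out[flat] <- lo[flat]
  out
}

#' Gaussian smoothing of a sampled trace
#'
#' Convolves with a discrete Gaussian kernel (support +/- 4 sigma) using
#' reflected edges, preserving constants everywhere.
#'
#' @param x Numeric vector.
#' @param sigma_samples Kernel standard deviation in samples; 0 returns `x`.
#' @return Smoothed vector, same length.
#' @export
gauss_smooth <- function(x, sigma_samples) {
  if (sigma_samples <= 0) return(x)
  n <- length(x)
  half <- min(ceiling(4 * sigma_samples), n - 1L)
  k <- exp(-(seq(-half, half))^2 / (2 * sigma_samples^2))
  k <- k / sum(k)
  xp <- c(x[pmin(half:1 + 1L, n)], x, x[pmax(n - seq_len(half), 1L)])
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1L):(half + n)]
}

# Analytic signal by the FFT method: zero out negative frequencies, double
# positive ones. Mod() of the result is the instantaneous-amplitude envelope.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Conversions between a (nx, ny, nt) array and a time-by-pixel matrix with
# pixels in column-major (x fastest) order. dim<- avoids an extra copy.
array_to_tp <- function(a) {
  d <- dim(a)
  m <- aperm(a, c(3L, 1L, 2L))
  dim(m) <- c(d[3L], d[1L] * d[2L])
  m
}

tp_to_array <- function(m, dims) {
  dim(m) <- c(dims[3L], dims[1L], dims[2L])
  aperm(m, c(2L, 3L, 1L))
}

# Normalized 2D Gaussian kernel for spatial filtering. `max_half` caps the
# kernel radius (filter2 requires kernels no larger than the image).
gaussian_kernel_2d <- function(sigma, max_half = Inf) {
  half <- min(max(1L, ceiling(4 * sigma)), max_half)
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

assert_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop("`", name, "` contains non-finite values", call. = FALSE)
  }
  invisible(x)
}
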