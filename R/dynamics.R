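# Transition-locked Ca2+ dynamics: causal smoothing of ROA frequency
# traces, alignment to state transitions, baseline z-scoring, onset and
# peak estimation, and astro-neuron cross-correlation.

#' Causal smoothing with a t*exp(-t/tau) kernel
#'
#' Convolves with the causal kernel `k(t) = t * exp(-t / tau)` for `t >= 0`,
#' normalized to unit sum so constants are preserved. Because the kernel
#' vanishes for `t <= 0`, the response to an impulse is exactly zero before
#' (and at) the impulse, so smoothing cannot shift onsets to earlier times
#' the way a symmetric Gaussian kernel would. The kernel peaks at
#' `t = tau`.
#'
#' @param x Numeric trace (e.g. a ROA frequency trace).
#' @param fs Sampling rate in Hz.
#' @param tau Kernel time constant in seconds (default 0.25).
#' @return Smoothed trace of the same length.
#' @export
smooth_causal <- function(x, fs, tau = 0.25) {
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  dt <- 1 / fs
  tt <- seq(0, 8 * tau, by = dt)
  k <- tt * exp(-tt / tau)
  k <- k / sum(k)
  n <- length(x)
  if (length(k) > n) {  # short series: truncate the kernel tail
    k <- k[seq_len(n)]
    k <- k / sum(k)
  }
  # direct (time-domain) causal convolution: exact zeros before an impulse
  y <- as.numeric(stats::filter(x, k, method = "convolution", sides = 1L))
  # shrink the kernel at the start so constants are preserved there too;
  # the first sample has zero kernel weight (k(0) = 0) and passes through
  head_n <- min(length(k) - 1L, n)
  if (head_n > 0L) {
    cw <- cumsum(k)[seq_len(head_n)]
    for (t in seq_len(head_n)) {
      y[t] <- if (cw[t] > 0) {
        sum(k[seq_len(t)] * x[t:1]) / cw[t]
      } else {
        x[t]
      }
    }
  }
  y
}

#' Align a trace to transitions and z-score by the pre-transition baseline
#'
#' Collects the trace in a window around every transition and z-scores each
#' row by the mean and SD of its baseline segment (default -15 to -5 s
#' before the transition). Transitions whose window does not fit inside the
#' recording, or whose baseline SD is zero, are dropped (counted in
#' attributes).
#'
#' @param x Numeric trace sampled at `fs` Hz, starting at time 0.
#' @param fs Sampling rate in Hz.
#' @param transition_times Transition times in seconds.
#' @param window Window around each transition in seconds (default
#'   `c(-15, 15)`).
#' @param baseline Baseline interval in seconds (default `c(-15, -5)`).
#' @return Matrix of class `aligned_traces`, one row per usable transition;
#'   attributes: `time_s` (column time axis), `transition_times`,
#'   `baseline`, `n_dropped_window`, `n_dropped_flat`.
#' @export
align_and_zscore <- function(x, fs, transition_times, window = c(-15, 15),
                             baseline = c(-15, -5)) {
  i_rel <- round(window[1L] * fs):round(window[2L] * fs)
  time_s <- i_rel / fs
  base_cols <- which(time_s >= baseline[1L] & time_s <= baseline[2L])
  rows <- list()
  used <- numeric()
  n_out <- 0L
  n_flat <- 0L
  for (tt in transition_times) {
    idx <- round(tt * fs) + 1L + i_rel
    if (idx[1L] < 1L || idx[length(idx)] > length(x)) {
      n_out <- n_out + 1L
      next
    }
    row <- x[idx]
    mu <- mean(row[base_cols])
    s <- sd(row[base_cols])
    if (s == 0) {
      n_flat <- n_flat + 1L
      next
    }
    rows[[length(rows) + 1L]] <- (row - mu) / s
    used <- c(used, tt)
  }
  m <- if (length(rows) > 0L) do.call(rbind, rows) else
    matrix(numeric(), 0L, length(i_rel))
  structure(m, time_s = time_s, transition_times = used,
            baseline = baseline, n_dropped_window = n_out,
            n_dropped_flat = n_flat, class = c("aligned_traces", "matrix"))
}

#' Onset of transition-locked activity
#'
#' For each aligned, z-scored row: the first time, scanning forward from
#' the end of the baseline window (default -5 s), at which the trace
#' crosses `threshold` standard deviations. Rows that never cross are
#' flagged undetected.
#'
#' @param aligned An `aligned_traces` matrix from [align_and_zscore()].
#' @param threshold Crossing threshold in baseline SD units (default 2.5).
#' @param scan_from Scan start in seconds relative to the transition
#'   (default -5, the end of the baseline window).
#' @return `data.frame`: `onset_s`, `detected`.
#' @export
estimate_onset <- function(aligned, threshold = 2.5, scan_from = -5) {
  time_s <- attr(aligned, "time_s")
  scan_cols <- which(time_s >= scan_from)
  onset <- rep(NA_real_, nrow(aligned))
  detected <- rep(FALSE, nrow(aligned))
  for (i in seq_len(nrow(aligned))) {
    hit <- scan_cols[aligned[i, scan_cols] > threshold]
    if (length(hit) > 0L) {
      onset[i] <- time_s[hit[1L]]
      detected[i] <- TRUE
    }
  }
  data.frame(onset_s = onset, detected = detected)
}

#' Peak of transition-locked activity
#'
#' Row maxima of the aligned z-scored matrix over the full window.
#'
#' @param aligned An `aligned_traces` matrix.
#' @return Numeric vector of per-transition peak values (z units).
#' @export
estimate_peak <- function(aligned) {
  if (nrow(aligned) == 0L) return(numeric())
  apply(aligned, 1L, max)
}

#' Maximum lagged Pearson correlation between astrocytic and neuronal traces
#'
#' Both traces are Gaussian-smoothed (sigma 0.25 s), then the Pearson
#' correlation is computed at every integer-sample lag within `max_lag_s`
#' and the maximum (by absolute value) is returned with its lag. Positive
#' lag means the astrocytic trace follows the neuronal trace.
#'
#' @param astro,neuron Equal-length traces (>= 100 samples) at `fs` Hz.
#' @param fs Sampling rate in Hz.
#' @param max_lag_s Lag search half-range in seconds (default 2).
#' @param smooth_sigma_s Gaussian smoothing sigma in seconds (default 0.25;
#'   0 disables).
#' @return List: `correlation`, `lag_s`, `lag_samples`. Constant traces
#'   give `NA` correlation with a warning.
#' @export
astro_neuron_correlation <- function(astro, neuron, fs, max_lag_s = 2,
                                     smooth_sigma_s = 0.25) {
  stopifnot(length(astro) == length(neuron))
  if (length(astro) < 100L) {
    stop("traces must have at least 100 samples", call. = FALSE)
  }
  a <- gauss_smooth(astro, smooth_sigma_s * fs)
  b <- gauss_smooth(neuron, smooth_sigma_s * fs)
  if (sd(a) == 0 || sd(b) == 0) {
    warning("constant trace: correlation undefined")
    return(list(correlation = NA_real_, lag_s = NA_real_,
                lag_samples = NA_integer_))
  }
  max_lag <- round(max_lag_s * fs)
  lags <- (-max_lag):max_lag
  n <- length(a)
  cors <- vapply(lags, function(l) {
    if (l >= 0) {
      ai <- (1L + l):n
      bi <- 1L:(n - l)
    } else {
      ai <- 1L:(n + l)
      bi <- (1L - l):n
    }
    if (sd(a[ai]) == 0 || sd(b[bi]) == 0) return(NA_real_)
    cor(a[ai], b[bi])
  }, numeric(1L))
  best <- which.max(abs(cors))
  list(correlation = cors[best], lag_s = lags[best] / fs,
       lag_samples = lags[best])
}
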