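# Sleep-wake scoring from ECoG/EMG/motion traces, microarousal detection,
# state transitions, band power, and sleep-spindle detection.

#' Standard ECoG band definitions
#'
#' Delta 0.5-4 Hz, theta 5-9 Hz, sigma 10-16 Hz (the spindle band; some
#' scoring conventions start it at 9 Hz, adjustable via `sigma_low`), and
#' total 0.5-30 Hz.
#'
#' @param sigma_low Lower edge of the sigma band in Hz (default 10).
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
band_definitions <- function(sigma_low = 10) {
  list(delta = c(0.5, 4), theta = c(5, 9), sigma = c(sigma_low, 16),
       beta = c(16, 30), total = c(0.5, 30))
}

#' Band-integrated power over sliding windows
#'
#' Splits the trace into non-overlapping windows of `window_s` seconds and
#' integrates the periodogram over the requested band in each window.
#'
#' @param x Numeric trace.
#' @param fs Sampling rate in Hz.
#' @param band `c(low, high)` in Hz; must lie below the Nyquist frequency.
#' @param window_s Window length in seconds (default 1).
#' @return Numeric vector of per-window band powers with attribute
#'   `"window_s"`; window `i` covers `[(i-1), i) * window_s` seconds.
#' @export
band_power <- function(x, fs, band, window_s = 1) {
  if (band[2L] > fs / 2) {
    stop("band upper edge (", band[2L], " Hz) exceeds the Nyquist frequency (",
         fs / 2, " Hz)", call. = FALSE)
  }
  if (band[1L] >= band[2L]) stop("band must satisfy low < high", call. = FALSE)
  win <- round(window_s * fs)
  n_win <- floor(length(x) / win)
  if (n_win < 1L) stop("trace shorter than one window", call. = FALSE)
  freqs <- (seq_len(win %/% 2L)) * fs / win
  sel <- freqs >= band[1L] & freqs <= band[2L]
  m <- matrix(x[seq_len(n_win * win)], nrow = win)
  m <- sweep(m, 2L, colMeans(m))  # remove per-window DC
  P <- Mod(mvfft(m))^2 / (win * fs)  # two-sided periodogram density
  # one-sided: double positive frequencies (rows 2..win/2(+1))
  pw <- 2 * colSums(P[1L + which(sel), , drop = FALSE]) * fs / win
  structure(pw, window_s = window_s)
}

#' Normalize band-power traces to NREM total power
#'
#' Divides every power trace by the scalar mean of the total-band
#' (0.5-30 Hz) power over NREM epochs, the standard reference for comparing
#' ECoG power across recordings.
#'
#' @param powers Named list of per-window power traces (must include
#'   `total`), all on the same window grid.
#' @param hyp A [hypnogram()] containing NREM episodes.
#' @param window_s Window length used to compute the powers.
#' @return List of normalized traces, with the reference scalar as
#'   attribute `"reference"`.
#' @export
normalize_power <- function(powers, hyp, window_s = 1) {
  stopifnot(is.list(powers), "total" %in% names(powers))
  times <- (seq_along(powers$total) - 0.5) * window_s
  lab <- hypnogram_labels(hyp, times)
  nrem <- !is.na(lab) & lab == "NREM"
  if (!any(nrem)) {
    stop("hypnogram contains no NREM epochs; supply an explicit reference ",
         "power instead", call. = FALSE)
  }
  ref <- mean(powers$total[nrem])
  out <- lapply(powers, function(p) p / ref)
  attr(out, "reference") <- ref
  out
}

#' Wakefulness sub-state labels from motion traces
#'
#' Locomotion whenever the wheel trace is above threshold (locomotion
#' comprises whisking, so it has precedence); whisking when only the snout
#' trace is above threshold; quiet otherwise.
#'
#' @param wheel,snout Time-aligned motion traces (mean absolute pixel
#'   difference between consecutive video frames).
#' @param wheel_threshold,snout_threshold Detection thresholds (default 0.5).
#' @return Character vector of per-sample labels.
#' @export
score_wake <- function(wheel, snout, wheel_threshold = 0.5,
                       snout_threshold = 0.5) {
  stopifnot(length(wheel) == length(snout))
  out <- rep("quiet", length(wheel))
  out[snout > snout_threshold] <- "whisking"
  out[wheel > wheel_threshold] <- "locomotion"
  out
}

#' Scoring thresholds for sleep-wake staging
#'
#' All thresholds are relative to per-recording reference statistics, so
#' scoring is invariant to the overall signal scale.
#'
#' @param emg_quantiles EMG RMS quantiles whose geometric midpoint separates
#'   wake from sleep muscle tone.
#' @param sigma_rel Sigma-band fraction of total epoch power above which a
#'   sleep epoch is IS (default 0.17).
#' @param theta_delta Theta/delta power ratio above which a (non-IS) sleep
#'   epoch is REM (default 0.5).
#' @param wheel_threshold,snout_threshold Motion thresholds for wake
#'   sub-states.
#' @param microarousal_max_s Wake intrusions shorter than this (seconds)
#'   flanked by sleep are kept as the host sleep state (default 3).
#' @return List of class `score_thresholds`.
#' @export
score_thresholds <- function(emg_quantiles = c(0.1, 0.9), sigma_rel = 0.17,
                             theta_delta = 0.5, wheel_threshold = 0.5,
                             snout_threshold = 0.5, microarousal_max_s = 3) {
  if (theta_delta <= 0 || sigma_rel <= 0 || sigma_rel >= 1) {
    stop("thresholds out of range", call. = FALSE)
  }
  structure(list(emg_quantiles = emg_quantiles, sigma_rel = sigma_rel,
                 theta_delta = theta_delta,
                 wheel_threshold = wheel_threshold,
                 snout_threshold = snout_threshold,
                 microarousal_max_s = microarousal_max_s),
            class = "score_thresholds")
}

epoch_rms <- function(x, win) {
  n_win <- floor(length(x) / win)
  sqrt(colMeans(matrix(x[seq_len(n_win * win)]^2, nrow = win)))
}

#' Rule-based sleep-wake scoring
#'
#' Scores 1 s epochs from ECoG band powers, EMG tone, and (optionally)
#' motion traces, then assembles contiguous epochs into a hypnogram.
#' Rules: an epoch is wake when EMG RMS is high (above the geometric
#' midpoint of its low/high quantiles) or motion is above threshold; wake
#' epochs are sub-staged by [score_wake()]. Sleep epochs are IS when the
#' sigma-band fraction of epoch power is elevated, otherwise REM when
#' theta/delta exceeds 0.5, otherwise NREM. Labels are smoothed by a
#' 3-epoch majority vote; brief wake intrusions (< `microarousal_max_s`)
#' flanked by sleep are kept as the host sleep state (microarousals are not
#' state changes). Sleep episodes of 30 s or less are flagged excluded.
#'
#' @param ecog,emg Numeric traces sampled at `fs` Hz.
#' @param fs Sampling rate in Hz (>= 100).
#' @param wheel,snout Optional time-aligned motion traces (resampled to
#'   `fs`); without them all wake is labeled quiet.
#' @param epoch_s Epoch length in seconds (default 1).
#' @param thresholds A [score_thresholds()].
#' @param bands A [band_definitions()] list.
#' @param smooth_epochs Width (in epochs) of the centered moving average
#'   applied to the band-power and EMG features before the rules (default
#'   5); stabilizes the noisy 1 s spectral estimates.
#' @return A [hypnogram()], with the per-epoch label vector attached as
#'   attribute `"epoch_labels"`.
#' @export
score_sleep <- function(ecog, emg, fs, wheel = NULL, snout = NULL,
                        epoch_s = 1, thresholds = score_thresholds(),
                        bands = band_definitions(), smooth_epochs = 5L) {
  stopifnot(length(ecog) == length(emg))
  if (fs < 100) stop("`fs` must be at least 100 Hz", call. = FALSE)
  win <- round(epoch_s * fs)
  n_ep <- floor(length(ecog) / win)
  if (n_ep < 3L) stop("recording shorter than 3 epochs", call. = FALSE)
  smooth_epochs <- min(smooth_epochs, n_ep)

  delta <- moving_average(band_power(ecog, fs, bands$delta, epoch_s),
                          smooth_epochs)
  theta <- moving_average(band_power(ecog, fs, bands$theta, epoch_s),
                          smooth_epochs)
  sigma <- moving_average(band_power(ecog, fs, bands$sigma, epoch_s),
                          smooth_epochs)
  total <- moving_average(band_power(ecog, fs, bands$total, epoch_s),
                          smooth_epochs)

  # EMG tone per epoch (highpass at 100 Hz where representable)
  hp_edge <- min(100, 0.4 * fs)
  bf <- signal::butter(2, hp_edge / (fs / 2), type = "high")
  emg_f <- signal::filtfilt(bf, emg)
  emg_rms <- moving_average(epoch_rms(emg_f, win)[seq_len(n_ep)],
                            min(3L, n_ep))

  lq <- quantile(emg_rms, thresholds$emg_quantiles, names = FALSE)
  lq[lq <= 0] <- min(emg_rms[emg_rms > 0], 1e-12)
  emg_thr <- exp(mean(log(lq)))
  # if the EMG distribution is unimodal the recording has a single muscle
  # tone regime; the RMS split is then uninformative and wake is scored
  # from motion alone
  emg_informative <- lq[2L] / lq[1L] >= 2

  motion_wake <- rep(FALSE, n_ep)
  wake_sub <- rep("quiet", n_ep)
  if (!is.null(wheel) && !is.null(snout)) {
    wheel_ep <- epoch_rms(wheel, win)[seq_len(n_ep)]
    snout_ep <- epoch_rms(snout, win)[seq_len(n_ep)]
    motion_wake <- wheel_ep > thresholds$wheel_threshold |
      snout_ep > thresholds$snout_threshold
    wake_sub <- score_wake(wheel_ep, snout_ep, thresholds$wheel_threshold,
                           thresholds$snout_threshold)
  }

  wake <- (emg_informative & emg_rms > emg_thr) | motion_wake
  lab <- character(n_ep)
  lab[wake] <- wake_sub[wake]
  sleep <- !wake
  is_ep <- sleep & (sigma / pmax(total, 1e-300) > thresholds$sigma_rel)
  rem <- sleep & !is_ep &
    (theta / pmax(delta, 1e-300) > thresholds$theta_delta)
  lab[is_ep] <- "IS"
  lab[rem] <- "REM"
  lab[sleep & !is_ep & !rem] <- "NREM"

  # 3-epoch majority smoothing
  smoothed <- lab
  for (i in 2:(n_ep - 1L)) {
    tri <- lab[(i - 1L):(i + 1L)]
    tb <- table(tri)
    if (max(tb) >= 2L) smoothed[i] <- names(tb)[which.max(tb)]
  }

  # brief wake intrusions flanked by sleep stay in the host sleep state
  r <- rle(smoothed %in% wake_states())
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  max_ep <- ceiling(thresholds$microarousal_max_s / epoch_s)
  for (j in seq_along(r$values)) {
    if (r$values[j] && r$lengths[j] <= max_ep && j > 1L &&
        j < length(r$values)) {
      host <- smoothed[starts[j] - 1L]
      if (host %in% sleep_states()) {
        smoothed[starts[j]:ends[j]] <- host
      }
    }
  }

  hyp <- labels_to_hypnogram(smoothed, epoch_s)
  attr(hyp, "epoch_labels") <- smoothed
  attr(hyp, "emg_threshold") <- emg_thr
  hyp
}

#' Microarousal detection from the snout motion trace
#'
#' Finds contiguous above-threshold intervals of the snout (whisker-pad)
#' trace inside NREM episodes and keeps those lasting at least 0.3 s but
#' less than 3 s. Longer intrusions are candidate awakenings, not
#' microarousals.
#'
#' @param snout Motion trace sampled at `fs` Hz.
#' @param fs Sampling rate in Hz.
#' @param hyp A scored [hypnogram()].
#' @param threshold Motion threshold (default 0.5).
#' @param min_s,max_s Duration rule in seconds (default `[0.3, 3)`).
#' @return `data.frame`: `start_s`, `duration_s`, `episode_id` (row of the
#'   host NREM episode in `hyp`).
#' @export
detect_microarousals <- function(snout, fs, hyp, threshold = 0.5,
                                 min_s = 0.3, max_s = 3) {
  above <- snout > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- data.frame(start_s = numeric(), duration_s = numeric(),
                    episode_id = integer())
  nrem_rows <- which(hyp$state == "NREM")
  for (j in which(r$values)) {
    t0 <- (starts[j] - 1L) / fs
    dur <- r$lengths[j] / fs
    if (dur < min_s || dur >= max_s) next
    host <- nrem_rows[hyp$start_s[nrem_rows] <= t0 &
                        hyp$end_s[nrem_rows] >= t0 + dur]
    if (length(host) == 1L) {
      out <- rbind(out, data.frame(start_s = t0, duration_s = dur,
                                   episode_id = host))
    }
  }
  out
}

#' State transitions from a hypnogram
#'
#' Lists every boundary between consecutive episodes. Sleep-to-wake
#' boundaries are flagged as awakenings; with `method = "delta_drop"` and an
#' ECoG trace, each awakening time is refined to the first 1 s window,
#' scanning from 5 s before the scored boundary, in which normalized delta
#' power falls below 50% of the preceding episode's median - an automated
#' surrogate for the first sign of ECoG desynchronization (refined rows are
#' flagged).
#'
#' @param hyp A [hypnogram()].
#' @param ecog Optional ECoG trace (needed for `"delta_drop"`).
#' @param fs ECoG sampling rate in Hz.
#' @param method `"hypnogram"` (boundary times as scored) or
#'   `"delta_drop"`.
#' @return `data.frame`: `from_state`, `to_state`, `time_s`, `awakening`,
#'   `refined`.
#' @export
detect_transitions <- function(hyp, ecog = NULL, fs = NULL,
                               method = c("hypnogram", "delta_drop")) {
  method <- match.arg(method)
  n <- nrow(hyp)
  if (n < 2L) {
    return(data.frame(from_state = character(), to_state = character(),
                      time_s = numeric(), awakening = logical(),
                      refined = logical()))
  }
  out <- data.frame(
    from_state = hyp$state[-n], to_state = hyp$state[-1L],
    time_s = hyp$end_s[-n],
    awakening = hyp$state[-n] %in% sleep_states() &
      hyp$state[-1L] %in% wake_states(),
    refined = FALSE)
  out <- out[out$from_state != out$to_state, , drop = FALSE]
  rownames(out) <- NULL
  if (method == "delta_drop") {
    if (is.null(ecog) || is.null(fs)) {
      stop("`delta_drop` refinement needs `ecog` and `fs`", call. = FALSE)
    }
    delta <- band_power(ecog, fs, band_definitions()$delta, window_s = 1)
    d_times <- seq_along(delta) - 0.5
    for (i in which(out$awakening)) {
      ep <- which(hyp$end_s == out$time_s[i])[1L]
      ref_win <- d_times >= hyp$start_s[ep] & d_times < hyp$end_s[ep]
      if (!any(ref_win)) next
      ref <- median(delta[ref_win])
      scan <- which(d_times >= out$time_s[i] - 5 &
                      d_times <= out$time_s[i] + 5)
      drop_idx <- scan[delta[scan] < 0.5 * ref]
      if (length(drop_idx) > 0L) {
        out$time_s[i] <- d_times[drop_idx[1L]] - 0.5
        out$refined[i] <- TRUE
      }
    }
  }
  out
}

#' Sleep-spindle detection (bandpass-Hilbert)
#'
#' Bandpass-filters the (normalized) ECoG in the sigma band with a
#' second-order zero-phase Butterworth filter (forward-backward), takes the
#' instantaneous amplitude from the Hilbert analytic signal, smooths it with
#' a Gaussian (sigma 0.2 s), and treats above-threshold envelope peaks as
#' putative spindles. Candidates whose width at the threshold level is
#' below 0.5 s or above 5 s are discarded.
#'
#' @param ecog Normalized ECoG trace.
#' @param fs Sampling rate in Hz (> 32).
#' @param threshold Envelope threshold; `NULL` (default) uses
#'   median + 2.5 MAD of the smoothed envelope within each scored episode
#'   (a robust scale: the spindles themselves inflate a plain SD and would
#'   push the threshold up with the spindle density).
#' @param episodes Optional `data.frame` with `start_s`, `end_s`: restrict
#'   detection (and the default threshold statistics) to these episodes,
#'   e.g. scored NREM/IS sleep. Without it the whole trace is one episode.
#' @param band Spindle band in Hz (default 10-16).
#' @param smooth_sigma_s Envelope smoothing sigma in seconds (default 0.2).
#' @param width_range_s Allowed width-at-threshold range in seconds
#'   (default 0.5-5).
#' @return `data.frame`: `start_s`, `end_s`, `peak_time_s`,
#'   `peak_amplitude`, `freq_hz` (zero-crossing frequency of the bandpassed
#'   segment), with the per-episode thresholds as attribute
#'   `"thresholds"`.
#' @export
detect_spindles <- function(ecog, fs, threshold = NULL, episodes = NULL,
                            band = c(10, 16), smooth_sigma_s = 0.2,
                            width_range_s = c(0.5, 5)) {
  if (fs <= 32) stop("`fs` must exceed 32 Hz", call. = FALSE)
  if (!is.null(threshold) && threshold <= 0) {
    stop("`threshold` must be positive", call. = FALSE)
  }
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, ecog)
  env <- Mod(analytic_signal(bp))
  env <- gauss_smooth(env, smooth_sigma_s * fs)
  n <- length(env)
  if (is.null(episodes)) {
    episodes <- data.frame(start_s = 0, end_s = n / fs)
  }

  out <- data.frame(start_s = numeric(), end_s = numeric(),
                    peak_time_s = numeric(), peak_amplitude = numeric(),
                    freq_hz = numeric())
  thrs <- numeric(nrow(episodes))
  for (e in seq_len(nrow(episodes))) {
    e0 <- max(1L, floor(episodes$start_s[e] * fs) + 1L)
    e1 <- min(n, ceiling(episodes$end_s[e] * fs))
    if (e1 <= e0) { thrs[e] <- NA_real_; next }
    env_e <- env[e0:e1]
    thr <- threshold %||% (median(env_e) + 2.5 * stats::mad(env_e))
    thrs[e] <- thr
    r <- rle(env_e > thr)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    for (j in which(r$values)) {
      width <- r$lengths[j] / fs
      if (width < width_range_s[1L] || width > width_range_s[2L]) next
      i0 <- e0 - 1L + starts[j]
      i1 <- e0 - 1L + ends[j]
      pk <- i0 - 1L + which.max(env[i0:i1])
      seg <- bp[i0:i1]
      zc <- sum(diff(sign(seg)) != 0)
      freq <- zc / 2 / width
      out <- rbind(out, data.frame(
        start_s = (i0 - 1L) / fs, end_s = i1 / fs,
        peak_time_s = (pk - 1L) / fs, peak_amplitude = env[pk],
        freq_hz = freq))
    }
  }
  attr(out, "thresholds") <- thrs
  out
}
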