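# Band power, scoring rules, microarousals, transitions, spindles.

test_that("band power concentrates, scales, and tracks bandwidth", {
  fs <- 500
  tt <- seq(0, 10 - 1 / fs, 1 / fs)
  x <- sin(2 * pi * 2 * tt)
  dl <- band_power(x, fs, c(0.5, 4), window_s = 10)
  tot <- band_power(x, fs, c(0.5, 30), window_s = 10)
  expect_gt(dl / tot, 0.95)
  expect_equal(unclass(tot), 0.5, tolerance = 0.02, ignore_attr = TRUE)
  # amplitude x2 -> power x4
  expect_equal(as.numeric(band_power(2 * x, fs, c(0.5, 4), 10)) /
                 as.numeric(dl), 4, tolerance = 1e-6)
  # white noise: band power proportional to bandwidth
  set.seed(1)
  w <- rnorm(fs * 200)
  p1 <- mean(band_power(w, fs, c(10, 20), window_s = 10))
  p2 <- mean(band_power(w, fs, c(10, 40), window_s = 10))
  expect_equal(p2 / p1, 3, tolerance = 0.1)
  expect_error(band_power(x, fs, c(10, 300)), "Nyquist")
})

test_that("normalization divides by the NREM total power scalar", {
  fs <- 250
  sch <- data.frame(state = c("NREM", "REM"), duration_s = c(60, 60))
  ph <- generate_physiology(sch, sampling_rate = fs, seed = 4)
  hyp <- ph$hypnogram_truth
  powers <- list(total = band_power(ph$ecog, fs, c(0.5, 30), 1),
                 delta = band_power(ph$ecog, fs, c(0.5, 4), 1))
  np <- normalize_power(powers, hyp, 1)
  lab <- hypnogram_labels(hyp, (seq_along(np$total) - 0.5))
  expect_equal(mean(np$total[lab == "NREM"]), 1)
  # scaling the raw signal changes nothing after normalization
  np2 <- normalize_power(lapply(powers, function(p) 9 * p), hyp, 1)
  expect_equal(unclass(np2$delta), unclass(np$delta))
  # already-normalized input is the identity
  np3 <- normalize_power(np, hyp, 1)
  expect_equal(unclass(np3$total), unclass(np$total))
  expect_error(normalize_power(powers, hyp[hyp$state == "REM", ], 1),
               "NREM")
})

test_that("wake sub-states follow the locomotion-precedence rules", {
  wheel <- c(1, 1, 0, 0)
  snout <- c(1, 0, 1, 0)
  expect_equal(score_wake(wheel, snout),
               c("locomotion", "locomotion", "whisking", "quiet"))
})

test_that("single-state segments score as constructed", {
  fs <- 500
  ph_n <- generate_physiology(data.frame(state = "NREM", duration_s = 60),
                              sampling_rate = fs, seed = 6)
  hyp_n <- score_sleep(ph_n$ecog, ph_n$emg, fs)
  lab_n <- attr(hyp_n, "epoch_labels")
  expect_gt(mean(lab_n == "NREM"), 0.9)

  ph_r <- generate_physiology(data.frame(state = "REM", duration_s = 60),
                              sampling_rate = fs, seed = 6)
  hyp_r <- score_sleep(ph_r$ecog, ph_r$emg, fs)
  expect_gt(mean(attr(hyp_r, "epoch_labels") == "REM"), 0.9)
})

test_that("scoring recovers the ground-truth hypnogram on full sessions", {
  sch <- data.frame(
    state = c("quiet", "locomotion", "whisking", "NREM", "IS", "REM",
              "NREM"),
    duration_s = c(40, 30, 30, 150, 60, 90, 100))
  for (s in 1:3) {
    ph <- generate_physiology(sch, seed = s)
    hyp <- score_sleep(ph$ecog, ph$emg, ph$sampling_rate,
                       wheel = ph$wheel, snout = ph$snout)
    expect_gt(hypnogram_accuracy(ph$hypnogram_truth, hyp), 0.9)
  }
})

test_that("microarousals obey the 0.3-3 s rule inside NREM", {
  fs <- 100
  hyp <- hypnogram(c("quiet", "NREM", "quiet"), c(0, 60, 260), c(60, 260, 280))
  snout <- numeric(280 * fs)
  put <- function(t0, dur) {
    i <- (round(t0 * fs) + 1):(round((t0 + dur) * fs))
    snout[i] <<- 1
  }
  put(100, 1)     # microarousal
  put(120, 0.2)   # too short
  put(140, 5)     # too long (candidate awakening)
  put(20, 1)      # in wake, not counted
  put(200, 0.3)   # exactly at the lower bound: counted
  ma <- detect_microarousals(snout, fs, hyp, threshold = 0.5)
  expect_equal(nrow(ma), 2L)
  expect_equal(sort(ma$start_s), c(100, 200))
  expect_true(all(ma$duration_s >= 0.3 & ma$duration_s < 3))
  expect_true(all(ma$episode_id == 2L))
})

test_that("microarousal counts match a brute-force interval scan", {
  fs <- 50
  set.seed(7)
  for (rep in 1:10) {
    hyp <- hypnogram(c("NREM", "REM", "NREM"), c(0, 100, 150),
                     c(100, 150, 300))
    snout <- runif(300 * fs) < 0.02
    snout <- as.numeric(snout)
    ma <- detect_microarousals(snout, fs, hyp, threshold = 0.5)
    # oracle: scan runs of above-threshold samples
    r <- rle(snout > 0.5)
    ends <- cumsum(r$lengths)
    starts <- c(1, head(ends, -1) + 1)
    n_expect <- 0
    for (j in which(r$values)) {
      dur <- r$lengths[j] / fs
      t0 <- (starts[j] - 1) / fs
      in_nrem <- (t0 >= 0 & t0 + dur <= 100) | (t0 >= 150 & t0 + dur <= 300)
      if (dur >= 0.3 && dur < 3 && in_nrem) n_expect <- n_expect + 1
    }
    expect_equal(nrow(ma), n_expect)
  }
})

test_that("transitions are enumerated and awakenings flagged", {
  hyp <- hypnogram(c("NREM", "IS", "REM", "locomotion"),
                   c(0, 100, 150, 250), c(100, 150, 250, 300))
  tr <- detect_transitions(hyp)
  expect_equal(nrow(tr), 3L)
  expect_equal(sum(tr$awakening), 1L)
  expect_equal(tr$time_s, c(100, 150, 250))
  expect_equal(nrow(detect_transitions(hypnogram("NREM", 0, 100))), 0L)
})

test_that("awakening onset is refined to the delta-power drop", {
  fs <- 250
  # NREM-like delta activity that collapses 0.5 s before the scored boundary
  set.seed(8)
  bf <- signal::butter(2, c(0.5, 4) / (fs / 2), "pass")
  delta_sig <- signal::filtfilt(bf, rnorm(110 * fs))
  ecog <- delta_sig
  drop_at <- 99.5
  ecog[(round(drop_at * fs) + 1):length(ecog)] <- 0.05 *
    rnorm(length(ecog) - round(drop_at * fs))
  hyp <- hypnogram(c("NREM", "quiet"), c(0, 100), c(100, 110))
  tr <- detect_transitions(hyp, ecog, fs, method = "delta_drop")
  expect_true(tr$refined[1])
  expect_equal(tr$time_s[1], drop_at, tolerance = 1)
})

test_that("spindle detection honors the width and band rules exactly", {
  fs <- 500
  tt <- seq(0, 60 - 1 / fs, 1 / fs)
  set.seed(9)
  base <- 0.05 * rnorm(length(tt))
  burst <- function(x, t0, dur, f, amp = 1) {
    i <- which(tt >= t0 & tt < t0 + dur)
    ph <- tt[i] - t0
    x[i] <- x[i] + amp * 0.5 * (1 - cos(2 * pi * ph / dur)) *
      sin(2 * pi * f * ph)
    x
  }
  x1 <- burst(base, 30, 1.0, 13)
  sp1 <- detect_spindles(x1, fs, threshold = 0.3)
  expect_equal(nrow(sp1), 1L)
  expect_equal(sp1$peak_time_s, 30.5, tolerance = 0.1)
  expect_equal(sp1$end_s - sp1$start_s, 1.0, tolerance = 0.3)
  expect_gt(sp1$freq_hz, 10)
  expect_lt(sp1$freq_hz, 16)

  # 0.3 s burst: width at threshold below the 0.5 s minimum
  x2 <- burst(base, 30, 0.3, 13)
  expect_equal(nrow(detect_spindles(x2, fs, threshold = 0.3)), 0L)

  # out-of-band 25 Hz burst: attenuated below threshold by the bandpass
  x3 <- burst(base, 30, 1.0, 25)
  expect_equal(nrow(detect_spindles(x3, fs, threshold = 0.3)), 0L)

  # very long burst: width above 5 s is discarded
  x4 <- burst(base, 20, 8, 13)
  expect_equal(nrow(detect_spindles(x4, fs, threshold = 0.3)), 0L)
})

test_that("detected spindles always satisfy the event invariants", {
  fs <- 500
  ph <- generate_physiology(data.frame(state = "IS", duration_s = 180),
                            sampling_rate = fs, spindle_rate_is = 5,
                            seed = 10)
  sp <- detect_spindles(ph$ecog, fs)
  expect_gt(nrow(sp), 0L)
  widths <- sp$end_s - sp$start_s
  expect_true(all(widths >= 0.5 & widths <= 5))
  expect_true(all(sp$peak_time_s >= sp$start_s & sp$peak_time_s <= sp$end_s))
})

test_that("spindle recall is complete for prominent bursts", {
  # the width-at-threshold rule intrinsically discards 0.5 s bursts whose
  # smoothed envelope barely clears the threshold, so recall is stratified
  # by envelope SNR: complete above 8 dB, partial near the 6 dB floor
  fs <- 500
  det <- logical(); snr <- numeric(); fp <- 0L; n_det <- 0L
  for (s in 1:5) {
    ph <- generate_physiology(data.frame(state = "IS", duration_s = 120),
                              sampling_rate = fs, spindle_rate_is = 4,
                              seed = s)
    bf <- signal::butter(2, c(10, 16) / (fs / 2), "pass")
    env <- gauss_smooth(Mod(roawake:::analytic_signal(
      signal::filtfilt(bf, ph$ecog))), 0.2 * fs)
    bg <- median(env)
    sp <- detect_spindles(ph$ecog, fs)
    n_det <- n_det + nrow(sp)
    truth <- ph$spindle_truth
    hit <- rep(FALSE, nrow(sp))
    for (i in seq_len(nrow(truth))) {
      i0 <- floor(truth$start_s[i] * fs) + 1
      i1 <- min(length(env), ceiling(truth$end_s[i] * fs))
      snr <- c(snr, max(env[i0:i1]) / bg)
      ov <- sp$end_s > truth$start_s[i] & sp$start_s < truth$end_s[i]
      det <- c(det, any(ov))
      if (any(ov)) hit[ov] <- TRUE
    }
    fp <- fp + sum(!hit)
  }
  strong <- snr >= 2.5  # ~8 dB envelope SNR
  expect_gt(sum(strong), 10)
  expect_gte(mean(det[strong]), 0.95)
  expect_gte(mean(det[snr >= 2]), 0.85)          # near the 6 dB floor
  expect_gte(1 - fp / n_det, 0.9)                # precision
})
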