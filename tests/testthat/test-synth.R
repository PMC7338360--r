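# Synthetic data generator: determinism, event placement, Poisson rate
# calibration, and the spectral structure of the generated physiology.

test_that("zero event rate yields an empty truth table and a flat movie", {
  cfg <- quiet_config(rate = 0, noise_sigma = 0, drift_amplitude = 0,
                      vessel_mask_fraction = 0)
  out <- generate_movie(cfg)
  expect_equal(nrow(out$truth), 0L)
  expect_true(all(out$movie$data == cfg$baseline_level))
})

test_that("a noiseless event exceeds half-max exactly on its blob support", {
  # seed chosen to give exactly one event at the configured low rate
  cfg <- quiet_config(rate = 0.1, duration_s = 60, noise_sigma = 0,
                      vessel_mask_fraction = 0, event_sigma_xy = 3,
                      seed = 5L)
  out <- generate_movie(cfg)
  expect_equal(nrow(out$truth), 1L)
  tr <- out$truth
  peak_frame <- which.max(apply(out$movie$data, 3L, max))
  above_half <- out$movie$data[, , peak_frame] >
    cfg$baseline_level * (1 + tr$amplitude / 2)
  # half-max support area matches the recorded truth footprint
  expect_equal(sum(above_half) * cfg$pixel_size^2, tr$footprint_area_um2)
  r_half <- tr$sigma_px * sqrt(2 * log(2))
  xy <- which(above_half, arr.ind = TRUE)
  dd <- sqrt((xy[, 1] - 1 - tr$cx)^2 + (xy[, 2] - 1 - tr$cy)^2)
  expect_true(all(dd <= r_half + 1e-9))
})

test_that("truth event half-max supports avoid the vessel mask", {
  cfg <- quiet_config(rate = 2, duration_s = 60, vessel_mask_fraction = 0.25,
                      event_sigma_xy = 2, seed = 9L)
  out <- generate_movie(cfg)
  expect_gt(nrow(out$truth), 0L)
  for (i in seq_len(nrow(out$truth))) {
    tr <- out$truth[i, ]
    r_half <- tr$sigma_px * sqrt(2 * log(2))
    xs <- pmax(1, ceiling(tr$cx - r_half + 1)):pmin(32, floor(tr$cx + r_half + 1))
    ys <- pmax(1, ceiling(tr$cy - r_half + 1)):pmin(32, floor(tr$cy + r_half + 1))
    dd <- outer((xs - 1 - tr$cx)^2, (ys - 1 - tr$cy)^2, "+")
    expect_false(any(out$vessel_mask[xs, ys][dd <= r_half^2]))
  }
})

test_that("the generator is bytewise deterministic in the seed", {
  cfg <- quiet_config(rate = 1.5, duration_s = 20, seed = 42L)
  a <- generate_movie(cfg)
  b <- generate_movie(cfg)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth, b$truth)
  ph1 <- generate_physiology(data.frame(state = "NREM", duration_s = 30),
                             seed = 7L)
  ph2 <- generate_physiology(data.frame(state = "NREM", duration_s = 30),
                             seed = 7L)
  expect_identical(ph1$ecog, ph2$ecog)
  expect_identical(ph1$emg, ph2$emg)
})

test_that("event counts are Poisson with the configured rate", {
  # 10 x 10 px at 1 um/px = 100 um^2; rate 20 events/100 um^2/min over
  # 1 min -> mean 20 per replicate
  counts <- vapply(1:200, function(s) {
    cfg <- simulation_config(
      image_shape = c(10L, 10L),
      state_schedule = data.frame(state = "quiet", duration_s = 60),
      event_rate_per_state = c(quiet = 20), noise_sigma = 0,
      event_sigma_xy = 1, vessel_mask_fraction = 0, seed = s)
    nrow(generate_movie(cfg)$truth)
  }, numeric(1L))
  expect_equal(mean(counts), 20, tolerance = 0.05)
  # chi-square goodness of fit against Poisson(20) on pooled count bins
  brks <- c(-Inf, 14, 17, 20, 23, 26, Inf)
  obs <- table(cut(counts, brks))
  p <- diff(ppois(c(-Inf, 14, 17, 20, 23, 26, Inf), 20))
  gof <- chisq.test(as.numeric(obs), p = p)
  expect_gt(gof$p.value, 0.01)
})

test_that("generated ECoG obeys the scoring definitions by construction", {
  fs <- 500
  ph_n <- generate_physiology(data.frame(state = "NREM", duration_s = 60),
                              sampling_rate = fs, seed = 3L)
  # delta dominates theta in every 10 s window of NREM
  for (w in seq_len(6)) {
    idx <- ((w - 1) * 10 * fs + 1):(w * 10 * fs)
    dl <- band_power(ph_n$ecog[idx], fs, c(0.5, 4), window_s = 10)
    th <- band_power(ph_n$ecog[idx], fs, c(5, 9), window_s = 10)
    expect_gt(dl, th)
  }
  ph_r <- generate_physiology(data.frame(state = "REM", duration_s = 60),
                              sampling_rate = fs, seed = 3L)
  dl <- band_power(ph_r$ecog, fs, c(0.5, 4), window_s = 60)
  th <- band_power(ph_r$ecog, fs, c(5, 9), window_s = 60)
  expect_gt(th / dl, 0.5)
  # REM muscle tone below NREM
  expect_lt(sd(ph_r$emg), sd(ph_n$emg))
})

test_that("generated spindles sit in the sigma band at the configured rate", {
  fs <- 500
  counts <- vapply(1:30, function(s) {
    ph <- generate_physiology(data.frame(state = "IS", duration_s = 120),
                              sampling_rate = fs, spindle_rate_is = 3,
                              seed = s)
    nrow(ph$spindle_truth)
  }, numeric(1L))
  expect_equal(mean(counts), 6, tolerance = 0.2)
  ph <- generate_physiology(data.frame(state = "IS", duration_s = 120),
                            sampling_rate = fs, spindle_rate_is = 3,
                            seed = 2L)
  expect_gt(nrow(ph$spindle_truth), 0L)
  for (i in seq_len(nrow(ph$spindle_truth))) {
    expect_gte(ph$spindle_truth$freq_hz[i], 10)
    expect_lte(ph$spindle_truth$freq_hz[i], 16)
    # spectral peak of the burst segment lies in the sigma band
    i0 <- floor(ph$spindle_truth$start_s[i] * fs) + 1
    i1 <- min(length(ph$ecog), ceiling(ph$spindle_truth$end_s[i] * fs))
    seg <- ph$ecog[i0:i1]
    spec <- Mod(fft(seg * (0.5 - 0.5 * cos(2 * pi * seq_along(seg) /
                                             length(seg)))))^2
    freqs <- (seq_along(seg) - 1) * fs / length(seg)
    keep <- freqs > 2 & freqs < fs / 2
    pk <- freqs[keep][which.max(spec[keep])]
    expect_gte(pk, 10)
    expect_lte(pk, 16)
  }
})

test_that("session assembly is consistent and deterministic", {
  cfg <- simulation_config(
    image_shape = c(16L, 16L),
    state_schedule = data.frame(state = "quiet", duration_s = 10),
    event_rate_per_state = c(quiet = 0.5), seed = 21L)
  s1 <- generate_session(cfg)
  expect_equal(dim(s1$movie$data)[3L], 300L)  # 10 s at 30 Hz
  expect_equal(as.data.frame(s1$hypnogram_truth),
               as.data.frame(schedule_to_hypnogram(cfg$state_schedule)))
  s2 <- generate_session(cfg)
  expect_identical(s1$movie$data, s2$movie$data)
  expect_identical(s1$physio$ecog, s2$physio$ecog)
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(simulation_config(image_shape = c(2, 2)), "image_shape")
  expect_error(quiet_config(rate = -1), "event_rate_per_state")
  expect_error(quiet_config(noise_sigma = -2), "noise_sigma")
  expect_error(simulation_config(
    state_schedule = data.frame(state = "napping", duration_s = 5)),
    "state label")
  expect_error(quiet_config(duration_s = 10, n_frames = 500), "n_frames")
  expect_error(generate_physiology(
    data.frame(state = "napping", duration_s = 5)), "state label")
})
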