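# Core ROA algorithm stages, each against closed forms or brute-force
# oracles, then the composed pipeline on constructed movies.

mk_movie <- function(data, pixel_size = 1, frame_rate = 30) {
  movie_stack(data, pixel_size, frame_rate)
}

test_that("spatial smoothing: identity, impulse kernel, constants, mass", {
  set.seed(1)
  m <- mk_movie(array(rnorm(16 * 16 * 4, 100), c(16, 16, 4)))
  expect_identical(spatial_smooth(m, 0)$data, m$data)

  imp <- array(0, c(33, 33, 2))
  imp[17, 17, 1] <- 1
  sm <- spatial_smooth(mk_movie(imp), 2)
  # closed form: center weight of the normalized discrete Gaussian
  half <- 8
  g <- exp(-(-half:half)^2 / (2 * 4))
  k <- outer(g, g) / sum(outer(g, g))
  expect_equal(sm$data[17, 17, 1], k[half + 1, half + 1], tolerance = 1e-12)
  expect_equal(sum(sm$data[, , 1]), 1, tolerance = 1e-9)   # mass preserved
  expect_equal(max(abs(sm$data[, , 2])), 0)                 # frames separate

  const <- mk_movie(array(7, c(12, 12, 3)))
  expect_equal(spatial_smooth(const, 2)$data, const$data, tolerance = 1e-12)
})

test_that("baseline is the per-pixel mode of the lowpass series", {
  const <- mk_movie(array(3.5, c(6, 6, 90)))
  bl <- compute_baseline(const, 1.0)
  expect_equal(bl$f0, matrix(3.5, 6, 6))
  expect_equal(bl$L_filt, 30L)

  # pixel at 1.0 for 90% of frames with sparse excursions to 3.0
  set.seed(2)
  nt <- 3000
  tr <- rep(1, nt)
  tr[sample(nt, nt / 10)] <- 3
  a <- array(rep(tr, each = 4), c(2, 2, nt))
  bl2 <- compute_baseline(mk_movie(a), 1.0)
  # oracle: dense-histogram mode of the smoothed trace
  sm_tr <- as.numeric(moving_average(tr, 30))
  dens <- hist(sm_tr, breaks = 200, plot = FALSE)
  oracle <- dens$mids[which.max(dens$counts)]
  expect_equal(bl2$f0[1, 1], oracle, tolerance = 0.1)
  expect_lt(abs(bl2$f0[1, 1] - 1.0), 0.3)
})

test_that("moving average of unit-variance noise has SD ~ 1/sqrt(L)", {
  set.seed(3)
  x <- rnorm(1e5)
  sm <- moving_average(x, 30)
  interior <- !attr(sm, "edge")
  expect_equal(sd(sm[interior]), 1 / sqrt(30), tolerance = 0.1)
})

test_that("dF/F0 arithmetic and baseline flooring", {
  f0 <- matrix(10, 4, 4)
  m <- mk_movie(array(12, c(4, 4, 5)))
  s <- compute_dff(m, f0)
  expect_equal(unique(as.numeric(s$data)), 0.2)
  expect_equal(attr(s, "n_floored"), 0L)
  s2 <- compute_dff(mk_movie(array(rep(f0, 5), c(4, 4, 5))), f0)
  expect_true(all(s2$data == 0))
  s3 <- compute_dff(mk_movie(array(2 * rep(f0, 5), c(4, 4, 5))), f0)
  expect_true(all(s3$data == 1))
  # a non-positive baseline pixel is floored and counted
  f0b <- f0
  f0b[1, 1] <- 0
  s4 <- compute_dff(m, f0b)
  expect_equal(attr(s4, "n_floored"), 1L)
  expect_true(all(is.finite(s4$data)))
})

test_that("noise map recovers sigma0 * sqrt(1 - 1/L) / sqrt(L) on iid noise", {
  set.seed(4)
  sigma0 <- 0.35
  a <- array(rnorm(8 * 8 * 3000, sd = sigma0), c(8, 8, 3000))
  nz <- estimate_noise(mk_movie(a), 1.0)
  L <- nz$L_filt
  expected <- sigma0 * sqrt(1 - 1 / L) / sqrt(L)
  expect_equal(mean(nz$sigma), expected, tolerance = 0.1)
  expect_true(all(abs(nz$sigma - expected) / expected < 0.25))
  # scale equivariance: doubling the noise doubles the map
  nz2 <- estimate_noise(mk_movie(2 * a), 1.0)
  expect_equal(nz2$sigma, 2 * nz$sigma, tolerance = 1e-12)
  # constant input is degenerate
  nzc <- estimate_noise(mk_movie(array(1, c(3, 3, 60))), 1.0)
  expect_true(all(nzc$sigma == 0))
  expect_equal(nzc$n_degenerate, 9L)
})

test_that("detrending removes slow trends per the moving-average response", {
  fr <- 30
  nt <- 3000
  ramp <- array(rep(seq(0, 1, length.out = nt), each = 4), c(2, 2, nt))
  bp <- detrend(mk_movie(ramp, frame_rate = fr), 10)
  interior <- 200:(nt - 200)
  # an even window is half a sample asymmetric, leaving at most slope/2
  expect_lt(max(abs(bp$data[1, 1, interior])), 1 / (nt - 1))
  expect_true(all(detrend(mk_movie(array(5, c(2, 2, nt))), 10)$data == 0))

  # closed-form moving-average frequency response H(f) = sin(pi f L / fs) /
  # (L sin(pi f / fs)); the residual after subtraction has gain 1 - H
  L <- 300
  tt <- (seq_len(nt) - 1) / fr
  for (f in c(0.02, 2)) {
    x <- array(rep(sin(2 * pi * f * tt), each = 1), c(1, 1, nt))
    y <- detrend(mk_movie(x, frame_rate = fr), 10)
    h <- sin(pi * f * L / fr) / (L * sin(pi * f / fr))
    gain <- sd(y$data[1, 1, interior]) / sd(x[1, 1, interior])
    expect_equal(gain, abs(1 - h), tolerance = 0.05)
  }
  # the slow component is attenuated far more than the fast one:
  # residual gains |1 - H| of ~0.06 (slow) vs ~1 (fast)
  h_slow <- sin(pi * 0.02 * L / fr) / (L * sin(pi * 0.02 / fr))
  h_fast <- sin(pi * 2 * L / fr) / (L * sin(pi * 2 / fr))
  expect_gt(abs(1 - h_fast) / abs(1 - h_slow), 10)
})

test_that("thresholding is exact, one-sided, monotone in k, and masked", {
  set.seed(5)
  sigma <- matrix(0.1, 4, 4)
  below <- mk_movie(array(0.3, c(4, 4, 10)))
  expect_false(any(threshold_activity(below, sigma, 5)))
  s_bp <- mk_movie(array(rnorm(4 * 4 * 50), c(4, 4, 50)))
  m4 <- threshold_activity(s_bp, matrix(0.5, 4, 4), 4)
  m5 <- threshold_activity(s_bp, matrix(0.5, 4, 4), 5)
  expect_true(all(m5 <= m4))  # k = 5 mask subset of k = 4 mask
  ig <- matrix(FALSE, 4, 4)
  ig[2, 3] <- TRUE
  mm <- threshold_activity(s_bp, matrix(0, 4, 4), 5, ignore_mask = ig)
  expect_false(any(mm[2, 3, ]))
  expect_true(all(mm[1, 1, ] == (s_bp$data[1, 1, ] > 0)))
  expect_error(threshold_activity(s_bp, sigma, 0), "k")
})

test_that("Gaussian tail: k = 5 exceedance on pure noise is ~ 2.9e-7", {
  set.seed(6)
  n <- 1e7
  s_bp <- mk_movie(array(rnorm(n), c(100, 100, 1000)))
  frac <- mean(threshold_activity(s_bp, matrix(1, 100, 100), 5))
  expect_lt(frac, 1e-4)
  # consistent with the analytic one-sided bound
  expect_lt(abs(frac - pnorm(5, lower.tail = FALSE)), 3e-6)
})

test_that("single-voxel and face-adjacent events have exact descriptors", {
  m <- array(FALSE, c(8, 8, 6))
  m[3, 4, 2] <- TRUE
  ev <- extract_roas(m, pixel_size = 1, frame_rate = 30)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration_s, 1 / 30)
  expect_equal(ev$footprint_area_um2, 1)
  expect_equal(ev$volume_um2s, 1 / 30)
  expect_equal(ev$start_frame, 1L)  # 0-based

  m[3, 4, 3] <- TRUE  # face-adjacent in time
  for (conn in c(6L, 26L)) {
    ev2 <- extract_roas(m, 1, 30, connectivity = conn)
    expect_equal(nrow(ev2), 1L)
    expect_equal(ev2$n_voxels, 2L)
    expect_equal(ev2$duration_s, 2 / 30)
    expect_equal(ev2$footprint_area_um2, 1)
  }
})

test_that("component labeling matches the flood-fill oracle", {
  set.seed(7)
  for (rep in 1:100) {
    mask <- array(runif(16 * 16 * 20) < 0.1, c(16, 16, 20))
    conn <- if (rep %% 2 == 0) 6L else 26L
    ev <- extract_roas(mask, 1, 30, connectivity = conn)
    ours <- label_sets(attr(ev, "labels"))
    oracle <- label_sets(flood_fill_oracle(mask, conn))
    expect_identical(ours, oracle)
    # conservation: events partition the active voxels
    expect_equal(sum(ev$n_voxels), sum(mask))
  }
})

test_that("footprint modes: union vs maximal instantaneous area", {
  m <- array(FALSE, c(6, 6, 4))
  m[1:3, 1, 1] <- TRUE   # 3 px in frame 1
  m[3:4, 1, 2] <- TRUE   # overlaps, drifts: union 4 px, max frame 3 px
  ev_u <- extract_roas(m, 1, 30, footprint = "union")
  ev_m <- extract_roas(m, 1, 30, footprint = "max_frame")
  expect_equal(ev_u$footprint_area_um2, 4)
  expect_equal(ev_m$footprint_area_um2, 3)
})

test_that("noiseless blob yields exactly one event overlapping the truth", {
  cfg <- quiet_config(rate = 0.1, duration_s = 60, noise_sigma = 1e-3,
                      vessel_mask_fraction = 0, event_sigma_xy = 3,
                      seed = 5L)
  out <- generate_movie(cfg)
  expect_equal(nrow(out$truth), 1L)
  det <- roa_detect(out$movie)
  # one dominant event covering the truth footprint
  main <- det$events[which.max(det$events$n_voxels), ]
  tr <- out$truth[1L, ]
  expect_true(main$x0 <= tr$cx && main$x1 >= tr$cx &&
                main$y0 <= tr$cy && main$y1 >= tr$cy)
  expect_true(main$t0 <= tr$end_frame && main$t1 >= tr$start_frame)
})

test_that("detection is deterministic and monotone in k", {
  cfg <- quiet_config(rate = 1, duration_s = 30, seed = 8L)
  out <- generate_movie(cfg)
  d1 <- roa_detect(out$movie, ignore_mask = out$vessel_mask)
  d2 <- roa_detect(out$movie, ignore_mask = out$vessel_mask)
  expect_identical(d1$events, d2$events)
  d_k4 <- roa_detect(out$movie, roa_params(k = 4),
                     ignore_mask = out$vessel_mask)
  expect_gte(nrow(d_k4$events), nrow(d1$events))
  expect_gte(sum(d_k4$active), sum(d1$active))
  # conservation through the full pipeline
  expect_equal(sum(d1$events$n_voxels), sum(d1$active))
  # no active voxels inside the ignore mask
  expect_false(any(d1$active & array(out$vessel_mask, dim(d1$active))))
})

test_that("degenerate parameters are rejected", {
  expect_error(roa_params(k = 0), "k")
  expect_error(roa_params(baseline_window_s = 0), "baseline_window_s")
  expect_error(roa_params(drift_window_s = 0.5), "drift_window_s")
  expect_error(roa_params(connectivity = 18), "connectivity")
  m <- mk_movie(array(1, c(4, 4, 10)))
  expect_error(compute_baseline(m, 5), "recording length")
  expect_error(movie_stack(array(c(NA, rep(1, 31)), c(4, 4, 2)), 1, 30),
               "finite")
})
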