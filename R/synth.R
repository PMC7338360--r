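# Ground-truthed synthetic data: fluorescence movies with Gaussian-blob
# Ca2+ events placed at state-dependent Poisson rates, plus ECoG/EMG/motion
# traces consistent with the same state schedule, so every downstream stage
# can be tested against known truth.

default_state_schedule <- function() {
  data.frame(
    state = c("quiet", "locomotion", "whisking", "quiet", "NREM", "IS",
              "REM", "NREM"),
    duration_s = c(30, 20, 20, 50, 120, 40, 60, 60))
}

default_event_rates <- function() {
  c(locomotion = 4, whisking = 2, quiet = 1, NREM = 0.23, IS = 0.23,
    REM = 0.35)
}

#' Simulation configuration
#'
#' Defines one synthetic imaging session: field geometry, acquisition rate,
#' the behavioral state schedule, per-state Ca2+ event rates, event
#' morphology, and the noise model. Defaults emulate a 30 Hz two-photon
#' acquisition with wakefulness event rates several-fold above sleep rates.
#'
#' @param image_shape Field size in pixels, length-2 integer (default 64x64).
#' @param frame_rate Acquisition rate in Hz (default 30).
#' @param pixel_size Pixel size in um/px (default 1).
#' @param state_schedule `data.frame` with columns `state`, `duration_s`;
#'   states from [state_levels()].
#' @param n_frames Total frames; defaults to the schedule duration times the
#'   frame rate, and must agree with it within one frame if given.
#' @param event_rate_per_state Named numeric, events per 100 um^2 per minute
#'   for each state in the schedule (rates apply to the non-vessel area).
#' @param event_amplitude Peak event amplitude in dF/F0 units (default 1).
#' @param event_sigma_xy Spatial Gaussian sigma of events in um (default 4).
#' @param event_duration_range Event duration range in seconds (default
#'   0.5-3 s, uniform).
#' @param baseline_level Baseline fluorescence in a.u. (default 100).
#' @param noise_sigma SD of additive i.i.d. Gaussian noise in a.u. (default
#'   5, i.e. 0.05 dF/F0 units at the default baseline).
#' @param shot_noise Add Poisson shot noise on top of the Gaussian term
#'   (default `FALSE`).
#' @param drift_amplitude Amplitude of a slow sinusoidal drift in a.u.
#'   (default 0); `drift_freq_hz` sets its frequency.
#' @param drift_freq_hz Drift frequency in Hz (default 0.02).
#' @param vessel_mask_fraction Fraction of the field covered by the vessel
#'   (ignore) mask, in `[0, 1)` (default 0.1).
#' @param seed Integer seed; every generator call is deterministic in it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(image_shape = c(64L, 64L), frame_rate = 30,
                              pixel_size = 1,
                              state_schedule = default_state_schedule(),
                              n_frames = NULL,
                              event_rate_per_state = default_event_rates(),
                              event_amplitude = 1, event_sigma_xy = 4,
                              event_duration_range = c(0.5, 3),
                              baseline_level = 100, noise_sigma = 5,
                              shot_noise = FALSE, drift_amplitude = 0,
                              drift_freq_hz = 0.02,
                              vessel_mask_fraction = 0.1, seed = 1L) {
  if (length(image_shape) != 2L || any(image_shape < 4L)) {
    stop("`image_shape` must be two pixel counts >= 4", call. = FALSE)
  }
  if (frame_rate <= 0) stop("`frame_rate` must be positive", call. = FALSE)
  if (pixel_size <= 0) stop("`pixel_size` must be positive", call. = FALSE)
  stopifnot(is.data.frame(state_schedule),
            all(c("state", "duration_s") %in% names(state_schedule)))
  bad <- setdiff(unique(state_schedule$state), state_levels())
  if (length(bad) > 0L) {
    stop("unknown state label(s) in `state_schedule`: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(state_schedule$duration_s <= 0)) {
    stop("`state_schedule` durations must be positive", call. = FALSE)
  }
  missing_rates <- setdiff(unique(state_schedule$state),
                           names(event_rate_per_state))
  if (length(missing_rates) > 0L) {
    stop("`event_rate_per_state` is missing rates for: ",
         paste(missing_rates, collapse = ", "), call. = FALSE)
  }
  if (any(event_rate_per_state < 0)) {
    stop("`event_rate_per_state` must be non-negative", call. = FALSE)
  }
  sched_frames <- round(sum(state_schedule$duration_s) * frame_rate)
  if (is.null(n_frames)) {
    n_frames <- sched_frames
  } else if (abs(n_frames - sched_frames) > 1) {
    stop("`n_frames` (", n_frames, ") disagrees with the schedule duration (",
         sched_frames, " frames) by more than one frame", call. = FALSE)
  }
  if (event_amplitude < 0) stop("`event_amplitude` must be >= 0", call. = FALSE)
  if (event_sigma_xy <= 0) stop("`event_sigma_xy` must be positive", call. = FALSE)
  if (length(event_duration_range) != 2L || any(event_duration_range <= 0) ||
      diff(event_duration_range) < 0) {
    stop("`event_duration_range` must be an increasing positive pair (s)",
         call. = FALSE)
  }
  if (baseline_level <= 0) stop("`baseline_level` must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (drift_amplitude < 0) stop("`drift_amplitude` must be >= 0", call. = FALSE)
  if (vessel_mask_fraction < 0 || vessel_mask_fraction >= 1) {
    stop("`vessel_mask_fraction` must be in [0, 1)", call. = FALSE)
  }
  structure(list(image_shape = as.integer(image_shape),
                 frame_rate = frame_rate, pixel_size = pixel_size,
                 state_schedule = state_schedule,
                 n_frames = as.integer(n_frames),
                 event_rate_per_state = event_rate_per_state,
                 event_amplitude = event_amplitude,
                 event_sigma_xy = event_sigma_xy,
                 event_duration_range = event_duration_range,
                 baseline_level = baseline_level, noise_sigma = noise_sigma,
                 shot_noise = isTRUE(shot_noise),
                 drift_amplitude = drift_amplitude,
                 drift_freq_hz = drift_freq_hz,
                 vessel_mask_fraction = vessel_mask_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Random vessel (ignore) mask
#'
#' Thresholded smoothed white noise: blob-shaped regions covering the
#' requested fraction of the field, emulating manually masked vessels.
#'
#' @param shape Field size in pixels (length 2).
#' @param fraction Covered fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @param blob_sigma_px Smoothing sigma controlling blob size (default 4).
#' @return Logical matrix; `TRUE` marks masked (ignored) pixels.
#' @export
generate_vessel_mask <- function(shape, fraction, seed = 1L,
                                 blob_sigma_px = 4) {
  if (fraction <= 0) return(matrix(FALSE, shape[1L], shape[2L]))
  set.seed(seed)
  z <- matrix(rnorm(prod(shape)), shape[1L], shape[2L])
  k <- gaussian_kernel_2d(blob_sigma_px, max_half = (min(shape) - 1L) %/% 2L)
  zs <- EBImage::filter2(z, k, boundary = "circular")
  zs >= quantile(zs, 1 - fraction, names = FALSE)
}

# Temporal event profile over `n_frames` frames: linear rise over the first
# 20%, then exponential decay reaching exp(-4) at the event end.
event_profile <- function(n_frames) {
  n_rise <- max(1L, round(0.2 * n_frames))
  n_decay <- n_frames - n_rise
  rise <- seq_len(n_rise) / n_rise
  if (n_decay == 0L) return(rise)
  decay <- exp(-4 * seq_len(n_decay) / n_decay)
  c(rise, decay)
}

#' Generate a synthetic fluorescence movie with ground-truth events
#'
#' Events are isotropic spatial Gaussian blobs with a linear-rise /
#' exponential-decay temporal profile, added multiplicatively to the
#' baseline (so `event_amplitude` is in dF/F0 units), plus additive i.i.d.
#' Gaussian noise and an optional slow sinusoidal drift. Event counts per
#' state segment are Poisson with the configured per-state rate applied to
#' the non-vessel area; event centers are placed so the blob's half-max
#' support avoids the vessel mask.
#'
#' @param config A [simulation_config()].
#' @param return_clean Also return the noiseless movie (used to derive a
#'   measurement-referred ground truth for recovery studies).
#' @return List with `movie` (a [movie_stack()]), `truth` (`data.frame`:
#'   `event_id`, `state`, `start_frame`, `end_frame` (0-based, inclusive),
#'   `cx`, `cy` (0-based px), `sigma_px`, `amplitude`,
#'   `footprint_area_um2` (half-max support), `peak_amplitude`),
#'   `vessel_mask`, and optionally `clean`.
#' @export
generate_movie <- function(config, return_clean = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  nx <- config$image_shape[1L]
  ny <- config$image_shape[2L]
  nt <- config$n_frames
  fr <- config$frame_rate
  px <- config$pixel_size
  vessel <- generate_vessel_mask(config$image_shape,
                                 config$vessel_mask_fraction,
                                 seed = config$seed)
  set.seed(config$seed + 1L)
  area_um2 <- sum(!vessel) * px^2
  sigma_px <- config$event_sigma_xy / px
  r_half <- sigma_px * sqrt(2 * log(2))

  # sample events per state segment
  seg_end <- cumsum(config$state_schedule$duration_s)
  seg_start <- c(0, head(seg_end, -1L))
  truth <- list()
  clean_rel <- array(0, dim = c(nx, ny, nt))  # sum of blob contributions (dF/F0)
  eid <- 0L
  for (i in seq_len(nrow(config$state_schedule))) {
    st <- config$state_schedule$state[i]
    rate <- config$event_rate_per_state[[st]]
    lam <- rate * (area_um2 / 100) * (config$state_schedule$duration_s[i] / 60)
    n_ev <- rpois(1L, lam)
    if (n_ev == 0L) next
    f0 <- max(0L, floor(seg_start[i] * fr))
    f1 <- min(nt - 1L, ceiling(seg_end[i] * fr) - 1L)
    if (f1 < f0) next
    for (e in seq_len(n_ev)) {
      dur_s <- runif(1L, config$event_duration_range[1L],
                     config$event_duration_range[2L])
      dur_f <- max(1L, round(dur_s * fr))
      start_f <- f0 + sample.int(f1 - f0 + 1L, 1L) - 1L
      end_f <- min(nt - 1L, start_f + dur_f - 1L)
      # place the center so the half-max support avoids the vessel mask
      placed <- FALSE
      for (try in 1:200) {
        cx <- runif(1L, 0, nx - 1L)
        cy <- runif(1L, 0, ny - 1L)
        ix <- pmax(1L, ceiling(cx - r_half + 1L)):pmin(nx, floor(cx + r_half + 1L))
        iy <- pmax(1L, ceiling(cy - r_half + 1L)):pmin(ny, floor(cy + r_half + 1L))
        dd <- outer((ix - 1L - cx)^2, (iy - 1L - cy)^2, "+")
        support <- dd <= r_half^2
        if (!any(vessel[ix, iy][support])) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place an event outside the vessel mask; ",
             "`vessel_mask_fraction` is too high for the field size",
             call. = FALSE)
      }
      # add the blob (truncated at 4 sigma) over the event's frames
      bx <- pmax(1L, ceiling(cx - 4 * sigma_px + 1L)):
        pmin(nx, floor(cx + 4 * sigma_px + 1L))
      by <- pmax(1L, ceiling(cy - 4 * sigma_px + 1L)):
        pmin(ny, floor(cy + 4 * sigma_px + 1L))
      blob <- config$event_amplitude *
        exp(-outer((bx - 1L - cx)^2, (by - 1L - cy)^2, "+") / (2 * sigma_px^2))
      prof <- event_profile(end_f - start_f + 1L)
      frames <- (start_f:end_f) + 1L
      clean_rel[bx, by, frames] <-
        clean_rel[bx, by, frames, drop = FALSE] + outer(blob, prof)
      eid <- eid + 1L
      truth[[eid]] <- data.frame(
        event_id = eid, state = st, start_frame = start_f, end_frame = end_f,
        cx = cx, cy = cy, sigma_px = sigma_px,
        amplitude = config$event_amplitude,
        footprint_area_um2 = sum(support) * px^2,
        peak_amplitude = config$event_amplitude)
    }
  }
  truth <- if (eid > 0L) do.call(rbind, truth) else data.frame(
    event_id = integer(), state = character(), start_frame = integer(),
    end_frame = integer(), cx = numeric(), cy = numeric(),
    sigma_px = numeric(), amplitude = numeric(),
    footprint_area_um2 = numeric(), peak_amplitude = numeric())

  clean <- config$baseline_level * (1 + clean_rel)
  rm(clean_rel)
  if (config$drift_amplitude > 0) {
    drift <- config$drift_amplitude *
      sin(2 * pi * config$drift_freq_hz * (seq_len(nt) - 1L) / fr)
    clean <- clean + rep(drift, each = nx * ny)
  }
  data <- clean
  if (config$shot_noise) {
    data <- array(rpois(length(data), pmax(data, 0)), dim = dim(data))
  }
  if (config$noise_sigma > 0) {
    data <- data + array(rnorm(length(data), sd = config$noise_sigma),
                         dim = dim(data))
  }
  out <- list(movie = movie_stack(data, px, fr), truth = truth,
              vessel_mask = vessel)
  if (return_clean) out$clean <- movie_stack(clean, px, fr)
  out
}

# Per-state ECoG band weights (power fractions before spindles) and EMG /
# motion levels used by the physiology generator. Weights are chosen so the
# standard scoring definitions hold by construction: NREM delta-dominant,
# REM theta/delta well above 0.5 with the lowest muscle tone, IS with
# elevated sigma and theta and reduced delta, wakefulness desynchronized
# with high EMG.
state_profiles <- function() {
  list(
    ecog = rbind(  # columns: delta, theta, sigma, beta
      locomotion = c(0.3, 0.4, 0.15, 0.5),
      whisking   = c(0.3, 0.4, 0.15, 0.5),
      quiet      = c(0.35, 0.4, 0.15, 0.5),
      NREM       = c(3.0, 0.5, 0.30, 0.2),
      IS         = c(1.0, 0.8, 0.90, 0.2),
      REM        = c(0.3, 1.2, 0.10, 0.2)),
    emg = c(locomotion = 3, whisking = 2, quiet = 1, NREM = 0.25, IS = 0.25,
            REM = 0.1),
    wheel = c(locomotion = 1, whisking = 0, quiet = 0, NREM = 0, IS = 0,
              REM = 0),
    snout = c(locomotion = 1, whisking = 1, quiet = 0, NREM = 0, IS = 0,
              REM = 0))
}

band_limited_noise <- function(n, fs, band, seed_offset = 0L) {
  w <- rnorm(n)
  ny <- fs / 2
  bf <- signal::butter(2, pmin(band, 0.99 * ny) / ny, type = "pass")
  x <- signal::filtfilt(bf, w)
  s <- sd(x)
  if (s == 0) return(x)
  x / s
}

#' Generate synthetic physiology for a state schedule
#'
#' ECoG is a sum of Butterworth-band-limited noise components (delta 0.5-4,
#' theta 5-9, sigma 10-16, beta 16-30 Hz) with state-specific weights, plus
#' Hann-windowed 12-14 Hz spindle bursts during IS. EMG is band-limited
#' noise with state-dependent tone; wheel and snout traces carry
#' above-threshold activity during locomotion/whisking, and brief snout
#' bursts inside NREM serve as ground-truth microarousals.
#'
#' @param state_schedule `data.frame` with `state`, `duration_s`.
#' @param sampling_rate Sampling rate in Hz (default 500).
#' @param spindle_rate_is Spindle rate during IS, per minute (default 4).
#' @param spindle_amplitude Peak spindle amplitude relative to the NREM
#'   ECoG RMS (default 2).
#' @param microarousal_rate_nrem Microarousal rate during NREM, per minute
#'   (default 1).
#' @param seed Integer seed.
#' @return List with `ecog`, `emg`, `wheel`, `snout` (numeric traces),
#'   `sampling_rate`, `hypnogram_truth`, `spindle_truth` (`data.frame`:
#'   `start_s`, `end_s`, `freq_hz`), and `microarousal_truth`
#'   (`data.frame`: `start_s`, `end_s`).
#' @export
generate_physiology <- function(state_schedule, sampling_rate = 500,
                                spindle_rate_is = 4, spindle_amplitude = 2,
                                microarousal_rate_nrem = 1, seed = 1L) {
  stopifnot(is.data.frame(state_schedule), nrow(state_schedule) > 0L)
  bad <- setdiff(unique(state_schedule$state), state_levels())
  if (length(bad) > 0L) {
    stop("unknown state label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  fs <- sampling_rate
  hyp <- schedule_to_hypnogram(state_schedule)
  n <- round(max(hyp$end_s) * fs)
  times <- (seq_len(n) - 1L) / fs
  lab <- hypnogram_labels(hyp, times)
  lab[is.na(lab)] <- tail(state_schedule$state, 1L)
  prof <- state_profiles()

  bands <- list(delta = c(0.5, 4), theta = c(5, 9), sigma = c(10, 16),
                beta = c(16, 30))
  ecog <- numeric(n)
  for (b in seq_along(bands)) {
    comp <- band_limited_noise(n, fs, bands[[b]])
    w <- prof$ecog[lab, b]
    ecog <- ecog + comp * sqrt(w)
  }
  # scale so the NREM-state ECoG RMS is ~1 (amplitudes are relative units)
  nrem_rms <- sqrt(sum(prof$ecog["NREM", ]))
  ecog <- ecog / nrem_rms

  # spindles during IS
  spindle_truth <- data.frame(start_s = numeric(), end_s = numeric(),
                              freq_hz = numeric())
  is_ep <- hyp[hyp$state == "IS", , drop = FALSE]
  for (i in seq_len(nrow(is_ep))) {
    lam <- spindle_rate_is * is_ep$duration_s[i] / 60
    n_sp <- rpois(1L, lam)
    for (s in seq_len(n_sp)) {
      dur <- runif(1L, 0.5, 2)
      t0 <- runif(1L, is_ep$start_s[i],
                  max(is_ep$start_s[i], is_ep$end_s[i] - dur))
      f_hz <- runif(1L, 12, 14)
      i0 <- floor(t0 * fs) + 1L
      i1 <- min(n, i0 + round(dur * fs) - 1L)
      tt <- (seq(i0, i1) - i0) / fs
      hann <- 0.5 * (1 - cos(2 * pi * tt / max(tt)))
      ecog[i0:i1] <- ecog[i0:i1] +
        spindle_amplitude * hann * sin(2 * pi * f_hz * tt)
      spindle_truth <- rbind(spindle_truth,
                             data.frame(start_s = t0, end_s = t0 + dur,
                                        freq_hz = f_hz))
    }
  }

  emg_band <- c(100, min(1000, 0.45 * fs))
  emg <- band_limited_noise(n, fs, emg_band) * prof$emg[lab]

  wheel <- abs(rnorm(n, sd = 0.02)) + prof$wheel[lab] * (0.8 + abs(rnorm(n, sd = 0.3)))
  snout <- abs(rnorm(n, sd = 0.02)) + prof$snout[lab] * (0.8 + abs(rnorm(n, sd = 0.3)))

  # microarousals: brief snout bursts inside NREM episodes
  ma_truth <- data.frame(start_s = numeric(), end_s = numeric())
  nrem_ep <- hyp[hyp$state == "NREM", , drop = FALSE]
  for (i in seq_len(nrow(nrem_ep))) {
    lam <- microarousal_rate_nrem * nrem_ep$duration_s[i] / 60
    n_ma <- rpois(1L, lam)
    for (s in seq_len(n_ma)) {
      dur <- runif(1L, 0.5, 2.5)
      t0 <- runif(1L, nrem_ep$start_s[i] + 1,
                  max(nrem_ep$start_s[i] + 1, nrem_ep$end_s[i] - dur - 1))
      i0 <- floor(t0 * fs) + 1L
      i1 <- min(n, i0 + round(dur * fs) - 1L)
      snout[i0:i1] <- snout[i0:i1] + 0.8 + abs(rnorm(i1 - i0 + 1L, sd = 0.3))
      ma_truth <- rbind(ma_truth, data.frame(start_s = t0, end_s = t0 + dur))
    }
  }

  list(ecog = ecog, emg = emg, wheel = wheel, snout = snout,
       sampling_rate = fs, hypnogram_truth = hyp,
       spindle_truth = spindle_truth, microarousal_truth = ma_truth)
}

#' Generate a complete synthetic session
#'
#' Combines [generate_movie()] and [generate_physiology()] for the same
#' state schedule into one session sharing a common time origin.
#'
#' @param config A [simulation_config()].
#' @param sampling_rate Physiology sampling rate in Hz (default 500).
#' @param return_clean Also keep the noiseless movie.
#' @param ... Further arguments passed to [generate_physiology()].
#' @return List of class `synthetic_session`: `movie`, `truth_events`,
#'   `vessel_mask`, `clean` (optional), `physio` (see
#'   [generate_physiology()]), `hypnogram_truth`, `spindle_truth`,
#'   `microarousal_truth`, `config`.
#' @export
generate_session <- function(config, sampling_rate = 500,
                             return_clean = FALSE, ...) {
  stopifnot(inherits(config, "simulation_config"))
  mv <- generate_movie(config, return_clean = return_clean)
  ph <- generate_physiology(config$state_schedule,
                            sampling_rate = sampling_rate,
                            seed = config$seed + 1000L, ...)
  structure(list(movie = mv$movie, truth_events = mv$truth,
                 vessel_mask = mv$vessel_mask, clean = mv$clean,
                 physio = ph, hypnogram_truth = ph$hypnogram_truth,
                 spindle_truth = ph$spindle_truth,
                 microarousal_truth = ph$microarousal_truth,
                 config = config),
            class = "synthetic_session")
}
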