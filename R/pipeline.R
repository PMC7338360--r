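# End-to-end pipeline plumbing: run all stages on a session, write CSV
# outputs with reproducibility headers, and summarize per state.
#
# Conventions used in all outputs: time in seconds from recording start,
# frame indices 0-based, intervals half-open [start, end).

csv_header <- function(seed, extra = character()) {
  c(sprintf("# roawake %s", as.character(packageVersion("roawake"))),
    sprintf("# seed=%s", format(seed)),
    "# time_s from recording start; frames 0-based; intervals [start,end)",
    extra)
}

#' Write / read a CSV with a reproducibility header
#'
#' Comment lines (`#`) carry the package version, the seed and the time
#' conventions; the table itself round-trips through [read.csv()].
#'
#' @param df Data frame.
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @param extra Additional header lines.
#' @return `path` invisibly; `read_output_csv` returns the data frame.
#' @export
write_output_csv <- function(df, path, seed = NA, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csv_header(seed, extra), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_output_csv
#' @export
read_output_csv <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Run the full analysis pipeline on a session
#'
#' Composition of all stages: ROA detection on the movie (vessel mask
#' ignored), ROA frequency metrics, sleep-wake scoring from the
#' physiology, transition and microarousal and spindle detection,
#' transition-locked alignment with onset estimation, per-episode heatmaps
#' with the PERMANOVA overlap analysis (when at least `min_episodes`
#' scoreable episodes exist), and a per-state summary. All outputs are
#' written as headed CSVs; reruns with the same session and seed are
#' byte-identical.
#'
#' @param session A [generate_session()] result, or a list with elements
#'   `movie` ([movie_stack()]), `vessel_mask`, and `physio` (list with
#'   `ecog`, `emg`, `wheel`, `snout`, `sampling_rate`).
#' @param out_dir Output directory (created if needed).
#' @param params [roa_params()] for detection.
#' @param thresholds [score_thresholds()] for scoring.
#' @param seed Seed for the permutation test and output headers.
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param min_episodes Episode minimum for the overlap analysis (default 8).
#' @param tau Causal smoothing time constant in seconds (default 0.25).
#' @return List of class `roa_bundle` with all intermediate tables and the
#'   paths written.
#' @export
run_pipeline <- function(session, out_dir, params = roa_params(),
                         thresholds = score_thresholds(), seed = 1L,
                         n_permutations = 999L, min_episodes = 8L,
                         tau = 0.25) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  movie <- session$movie
  physio <- session$physio
  fr <- movie$frame_rate
  d <- dim(movie$data)
  n_frames <- d[3L]

  det <- roa_detect(movie, params, ignore_mask = session$vessel_mask,
                    keep_labels = FALSE)
  events <- det$events
  sampled_area <- sum(!session$vessel_mask) * movie$pixel_size^2
  freq <- roa_frequency_trace(events, n_frames, sampled_area, fr)

  hyp <- score_sleep(physio$ecog, physio$emg, physio$sampling_rate,
                     wheel = physio$wheel, snout = physio$snout,
                     thresholds = thresholds)
  trans <- detect_transitions(hyp, ecog = physio$ecog,
                              fs = physio$sampling_rate,
                              method = "delta_drop")
  ma <- detect_microarousals(physio$snout, physio$sampling_rate, hyp,
                             threshold = thresholds$snout_threshold)
  sleep_eps <- hyp[hyp$state %in% c("NREM", "IS"), , drop = FALSE]
  spindles <- detect_spindles(physio$ecog, physio$sampling_rate,
                              episodes = if (nrow(sleep_eps) > 0L)
                                sleep_eps else NULL)
  if (nrow(spindles) > 0L) {
    spindles$state <- hypnogram_labels(hyp, spindles$peak_time_s)
  } else {
    spindles$state <- character()
  }

  freq_s <- smooth_causal(freq, fr, tau)
  awak <- trans$time_s[trans$awakening]
  aligned <- align_and_zscore(freq_s, fr, awak)
  onsets <- estimate_onset(aligned)
  if (nrow(aligned) > 0L) {
    onsets$peak_z <- estimate_peak(aligned)
    onsets$transition_time_s <- attr(aligned, "transition_times")
  }

  # per-episode heatmaps for analyzable (non-excluded) episodes
  ep_keep <- which(!hyp$excluded)
  heatmaps <- list()
  hm_states <- character()
  for (i in ep_keep) {
    fr0 <- max(1L, floor(hyp$start_s[i] * fr) + 1L)
    fr1 <- min(n_frames, ceiling(hyp$end_s[i] * fr))
    if (fr1 <= fr0) next
    heatmaps[[length(heatmaps) + 1L]] <-
      compute_heatmap(det$active, fr0:fr1, session$vessel_mask,
                      state = hyp$state[i], episode_id = i)
    hm_states <- c(hm_states, hyp$state[i])
  }
  perm <- NULL
  if (length(heatmaps) >= min_episodes &&
      length(unique(hm_states)) >= 2L &&
      all(table(hm_states) >= 2L)) {
    perm <- tryCatch(
      overlap_analysis(heatmaps, hm_states, n_permutations, seed,
                       min_episodes = min_episodes),
      warning = function(w) NULL, error = function(e) NULL)
  }

  summary_df <- summarize_bundle(events, det$active, session$vessel_mask,
                                 hyp, fr, movie$pixel_size, spindles, ma)

  paths <- c(
    events = write_output_csv(events, file.path(out_dir, "events.csv"), seed,
                              sprintf("# k=%g; connectivity=%d", params$k,
                                      params$connectivity)),
    hypnogram = write_output_csv(as.data.frame(hyp),
                                 file.path(out_dir, "hypnogram.csv"), seed),
    transitions = write_output_csv(trans,
                                   file.path(out_dir, "transitions.csv"),
                                   seed),
    microarousals = write_output_csv(ma,
                                     file.path(out_dir, "microarousals.csv"),
                                     seed),
    spindles = write_output_csv(spindles,
                                file.path(out_dir, "spindles.csv"), seed),
    aligned = write_output_csv(
      if (nrow(aligned) > 0L) {
        data.frame(transition = rep(seq_len(nrow(aligned)),
                                    each = ncol(aligned)),
                   time_s = rep(attr(aligned, "time_s"), nrow(aligned)),
                   z = as.numeric(t(aligned)))
      } else {
        data.frame(transition = integer(), time_s = numeric(), z = numeric())
      }, file.path(out_dir, "aligned.csv"), seed),
    onsets = write_output_csv(onsets, file.path(out_dir, "onsets.csv"), seed),
    summary = write_output_csv(summary_df, file.path(out_dir, "summary.csv"),
                               seed))
  if (!is.null(perm)) {
    paths <- c(paths, permanova = write_output_csv(
      data.frame(n_episodes = length(heatmaps), R2 = perm$R2,
                 p_value = perm$p_value, pseudo_F = perm$pseudo_F,
                 n_permutations = perm$n_permutations, seed = perm$seed),
      file.path(out_dir, "permanova.csv"), seed))
  }

  structure(list(events = events, detection = det, frequency = freq,
                 hypnogram = hyp, transitions = trans, microarousals = ma,
                 spindles = spindles, aligned = aligned, onsets = onsets,
                 permanova = perm, summary = summary_df, paths = paths,
                 seed = seed),
            class = "roa_bundle")
}

#' Per-state summary of a session
#'
#' One row per state present in the hypnogram: episode counts and bout
#' statistics, mean ROA frequency (events per 100 um^2 per minute, counted
#' by start frame within the state's non-excluded episodes), active-voxel
#' percentage, mean event morphology, plus microarousals per hour of NREM
#' and spindles per minute of IS.
#'
#' @param events Event table from [extract_roas()].
#' @param active Logical activity volume.
#' @param vessel_mask Logical ignore mask.
#' @param hyp A [hypnogram()].
#' @param frame_rate,pixel_size Movie geometry.
#' @param spindles,microarousals Optional event tables from the detectors.
#' @return `data.frame`, one row per state.
#' @export
summarize_bundle <- function(events, active, vessel_mask, hyp, frame_rate,
                             pixel_size, spindles = NULL,
                             microarousals = NULL) {
  n_frames <- dim(active)[3L]
  sampled_area <- sum(!vessel_mask) * pixel_size^2
  ev_state <- hypnogram_labels(hyp, events$start_time_s)
  out <- list()
  for (st in intersect(state_levels(), unique(hyp$state))) {
    eps <- hyp[hyp$state == st & !hyp$excluded, , drop = FALSE]
    total_s <- sum(eps$duration_s)
    frames <- integer()
    for (i in seq_len(nrow(eps))) {
      fr0 <- max(1L, floor(eps$start_s[i] * frame_rate) + 1L)
      fr1 <- min(n_frames, ceiling(eps$end_s[i] * frame_rate))
      if (fr1 >= fr0) frames <- c(frames, fr0:fr1)
    }
    in_state <- !is.na(ev_state) & ev_state == st &
      events$start_time_s >= 0
    sel_ev <- events[in_state, , drop = FALSE]
    # keep only events starting inside non-excluded episodes
    if (nrow(sel_ev) > 0L && nrow(eps) > 0L) {
      keep <- vapply(sel_ev$start_time_s, function(t0) {
        any(t0 >= eps$start_s & t0 < eps$end_s)
      }, logical(1L))
      sel_ev <- sel_ev[keep, , drop = FALSE]
    } else {
      sel_ev <- sel_ev[integer(), , drop = FALSE]
    }
    mean_freq <- if (total_s > 0) {
      nrow(sel_ev) / (sampled_area / 100) / (total_s / 60)
    } else NA_real_
    avf <- if (length(frames) > 0L) {
      active_voxel_fraction(active, frames, vessel_mask)
    } else NA_real_
    all_eps <- hyp[hyp$state == st, , drop = FALSE]
    hours <- sum(hyp$duration_s) / 3600
    row <- data.frame(
      state = st, n_episodes = nrow(all_eps),
      n_episodes_analyzed = nrow(eps),
      total_s = total_s,
      mean_bout_s = mean(all_eps$duration_s),
      bouts_per_h = nrow(all_eps) / hours,
      mean_freq_per_100um2_min = mean_freq,
      active_voxel_pct = avf,
      mean_area_um2 = mean(sel_ev$footprint_area_um2),
      mean_duration_s = mean(sel_ev$duration_s),
      mean_volume_um2s = mean(sel_ev$volume_um2s),
      n_events = nrow(sel_ev))
    if (st == "NREM" && !is.null(microarousals)) {
      row$microarousals_per_h <- if (total_s > 0) {
        nrow(microarousals) / (total_s / 3600)
      } else NA_real_
    }
    if (st == "IS" && !is.null(spindles)) {
      n_sp <- sum(!is.na(spindles$state) & spindles$state == "IS")
      row$spindles_per_min <- if (total_s > 0) n_sp / (total_s / 60) else
        NA_real_
    }
    out[[st]] <- row
  }
  df <- do.call(rbind, lapply(out, function(r) {
    for (col in c("microarousals_per_h", "spindles_per_min")) {
      if (is.null(r[[col]])) r[[col]] <- NA_real_
    }
    r
  }))
  rownames(df) <- NULL
  df
}

#' @export
print.roa_bundle <- function(x, ...) {
  cat(sprintf(
    "roa_bundle: %d events, %d episodes, %d transitions, %d spindles, %d microarousals\n",
    nrow(x$events), nrow(x$hypnogram), nrow(x$transitions),
    nrow(x$spindles), nrow(x$microarousals)))
  invisible(x)
}
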