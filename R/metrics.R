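# Summary measures over detected events and activity masks: ROA frequency
# traces, active-voxel percentages, per-episode activity heatmaps, and
# hotspot overlap.

#' Per-frame ROA frequency trace
#'
#' Counts events by start frame and converts to ROAs per 100 um^2 per
#' minute: `count[t] / (sampled_area / 100) / frame_period_min`. The
#' integral of the trace over the recording recovers the total event count.
#'
#' @param events Event table from [extract_roas()] (uses `start_frame`,
#'   0-based).
#' @param n_frames Number of frames in the recording.
#' @param sampled_area_um2 Analyzed area in um^2 (field minus ignored
#'   regions); must be positive.
#' @param frame_rate Frame rate in Hz.
#' @return Numeric vector of length `n_frames` (ROAs / 100 um^2 / min) with
#'   attributes `frame_rate` and `sampled_area_um2`.
#' @export
roa_frequency_trace <- function(events, n_frames, sampled_area_um2,
                                frame_rate) {
  if (sampled_area_um2 <= 0) {
    stop("`sampled_area_um2` must be positive", call. = FALSE)
  }
  counts <- tabulate(events$start_frame + 1L, n_frames)
  out <- counts / (sampled_area_um2 / 100) * frame_rate * 60
  attr(out, "frame_rate") <- frame_rate
  attr(out, "sampled_area_um2") <- sampled_area_um2
  out
}

#' Percentage of active voxels in an episode
#'
#' `100 * active / total` over the episode's frames, where totals exclude
#' ignored pixels.
#'
#' @param active Logical x-y-t activity array.
#' @param frames Integer frame indices (1-based) of the episode; default all.
#' @param ignore_mask Optional logical x-by-y matrix of excluded pixels.
#' @return Percentage in `[0, 100]`.
#' @export
active_voxel_fraction <- function(active, frames = NULL,
                                  ignore_mask = NULL) {
  d <- dim(active)
  if (is.null(frames)) frames <- seq_len(d[3L])
  if (length(frames) == 0L) stop("empty episode", call. = FALSE)
  sub <- active[, , frames, drop = FALSE]
  if (!is.null(ignore_mask)) {
    keep <- !as.logical(ignore_mask)
    n_act <- sum(sub & array(keep, dim = dim(sub)))
    n_tot <- sum(keep) * length(frames)
  } else {
    n_act <- sum(sub)
    n_tot <- prod(d[1:2]) * length(frames)
  }
  100 * n_act / n_tot
}

#' Activity heatmap for an episode
#'
#' Per-pixel fraction of the episode's frames in which the pixel was active.
#'
#' @inheritParams active_voxel_fraction
#' @param state Optional state label attached as an attribute.
#' @param episode_id Optional episode identifier attached as an attribute.
#' @return Numeric x-by-y matrix in `[0, 1]`; ignored pixels are `NA`.
#' @export
compute_heatmap <- function(active, frames = NULL, ignore_mask = NULL,
                            state = NULL, episode_id = NULL) {
  d <- dim(active)
  if (is.null(frames)) frames <- seq_len(d[3L])
  if (length(frames) == 0L) stop("empty episode", call. = FALSE)
  hm <- rowMeans(active[, , frames, drop = FALSE], dims = 2L)
  if (!is.null(ignore_mask)) hm[as.logical(ignore_mask)] <- NA_real_
  attr(hm, "state") <- state
  attr(hm, "episode_id") <- episode_id
  hm
}

#' Hotspot overlap between two heatmaps
#'
#' Binarizes each heatmap at its own `top_fraction` activity quantile (ties
#' at the cutoff are all included) and returns the Jaccard index of the two
#' binary hotspot sets: intersection area over union area.
#'
#' @param a,b Heatmaps of equal shape (from [compute_heatmap()]).
#' @param top_fraction Fraction of most-active pixels defining hotspots
#'   (default 0.05).
#' @return Overlap in `[0, 1]`; `NA` with a warning if either heatmap is
#'   all-zero.
#' @export
hotspot_overlap <- function(a, b, top_fraction = 0.05) {
  stopifnot(all(dim(a) == dim(b)))
  if (top_fraction <= 0 || top_fraction >= 1) {
    stop("`top_fraction` must be in (0, 1)", call. = FALSE)
  }
  av <- as.numeric(a)[!is.na(a)]
  bv <- as.numeric(b)[!is.na(b)]
  if (all(av == 0) || all(bv == 0)) {
    warning("all-zero heatmap: hotspot overlap is undefined")
    return(NA_real_)
  }
  ta <- !is.na(a) & a >= quantile(av, 1 - top_fraction, names = FALSE)
  tb <- !is.na(b) & b >= quantile(bv, 1 - top_fraction, names = FALSE)
  sum(ta & tb) / sum(ta | tb)
}
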