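# Independent oracles and fixture builders shared across tests.

# Brute-force flood fill over a 3D logical mask, independent of the
# package's compiled labeling (plain R, explicit neighbor enumeration).
flood_fill_oracle <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dt = -1:1)
  offsets <- offsets[!(offsets$dx == 0 & offsets$dy == 0 & offsets$dt == 0), ]
  if (connectivity == 6L) {
    offsets <- offsets[abs(offsets$dx) + abs(offsets$dy) +
                         abs(offsets$dt) == 1, ]
  }
  current <- 0L
  for (idx in which(mask)) {
    if (labels[idx] != 0L) next
    current <- current + 1L
    queue <- idx
    labels[idx] <- current
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      v0 <- v - 1L
      t <- v0 %/% (d[1L] * d[2L])
      rem <- v0 %% (d[1L] * d[2L])
      y <- rem %/% d[1L]
      x <- rem %% d[1L]
      for (o in seq_len(nrow(offsets))) {
        xx <- x + offsets$dx[o]
        yy <- y + offsets$dy[o]
        tt <- t + offsets$dt[o]
        if (xx < 0 || xx >= d[1L] || yy < 0 || yy >= d[2L] || tt < 0 ||
            tt >= d[3L]) next
        w <- 1L + xx + d[1L] * (yy + d[2L] * tt)
        if (mask[w] && labels[w] == 0L) {
          labels[w] <- current
          queue <- c(queue, w)
        }
      }
    }
  }
  labels
}

# Canonical form of a labeling: list of sorted voxel-index sets.
label_sets <- function(labels) {
  sets <- split(which(labels > 0L), labels[labels > 0L])
  unname(sets[order(vapply(sets, min, numeric(1L)))])
}

# Match detected events to truth events by space-time bounding-box overlap
# (truth boxes padded to the blob's 4-sigma support). Returns per-truth
# matched detected ids (0 = unmatched) and the unmatched detected count.
match_events <- function(events, truth, pad_sigma = 4) {
  n_det <- nrow(events)
  det_used <- rep(FALSE, n_det)
  matched <- integer(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    r <- truth$sigma_px[i] * pad_sigma
    hit <- which(!logical(n_det) &
                   events$x0 <= truth$cx[i] + r &
                   events$x1 >= truth$cx[i] - r &
                   events$y0 <= truth$cy[i] + r &
                   events$y1 >= truth$cy[i] - r &
                   events$t0 <= truth$end_frame[i] &
                   events$t1 >= truth$start_frame[i])
    if (length(hit) > 0L) {
      matched[i] <- hit[1L]
      det_used[hit] <- TRUE
    }
  }
  list(matched = matched, n_unmatched_detected = sum(!det_used))
}

# Small single-state simulation config used by several tests.
quiet_config <- function(..., duration_s = 30, rate = 1, seed = 1L) {
  simulation_config(
    image_shape = c(32L, 32L),
    state_schedule = data.frame(state = "quiet", duration_s = duration_s),
    event_rate_per_state = c(quiet = rate), seed = seed, ...)
}
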