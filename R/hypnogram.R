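#' Hypnogram: time-ordered behavioral episodes
#'
#' An ordered table of non-overlapping episodes labeled with one of the six
#' sleep-wake states (see [state_levels()]). Intervals are half-open
#' `[start_s, end_s)` in seconds from recording start. Sleep episodes of
#' 30 s or less are flagged `excluded` (too short for state-level analysis).
#'
#' @param state Character vector of state labels.
#' @param start_s,end_s Episode boundaries in seconds.
#' @param excluded Optional logical; defaults to flagging sleep episodes
#'   with duration <= 30 s.
#' @return A `data.frame` of class `hypnogram` with columns `state`,
#'   `start_s`, `end_s`, `duration_s`, `excluded`.
#' @export
hypnogram <- function(state, start_s, end_s, excluded = NULL) {
  state <- as.character(state)
  bad <- setdiff(unique(state), state_levels())
  if (length(bad) > 0L) {
    stop("unknown state label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(state_levels(), collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(end_s <= start_s)) stop("episodes must have end_s > start_s",
                                  call. = FALSE)
  o <- order(start_s)
  state <- state[o]; start_s <- start_s[o]; end_s <- end_s[o]
  if (length(start_s) > 1L && any(start_s[-1L] < end_s[-length(end_s)] - 1e-9)) {
    stop("episodes must not overlap", call. = FALSE)
  }
  duration_s <- end_s - start_s
  if (is.null(excluded)) {
    excluded <- state %in% sleep_states() & duration_s <= 30
  }
  structure(data.frame(state = state, start_s = start_s, end_s = end_s,
                       duration_s = duration_s, excluded = excluded),
            class = c("hypnogram", "data.frame"))
}

#' Build a hypnogram from a state schedule
#'
#' @param schedule `data.frame` with columns `state` and `duration_s`, in
#'   order from recording start.
#' @return A [hypnogram()].
#' @export
schedule_to_hypnogram <- function(schedule) {
  stopifnot(is.data.frame(schedule), all(c("state", "duration_s") %in%
                                           names(schedule)))
  end_s <- cumsum(schedule$duration_s)
  hypnogram(schedule$state, c(0, head(end_s, -1L)), end_s)
}

#' State label at given times
#'
#' @param h A [hypnogram()].
#' @param times Numeric vector of times in seconds.
#' @return Character vector of state labels (`NA` outside all episodes).
#' @export
hypnogram_labels <- function(h, times) {
  out <- rep(NA_character_, length(times))
  for (i in seq_len(nrow(h))) {
    sel <- times >= h$start_s[i] & times < h$end_s[i]
    out[sel] <- h$state[i]
  }
  out
}

#' Per-second agreement between two hypnograms
#'
#' Samples both hypnograms on a common grid and returns the fraction of
#' samples where the state labels agree (samples unscored in either are
#' ignored).
#'
#' @param truth,scored Two [hypnogram()] objects.
#' @param step_s Sampling step in seconds (default 1).
#' @return Agreement fraction in `[0, 1]`.
#' @export
hypnogram_accuracy <- function(truth, scored, step_s = 1) {
  t_end <- min(max(truth$end_s), max(scored$end_s))
  times <- seq(step_s / 2, t_end, by = step_s)
  a <- hypnogram_labels(truth, times)
  b <- hypnogram_labels(scored, times)
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  mean(a[ok] == b[ok])
}

# Collapse a vector of per-epoch labels into a hypnogram.
labels_to_hypnogram <- function(labels, epoch_s, start_s = 0) {
  r <- rle(labels)
  end_idx <- cumsum(r$lengths)
  start_idx <- c(0L, head(end_idx, -1L))
  keep <- !is.na(r$values)
  hypnogram(r$values[keep], start_s + start_idx[keep] * epoch_s,
            start_s + end_idx[keep] * epoch_s)
}
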