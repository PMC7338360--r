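# State-specificity of activation maps: Jaccard distances between episode
# heatmaps and PERMANOVA with the per-episode mean activation as covariate.

#' Jaccard similarity of two non-negative activation maps
#'
#' `J(x, y) = sum_i min(x_i, y_i) / sum_i max(x_i, y_i)`: 0 means no
#' overlap, 1 identical activation.
#'
#' @param x,y Non-negative numeric vectors of equal length (flattened
#'   heatmaps; `NA` pixels must match and are dropped).
#' @return Similarity in `[0, 1]`; `NA` with a warning if both vectors are
#'   all zero.
#' @export
jaccard_similarity <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (any(x < 0) || any(y < 0)) {
    stop("activation maps must be non-negative", call. = FALSE)
  }
  denom <- sum(pmax(x, y))
  if (denom == 0) {
    warning("both maps are all-zero: Jaccard similarity is undefined")
    return(NA_real_)
  }
  sum(pmin(x, y)) / denom
}

#' Jaccard distance matrix between episode heatmaps
#'
#' Pairwise `1 - J` between all episode heatmaps of one field of view. At
#' least `min_episodes` episodes (default 8) are required for the
#' state-specificity analysis; undersized sets are rejected.
#'
#' @param heatmaps A list of heatmaps (matrices or vectors) or a matrix with
#'   one episode per row.
#' @param min_episodes Minimum number of episodes (default 8).
#' @return Symmetric distance matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
jaccard_distance_matrix <- function(heatmaps, min_episodes = 8L) {
  if (is.list(heatmaps)) {
    heatmaps <- do.call(rbind, lapply(heatmaps, as.numeric))
  }
  n <- nrow(heatmaps)
  if (n < min_episodes) {
    stop("only ", n, " episodes; at least ", min_episodes,
         " episodes are required for the overlap analysis", call. = FALSE)
  }
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- 1 - jaccard_similarity(heatmaps[i, ],
                                                   heatmaps[j, ])
    }
  }
  d
}

# Projection (hat) matrix onto the column span of X.
hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' PERMANOVA on a distance matrix with an activation covariate
#'
#' Permutational multivariate analysis of variance (Anderson-style
#' partitioning on the Gower-centered inner-product matrix) testing whether
#' episodes of the same behavioral state have more similar activation maps
#' than episodes of different states, conditional on each episode's overall
#' activation level. Sums of squares are sequential (covariate first, then
#' state), so the reported state effect is adjusted for the covariate.
#' The p-value is `(1 + #permuted F >= observed F) / (1 + n_permutations)`.
#'
#' @param d Symmetric distance matrix (e.g. [jaccard_distance_matrix()]).
#' @param states Factor or character vector of state labels, one per
#'   episode; at least 2 states with at least 2 episodes each.
#' @param covariate Optional numeric covariate per episode (mean activation);
#'   a constant covariate is dropped (one-factor PERMANOVA).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutation stream (mandatory).
#' @param permutation `"free"` (default): permute raw state labels;
#'   `"residual"`: permute after removing the covariate projection from the
#'   centered inner-product matrix (covariate-adjusted null).
#' @return List of class `permanova_result`: `R2`, `p_value`, `pseudo_F`,
#'   `df`, `ss` (sequential sums of squares), `n_permutations`, `seed`,
#'   `permutation`.
#' @export
roa_permanova <- function(d, states, covariate = NULL, n_permutations = 999L,
                          seed, permutation = c("free", "residual")) {
  permutation <- match.arg(permutation)
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(ncol(d) == n, length(states) == n)
  if (missing(seed)) stop("`seed` is required for reproducible permutations",
                          call. = FALSE)
  states <- factor(states)
  if (nlevels(droplevels(states)) < 2L) {
    stop("at least 2 states are required", call. = FALSE)
  }
  states <- droplevels(states)
  if (any(table(states) < 2L)) {
    stop("every state needs at least 2 episodes (singleton levels: ",
         paste(names(which(table(states) < 2L)), collapse = ", "), ")",
         call. = FALSE)
  }
  if (!is.null(covariate)) {
    stopifnot(length(covariate) == n)
    if (sd(covariate) == 0) covariate <- NULL
  }

  # Gower-centered inner-product matrix
  A <- -0.5 * d^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  ss_total <- sum(diag(G))

  one <- matrix(1, n, 1L)
  X_cov <- if (is.null(covariate)) one else cbind(one, covariate)
  H_cov <- hat_matrix(X_cov)
  rank_cov <- qr(X_cov)$rank

  G_work <- G
  if (permutation == "residual" && !is.null(covariate)) {
    R <- diag(n) - H_cov
    G_work <- R %*% G %*% R
  }

  # trace identities: for symmetric A, B: tr(A B) = sum(A * B)
  ind <- diag(nlevels(states))
  state_f <- function(st, Gm) {
    X_full <- cbind(X_cov, ind[as.integer(st), -1L, drop = FALSE])
    qf <- qr(X_full)
    H_full <- tcrossprod(qr.Q(qf)[, seq_len(qf$rank), drop = FALSE])
    df_state <- qf$rank - rank_cov
    df_res <- n - qf$rank
    ss_state <- sum((H_full - H_cov) * Gm)
    ss_res <- sum(diag(Gm)) - sum(H_full * Gm)
    list(F = (ss_state / df_state) / (ss_res / df_res), ss_state = ss_state,
         ss_res = ss_res, df_state = df_state, df_res = df_res)
  }

  obs <- state_f(states, G_work)
  set.seed(seed)
  n_ge <- 0L
  for (p in seq_len(n_permutations)) {
    f_p <- state_f(states[sample.int(n)], G_work)$F
    if (f_p >= obs$F - 1e-12) n_ge <- n_ge + 1L
  }
  ss_cov <- sum((H_cov - hat_matrix(one)) * G)
  structure(list(
    R2 = obs$ss_state / ss_total,
    p_value = (1 + n_ge) / (1 + n_permutations),
    pseudo_F = obs$F,
    df = c(state = obs$df_state, residual = obs$df_res),
    ss = c(covariate = ss_cov, state = obs$ss_state, residual = obs$ss_res,
           total = ss_total),
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed),
    permutation = permutation), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (state factor, %s permutation): R2 = %.3f, pseudo-F = %.2f, p = %.4g (%d permutations)\n",
    x$permutation, x$R2, x$pseudo_F, x$p_value, x$n_permutations))
  invisible(x)
}

#' Per-FOV overlap analysis from episode heatmaps
#'
#' Convenience wrapper: builds the Jaccard distance matrix, computes the
#' per-episode mean activation covariate, and runs [roa_permanova()].
#'
#' @param heatmaps List of episode heatmaps or matrix with episodes as rows.
#' @param states State label per episode.
#' @param n_permutations,seed,permutation Passed to [roa_permanova()].
#' @param min_episodes Minimum episode count (default 8).
#' @return A `permanova_result` with the distance matrix attached as
#'   attribute `"distance"`.
#' @export
overlap_analysis <- function(heatmaps, states, n_permutations = 999L, seed,
                             permutation = c("free", "residual"),
                             min_episodes = 8L) {
  if (is.list(heatmaps)) {
    heatmaps <- do.call(rbind, lapply(heatmaps, as.numeric))
  }
  d <- jaccard_distance_matrix(heatmaps, min_episodes)
  covariate <- rowMeans(heatmaps, na.rm = TRUE)
  res <- roa_permanova(d, states, covariate, n_permutations, seed,
                       permutation)
  attr(res, "distance") <- d
  res
}
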