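#' Per-instance adaptive neighborhood radii (MultiSURF rule)
#'
#' MultiSURF gives each target instance its own radius
#' `R_i = mean(D_ij, j != i) - alpha * sd(D_ij, j != i)`, with `alpha = 0.5`
#' the standard choice.
#'
#' @param D Symmetric pairwise distance matrix (a `distance_matrix` or plain
#'   matrix), `m >= 3`.
#' @param alpha Number of distance standard deviations subtracted from the
#'   row mean.
#' @return Numeric vector of `m` radii.
#' @export
multisurf_radii <- function(D, alpha = 0.5) {
  D <- as.matrix(D)
  m <- nrow(D)
  if (m < 3) stop("need at least 3 instances (row SD undefined otherwise)")
  vapply(seq_len(m), function(i) {
    d <- D[i, -i]
    mean(d) - alpha * stats::sd(d)
  }, numeric(1))
}

#' Distance-distribution-informed neighborhood size
#'
#' Under an approximately normal distance distribution, the probability that
#' a random instance falls inside the MultiSURF radius (mean minus `alpha`
#' standard deviations) gives the expected neighborhood size
#' `k = floor((m - 1) * q_alpha)`. The implementation uses
#' `q_alpha = pnorm(-2 * alpha) = (1 - erf(alpha * sqrt(2))) / 2`, the
#' closed form consistent with the standard MultiSURF-equivalent evaluation
#' `k = floor(0.154 (m - 1)) = 15` at `alpha = 1/2`, `m = 100` (and with
#' `q_0 = 1/2`).
#'
#' @param m Number of instances, `m >= 2`.
#' @param alpha Radius parameter, `alpha >= 0` (`0.5` for MultiSURF).
#' @return Integer expected neighborhood size; strictly nonincreasing in
#'   `alpha`.
#' @examples
#' informed_k(100, 0.5)  # 15
#' @export
informed_k <- function(m, alpha = 0.5) {
  stopifnot(m >= 2, alpha >= 0)
  q_alpha <- stats::pnorm(-2 * alpha)
  as.integer(floor((m - 1) * q_alpha))
}

#' Rule-of-thumb neighborhood size
#'
#' The empirical fixed-k rule `k = floor(m / 6)`, which approximately
#' matches the average MultiSURF neighborhood size (16 at `m = 100`,
#' one neighbor more than [informed_k()]'s 15).
#'
#' @param m Number of instances, `m >= 6`.
#' @return Integer neighborhood size.
#' @export
rule_of_thumb_k <- function(m) {
  stopifnot(m >= 6)
  as.integer(floor(m / 6))
}

#' Neighbor index sets
#'
#' Builds per-instance neighbor sets from a pairwise distance matrix, either
#' the `k` nearest instances (self excluded, ties broken by ascending index)
#' or all instances within the per-instance MultiSURF radius at `alpha`.
#'
#' @param D Symmetric pairwise distance matrix.
#' @param k Fixed neighborhood size (`1 <= k < m`), or `NULL` to use radii.
#' @param alpha Radius parameter used when `k` is `NULL`.
#' @return List of `m` integer vectors of neighbor indices.
#' @export
neighbors <- function(D, k = NULL, alpha = 0.5) {
  D <- as.matrix(D)
  m <- nrow(D)
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 1L || k >= m) stop("k must satisfy 1 <= k < m")
    lapply(seq_len(m), function(i) {
      others <- setdiff(seq_len(m), i)
      others[order(D[i, others])][seq_len(k)]
    })
  } else {
    radii <- multisurf_radii(D, alpha)
    lapply(seq_len(m), function(i) {
      others <- setdiff(seq_len(m), i)
      others[D[i, others] <= radii[i]]
    })
  }
}

#' Relief-style attribute scores
#'
#' Minimal Relief scoring over precomputed neighborhoods: for each attribute
#' the score is the average, over all (instance, neighbor) pairs, of the
#' range-normalized diff signed by class agreement (positive for misses,
#' negative for hits). Neighbors are found on the unnormalized Manhattan
#' distance; scoring always uses range-normalized diffs (the Relief
#' convention), so scores lie in `[-1, 1]`.
#'
#' @param X Continuous data matrix (`m x p`).
#' @param y Binary outcome of length `m` (exactly two classes, each with at
#'   least 2 members).
#' @param k Fixed neighborhood size; `NULL` for MultiSURF radii.
#' @param alpha Radius parameter used when `k` is `NULL`.
#' @return Numeric vector of `p` attribute scores.
#' @export
relief_scores <- function(X, y, k = NULL, alpha = 0.5) {
  X <- continuous_matrix(X)
  m <- nrow(X)
  if (length(y) != m) stop("y must have one label per instance")
  if (length(unique(y)) != 2L) stop("y must be binary")
  if (min(table(y)) < 2L) stop("each class needs at least 2 members")
  D <- lq_distance_matrix(X, q = 1L)
  nb <- neighbors(D, k = k, alpha = alpha)
  rng <- apply(X, 2L, function(col) max(col) - min(col))
  rng[rng <= 0] <- 1 # constant attribute: diff is 0 anyway
  scores <- numeric(ncol(X))
  n_pairs <- 0L
  for (i in seq_len(m)) {
    js <- nb[[i]]
    if (!length(js)) next
    diffs <- abs(sweep(unclass(X)[js, , drop = FALSE], 2L, unclass(X)[i, ]))
    sgn <- ifelse(y[js] == y[i], -1, 1)
    scores <- scores + colSums(diffs * sgn)
    n_pairs <- n_pairs + length(js)
  }
  if (n_pairs == 0L) stop("no neighbors found; widen the neighborhood")
  (scores / rng) / n_pairs
}
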