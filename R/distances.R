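#' Pairwise L_q distance matrix
#'
#' Computes the `m x m` matrix of pairwise distances
#' `D_ij = (sum_a |X_ia - X_ja|^q)^(1/q)` between instances (rows) of a
#' continuous data matrix. With `normalized = TRUE` each attribute difference
#' is divided by that attribute's observed range `max(a) - min(a)` first (the
#' Relief max-min convention, which bounds every one-dimensional projection
#' by 1).
#'
#' @param X Numeric matrix or [continuous_matrix()], instances as rows.
#' @param q Positive integer order of the metric (1 = Manhattan,
#'   2 = Euclidean).
#' @param normalized Divide attribute differences by the attribute range.
#' @param degenerate Policy for a zero-range attribute under normalization:
#'   `"error"` (default) or `"drop"` (drop the attribute with a warning).
#' @return A `distance_matrix` (symmetric, zero diagonal) with metric
#'   provenance.
#' @examples
#' X <- matrix(c(0, 1, 0, 1), 2, 2)
#' lq_distance_matrix(X, q = 1)[1, 2]  # 2
#' @export
lq_distance_matrix <- function(X, q = 1L, normalized = FALSE,
                               degenerate = c("error", "drop")) {
  degenerate <- match.arg(degenerate)
  X <- continuous_matrix(X)
  q <- check_q(q)
  if (normalized) X <- range_scale(X, degenerate)
  method <- if (q == 1L) "manhattan" else if (q == 2L) "euclidean" else "minkowski"
  D <- as.matrix(stats::dist(unclass(X), method = method, p = q))
  new_distance_matrix(
    D, list(family = if (normalized) "lq_maxmin" else "lq",
            q = q, normalized = normalized))
}

#' One-dimensional projection (diff) of the distance onto an attribute
#'
#' The projection `d_ij(a) = |X_ia - X_ja|` over all unordered instance pairs
#' for a single attribute, optionally range-normalized. This is the per-pair
#' predictor used in projected-distance regression and the diff of
#' Relief-based algorithms.
#'
#' @inheritParams lq_distance_matrix
#' @param a Attribute (column) index.
#' @return Numeric vector of `m(m-1)/2` projection values, ordered as the
#'   upper triangle (column-major) of the pairwise matrix.
#' @export
attribute_diff <- function(X, a, normalized = FALSE,
                           degenerate = c("error", "drop")) {
  degenerate <- match.arg(degenerate)
  X <- continuous_matrix(X)
  if (!(is.numeric(a) && length(a) == 1L && a >= 1 && a <= ncol(X)))
    stop("attribute index out of bounds")
  x <- X[, a]
  if (normalized) {
    rng <- max(x) - min(x)
    if (rng <= 0) {
      if (degenerate == "error")
        stop(sprintf("attribute %d has zero range under normalization", a))
      warning(sprintf("attribute %d has zero range; returning zeros", a))
      return(rep(0, nrow(X) * (nrow(X) - 1L) / 2L))
    }
    x <- x / rng
  }
  d <- abs(outer(x, x, "-"))
  d[upper.tri(d)]
}

# internal: scale each column of X by its range, honouring degenerate policy
range_scale <- function(X, degenerate) {
  rng <- apply(X, 2L, function(col) max(col) - min(col))
  if (any(rng <= 0)) {
    bad <- which(rng <= 0)
    if (degenerate == "error")
      stop(sprintf("constant attribute(s) under normalization: %s",
                   paste(bad, collapse = ", ")))
    warning(sprintf("dropping %d constant attribute(s) under normalization",
                    length(bad)))
    X <- X[, -bad, drop = FALSE]
    rng <- rng[-bad]
    if (ncol(X) == 0L) stop("no attributes left after dropping constants")
  }
  sweep(X, 2L, rng, "/")
}

check_q <- function(q) {
  if (!(is.numeric(q) && length(q) == 1L && q >= 1 && q == round(q)))
    stop("q must be a positive integer >= 1")
  as.integer(q)
}

#' GWAS attribute diff (GM, AM, TiTv)
#'
#' One-locus distance contribution between two genotypes (minor-allele
#' counts in `{0, 1, 2}`). Metrics:
#' * `gm` genotype mismatch: 1 if the genotypes differ, else 0;
#' * `am` allele mismatch: `|g_i - g_j| / 2`;
#' * `titv` transition/transversion weighted: 0 on match, 1/4 (one-allele
#'   difference, transition), 1/2 (one-allele difference, transversion),
#'   3/4 (two-allele difference, transition), 1 (two-allele difference,
#'   transversion). A locus encoded PuPu or PyPy substitutes by transition;
#'   PuPy by transversion.
#'
#' @param gi,gj Genotype values in `{0, 1, 2}` (vectorized).
#' @param metric One of `"gm"`, `"am"`, `"titv"`.
#' @param encoding Locus encoding(s) in `c("PuPu", "PuPy", "PyPy")`;
#'   required for `titv` only.
#' @return Numeric diff value(s) in `{0, 1/4, 1/2, 3/4, 1}`.
#' @examples
#' gwas_diff(0, 2, "titv", "PuPy")  # 1
#' gwas_diff(1, 2, "titv", "PuPu")  # 0.25
#' @export
gwas_diff <- function(gi, gj, metric = c("gm", "am", "titv"),
                      encoding = NULL) {
  metric <- match.arg(metric)
  if (!all(gi %in% 0:2) || !all(gj %in% 0:2))
    stop("genotype values must be in {0, 1, 2}")
  delta <- abs(gi - gj)
  switch(metric,
    gm = as.numeric(delta > 0),
    am = delta / 2,
    titv = {
      if (is.null(encoding)) stop("titv metric requires a locus encoding")
      if (!all(encoding %in% c("PuPu", "PuPy", "PyPy")))
        stop("encoding labels must be PuPu, PuPy or PyPy")
      ti <- encoding %in% c("PuPu", "PyPy")
      ifelse(delta == 0, 0,
        ifelse(delta == 1, ifelse(ti, 1 / 4, 1 / 2),
               ifelse(ti, 3 / 4, 1)))
    })
}

#' Pairwise GWAS distance matrix
#'
#' Distance between instances as the sum of per-locus diffs
#' ([gwas_diff()]) across all loci.
#'
#' @param G A [genotype_data()] object (or plain genotype matrix).
#' @param metric One of `"gm"`, `"am"`, `"titv"` (the latter requires locus
#'   encodings in `G`).
#' @return A `distance_matrix`.
#' @export
gwas_distance_matrix <- function(G, metric = c("gm", "am", "titv")) {
  metric <- match.arg(metric)
  if (!inherits(G, "genotype_data")) G <- genotype_data(G)
  X <- G$genotypes
  m <- nrow(X)
  if (metric == "titv" && is.null(G$encoding))
    stop("titv metric requires locus encodings in the genotype data")
  D <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      D[i, j] <- D[j, i] <-
        sum(gwas_diff(X[i, ], X[j, ], metric, G$encoding))
    }
  }
  new_distance_matrix(D, list(family = metric, normalized = FALSE))
}

#' Row block of a region of interest in a correlation stack
#'
#' In the `p(p-1) x m` stack layout, ROI `k` occupies rows
#' `start_k = (k - 1)(p - 1) + 1` through `end_k = k(p - 1)` (1-based).
#'
#' @param k ROI index, `1 <= k <= p`.
#' @param p Number of ROIs.
#' @return Integer vector `c(start, end)`.
#' @examples
#' roi_block_indices(1, 10)   # 1 9
#' roi_block_indices(10, 10)  # 82 90
#' @export
roi_block_indices <- function(k, p) {
  k <- as.integer(k); p <- as.integer(p)
  if (p < 2L) stop("need at least 2 ROIs")
  if (k < 1L || k > p) stop("ROI index out of range")
  c(start = (k - 1L) * (p - 1L) + 1L, end = k * (p - 1L))
}

#' ROI-level diff between two subjects of a correlation stack
#'
#' `d_ij(a) = sum_{k != a} |A_ka(i) - A_ka(j)|`: the sum over ROI `a`'s block
#' of absolute differences between the two subjects' transformed
#' correlations.
#'
#' @param S A [correlation_stack()].
#' @param i,j Subject (column) indices.
#' @param a ROI index.
#' @return Nonnegative scalar.
#' @export
fmri_roi_diff <- function(S, i, j, a) {
  stopifnot(inherits(S, "correlation_stack"))
  if (any(c(i, j) < 1L) || any(c(i, j) > S$m)) stop("subject index out of bounds")
  blk <- roi_block_indices(a, S$p)
  rows <- blk[["start"]]:blk[["end"]]
  sum(abs(S$values[rows, i] - S$values[rows, j]))
}

#' Pairwise distance matrix for stacked correlation data
#'
#' `D_ij = sum_a d_ij(a)` with the ROI diff of [fmri_roi_diff()]; because
#' every unordered ROI pair appears in two blocks, this is exactly the
#' Manhattan (L_1) distance between the subjects' stack columns. With
#' `normalized = TRUE` each ROI block's differences are divided by that
#' block's range (max - min over all `m(p-1)` block values).
#'
#' @param S A [correlation_stack()].
#' @param normalized Range-normalize per ROI block.
#' @param degenerate Policy for a zero-range ROI block under normalization.
#' @return A `distance_matrix`.
#' @export
fmri_distance_matrix <- function(S, normalized = FALSE,
                                 degenerate = c("error", "drop")) {
  degenerate <- match.arg(degenerate)
  stopifnot(inherits(S, "correlation_stack"))
  V <- S$values
  if (normalized) {
    for (a in seq_len(S$p)) {
      blk <- roi_block_indices(a, S$p)
      rows <- blk[["start"]]:blk[["end"]]
      rng <- max(V[rows, ]) - min(V[rows, ])
      if (rng <= 0) {
        if (degenerate == "error")
          stop(sprintf("ROI %d has zero range under normalization", a))
        warning(sprintf("ROI %d has zero range; its block contributes 0", a))
        V[rows, ] <- 0
        next
      }
      V[rows, ] <- V[rows, ] / rng
    }
  }
  D <- as.matrix(stats::dist(t(V), method = "manhattan"))
  new_distance_matrix(
    D, list(family = if (normalized) "fmri_maxmin" else "fmri",
            q = 1L, normalized = normalized))
}
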