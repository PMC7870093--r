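#' Construct a continuous data matrix
#'
#' A continuous data set is an `m x p` numeric matrix with instances (samples)
#' as rows and attributes (features) as columns. All entries must be finite,
#' with at least two instances and one attribute.
#'
#' @param values Numeric matrix, `m` instances by `p` attributes.
#' @return A `continuous_matrix`: the validated matrix with class attribute.
#' @export
continuous_matrix <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("continuous data must be numeric")
  if (nrow(values) < 2L) stop("need at least 2 instances (rows)")
  if (ncol(values) < 1L) stop("need at least 1 attribute (column)")
  if (!all(is.finite(values))) stop("all entries must be finite")
  storage.mode(values) <- "double"
  class(values) <- c("continuous_matrix", "matrix", "array")
  values
}

#' Construct a GWAS genotype data set
#'
#' Genotypes are minor-allele counts in `{0, 1, 2}` (homozygous common,
#' heterozygous, homozygous minor). Each locus may carry a minor allele
#' frequency (MAF) and a purine/pyrimidine encoding (`PuPu`, `PuPy`, `PyPy`)
#' which determines whether a substitution at that locus is a transition
#' (PuPu or PyPy) or a transversion (PuPy). The transition/transversion
#' ratio `eta` and the encoding probabilities `gammas = (gamma0, gamma1,
#' gamma2)` describe the generating model when known.
#'
#' @param genotypes Integer matrix (`m x p`) with entries in `{0, 1, 2}`.
#' @param maf Optional numeric vector of `p` minor allele frequencies in (0, 1).
#' @param encoding Optional character vector of `p` labels in
#'   `c("PuPu", "PuPy", "PyPy")`.
#' @param eta Optional positive transition/transversion ratio.
#' @param gammas Optional probabilities of PuPu, PuPy, PyPy (sum to 1).
#' @return A `genotype_data` list with elements `genotypes`, `maf`,
#'   `encoding`, `eta`, `gammas`, `m`, `p`.
#' @export
genotype_data <- function(genotypes, maf = NULL, encoding = NULL,
                          eta = NULL, gammas = NULL) {
  genotypes <- as.matrix(genotypes)
  if (!all(genotypes %in% c(0L, 1L, 2L)))
    stop("genotypes must be in {0, 1, 2}")
  storage.mode(genotypes) <- "integer"
  p <- ncol(genotypes)
  if (!is.null(maf)) {
    if (length(maf) != p) stop("maf must have one value per locus")
    if (any(maf <= 0 | maf >= 1)) stop("maf values must lie strictly in (0, 1)")
  }
  if (!is.null(encoding)) {
    if (length(encoding) != p) stop("encoding must have one label per locus")
    if (!all(encoding %in% c("PuPu", "PuPy", "PyPy")))
      stop("encoding labels must be PuPu, PuPy or PyPy")
  }
  if (!is.null(gammas)) {
    if (length(gammas) != 3L || any(gammas < 0))
      stop("gammas must be 3 nonnegative probabilities")
    if (abs(sum(gammas) - 1) > 1e-8) stop("gammas must sum to 1")
  }
  if (!is.null(eta) && eta <= 0) stop("eta must be positive")
  structure(list(genotypes = genotypes, maf = maf, encoding = encoding,
                 eta = eta, gammas = gammas,
                 m = nrow(genotypes), p = p),
            class = "genotype_data")
}

#' Construct a stacked correlation data set
#'
#' Time-series correlation data (for example resting-state fMRI functional
#' connectivity) is organised as a `p(p-1) x m` matrix: one column per
#' subject, and for each region of interest (ROI) `a` a block of `p - 1`
#' consecutive rows holding that ROI's transformed correlations with every
#' other ROI. Each unordered ROI pair therefore appears twice per column.
#' Use [build_correlation_stack()] to produce this layout from per-subject
#' correlation matrices (Fisher r-to-z plus column standardization).
#'
#' @param values Numeric matrix with `p * (p - 1)` rows and `m` columns.
#' @param p Number of ROIs.
#' @param standardized Logical flag recording whether Fisher z transform and
#'   per-column zero-mean/unit-variance standardization were applied.
#' @return A `correlation_stack` list with elements `values`, `p`, `m`,
#'   `standardized`.
#' @export
correlation_stack <- function(values, p, standardized = TRUE) {
  values <- as.matrix(values)
  p <- as.integer(p)
  if (p < 2L) stop("need at least 2 ROIs")
  if (nrow(values) != p * (p - 1L))
    stop(sprintf("stack must have p(p-1) = %d rows, got %d",
                 p * (p - 1L), nrow(values)))
  if (ncol(values) < 2L) stop("need at least 2 subjects (columns)")
  if (!all(is.finite(values))) stop("all entries must be finite")
  structure(list(values = values, p = p, m = ncol(values),
                 standardized = isTRUE(standardized)),
            class = "correlation_stack")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d instances x %d loci", x$m, x$p))
  if (!is.null(x$encoding)) cat(", with Pu/Py encodings")
  if (!is.null(x$eta)) cat(sprintf(", Ti/Tv ratio %.3g", x$eta))
  cat("\n")
  invisible(x)
}

#' @export
print.correlation_stack <- function(x, ...) {
  cat(sprintf("correlation_stack: %d ROIs, %d subjects (%d x %d)%s\n",
              x$p, x$m, nrow(x$values), x$m,
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

# internal: wrap a symmetric pairwise-distance matrix with metric provenance
new_distance_matrix <- function(values, metric) {
  dimnames(values) <- dimnames(values) %||%
    list(seq_len(nrow(values)), seq_len(nrow(values)))
  structure(values, metric = metric,
            class = c("distance_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Metric provenance of a distance matrix
#'
#' @param D A `distance_matrix`.
#' @return A list describing the metric (family, and `q` for L_q families).
#' @export
metric_spec <- function(D) attr(D, "metric")

#' @export
print.distance_matrix <- function(x, ...) {
  ms <- attr(x, "metric")
  cat(sprintf("distance_matrix: %d x %d, metric %s%s%s\n",
              nrow(x), ncol(x), ms$family,
              if (!is.null(ms$q)) sprintf(" (q = %d)", ms$q) else "",
              if (isTRUE(ms$normalized)) ", max-min normalized" else ""))
  invisible(x)
}

#' Upper-triangle distances of a distance matrix
#'
#' Convenience accessor for the `m(m-1)/2` pairwise distances above the
#' diagonal, the sample on which distance-distribution moments are computed.
#'
#' @param D A `distance_matrix` (or plain symmetric matrix).
#' @return Numeric vector of length `m(m-1)/2`.
#' @export
pairwise_values <- function(D) {
  D <- unclass(D)
  D[upper.tri(D)]
}
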