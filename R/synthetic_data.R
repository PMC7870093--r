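#' Generate an iid continuous data matrix
#'
#' `m x p` matrix of iid standard normal or standard uniform entries, the
#' null data model of the distance-distribution theory.
#'
#' @param m Number of instances.
#' @param p Number of attributes.
#' @param data_model `"normal"` or `"uniform"`.
#' @param seed Integer seed.
#' @return A [continuous_matrix()].
#' @export
gen_continuous <- function(m, p, data_model = c("normal", "uniform"),
                           seed = 1L) {
  data_model <- match.arg(data_model)
  stopifnot(m >= 2, p >= 1)
  set.seed(seed)
  vals <- if (data_model == "normal") stats::rnorm(m * p) else stats::runif(m * p)
  continuous_matrix(matrix(vals, m, p))
}

#' Generate a random GWAS genotype data set
#'
#' Per-locus minor allele frequencies are drawn `f_a ~ U(maf_low, maf_high)`
#' and genotypes are binomial minor-allele counts `X_ia ~ B(2, f_a)`. Locus
#' encodings (PuPu / PuPy / PyPy) are drawn with the probabilities implied
#' by the Ti/Tv ratio `eta` (see [encoding_gammas()]).
#'
#' @param m Number of instances.
#' @param p Number of loci.
#' @param maf_low,maf_high MAF sampling bounds, `0 < maf_low < maf_high < 1`.
#' @param eta Ti/Tv ratio (about 2 in human data).
#' @param epsilon Margin for the gamma0 draw.
#' @param seed Integer seed.
#' @return A [genotype_data()] with `maf`, `encoding`, `eta` and `gammas`
#'   recorded.
#' @export
gen_gwas <- function(m, p, maf_low = 0.05, maf_high = 0.5, eta = 2,
                     epsilon = 0.01, seed = 1L) {
  stopifnot(m >= 2, p >= 1)
  if (!(maf_low > 0 && maf_low < maf_high && maf_high < 1))
    stop("need 0 < maf_low < maf_high < 1")
  set.seed(seed)
  enc_model <- encoding_gammas(eta, epsilon)
  maf <- stats::runif(p, maf_low, maf_high)
  genotypes <- matrix(stats::rbinom(m * p, size = 2,
                                    prob = rep(maf, each = m)), m, p)
  encoding <- sample(c("PuPu", "PuPy", "PyPy"), p, replace = TRUE,
                     prob = c(enc_model$gamma0, enc_model$gamma1,
                              enc_model$gamma2))
  genotype_data(genotypes, maf = maf, encoding = encoding, eta = eta,
                gammas = c(enc_model$gamma0, enc_model$gamma1,
                           enc_model$gamma2))
}

#' Generate a null correlation stack
#'
#' Emulates null resting-state connectivity data: for each of `m` subjects,
#' `p` independent Gaussian time series of length `T` are correlated, the
#' off-diagonal correlations are Fisher r-to-z transformed and arranged in
#' the ROI-block stack layout (each unordered ROI pair appearing twice per
#' column), and columns are standardized to zero mean and unit variance.
#' After standardization the entries are approximately standard normal,
#' which is the premise of the stack-distance moment formulas.
#'
#' @param m Number of subjects.
#' @param p Number of ROIs.
#' @param T Time-series length (default `4 * p`; `T > p` recommended).
#' @param seed Integer seed.
#' @param z_clamp Bound at which Fisher z values of |r| near 1 are clamped
#'   (only reachable on degenerate inputs).
#' @return A [correlation_stack()] with `standardized = TRUE`.
#' @export
gen_fmri_stack <- function(m, p, T = 4L * p, seed = 1L, z_clamp = 12) {
  stopifnot(m >= 2, p >= 2, T >= 3)
  set.seed(seed)
  X <- matrix(0, p * (p - 1L), m)
  for (i in seq_len(m)) {
    ts <- matrix(stats::rnorm(T * p), T, p)
    Z <- atanh(pmin(pmax(stats::cor(ts), -1 + 1e-15), 1 - 1e-15))
    Z <- pmin(pmax(Z, -z_clamp), z_clamp)
    # ROI a's block: correlations of a with every k != a
    X[, i] <- unlist(lapply(seq_len(p), function(a) Z[-a, a]),
                     use.names = FALSE)
  }
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  correlation_stack(X, p = p, standardized = TRUE)
}

#' Build a correlation stack from per-subject correlation matrices
#'
#' Applies the Fisher r-to-z transform to each subject's `p x p` symmetric
#' correlation matrix, stacks the off-diagonal entries in the ROI-block
#' layout, and standardizes each subject column to zero mean and unit
#' variance.
#'
#' @param mats List of `m` symmetric `p x p` correlation matrices.
#' @param z_clamp Clamp for Fisher z of correlations at |r| = 1.
#' @return A [correlation_stack()].
#' @export
build_correlation_stack <- function(mats, z_clamp = 12) {
  stopifnot(is.list(mats), length(mats) >= 2)
  p <- nrow(mats[[1]])
  cols <- lapply(mats, function(R) {
    R <- as.matrix(R)
    if (nrow(R) != p || ncol(R) != p) stop("all matrices must be p x p")
    if (max(abs(R - t(R))) > 1e-8) stop("correlation matrices must be symmetric")
    Z <- atanh(pmin(pmax(R, -1 + 1e-15), 1 - 1e-15))
    Z <- pmin(pmax(Z, -z_clamp), z_clamp)
    unlist(lapply(seq_len(p), function(a) Z[-a, a]), use.names = FALSE)
  })
  X <- scale(do.call(cbind, cols))
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  correlation_stack(X, p = p, standardized = TRUE)
}

#' Random structured correlation target from a random graph
#'
#' Draws an Erdos-Renyi-style graph on the `p` attributes, assigns
#' correlation `hi` to connected pairs and `lo` to non-connections (unit
#' diagonal), then repairs the matrix to positive definiteness by clipping
#' eigenvalues at a small floor and renormalizing to unit diagonal. Varying
#' the connection probability dials the average absolute pairwise
#' correlation of data generated from the target.
#'
#' @param p Number of attributes.
#' @param connection_prob Edge probability of the random graph.
#' @param hi Correlation on edges (|hi| < 1).
#' @param lo Correlation on non-edges (|lo| < 1).
#' @param seed Integer seed.
#' @param eig_floor Eigenvalue floor used in the positive-definite repair.
#' @return A `correlation_target` list with the `p x p` matrix and the
#'   generation parameters.
#' @export
random_structured_correlation <- function(p, connection_prob, hi = 0.8,
                                          lo = 0, seed = 1L,
                                          eig_floor = 1e-4) {
  stopifnot(p >= 2, connection_prob >= 0, connection_prob <= 1,
            abs(hi) < 1, abs(lo) < 1)
  set.seed(seed)
  R <- matrix(lo, p, p)
  n_pairs <- p * (p - 1L) / 2L
  edges <- stats::runif(n_pairs) < connection_prob
  R[upper.tri(R)][edges] <- hi
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  diag(R) <- 1
  R <- repair_positive_definite(R, eig_floor)
  structure(list(matrix = R, source = "random_graph",
                 connection_prob = connection_prob, hi = hi, lo = lo,
                 seed = seed),
            class = "correlation_target")
}

# eigenvalue clipping followed by renormalization to unit diagonal
repair_positive_definite <- function(R, eig_floor = 1e-4) {
  eg <- eigen(R, symmetric = TRUE)
  if (min(eg$values) < eig_floor) {
    vals <- pmax(eg$values, eig_floor)
    R <- eg$vectors %*% diag(vals) %*% t(eg$vectors)
    R <- stats::cov2cor(R)
    R <- (R + t(R)) / 2
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("positive-definite repair failed")
  R
}

#' Impose a target correlation structure on iid normal data
#'
#' Multiplies an `m x p` matrix of iid standard normal columns by the
#' Cholesky factor of the target correlation matrix, so the columns of the
#' result have (population) correlation equal to the target.
#'
#' @param X Matrix of iid standard normal data (`m x p`).
#' @param R A `correlation_target` or plain positive-definite correlation
#'   matrix with `p` rows.
#' @return A [continuous_matrix()] with correlated columns.
#' @export
impose_correlation <- function(X, R) {
  X <- continuous_matrix(X)
  if (inherits(R, "correlation_target")) R <- R$matrix
  R <- as.matrix(R)
  if (ncol(X) != nrow(R)) stop("dimension mismatch between X and R")
  U <- chol(R) # upper triangular, R = t(U) %*% U
  continuous_matrix(unclass(X) %*% U)
}

#' Map correlated Gaussian attributes to binomial genotypes
#'
#' Applies the standard normal cdf to each entry (giving correlated uniform
#' variates) and then the binomial(2, f_a) quantile function per locus,
#' yielding genotypes in `{0, 1, 2}` with approximately preserved rank
#' correlation structure.
#'
#' @param Xcorr Matrix of (possibly correlated) approximately standard
#'   normal attributes.
#' @param maf Vector of per-locus minor allele frequencies.
#' @return A [genotype_data()] carrying `maf`.
#' @export
gaussian_to_binomial <- function(Xcorr, maf) {
  Xcorr <- as.matrix(Xcorr)
  if (length(maf) != ncol(Xcorr)) stop("one MAF per attribute required")
  G <- vapply(seq_len(ncol(Xcorr)), function(a)
    stats::qbinom(stats::pnorm(Xcorr[, a]), size = 2, prob = maf[a]),
    numeric(nrow(Xcorr)))
  genotype_data(G, maf = maf)
}

#' Average absolute pairwise attribute correlation
#'
#' `rbar_abs = 2 / (p (p - 1)) * sum_{a < b} |r_ab|`, the dial used to
#' quantify how far a data set departs from the uncorrelated null.
#'
#' @param X Data matrix with at least two attributes.
#' @param warn_constant Warn and exclude constant attributes (undefined
#'   correlations) rather than failing.
#' @return Scalar in `[0, 1]`.
#' @export
mean_abs_correlation <- function(X, warn_constant = TRUE) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 attributes")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    if (!warn_constant) stop("constant attribute: correlation undefined")
    warning(sprintf("excluding %d constant attribute(s)", sum(sds == 0)))
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) < 2) stop("fewer than 2 non-constant attributes")
  }
  R <- stats::cor(X)
  mean(abs(R[upper.tri(R)]))
}

#' Simulate a feature-selection benchmark data set
#'
#' Case/control data with `p` continuous attributes of which `n_functional`
#' carry signal. Main-effect attributes receive a between-group mean shift
#' of `main_delta` standard deviations; interaction attributes have zero
#' marginal mean shift but are pairwise correlated (at `int_rho`) within
#' cases and uncorrelated within controls, i.e. group-differential
#' correlation. `effect = "mixed"` splits the functional set evenly between
#' the two mechanisms. The differential-correlation construction is a
#' surrogate for interaction-network simulators; it produces the epistasis
#' signature (group-wise correlation difference without marginal shift)
#' without modelling a specific network.
#'
#' @param m Number of instances (even; classes are balanced).
#' @param p Number of attributes.
#' @param n_functional Number of signal attributes (`< p`).
#' @param effect `"main"`, `"interaction"` or `"mixed"`.
#' @param main_delta Group mean shift for main-effect attributes, in SD
#'   units.
#' @param int_rho Within-case pairwise correlation of interaction
#'   attributes.
#' @param seed Integer seed.
#' @return List with `X` (a [continuous_matrix()]), `y` (0/1 outcome),
#'   `functional` (logical mask of signal attributes), and the generation
#'   parameters.
#' @export
gen_feature_selection_benchmark <- function(m = 100L, p = 1000L,
                                            n_functional = 100L,
                                            effect = c("mixed", "main",
                                                       "interaction"),
                                            main_delta = 0.8, int_rho = 0.6,
                                            seed = 1L) {
  effect <- match.arg(effect)
  stopifnot(n_functional < p, m %% 2L == 0L, m >= 4L)
  set.seed(seed)
  X <- matrix(stats::rnorm(m * p), m, p)
  y <- rep(c(0L, 1L), each = m %/% 2L)
  functional <- rep(FALSE, p)
  functional[seq_len(n_functional)] <- TRUE
  idx <- which(functional)
  main_idx <- int_idx <- integer(0)
  if (effect == "main") main_idx <- idx
  if (effect == "interaction") int_idx <- idx
  if (effect == "mixed") {
    half <- length(idx) %/% 2L
    main_idx <- idx[seq_len(half)]
    int_idx <- idx[(half + 1L):length(idx)]
  }
  if (length(main_idx))
    X[y == 1L, main_idx] <- X[y == 1L, main_idx] + main_delta
  if (length(int_idx) >= 2L) {
    k <- length(int_idx)
    R <- matrix(int_rho, k, k); diag(R) <- 1
    R <- repair_positive_definite(R)
    X[y == 1L, int_idx] <- X[y == 1L, int_idx, drop = FALSE] %*% chol(R)
  }
  list(X = continuous_matrix(X), y = y, functional = functional,
       effect = effect, main_idx = main_idx, int_idx = int_idx,
       main_delta = main_delta, int_rho = int_rho, seed = seed)
}
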