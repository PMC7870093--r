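#' Asymptotic moments of the stacked-correlation (ROI) distance
#'
#' For a standardized `p(p-1) x m` correlation stack with approximately
#' standard normal entries, the pairwise distance has mean
#' `2 p (p - 1) / sqrt(pi)`. Treating all `p(p-1)` row differences as
#' independent gives the naive variance `2 (pi - 2) p (p - 1) / pi`; the
#' shared-ROI structure of the stack adds cross-covariance, captured by the
#' corrected variance `9 p (pi - 2)(p - 1) / (4 pi)` (the naive value plus
#' `p (pi - 2)(p - 1) / (4 pi)`), which tracks sample variances on null
#' stacks more closely and is the default.
#'
#' @param p Number of ROIs, `p >= 2`.
#' @param corrected Use the covariance-corrected variance (default `TRUE`).
#' @return A `moment_summary`.
#' @export
fmri_distance_moments <- function(p, corrected = TRUE) {
  if (p < 2) stop("p must be at least 2")
  mean <- 2 * p * (p - 1) / sqrt(pi)
  variance <- if (corrected) {
    9 * p * (pi - 2) * (p - 1) / (4 * pi)
  } else {
    2 * (pi - 2) * p * (p - 1) / pi
  }
  moment_summary(mean, variance,
                 params = list(metric = "fmri", p = p, corrected = corrected,
                               normalized = FALSE))
}

#' Moments of the ROI-level diff
#'
#' The projection of the stack distance onto a single ROI sums `p - 1`
#' absolute differences: mean `2 (p - 1) / sqrt(pi)` and variance
#' `2 (pi - 2)(p - 1) / pi`. For a single fixed ROI the cross-covariance
#' between row differences is negligible, so this linear-variance estimate
#' is the default; the covariance-scaled alternative
#' `9 (pi - 2)(p - 1) / (4 pi)` is available via `corrected = TRUE`.
#'
#' @param p Number of ROIs, `p >= 2`.
#' @param corrected Use the covariance-scaled variance (default `FALSE`).
#' @return A `diff_moments` list with `mu_z`, `sigma2_z`.
#' @export
fmri_diff_moments <- function(p, corrected = FALSE) {
  if (p < 2) stop("p must be at least 2")
  mu <- 2 * (p - 1) / sqrt(pi)
  sigma2 <- if (corrected) {
    9 * (pi - 2) * (p - 1) / (4 * pi)
  } else {
    2 * (pi - 2) * (p - 1) / pi
  }
  structure(list(mu_z = mu, sigma2_z = sigma2, q = 1L, data_model = "fmri"),
            class = "diff_moments")
}

#' Moments of the max-min normalized stack distance
#'
#' Range normalization of an ROI block draws its extremes from the
#' `m (p - 1)` approximately standard normal values of the block, so the
#' extreme-value sample size is `m (p - 1)`. With `mu_max` the Gumbel-limit
#' median of the normal sample maximum at that size and `(mu_D, sigma2_D)`
#' the corrected stack-distance moments, the normalized distance has mean
#' `mu_D / (2 mu_max)` and variance
#' `6 sigma2_D log(m(p-1)) / (pi^2 + 24 mu_max^2 log(m(p-1)))`. The variance
#' vanishes as `m (p - 1)` grows.
#'
#' @param m Number of subjects.
#' @param p Number of ROIs, with `m (p - 1) >= 2`.
#' @return A `moment_summary`.
#' @export
fmri_maxmin_moments <- function(m, p) {
  if (p < 2) stop("p must be at least 2")
  n <- m * (p - 1)
  if (n < 2) stop("effective extreme-value sample size m(p-1) must be >= 2")
  base <- fmri_distance_moments(p, corrected = TRUE)
  mu_max <- normal_max_stats(n)$median
  mean <- base$mean / (2 * mu_max)
  variance <- 6 * base$variance * log(n) / (pi^2 + 24 * mu_max^2 * log(n))
  moment_summary(mean, variance,
                 params = list(metric = "fmri", p = p, m = m,
                               normalized = TRUE))
}

#' Fit the stack-distance variance-correction coefficients
#'
#' On null correlation stacks the sample variance of pairwise distances
#' exceeds the independence-assumption variance
#' `2 p (pi - 2)(p - 1) / pi`; the discrepancy grows quadratically in `p`.
#' This routine simulates null stacks over a grid of ROI counts
#' ([gen_fmri_stack()]), computes each stack's sample distance variance,
#' subtracts the independence variance, and least-squares fits the
#' discrepancy to `beta1 * p^2 + beta0 * p` (no intercept). The quadratic
#' coefficient summarizes the cross-covariance induced by the shared-ROI
#' stack structure.
#'
#' @param p_grid Increasing grid of ROI counts (at least 3 values).
#' @param m Number of subjects per stack.
#' @param replicates Stacks per grid point (at least 5).
#' @param T Time-series length per subject; default `4 * p`.
#' @param seed Integer seed for reproducibility.
#' @return A `correction_fit` list with `beta0`, `beta1`, the per-cell
#'   discrepancy table, residual standard error, and the call parameters.
#' @export
fit_variance_correction <- function(p_grid, m = 100L, replicates = 20L,
                                    T = NULL, seed = 1L) {
  p_grid <- sort(as.integer(p_grid))
  if (length(p_grid) < 3L) stop("p_grid needs at least 3 points")
  if (replicates < 5L) stop("need at least 5 replicates per grid point")
  rows <- vector("list", length(p_grid) * replicates)
  idx <- 1L
  for (gi in seq_along(p_grid)) {
    p <- p_grid[gi]
    Tp <- if (is.null(T)) 4L * p else as.integer(T)
    naive <- 2 * p * (pi - 2) * (p - 1) / pi
    for (r in seq_len(replicates)) {
      S <- gen_fmri_stack(m, p, T = Tp,
                          seed = derive_seed(seed, gi * 1000L + r))
      D <- fmri_distance_matrix(S)
      rows[[idx]] <- data.frame(
        p = p, replicate = r,
        sample_variance = stats::var(pairwise_values(D)),
        naive_variance = naive)
      idx <- idx + 1L
    }
  }
  tab <- do.call(rbind, rows)
  tab$discrepancy <- tab$sample_variance - tab$naive_variance
  fit <- stats::lm(discrepancy ~ 0 + I(p^2) + p, data = tab)
  beta <- stats::coef(fit)
  structure(list(beta1 = unname(beta[["I(p^2)"]]),
                 beta0 = unname(beta[["p"]]),
                 table = tab,
                 sigma = summary(fit)$sigma,
                 coef_se = summary(fit)$coefficients[, "Std. Error"],
                 p_grid = p_grid, m = m, replicates = replicates,
                 seed = seed),
            class = "correction_fit")
}

#' @export
print.correction_fit <- function(x, ...) {
  cat(sprintf(
    "stack-distance variance correction: beta1 = %.4f, beta0 = %.4f\n",
    x$beta1, x$beta0))
  cat(sprintf("  (p grid %d..%d, m = %d, %d replicates per p)\n",
              min(x$p_grid), max(x$p_grid), x$m, x$replicates))
  invisible(x)
}

# deterministic per-task sub-seed below 2^31 (double arithmetic: the
# intermediate product overflows integer range)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629)
}
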