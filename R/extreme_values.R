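#' Distributions of the sample maximum and minimum
#'
#' For an iid sample of size `m` from a distribution with cdf `FX` and
#' density `fX`, the sample maximum has cdf `FX(x)^m` and density
#' `m FX(x)^(m-1) fX(x)`; the sample minimum has cdf `1 - (1 - FX(x))^m`
#' and density `m (1 - FX(x))^(m-1) fX(x)`.
#'
#' @param FX Vectorized cdf of the data distribution.
#' @param fX Vectorized density of the data distribution.
#' @param m Sample size, `m >= 1`.
#' @return A list of vectorized functions `Fmax`, `fmax`, `Fmin`, `fmin`.
#' @export
extreme_distributions <- function(FX, fX, m) {
  stopifnot(m >= 1)
  list(
    Fmax = function(x) FX(x)^m,
    fmax = function(x) m * FX(x)^(m - 1) * fX(x),
    Fmin = function(x) 1 - (1 - FX(x))^m,
    fmin = function(x) m * (1 - FX(x))^(m - 1) * fX(x)
  )
}

#' Raw moments of sample extremes by quadrature
#'
#' First and second raw moments (and variances) of the sample maximum and
#' minimum of an iid sample of size `m`, by adaptive quadrature of
#' `m * integral x^r fX(x) FX(x)^(m-1) dx` and its minimum analogue.
#'
#' @inheritParams extreme_distributions
#' @param lower,upper Support bounds for the quadrature.
#' @param abs_tol Absolute quadrature tolerance.
#' @return An `extreme_moments` list with `mu_max1`, `mu_max2`, `var_max`,
#'   `mu_min1`, `mu_min2`, `var_min`, `m`.
#' @export
extreme_moments_numeric <- function(FX, fX, m, lower = -Inf, upper = Inf,
                                    abs_tol = 1e-10) {
  stopifnot(m >= 1)
  ev <- extreme_distributions(FX, fX, m)
  quad <- function(f) {
    int <- stats::integrate(f, lower, upper, abs.tol = abs_tol,
                            rel.tol = 1e-9, subdivisions = 400L)
    if (int$message != "OK") stop("quadrature failed: ", int$message)
    int$value
  }
  mu_max1 <- quad(function(x) x * ev$fmax(x))
  mu_max2 <- quad(function(x) x^2 * ev$fmax(x))
  mu_min1 <- quad(function(x) x * ev$fmin(x))
  mu_min2 <- quad(function(x) x^2 * ev$fmin(x))
  structure(list(mu_max1 = mu_max1, mu_max2 = mu_max2,
                 var_max = mu_max2 - mu_max1^2,
                 mu_min1 = mu_min1, mu_min2 = mu_min2,
                 var_min = mu_min2 - mu_min1^2, m = m),
            class = "extreme_moments")
}

#' Gumbel-limit statistics of the normal sample maximum
#'
#' For `m` iid standard normal draws, the sample maximum is asymptotically
#' Gumbel with location `c_m = -qnorm(1/m)` and scale `1/c_m`. This gives
#' * mean `c_m + gamma / c_m` (Euler-Mascheroni constant `gamma`),
#' * median `c_m - log(log 2) / c_m`,
#' * variance `pi^2 / (12 log m)`.
#'
#' The median is the preferred point estimate of the sample maximum for
#' range normalization: the Gumbel mean slightly overestimates the observed
#' maximum at practical `m`.
#'
#' @param m Sample size, `m >= 2`.
#' @return List with `mean_gumbel`, `median`, `variance`.
#' @examples
#' normal_max_stats(100)$median  # about 2.484
#' @export
normal_max_stats <- function(m) {
  if (m < 2) stop("m must be at least 2")
  cm <- -stats::qnorm(1 / m)
  euler_gamma <- -digamma(1)
  list(mean_gumbel = cm + euler_gamma / cm,
       median = cm - log(log(2)) / cm,
       variance = pi^2 / (12 * log(m)))
}

#' Moments of the range of a normal sample
#'
#' The standard normal density is even, so the expected range of `m` iid
#' draws is twice the expected maximum; with nearly uncorrelated extremes
#' the range variance is twice the maximum's variance, `pi^2 / (6 log m)`.
#' By default the expected maximum is estimated by the Gumbel-limit median
#' (see [normal_max_stats()]); set `use_median = FALSE` for the Gumbel mean.
#'
#' @param m Sample size, `m >= 2`.
#' @param use_median Use the median (default) rather than the Gumbel mean of
#'   the sample maximum.
#' @return List with `mean_range`, `var_range`, and the `mu_max` used.
#' @export
normal_range_moments <- function(m, use_median = TRUE) {
  st <- normal_max_stats(m)
  mu_max <- if (use_median) st$median else st$mean_gumbel
  list(mean_range = 2 * mu_max, var_range = pi^2 / (6 * log(m)),
       mu_max = mu_max)
}

#' Closed-form extreme moments for standard uniform samples
#'
#' For `m` iid U(0, 1) draws: `E[max] = m/(m+1)`, `E[min] = 1/(m+1)`,
#' `E[max^2] = m/(m+2)`, `E[min^2] = 2/((m+1)(m+2))`, and (treating max and
#' min as uncorrelated, the large-`m` approximation)
#' `E[(max - min)^2] = (m^3 - m + 2) / ((m+2)(m+1)^2)`. The independence
#' approximation is not valid at `m = 1`, so `m >= 2` is required.
#'
#' @param m Sample size, `m >= 2`.
#' @return An `extreme_moments` list with the additional element
#'   `range_second_moment`.
#' @export
uniform_extreme_moments <- function(m) {
  if (m < 2) stop("m must be at least 2")
  mu_max1 <- m / (m + 1)
  mu_max2 <- m / (m + 2)
  mu_min1 <- 1 / (m + 1)
  mu_min2 <- 2 / ((m + 1) * (m + 2))
  out <- structure(list(mu_max1 = mu_max1, mu_max2 = mu_max2,
                        var_max = mu_max2 - mu_max1^2,
                        mu_min1 = mu_min1, mu_min2 = mu_min2,
                        var_min = mu_min2 - mu_min1^2, m = m),
                   class = "extreme_moments")
  out$range_second_moment <- (m^3 - m + 2) / ((m + 2) * (m + 1)^2)
  out
}

#' Moments of the max-min (range-) normalized L_q distance
#'
#' Asymptotic mean and variance of the range-normalized L_q distance
#' computed on `m x p` iid data, combining the standard L_q moments
#' ([lq_distance_moments()]) with extreme-value moments of the attribute
#' range:
#' * normal data: mean `mu_D / (2 mu_max)` and variance
#'   `6 sigma2_D log(m) / (pi^2 + 24 mu_max^2 log(m))`, with `mu_max` the
#'   Gumbel-limit median of the sample maximum;
#' * uniform data: mean `(m+1) mu_D / (m-1)` and variance
#'   `(m+2)(m+1)^2 sigma2_D / (m^3 - m + 2)`.
#'
#' As `m` grows the uniform moments converge to the standard L_q moments;
#' the normal variance vanishes.
#'
#' @param p Number of attributes.
#' @param q Metric order.
#' @param m Sample size (source of the attribute extremes), `m >= 2`.
#' @param data_model `"normal"` or `"uniform"`.
#' @param improved Use the improved `q = 2` mean for the underlying standard
#'   metric.
#' @return A `moment_summary`.
#' @export
maxmin_lq_moments <- function(p, q, m, data_model = c("normal", "uniform"),
                              improved = TRUE) {
  data_model <- match.arg(data_model)
  if (m < 2) stop("m must be at least 2")
  base <- lq_distance_moments(p, q, data_model, improved = improved)
  if (data_model == "normal") {
    mu_max <- normal_max_stats(m)$median
    mean <- base$mean / (2 * mu_max)
    variance <- 6 * base$variance * log(m) /
      (pi^2 + 24 * mu_max^2 * log(m))
  } else {
    mean <- (m + 1) * base$mean / (m - 1)
    variance <- (m + 2) * (m + 1)^2 * base$variance / (m^3 - m + 2)
  }
  moment_summary(mean, variance,
                 params = list(q = q, p = p, m = m, data_model = data_model,
                               normalized = TRUE,
                               improved = base$params$improved))
}
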