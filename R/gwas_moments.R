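# per-locus polynomial building blocks of the GWAS diff distributions,
# as functions of the minor allele frequency f
F_gm <- function(f) 2 * (1 - f)^3 * f + 2 * f^3 * (1 - f) + (1 - f)^2 * f^2
F_am <- function(f) (1 - f)^3 * f + f^3 * (1 - f) + (1 - f)^2 * f^2
G_am <- function(f) (1 - f)^3 * f + f^3 * (1 - f) + 2 * (1 - f)^2 * f^2
F_titv <- function(f) (1 - f)^3 * f + f^3 * (1 - f)
G_titv <- function(f) (1 - f)^2 * f^2
P_match <- function(f) (1 - f)^4 + 4 * f^2 * (1 - f)^2 + f^4

#' Estimate minor allele frequencies from genotypes
#'
#' `f_a = sum_i X_ia / (2m)`: the minor-allele count at locus `a` divided by
#' the total allele count.
#'
#' @param G A [genotype_data()] object or genotype matrix in `{0, 1, 2}`.
#' @return Numeric vector of `p` estimated MAFs in `[0, 1]`.
#' @export
estimate_maf <- function(G) {
  if (inherits(G, "genotype_data")) G <- G$genotypes
  G <- as.matrix(G)
  if (!all(G %in% 0:2)) stop("genotypes must be in {0, 1, 2}")
  colSums(G) / (2 * nrow(G))
}

#' Encoding probabilities under a Ti/Tv ratio constraint
#'
#' The PuPy probability is pinned by the transition/transversion ratio:
#' `P(Tv) = gamma1 = 1/(eta + 1)` and `P(Ti) = gamma0 + gamma2 =
#' eta/(eta + 1)`. The split of P(Ti) between PuPu and PyPy is arbitrary, so
#' `gamma0` is drawn uniformly on `(epsilon, eta/(eta+1) - epsilon)` and
#' `gamma2` takes the remainder. All closed-form TiTv moments depend on the
#' gammas only through `gamma1` and `gamma0 + gamma2`, so the split does not
#' affect theoretical curves.
#'
#' @param eta Positive Ti/Tv ratio.
#' @param epsilon Sampling margin, `0 < epsilon < eta / (2 (eta + 1))`.
#' @return An `encoding_model` list with `gamma0`, `gamma1`, `gamma2`,
#'   `eta`, `epsilon`.
#' @export
encoding_gammas <- function(eta, epsilon = 0.01) {
  if (eta <= 0) stop("eta must be positive")
  p_ti <- eta / (eta + 1)
  if (epsilon <= 0 || epsilon >= p_ti / 2)
    stop("epsilon must lie in (0, eta / (2 (eta + 1)))")
  gamma0 <- stats::runif(1, epsilon, p_ti - epsilon)
  structure(list(gamma0 = gamma0, gamma1 = 1 / (eta + 1),
                 gamma2 = p_ti - gamma0, eta = eta, epsilon = epsilon),
            class = "encoding_model")
}

as_encoding_model <- function(enc) {
  if (inherits(enc, "encoding_model")) return(enc)
  if (is.list(enc) && all(c("gamma0", "gamma1", "gamma2") %in% names(enc)))
    return(structure(enc, class = "encoding_model"))
  stop("enc must be an encoding_model (see encoding_gammas())")
}

#' Probability mass function of a GWAS diff
#'
#' Exact pmf of the per-locus diff under the binomial genotype model
#' `X ~ B(2, f)`:
#' * GM: support `{0, 1}` with `P(1) = 2 F_GM(f)`;
#' * AM: support `{0, 1/2, 1}`;
#' * TiTv: support `{0, 1/4, 1/2, 3/4, 1}`, with the transition values
#'   weighted by `gamma0 + gamma2` and the transversion values by `gamma1`.
#'
#' @param metric `"gm"`, `"am"` or `"titv"`.
#' @param f Minor allele frequency in (0, 1).
#' @param enc An `encoding_model` (required for `titv`).
#' @return A `gwas_diff_pmf` list with `support`, `prob`, `metric`, `f`.
#' @export
gwas_diff_pmf <- function(metric = c("gm", "am", "titv"), f, enc = NULL) {
  metric <- match.arg(metric)
  stopifnot(f > 0, f < 1)
  if (metric == "gm") {
    support <- c(0, 1)
    prob <- c(P_match(f), 2 * F_gm(f))
  } else if (metric == "am") {
    support <- c(0, 1 / 2, 1)
    prob <- c(P_match(f),
              4 * ((1 - f)^3 * f + f^3 * (1 - f)),
              2 * f^2 * (1 - f)^2)
  } else {
    if (is.null(enc)) stop("titv pmf requires an encoding model")
    enc <- as_encoding_model(enc)
    ti <- enc$gamma0 + enc$gamma2
    tv <- enc$gamma1
    support <- c(0, 1 / 4, 1 / 2, 3 / 4, 1)
    prob <- c(P_match(f),
              4 * ti * F_titv(f),
              4 * tv * F_titv(f),
              2 * ti * G_titv(f),
              2 * tv * G_titv(f))
  }
  structure(list(support = support, prob = prob, metric = metric, f = f,
                 enc = if (metric == "titv") enc else NULL),
            class = "gwas_diff_pmf")
}

#' Closed-form moments of a GWAS diff
#'
#' Per-locus mean and variance of the diff:
#' * GM: mean `2 F_GM(f)`, variance `2 F_GM(f) (1 - 2 F_GM(f))`;
#' * AM: mean `2 F_AM(f)`, variance `G_AM(f) - 4 F_AM(f)^2`;
#' * TiTv: mean `(g02 + 2 g1) F + (3/2 g02 + 2 g1) G` and variance
#'   `(g02/4 + g1) F + (9/8 g02 + 2 g1) G - mean^2`, with
#'   `F = (1-f)^3 f + f^3 (1-f)`, `G = f^2 (1-f)^2`, `g02 = gamma0 + gamma2`
#'   and `g1 = gamma1`.
#'
#' These equal the mean and variance of [gwas_diff_pmf()] exactly.
#'
#' @inheritParams gwas_diff_pmf
#' @return A `diff_moments` list with `mu_z`, `sigma2_z` (and `q = 1`).
#' @export
gwas_diff_moments <- function(metric = c("gm", "am", "titv"), f, enc = NULL) {
  metric <- match.arg(metric)
  stopifnot(all(f > 0), all(f < 1))
  if (metric == "gm") {
    mu <- 2 * F_gm(f)
    sigma2 <- mu * (1 - mu) # Bernoulli on {0,1}
  } else if (metric == "am") {
    mu <- 2 * F_am(f)
    sigma2 <- G_am(f) - 4 * F_am(f)^2
  } else {
    if (is.null(enc)) stop("titv moments require an encoding model")
    enc <- as_encoding_model(enc)
    g02 <- enc$gamma0 + enc$gamma2
    g1 <- enc$gamma1
    mu <- (g02 + 2 * g1) * F_titv(f) + (1.5 * g02 + 2 * g1) * G_titv(f)
    second <- (g02 / 4 + g1) * F_titv(f) + (9 / 8 * g02 + 2 * g1) * G_titv(f)
    sigma2 <- second - mu^2
  }
  structure(list(mu_z = mu, sigma2_z = sigma2, q = 1L, data_model = metric),
            class = "diff_moments")
}

#' Asymptotic GWAS distance-distribution moments
#'
#' Mean and variance of the pairwise GWAS distance over `p` independent
#' loci: the sums of the per-locus diff means and variances
#' ([gwas_diff_moments()]); the distance is asymptotically normal.
#'
#' @param metric `"gm"`, `"am"` or `"titv"`.
#' @param maf Vector of per-locus minor allele frequencies.
#' @param enc An `encoding_model` (required for `titv`).
#' @return A `moment_summary`.
#' @export
gwas_distance_moments <- function(metric = c("gm", "am", "titv"), maf,
                                  enc = NULL) {
  metric <- match.arg(metric)
  dm <- gwas_diff_moments(metric, maf, enc)
  moment_summary(sum(dm$mu_z), sum(dm$sigma2_z),
                 params = list(metric = metric, p = length(maf),
                               enc = if (metric == "titv")
                                 as_encoding_model(enc) else NULL))
}

#' Predicted mean TiTv distance as a function of average MAF
#'
#' Evaluates the closed-form expected TiTv distance with every per-locus MAF
#' set to a common average value `fbar` over a grid, using the expected
#' encoding probabilities implied by the Ti/Tv ratio
#' (`gamma1 = 1/(eta+1)`, `gamma0 + gamma2 = eta/(eta+1)`). The curve is
#' symmetric about `fbar = 0.5` (the inflection point at which the minor
#' allele switches), where its maximum occurs; it vanishes as `fbar` tends
#' to 0 or 1. The curve decreases in `eta` at fixed `fbar`: transversions
#' carry more weight, so transversion-rich data (small `eta`) yields larger
#' distances.
#'
#' @param fbar_grid Grid of average MAF values in (0, 1).
#' @param eta Positive Ti/Tv ratio.
#' @param p Number of loci (the curve scales linearly in `p`).
#' @return A data frame with columns `fbar` and `mean_distance`, with the
#'   grid argmax in attribute `"argmax"`.
#' @export
titv_mean_curve <- function(fbar_grid, eta, p = 100L) {
  stopifnot(all(fbar_grid > 0), all(fbar_grid < 1), eta > 0, p >= 1)
  enc <- list(gamma0 = eta / (2 * (eta + 1)), gamma1 = 1 / (eta + 1),
              gamma2 = eta / (2 * (eta + 1)), eta = eta)
  mu <- vapply(fbar_grid, function(f)
    p * gwas_diff_moments("titv", f, enc)$mu_z, numeric(1))
  out <- data.frame(fbar = fbar_grid, mean_distance = mu)
  attr(out, "argmax") <- fbar_grid[which.max(mu)]
  out
}
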