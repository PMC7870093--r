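test_that("generators are deterministic under a fixed seed", {
  expect_identical(gen_continuous(20, 5, "normal", seed = 3),
                   gen_continuous(20, 5, "normal", seed = 3))
  g1 <- gen_gwas(10, 8, seed = 3); g2 <- gen_gwas(10, 8, seed = 3)
  expect_identical(g1$genotypes, g2$genotypes)
  expect_identical(g1$encoding, g2$encoding)
  expect_identical(gen_fmri_stack(5, 4, seed = 3)$values,
                   gen_fmri_stack(5, 4, seed = 3)$values)
  b1 <- gen_feature_selection_benchmark(20, 30, 6, seed = 3)
  b2 <- gen_feature_selection_benchmark(20, 30, 6, seed = 3)
  expect_identical(unclass(b1$X), unclass(b2$X))
  expect_false(identical(gen_continuous(20, 5, seed = 3),
                         gen_continuous(20, 5, seed = 4)))
})

test_that("continuous generators match their data models", {
  X <- gen_continuous(10000, 3, "normal", seed = 5)
  expect_true(all(abs(colMeans(X)) < 0.05))
  expect_true(all(abs(apply(X, 2, var) - 1) < 0.06))
  U <- gen_continuous(500, 4, "uniform", seed = 5)
  expect_true(all(U >= 0 & U < 1))
})

test_that("GWAS generator recovers its MAF and encoding model", {
  G <- gen_gwas(200, 2000, maf_low = 0.1, maf_high = 0.4, eta = 2, seed = 9)
  expect_true(all(G$genotypes %in% 0:2))
  expect_equal(mean(estimate_maf(G)), (0.1 + 0.4) / 2, tolerance = 0.02)
  expect_equal(mean(G$encoding == "PuPy"), 1 / 3, tolerance = 0.1)
  expect_equal(mean(G$maf), 0.25, tolerance = 0.02)
  expect_error(gen_gwas(10, 5, maf_low = 0.5, maf_high = 0.2), "maf")
})

test_that("null stacks have the declared layout and standardization", {
  S <- gen_fmri_stack(12, 7, seed = 2)
  expect_equal(nrow(S$values), 7 * 6)
  expect_equal(S$m, 12)
  expect_true(all(abs(colMeans(S$values)) < 1e-12))
  expect_true(all(abs(apply(S$values, 2, var) - 1) < 1e-12))
  # builder applied to raw correlation matrices gives the same layout
  set.seed(30)
  mats <- replicate(5, cor(matrix(rnorm(50 * 4), 50, 4)), simplify = FALSE)
  S2 <- build_correlation_stack(mats)
  expect_equal(nrow(S2$values), 4 * 3)
  expect_equal(S2$m, 5)
})

test_that("stack distances agree with the corrected moment predictions", {
  p <- 30
  d <- unlist(lapply(1:4, function(r)
    pairwise_values(fmri_distance_matrix(gen_fmri_stack(40, p,
                                                        seed = 60 + r)))))
  th <- fmri_distance_moments(p, corrected = TRUE)
  expect_equal(mean(d), th$mean, tolerance = 0.02)
  expect_equal(var(d), th$variance, tolerance = 0.35)
})

test_that("random-graph correlation targets are valid and controllable", {
  R0 <- random_structured_correlation(8, 0, hi = 0.8, lo = 0, seed = 1)
  expect_equal(R0$matrix, diag(8))
  R1 <- random_structured_correlation(8, 1, hi = 0.5, lo = 0, seed = 1)
  off <- R1$matrix[upper.tri(R1$matrix)]
  expect_true(all(abs(off - 0.5) < 0.05))
  Rh <- random_structured_correlation(20, 0.3, hi = 0.9, lo = 0.05, seed = 2)
  expect_gt(min(eigen(Rh$matrix, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  expect_equal(unname(diag(Rh$matrix)), rep(1, 20))
})

test_that("imposed correlation reaches the target structure", {
  X <- gen_continuous(200, 6, "normal", seed = 12)
  expect_equal(unclass(impose_correlation(X, diag(6))), unclass(X))
  X2 <- gen_continuous(100000, 2, "normal", seed = 13)
  R <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  Xc <- impose_correlation(X2, R)
  expect_equal(cor(unclass(Xc))[1, 2], 0.6, tolerance = 0.01)
  expect_error(impose_correlation(X2, diag(5)), "dimension")
  # mean |r| of the generated data tracks the target's
  Xl <- gen_continuous(3000, 15, "normal", seed = 14)
  Rt <- random_structured_correlation(15, 0.4, hi = 0.7, lo = 0, seed = 3)
  got <- mean_abs_correlation(impose_correlation(Xl, Rt))
  want <- mean(abs(Rt$matrix[upper.tri(Rt$matrix)]))
  expect_equal(got, want, tolerance = 0.15)
})

test_that("the Gaussian-to-binomial map preserves marginals and structure", {
  expect_equal(unclass(gaussian_to_binomial(matrix(c(-50, 50), 2, 1),
                                            0.3))$genotypes[, 1],
               c(0L, 2L), ignore_attr = TRUE)
  X <- gen_continuous(20000, 2, "normal", seed = 15)
  G <- gaussian_to_binomial(X, c(0.5, 0.2))
  tab <- table(G$genotypes[, 1]) / 20000
  expect_equal(as.numeric(tab), c(0.25, 0.5, 0.25), tolerance = 0.03)
  expect_equal(mean(G$genotypes[, 2]), 2 * 0.2, tolerance = 0.02)
})

test_that("mean absolute correlation behaves as a correlation dial", {
  X <- gen_continuous(10000, 10, "normal", seed = 16)
  expect_lt(mean_abs_correlation(X), 0.03)
  dup <- cbind(X[, 1], X[, 1])
  expect_equal(mean_abs_correlation(dup), 1)
  flip <- unclass(X); flip[, 3] <- -flip[, 3]
  expect_equal(mean_abs_correlation(flip), mean_abs_correlation(X))
  const <- cbind(unclass(X)[, 1:2], 5)
  expect_warning(v <- mean_abs_correlation(const), "constant")
  expect_lt(v, 0.05)
})

test_that("distance skewness increases with imposed correlation", {
  probs <- c(0, 0.05, 0.2, 0.5, 0.8)
  sk <- rbar <- numeric(length(probs))
  for (i in seq_along(probs)) {
    X <- gen_continuous(100, 100, "normal", seed = 40 + i)
    if (probs[i] > 0)
      X <- impose_correlation(
        X, random_structured_correlation(100, probs[i], hi = 0.8, lo = 0,
                                         seed = 50 + i))
    rbar[i] <- mean_abs_correlation(X)
    sk[i] <- sample_skewness(pairwise_values(lq_distance_matrix(X, 2)))
  }
  expect_true(all(diff(rbar) > 0))
  expect_gt(cor(rbar, sk, method = "spearman"), 0.8)
})

test_that("the benchmark generator plants detectable effects", {
  b <- gen_feature_selection_benchmark(100, 300, 40, effect = "mixed",
                                       seed = 21)
  expect_equal(sum(b$y == 0), 50)
  expect_equal(sum(b$functional), 40)
  X <- unclass(b$X)
  tstat <- function(a) abs(t.test(X[b$y == 1, a], X[b$y == 0, a])$statistic)
  t_main <- mean(sapply(b$main_idx, tstat))
  t_null <- mean(sapply(sample(which(!b$functional), 20), tstat))
  expect_gt(t_main, 2 * t_null)
  # interaction attributes: differential correlation, no marginal shift
  ii <- b$int_idx[1:10]
  cor_diff <- abs(mean(cor(X[b$y == 1, ii])[upper.tri(diag(10))]) -
                    mean(cor(X[b$y == 0, ii])[upper.tri(diag(10))]))
  expect_gt(cor_diff, 0.3)
  mshift <- mean(abs(colMeans(X[b$y == 1, ii]) - colMeans(X[b$y == 0, ii])))
  expect_lt(mshift, 0.5)
})
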