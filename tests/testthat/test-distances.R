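test_that("L_q distances match hand values and the brute-force oracle", {
  X <- matrix(c(0, 1, 0, 1), 2, 2)
  expect_equal(lq_distance_matrix(X, q = 1)[1, 2], 2)

  same <- rbind(c(1.3, -2, 0.5), c(1.3, -2, 0.5), c(0, 0, 0))
  for (q in 1:3)
    expect_equal(lq_distance_matrix(same, q = q)[1, 2], 0)

  set.seed(11)
  X <- matrix(rnorm(30), 6, 5)
  for (q in c(1L, 2L, 3L)) {
    D <- lq_distance_matrix(X, q = q)
    expect_equal(unclass(D), naive_lq(X, q), ignore_attr = TRUE)
    Dn <- lq_distance_matrix(X, q = q, normalized = TRUE)
    expect_equal(unclass(Dn), naive_lq(X, q, normalized = TRUE),
                 ignore_attr = TRUE)
  }
})

test_that("attribute diffs project the distance onto one attribute", {
  X <- cbind(c(0, 1, 3), c(5, 5, 5) + c(0, 2, 1))
  expect_equal(attribute_diff(X, 1), c(1, 3, 2))
  expect_equal(attribute_diff(X, 1, normalized = TRUE), c(1 / 3, 1, 2 / 3))
  expect_true(all(attribute_diff(X, 2, normalized = TRUE) <= 1))

  set.seed(4)
  Y <- matrix(runif(40), 8, 5)
  D1 <- lq_distance_matrix(Y, q = 1)
  diff_sum <- Reduce(`+`, lapply(1:5, function(a) attribute_diff(Y, a)))
  expect_equal(pairwise_values(D1), diff_sum)
})

test_that("constant attributes under normalization follow the policy", {
  X <- cbind(c(1, 2, 3), c(7, 7, 7))
  expect_error(lq_distance_matrix(X, normalized = TRUE), "constant")
  expect_warning(
    D <- lq_distance_matrix(X, normalized = TRUE, degenerate = "drop"),
    "dropping")
  expect_equal(D[1, 3], 1) # remaining attribute spans its range
  expect_error(attribute_diff(X, 2, normalized = TRUE), "zero range")
})

test_that("distance matrices satisfy the metric axioms on random inputs", {
  set.seed(21)
  for (rep in 1:3) {
    X <- matrix(rnorm(8 * 6), 8, 6)
    for (q in c(1L, 2L, 3L)) for (nrm in c(FALSE, TRUE)) {
      D <- unclass(lq_distance_matrix(X, q = q, normalized = nrm))
      expect_equal(D, t(D))
      expect_equal(unname(diag(D)), rep(0, 8))
      expect_true(all(D >= 0))
      for (i in 1:8) for (j in 1:8) for (k in 1:8)
        expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
    }
  }
})

test_that("distances are invariant to attribute permutation", {
  set.seed(5)
  X <- matrix(runif(50), 10, 5)
  perm <- sample(5)
  expect_equal(unclass(lq_distance_matrix(X, 2)),
               unclass(lq_distance_matrix(X[, perm], 2)))
  G <- gen_gwas(10, 20, seed = 8)
  gperm <- sample(20)
  Gp <- genotype_data(G$genotypes[, gperm], encoding = G$encoding[gperm])
  expect_equal(unclass(gwas_distance_matrix(G, "titv")),
               unclass(gwas_distance_matrix(Gp, "titv")))
})

test_that("GWAS diffs take the tabulated values with the right supports", {
  expect_equal(gwas_diff(0, 2, "titv", "PuPy"), 1)
  expect_equal(gwas_diff(1, 2, "titv", "PuPu"), 1 / 4)
  expect_equal(gwas_diff(1, 2, "titv", "PuPy"), 1 / 2)
  expect_equal(gwas_diff(0, 2, "titv", "PyPy"), 3 / 4)
  for (metric in c("gm", "am", "titv"))
    expect_equal(gwas_diff(2, 2, metric, "PuPu"), 0)
  expect_equal(gwas_diff(0, 2, "am"), 1)
  expect_equal(gwas_diff(0, 1, "am"), 1 / 2)
  expect_equal(gwas_diff(0, 1, "gm"), 1)
  expect_error(gwas_diff(3, 0, "gm"), "0, 1, 2")
  expect_error(gwas_diff(0, 1, "titv"), "encoding")

  g <- expand.grid(gi = 0:2, gj = 0:2)
  expect_true(all(gwas_diff(g$gi, g$gj, "gm") %in% c(0, 1)))
  expect_true(all(gwas_diff(g$gi, g$gj, "am") %in% c(0, 1 / 2, 1)))
  expect_true(all(gwas_diff(g$gi, g$gj, "titv", rep("PuPu", 9)) %in%
                    c(0, 1 / 4, 3 / 4)))
})

test_that("GWAS distance matrices sum the per-locus diffs", {
  Gsame <- genotype_data(matrix(1L, 4, 6))
  expect_equal(max(abs(gwas_distance_matrix(Gsame, "am"))), 0)

  G2 <- genotype_data(rbind(c(0L, 1L), c(2L, 2L)))
  expect_equal(gwas_distance_matrix(G2, "gm")[1, 2], 2)

  set.seed(14)
  G <- gen_gwas(8, 20, seed = 31)
  D <- gwas_distance_matrix(G, "am")
  ref <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    ref[i, j] <- sum(abs(G$genotypes[i, ] - G$genotypes[j, ])) / 2
  expect_equal(unclass(D), ref, ignore_attr = TRUE)
})

test_that("ROI blocks tile the stack and the ROI diff matches hand sums", {
  expect_equal(unname(roi_block_indices(1, 10)), c(1, 9))
  expect_equal(unname(roi_block_indices(10, 10)), c(82, 90))
  expect_error(roi_block_indices(11, 10), "out of range")
  for (p in 2:6) {
    covered <- unlist(lapply(1:p, function(k) {
      b <- roi_block_indices(k, p); b[["start"]]:b[["end"]]
    }))
    expect_equal(sort(covered), 1:(p * (p - 1)))
    expect_equal(anyDuplicated(covered), 0L)
  }

  # p = 3 stack: ROI 1 block holds (A_21, A_31); hand-set those values
  Zi <- matrix(0, 3, 3); Zj <- matrix(0, 3, 3)
  Zi[2, 1] <- Zi[1, 2] <- 0.1; Zi[3, 1] <- Zi[1, 3] <- 0.2
  Zj[2, 1] <- Zj[1, 2] <- 0.4; Zj[3, 1] <- Zj[1, 3] <- 0.0
  S <- stack_from_matrices(list(Zi, Zj))
  expect_equal(fmri_roi_diff(S, 1, 2, 1), abs(-0.3) + abs(0.2))
  expect_equal(fmri_roi_diff(S, 1, 1, 2), 0)
})

test_that("the stack distance equals Manhattan on columns and sums ROI diffs", {
  S <- gen_fmri_stack(6, 5, seed = 9)
  D <- fmri_distance_matrix(S)
  expect_equal(unclass(D),
               unclass(as.matrix(dist(t(S$values), method = "manhattan"))),
               ignore_attr = TRUE)
  roi_sum <- sum(vapply(1:5, function(a) fmri_roi_diff(S, 2, 4, a),
                        numeric(1)))
  expect_equal(D[2, 4], roi_sum)
  # every unordered ROI pair appears in two blocks
  pair_l1 <- sum(abs(S$values[, 2] - S$values[, 4])) / 2
  expect_equal(roi_sum, 2 * pair_l1)

  Dz <- fmri_distance_matrix(
    correlation_stack(matrix(1, 12, 3), p = 4, standardized = FALSE))
  expect_equal(max(abs(Dz)), 0)

  Dn <- fmri_distance_matrix(S, normalized = TRUE)
  expect_true(all(unclass(Dn) >= 0))
  expect_equal(unclass(Dn), t(unclass(Dn)))
})
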