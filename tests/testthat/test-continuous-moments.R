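test_that("projection moments match closed forms and a Monte-Carlo oracle", {
  pm <- projection_moments(1, "uniform")
  expect_equal(pm$mu_z, 1 / 3)
  expect_equal(pm$sigma2_z, 1 / 18)

  pm <- projection_moments(2, "normal")
  expect_equal(pm$mu_z, 2) # X - Y ~ N(0, 2)
  expect_equal(pm$sigma2_z, 8) # Gaussian fourth moment: E[(X-Y)^4] = 12

  pm <- projection_moments(1, "normal")
  expect_equal(pm$mu_z, 2 / sqrt(pi))
  expect_equal(pm$sigma2_z, 2 - 4 / pi)
  set.seed(1)
  z <- abs(rnorm(1e6) - rnorm(1e6))
  expect_equal(pm$mu_z, mean(z), tolerance = 3 * sd(z) / sqrt(1e6) / pm$mu_z)
  expect_equal(pm$sigma2_z, var(z), tolerance = 0.01)

  expect_error(projection_moments(0, "normal"), "positive integer")
})

test_that("projection densities normalize and reproduce their moments", {
  for (model in c("normal", "uniform")) {
    upper <- if (model == "uniform") 1 else Inf
    for (q in 1:3) {
      total <- integrate(projection_density, 0, upper, q = q,
                         data_model = model, rel.tol = 1e-10)$value
      expect_equal(total, 1, tolerance = 1e-8)
      m1 <- integrate(function(z) z * projection_density(z, q, model),
                      0, upper, rel.tol = 1e-10)$value
      m2 <- integrate(function(z) z^2 * projection_density(z, q, model),
                      0, upper, rel.tol = 1e-10)$value
      pm <- projection_moments(q, model)
      expect_equal(m1, pm$mu_z, tolerance = 1e-8)
      expect_equal(m2 - m1^2, pm$sigma2_z, tolerance = 1e-8)
    }
  }
  # q = 1 uniform density is the triangle-difference density 2(1 - z)
  z <- c(0.1, 0.5, 0.9)
  expect_equal(projection_density(z, 1, "uniform"), 2 * (1 - z))
  expect_equal(projection_density(c(-1, 1.5), 1, "uniform"), c(0, 0))
})

test_that("numeric projection density agrees with the closed forms", {
  z <- c(0.5, 1, 2)
  expect_equal(projection_density_numeric(z, 1, dnorm),
               projection_density(z, 1, "normal"), tolerance = 1e-6)
  expect_equal(projection_density_numeric(0.25, 2, dunif, 0, 1),
               projection_density(0.25, 2, "uniform"), tolerance = 1e-6)
  # arbitrary density: |X - Y| for iid Exp(rate) is again Exp(rate), an
  # independent closed-form oracle for the quadrature path
  fX <- function(x) dexp(x, rate = 2) # support [0, Inf)
  zs <- seq(0.05, 3, by = 0.05)
  vals <- projection_density_numeric(zs, 1, fX, lower = 0, upper = Inf)
  expect_true(all(vals >= 0))
  expect_equal(vals, dexp(zs, rate = 2), tolerance = 1e-6)
})

test_that("delta-method distance moments match the printed specializations", {
  s <- delta_method_distribution(projection_moments(2, "normal"), 37,
                                 improved = FALSE)
  expect_equal(s$variance, 1)
  expect_equal(s$mean, sqrt(2 * 37))
  s <- delta_method_distribution(projection_moments(2, "normal"), 100)
  expect_equal(s$mean, sqrt(199))

  s <- delta_method_distribution(projection_moments(1, "uniform"), 18)
  expect_equal(s$mean, 6)
  expect_equal(s$variance, 1)

  ms <- lq_distance_moments(100, 1, "normal")
  expect_equal(ms$mean, 200 / sqrt(pi))
  expect_equal(ms$variance, 200 * (pi - 2) / pi)

  ms <- lq_distance_moments(100, 1, "uniform")
  expect_equal(ms$mean, 100 / 3)
  expect_equal(ms$variance, 100 / 18)

  ms <- lq_distance_moments(100, 2, "uniform")
  expect_equal(ms$mean, sqrt(100 / 6 - 7 / 120))
  expect_equal(ms$variance, 7 / 120)
})

test_that("moments grow with dimension and the improved mean is conservative", {
  for (model in c("normal", "uniform")) {
    means1 <- sapply(c(1, 10, 100, 1000), function(p)
      lq_distance_moments(p, 1, model)$mean)
    vars1 <- sapply(c(1, 10, 100, 1000), function(p)
      lq_distance_moments(p, 1, model)$variance)
    expect_true(all(diff(means1) > 0))
    expect_true(all(diff(vars1) > 0))
    ratio <- sapply(c(10, 100, 10000), function(p)
      lq_distance_moments(p, 2, model, improved = TRUE)$mean /
        lq_distance_moments(p, 2, model, improved = FALSE)$mean)
    expect_true(all(ratio <= 1))
    expect_equal(ratio[3], 1, tolerance = 1e-4)
  }
})

test_that("simulated pairwise distances match the theory within 3 SEs", {
  grid <- expand.grid(family = "lq", data_model = c("normal", "uniform"),
                      q = c(1L, 2L), p = c(10L, 100L, 1000L), m = 100L,
                      replicates = 8L, stringsAsFactors = FALSE)
  tab <- moment_comparison(grid, seed = 42)
  expect_true(all(abs(tab$sim_mean - tab$theory_mean) <=
                    pmax(3 * tab$se_mean, 0.015 * tab$theory_mean)))
  expect_true(all(abs(tab$sim_sd - tab$theory_sd) <=
                    pmax(3 * tab$se_sd, 0.1 * tab$theory_sd)))
})
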