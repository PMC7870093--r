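#' Compare theoretical and simulated distance moments
#'
#' For each row of an experiment grid, generates `replicates` null data sets,
#' computes the pairwise distance matrix, records the average simulated mean
#' and standard deviation of distances (with Monte-Carlo standard errors
#' across replicates), and pairs them with the analytic prediction for that
#' metric/data-model/dimension cell.
#'
#' Supported families: `"lq"` and `"lq_maxmin"` (columns `data_model`, `q`),
#' `"gm"`, `"am"`, `"titv"` (columns `maf_low`, `maf_high`, `eta`; theory is
#' evaluated at each replicate's sampled MAFs), and `"fmri"` /
#' `"fmri_maxmin"`. Required columns: `family`, `p`, `m`; optional
#' `replicates` (default 20).
#'
#' @param grid Data frame describing the experiment cells.
#' @param seed Integer seed; every replicate derives its own sub-seed.
#' @return Data frame with one row per cell: theoretical and simulated
#'   mean/SD plus Monte-Carlo standard errors.
#' @export
moment_comparison <- function(grid, seed = 1L) {
  stopifnot(all(c("family", "p", "m") %in% names(grid)))
  if (is.null(grid$replicates)) grid$replicates <- 20L
  out <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cell <- grid[r, ]
    reps <- replicate_moments(cell, seed, r)
    th <- reps$theory
    out[[r]] <- data.frame(
      family = cell$family,
      q = if (!is.null(cell$q)) cell$q else NA_integer_,
      p = cell$p, m = cell$m, replicates = cell$replicates,
      theory_mean = th$mean, theory_sd = sqrt(th$variance),
      sim_mean = mean(reps$means), sim_sd = mean(reps$sds),
      se_mean = stats::sd(reps$means) / sqrt(length(reps$means)),
      se_sd = stats::sd(reps$sds) / sqrt(length(reps$sds)),
      seed = seed)
  }
  do.call(rbind, out)
}

# one grid cell: run replicates, return simulated moments + averaged theory
replicate_moments <- function(cell, seed, cell_id) {
  family <- as.character(cell$family)
  reps <- cell$replicates
  means <- sds <- numeric(reps)
  theories <- vector("list", reps)
  for (b in seq_len(reps)) {
    s <- derive_seed(seed, cell_id * 10000L + b)
    if (family %in% c("lq", "lq_maxmin")) {
      q <- if (!is.null(cell$q)) cell$q else 1L
      model <- if (!is.null(cell$data_model)) as.character(cell$data_model)
               else "normal"
      X <- gen_continuous(cell$m, cell$p, model, seed = s)
      D <- lq_distance_matrix(X, q = q, normalized = family == "lq_maxmin")
      theories[[b]] <- if (family == "lq") {
        lq_distance_moments(cell$p, q, model)
      } else {
        maxmin_lq_moments(cell$p, q, cell$m, model)
      }
    } else if (family %in% c("gm", "am", "titv")) {
      l <- if (!is.null(cell$maf_low)) cell$maf_low else 0.05
      u <- if (!is.null(cell$maf_high)) cell$maf_high else 0.5
      eta <- if (!is.null(cell$eta)) cell$eta else 2
      G <- gen_gwas(cell$m, cell$p, l, u, eta = eta, seed = s)
      D <- gwas_distance_matrix(G, family)
      enc <- list(gamma0 = G$gammas[1], gamma1 = G$gammas[2],
                  gamma2 = G$gammas[3], eta = eta)
      theories[[b]] <- gwas_distance_moments(family, G$maf,
                                             if (family == "titv") enc)
    } else if (family %in% c("fmri", "fmri_maxmin")) {
      S <- gen_fmri_stack(cell$m, cell$p, seed = s)
      D <- fmri_distance_matrix(S, normalized = family == "fmri_maxmin")
      theories[[b]] <- if (family == "fmri") {
        fmri_distance_moments(cell$p)
      } else {
        fmri_maxmin_moments(cell$m, cell$p)
      }
    } else stop("unknown family: ", family)
    d <- pairwise_values(D)
    means[b] <- mean(d)
    sds[b] <- stats::sd(d)
  }
  theory <- list(
    mean = mean(vapply(theories, `[[`, numeric(1), "mean")),
    variance = mean(vapply(theories, `[[`, numeric(1), "variance")))
  list(means = means, sds = sds, theory = theory)
}

#' Normality screen of a distance distribution
#'
#' Shapiro-Wilk test over the upper-triangle pairwise distances (subsampled
#' with a fixed seed to `max_n` values if above the test's size cap),
#' quantile-quantile pairs against a fitted normal, and sample skewness.
#'
#' @param D Pairwise distance matrix.
#' @param max_n Subsample cap for the Shapiro-Wilk statistic.
#' @param seed Seed for the subsample.
#' @return List with `statistic`, `p_value`, `skewness`, and `qq` (data
#'   frame of theoretical and sample quantiles).
#' @export
normality_report <- function(D, max_n = 5000L, seed = 1L) {
  d <- pairwise_values(as_dist_values(D))
  if (length(d) < 20L) stop("need at least 20 pairwise distances")
  if (stats::sd(d) == 0) stop("degenerate distances: all values equal")
  x <- d
  if (length(x) > max_n) {
    set.seed(seed)
    x <- sample(x, max_n)
  }
  sw <- stats::shapiro.test(x)
  qs <- stats::ppoints(min(length(d), 500L))
  qq <- data.frame(
    theoretical = stats::qnorm(qs, mean(d), stats::sd(d)),
    sample = stats::quantile(d, qs, names = FALSE))
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       skewness = sample_skewness(d), qq = qq)
}

as_dist_values <- function(D) {
  if (inherits(D, "distance_matrix")) return(D)
  new_distance_matrix(as.matrix(D), list(family = "unknown"))
}

#' Sample skewness
#'
#' Third standardized sample moment, `mean((x - xbar)^3) / sd(x)^3` with the
#' population-style denominator.
#'
#' @param x Numeric vector.
#' @return Scalar skewness.
#' @export
sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^3) / s2^1.5
}

#' Run a canned theory-vs-simulation experiment
#'
#' Drives the package end to end for a named experiment and writes its
#' outputs (TSV tables, PNG plots, and a JSON parameter manifest) to a
#' directory:
#' * `fig1`: Gaussian convergence of Manhattan/Euclidean distances on
#'   uniform data across attribute dimensions;
#' * `fig6`: predicted mean TiTv distance curves over average MAF for a set
#'   of Ti/Tv ratios;
#' * `fig7`: theoretical vs simulated TiTv moments over `eta` and over
#'   average MAF;
#' * `fig11`: theoretical vs simulated Manhattan moments on normal data
#'   over a grid of attribute counts;
#' * `fig12`: distance skewness as a function of imposed average absolute
#'   attribute correlation.
#'
#' @param which Experiment selector.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param scale Multiplier in (0, 1] applied to the default replicate
#'   counts, for quick runs.
#' @return Invisibly, the paths of the files written.
#' @export
run_figure_suite <- function(which = c("fig1", "fig6", "fig7", "fig11",
                                       "fig12"),
                             out_dir, seed = 1L, scale = 1) {
  which <- match.arg(which)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reps <- max(2L, as.integer(round(20 * scale)))
  files <- character(0)
  tsv <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  png_plot <- function(name, expr) {
    path <- file.path(out_dir, paste0(name, ".png"))
    grDevices::png(path, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(expr)
    path
  }

  if (which == "fig1") {
    rows <- list()
    for (p in c(10L, 100L, 1000L)) for (q in c(1L, 2L)) {
      X <- gen_continuous(100L, p, "uniform",
                          seed = derive_seed(seed, p + q))
      rep_ <- normality_report(lq_distance_matrix(X, q = q), seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        p = p, q = q, shapiro_w = rep_$statistic, p_value = rep_$p_value,
        skewness = rep_$skewness)
    }
    tab <- do.call(rbind, rows)
    files <- c(tsv(tab, "fig1_normality"),
               png_plot("fig1_normality", {
                 plot(tab$p, tab$shapiro_w, log = "x", pch = 19,
                      col = tab$q, xlab = "attributes p",
                      ylab = "Shapiro-Wilk W",
                      main = "Gaussian convergence of pairwise distances")
                 graphics::legend("bottomright", legend = c("q = 1", "q = 2"),
                                  col = 1:2, pch = 19)
               }))
  } else if (which == "fig6") {
    grid <- seq(0.01, 0.9, by = 0.009)
    tabs <- lapply(c(0.1, 1, 2), function(eta) {
      cv <- titv_mean_curve(grid, eta, p = 100L)
      cv$eta <- eta
      cv
    })
    tab <- do.call(rbind, tabs)
    files <- c(tsv(tab, "fig6_titv_mean_curve"),
               png_plot("fig6_titv_mean_curve", {
                 plot(NULL, xlim = range(grid),
                      ylim = range(tab$mean_distance),
                      xlab = "average MAF", ylab = "predicted TiTv distance",
                      main = "Mean TiTv distance vs average MAF")
                 for (i in seq_along(tabs))
                   graphics::lines(tabs[[i]]$fbar, tabs[[i]]$mean_distance,
                                   col = i, lwd = 2)
                 graphics::legend("topleft",
                                  legend = paste("eta =", c(0.1, 1, 2)),
                                  col = 1:3, lwd = 2)
               }))
  } else if (which == "fig7") {
    g1 <- expand.grid(family = "titv", p = 100L, m = 100L,
                      eta = c(0.5, 1, 1.5, 2), stringsAsFactors = FALSE)
    g1$maf_low <- 0.01; g1$maf_high <- 0.1; g1$replicates <- reps
    g2 <- data.frame(family = "titv", p = 100L, m = 100L, eta = 2,
                     maf_low = c(0.01, 0.1, 0.2, 0.3),
                     maf_high = c(0.1, 0.2, 0.3, 0.4), replicates = reps)
    tab <- rbind(cbind(moment_comparison(g1, seed), sweep_var = "eta",
                       sweep_value = g1$eta),
                 cbind(moment_comparison(g2, seed), sweep_var = "fbar",
                       sweep_value = (g2$maf_low + g2$maf_high) / 2))
    files <- c(tsv(tab, "fig7_titv_moments"),
               png_plot("fig7_titv_moments", {
                 graphics::par(mfrow = c(1, 2))
                 for (sv in c("eta", "fbar")) {
                   sub <- tab[tab$sweep_var == sv, ]
                   plot(sub$sweep_value, sub$sim_mean, pch = 19,
                        xlab = sv, ylab = "mean TiTv distance",
                        main = paste("sweep over", sv))
                   graphics::lines(sub$sweep_value, sub$theory_mean, lwd = 2)
                 }
               }))
  } else if (which == "fig11") {
    grid <- data.frame(family = "lq", data_model = "normal", q = 1L,
                       p = c(1000L, 2000L, 3000L, 4000L, 5000L), m = 100L,
                       replicates = reps)
    tab <- moment_comparison(grid, seed)
    files <- c(tsv(tab, "fig11_lq_normal"),
               png_plot("fig11_lq_normal", {
                 graphics::par(mfrow = c(1, 2))
                 plot(tab$theory_mean, tab$sim_mean, pch = 19,
                      xlab = "theoretical mean", ylab = "simulated mean")
                 graphics::abline(0, 1, lty = 2)
                 plot(tab$theory_sd, tab$sim_sd, pch = 19,
                      xlab = "theoretical SD", ylab = "simulated SD")
                 graphics::abline(0, 1, lty = 2)
               }))
  } else { # fig12
    probs <- c(0, 0.05, 0.2, 0.5, 0.8)
    rows <- lapply(seq_along(probs), function(i) {
      X <- gen_continuous(100L, 100L, "normal",
                          seed = derive_seed(seed, 300L + i))
      if (probs[i] > 0) {
        R <- random_structured_correlation(100L, probs[i], hi = 0.8,
                                           lo = 0,
                                           seed = derive_seed(seed, 400L + i))
        X <- impose_correlation(X, R)
      }
      D <- lq_distance_matrix(X, q = 2L)
      data.frame(connection_prob = probs[i],
                 rbar_abs = mean_abs_correlation(X),
                 skewness = sample_skewness(pairwise_values(D)),
                 sd = stats::sd(pairwise_values(D)))
    })
    tab <- do.call(rbind, rows)
    files <- c(tsv(tab, "fig12_correlation_skewness"),
               png_plot("fig12_correlation_skewness", {
                 plot(tab$rbar_abs, tab$skewness, pch = 19, type = "b",
                      xlab = "average |correlation|",
                      ylab = "distance skewness",
                      main = "Correlation-induced skewness of distances")
               }))
  }
  manifest <- file.path(out_dir, paste0(which, "_params.json"))
  jsonlite::write_json(list(experiment = which, seed = seed, scale = scale,
                            replicates = reps),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, manifest))
}
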