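# brute-force oracles kept independent of the package's computation paths

# naive double-loop L_q distance matrix
naive_lq <- function(X, q, normalized = FALSE) {
  X <- as.matrix(X)
  if (normalized) {
    rng <- apply(X, 2, function(v) max(v) - min(v))
    X <- sweep(X, 2, rng, "/")
  }
  m <- nrow(X)
  D <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    D[i, j] <- sum(abs(X[i, ] - X[j, ])^q)^(1 / q)
  D
}

# exhaustive enumeration of the per-locus diff distribution over the
# 3 x 3 genotype-pair table with binomial(2, f) weights (and, for titv,
# over the Ti/Tv encoding mixture)
enumerate_gwas_diff <- function(metric, f, gammas = NULL) {
  gprob <- dbinom(0:2, 2, f)
  vals <- c()
  wts <- c()
  encs <- if (metric == "titv") c("PuPu", "PuPy", "PyPy") else "PuPy"
  eprob <- if (metric == "titv") gammas else 1
  for (e in seq_along(encs)) {
    for (gi in 0:2) for (gj in 0:2) {
      d <- abs(gi - gj)
      v <- switch(metric,
        gm = as.numeric(d > 0),
        am = d / 2,
        titv = {
          ti <- encs[e] %in% c("PuPu", "PyPy")
          if (d == 0) 0
          else if (d == 1) if (ti) 1 / 4 else 1 / 2
          else if (ti) 3 / 4 else 1
        })
      vals <- c(vals, v)
      wts <- c(wts, gprob[gi + 1] * gprob[gj + 1] * eprob[e])
    }
  }
  support <- sort(unique(vals))
  prob <- vapply(support, function(s) sum(wts[vals == s]), numeric(1))
  list(support = support, prob = prob,
       mean = sum(vals * wts),
       var = sum(vals^2 * wts) - sum(vals * wts)^2)
}

# tiny stack with known values: p ROIs, m subjects, entries supplied per
# subject as a p x p symmetric matrix of already-transformed values
stack_from_matrices <- function(mats) {
  p <- nrow(mats[[1]])
  cols <- vapply(mats, function(Z) {
    unlist(lapply(seq_len(p), function(a) Z[-a, a]), use.names = FALSE)
  }, numeric(p * (p - 1)))
  correlation_stack(cols, p = p, standardized = FALSE)
}
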