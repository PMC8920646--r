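# Independent oracles and shared fixtures for the test suite.

# Brute-force GLCM by explicit pair enumeration (independent of the
# vectorized implementation under test).
glcm_bruteforce <- function(q, distance, angle, levels = 16L) {
  off <- switch(as.character(angle),
                "0" = c(0L, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0L), "135" = c(-distance, -distance))
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q))
      counts[q[r, cc], q[r2, c2]] <- counts[q[r, cc], q[r2, c2]] + 1
  }
  counts / sum(counts)
}

# Independent greedy forward search: exhaustive candidate evaluation each
# round, first-minimum tie break, strict-improvement stopping.
greedy_sfs_oracle <- function(X, y, evaluator) {
  selected <- integer(0)
  best <- Inf
  repeat {
    cand <- setdiff(seq_len(ncol(X)), selected)
    if (!length(cand)) break
    crit <- vapply(cand, function(f)
      evaluator(X[, c(selected, f), drop = FALSE], y), numeric(1))
    i <- which.min(crit)
    if (crit[i] < best) {
      best <- crit[i]
      selected <- c(selected, cand[i])
    } else break
    if (best == 0) break
  }
  colnames(X)[selected]
}

# Homodyned-K pdf by deterministic quadrature of the compound form: the
# conditional Rician density integrated over the gamma mixing law of the
# diffuse energy. Scaled Bessel avoids overflow.
hk_pdf_oracle <- function(A, k, mu, sigma2 = 1) {
  s <- k * sqrt(sigma2)
  vapply(A, function(a) {
    f <- function(g2) {
      arg <- 2 * a * s / g2
      (2 * a / g2) * exp(-(a^2 + s^2) / g2 + arg) *
        besselI(arg, 0, expon.scaled = TRUE) *
        stats::dgamma(g2, shape = mu, scale = sigma2 / mu)
    }
    stats::integrate(f, 0, Inf, rel.tol = 1e-8)$value
  }, numeric(1))
}

# Numeric CDF of the homodyned-K amplitude for ks.test.
hk_cdf_oracle <- function(k, mu, sigma2 = 1, amax = 12, n_grid = 4000L) {
  a <- seq(0, amax, length.out = n_grid)
  pdf <- hk_pdf_oracle(a[-1], k, mu, sigma2)
  cdf <- c(0, cumsum((pdf[-1] + pdf[-length(pdf)]) / 2 * diff(a[-1])))
  cdf <- c(0, cdf)
  cdf <- pmin(cdf / max(cdf[length(cdf)], 1), 1)
  stats::approxfun(a, cdf, yleft = 0, yright = 1)
}

# Rayleigh CDF with scale sigma (E[A^2] = 2 sigma^2).
prayleigh <- function(q, sigma) 1 - exp(-q^2 / (2 * sigma^2))

# Session-wide homodyned-K lookup table at the default grid; built once and
# reused by the envelope-statistics, pipeline and acceptance tests.
.lookup_env <- new.env(parent = emptyenv())
get_test_lookup <- function() {
  if (is.null(.lookup_env$tab))
    .lookup_env$tab <- build_hk_lookup(cache = file.path(tempdir(), "qustc_lookup"))
  .lookup_env$tab
}

# Small deterministic feature table builder.
toy_feature_table <- function(n_benign = 5, n_malignant = 5, seed = 42) {
  simulate_feature_table(n_benign, n_malignant, seed = seed)
}
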