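# Independent oracles used across the suite.  These deliberately take the
# slow, direct route (full per-marker refits, explicit dense inverses) so
# they share no code with the blockwise/eigen-rotated implementations they
# check.

# full OLS refit of y on [W, x], rebuilding and inverting the whole
# cross-product for this one marker
naive_ols_marker <- function(y, W, x) {
  X <- cbind(W, x)
  XtXinv <- solve(crossprod(X))
  b <- XtXinv %*% crossprod(X, y)
  r <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(r^2) / df
  se <- sqrt(s2 * XtXinv[ncol(X), ncol(X)])
  eff <- b[ncol(X)]
  list(effect = eff, se = se,
       p = 2 * pt(-abs(eff / se), df))
}

# dense GLS refit with an explicit V inverse
dense_gls_marker <- function(y, W, x, V) {
  X <- cbind(W, x)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- drop(t(r) %*% Vi %*% r) / df
  se <- sqrt(s2 * solve(XtViX)[ncol(X), ncol(X)])
  eff <- b[ncol(X)]
  list(effect = eff, se = se,
       p = 2 * pt(-abs(eff / se), df))
}

# direct dense restricted log-likelihood (total variance profiled out),
# evaluated with an explicit inverse of V0 = h2*K + (1-h2)*I
dense_reml_ll <- function(h2, y, X, K) {
  n <- length(y)
  p <- ncol(X)
  V0 <- h2 * K + (1 - h2) * diag(n)
  Vi <- solve(V0)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  rss <- drop(t(r) %*% Vi %*% r)
  np <- n - p
  sigmaP2 <- rss / np
  -0.5 * (np * log(2 * pi * sigmaP2) +
          determinant(V0, logarithm = TRUE)$modulus +
          determinant(XtViX, logarithm = TRUE)$modulus -
          determinant(crossprod(X), logarithm = TRUE)$modulus + np)
}

# dense one-pass evaluation of the VanRaden construction (no streaming)
dense_vanraden <- function(dos) {
  p <- rowMeans(dos) / 2
  poly <- apply(dos, 1, var) > 0
  Z <- dos[poly, , drop = FALSE] - 2 * p[poly]
  crossprod(Z) / (2 * sum(p[poly] * (1 - p[poly])))
}

# quick in-memory store from a dosage matrix
make_store <- function(dos, chrom = NULL, pos = NULL, dtype = "byte") {
  m <- nrow(dos)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m)
  createGenotypeStore(dos,
    data.frame(snp_id = paste0("m", seq_len(m)), chrom = chrom,
               pos = pos),
    samples = paste0("s", seq_len(ncol(dos))),
    path = tempfile("store_"), dtype = dtype)
}

sim_pair <- function(n, m, seed, ...) {
  cfg <- simConfig(n = n, m = m, seed = seed, ...)
  st <- simulateGenotypes(cfg)
  list(cfg = cfg, store = st, sim = simulatePhenotype(st, cfg))
}
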