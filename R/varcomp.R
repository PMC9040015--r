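# Variance components for y = X beta + g + e, Var(g) = sigmaG2 * K,
# Var(e) = sigmaE2 * I.  All likelihood routes maximize the same
# restricted likelihood, parameterized by heritability
# h2 = sigmaG2 / (sigmaG2 + sigmaE2); the total variance is profiled out
# analytically.  In the eigenbasis of K the covariance is diagonal with
# entries h2*lambda_i + (1 - h2) (times the total variance), so every
# objective evaluation is O(n p) after a one-time rotation.

.H2_LO <- 1e-6
.H2_HI <- 1 - 1e-6

# Restricted log-likelihood profiled over total variance, evaluated from a
# spectral representation.  Full-rank case: r = n components (yr, Xr are
# the fully rotated data and the aggregates vanish).  Low-rank case: r < n
# components plus aggregate cross-products for the zero-eigenvalue
# complement, which never needs to be formed explicitly.
.reml_profile <- function(h2, sp) {
  dr <- h2 * sp$lambda + (1 - h2)
  d0 <- 1 - h2
  yDy <- sum(sp$yr^2 / dr)
  XDy <- crossprod(sp$Xr, sp$yr / dr)
  XDX <- crossprod(sp$Xr, sp$Xr / dr)
  sumlogd <- sum(log(dr))
  if (sp$r < sp$n) {
    yDy <- yDy + (sp$yy - sum(sp$yr^2)) / d0
    XDy <- XDy + (sp$Xy - crossprod(sp$Xr, sp$yr)) / d0
    XDX <- XDX + (sp$XX - crossprod(sp$Xr)) / d0
    sumlogd <- sumlogd + (sp$n - sp$r) * log(d0)
  }
  sol <- tryCatch(solve(XDX, XDy), error = function(e) NULL)
  if (is.null(sol)) return(list(ll = -Inf, sigmaP2 = NA_real_))
  rss <- max(yDy - drop(crossprod(XDy, sol)), 1e-300)
  np <- sp$n - sp$p
  sigmaP2 <- rss / np
  ll <- -0.5 * (np * log(2 * pi * sigmaP2) + sumlogd +
                determinant(XDX, logarithm = TRUE)$modulus -
                sp$logdetXX + np)
  list(ll = as.numeric(ll), sigmaP2 = sigmaP2)
}

# spectral representation from a full GRM eigendecomposition
.spectral_full <- function(y, X, eig) {
  U <- eigenVectors(eig)
  n <- length(y)
  if (nrow(U) != n) stop("dimension mismatch between phenotype and eigendecomposition")
  XX <- crossprod(X)
  list(lambda = eigenValues(eig), yr = drop(crossprod(U, y)),
       Xr = crossprod(U, X), r = n, n = n, p = ncol(X),
       logdetXX = as.numeric(determinant(XX, logarithm = TRUE)$modulus))
}

# spectral representation from the nonzero singular structure of a scaled
# marker matrix Zs (markers x samples, K = Zs' Zs)
.spectral_lowrank <- function(y, X, Zs) {
  n <- length(y)
  if (ncol(Zs) != n) stop("marker matrix and phenotype dimensions differ")
  if (nrow(Zs) < n) {
    sv <- svd(Zs, nu = 0)
    lam <- sv$d^2
    V <- sv$v
  } else {
    e <- eigen(crossprod(Zs), symmetric = TRUE)
    lam <- pmax(e$values, 0)
    V <- e$vectors
  }
  keep <- lam > max(lam) * 1e-12
  V <- V[, keep, drop = FALSE]
  lam <- lam[keep]
  XX <- crossprod(X)
  list(lambda = lam, yr = drop(crossprod(V, y)), Xr = crossprod(V, X),
       r = length(lam), n = n, p = ncol(X),
       yy = sum(y^2), Xy = crossprod(X, y), XX = XX,
       logdetXX = as.numeric(determinant(XX, logarithm = TRUE)$modulus))
}

.check_design <- function(X, n) {
  X <- as.matrix(X)
  if (nrow(X) != n) stop("covariate rows must match phenotype length")
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  X
}

.with_intercept <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1))
  X <- as.matrix(covariates)
  if (nrow(X) != n) stop("covariate rows must match phenotype length")
  csd <- apply(X, 2L, stats::sd)
  cmn <- colMeans(X)
  if (!any(csd == 0 & cmn != 0)) X <- cbind(1, X)  # prepend intercept if absent
  X
}

.vc_result <- function(h2, sigmaP2, logLik, method, flags = character()) {
  new("VarianceComponents", sigmaG2 = h2 * sigmaP2,
      sigmaE2 = (1 - h2) * sigmaP2, h2 = h2, logLik = logLik,
      method = method, flags = flags)
}

# a kinship proportional to the identity makes the restricted likelihood
# flat in h2; report h2 = 0 with a flag instead of an arbitrary optimum
.flat_spectrum <- function(lambda) {
  (max(lambda) - min(lambda)) < 1e-10 * max(abs(lambda), 1)
}

#' REML by Brent's method on heritability
#'
#' The default variance-component estimator: one-dimensional,
#' derivative-free maximization of the restricted likelihood over
#' \eqn{h^2 \in [10^{-6}, 1-10^{-6}]}, with convergence measured by an
#' absolute tolerance on heritability itself.  Consumes the shared GRM
#' eigendecomposition, so no n-by-n matrix inverse is ever formed.
#'
#' @param y numeric phenotype vector (no missing values; align first).
#' @param covariates optional covariate matrix; an intercept column is
#'   prepended when absent.
#' @param eig a \code{GRMEigen} from the analysis GRM.
#' @param tol absolute convergence tolerance on h2.
#' @return a \code{VarianceComponents}.
#' @export
remlBrent <- function(y, covariates = NULL, eig, tol = 1e-6) {
  n <- length(y)
  if (any(!is.finite(y))) stop("phenotype must be finite")
  X <- .check_design(.with_intercept(covariates, n), n)
  sp <- .spectral_full(y, X, eig)
  if (.flat_spectrum(sp$lambda)) {
    fit <- .reml_profile(.H2_LO, sp)
    return(.vc_result(0, fit$sigmaP2, fit$ll, "brent",
                      "flat likelihood: kinship proportional to identity"))
  }
  opt <- stats::optimize(function(h2) .reml_profile(h2, sp)$ll,
                         c(.H2_LO, .H2_HI), maximum = TRUE, tol = tol)
  fit <- .reml_profile(opt$maximum, sp)
  .vc_result(opt$maximum, fit$sigmaP2, fit$ll, "brent")
}

#' REML by EMMAX-style grid search over the variance ratio
#'
#' Maximizes the same restricted likelihood as \code{remlBrent}, but over
#' \eqn{\delta = \sigma_e^2/\sigma_g^2} on a log-spaced grid (100 points in
#' \eqn{[10^{-5}, 10^5]}) followed by Brent refinement inside the best
#' bracket.  The two routes agree to the optimizer tolerance; this one is
#' robust to multimodal profiles.
#'
#' @inheritParams remlBrent
#' @param nGrid number of log-spaced grid points.
#' @return a \code{VarianceComponents}.
#' @export
remlEmmax <- function(y, covariates = NULL, eig, nGrid = 100L, tol = 1e-6) {
  n <- length(y)
  if (any(!is.finite(y))) stop("phenotype must be finite")
  X <- .check_design(.with_intercept(covariates, n), n)
  sp <- .spectral_full(y, X, eig)
  if (.flat_spectrum(sp$lambda)) {
    fit <- .reml_profile(.H2_LO, sp)
    return(.vc_result(0, fit$sigmaP2, fit$ll, "emmax",
                      "flat likelihood: kinship proportional to identity"))
  }
  delta <- exp(seq(log(1e-5), log(1e5), length.out = nGrid))
  h2grid <- pmin(pmax(1 / (1 + delta), .H2_LO), .H2_HI)
  ll <- vapply(h2grid, function(h) .reml_profile(h, sp)$ll, numeric(1))
  i <- which.max(ll)
  lo <- if (i < nGrid) h2grid[i + 1L] else .H2_LO  # h2 decreases with delta
  hi <- if (i > 1L) h2grid[i - 1L] else .H2_HI
  opt <- stats::optimize(function(h2) .reml_profile(h2, sp)$ll,
                         c(lo, hi), maximum = TRUE, tol = tol)
  fit <- .reml_profile(opt$maximum, sp)
  .vc_result(opt$maximum, fit$sigmaP2, fit$ll, "emmax")
}

#' REML through the singular structure of the genotype matrix
#'
#' Evaluates the identical restricted likelihood through the nonzero
#' spectral components of the centered, scaled marker matrix plus the
#' identity complement, without ever forming the GRM.  Most efficient when
#' the marker count is below the sample count (the thin-SVD regime); for
#' larger marker sets the same components are obtained from the
#' marker-matrix Gram matrix.
#'
#' @inheritParams remlBrent
#' @param markers a \code{GenotypeStore}, or a marker-by-sample dosage
#'   matrix, holding the markers that define the kinship.
#' @param sampleIndex optional sample column subset (store input only).
#' @param denominator frequency-scaling convention, as in
#'   \code{\link{computeGRM}}.
#' @return a \code{VarianceComponents}.
#' @export
remlFastlmm <- function(y, covariates = NULL, markers, sampleIndex = NULL,
                        denominator = "vanraden2", tol = 1e-6) {
  n <- length(y)
  if (any(!is.finite(y))) stop("phenotype must be finite")
  X <- .check_design(.with_intercept(covariates, n), n)
  x <- if (is(markers, "GenotypeStore"))
    readDosages(markers, samples = sampleIndex) else as.matrix(markers)
  Zs <- .scaled_markers(x, denominator)
  fit <- .reml_lowrank_fit(y, X, Zs, tol = tol, method = "fastlmm")
  fit
}

.reml_lowrank_fit <- function(y, X, Zs, tol = 1e-6, method = "fastlmm") {
  sp <- .spectral_lowrank(y, X, Zs)
  opt <- stats::optimize(function(h2) .reml_profile(h2, sp)$ll,
                         c(.H2_LO, .H2_HI), maximum = TRUE, tol = tol)
  fit <- .reml_profile(opt$maximum, sp)
  .vc_result(opt$maximum, fit$sigmaP2, fit$ll, method)
}

#' Haseman-Elston regression
#'
#' Moment-based heritability: residualize the phenotype on the covariates,
#' standardize, and regress the pairwise products
#' \eqn{\tilde y_i \tilde y_j} (upper triangle, diagonal excluded) on the
#' corresponding relationship entries \eqn{G_{ij}} by ordinary least
#' squares with an intercept.  The slope estimates \eqn{h^2} (clipped to
#' [0,1]).  Less accurate than the likelihood routes but needs no
#' eigendecomposition.
#'
#' @inheritParams remlBrent
#' @param grm a \code{GRM} (or plain symmetric matrix).
#' @return a \code{VarianceComponents} with \code{logLik = NA}.
#' @export
heRegression <- function(y, grm, covariates = NULL) {
  n <- length(y)
  if (n < 3L) stop("Haseman-Elston regression needs at least 3 samples")
  G <- if (is(grm, "GRM")) grmMatrix(grm) else as.matrix(grm)
  if (nrow(G) != n) stop("GRM dimension must match phenotype length")
  X <- .check_design(.with_intercept(covariates, n), n)
  r <- stats::lm.fit(X, y)$residuals
  vr <- stats::var(r)
  if (vr <= 0) stop("phenotype has zero residual variance")
  z <- (r - mean(r)) / stats::sd(r)
  ut <- upper.tri(G)
  g <- G[ut]
  if (stats::var(g) == 0)
    stop("degenerate regressor: all off-diagonal GRM entries are equal")
  prod <- tcrossprod(z)[ut]
  slope <- stats::cov(prod, g) / stats::var(g)
  h2 <- min(max(slope, 0), 1)
  .vc_result(h2, vr, NA_real_, "he")
}
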