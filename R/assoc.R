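# Per-marker association scans.  All models run through the same blockwise
# design-matrix inversion: with covariate block w and marker column x, the
# inverse of M = [w,x]'[w,x] is assembled from the once-computed (w'w)^-1
# and the scalar Schur complement x'x - x'w (w'w)^-1 w'x, so the covariate
# inverse is never recomputed per marker.

#' Blockwise inverse of the bordered design cross-product
#'
#' Given the cached inverse of the covariate block \eqn{(w'w)^{-1}} and the
#' marker cross-products, assembles the four blocks of
#' \eqn{M^{-1} = ([w,x]'[w,x])^{-1}}:
#' \deqn{M22 = (x'x - x'w(w'w)^{-1}w'x)^{-1}}
#' \deqn{M12 = -(w'w)^{-1} w'x \, M22, \quad M21 = M12'}
#' \deqn{M11 = (w'w)^{-1} + (w'w)^{-1} w'x \, M22 \, x'w (w'w)^{-1}}
#'
#' @param wtwInv k x k inverse of the covariate cross-product (symmetric).
#' @param wtx k x 1 covariate-marker cross-product.
#' @param xtx scalar marker sum of squares.
#' @param tol degeneracy tolerance on the Schur complement.
#' @return list with \code{M11}, \code{M12}, \code{M21}, \code{M22},
#'   \code{schur} and logical \code{degenerate} (marker collinear with the
#'   covariates; the blocks are NA in that case).
#' @export
blockInverse <- function(wtwInv, wtx, xtx, tol = 1e-12) {
  wtwInv <- as.matrix(wtwInv)
  wtx <- matrix(wtx, ncol = 1L)
  a <- wtwInv %*% wtx
  schur <- as.numeric(xtx - crossprod(wtx, a))
  if (!is.finite(schur) || schur <= tol)
    return(list(M11 = NULL, M12 = NULL, M21 = NULL, M22 = NA_real_,
                schur = schur, degenerate = TRUE))
  M22 <- 1 / schur
  M12 <- -a * M22
  M11 <- wtwInv + tcrossprod(a) * M22
  list(M11 = M11, M12 = M12, M21 = t(M12), M22 = M22,
       schur = schur, degenerate = FALSE)
}

# core vectorized scan: ordinary least squares of y on [W, x_j] for every
# marker row j of the (already transformed) block supplier, using the
# blockwise inverse so solve(crossprod(W)) happens exactly once.
.blockwise_scan <- function(y, W, getBlock, m, blockSize = 4096L,
                            workers = 1L) {
  n <- length(y)
  k <- ncol(W)
  df <- n - k - 1L
  if (df < 1L) stop("not enough samples for the model degrees of freedom")
  WtWinv <- tryCatch(solve(crossprod(W)),
                     error = function(e) stop("covariate matrix is rank deficient"))
  Wty <- crossprod(W, y)
  WtWinvWty <- WtWinv %*% Wty
  yty <- sum(y^2)
  starts <- seq(1L, m, by = blockSize)
  scan_chunk <- function(start) {
    rows <- start:min(m, start + blockSize - 1L)
    X <- getBlock(rows)                      # B x n, markers in rows
    B <- nrow(X)
    M <- X %*% W                             # B x k  (rows are x'w)
    xty <- drop(X %*% y)
    xtx <- rowSums(X^2)
    A <- M %*% WtWinv                        # B x k  (rows are x'w (w'w)^-1)
    schur <- xtx - rowSums(A * M)
    cc <- (xty - drop(M %*% WtWinvWty)) / schur
    # fitted sum b'X'y = Wty' b_w + c x'y with b_w = WtWinv(Wty - wtx c)
    bw_term <- drop(crossprod(WtWinvWty, Wty)) - drop(A %*% Wty) * cc
    fitted <- drop(bw_term) + cc * xty
    rss <- pmax(yty - fitted, 0)
    bad <- !is.finite(schur) | schur <= 1e-12 * pmax(xtx, 1)
    schur[bad] <- NA_real_
    sigma2 <- rss / df
    se <- sqrt(sigma2 / schur)
    tstat <- cc / se
    pval <- 2 * stats::pt(-abs(tstat), df)
    perfect <- !bad & rss <= 1e-12 * max(yty, .Machine$double.eps)
    if (any(perfect)) {
      pval[perfect] <- .Machine$double.xmin
      se[perfect] <- pmax(se[perfect], .Machine$double.xmin)
    }
    cc[bad] <- NA_real_; se[bad] <- NA_real_; pval[bad] <- NA_real_
    data.frame(effect = cc, se = se, pvalue = pval,
               perfect_fit = perfect)
  }
  if (workers > 1L && length(starts) > 1L) {
    parts <- parallel::mclapply(starts, scan_chunk, mc.cores = workers,
                                mc.preschedule = TRUE)
  } else {
    parts <- lapply(starts, scan_chunk)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

.marker_frame <- function(store, m) {
  if (is(store, "GenotypeStore")) {
    mm <- markerMap(store)
    data.frame(snp_id = mm$snp_id, chrom = mm$chrom, pos = mm$pos,
               stringsAsFactors = FALSE)
  } else {
    data.frame(snp_id = paste0("m", seq_len(m)), chrom = "1",
               pos = seq_len(m), stringsAsFactors = FALSE)
  }
}

.block_reader <- function(store, sampleIndex) {
  if (is(store, "GenotypeStore")) {
    function(rows) readDosages(store, rows, samples = sampleIndex,
                               impute = TRUE)
  } else {
    X <- as.matrix(store)
    if (!is.null(sampleIndex)) X <- X[, sampleIndex, drop = FALSE]
    function(rows) .impute_rows(X[rows, , drop = FALSE])
  }
}

#' General linear model scan
#'
#' Fixed-effects regression of the phenotype on each marker plus the
#' covariates.  Missing dosages are mean-imputed per marker; the marker
#' effect, its standard error \eqn{\sqrt{M22\,\hat\sigma_e^2}} with
#' \eqn{\hat\sigma_e^2 = RSS/(n-k-1)}, and a two-sided t p-value are
#' reported.  Monomorphic or covariate-collinear markers get missing
#' statistics; perfect fits (zero residual) report the smallest positive
#' normal double with a flag.
#'
#' @param y numeric phenotype, aligned to the analyzed samples.
#' @param store a \code{GenotypeStore} or marker-by-sample dosage matrix.
#' @param covariates optional n x c covariate matrix (intercept prepended
#'   when absent).
#' @param sampleIndex store sample columns corresponding to \code{y}.
#' @param trait trait name recorded in the result.
#' @param blockSize marker rows per streamed block.
#' @param workers number of forked workers; results are identical for any
#'   worker count.
#' @return an \code{AssocResults}.
#' @export
glmScan <- function(y, store, covariates = NULL, sampleIndex = NULL,
                    trait = "trait", blockSize = 4096L, workers = 1L) {
  n <- length(y)
  if (any(!is.finite(y))) stop("phenotype must be finite (align/drop first)")
  W <- .check_design(.with_intercept(covariates, n), n)
  m <- if (is(store, "GenotypeStore")) nMarkers(store) else nrow(store)
  getBlock <- .block_reader(store, sampleIndex)
  stats <- .blockwise_scan(y, W, getBlock, m, blockSize, workers)
  if (all(is.na(stats$pvalue))) stop("no polymorphic markers to test")
  mk <- .marker_frame(store, m)
  res <- cbind(mk, stats[, c("effect", "se", "pvalue")],
               n = n, stringsAsFactors = FALSE)
  new("AssocResults", results = res, model = "glm", trait = trait,
      info = list(perfect_fit = which(stats$perfect_fit),
                  df = n - ncol(W) - 1L, k = ncol(W)))
}

#' Mixed linear model scan (P3D)
#'
#' Generalized least squares under "population parameters previously
#' determined": variance components are estimated once on the null model
#' and fixed for every marker.  Phenotype, covariates and each marker are
#' rotated by the GRM eigenvectors and whitened by
#' \eqn{1/\sqrt{h^2\lambda_i + (1-h^2)}}; the identical blockwise GLM
#' kernel then runs on the transformed system, and the Wald p-value uses
#' the t distribution with n-k-1 degrees of freedom.  With \eqn{h^2 = 0}
#' the transform is orthonormal and the scan reduces exactly to the GLM.
#'
#' @inheritParams glmScan
#' @param eig the shared \code{GRMEigen} of the analysis GRM.
#' @param vc \code{VarianceComponents} estimated from the same GRM.
#' @return an \code{AssocResults}.
#' @export
mlmScan <- function(y, store, covariates = NULL, eig, vc,
                    sampleIndex = NULL, trait = "trait",
                    blockSize = 4096L, workers = 1L) {
  n <- length(y)
  if (any(!is.finite(y))) stop("phenotype must be finite (align/drop first)")
  if (length(eigenValues(eig)) != n)
    stop("eigendecomposition dimension does not match phenotype")
  h2 <- heritability(vc)
  d <- h2 * eigenValues(eig) + (1 - h2)
  Us <- sweep(eigenVectors(eig), 2L, sqrt(d), `/`)  # U D^{-1/2}
  yt <- drop(crossprod(Us, y))
  W <- .check_design(.with_intercept(covariates, n), n)
  Wt <- crossprod(Us, W)
  m <- if (is(store, "GenotypeStore")) nMarkers(store) else nrow(store)
  raw <- .block_reader(store, sampleIndex)
  getBlock <- function(rows) raw(rows) %*% Us
  stats <- .blockwise_scan(yt, Wt, getBlock, m, blockSize, workers)
  if (all(is.na(stats$pvalue))) stop("no polymorphic markers to test")
  mk <- .marker_frame(store, m)
  res <- cbind(mk, stats[, c("effect", "se", "pvalue")],
               n = n, stringsAsFactors = FALSE)
  new("AssocResults", results = res, model = "mlm", trait = trait,
      info = list(perfect_fit = which(stats$perfect_fit), h2 = h2,
                  df = n - ncol(W) - 1L, k = ncol(W)))
}

#' Genomic inflation factor
#'
#' Median of the observed one-degree-of-freedom chi-square quantiles of the
#' p-values, divided by the null median 0.4549; values near 1 indicate
#' calibrated tests.
#'
#' @param x an \code{AssocResults} or a numeric vector of p-values.
#' @param minP minimum number of non-missing p-values required.
#' @return scalar lambda_GC.
#' @export
genomicInflation <- function(x, minP = 100L) {
  p <- if (is(x, "AssocResults")) assocTable(x)$pvalue else as.numeric(x)
  p <- p[!is.na(p)]
  if (length(p) < minP)
    stop("need at least ", minP, " non-missing p-values")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Write an association result table
#'
#' Tab-delimited with the header \code{SNP CHROM POS EFFECT SE PVALUE N}.
#' The conventional file name is \code{<trait>.<model>.assoc.txt}.
#'
#' @param res an \code{AssocResults}.
#' @param file output path; when a directory, the conventional name is
#'   used inside it.
#' @return the path written, invisibly.
#' @export
writeAssocResults <- function(res, file) {
  if (dir.exists(file))
    file <- file.path(file, paste0(res@trait, ".", res@model, ".assoc.txt"))
  tab <- assocTable(res)
  out <- data.frame(SNP = tab$snp_id, CHROM = tab$chrom, POS = tab$pos,
                    EFFECT = tab$effect, SE = tab$se, PVALUE = tab$pvalue,
                    N = tab$n)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
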