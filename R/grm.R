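# VanRaden relationship matrix and the single eigendecomposition that the
# whole pipeline reuses (PCs, REML, mixed-model scan).

#' Compute the VanRaden genomic relationship matrix
#'
#' Streams the store in marker blocks: each block is mean-imputed, centered
#' per marker by twice the allele frequency, and accumulated as
#' \eqn{G \mathrel{+}= Z_b^T Z_b}.  The final matrix is scaled by the
#' frequency denominator, by default the standard VanRaden form
#' \eqn{2\sum_j p_j(1-p_j)} over polymorphic markers; \code{"unscaled_pq"}
#' uses \eqn{\sum_j p_j(1-p_j)} (no factor 2) for compatibility with tools
#' that omit it.  Peak memory is O(n^2 + blockSize x n).
#'
#' @param store a \code{GenotypeStore} (or a plain marker-by-sample dosage
#'   matrix for small in-memory problems).
#' @param sampleIndex optional sample column subset (indices into the
#'   store); allele frequencies are computed on this subset.
#' @param blockSize marker rows per streamed block.
#' @param denominator \code{"vanraden2"} (default) or \code{"unscaled_pq"}.
#' @param onMissing \code{"impute"} mean-imputes missing dosages per marker
#'   (the default); \code{"fail"} errors on any missing genotype.
#' @return a \code{GRM}.  Monomorphic markers contribute nothing to
#'   numerator or denominator; an error is raised if every marker is
#'   monomorphic.
#' @export
computeGRM <- function(store, sampleIndex = NULL, blockSize = 2048L,
                       denominator = c("vanraden2", "unscaled_pq"),
                       onMissing = c("impute", "fail")) {
  denominator <- match.arg(denominator)
  onMissing <- match.arg(onMissing)
  if (is.matrix(store))
    store <- createGenotypeStore(store,
      data.frame(snp_id = paste0("m", seq_len(nrow(store))),
                 chrom = "1", pos = seq_len(nrow(store))),
      samples = if (is.null(colnames(store)))
                  paste0("s", seq_len(ncol(store))) else colnames(store),
      path = tempfile("gwaskit_grm_tmp_"),
      dtype = if (all(is.na(store) | store == round(store))) "byte" else "double")
  m <- nMarkers(store)
  ids <- if (is.null(sampleIndex)) sampleIDs(store)
         else sampleIDs(store)[sampleIndex]
  n <- length(ids)
  if (n < 2L) stop("GRM needs at least two samples")
  G <- matrix(0, n, n)
  denom <- 0
  used <- 0L
  for (start in seq(1L, m, by = blockSize)) {
    rows <- start:min(m, start + blockSize - 1L)
    x <- readDosages(store, rows, samples = sampleIndex)
    if (onMissing == "fail" && anyNA(x))
      stop("missing genotypes present and onMissing = 'fail'")
    x <- .impute_rows(x)
    p <- rowMeans(x) / 2
    v <- rowSums((x - 2 * p)^2)
    poly <- v > 0
    if (!any(poly)) next
    Z <- x[poly, , drop = FALSE] - 2 * p[poly]
    G <- G + crossprod(Z)
    denom <- denom + sum(p[poly] * (1 - p[poly]))
    used <- used + sum(poly)
  }
  if (used == 0L || denom <= 0)
    stop("all markers are monomorphic; GRM denominator is zero")
  if (denominator == "vanraden2") denom <- 2 * denom
  G <- G / denom
  G <- (G + t(G)) / 2  # enforce exact symmetry against rounding
  dimnames(G) <- list(ids, ids)
  new("GRM", G = G, samples = ids, denominator = denom,
      nMarkers = as.integer(used))
}

#' Eigendecomposition of the GRM
#'
#' Full symmetric eigendecomposition, eigenvalues descending.  Tiny
#' negative eigenvalues (down to -1e-8) are numerical noise and are
#' clipped to zero; anything below that signals a malformed GRM and is an
#' error.  The package counts every call (see \code{eigenCount}) so a
#' pipeline can assert the decomposition really is computed once and
#' shared.
#'
#' @param grm a \code{GRM} (or a plain symmetric matrix).
#' @return a \code{GRMEigen}.
#' @export
eigenGRM <- function(grm) {
  G <- if (is(grm, "GRM")) grmMatrix(grm) else as.matrix(grm)
  if (any(!is.finite(G))) stop("GRM has non-finite entries")
  if (max(abs(G - t(G))) > 1e-8 * max(1, max(abs(G))))
    stop("GRM is not symmetric")
  e <- eigen(G, symmetric = TRUE)
  if (any(e$values < -1e-8))
    stop("GRM has eigenvalue ", format(min(e$values)),
         " < -1e-8; not positive semi-definite")
  vals <- pmax(e$values, 0)
  .pkg_env$eigen_count <- .pkg_env$eigen_count + 1L
  ids <- if (is(grm, "GRM")) sampleIDs(grm)
         else if (!is.null(rownames(G))) rownames(G)
         else paste0("s", seq_len(nrow(G)))
  new("GRMEigen", values = vals, vectors = e$vectors, samples = ids)
}

#' @rdname eigenGRM
#' @return \code{eigenCount} returns the number of \code{eigenGRM} calls
#'   since the last \code{resetEigenCount}.
#' @export
eigenCount <- function() .pkg_env$eigen_count

#' @rdname eigenGRM
#' @export
resetEigenCount <- function() {
  .pkg_env$eigen_count <- 0L
  invisible(NULL)
}

#' Principal component scores from the GRM eigendecomposition
#'
#' Column j of the result is \eqn{U_j \sqrt{\lambda_j}} (score scaling),
#' columns ordered by eigenvalue.  Up to scaling these match the left
#' singular vectors of the centered genotype matrix, so the one
#' decomposition serves as the PCA of the cohort.  Signs are fixed so the
#' largest-magnitude loading of each eigenvector is positive.
#'
#' @param eig a \code{GRMEigen}.
#' @param k number of components, 1 <= k < n.
#' @return n x k matrix of PC scores with sample IDs as row names.
#' @export
computePCs <- function(eig, k) {
  n <- length(eigenValues(eig))
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n")
  U <- eigenVectors(eig)[, seq_len(k), drop = FALSE]
  sgn <- apply(U, 2L, function(u) sign(u[which.max(abs(u))]))
  sgn[sgn == 0] <- 1
  U <- sweep(U, 2L, sgn, `*`)
  scores <- sweep(U, 2L, sqrt(eigenValues(eig)[seq_len(k)]), `*`)
  dimnames(scores) <- list(sampleIDs(eig), paste0("PC", seq_len(k)))
  scores
}

#' Write / read a GRM as a whitespace-delimited matrix with ID header
#'
#' @param grm a \code{GRM}.
#' @param file text file path.
#' @export
writeGRM <- function(grm, file) {
  utils::write.table(format(grmMatrix(grm), digits = 17), file,
                     quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}

#' @rdname writeGRM
#' @return \code{readGRM} returns a \code{GRM} (denominator unknown from
#'   file, stored as 1).
#' @export
readGRM <- function(file) {
  x <- as.matrix(utils::read.table(file, header = TRUE, check.names = FALSE))
  rownames(x) <- colnames(x)
  new("GRM", G = (x + t(x)) / 2, samples = colnames(x),
      denominator = 1, nMarkers = NA_integer_)
}

# centered & scaled marker block: rows z_j = (x_j - 2 p_j)/sqrt(denom) so
# that crossprod over all polymorphic markers equals the GRM; shared by
# the low-rank REML route and FarmCPU's pseudo-QTN kinship
.scaled_markers <- function(x, denominator = c("vanraden2", "unscaled_pq")) {
  denominator <- match.arg(denominator)
  x <- .impute_rows(x)
  p <- rowMeans(x) / 2
  poly <- rowSums((x - 2 * p)^2) > 0
  if (!any(poly)) stop("all markers are monomorphic")
  Z <- x[poly, , drop = FALSE] - 2 * p[poly]
  denom <- sum(p[poly] * (1 - p[poly]))
  if (denominator == "vanraden2") denom <- 2 * denom
  Z / sqrt(denom)
}
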