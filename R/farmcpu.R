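# FarmCPU: iterative alternation of a fixed effect model (marker tests
# with pseudo-QTN covariates, same cost as a GLM scan) and a random
# effect model (pseudo-QTN selection by restricted likelihood of a
# kinship built from the pseudo-QTN dosages only).

#' FarmCPU association scan
#'
#' Iterates: (i) a fixed-effect scan (\code{\link{glmScan}} machinery)
#' with the current pseudo-QTN dosages appended to the covariates, a
#' pseudo-QTN being dropped from the covariate block while it is itself
#' the tested marker; (ii) genome binning at each candidate bin size,
#' keeping the most significant marker per bin (ties broken by smaller p,
#' then lower position), with the pseudo-QTN set chosen as the
#' (bin size, count) combination maximizing the restricted likelihood of
#' a random-effect model whose kinship is built from the pseudo-QTN
#' dosages alone; (iii) termination when the pseudo-QTN set repeats or
#' \code{maxLoop} is reached.  The reported statistics are those of the
#' final fixed-effect scan.
#'
#' Markers only enter the candidate pool when their previous fixed-effect
#' p-value passes a Bonferroni-informed threshold
#' (\code{qtnThreshold / m}).
#'
#' @inheritParams glmScan
#' @param maxLoop maximum number of iterations (>= 1).
#' @param binSizes candidate genome bin sizes in bp.
#' @param qtnCounts candidate pseudo-QTN counts (capped at n/10).
#' @param qtnThreshold Bonferroni-informed entry level: a marker must have
#'   p < qtnThreshold / m in the previous scan to become a candidate.
#' @return an \code{AssocResults} with model tag \code{"farmcpu"}; the
#'   \code{info} list carries \code{pseudoQTNs} (snp_ids of the final
#'   set), \code{loops} and \code{converged}.
#' @export
farmcpuScan <- function(y, store, covariates = NULL, sampleIndex = NULL,
                        trait = "trait", maxLoop = 10L,
                        binSizes = c(5e5, 5e6, 5e7),
                        qtnCounts = seq(10L, 100L, by = 10L),
                        qtnThreshold = 0.01, blockSize = 4096L,
                        workers = 1L) {
  if (maxLoop < 1L) stop("maxLoop must be at least 1")
  n <- length(y)
  mk <- .marker_frame(store, if (is(store, "GenotypeStore"))
                              nMarkers(store) else nrow(store))
  if (any(is.na(mk$pos))) stop("marker map has missing positions")
  m <- nrow(mk)
  qtnCounts <- qtnCounts[qtnCounts <= max(1L, floor(n / 10))]
  if (!length(qtnCounts)) qtnCounts <- max(1L, floor(n / 10))
  getBlock <- .block_reader(store, sampleIndex)
  W0 <- .with_intercept(covariates, n)
  pthr <- qtnThreshold / m

  res <- glmScan(y, store, covariates, sampleIndex, trait,
                 blockSize, workers)
  qtn <- integer(0)
  converged <- FALSE
  loops <- 1L
  while (loops < maxLoop) {
    newqtn <- .select_pseudo_qtn(assocTable(res)$pvalue, mk, getBlock,
                                 y, W0, binSizes, qtnCounts, pthr)
    if (identical(sort(newqtn), sort(qtn))) { converged <- TRUE; break }
    qtn <- newqtn
    loops <- loops + 1L
    res <- .fem_scan(y, store, W0, qtn, getBlock, sampleIndex, trait,
                     blockSize, workers)
    if (!length(qtn)) { converged <- TRUE; break }
  }
  out <- res
  out@model <- "farmcpu"
  out@info$pseudoQTNs <- mk$snp_id[qtn]
  out@info$pseudoQTNidx <- qtn
  out@info$loops <- loops
  out@info$converged <- converged
  out
}

# bin the genome, keep the best marker per bin, and pick the
# (bin size x count) combination maximizing the REM restricted likelihood
.select_pseudo_qtn <- function(p, mk, getBlock, y, W0, binSizes,
                               qtnCounts, pthr) {
  eligible <- which(!is.na(p) & p < pthr)
  if (!length(eligible)) return(integer(0))
  best_ll <- -Inf
  best_set <- integer(0)
  for (bs in binSizes) {
    bin <- paste0(mk$chrom[eligible], ":",
                  floor(mk$pos[eligible] / bs))
    ord <- eligible[order(p[eligible], mk$pos[eligible])]
    binord <- paste0(mk$chrom[ord], ":", floor(mk$pos[ord] / bs))
    keep <- ord[!duplicated(binord)]      # best (smallest p) per bin
    for (cnt in qtnCounts) {
      set <- keep[seq_len(min(cnt, length(keep)))]
      x <- getBlock(set)
      Zs <- tryCatch(.scaled_markers(x), error = function(e) NULL)
      if (is.null(Zs)) next
      fit <- tryCatch(.reml_lowrank_fit(y, W0, Zs, method = "rem"),
                      error = function(e) NULL)
      if (is.null(fit)) next
      if (fit@logLik > best_ll) { best_ll <- fit@logLik; best_set <- set }
      if (length(keep) <= cnt) break     # larger counts give the same set
    }
  }
  sort(best_set)
}

# fixed-effect scan with pseudo-QTN dosages as covariates; a pseudo-QTN
# is tested against the covariate block that excludes its own column
.fem_scan <- function(y, store, W0, qtn, getBlock, sampleIndex, trait,
                      blockSize, workers) {
  if (!length(qtn))
    return(glmScan(y, store, W0[, -1, drop = FALSE], sampleIndex, trait,
                   blockSize, workers))
  Q <- t(getBlock(qtn))                 # n x q pseudo-QTN dosages
  # prune pseudo-QTNs collinear with the covariates or each other
  qr_all <- qr(cbind(W0, Q))
  keep_q <- qr_all$pivot[seq_len(qr_all$rank)]
  keep_q <- sort(keep_q[keep_q > ncol(W0)] - ncol(W0))
  qtn <- qtn[keep_q]
  Q <- Q[, keep_q, drop = FALSE]
  W <- cbind(W0, Q)
  res <- glmScan(y, store, W[, -1, drop = FALSE], sampleIndex, trait,
                 blockSize, workers)
  tab <- assocTable(res)
  # re-test each pseudo-QTN without its own column in the design
  for (j in seq_along(qtn)) {
    Wj <- cbind(W0, Q[, -j, drop = FALSE])
    xj <- matrix(getBlock(qtn[j]), nrow = 1L)
    rj <- assocTable(glmScan(y, xj, Wj[, -1, drop = FALSE],
                             trait = trait))
    tab[qtn[j], c("effect", "se", "pvalue")] <-
      rj[1L, c("effect", "se", "pvalue")]
  }
  res@results <- tab
  res
}
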