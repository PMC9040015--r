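#' @import methods
#' @importFrom stats var sd median optimize pt pchisq qchisq qbeta rnorm runif
#'   rbinom rbeta dnorm density complete.cases setNames quantile lm.fit
#' @importFrom utils write.table read.table head tail
NULL

#' File-backed genotype store
#'
#' A \code{GenotypeStore} is the package's central data object: an on-disk
#' marker-by-sample dosage matrix together with its marker map and sample
#' identifiers.  Dosages are additively coded (0/1/2 copies of the counted
#' allele, or fractional dosages in [0,2]); missing genotypes are stored as a
#' sentinel.  The dosage matrix lives in a flat binary file and is read in
#' marker blocks on demand, so random access to any block of marker rows
#' needs memory proportional to the block, never to the full matrix, and any
#' number of concurrent readers (e.g. forked scan workers) share the same
#' immutable file.
#'
#' @slot path directory holding \code{dosage.bin}, \code{meta.json} and
#'   \code{markers.tsv}.
#' @slot dim integer vector \code{c(m, n)}: marker and sample counts.
#' @slot dtype \code{"byte"} (hard calls, one byte per genotype, 255 =
#'   missing) or \code{"double"} (fractional dosages, 8 bytes, NA = missing).
#' @slot samples ordered sample identifiers (store column order).
#' @slot markers \code{data.frame} with columns \code{snp_id},
#'   \code{chrom}, \code{pos}, \code{allele_major}, \code{allele_minor} and
#'   cached \code{maf}, one row per marker in store row order.
#' @exportClass GenotypeStore
setClass("GenotypeStore",
  representation(
    path = "character",
    dim = "integer",
    dtype = "character",
    samples = "character",
    markers = "data.frame"
  )
)

setValidity("GenotypeStore", function(object) {
  msg <- character()
  if (length(object@dim) != 2L || any(object@dim < 0L))
    msg <- c(msg, "dim must be two non-negative integers (markers, samples)")
  if (!object@dtype %in% c("byte", "double"))
    msg <- c(msg, "dtype must be 'byte' or 'double'")
  if (nrow(object@markers) != object@dim[1L])
    msg <- c(msg, "marker map rows must equal dosage matrix rows")
  if (length(object@samples) != object@dim[2L])
    msg <- c(msg, "sample count must equal dosage matrix columns")
  if (anyDuplicated(object@samples))
    msg <- c(msg, "sample identifiers must be unique")
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(object@markers)))
    msg <- c(msg, "marker map needs snp_id, chrom, pos columns")
  else if (nrow(object@markers) && any(object@markers$pos <= 0))
    msg <- c(msg, "marker positions must be positive (1-based)")
  if (length(msg)) msg else TRUE
})

#' Genomic relationship matrix
#'
#' VanRaden's centered cross-product relationship matrix
#' \eqn{G = Z^T Z / d}, where \eqn{Z} is the marker-by-sample dosage matrix
#' centered per marker by twice the allele frequency and \eqn{d} is the
#' scaling denominator summed over polymorphic markers.
#'
#' @slot G n-by-n symmetric relationship matrix.
#' @slot samples sample identifiers for rows/columns of \code{G}.
#' @slot denominator the marker-frequency scaling sum used.
#' @slot nMarkers number of polymorphic markers that contributed.
#' @exportClass GRM
setClass("GRM",
  representation(
    G = "matrix",
    samples = "character",
    denominator = "numeric",
    nMarkers = "integer"
  )
)

setValidity("GRM", function(object) {
  msg <- character()
  G <- object@G
  if (nrow(G) != ncol(G)) msg <- c(msg, "G must be square")
  if (length(object@samples) != nrow(G))
    msg <- c(msg, "sample labels must match G dimension")
  if (any(!is.finite(G))) msg <- c(msg, "G must be finite")
  else if (max(abs(G - t(G))) > 1e-8 * max(1, max(abs(G))))
    msg <- c(msg, "G must be symmetric to machine precision")
  if (length(object@denominator) != 1L || object@denominator <= 0)
    msg <- c(msg, "denominator must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Eigendecomposition of a GRM
#'
#' Computed once per analysis and reused for principal components, REML
#' variance-component estimation and the mixed-model scan.
#'
#' @slot values eigenvalues, descending, clipped at a small negative
#'   tolerance (a genuine negative eigenvalue signals a malformed GRM).
#' @slot vectors n-by-n orthonormal eigenvector matrix U.
#' @slot samples sample identifiers.
#' @exportClass GRMEigen
setClass("GRMEigen",
  representation(
    values = "numeric",
    vectors = "matrix",
    samples = "character"
  )
)

setValidity("GRMEigen", function(object) {
  msg <- character()
  n <- length(object@values)
  if (!all(dim(object@vectors) == c(n, n)))
    msg <- c(msg, "vectors must be n x n for n eigenvalues")
  if (is.unsorted(rev(object@values)))
    msg <- c(msg, "eigenvalues must be in descending order")
  if (any(object@values < 0))
    msg <- c(msg, "eigenvalues must be non-negative after clipping")
  if (length(object@samples) != n)
    msg <- c(msg, "sample labels must match dimension")
  if (length(msg)) msg else TRUE
})

#' Variance components of the single-kinship mixed model
#'
#' Genetic variance \eqn{\sigma_g^2}, residual variance \eqn{\sigma_e^2}
#' and narrow-sense heritability
#' \eqn{h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)} for the model
#' \eqn{y = X\beta + g + e} with \eqn{Var(g) = \sigma_g^2 K}.
#'
#' @slot sigmaG2 genetic variance (non-negative).
#' @slot sigmaE2 residual variance (non-negative).
#' @slot h2 heritability in [0,1], consistent with the two variances.
#' @slot logLik restricted log-likelihood at the optimum (NA for
#'   moment-based estimators such as Haseman-Elston regression).
#' @slot method estimator tag ("brent", "emmax", "fastlmm", "he").
#' @slot flags character vector of warnings raised during fitting (e.g.
#'   a flat likelihood when the kinship is proportional to the identity).
#' @exportClass VarianceComponents
setClass("VarianceComponents",
  representation(
    sigmaG2 = "numeric",
    sigmaE2 = "numeric",
    h2 = "numeric",
    logLik = "numeric",
    method = "character",
    flags = "character"
  )
)

setValidity("VarianceComponents", function(object) {
  msg <- character()
  if (object@sigmaG2 < 0 || object@sigmaE2 < 0)
    msg <- c(msg, "variance components must be non-negative")
  tot <- object@sigmaG2 + object@sigmaE2
  if (tot > 0 && abs(object@h2 - object@sigmaG2 / tot) > 1e-10)
    msg <- c(msg, "h2 must equal sigmaG2/(sigmaG2+sigmaE2) within 1e-10")
  if (object@h2 < 0 || object@h2 > 1) msg <- c(msg, "h2 must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Per-marker association scan results
#'
#' One row per tested marker: identifier, map position, additive effect
#' estimate, its standard error, the two-sided p-value and the sample size
#' used.  Degenerate markers (monomorphic, or collinear with the
#' covariates) carry missing effect/SE/p.
#'
#' @slot results \code{data.frame} with columns \code{snp_id},
#'   \code{chrom}, \code{pos}, \code{effect}, \code{se}, \code{pvalue},
#'   \code{n}.
#' @slot model model tag ("glm", "mlm", "farmcpu").
#' @slot trait trait name.
#' @slot info list of model-specific extras (e.g. FarmCPU pseudo-QTNs,
#'   loop count; perfect-fit flags).
#' @exportClass AssocResults
setClass("AssocResults",
  representation(
    results = "data.frame",
    model = "character",
    trait = "character",
    info = "list"
  )
)

setValidity("AssocResults", function(object) {
  msg <- character()
  need <- c("snp_id", "chrom", "pos", "effect", "se", "pvalue", "n")
  if (!all(need %in% names(object@results)))
    msg <- c(msg, paste("results needs columns:", paste(need, collapse = ", ")))
  else {
    p <- object@results$pvalue
    ok <- is.na(p) | (p > 0 & p <= 1)
    if (!all(ok)) msg <- c(msg, "p-values must lie in (0,1] or be missing")
    se <- object@results$se
    if (any(!is.na(p) & (is.na(se) | se <= 0)))
      msg <- c(msg, "SE must be positive wherever a p-value is present")
  }
  if (length(msg)) msg else TRUE
})
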