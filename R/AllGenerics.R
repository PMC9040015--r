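# Accessor generics for the core classes.  Slot access from user code is
# discouraged; these are the supported surface.

#' @rdname GenotypeStore-class
#' @param x,object a \code{GenotypeStore} (or other core object).
#' @export
setGeneric("storePath", function(x) standardGeneric("storePath"))

#' @rdname GenotypeStore-class
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname GenotypeStore-class
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname GenotypeStore-class
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname GenotypeStore-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GRM-class
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))

#' @rdname GRMEigen-class
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' @rdname GRMEigen-class
#' @export
setGeneric("eigenVectors", function(x) standardGeneric("eigenVectors"))

#' @rdname VarianceComponents-class
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' @rdname AssocResults-class
#' @export
setGeneric("assocTable", function(x) standardGeneric("assocTable"))

#' @rdname GenotypeStore-class
#' @export
setMethod("storePath", "GenotypeStore", function(x) x@path)

#' @rdname GenotypeStore-class
#' @export
setMethod("markerMap", "GenotypeStore", function(x) x@markers)

#' @rdname GenotypeStore-class
#' @export
setMethod("sampleIDs", "GenotypeStore", function(x) x@samples)

#' @rdname GRM-class
#' @export
setMethod("sampleIDs", "GRM", function(x) x@samples)

#' @rdname GRMEigen-class
#' @export
setMethod("sampleIDs", "GRMEigen", function(x) x@samples)

#' @rdname GenotypeStore-class
#' @export
setMethod("nMarkers", "GenotypeStore", function(x) x@dim[1L])

#' @rdname GenotypeStore-class
#' @export
setMethod("nSamples", "GenotypeStore", function(x) x@dim[2L])

#' @rdname GenotypeStore-class
#' @export
setMethod("dim", "GenotypeStore", function(x) as.integer(x@dim))

#' @rdname GRM-class
#' @export
setMethod("grmMatrix", "GRM", function(x) x@G)

#' @rdname GRMEigen-class
#' @export
setMethod("eigenValues", "GRMEigen", function(x) x@values)

#' @rdname GRMEigen-class
#' @export
setMethod("eigenVectors", "GRMEigen", function(x) x@vectors)

#' @rdname VarianceComponents-class
#' @export
setMethod("heritability", "VarianceComponents", function(x) x@h2)

#' @rdname AssocResults-class
#' @export
setMethod("assocTable", "AssocResults", function(x) x@results)

#' @rdname AssocResults-class
#' @export
setMethod("as.data.frame", "AssocResults",
  function(x, row.names = NULL, optional = FALSE, ...) x@results)

setMethod("show", "GenotypeStore", function(object) {
  cat("GenotypeStore:", object@dim[1L], "markers x", object@dim[2L],
      "samples (", object@dtype, ")\n")
  cat("  path:", object@path, "\n")
  chroms <- unique(object@markers$chrom)
  cat("  chromosomes:", length(chroms), "\n")
})

setMethod("show", "GRM", function(object) {
  cat("GRM:", nrow(object@G), "x", ncol(object@G),
      "(VanRaden), built from", object@nMarkers, "markers\n")
  cat("  mean diagonal:", format(mean(diag(object@G)), digits = 4), "\n")
})

setMethod("show", "GRMEigen", function(object) {
  cat("GRMEigen:", length(object@values), "eigenpairs, top values:",
      paste(format(head(object@values, 3), digits = 4), collapse = ", "),
      "\n")
})

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents [", object@method, "]\n", sep = "")
  cat("  sigmaG2 =", format(object@sigmaG2, digits = 6),
      " sigmaE2 =", format(object@sigmaE2, digits = 6),
      " h2 =", format(object@h2, digits = 6), "\n")
  if (is.finite(object@logLik))
    cat("  restricted logLik =", format(object@logLik, digits = 8), "\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "AssocResults", function(object) {
  cat("AssocResults [", object@model, "] trait '", object@trait, "': ",
      nrow(object@results), " markers\n", sep = "")
  p <- object@results$pvalue
  if (any(!is.na(p)))
    cat("  min p =", format(min(p, na.rm = TRUE), digits = 4), "\n")
})
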