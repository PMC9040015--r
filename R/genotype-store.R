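# On-disk layout: <path>/dosage.bin (marker-major flat binary),
# <path>/meta.json (shape, dtype, sample IDs), <path>/markers.tsv
# (tab-delimited marker map).  Byte stores use 255 as the missing
# sentinel; double stores use NA.  The file is immutable after creation,
# so forked workers can read it concurrently without coordination.

.pkg_env <- new.env(parent = emptyenv())
.pkg_env$eigen_count <- 0L
.pkg_env$peak_block_rows <- 0L

.note_block <- function(nrows) {
  if (nrows > .pkg_env$peak_block_rows)
    .pkg_env$peak_block_rows <- as.integer(nrows)
  invisible(NULL)
}

#' Row-buffer accounting for streamed access
#'
#' The store contract is that streaming operations (conversion, GRM
#' construction, association scans) hold at most a bounded block of marker
#' rows in memory.  These helpers expose the instrumented peak block size so
#' the contract can be asserted.
#'
#' @return \code{peakBlockRows} returns the largest number of marker rows
#'   materialized by any single block read since the last reset.
#' @export
peakBlockRows <- function() .pkg_env$peak_block_rows

#' @rdname peakBlockRows
#' @export
resetPeakBlockRows <- function() {
  .pkg_env$peak_block_rows <- 0L
  invisible(NULL)
}

.dosage_file <- function(path) file.path(path, "dosage.bin")

.elt_size <- function(dtype) if (dtype == "byte") 1L else 8L

#' Create a file-backed genotype store from an in-memory dosage matrix
#'
#' Writes the marker-by-sample dosage matrix \code{dosages} to disk in the
#' store layout and returns the \code{GenotypeStore} handle.  Values must
#' lie in [0,2] or be missing.  Rows are written in marker-map order after
#' sorting the map by (chromosome, position).
#'
#' @param dosages numeric matrix, markers in rows, samples in columns;
#'   values in [0,2], NA for missing.
#' @param markers data.frame with \code{snp_id}, \code{chrom}, \code{pos}
#'   and optionally \code{allele_major}/\code{allele_minor}.
#' @param samples character vector of sample identifiers.
#' @param path output directory (created; must not already contain a store
#'   unless \code{overwrite = TRUE}).
#' @param dtype \code{"byte"} for hard calls, \code{"double"} for
#'   fractional dosages.
#' @param sort sort markers by (chromosome, position) before writing
#'   (default TRUE).
#' @param overwrite replace an existing store at \code{path}.
#' @return a \code{GenotypeStore}.
#' @export
createGenotypeStore <- function(dosages, markers, samples, path,
                                dtype = c("byte", "double"),
                                sort = TRUE, overwrite = FALSE) {
  dtype <- match.arg(dtype)
  dosages <- as.matrix(dosages)
  m <- nrow(dosages); n <- ncol(dosages)
  stopifnot(nrow(markers) == m, length(samples) == n)
  bad <- !is.na(dosages) & (dosages < 0 | dosages > 2)
  if (any(bad)) stop("dosage values must lie in [0,2] or be missing")
  if (dtype == "byte" && any(!is.na(dosages) & dosages != round(dosages)))
    stop("fractional dosages require dtype = 'double'")
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "chrom", "pos") %in% names(markers)))
    stop("marker map needs snp_id, chrom, pos")
  if (is.null(markers$allele_major)) markers$allele_major <- NA_character_
  if (is.null(markers$allele_minor)) markers$allele_minor <- NA_character_
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  if (sort && m > 1L) {
    ord <- order(markers$chrom, markers$pos)
    markers <- markers[ord, , drop = FALSE]
    dosages <- dosages[ord, , drop = FALSE]
  }
  rownames(markers) <- NULL
  if (dir.exists(path)) {
    if (file.exists(.dosage_file(path)) && !overwrite)
      stop("store already exists at ", path, " (use overwrite = TRUE)")
  } else dir.create(path, recursive = TRUE)

  con <- file(.dosage_file(path), "wb")
  on.exit(close(con))
  chunk <- max(1L, min(m, 4096L))
  for (start in seq(1L, m, by = chunk)) {
    end <- min(m, start + chunk - 1L)
    block <- dosages[start:end, , drop = FALSE]
    .note_block(nrow(block))
    if (dtype == "byte") {
      v <- as.integer(t(block))
      v[is.na(v)] <- 255L
      writeBin(as.raw(v), con)
    } else {
      writeBin(as.numeric(t(block)), con)
    }
  }
  # per-marker MAF cached in the map (computed from non-missing dosages)
  af <- rowMeans(dosages, na.rm = TRUE) / 2
  af[is.nan(af)] <- NA_real_
  markers$maf <- pmin(af, 1 - af)
  .write_store_meta(path, m, n, dtype, samples, markers)
  new("GenotypeStore", path = normalizePath(path), dim = c(m, n),
      dtype = dtype, samples = as.character(samples), markers = markers)
}

.write_store_meta <- function(path, m, n, dtype, samples, markers) {
  meta <- list(format = "gwaskit-store", version = 1L,
               n_markers = m, n_samples = n, dtype = dtype,
               missing_sentinel = if (dtype == "byte") 255L else NA,
               samples = as.character(samples))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(markers, file.path(path, "markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Open an existing genotype store
#'
#' @param path store directory written by \code{createGenotypeStore} or
#'   \code{convertGenotypes}.
#' @return a \code{GenotypeStore}.
#' @export
openGenotypeStore <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) stop("no store at ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  markers <- utils::read.table(file.path(path, "markers.tsv"),
                               header = TRUE, sep = "\t",
                               colClasses = c(chrom = "character"),
                               stringsAsFactors = FALSE)
  new("GenotypeStore", path = normalizePath(path),
      dim = c(as.integer(meta$n_markers), as.integer(meta$n_samples)),
      dtype = meta$dtype, samples = as.character(meta$samples),
      markers = markers)
}

#' Read a block of marker rows from a store
#'
#' Seeks to the requested rows and reads only them; memory use is
#' O(block size x n), never O(m x n).  Missing genotypes come back as NA.
#'
#' @param store a \code{GenotypeStore}.
#' @param rows integer vector of marker row indices (1-based).  Contiguous
#'   runs are read with a single seek.
#' @param samples optional integer vector of sample column indices to keep.
#' @param impute mean-impute missing dosages per marker (markers with all
#'   values missing impute to 0).
#' @return numeric matrix, \code{length(rows)} x \code{n} (or selected
#'   samples), rows in the requested order.
#' @export
readDosages <- function(store, rows = seq_len(nMarkers(store)),
                        samples = NULL, impute = FALSE) {
  m <- nMarkers(store); n <- nSamples(store)
  rows <- as.integer(rows)
  if (length(rows) && (min(rows) < 1L || max(rows) > m))
    stop("marker row index out of range")
  .note_block(length(rows))
  esize <- .elt_size(store@dtype)
  con <- file(.dosage_file(store@path), "rb")
  on.exit(close(con))
  out <- matrix(NA_real_, length(rows), n)
  # split requested rows into contiguous runs: one seek per run
  if (length(rows)) {
    runs <- split(seq_along(rows), cumsum(c(TRUE, diff(rows) != 1L)))
    for (idx in runs) {
      r0 <- rows[idx[1L]]
      nr <- length(idx)
      seek(con, where = (r0 - 1) * as.double(n) * esize, origin = "start")
      if (store@dtype == "byte") {
        raw <- as.integer(readBin(con, "raw", n * nr))
        raw[raw == 255L] <- NA_integer_
        out[idx, ] <- matrix(as.numeric(raw), nr, n, byrow = TRUE)
      } else {
        v <- readBin(con, "double", n * nr)
        out[idx, ] <- matrix(v, nr, n, byrow = TRUE)
      }
    }
  }
  if (!is.null(samples)) out <- out[, samples, drop = FALSE]
  if (impute && anyNA(out)) out <- .impute_rows(out)
  dimnames(out) <- list(store@markers$snp_id[rows],
                        if (is.null(samples)) store@samples
                        else store@samples[samples])
  out
}

# mean-impute missing entries per row; all-missing rows become 0
.impute_rows <- function(x) {
  miss <- is.na(x)
  if (!any(miss)) return(x)
  mu <- rowMeans(x, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(miss, arr.ind = TRUE)
  x[idx] <- mu[idx[, 1L]]
  x
}

#' Per-marker summary statistics
#'
#' Minor allele frequency, missing rate and a monomorphic flag for every
#' marker, computed from non-missing dosages by streaming the store in
#' blocks.
#'
#' @param store a \code{GenotypeStore}.
#' @param samples optional sample column subset.
#' @param blockSize marker rows per streamed block.
#' @return data.frame with \code{snp_id}, \code{maf}, \code{missing_rate},
#'   \code{monomorphic}.  All-missing markers get \code{maf = NA} and are
#'   flagged monomorphic.
#' @export
markerStats <- function(store, samples = NULL, blockSize = 4096L) {
  m <- nMarkers(store)
  maf <- numeric(m); missr <- numeric(m); mono <- logical(m)
  for (start in seq(1L, m, by = blockSize)) {
    rows <- start:min(m, start + blockSize - 1L)
    x <- readDosages(store, rows, samples = samples)
    nm <- rowSums(!is.na(x))
    af <- rowMeans(x, na.rm = TRUE) / 2
    v <- apply(x, 1L, function(r) stats::var(r[!is.na(r)]))
    af[nm == 0L] <- NA_real_
    maf[rows] <- pmin(af, 1 - af)
    missr[rows] <- 1 - nm / ncol(x)
    mono[rows] <- nm == 0L | (!is.na(v) & v == 0) | nm == 1L
  }
  data.frame(snp_id = store@markers$snp_id, maf = maf,
             missing_rate = missr, monomorphic = mono,
             stringsAsFactors = FALSE)
}

#' Align phenotype (and covariate) rows to store samples
#'
#' Intersects sample identifiers, preserving store column order, and drops
#' phenotype rows missing the analyzed trait.
#'
#' @param store a \code{GenotypeStore}.
#' @param pheno data.frame whose first column is the sample ID, remaining
#'   columns are traits.
#' @param covar optional data.frame with sample IDs in the first column and
#'   covariates in the rest.
#' @param trait trait column to analyze (name or index into the trait
#'   columns); default the first trait.
#' @return list with \code{sampleIndex} (column indices into the store, in
#'   store order), \code{phenotype} (aligned data.frame), \code{y} (trait
#'   vector), \code{covariates} (aligned matrix or NULL) and
#'   \code{nDropped} (rows lost to missing trait values).
#' @export
alignSamples <- function(store, pheno, covar = NULL, trait = 1L) {
  pheno <- as.data.frame(pheno)
  ids <- as.character(pheno[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample IDs in phenotype table")
  if (ncol(pheno) < 2L) stop("phenotype table needs at least one trait column")
  tr_cols <- names(pheno)[-1L]
  tr <- if (is.numeric(trait)) tr_cols[trait] else trait
  if (is.na(tr) || !tr %in% tr_cols) stop("unknown trait: ", trait)
  keep <- !is.na(pheno[[tr]])
  nDropped <- sum(!keep)
  pheno <- pheno[keep, , drop = FALSE]
  ids <- ids[keep]
  if (!is.null(covar)) {
    covar <- as.data.frame(covar)
    cids <- as.character(covar[[1L]])
    common <- intersect(ids, cids)
    pheno <- pheno[match(common, ids), , drop = FALSE]
    ids <- common
  }
  idx <- which(sampleIDs(store) %in% ids)
  if (!length(idx)) stop("no shared sample IDs between store and phenotype")
  ord_ids <- sampleIDs(store)[idx]
  pheno <- pheno[match(ord_ids, ids), , drop = FALSE]
  rownames(pheno) <- NULL
  covmat <- NULL
  if (!is.null(covar)) {
    cm <- covar[match(ord_ids, as.character(covar[[1L]])), -1L, drop = FALSE]
    covmat <- as.matrix(cm)
    storage.mode(covmat) <- "double"
    if (anyNA(covmat)) {
      ok <- stats::complete.cases(covmat)
      idx <- idx[ok]; pheno <- pheno[ok, , drop = FALSE]
      covmat <- covmat[ok, , drop = FALSE]
      nDropped <- nDropped + sum(!ok)
    }
  }
  list(sampleIndex = idx, phenotype = pheno, y = as.numeric(pheno[[tr]]),
       trait = tr, covariates = covmat, nDropped = nDropped)
}

#' Read a phenotype table
#'
#' Tab- or comma-delimited, first column sample ID, remaining columns
#' traits (real-valued, NA allowed).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPhenotype <- function(path) {
  ph <- data.table::fread(path, data.table = FALSE)
  if (ncol(ph) < 2L) stop("phenotype table needs sample ID + >=1 trait column")
  if (anyDuplicated(ph[[1L]])) stop("duplicate sample IDs in phenotype table")
  ph
}
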