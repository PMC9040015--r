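# Format converters: VCF, PLINK binary (bed/bim/fam), HapMap text and
# delimited numeric dosage matrices all end up in the same on-disk store.
# Conversion is idempotent: the same input always produces byte-identical
# dosage content.

#' Convert genotype input files to a file-backed store
#'
#' Accepts the four common genotype formats and writes the store layout
#' used by all downstream analyses.  Additive coding throughout: 0/1/2
#' copies of the counted allele (VCF: the ALT allele; PLINK: allele A1;
#' HapMap: the second allele of the \code{alleles} field), or fractional
#' dosage in [0,2] for numeric input.
#'
#' @param source input path.  For \code{plink_bed} give the \code{.bed}
#'   file or the bare prefix of the bed/bim/fam triple.
#' @param format one of \code{"vcf"}, \code{"plink_bed"}, \code{"hapmap"},
#'   \code{"numeric"}.
#' @param out output store directory.
#' @param mapFile marker map side file for \code{numeric} input
#'   (tab-delimited, columns \code{snp_id}, \code{chrom}, \code{pos}).
#' @param dtype element type for \code{numeric} input: \code{"byte"} for
#'   integer hard calls, \code{"double"} for fractional dosages.  Detected
#'   from the data when NULL.
#' @param overwrite replace an existing store.
#' @return a \code{GenotypeStore}.  Multiallelic VCF records are skipped
#'   with a warning; the count is available as
#'   \code{attr(store, "n_multiallelic_skipped")}.
#' @export
convertGenotypes <- function(source, format = c("vcf", "plink_bed",
                                                "hapmap", "numeric"),
                             out, mapFile = NULL, dtype = NULL,
                             overwrite = FALSE) {
  format <- match.arg(format)
  switch(format,
    vcf = .convert_vcf(source, out, overwrite),
    plink_bed = .convert_plink(source, out, overwrite),
    hapmap = .convert_hapmap(source, out, overwrite),
    numeric = .convert_numeric(source, mapFile, out, dtype, overwrite))
}

.convert_vcf <- function(source, out, overwrite = FALSE) {
  if (!file.exists(source)) stop("VCF not found: ", source)
  v <- vcfR::read.vcfR(source, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  nskip <- sum(multi)
  if (nskip > 0)
    warning(nskip, " multiallelic VCF record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (!nrow(gt)) stop("no biallelic records in VCF")
  dos <- .gt_to_dosage(gt)
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  markers <- data.frame(snp_id = ids, chrom = as.character(fix[, "CHROM"]),
                        pos = as.integer(fix[, "POS"]),
                        allele_major = fix[, "REF"],
                        allele_minor = fix[, "ALT"],
                        stringsAsFactors = FALSE)
  st <- createGenotypeStore(dos, markers, colnames(gt), out,
                            dtype = "byte", overwrite = overwrite)
  attr(st, "n_multiallelic_skipped") <- nskip
  st
}

# diploid GT strings -> 0/1/2 ALT-allele counts; any missing allele
# (including half-missing calls like ./1) counts as missing
.gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (length(al) != 2L || any(al == ".") || any(is.na(suppressWarnings(as.integer(al)))))
      return(NA_real_)
    sum(as.integer(al) > 0L)
  }, numeric(1))
  out <- matrix(map[match(as.vector(gt), u)], nrow(gt), ncol(gt))
  dimnames(out) <- dimnames(gt)
  out
}

.convert_plink <- function(source, out, overwrite = FALSE) {
  prefix <- sub("\\.bed$", "", source)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  if (!all(file.exists(bed, bim, fam)))
    stop("bed/bim/fam triple not found for prefix ", prefix)
  bimdf <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = c("character", "character",
                                            "numeric", "integer",
                                            "character", "character"))
  names(bimdf) <- c("chrom", "snp_id", "cm", "pos", "a1", "a2")
  famdf <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  samples <- as.character(famdf[[2L]])
  m <- nrow(bimdf); n <- length(samples)
  bpm <- ceiling(n / 4)  # bytes per marker, SNP-major
  expect <- 3 + as.double(m) * bpm
  if (file.info(bed)$size != expect)
    stop("bed size does not match bim/fam dimensions (",
         file.info(bed)$size, " vs ", expect,
         " bytes); sample or marker count mismatch")
  con <- file(bed, "rb")
  magic <- readBin(con, "raw", 3L)
  close(con)
  if (!identical(as.integer(magic), c(0x6CL, 0x1BL, 0x01L)))
    stop("not a SNP-major PLINK bed file (bad magic bytes)")
  markers <- data.frame(snp_id = bimdf$snp_id, chrom = bimdf$chrom,
                        pos = bimdf$pos, allele_major = bimdf$a2,
                        allele_minor = bimdf$a1, stringsAsFactors = FALSE)
  # 2-bit codes per sample: 00 = hom A1 (dosage 2), 01 = missing,
  # 10 = het, 11 = hom A2 (dosage 0); dosage counts the A1 allele
  code <- c(`0` = 2, `1` = NA_real_, `2` = 1, `3` = 0)
  reader <- function(rows) {
    con <- file(bed, "rb")
    on.exit(close(con))
    blk <- matrix(NA_real_, length(rows), n)
    runs <- split(seq_along(rows), cumsum(c(TRUE, diff(rows) != 1L)))
    for (idx in runs) {
      seek(con, where = 3 + (rows[idx[1L]] - 1) * as.double(bpm),
           origin = "start")
      bytes <- as.integer(readBin(con, "raw", bpm * length(idx)))
      twobit <- rbind(bytes %% 4L, (bytes %/% 4L) %% 4L,
                      (bytes %/% 16L) %% 4L, bytes %/% 64L)
      g <- matrix(code[twobit + 1L], nrow = 4L * bpm)
      blk[idx, ] <- t(g[seq_len(n), , drop = FALSE])
    }
    blk
  }
  .store_from_reader(reader, markers, samples, out, dtype = "byte",
                     overwrite = overwrite)
}

# stream a store from a random-access row reader, writing rows in
# (chrom, pos) sorted order chunk by chunk
.store_from_reader <- function(reader, markers, samples, out, dtype,
                               overwrite = FALSE, chunk = 4096L) {
  m <- nrow(markers); n <- length(samples)
  ord <- order(markers$chrom, markers$pos)
  markers <- markers[ord, , drop = FALSE]
  rownames(markers) <- NULL
  if (dir.exists(out)) {
    if (file.exists(.dosage_file(out)) && !overwrite)
      stop("store already exists at ", out)
  } else dir.create(out, recursive = TRUE)
  con <- file(.dosage_file(out), "wb")
  on.exit(close(con))
  af <- numeric(m)
  for (start in seq(1L, m, by = chunk)) {
    sel <- start:min(m, start + chunk - 1L)
    block <- reader(ord[sel])
    .note_block(nrow(block))
    if (any(!is.na(block) & (block < 0 | block > 2)))
      stop("dosage values outside [0,2]")
    a <- rowMeans(block, na.rm = TRUE) / 2
    a[is.nan(a)] <- NA_real_
    af[sel] <- a
    if (dtype == "byte") {
      v <- as.integer(t(block))
      v[is.na(v)] <- 255L
      writeBin(as.raw(v), con)
    } else writeBin(as.numeric(t(block)), con)
  }
  markers$maf <- pmin(af, 1 - af)
  .write_store_meta(out, m, n, dtype, samples, markers)
  new("GenotypeStore", path = normalizePath(out), dim = c(m, n),
      dtype = dtype, samples = as.character(samples), markers = markers)
}

.convert_hapmap <- function(source, out, overwrite = FALSE) {
  if (!file.exists(source)) stop("HapMap file not found: ", source)
  hdr <- strsplit(readLines(source, n = 1L), "\t", fixed = TRUE)[[1L]]
  std <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
           "center", "protLSID", "assayLSID", "panelLSID", "QCcode")
  if (length(hdr) < 12L || !identical(tolower(hdr[1:4]), tolower(std[1:4])))
    stop("malformed HapMap header: expected the 11 standard columns ",
         "(rs#, alleles, chrom, pos, ...) followed by sample columns")
  dt <- data.table::fread(source, sep = "\t", header = TRUE,
                          data.table = FALSE, colClasses = "character")
  samples <- hdr[-(1:11)]
  gm <- as.matrix(dt[, -(1:11), drop = FALSE])
  alleles <- strsplit(dt[[2L]], "/", fixed = TRUE)
  a1 <- vapply(alleles, `[`, "", 1L)
  a2 <- vapply(alleles, function(a) if (length(a) > 1L) a[2L] else NA_character_, "")
  dos <- .hapmap_to_dosage(gm, a1, a2)
  markers <- data.frame(snp_id = dt[[1L]], chrom = as.character(dt[[3L]]),
                        pos = as.integer(dt[[4L]]),
                        allele_major = a1, allele_minor = a2,
                        stringsAsFactors = FALSE)
  createGenotypeStore(dos, markers, samples, out, dtype = "byte",
                      overwrite = overwrite)
}

# two-letter (AA/AG/...) or IUPAC single-letter genotype codes ->
# counts of the second listed allele; N/NN -> missing
.hapmap_to_dosage <- function(gm, a1, a2) {
  iupac_het <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")
  m <- nrow(gm); n <- ncol(gm)
  out <- matrix(NA_real_, m, n)
  for (i in seq_len(m)) {
    g <- gm[i, ]
    g[g %in% c("N", "NN", "", "--")] <- NA_character_
    one <- !is.na(g) & nchar(g) == 1L
    if (any(one)) {
      gg <- g[one]
      expand <- ifelse(gg %in% names(iupac_het), iupac_het[gg],
                       paste0(gg, gg))
      g[one] <- expand
    }
    cnt <- ifelse(is.na(g), NA_real_,
                  (substr(g, 1, 1) == a2[i]) + (substr(g, 2, 2) == a2[i]))
    # genotypes containing an allele not in the alleles field -> missing
    legal <- is.na(g) | (substr(g, 1, 1) %in% c(a1[i], a2[i]) &
                         substr(g, 2, 2) %in% c(a1[i], a2[i]))
    cnt[!legal] <- NA_real_
    out[i, ] <- cnt
  }
  out
}

.convert_numeric <- function(source, mapFile, out, dtype = NULL,
                             overwrite = FALSE, chunk = 4096L) {
  if (!file.exists(source)) stop("numeric matrix not found: ", source)
  if (is.null(mapFile) || !file.exists(mapFile))
    stop("numeric input needs a marker-map side file (snp_id, chrom, pos)")
  markers <- data.table::fread(mapFile, data.table = FALSE,
                               colClasses = list(character = "chrom"))
  if (!all(c("snp_id", "chrom", "pos") %in% names(markers)))
    stop("marker map needs snp_id, chrom, pos columns")
  markers$chrom <- as.character(markers$chrom)
  samples <- as.character(data.table::fread(source, nrows = 0L,
                                            data.table = FALSE,
                                            header = TRUE) |> names())
  m <- nrow(markers); n <- length(samples)
  if (is.null(dtype)) {
    probe <- as.matrix(data.table::fread(source, nrows = min(m, 200L),
                                         header = TRUE, data.table = FALSE))
    dtype <- if (all(is.na(probe) | probe == round(probe))) "byte" else "double"
  }
  # pass 1: stream chunks into a temp store in input order; pass 2 (only
  # if the map is unsorted) permutes rows through bounded block reads
  sorted <- !is.unsorted(order(markers$chrom, markers$pos))
  tmp <- if (sorted) out else tempfile("gwaskit_store_")
  wcon_path <- .dosage_file(tmp)
  if (dir.exists(tmp)) {
    if (file.exists(wcon_path) && !overwrite) stop("store already exists at ", tmp)
  } else dir.create(tmp, recursive = TRUE)
  wcon <- file(wcon_path, "wb")
  af <- numeric(m)
  nread <- 0L
  while (nread < m) {
    nr <- min(chunk, m - nread)
    block <- as.matrix(data.table::fread(source, skip = nread + 1L,
                                         nrows = nr, header = FALSE,
                                         data.table = FALSE))
    storage.mode(block) <- "double"
    .note_block(nrow(block))
    if (ncol(block) != n) { close(wcon); stop("column count mismatch in numeric matrix") }
    if (any(!is.na(block) & (block < 0 | block > 2))) {
      close(wcon); stop("dosage values outside [0,2]")
    }
    a <- rowMeans(block, na.rm = TRUE) / 2
    a[is.nan(a)] <- NA_real_
    af[(nread + 1L):(nread + nr)] <- a
    if (dtype == "byte") {
      v <- as.integer(t(block)); v[is.na(v)] <- 255L
      writeBin(as.raw(v), wcon)
    } else writeBin(as.numeric(t(block)), wcon)
    nread <- nread + nr
  }
  close(wcon)
  markers$maf <- pmin(af, 1 - af)
  .write_store_meta(tmp, m, n, dtype, samples, markers)
  st <- new("GenotypeStore", path = normalizePath(tmp), dim = c(m, n),
            dtype = dtype, samples = samples, markers = markers)
  if (sorted) return(st)
  res <- .store_from_reader(function(rows) readDosages(st, rows),
                            markers[, c("snp_id", "chrom", "pos")],
                            samples, out, dtype, overwrite = overwrite)
  unlink(tmp, recursive = TRUE)
  res
}

#' Export a store back to a numeric dosage matrix file
#'
#' @param store a \code{GenotypeStore}.
#' @param file output path (tab-delimited, sample header row).
#' @param mapFile optional path for the marker-map side file.
#' @export
writeNumeric <- function(store, file, mapFile = NULL) {
  x <- readDosages(store)
  dt <- data.table::as.data.table(x)
  data.table::setnames(dt, sampleIDs(store))
  data.table::fwrite(dt, file, sep = "\t", na = "NA", quote = FALSE)
  if (!is.null(mapFile))
    utils::write.table(markerMap(store)[, c("snp_id", "chrom", "pos")],
                       mapFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
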