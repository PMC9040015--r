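# Conversion to and random access of the file-backed store.

write_toy_vcf <- function(path, gts, chrom, pos, ref = "A", alt = "G",
                          samples = paste0("s", seq_len(ncol(gts)))) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(chrom), ">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                   "FILTER", "INFO", "FORMAT", samples),
                 collapse = "\t"))
  rows <- vapply(seq_len(nrow(gts)), function(i) {
    paste(c(chrom[i], pos[i], paste0("rs", i), ref, alt[i], ".",
            "PASS", ".", "GT", gts[i, ]), collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
}

test_that("numeric matrix round trip is the identity", {
  set.seed(1)
  x <- matrix(sample(0:2, 12, replace = TRUE), 3, 4)
  src <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".tsv")
  write.table(setNames(as.data.frame(x), paste0("s", 1:4)), src,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(snp_id = paste0("m", 1:3), chrom = "1",
                         pos = 1:3), mp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  st <- convertGenotypes(src, "numeric", tempfile(), mapFile = mp)
  expect_identical(unname(readDosages(st)), matrix(as.numeric(x), 3, 4))
  expect_identical(sampleIDs(st), paste0("s", 1:4))
  # fractional dosages go to the floating-point store variant
  xf <- matrix(c(0.1, 0.3, 0.6, 1.9), 2, 2)
  stf <- make_store(xf, dtype = "double")
  expect_equal(unname(readDosages(stf)), xf, tolerance = 0)
})

test_that("conversion is idempotent at the byte level", {
  set.seed(2)
  x <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 10, 6)
  p1 <- tempfile(); p2 <- tempfile()
  make_store_at <- function(p) createGenotypeStore(x,
    data.frame(snp_id = paste0("m", 1:10), chrom = "1", pos = 1:10),
    paste0("s", 1:6), p)
  make_store_at(p1); make_store_at(p2)
  expect_identical(readBin(file.path(p1, "dosage.bin"), "raw", 1000),
                   readBin(file.path(p2, "dosage.bin"), "raw", 1000))
})

test_that("VCF genotypes convert to 0/1/2 ALT counts", {
  gts <- rbind(c("0/0", "0/1", "1/1", "./."),
               c("0|0", "1|1", "./1", "0/1"))
  f <- tempfile(fileext = ".vcf")
  write_toy_vcf(f, gts, chrom = c("1", "1"), pos = c(100, 200),
                alt = c("G", "T"))
  st <- convertGenotypes(f, "vcf", tempfile())
  d <- readDosages(st)
  expect_equal(unname(d[1, ]), c(0, 1, 2, NA))
  # half-missing ./1 is treated as missing
  expect_equal(unname(d[2, ]), c(0, 2, NA, 1))
  expect_equal(markerMap(st)$pos, c(100L, 200L))
})

test_that("multiallelic VCF records are skipped with a warning and count", {
  gts <- rbind(c("0/0", "0/1"), c("0/1", "1/2"), c("1/1", "0/0"))
  f <- tempfile(fileext = ".vcf")
  write_toy_vcf(f, gts, chrom = rep("2", 3), pos = c(10, 20, 30),
                alt = c("G", "G,T", "C"))
  expect_warning(st <- convertGenotypes(f, "vcf", tempfile()),
                 "multiallelic")
  expect_equal(nMarkers(st), 2L)
  expect_equal(attr(st, "n_multiallelic_skipped"), 1L)
})

test_that("VCF and equivalently coded numeric input give identical stores", {
  set.seed(3)
  x <- matrix(sample(0:2, 5 * 6, replace = TRUE), 5, 6)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[x + 1], 5, 6)
  f <- tempfile(fileext = ".vcf")
  write_toy_vcf(f, gt_str, chrom = rep("1", 5), pos = 1:5 * 10,
                alt = rep("G", 5))
  st_vcf <- convertGenotypes(f, "vcf", tempfile())
  src <- tempfile(); mp <- tempfile()
  write.table(setNames(as.data.frame(x), paste0("s", 1:6)), src,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(snp_id = paste0("rs", 1:5), chrom = "1",
                         pos = 1:5 * 10), mp, sep = "\t",
              quote = FALSE, row.names = FALSE)
  st_num <- convertGenotypes(src, "numeric", tempfile(), mapFile = mp)
  expect_identical(unname(readDosages(st_vcf)),
                   unname(readDosages(st_num)))
})

test_that("hand-written PLINK bed decodes against the published bit layout", {
  # 4 samples, 2 markers; per marker one byte, two bits per sample,
  # low-order bits first: 00 = hom A1 (dosage 2), 01 = missing,
  # 10 = het (1), 11 = hom A2 (0)
  truth <- rbind(c(2, 1, 0, NA),   # codes 00, 10, 11, 01
                 c(0, 0, 2, 1))    # codes 11, 11, 00, 10
  code_of <- function(d) if (is.na(d)) 1L else c(`2` = 0L, `1` = 2L,
                                                 `0` = 3L)[as.character(d)]
  bytes <- vapply(1:2, function(i) {
    cs <- vapply(truth[i, ], code_of, integer(1))
    as.raw(cs[1] + cs[2] * 4L + cs[3] * 16L + cs[4] * 64L)
  }, raw(1))
  pre <- tempfile()
  writeBin(c(as.raw(c(0x6C, 0x1B, 0x01)), bytes), paste0(pre, ".bed"))
  writeLines(c("1\tsnpA\t0\t50\tA\tG", "1\tsnpB\t0\t150\tC\tT"),
             paste0(pre, ".bim"))
  writeLines(paste0("f", 1:4, "\tind", 1:4, "\t0\t0\t0\t-9"),
             paste0(pre, ".fam"))
  st <- convertGenotypes(paste0(pre, ".bed"), "plink_bed", tempfile())
  expect_equal(unname(readDosages(st)), unname(truth))
  expect_identical(sampleIDs(st), paste0("ind", 1:4))
  expect_identical(markerMap(st)$allele_minor, c("A", "C"))
})

test_that("bed size mismatch with fam/bim is an error", {
  pre <- tempfile()
  writeBin(c(as.raw(c(0x6C, 0x1B, 0x01)), as.raw(0)), paste0(pre, ".bed"))
  writeLines(c("1\tsnpA\t0\t50\tA\tG", "1\tsnpB\t0\t150\tC\tT"),
             paste0(pre, ".bim"))
  writeLines(paste0("f", 1:4, "\tind", 1:4, "\t0\t0\t0\t-9"),
             paste0(pre, ".fam"))
  expect_error(convertGenotypes(paste0(pre, ".bed"), "plink_bed",
                                tempfile()), "mismatch")
})

test_that("HapMap two-letter and IUPAC codes convert; bad header errors", {
  hdr <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID",
                 "QCcode", "s1", "s2", "s3"), collapse = "\t")
  rows <- c(paste(c("rs1", "A/G", "1", "100", "+", rep("NA", 6),
                    "AA", "AG", "GG"), collapse = "\t"),
            paste(c("rs2", "C/T", "1", "200", "+", rep("NA", 6),
                    "Y", "NN", "CC"), collapse = "\t"))
  f <- tempfile(); writeLines(c(hdr, rows), f)
  st <- convertGenotypes(f, "hapmap", tempfile())
  d <- readDosages(st)
  expect_equal(unname(d[1, ]), c(0, 1, 2))         # counts of G
  expect_equal(unname(d[2, ]), c(1, NA, 0))        # Y = C/T het
  bad <- tempfile()
  writeLines(c("id\tchrom\tpos\ts1", "rs1\t1\t100\tAA"), bad)
  expect_error(convertGenotypes(bad, "hapmap", tempfile()), "header")
})

test_that("marker map is position-sorted within chromosome after conversion", {
  x <- matrix(sample(0:2, 8, replace = TRUE), 4, 2)
  st <- createGenotypeStore(x,
    data.frame(snp_id = c("d", "c", "b", "a"), chrom = c("2", "1", "2", "1"),
               pos = c(5L, 9L, 1L, 2L)),
    c("s1", "s2"), tempfile())
  mm <- markerMap(st)
  expect_identical(mm$snp_id, c("a", "c", "b", "d"))
  expect_true(!is.unsorted(mm$pos[mm$chrom == "2"]))
  # rows follow the map: row for snp "d" holds the original first row
  expect_equal(unname(readDosages(st, 4)), matrix(as.numeric(x[1, ]), 1))
})

test_that("marker stats: MAF, missing rate and monomorphic flag", {
  st <- make_store(rbind(c(0, 0, 2, 2),
                         c(2, 2, 2, 2),
                         c(0, 1, 2, NA)))
  ms <- markerStats(st)
  expect_equal(ms$maf, c(0.5, 0, 0.5))
  expect_equal(ms$missing_rate, c(0, 0, 0.25))
  expect_identical(ms$monomorphic, c(FALSE, TRUE, FALSE))
  # all-missing marker: undefined MAF, flagged
  st2 <- make_store(rbind(c(NA, NA, NA), c(0, 1, 2)))
  ms2 <- markerStats(st2)
  expect_true(is.na(ms2$maf[1]) && ms2$monomorphic[1])
})

test_that("alignSamples intersects in store order and drops missing traits", {
  st <- make_store(matrix(0:2, 3, 3), pos = 1:3)  # samples s1 s2 s3
  ph <- data.frame(id = c("s3", "s1"), trait1 = c(2.0, 1.0))
  al <- alignSamples(st, ph)
  expect_equal(al$sampleIndex, c(1L, 3L))
  expect_equal(al$phenotype$id, c("s1", "s3"))
  expect_equal(al$y, c(1.0, 2.0))
  # identity when lists agree
  ph2 <- data.frame(id = paste0("s", 1:3), trait1 = rnorm(3))
  expect_equal(alignSamples(st, ph2)$sampleIndex, 1:3)
  # one missing trait value -> excluded and counted
  ph2$trait1[2] <- NA
  al2 <- alignSamples(st, ph2)
  expect_equal(al2$nDropped, 1L)
  expect_equal(al2$sampleIndex, c(1L, 3L))
  expect_error(alignSamples(st, data.frame(id = "zz", trait1 = 1)),
               "no shared sample")
})

test_that("streamed access keeps the row-buffer bounded by the block size", {
  set.seed(4)
  st <- make_store(matrix(sample(0:2, 400 * 20, replace = TRUE), 400, 20))
  resetPeakBlockRows()
  ms <- markerStats(st, blockSize = 32L)
  g <- computeGRM(st, blockSize = 32L)
  expect_lte(peakBlockRows(), 32L)
  expect_equal(nrow(grmMatrix(g)), 20L)
})

test_that("concurrent readers see identical values", {
  set.seed(5)
  st <- make_store(matrix(sample(0:2, 50 * 8, replace = TRUE), 50, 8))
  ref <- readDosages(st)
  reads <- parallel::mclapply(1:3, function(i) readDosages(st),
                              mc.cores = 2L)
  for (r in reads) expect_identical(r, ref)
})
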