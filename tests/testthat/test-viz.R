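# Plots are asserted through their coordinate tables, never their pixels.

toy_results <- function(chrom, pos, p) {
  data.frame(SNP = paste0("s", seq_along(p)), CHROM = chrom, POS = pos,
             PVALUE = p)
}

test_that("Manhattan cumulative coordinates follow chromosome offsets", {
  # chromosome lengths 100 and 50 (max position per chromosome);
  # the inter-chromosome gap is 1% of the genome length = 1.5
  tab <- toy_results(c("1", "1", "2", "2"), c(40, 100, 10, 50),
                     c(0.5, 1e-4, 0.01, 0.2))
  spec <- plotSpec(tempfile(fileext = ".png"))
  co <- manhattanPlot(tab, spec)
  expect_equal(co$x[co$CHROM == "2" & co$POS == 10], 100 + 1.5 + 10)
  expect_equal(co$x[co$POS == 40], 40)
  expect_equal(co$y, -log10(tab$PVALUE))
  expect_true(file.exists(spec$output))
  expect_gt(file.info(spec$output)$size, 0)
  expect_true(file.exists(paste0(spec$output, ".coords.tsv")))
})

test_that("flat p-values sit at zero and below every threshold line", {
  tab <- toy_results(rep(c("1", "2"), each = 5), rep(1:5 * 10, 2),
                     rep(1, 10))
  spec <- plotSpec(tempfile(fileext = ".png"), thresholds = 0.05)
  co <- manhattanPlot(tab, spec)
  expect_true(all(co$y == 0))
  expect_true(all(co$y < -log10(0.05)))
})

test_that("multi-group layouts and highlighting work on one coordinate table", {
  set.seed(80)
  t1 <- toy_results(rep("1", 50), 1:50 * 100, runif(50))
  t2 <- toy_results(rep("1", 50), 1:50 * 100, runif(50))
  for (lay in c("rectangular-overlaid", "rectangular-stacked",
                "circular")) {
    spec <- plotSpec(tempfile(fileext = ".png"), layout = lay,
                     thresholds = 1e-3)
    co <- manhattanPlot(list(a = t1, b = t2), spec)
    expect_setequal(unique(co$group), c("a", "b"))
    expect_true(file.exists(spec$output))
  }
  spec <- plotSpec(tempfile(fileext = ".png"),
                   highlight = c("s3", "nope"))
  expect_warning(manhattanPlot(t1, spec), "not found")
})

test_that("qq plot expected quantiles follow -log10((i-0.5)/N)", {
  tab <- toy_results(rep("1", 3), 1:3, c(0.5, 0.5, 0.5))
  spec <- plotSpec(tempfile(fileext = ".pdf"))
  co <- qqPlot(tab, spec)
  expect_equal(co$expected,
               -log10((1:3 - 0.5) / 3), tolerance = 1e-12)
  expect_equal(co$observed, rep(-log10(0.5), 3))
  expect_true(file.exists(spec$output))
})

test_that("uniform p-values stay inside the 95% concentration band", {
  set.seed(81)
  tab <- toy_results(rep("1", 2000), 1:2000, runif(2000))
  co <- qqPlot(tab, plotSpec(tempfile(fileext = ".png")))
  inside <- co$observed >= co$band_lo & co$observed <= co$band_hi
  expect_gte(mean(inside), 0.90)
})

test_that("two groups give two series in the qq coordinates", {
  set.seed(82)
  co <- qqPlot(list(g1 = toy_results(rep("1", 30), 1:30, runif(30)),
                    g2 = toy_results(rep("1", 30), 1:30, runif(30))),
               plotSpec(tempfile(fileext = ".png")))
  expect_setequal(unique(co$group), c("g1", "g2"))
})

test_that("marker density windows count markers exactly", {
  map <- data.frame(chrom = rep("1", 10), pos = seq(2e5, 9e5, length.out = 10))
  co <- markerDensityPlot(map, 1e6, plotSpec(tempfile(fileext = ".png")))
  expect_equal(co$count[1], 10)
  expect_true(all(co$count[-1] == 0))
  # empty chromosome renders a zero track without error
  co2 <- markerDensityPlot(map, 1e6, plotSpec(tempfile(fileext = ".png")),
                           chromosomes = c("1", "2"))
  expect_true(all(co2$count[co2$chrom == "2"] == 0))
})

test_that("uniform marker positions give near-uniform window counts", {
  set.seed(83)
  map <- data.frame(chrom = "1", pos = sample.int(10e6, 10000))
  co <- markerDensityPlot(map, 1e6, plotSpec(tempfile(fileext = ".png")))
  full <- co$count[co$window_end <= 10e6]
  sd3 <- 3 * sqrt(10000 * 0.1 * 0.9)
  expect_true(all(abs(full - 1000) < sd3))
})

test_that("phenotype distribution reports skewness; constant trait warns", {
  set.seed(84)
  ph <- data.frame(id = 1:2000, t1 = rnorm(2000))
  co <- phenoDistPlot(ph, plotSpec(tempfile(fileext = ".png")))
  expect_lt(abs(attr(co, "skewness")[["t1"]]), 0.2)
  phc <- data.frame(id = 1:10, t1 = rep(3, 10))
  expect_warning(phenoDistPlot(phc, plotSpec(tempfile(fileext = ".png"))),
                 "constant")
})

test_that("PCA plot dims validation and coordinates", {
  set.seed(85)
  pcs <- matrix(rnorm(60), 30, 2,
                dimnames = list(paste0("s", 1:30), c("PC1", "PC2")))
  expect_error(pcaPlot(pcs, spec = plotSpec(tempfile(fileext = ".png")),
                       dims = 3), "needs at least")
  co <- pcaPlot(pcs, labels = rep(c("a", "b"), 15),
                spec = plotSpec(tempfile(fileext = ".png")))
  expect_equal(co$PC1, unname(pcs[, 1]))
  expect_setequal(unique(co$group), c("a", "b"))
  pcs3 <- cbind(pcs, PC3 = rnorm(30))
  co3 <- pcaPlot(pcs3, spec = plotSpec(tempfile(fileext = ".png")),
                 dims = 3)
  expect_true(all(c("x", "y", "PC3") %in% names(co3)))
})

test_that("foreign column dialects are read through a column map", {
  f <- tempfile()
  write.table(data.frame(CHR = "1", BP = 100, P = 0.01, SNP = "rs1"),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- readAssocTable(f, columnMap = c(CHR = "CHROM", BP = "POS",
                                         P = "PVALUE"))
  expect_identical(names(tab)[1:3], c("CHROM", "POS", "PVALUE"))
  co <- manhattanPlot(tab, plotSpec(tempfile(fileext = ".png")))
  expect_equal(nrow(co), 1L)
  expect_error(readAssocTable(f), "columnMap")
})

test_that("plot spec validates thresholds and formats", {
  expect_error(plotSpec(tempfile(fileext = ".png"), thresholds = 2),
               "thresholds")
  expect_error(plotSpec(tempfile(fileext = ".bmp")), "format")
})
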