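# Blockwise inversion kernel and the GLM / MLM scans.

test_that("blockwise inverse collapses correctly when w'x = 0", {
  set.seed(50)
  W <- cbind(1, matrix(rnorm(40), 20, 2))
  x <- rnorm(20)
  x <- x - W %*% solve(crossprod(W), crossprod(W, x))  # orthogonalize
  bi <- blockInverse(solve(crossprod(W)), crossprod(W, x), sum(x^2))
  expect_false(bi$degenerate)
  expect_lt(max(abs(bi$M11 - solve(crossprod(W)))), 1e-10)
  expect_lt(max(abs(bi$M12)), 1e-10)
  expect_equal(bi$M22, 1 / sum(x^2), tolerance = 1e-12)
})

test_that("a marker equal to a covariate is flagged degenerate", {
  W <- cbind(1, rnorm(10))
  bi <- blockInverse(solve(crossprod(W)), crossprod(W, W[, 2]),
                     sum(W[, 2]^2))
  expect_true(bi$degenerate)
})

test_that("assembled blocks equal the direct full inverse (random designs)", {
  set.seed(51)
  for (k in c(1, 3, 5)) {
    for (trial in 1:20) {
      n <- 50
      W <- cbind(1, matrix(rnorm(n * (k - 1)), n))[, 1:k, drop = FALSE]
      x <- rnorm(n)
      bi <- blockInverse(solve(crossprod(W)), crossprod(W, x), sum(x^2))
      Minv <- rbind(cbind(bi$M11, bi$M12), cbind(bi$M21, bi$M22))
      direct <- solve(crossprod(cbind(W, x)))
      expect_lt(max(abs(Minv - direct)), 1e-8)
      expect_equal(bi$M12, t(bi$M21), tolerance = 1e-14)
    }
  }
})

test_that("exact linear phenotype gives the effect back with a perfect-fit flag", {
  x <- c(0, 1, 2, 0, 1, 2, 0, 2)
  y <- 2 * x + 5
  res <- glmScan(y, matrix(x, 1, 8))
  tab <- assocTable(res)
  expect_equal(tab$effect, 2, tolerance = 1e-10)
  expect_identical(tab$pvalue, .Machine$double.xmin)
  expect_identical(res@info$perfect_fit, 1L)
})

test_that("monomorphic markers report missing statistics", {
  set.seed(52)
  y <- rnorm(12)
  res <- glmScan(y, rbind(rep(2, 12), rbinom(12, 2, 0.5)))
  expect_true(is.na(assocTable(res)$pvalue[1]))
  expect_false(is.na(assocTable(res)$pvalue[2]))
})

test_that("GLM scan matches the naive per-marker full OLS refit", {
  sp <- sim_pair(n = 120, m = 300, seed = 53, nQtn = 5, h2 = 0.4,
                 nSubpop = 2, fst = 0.05)
  y <- sp$sim$phenotype$trait1
  pcs <- computePCs(eigenGRM(computeGRM(sp$store)), 3)
  res <- assocTable(glmScan(y, sp$store, pcs))
  dos <- readDosages(sp$store, impute = TRUE)
  W <- cbind(1, pcs)
  for (j in seq(1, 300, by = 17)) {
    o <- naive_ols_marker(y, W, dos[j, ])
    expect_equal(res$effect[j], o$effect, tolerance = 1e-10)
    expect_equal(res$se[j], o$se, tolerance = 1e-10)
    expect_equal(res$pvalue[j], o$p, tolerance = 1e-8)
  }
})

test_that("MLM scan matches a naive dense GLS oracle on toy data", {
  sp <- sim_pair(n = 40, m = 200, seed = 54, nQtn = 4, h2 = 0.5,
                 familySize = 4L)
  y <- sp$sim$phenotype$trait1
  grm <- computeGRM(sp$store)
  eig <- eigenGRM(grm)
  vc <- remlBrent(y, NULL, eig)
  res <- assocTable(mlmScan(y, sp$store, NULL, eig, vc))
  V <- vc@sigmaG2 * grmMatrix(grm) + vc@sigmaE2 * diag(40)
  dos <- readDosages(sp$store, impute = TRUE)
  W <- matrix(1, 40, 1)
  for (j in seq(1, 200, by = 11)) {
    if (is.na(res$pvalue[j])) next
    o <- dense_gls_marker(y, W, dos[j, ], V)
    expect_equal(res$effect[j], o$effect, tolerance = 1e-8)
    expect_equal(res$se[j], o$se, tolerance = 1e-8)
    expect_equal(res$pvalue[j], o$p, tolerance = 1e-6)
  }
})

test_that("MLM with h2 = 0 reduces exactly to the GLM", {
  sp <- sim_pair(n = 60, m = 150, seed = 55, nQtn = 3, h2 = 0.3)
  y <- sp$sim$phenotype$trait1
  eig <- eigenGRM(computeGRM(sp$store))
  vc0 <- new("VarianceComponents", sigmaG2 = 0, sigmaE2 = 1, h2 = 0,
             logLik = NA_real_, method = "brent", flags = character())
  pg <- assocTable(glmScan(y, sp$store))$pvalue
  pm <- assocTable(mlmScan(y, sp$store, NULL, eig, vc0))$pvalue
  expect_lt(max(abs(pg - pm), na.rm = TRUE), 1e-10)
})

test_that("scan results are identical for 1 and 4 workers", {
  sp <- sim_pair(n = 80, m = 500, seed = 56, nQtn = 5, h2 = 0.4)
  y <- sp$sim$phenotype$trait1
  r1 <- glmScan(y, sp$store, blockSize = 64L, workers = 1L)
  r4 <- glmScan(y, sp$store, blockSize = 64L, workers = 4L)
  expect_identical(assocTable(r1), assocTable(r4))
})

test_that("results do not depend on input marker order", {
  set.seed(57)
  dos <- matrix(rbinom(100 * 30, 2, 0.3), 100, 30)
  pos <- sample(1:1000, 100)
  perm <- sample(100)
  mk_at <- function(d, p) createGenotypeStore(d,
    data.frame(snp_id = paste0("p", p), chrom = "1", pos = p),
    paste0("s", 1:30), tempfile("store_"))
  st1 <- mk_at(dos, pos)
  st2 <- mk_at(dos[perm, ], pos[perm])
  y <- rnorm(30) + 0.8 * dos[5, ]
  t1 <- assocTable(glmScan(y, st1))
  t2 <- assocTable(glmScan(y, st2))
  expect_equal(t1, t2, ignore_attr = TRUE)
})

test_that("genomic inflation factor behaves as a median chi-square ratio", {
  expect_equal(genomicInflation(rep(0.5, 200)), 1, tolerance = 1e-12)
  set.seed(58)
  p <- runif(10000)
  l1 <- genomicInflation(p)
  expect_gt(l1, 0.95); expect_lt(l1, 1.05)
  expect_gt(genomicInflation(p / 2), l1)  # monotone in evidence
  expect_error(genomicInflation(runif(50)), "at least")
})

test_that("result tables write with the standard header", {
  sp <- sim_pair(n = 30, m = 20, seed = 59, nQtn = 2, h2 = 0.5)
  res <- glmScan(sp$sim$phenotype$trait1, sp$store, trait = "bw")
  d <- tempfile(); dir.create(d)
  f <- writeAssocResults(res, d)
  expect_match(basename(f), "bw.glm.assoc.txt", fixed = TRUE)
  tab <- read.table(f, header = TRUE)
  expect_identical(names(tab),
                   c("SNP", "CHROM", "POS", "EFFECT", "SE", "PVALUE", "N"))
  expect_equal(nrow(tab), 20L)
})
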