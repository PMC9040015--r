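# The four variance-component estimators share one restricted-likelihood
# definition; the oracles here evaluate it the slow dense way.

make_structured <- function(n, m, seed, h2 = 0.5, nQtn = 50) {
  sp <- sim_pair(n = n, m = m, seed = seed, nQtn = nQtn, h2 = h2,
                 familySize = 5L)
  grm <- computeGRM(sp$store)
  list(y = sp$sim$phenotype$trait1, grm = grm, eig = eigenGRM(grm),
       store = sp$store, realized = sp$sim$realizedH2)
}

test_that("eigen-rotated REML equals the dense explicit-inverse objective", {
  d <- make_structured(40, 300, seed = 21)
  X <- matrix(1, 40, 1)
  vc <- remlBrent(d$y, NULL, d$eig)
  ll_dense <- dense_reml_ll(heritability(vc), d$y, X, grmMatrix(d$grm))
  expect_lt(abs(vc@logLik - ll_dense), 1e-8)
  # and at arbitrary points of the likelihood surface
  for (h2 in c(0.1, 0.45, 0.9)) {
    sp <- gwaskit:::.spectral_full(d$y, X, d$eig)
    expect_lt(abs(gwaskit:::.reml_profile(h2, sp)$ll -
                  dense_reml_ll(h2, d$y, X, grmMatrix(d$grm))), 1e-8)
  }
})

test_that("Brent optimum beats a 1001-point grid on the profile likelihood", {
  d <- make_structured(120, 800, seed = 22)
  vc <- remlBrent(d$y, NULL, d$eig)
  sp <- gwaskit:::.spectral_full(d$y, matrix(1, 120, 1), d$eig)
  grid <- seq(1e-6, 1 - 1e-6, length.out = 1001)
  ll_grid <- vapply(grid, function(h) gwaskit:::.reml_profile(h, sp)$ll,
                    numeric(1))
  expect_gte(vc@logLik, max(ll_grid) - 1e-6)
})

test_that("Brent and EMMAX parameterizations agree", {
  for (s in 1:5) {
    d <- make_structured(120, 600, seed = 30 + s,
                         h2 = c(0.2, 0.4, 0.5, 0.6, 0.8)[s])
    b <- remlBrent(d$y, NULL, d$eig)
    e <- remlEmmax(d$y, NULL, d$eig)
    expect_lt(abs(heritability(b) - heritability(e)), 1e-3)
    expect_equal(b@sigmaG2 / b@sigmaE2, e@sigmaG2 / e@sigmaE2,
                 tolerance = 1e-2)
  }
})

test_that("the low-rank spectral route matches the GRM route", {
  # kinship built from the same 50 markers either way
  set.seed(40)
  sp <- sim_pair(n = 300, m = 50, seed = 41, nQtn = 20, h2 = 0.6)
  y <- sp$sim$phenotype$trait1
  eig <- eigenGRM(computeGRM(sp$store))
  b <- remlBrent(y, NULL, eig)
  f <- remlFastlmm(y, NULL, sp$store)
  expect_lt(abs(heritability(b) - heritability(f)), 1e-3)
  expect_equal(f@method, "fastlmm")
})

test_that("single-marker spectrum matches the dense-V objective", {
  set.seed(42)
  x <- matrix(rbinom(30, 2, 0.4), 1, 30)
  y <- rnorm(30) + 0.5 * drop(x)
  f <- remlFastlmm(y, NULL, x)
  Zs <- gwaskit:::.scaled_markers(x)
  K <- crossprod(Zs)
  ll_dense <- dense_reml_ll(heritability(f), y, matrix(1, 30, 1), K)
  expect_lt(abs(f@logLik - ll_dense), 1e-8)
})

test_that("monomorphic marker sets are rejected", {
  expect_error(remlFastlmm(rnorm(5), NULL, matrix(2, 3, 5)),
               "monomorphic")
})

test_that("kinship proportional to identity yields flat likelihood handling", {
  set.seed(43)
  eigI <- eigenGRM(diag(50))
  vc <- remlBrent(rnorm(50), NULL, eigI)
  expect_identical(heritability(vc), 0)
  expect_match(vc@flags, "flat")
  expect_identical(heritability(remlEmmax(rnorm(50), NULL, eigI)), 0)
})

test_that("heritability field is consistent and variances non-negative", {
  d <- make_structured(100, 500, seed = 44)
  for (vc in list(remlBrent(d$y, NULL, d$eig),
                  remlEmmax(d$y, NULL, d$eig),
                  heRegression(d$y, d$grm))) {
    expect_gte(vc@sigmaG2, 0); expect_gte(vc@sigmaE2, 0)
    expect_lt(abs(vc@h2 - vc@sigmaG2 / (vc@sigmaG2 + vc@sigmaE2)), 1e-10)
  }
})

test_that("Haseman-Elston slope equals the closed-form OLS on pairs", {
  # 3-point hand check: z = (1,-1,0) (already standardized), off-diagonals
  # for pairs (1,2),(1,3),(2,3) are 0.5, 0.0, -0.5
  G <- diag(3)
  G[1, 2] <- G[2, 1] <- 0.5
  G[1, 3] <- G[3, 1] <- 0.0
  G[2, 3] <- G[3, 2] <- -0.5
  y <- c(1, -1, 0)                      # mean 0, sd 1
  prods <- c(1 * -1, 1 * 0, -1 * 0)     # pair products of z
  g <- c(0.5, 0.0, -0.5)
  slope_hand <- sum((prods - mean(prods)) * (g - mean(g))) /
    sum((g - mean(g))^2)
  vc <- heRegression(y, G)
  expect_equal(heritability(vc), min(max(slope_hand, 0), 1))
  # interior case against the same closed form, n = 12
  set.seed(45)
  A <- matrix(rnorm(144), 12); K <- tcrossprod(A) / 12
  K <- K / mean(diag(K))
  y2 <- rnorm(12)
  z <- (y2 - mean(y2)) / sd(y2)
  ut <- upper.tri(K)
  slope2 <- cov(tcrossprod(z)[ut], K[ut]) / var(K[ut])
  expect_equal(heritability(heRegression(y2, K)),
               min(max(slope2, 0), 1), tolerance = 1e-12)
  expect_error(heRegression(y2, matrix(0.3, 12, 12) + diag(12) * 0.7),
               "degenerate")
})

test_that("a phenotype independent of the kinship estimates near-zero h2", {
  sp <- sim_pair(n = 500, m = 2000, seed = 46, familySize = 5L)
  y <- rnorm(500)   # noise unrelated to the genotypes
  vc <- remlBrent(y, NULL, eigenGRM(computeGRM(sp$store)))
  expect_lt(heritability(vc), 0.1)
})

test_that("all four estimators recover a moderate simulated h2", {
  h2hat <- vapply(c(101, 102, 103), function(s) {
    d <- make_structured(400, 3000, seed = s, h2 = 0.5)
    c(brent = heritability(remlBrent(d$y, NULL, d$eig)),
      he = heritability(heRegression(d$y, d$grm)))
  }, numeric(2))
  expect_lt(abs(median(h2hat["brent", ]) - 0.5), 0.15)
  expect_lt(abs(median(h2hat["he", ]) - 0.5), 0.2)
})
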