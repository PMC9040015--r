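# Synthetic genotypes and phenotypes with known truth.  Population
# structure follows the Balding-Nichols drift model; cryptic relatedness
# comes from full-sib family blocks generated by Mendelian transmission
# from simulated parents.  Everything is reproducible from the config
# seed; there is no hidden global randomness.

#' Simulation configuration
#'
#' @param n number of samples.
#' @param m number of markers.
#' @param seed mandatory RNG seed.
#' @param mafRange ancestral minor allele frequency range, a subset of
#'   (0, 0.5].
#' @param nSubpop number of subpopulations (1 = unstructured).
#' @param fst Balding-Nichols divergence F between subpopulations.
#' @param familySize full-sib family block size (1 = unrelated samples).
#' @param nQtn number of causal markers for the phenotype.
#' @param h2 target narrow-sense heritability (realized value is enforced
#'   by construction).
#' @param qtnEffectDist \code{"normal"} draws additive effects from a
#'   standard normal; \code{"equal_var"} scales each effect so every
#'   causal marker explains the same share (h2 / nQtn) of the phenotypic
#'   variance, with random sign.
#' @param nChrom number of chromosomes markers are spread over.
#' @param bpPerMarker average marker spacing in bp.
#' @return a classed list.
#' @export
simConfig <- function(n, m, seed, mafRange = c(0.05, 0.5), nSubpop = 1L,
                      fst = 0, familySize = 1L, nQtn = 0L, h2 = 0,
                      qtnEffectDist = c("normal", "equal_var"),
                      nChrom = 10L, bpPerMarker = 1000L) {
  qtnEffectDist <- match.arg(qtnEffectDist)
  if (n < 2L || m < 1L) stop("need n >= 2 samples and m >= 1 markers")
  if (missing(seed)) stop("a seed is mandatory")
  if (mafRange[1L] <= 0 || mafRange[2L] > 0.5 ||
      mafRange[1L] > mafRange[2L])
    stop("mafRange must be within (0, 0.5]")
  if (nQtn > 0L && (h2 <= 0 || h2 > 1))
    stop("h2 must lie in (0,1] when nQtn > 0")
  if (fst < 0 || fst >= 1) stop("fst must lie in [0,1)")
  nChrom <- min(nChrom, m)
  structure(list(n = as.integer(n), m = as.integer(m),
                 seed = as.integer(seed), mafRange = mafRange,
                 nSubpop = as.integer(nSubpop), fst = fst,
                 familySize = as.integer(familySize),
                 nQtn = as.integer(nQtn), h2 = h2,
                 qtnEffectDist = qtnEffectDist,
                 nChrom = as.integer(nChrom),
                 bpPerMarker = as.integer(bpPerMarker)),
            class = "SimConfig")
}

#' Simulate genotypes into a file-backed store
#'
#' Ancestral allele frequencies are drawn uniformly from the configured
#' range; with more than one subpopulation, subpopulation frequencies
#' drift as Beta(p(1-F)/F, (1-p)(1-F)/F).  Within full-sib families,
#' offspring dosages come from Mendelian transmission out of two
#' simulated parents; all other samples are drawn under Hardy-Weinberg
#' equilibrium.  The same config always produces an identical store.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param path store output directory (a temporary directory when NULL).
#' @param overwrite replace an existing store.
#' @return a \code{GenotypeStore}; sample metadata (subpopulation and
#'   family assignment) is attached as \code{attr(store, "labels")}.
#' @export
simulateGenotypes <- function(cfg, path = NULL, overwrite = FALSE) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (is.null(path)) path <- tempfile("gwaskit_sim_")
  set.seed(cfg$seed)
  n <- cfg$n; m <- cfg$m
  p0 <- stats::runif(m, cfg$mafRange[1L], cfg$mafRange[2L])
  subpop <- rep(seq_len(cfg$nSubpop), length.out = n)
  subpop <- sort(subpop)
  # per-subpopulation drifted frequencies (m x nSubpop)
  P <- if (cfg$nSubpop > 1L && cfg$fst > 0) {
    a <- p0 * (1 - cfg$fst) / cfg$fst
    b <- (1 - p0) * (1 - cfg$fst) / cfg$fst
    matrix(stats::rbeta(m * cfg$nSubpop, rep(a, cfg$nSubpop),
                        rep(b, cfg$nSubpop)), m, cfg$nSubpop)
  } else matrix(p0, m, cfg$nSubpop)
  P <- pmin(pmax(P, 1e-4), 1 - 1e-4)

  dos <- matrix(0L, m, n)
  fam <- integer(n)
  if (cfg$familySize == 1L) {
    # unrelated: draw each subpopulation block in one vectorized call
    for (sp in seq_len(cfg$nSubpop)) {
      cols <- which(subpop == sp)
      dos[, cols] <- stats::rbinom(m * length(cols), 2L, P[, sp])
    }
    fam <- seq_len(n)
    col <- n + 1L
    famid <- n
  } else {
  col <- 1L
  famid <- 0L
  while (col <= n) {
    size <- min(cfg$familySize, n - col + 1L)
    sp <- subpop[col]
    famid <- famid + 1L
    pv <- P[, sp]
    if (size == 1L) {
      dos[, col] <- stats::rbinom(m, 2L, pv)
    } else {
      par1 <- stats::rbinom(m, 2L, pv)
      par2 <- stats::rbinom(m, 2L, pv)
      for (s in 0:(size - 1L)) {
        a1 <- stats::rbinom(m, 1L, par1 / 2)
        a2 <- stats::rbinom(m, 1L, par2 / 2)
        dos[, col + s] <- a1 + a2
      }
    }
    fam[col:(col + size - 1L)] <- famid
    col <- col + size
  }
  }
  perChrom <- ceiling(m / cfg$nChrom)
  chrom <- as.character(rep(seq_len(cfg$nChrom), each = perChrom)[seq_len(m)])
  chromLen <- perChrom * cfg$bpPerMarker
  pos <- integer(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- sort(sample.int(chromLen, length(idx)))
  }
  markers <- data.frame(snp_id = sprintf("snp_%s_%d", chrom, pos),
                        chrom = chrom, pos = pos,
                        allele_major = "A", allele_minor = "B",
                        stringsAsFactors = FALSE)
  samples <- sprintf("ind%04d", seq_len(n))
  st <- createGenotypeStore(dos, markers, samples, path, dtype = "byte",
                            overwrite = overwrite)
  attr(st, "labels") <- data.frame(sample = samples, subpop = subpop,
                                   family = fam,
                                   stringsAsFactors = FALSE)
  st
}

#' Simulate a phenotype with known causal markers
#'
#' Picks \code{nQtn} polymorphic markers, draws additive effects from a
#' standard normal, and adds environmental noise scaled (after removing
#' its sample correlation with the genetic values) so the realized
#' heritability var(g)/var(y) equals the target exactly.
#'
#' @param store a \code{GenotypeStore}.
#' @param cfg the \code{\link{simConfig}} used (supplies nQtn, h2 and the
#'   seed; the phenotype stream is offset from the genotype stream).
#' @return list with \code{phenotype} (data.frame: sample_id, trait1),
#'   \code{truth} (data.frame: snp_id, chrom, pos, effect) and
#'   \code{realizedH2}.
#' @export
simulatePhenotype <- function(store, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed + 7919L)
  n <- nSamples(store)
  mm <- markerMap(store)
  if (cfg$nQtn > 0L) {
    poly <- which(!is.na(mm$maf) & mm$maf > 0)
    if (length(poly) < cfg$nQtn) stop("not enough polymorphic markers")
    qtn <- sort(sample(poly, cfg$nQtn))
    X <- readDosages(store, qtn, impute = TRUE)
    eff <- if (identical(cfg$qtnEffectDist, "equal_var")) {
      sds <- apply(X, 1L, stats::sd)
      sample(c(-1, 1), cfg$nQtn, replace = TRUE) / pmax(sds, 1e-8)
    } else stats::rnorm(cfg$nQtn)
    g <- drop(crossprod(X, eff))
  } else {
    qtn <- integer(0)
    eff <- numeric(0)
    g <- numeric(n)
  }
  e <- stats::rnorm(n)
  h2 <- if (cfg$nQtn > 0L) cfg$h2 else 0
  if (h2 >= 1) {
    y <- g
    realized <- 1
  } else if (h2 <= 0 || stats::var(g) == 0) {
    y <- e
    realized <- 0
  } else {
    # decorrelate noise from g in-sample, then scale exactly
    e <- stats::lm.fit(cbind(1, g), e)$residuals
    e <- e / stats::sd(e) * stats::sd(g) * sqrt((1 - h2) / h2)
    y <- g + e
    realized <- stats::var(g) / stats::var(y)
  }
  list(phenotype = data.frame(sample_id = sampleIDs(store), trait1 = y,
                              stringsAsFactors = FALSE),
       truth = data.frame(snp_id = mm$snp_id[qtn], chrom = mm$chrom[qtn],
                          pos = mm$pos[qtn], effect = eff,
                          stringsAsFactors = FALSE),
       realizedH2 = realized)
}
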