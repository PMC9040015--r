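# gwaskit

An R package for genome-wide association studies (GWAS) on cohorts that
are too large to hold comfortably in memory. It is built for
quantitative-genetics practitioners who need the standard pipeline —
genotype conversion, population-structure control, variance-component
estimation, single-marker scans, publication figures — in one place,
with every statistical step validated against independent oracles.

## What it does

* **File-backed genotype store.** VCF, PLINK binary (bed/bim/fam),
  HapMap text and numeric dosage matrices all convert to an on-disk
  marker-by-sample store (`convertGenotypes`) that is streamed in
  bounded blocks; forked scan workers share the immutable file instead
  of copying it.
* **Population structure.** VanRaden genomic relationship matrix

  G = ZᵀZ / (2 Σⱼ pⱼ(1−pⱼ)),

  with Z the per-marker 2p-centered dosage matrix, and principal
  components taken from the GRM eigendecomposition — computed **once**
  and reused for PCs, REML and the mixed-model scan (`eigenCount()`
  proves it).
* **Variance components.** Four estimators of h² = σg²/(σg²+σe²):
  Brent REML on heritability (default), EMMAX-style grid over
  δ = σe²/σg², a low-rank spectral route through the SVD of the marker
  matrix, and Haseman–Elston regression of pairwise phenotype products
  on relatedness.
* **Association scans.** GLM, MLM (generalized least squares under
  P3D: variance components fixed from the null model) and FarmCPU
  (iterated fixed/random effect models with pseudo-QTN selection by
  restricted likelihood). All three run on one blockwise
  design-matrix-inversion kernel: with covariate block w and marker x,
  M⁻¹ is assembled from the once-computed (w′w)⁻¹ and the scalar Schur
  complement x′x − x′w(w′w)⁻¹w′x, so the covariate inverse is never
  recomputed per marker.
* **Figures.** Manhattan (single, overlaid, stacked, circular), Q-Q
  with a 95% concentration band, marker density, phenotype
  distribution and 2-D/3-D PCA plots; every plot also emits its
  coordinate table, and result tables from other tools are read
  through a column-mapping config.
* **Simulator.** Balding–Nichols population structure, full-sib family
  blocks, QTN effects with exact realized heritability — the known
  truth behind every validation.

## Worked example

Simulate a structured cohort with ten causal markers, run the full
pipeline, and look at what it found:

```r
library(gwaskit)

cfg   <- simConfig(n = 1000, m = 10000, seed = 42, nQtn = 10, h2 = 0.5,
                   nSubpop = 2, fst = 0.05)
store <- simulateGenotypes(cfg)
sim   <- simulatePhenotype(store, cfg)

run <- runGWAS(store, phenotype = sim$phenotype,
               models = c("glm", "mlm", "farmcpu"),
               npc = 5, outDir = "example_out", seed = 42)

run$varcomp
#> VarianceComponents [brent]
#>   sigmaG2 = 0.8029  sigmaE2 = 1.34209  h2 = 0.374315
#>   restricted logLik = -1780.5229

genomicInflation(run$results$glm)
#> [1] 1.006485
genomicInflation(run$results$mlm)
#> [1] 0.9610808

tab <- assocTable(run$results$mlm)
head(tab[order(tab$pvalue), ], 3)
#>             snp_id chrom    pos     effect         se       pvalue    n
#> 1317 snp_10_321771    10 321771 -1.2011894 0.08137536 9.946135e-45 1000
#> 5070   snp_5_75936     5  75936  0.8408169 0.06830621 1.650375e-32 1000
#> 6861  snp_6_867097     6 867097 -0.5902289 0.07396421 4.020587e-15 1000
```

The genomic inflation factor λ_GC is ~1 for both scans — calibrated
despite the two subpopulations — and the three strongest hits are all
simulated causal loci (`sim$truth` lists them). The REML h² (0.37) sits
below the simulated 0.50, as expected when only ten causal markers
drive the trait and the whole-genome GRM tags them weakly; with a
polygenic background (many QTNs, or family relatedness) the estimate
centers on the target, which is what the test suite asserts. `example_out/` now contains the result
tables (`assoc/trait1.<model>.assoc.txt`), the plots with their
coordinate tables, the GRM, PCs, the run log and `manifest.json` —
which records `eigen_decompositions: 1`: PCs, REML and the MLM all
consumed the same single eigendecomposition.

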