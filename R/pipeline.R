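# One-command orchestration of the standard pipeline:
# convert -> GRM -> eigendecomposition (once) -> PCs -> variance
# components -> association scans -> report.  The single GRMEigen object
# is threaded through PCs, REML and the MLM scan; eigenCount() lets a
# caller assert the decomposition really was computed once.

#' Read a flat key=value run configuration file
#'
#' Lines of the form \code{key = value}; blank lines and \code{#} comments
#' ignored.  List-valued keys (e.g. \code{models}) are comma-separated.
#'
#' @param path config file.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- lapply(kv, function(x) trimws(paste(x[-1L], collapse = "=")))
  names(cfg) <- vapply(kv, function(x) trimws(x[1L]), "")
  cfg
}

.stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  msg <- sprintf("[%s] stage %s: start", format(Sys.time()), name)
  cat(msg, "\n", file = log, append = TRUE)
  message(msg)
  out <- tryCatch(force(expr), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  el <- proc.time()[["elapsed"]] - t0
  msg <- sprintf("[%s] stage %s: done (%.2f s)", format(Sys.time()),
                 name, el)
  cat(msg, "\n", file = log, append = TRUE)
  message(msg)
  attr(out, "elapsed") <- el
  out
}

#' Run the full GWAS pipeline
#'
#' @param genotype a \code{GenotypeStore}, or an input path to convert.
#' @param format genotype format when \code{genotype} is a path (see
#'   \code{\link{convertGenotypes}}).
#' @param phenotype phenotype data.frame or file path.
#' @param covariates optional covariate table (sample ID first column) or
#'   path.
#' @param trait trait to analyze (default first trait column).
#' @param models subset of \code{c("glm", "mlm", "farmcpu")}.
#' @param npc number of principal components used as covariates (0 for
#'   none; default 5).
#' @param vcMethod variance-component estimator for the MLM
#'   (\code{"brent"}, \code{"emmax"}, \code{"fastlmm"}, \code{"he"}).
#' @param outDir output directory; results land under
#'   \code{store/ grm/ pca/ varcomp/ assoc/ plots/} plus
#'   \code{manifest.json} and \code{run.log}.
#' @param seed RNG seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @param workers forked workers for the scans.
#' @param plots produce Manhattan/Q-Q/density/phenotype/PCA plots.
#' @param mapFile marker map side file for numeric genotype input.
#' @return invisibly, a list with the per-model \code{AssocResults}, the
#'   \code{GRM}, \code{GRMEigen}, PCs, \code{VarianceComponents} and the
#'   manifest.  A plotting failure is logged but does not invalidate the
#'   written result tables.
#' @export
runGWAS <- function(genotype, format = NULL, phenotype, covariates = NULL,
                    trait = 1L, models = c("glm", "mlm"), npc = 5L,
                    vcMethod = c("brent", "emmax", "fastlmm", "he"),
                    outDir, seed = 1L, workers = 1L, plots = TRUE,
                    mapFile = NULL) {
  vcMethod <- match.arg(vcMethod)
  stopifnot(all(models %in% c("glm", "mlm", "farmcpu")), npc >= 0)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("assoc", "plots", "grm", "pca", "varcomp"))
    dir.create(file.path(outDir, d), showWarnings = FALSE)
  log <- file.path(outDir, "run.log")
  cat(sprintf("[%s] gwaskit run start (seed %d)\n", format(Sys.time()),
              seed), file = log)
  set.seed(seed)
  resetEigenCount()
  times <- list()

  store <- .stage("convert", log, {
    if (is(genotype, "GenotypeStore")) genotype
    else convertGenotypes(genotype, format, file.path(outDir, "store"),
                          mapFile = mapFile, overwrite = TRUE)
  })
  times$convert <- attr(store, "elapsed")
  if (is.character(phenotype)) phenotype <- readPhenotype(phenotype)
  if (is.character(covariates)) covariates <- readPhenotype(covariates)
  al <- alignSamples(store, phenotype, covariates, trait)
  cat(sprintf("  %d samples aligned, %d dropped; %d markers\n",
              length(al$sampleIndex), al$nDropped, nMarkers(store)),
      file = log, append = TRUE)

  need_grm <- npc > 0L || any(c("mlm") %in% models)
  grm <- eig <- pcs <- vc <- NULL
  if (need_grm) {
    grm <- .stage("grm", log,
                  computeGRM(store, sampleIndex = al$sampleIndex))
    times$grm <- attr(grm, "elapsed")
    writeGRM(grm, file.path(outDir, "grm", "grm.txt"))
    eig <- .stage("eigen", log, eigenGRM(grm))
    times$eigen <- attr(eig, "elapsed")
  }
  covmat <- al$covariates
  if (npc > 0L) {
    pcs <- .stage("pca", log, computePCs(eig, npc))
    times$pca <- attr(pcs, "elapsed")
    utils::write.table(data.frame(sample = rownames(pcs), pcs),
                       file.path(outDir, "pca", "pcs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    covmat <- cbind(covmat, pcs)
  }
  if ("mlm" %in% models) {
    vc <- .stage("varcomp", log, switch(vcMethod,
      brent = remlBrent(al$y, covmat, eig),
      emmax = remlEmmax(al$y, covmat, eig),
      fastlmm = remlFastlmm(al$y, covmat, store,
                            sampleIndex = al$sampleIndex),
      he = heRegression(al$y, grm, covmat)))
    times$varcomp <- attr(vc, "elapsed")
    writeLines(c(sprintf("method\t%s", vc@method),
                 sprintf("sigmaG2\t%.10g", vc@sigmaG2),
                 sprintf("sigmaE2\t%.10g", vc@sigmaE2),
                 sprintf("h2\t%.10g", vc@h2),
                 sprintf("logLik\t%.10g", vc@logLik)),
               file.path(outDir, "varcomp", "varcomp.txt"))
  }

  results <- list()
  for (mod in models) {
    results[[mod]] <- .stage(paste0("assoc_", mod), log, switch(mod,
      glm = glmScan(al$y, store, covmat, al$sampleIndex, al$trait,
                    workers = workers),
      mlm = mlmScan(al$y, store, covmat, eig, vc, al$sampleIndex,
                    al$trait, workers = workers),
      farmcpu = farmcpuScan(al$y, store, covmat, al$sampleIndex,
                            al$trait, workers = workers)))
    times[[paste0("assoc_", mod)]] <- attr(results[[mod]], "elapsed")
    writeAssocResults(results[[mod]], file.path(outDir, "assoc"))
  }

  if (plots) {
    ok <- tryCatch({
      pd <- file.path(outDir, "plots")
      for (mod in models) {
        manhattanPlot(results[[mod]],
          plotSpec(file.path(pd, paste0(mod, ".manhattan.png"))))
        qqPlot(results[[mod]],
          plotSpec(file.path(pd, paste0(mod, ".qq.png"))))
      }
      markerDensityPlot(store, spec =
        plotSpec(file.path(pd, "density.png")))
      phenoDistPlot(al$phenotype[c(1, match(al$trait,
                                            names(al$phenotype)))],
        plotSpec(file.path(pd, "phenotype.png")))
      if (!is.null(pcs))
        pcaPlot(pcs, spec = plotSpec(file.path(pd, "pca.png")))
      TRUE
    }, error = function(e) {
      cat("plotting failed: ", conditionMessage(e), "\n",
          file = log, append = TRUE)
      FALSE
    })
    times$plots_ok <- ok
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gwaskit")),
    r_version = R.version.string,
    seed = seed, trait = al$trait, models = models, npc = npc,
    vc_method = vcMethod,
    n_samples = length(al$sampleIndex), n_markers = nMarkers(store),
    n_dropped = al$nDropped,
    eigen_decompositions = eigenCount(),
    stage_seconds = times)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)
  cat(sprintf("[%s] gwaskit run done\n", format(Sys.time())),
      file = log, append = TRUE)
  invisible(list(results = results, grm = grm, eigen = eig, pcs = pcs,
                 varcomp = vc, manifest = manifest, align = al))
}
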