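# Publication plots: Manhattan (single / overlaid / stacked / circular),
# Q-Q, marker density, phenotype distribution and PCA.  Every plot
# function writes its image, writes a companion coordinate table
# ("<image>.coords.tsv") and returns that table invisibly: the coordinate
# table, not the pixels, is the testable surface.

#' Plot specification
#'
#' Collects the rendering options shared by the plot functions.
#'
#' @param output image file path; the extension selects the device unless
#'   \code{format} is given.
#' @param format "png", "pdf" or "svg".
#' @param dpi raster resolution.
#' @param colors color cycle over chromosomes/groups.
#' @param thresholds significance p-value cut-offs for threshold lines; all
#'   must lie in (0,1).  Default (NULL) draws the Bonferroni line 0.05/m.
#' @param highlight SNP IDs to highlight.
#' @param highlightLabels labels for the highlighted SNPs (defaults to the
#'   IDs).  Unresolvable IDs warn, never error.
#' @param layout "rectangular-single", "rectangular-overlaid",
#'   "rectangular-stacked" or "circular".
#' @param style pass-through list of par()-style settings.
#' @return a classed list.
#' @export
plotSpec <- function(output, format = NULL, dpi = 150,
                     colors = c("#4197d8", "#f8c120", "#413496",
                                "#d60b6f", "#999999"),
                     thresholds = NULL, highlight = NULL,
                     highlightLabels = NULL,
                     layout = c("rectangular-single",
                                "rectangular-overlaid",
                                "rectangular-stacked", "circular"),
                     style = list()) {
  layout <- match.arg(layout)
  if (!is.null(thresholds) &&
      (any(thresholds <= 0) || any(thresholds >= 1)))
    stop("thresholds must lie in (0,1)")
  if (is.null(format))
    format <- tolower(tools::file_ext(output))
  if (!format %in% c("png", "pdf", "svg"))
    stop("format must be png, pdf or svg")
  structure(list(output = output, format = format, dpi = dpi,
                 colors = colors, thresholds = thresholds,
                 highlight = highlight,
                 highlightLabels = highlightLabels, layout = layout,
                 style = style),
            class = "PlotSpec")
}

.open_device <- function(spec, width = 9, height = 5) {
  dir.create(dirname(spec$output), recursive = TRUE, showWarnings = FALSE)
  switch(spec$format,
    png = grDevices::png(spec$output, width = width, height = height,
                         units = "in", res = spec$dpi),
    pdf = grDevices::pdf(spec$output, width = width, height = height),
    svg = grDevices::svg(spec$output, width = width, height = height))
}

.write_coords <- function(spec, coords) {
  utils::write.table(coords, paste0(spec$output, ".coords.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(coords)
}

#' Read an association result table, possibly from another tool
#'
#' Understands this package's header (SNP, CHROM, POS, PVALUE, ...) out of
#' the box; foreign column dialects (e.g. PLINK's CHR/BP/P) are mapped via
#' \code{columnMap}.
#'
#' @param path result table path (delimited text).
#' @param columnMap named character vector mapping foreign names to the
#'   standard ones, e.g. \code{c(CHR = "CHROM", BP = "POS", P = "PVALUE")}.
#' @return data.frame with at least SNP, CHROM, POS, PVALUE.
#' @export
readAssocTable <- function(path, columnMap = NULL) {
  tab <- data.table::fread(path, data.table = FALSE)
  if (!is.null(columnMap)) {
    hit <- names(tab) %in% names(columnMap)
    names(tab)[hit] <- columnMap[names(tab)[hit]]
  }
  if (!all(c("CHROM", "POS", "PVALUE") %in% names(tab)))
    stop("result table needs CHROM, POS, PVALUE columns ",
         "(use columnMap for foreign headers)")
  if (is.null(tab$SNP)) tab$SNP <- paste0(tab$CHROM, "_", tab$POS)
  tab$CHROM <- as.character(tab$CHROM)
  tab
}

.as_result_tables <- function(results) {
  if (is(results, "AssocResults")) results <- list(results)
  if (is.data.frame(results)) results <- list(results)
  lapply(seq_along(results), function(i) {
    r <- results[[i]]
    nm <- if (!is.null(names(results)) && nzchar(names(results)[i]))
            names(results)[i]
          else if (is(r, "AssocResults")) paste0(r@trait, ".", r@model)
          else paste0("group", i)
    tab <- if (is(r, "AssocResults")) {
      d <- assocTable(r)
      data.frame(SNP = d$snp_id, CHROM = as.character(d$chrom),
                 POS = d$pos, PVALUE = d$pvalue, stringsAsFactors = FALSE)
    } else {
      data.frame(SNP = r$SNP, CHROM = as.character(r$CHROM), POS = r$POS,
                 PVALUE = r$PVALUE, stringsAsFactors = FALSE)
    }
    tab$group <- nm
    tab
  })
}

# cumulative genome coordinates; gap between chromosomes is 1% of the
# genome length
.genome_coords <- function(chrom, pos) {
  chroms <- unique(chrom)
  len <- vapply(chroms, function(cc) max(pos[chrom == cc]), numeric(1))
  gap <- 0.01 * sum(len)
  offset <- cumsum(c(0, head(len + gap, -1)))
  names(offset) <- chroms
  list(cum = offset[chrom] + pos, offset = offset, len = len, gap = gap,
       chroms = chroms)
}

#' Manhattan plot
#'
#' -log10(p) against cumulative genomic position, chromosomes in
#' alternating colors, one or more result groups in rectangular
#' (single / overlaid / stacked) or circular layout, with threshold lines
#' and optional SNP highlighting (labels displaced greedily to avoid
#' overlap) and a marker-density strip.
#'
#' @param results an \code{AssocResults}, a data.frame with
#'   SNP/CHROM/POS/PVALUE, or a (possibly named) list of either for
#'   multi-group layouts.
#' @param spec a \code{\link{plotSpec}}.
#' @param densityStrip add a marker-density strip under the axis
#'   (rectangular layouts).
#' @param windowBp window for the density strip.
#' @return invisibly, the plotted coordinate table (SNP, CHROM, POS,
#'   group, cumulative coordinate \code{x}, \code{y} = -log10 p).
#' @export
manhattanPlot <- function(results, spec, densityStrip = FALSE,
                          windowBp = 1e6) {
  tabs <- .as_result_tables(results)
  all <- do.call(rbind, tabs)
  all <- all[!is.na(all$PVALUE), , drop = FALSE]
  if (!nrow(all)) stop("no non-missing p-values to plot")
  gc <- .genome_coords(all$CHROM, all$POS)
  all$x <- gc$cum
  all$y <- -log10(pmax(all$PVALUE, .Machine$double.xmin))
  thr <- spec$thresholds
  if (is.null(thr)) thr <- 0.05 / nrow(tabs[[1L]])
  groups <- unique(all$group)
  chr_i <- match(all$CHROM, gc$chroms)
  ymax <- max(c(all$y, -log10(thr))) * 1.05

  .open_device(spec, width = 9,
               height = if (spec$layout == "rectangular-stacked")
                          2.5 * length(groups)
                        else if (spec$layout == "circular") 8 else 5)
  on.exit(grDevices::dev.off())
  if (spec$layout == "circular") {
    .manhattan_circular(all, gc, groups, spec, thr)
  } else {
    panels <- if (spec$layout == "rectangular-stacked") groups else "all"
    graphics::par(mfrow = c(length(panels), 1), mar = c(3, 4, 1, 1))
    for (pn in panels) {
      sub <- if (identical(pn, "all")) all else all[all$group == pn, ]
      ci <- match(sub$CHROM, gc$chroms)
      col <- if (spec$layout == "rectangular-overlaid" &&
                 length(groups) > 1L)
               spec$colors[(match(sub$group, groups) - 1L) %%
                           length(spec$colors) + 1L]
             else spec$colors[(ci - 1L) %% 2L + 1L]
      graphics::plot(sub$x, sub$y, pch = 20, cex = 0.5, col = col,
                     xlab = "", ylab = expression(-log[10](italic(p))),
                     xaxt = "n", ylim = c(0, ymax), main = if (!identical(pn, "all")) pn else "")
      graphics::axis(1, at = gc$offset + gc$len / 2, labels = gc$chroms)
      graphics::abline(h = -log10(thr), lty = 2, col = "grey40")
      if (spec$layout == "rectangular-overlaid" && length(groups) > 1L)
        graphics::legend("topright", legend = groups, col =
          spec$colors[seq_along(groups)], pch = 20, bty = "n")
      .highlight_points(sub, spec)
      if (densityStrip) .density_strip(sub, gc, windowBp)
    }
  }
  .write_coords(spec, all[, c("SNP", "CHROM", "POS", "group", "x", "y")])
}

.highlight_points <- function(sub, spec) {
  if (is.null(spec$highlight)) return(invisible(NULL))
  hit <- match(spec$highlight, sub$SNP)
  if (anyNA(hit))
    warning("highlight SNPs not found: ",
            paste(spec$highlight[is.na(hit)], collapse = ", "))
  hit_ok <- which(!is.na(hit))
  if (!length(hit_ok)) return(invisible(NULL))
  idx <- hit[hit_ok]
  labs <- if (is.null(spec$highlightLabels)) spec$highlight
          else spec$highlightLabels
  graphics::points(sub$x[idx], sub$y[idx], pch = 19, col = "red",
                   cex = 0.9)
  # greedy vertical displacement so labels never overlap
  oy <- sub$y[idx]
  ord <- order(sub$x[idx])
  step <- graphics::strheight("M") * 1.2
  lab_y <- oy + step
  if (length(ord) > 1L)
    for (i in 2:length(ord)) {
      a <- ord[i - 1L]; b <- ord[i]
      if (abs(sub$x[idx][b] - sub$x[idx][a]) <
          graphics::strwidth(labs[hit_ok][a]) &&
          abs(lab_y[b] - lab_y[a]) < step)
        lab_y[b] <- lab_y[a] + step
    }
  graphics::text(sub$x[idx], lab_y, labs[hit_ok], cex = 0.7, col = "red")
}

.density_strip <- function(sub, gc, windowBp) {
  usr <- graphics::par("usr")
  y0 <- usr[3]; h <- (usr[4] - usr[3]) * 0.03
  for (cc in gc$chroms) {
    p <- sub$POS[sub$CHROM == cc]
    if (!length(p)) next
    br <- seq(0, max(p) + windowBp, by = windowBp)
    cnt <- graphics::hist(p, breaks = br, plot = FALSE)$counts
    cols <- grDevices::colorRampPalette(c("darkgreen", "yellow",
                                          "red"))(max(cnt) + 1L)
    graphics::rect(gc$offset[cc] + head(br, -1), y0,
                   gc$offset[cc] + br[-1], y0 + h,
                   col = cols[cnt + 1L], border = NA)
  }
}

.manhattan_circular <- function(all, gc, groups, spec, thr) {
  graphics::par(mar = c(1, 1, 1, 1))
  graphics::plot(0, 0, type = "n", xlim = c(-1.1, 1.1),
                 ylim = c(-1.1, 1.1), asp = 1, axes = FALSE,
                 xlab = "", ylab = "")
  total <- max(all$x)
  theta <- 2 * pi * all$x / total
  ng <- length(groups)
  # one concentric track per group; each track's -log10(p) normalized to
  # its own radial band
  r0 <- 0.35; width <- (1 - r0) / ng * 0.9
  for (gi in seq_len(ng)) {
    sel <- all$group == groups[gi]
    base <- r0 + (gi - 1L) * (1 - r0) / ng
    yv <- all$y[sel]
    rr <- base + width * yv / max(yv, 1e-12)
    ci <- match(all$CHROM[sel], gc$chroms)
    graphics::points(rr * cos(theta[sel]), rr * sin(theta[sel]),
                     pch = 20, cex = 0.4,
                     col = spec$colors[(ci - 1L) %% 2L + 1L])
    tr <- base + width * (-log10(thr[1L])) / max(yv, 1e-12)
    ang <- seq(0, 2 * pi, length.out = 200)
    graphics::lines(tr * cos(ang), tr * sin(ang), lty = 2,
                    col = "grey40")
  }
  graphics::text(0, 0, "chr", cex = 0.8)
}

#' Quantile-quantile plot
#'
#' Observed versus expected -log10(p) with expected quantiles
#' \eqn{-\log_{10}((i-0.5)/N)} for ranked p-values, a 95\% concentration
#' band from the beta distribution of uniform order statistics, and one
#' overlaid series per result group.
#'
#' @inheritParams manhattanPlot
#' @return invisibly, the plotted coordinates (group, rank, expected,
#'   observed, band bounds).
#' @export
qqPlot <- function(results, spec) {
  tabs <- .as_result_tables(results)
  coords <- do.call(rbind, lapply(tabs, function(tt) {
    p <- sort(tt$PVALUE[!is.na(tt$PVALUE)])
    N <- length(p)
    if (!N) stop("no non-missing p-values to plot")
    i <- seq_len(N)
    data.frame(group = tt$group[1L], rank = i,
               expected = -log10((i - 0.5) / N),
               observed = -log10(pmax(p, .Machine$double.xmin)),
               band_lo = -log10(stats::qbeta(0.975, i, N - i + 1)),
               band_hi = -log10(stats::qbeta(0.025, i, N - i + 1)))
  }))
  groups <- unique(coords$group)
  .open_device(spec, width = 5.5, height = 5.5)
  on.exit(grDevices::dev.off())
  lim <- c(0, max(coords$expected, coords$observed) * 1.05)
  graphics::plot(NA, xlim = lim, ylim = lim,
                 xlab = expression(Expected ~ -log[10](italic(p))),
                 ylab = expression(Observed ~ -log[10](italic(p))))
  g1 <- coords[coords$group == groups[1L], ]
  graphics::polygon(c(g1$expected, rev(g1$expected)),
                    c(g1$band_lo, rev(g1$band_hi)),
                    col = "grey90", border = NA)
  graphics::abline(0, 1, col = "grey50")
  for (gi in seq_along(groups)) {
    gg <- coords[coords$group == groups[gi], ]
    graphics::points(gg$expected, gg$observed, pch = 20, cex = 0.5,
                     col = spec$colors[(gi - 1L) %% length(spec$colors) + 1L])
  }
  if (length(groups) > 1L)
    graphics::legend("topleft", legend = groups,
                     col = spec$colors[seq_along(groups)], pch = 20,
                     bty = "n")
  .write_coords(spec, coords)
}

#' Marker density plot
#'
#' Per-chromosome marker counts in fixed windows, rendered as
#' color-graded bars.
#'
#' @param map marker map data.frame (\code{chrom}, \code{pos}) or a
#'   \code{GenotypeStore}.
#' @param windowBp window size in bp (e.g. 1e6 for 1 Mb).
#' @param spec a \code{\link{plotSpec}}.
#' @param chromosomes optional chromosome set to render (allows empty
#'   tracks).
#' @return invisibly, the window-count table (chrom, window_start,
#'   window_end, count).
#' @export
markerDensityPlot <- function(map, windowBp = 1e6, spec,
                              chromosomes = NULL) {
  if (is(map, "GenotypeStore")) map <- markerMap(map)
  chroms <- if (is.null(chromosomes)) unique(as.character(map$chrom))
            else as.character(chromosomes)
  counts <- do.call(rbind, lapply(chroms, function(cc) {
    p <- map$pos[map$chrom == cc]
    hi <- if (length(p)) max(p) else windowBp
    br <- seq(0, hi + windowBp, by = windowBp)
    cnt <- if (length(p)) graphics::hist(p, breaks = br,
                                         plot = FALSE)$counts
           else integer(length(br) - 1L)
    data.frame(chrom = cc, window_start = head(br, -1) + 1,
               window_end = br[-1], count = cnt,
               stringsAsFactors = FALSE)
  }))
  .open_device(spec, width = 8,
               height = max(2.5, 0.5 + 0.4 * length(chroms)))
  on.exit(grDevices::dev.off())
  maxc <- max(counts$count, 1L)
  pal <- grDevices::colorRampPalette(c("darkgreen", "yellow",
                                       "red"))(maxc + 1L)
  graphics::par(mar = c(4, 4, 1, 2))
  graphics::plot(NA, xlim = c(0, max(counts$window_end)),
                 ylim = c(0, length(chroms)), axes = FALSE,
                 xlab = "Position (bp)", ylab = "")
  for (i in seq_along(chroms)) {
    sub <- counts[counts$chrom == chroms[i], ]
    graphics::rect(sub$window_start - 1, length(chroms) - i + 0.2,
                   sub$window_end, length(chroms) - i + 0.8,
                   col = pal[sub$count + 1L], border = NA)
  }
  graphics::axis(1)
  graphics::axis(2, at = length(chroms) - seq_along(chroms) + 0.5,
                 labels = chroms, las = 2, tick = FALSE)
  .write_coords(spec, counts)
}

#' Phenotype distribution plot
#'
#' Histogram with overlaid density curve for each trait; constant traits
#' render as a single bin with a warning.
#'
#' @param pheno phenotype data.frame (first column sample ID).
#' @param spec a \code{\link{plotSpec}}.
#' @return invisibly, the histogram coordinate table (trait, mid, count,
#'   density) with per-trait sample skewness in
#'   \code{attr(, "skewness")}.
#' @export
phenoDistPlot <- function(pheno, spec) {
  traits <- names(pheno)[-1L]
  .open_device(spec, width = 5 * length(traits), height = 4.5)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, length(traits)))
  skew <- stats::setNames(numeric(length(traits)), traits)
  coords <- do.call(rbind, lapply(traits, function(tr) {
    v <- pheno[[tr]]
    v <- v[!is.na(v)]
    if (stats::sd(v) == 0) {
      warning("trait '", tr, "' is constant; single-bin histogram")
      h <- list(mids = v[1L], counts = length(v), density = 1)
      graphics::plot(v[1L], length(v), type = "h", lwd = 10,
                     main = tr, xlab = tr, ylab = "count")
    } else {
      h <- graphics::hist(v, breaks = "FD", main = tr, xlab = tr,
                          col = spec$colors[1L], border = "white",
                          freq = FALSE)
      graphics::lines(stats::density(v), col = spec$colors[4L], lwd = 2)
      skew[tr] <<- mean((v - mean(v))^3) / stats::sd(v)^3
    }
    data.frame(trait = tr, mid = h$mids, count = h$counts,
               density = h$density)
  }))
  attr(coords, "skewness") <- skew
  .write_coords(spec, coords)
  invisible(coords)
}

#' PCA scatter plot
#'
#' PC1 vs PC2 in two dimensions, or PC1-PC3 as an orthographic 3-D
#' projection, optionally colored by group labels.
#'
#' @param pcs n x k PC score matrix (k >= dims).
#' @param labels optional group labels (length n).
#' @param spec a \code{\link{plotSpec}}.
#' @param dims 2 or 3.
#' @return invisibly, the plotted coordinates.
#' @export
pcaPlot <- function(pcs, labels = NULL, spec, dims = 2L) {
  pcs <- as.matrix(pcs)
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3")
  if (ncol(pcs) < dims)
    stop("PC matrix has ", ncol(pcs), " columns; dims = ", dims,
         " needs at least that many")
  grp <- if (is.null(labels)) factor(rep("all", nrow(pcs)))
         else factor(labels)
  cols <- spec$colors[(as.integer(grp) - 1L) %% length(spec$colors) + 1L]
  .open_device(spec, width = 5.5, height = 5.5)
  on.exit(grDevices::dev.off())
  if (dims == 2L) {
    graphics::plot(pcs[, 1L], pcs[, 2L], col = cols, pch = 19,
                   cex = 0.7, xlab = "PC1", ylab = "PC2")
    coords <- data.frame(sample = rownames(pcs), PC1 = pcs[, 1L],
                         PC2 = pcs[, 2L], group = as.character(grp))
  } else {
    pm <- graphics::persp(x = range(pcs[, 1L]), y = range(pcs[, 2L]),
                          z = matrix(range(pcs[, 3L]), 2, 2),
                          xlab = "PC1", ylab = "PC2", zlab = "PC3",
                          theta = 40, phi = 20, col = NA, border = NA)
    pr <- grDevices::trans3d(pcs[, 1L], pcs[, 2L], pcs[, 3L], pm)
    graphics::points(pr, col = cols, pch = 19, cex = 0.7)
    coords <- data.frame(sample = rownames(pcs), PC1 = pcs[, 1L],
                         PC2 = pcs[, 2L], PC3 = pcs[, 3L],
                         x = pr$x, y = pr$y, group = as.character(grp))
  }
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(grp),
                     col = spec$colors[seq_along(levels(grp))], pch = 19,
                     bty = "n")
  .write_coords(spec, coords)
}
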