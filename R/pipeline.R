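#' Run the full gene-loss mechanism analysis
#'
#' Orchestrates the pipeline: genome summaries, similarity window selection,
#' anchor chaining, block filtering by mean similarity, deletion-interval
#' scanning, the bp-versus-length regressions on both sides with the Welch
#' slope test, the density-versus-genome-diagonal comparison, and (on
#' request) the translocation audit. All auto-selected parameters are
#' recorded in the returned report and, if `outDir` is given, in the
#' written `params.json` alongside the TSV/JSON artifacts; re-running with
#' identical inputs reproduces the artifacts byte for byte.
#'
#' @param tableA,tableB [GeneTable-class] objects; omit `tableB` for a
#'   self-comparison.
#' @param pairs anchor pair data.frame (`gene_a`, `gene_b`, `similarity`).
#' @param sizesA,sizesB named chromosome-length vectors.
#' @param mode `"cross"` or `"self"`.
#' @param maxGap,minBlockSize chaining parameters (defaults 20 ranks / 5
#'   anchors).
#' @param window a [similarityWindow()], or `NULL` to auto-select the
#'   highest-similarity mode of the pair-similarity histogram.
#' @param binWidth histogram bin width for the auto window.
#' @param regression `"raw"` or `"length_means"` (see [fitLinear()]).
#' @param lCap maximum interval length entering the fits.
#' @param strict drop intervals with unpaired annotated genes on the
#'   fractionated side.
#' @param audit run the translocation audit.
#' @param outDir optional output directory for TSV/JSON artifacts.
#' @return list of class `FracReport`: summaries, window, blocks (filtered
#'   [SyntenyBlockSet-class]), intervals, profile, per-group regression
#'   fits (`unfractionated`, `fractionated`, `comparison`), density table
#'   and audits.
#' @export
runPipeline <- function(tableA, tableB = NULL, pairs, sizesA, sizesB = NULL,
                        mode = if (is.null(tableB)) "self" else "cross",
                        maxGap = 20L, minBlockSize = 5L,
                        window = NULL, binWidth = 1,
                        regression = c("raw", "length_means"), lCap = 30,
                        strict = FALSE, audit = FALSE, outDir = NULL) {
  regression <- match.arg(regression)
  mode <- match.arg(mode, c("cross", "self"))
  if (minBlockSize < 1L) .stopf("minBlockSize must be >= 1")
  self <- mode == "self"
  if (self) { tableB <- tableA; if (is.null(sizesB)) sizesB <- sizesA }
  pairs <- anchorPairs(pairs, self = self)

  sumA <- summarizeGenome(tableA, sizesA)
  sumB <- if (self) sumA else summarizeGenome(tableB, sizesB)

  autoWindow <- is.null(window)
  if (autoWindow) {
    hist <- similarityHistogram(pairs, binWidth)
    window <- selectSimilarityWindow(hist, "highest_mode")
  }

  chained <- chainAnchors(pairs, tableA, tableB, maxGap = maxGap,
                          minBlockSize = minBlockSize, self = self)
  if (nBlocks(chained) == 0L)
    .stopf(paste("no synteny blocks: chaining with max_gap=%d,",
                 "min_block_size=%d produced nothing"), maxGap, minBlockSize)
  blocks <- filterBlocksBySimilarity(chained, window)
  if (nBlocks(blocks) == 0L)
    .stopf(paste("no synteny blocks: the similarity window [%g, %g]",
                 "removed all %d chained blocks"),
           window$lower, window$upper, nBlocks(chained))

  intervals <- scanDeletionIntervals(blocks, tableA, tableB,
                                     allPairs = pairs, strict = strict)
  profile <- aggregateProfile(intervals)

  groups <- if (self) list(all = intervals) else
    list(A = intervals[intervals$fractionated_genome == "A", , drop = FALSE],
         B = intervals[intervals$fractionated_genome == "B", , drop = FALSE])
  fits <- lapply(groups, function(iv) {
    if (nrow(iv) < 3L) return(NULL)
    fu <- fitLinear(intervalPoints(iv, "unfractionated"), regression, lCap)
    ff <- fitLinear(intervalPoints(iv, "fractionated"), regression, lCap)
    list(unfractionated = fu, fractionated = ff,
         comparison = compareSlopes(fu, ff))
  })

  density <- densityComparison(intervals, sumA,
                               if (self) NULL else sumB, lCap = lCap)

  audits <- NULL
  if (audit) {
    audits <- list()
    for (side in c("A", "B")) {
      sg <- collectSingletons(intervals, tableA, tableB, side = side)
      if (length(sg))
        audits[[side]] <- findRemotePartners(
          sg, pairs, window,
          genomeId = genomeId(if (side == "A") tableA else tableB))
      if (self) break
    }
  }

  report <- structure(list(
    mode = mode, summaryA = sumA, summaryB = sumB, window = window,
    window_auto = autoWindow, blocks = blocks, n_blocks_prefilter =
      nBlocks(chained), intervals = intervals, profile = profile,
    fits = fits, density = density, audits = audits,
    params = list(max_gap = maxGap, min_block_size = minBlockSize,
                  similarity_window = c(window$lower, window$upper),
                  window_policy = if (autoWindow) "highest_mode" else "manual",
                  regression = regression, l_cap = lCap, strict = strict)),
    class = "FracReport")
  if (!is.null(outDir)) .writeReport(report, outDir)
  report
}

.writeReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeBlocksTsv(report$blocks, file.path(outDir, "blocks.tsv"))
  writeIntervalsTsv(report$intervals, file.path(outDir, "intervals.tsv"))
  data.table::fwrite(report$density, file.path(outDir, "density.tsv"),
                     sep = "\t", quote = FALSE)
  fitJson <- lapply(report$fits, function(f) {
    if (is.null(f)) return(NULL)
    list(unfractionated = unclass(f$unfractionated),
         fractionated = unclass(f$fractionated),
         comparison = unclass(f$comparison))
  })
  jsonlite::write_json(fitJson, file.path(outDir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(report$audits)) {
    jsonlite::write_json(
      lapply(report$audits, function(a) {
        a$similarity_window_used <- unclass(a$similarity_window_used)
        unclass(a)
      }),
      file.path(outDir, "audit.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(report$params, file.path(outDir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' @export
print.FracReport <- function(x, ...) {
  cat(sprintf("FracReport (%s comparison)\n", x$mode))
  cat(sprintf("  window [%g, %g]%% (%s); %d/%d blocks retained; %d intervals\n",
              x$window$lower, x$window$upper,
              if (x$window_auto) "auto" else "manual",
              nBlocks(x$blocks), x$n_blocks_prefilter, nrow(x$intervals)))
  for (g in names(x$fits)) {
    f <- x$fits[[g]]
    if (is.null(f)) next
    cat(sprintf(
      "  losses in %s: unfractionated %.0f bp/gene, fractionated %.0f bp/gene, p = %.3g\n",
      g, f$unfractionated$slope, f$fractionated$slope, f$comparison$p_value))
  }
  if (!is.null(x$audits))
    for (a in x$audits)
      cat(sprintf("  audit %s: %d%% of %d singletons paired elsewhere\n",
                  a$genome_id, a$percent_paired, a$n_singletons))
  invisible(x)
}

#' Minimum-block-size sensitivity, pipeline wrapper
#'
#' @inheritParams runPipeline
#' @param thresholds block-size thresholds to sweep, default `3:6`.
#' @return data.frame with `threshold` and `genes_in_blocks`.
#' @export
runSensitivity <- function(tableA, tableB = NULL, pairs, maxGap = 20L,
                           thresholds = c(3L, 4L, 5L, 6L),
                           mode = if (is.null(tableB)) "self" else "cross") {
  mode <- match.arg(mode, c("cross", "self"))
  self <- mode == "self"
  if (self) tableB <- tableA
  pairs <- anchorPairs(pairs, self = self)
  blockSizeSensitivity(pairs, tableA, tableB, maxGap = maxGap,
                       thresholds = thresholds, self = self)
}
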