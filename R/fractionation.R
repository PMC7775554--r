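# Deletion-interval scanning.
#
# Between two consecutive anchors of a retained block, the genes strictly
# between the bounding pairs are counted on both sides. An interval is
# emitted when one side (the unfractionated side) still carries a run of L
# annotated genes while the other (the fractionated side) carries none that
# the comparison can see, i.e. none that participate in any anchor pair.
# Annotated-but-unpaired genes on the fractionated side do not disqualify
# the interval -- a homology-based screen cannot see them -- but they are
# counted in nonanchor_genes_in_gap and `strict = TRUE` drops such
# intervals. The DNA span on each side runs from the end of the positionally
# earlier bounding gene to the start of the later one (gene-end to
# gene-start), so the unfractionated span covers the L genes plus their L+1
# intergenic stretches, and the fractionated span is whatever residue
# remains between the same two bounding pairs.

.rowOffsets <- function(table) {
  g <- geneRecords(table)
  # genes are stored grouped by chromosome in rank order, so the row number
  # is a global position index; offset maps (chrom, rank) -> row
  chroms <- unique(g$chrom)
  off <- cumsum(c(0L, head(as.integer(table(factor(g$chrom, levels = chroms))), -1L)))
  stats::setNames(off, chroms)
}

.spanBetween <- function(start1, end1, start2, end2, mode) {
  if (mode == "midpoint") {
    m1 <- (start1 + end1) / 2; m2 <- (start2 + end2) / 2
    raw <- abs(m2 - m1)
  } else {
    later1 <- start1 >= start2
    raw <- ifelse(later1, start1 - end2, start2 - end1)
  }
  list(bp = pmax(raw, 0), clamped = raw < 0)
}

#' Measure the DNA span between two bounding anchor pairs
#'
#' For each side, the span is the start coordinate of the positionally later
#' bounding gene minus the end coordinate of the earlier one (orientation of
#' the block is irrelevant because genes are ordered by coordinate first).
#' Overlapping bounding genes give a negative raw span, which is clamped to
#' zero and flagged. `mode = "midpoint"` measures midpoint-to-midpoint
#' instead.
#'
#' @param tableA,tableB [GeneTable-class] objects for the two sides.
#' @param geneA1,geneA2 bounding gene ids on side A (vectorized).
#' @param geneB1,geneB2 bounding gene ids on side B.
#' @param mode `"endstart"` (default) or `"midpoint"`.
#' @return data.frame with `bp_a`, `bp_b`, `clamped_a`, `clamped_b`.
#' @export
measureSpans <- function(tableA, tableB, geneA1, geneA2, geneB1, geneB2,
                         mode = c("endstart", "midpoint")) {
  mode <- match.arg(mode)
  ga <- geneRecords(tableA); gb <- geneRecords(tableB)
  i1 <- match(geneA1, ga$gene_id); i2 <- match(geneA2, ga$gene_id)
  j1 <- match(geneB1, gb$gene_id); j2 <- match(geneB2, gb$gene_id)
  if (anyNA(c(i1, i2))) .stopf("bounding gene not found on side A")
  if (anyNA(c(j1, j2))) .stopf("bounding gene not found on side B")
  if (any(ga$chrom[i1] != ga$chrom[i2]))
    .stopf("side-A bounding genes on different chromosomes")
  if (any(gb$chrom[j1] != gb$chrom[j2]))
    .stopf("side-B bounding genes on different chromosomes")
  sa <- .spanBetween(ga$start[i1], ga$end[i1], ga$start[i2], ga$end[i2], mode)
  sb <- .spanBetween(gb$start[j1], gb$end[j1], gb$start[j2], gb$end[j2], mode)
  data.frame(bp_a = sa$bp, bp_b = sb$bp,
             clamped_a = sa$clamped, clamped_b = sb$clamped)
}

#' Scan retained synteny blocks for deletion intervals
#'
#' @param blockSet a (similarity-filtered) [SyntenyBlockSet-class].
#' @param tableA,tableB [GeneTable-class] objects; `tableB` defaults to
#'   `tableA` for self-comparisons.
#' @param allPairs the full anchor-pair table of the comparison, used to
#'   decide which annotated genes the homology search can "see". Defaults to
#'   the anchors of `blockSet` itself; pass the raw pair list for the
#'   faithful screen.
#' @param strict drop intervals whose fractionated side contains annotated
#'   (but unpaired) genes.
#' @param spanMode span convention, see [measureSpans()].
#' @return data.frame of deletion intervals: `block_id`, chromosomes,
#'   bounding gene ids and ranks per side, `length` (number of contiguous
#'   single-copy genes on the unfractionated side), `bp_unfractionated`,
#'   `bp_fractionated`, `fractionated_genome` (`"A"` or `"B"`),
#'   `nonanchor_genes_in_gap` and a `clamped` flag.
#' @export
scanDeletionIntervals <- function(blockSet, tableA, tableB = tableA,
                                  allPairs = NULL, strict = FALSE,
                                  spanMode = c("endstart", "midpoint")) {
  spanMode <- match.arg(spanMode)
  a <- blockAnchors(blockSet)
  b <- syntenyBlocks(blockSet)
  emptyOut <- data.frame(
    block_id = integer(), chrom_a = character(), chrom_b = character(),
    left_gene_a = character(), right_gene_a = character(),
    left_gene_b = character(), right_gene_b = character(),
    rank_left_a = integer(), rank_right_a = integer(),
    rank_lo_b = integer(), rank_hi_b = integer(), length = integer(),
    bp_unfractionated = numeric(), bp_fractionated = numeric(),
    fractionated_genome = character(), nonanchor_genes_in_gap = integer(),
    clamped = logical(), stringsAsFactors = FALSE)
  if (nrow(a) < 2L) return(emptyOut)
  selfCmp <- isTRUE(blockSet@params$self)
  ga <- geneRecords(tableA); gb <- geneRecords(tableB)

  if (is.null(allPairs)) {
    visIdsA <- unique(a$gene_a); visIdsB <- unique(a$gene_b)
  } else {
    visIdsA <- unique(allPairs$gene_a); visIdsB <- unique(allPairs$gene_b)
  }
  if (selfCmp) visIdsA <- visIdsB <- unique(c(visIdsA, visIdsB))
  visA <- ga$gene_id %in% visIdsA
  visB <- gb$gene_id %in% visIdsB
  CA <- c(0L, cumsum(visA)); CB <- c(0L, cumsum(visB))
  offA <- .rowOffsets(tableA); offB <- .rowOffsets(tableB)

  i <- seq_len(nrow(a) - 1L)
  same <- a$block_id[i] == a$block_id[i + 1L]
  l <- i[same]; r <- i[same] + 1L
  if (length(l) == 0L) return(emptyOut)

  ra1 <- a$rank_a[l]; ra2 <- a$rank_a[r]
  rb1 <- a$rank_b[l]; rb2 <- a$rank_b[r]
  if (any(ra2 <= ra1))
    .stopf("block %d: anchors out of order on side A",
           a$block_id[l][which(ra2 <= ra1)[1L]])
  chromA <- a$chrom_a[l]; chromB <- a$chrom_b[l]
  decl <- match(a$block_id[l], b$block_id)
  if (any(chromA != b$chrom_a[decl] | chromB != b$chrom_b[decl]))
    .stopf("anchor chromosome differs from the block's declared chromosomes")

  gA <- ra2 - ra1 - 1L
  gB <- abs(rb2 - rb1) - 1L
  rowA1 <- offA[chromA] + ra1 + 1L; rowA2 <- offA[chromA] + ra2 + 1L
  rbLo <- pmin(rb1, rb2); rbHi <- pmax(rb1, rb2)
  rowB1 <- offB[chromB] + rbLo + 1L; rowB2 <- offB[chromB] + rbHi + 1L
  vA <- CA[rowA2] - CA[rowA1 + 1L]
  vB <- CB[rowB2] - CB[rowB1 + 1L]

  fracB <- (gA >= 1L & gB == 0L) | (gA >= 1L & gB >= 1L & vB == 0L & vA >= 1L)
  fracA <- (gB >= 1L & gA == 0L) | (gA >= 1L & gB >= 1L & vA == 0L & vB >= 1L)
  keep <- xor(fracA, fracB)
  if (!any(keep)) return(emptyOut)

  k <- which(keep)
  spans <- measureSpans(tableA, tableB, a$gene_a[l[k]], a$gene_a[r[k]],
                        a$gene_b[l[k]], a$gene_b[r[k]], mode = spanMode)
  fracIsA <- fracA[k]
  out <- data.frame(
    block_id = a$block_id[l[k]], chrom_a = chromA[k], chrom_b = chromB[k],
    left_gene_a = a$gene_a[l[k]], right_gene_a = a$gene_a[r[k]],
    left_gene_b = a$gene_b[l[k]], right_gene_b = a$gene_b[r[k]],
    rank_left_a = ra1[k], rank_right_a = ra2[k],
    rank_lo_b = rbLo[k], rank_hi_b = rbHi[k],
    length = ifelse(fracIsA, gB[k], gA[k]),
    bp_unfractionated = ifelse(fracIsA, spans$bp_b, spans$bp_a),
    bp_fractionated = ifelse(fracIsA, spans$bp_a, spans$bp_b),
    fractionated_genome = ifelse(fracIsA, "A", "B"),
    nonanchor_genes_in_gap = as.integer(          # annotated minus visible,
      ifelse(fracIsA, gA[k] - vA[k], gB[k] - vB[k])),  # fractionated side
    clamped = spans$clamped_a | spans$clamped_b,
    stringsAsFactors = FALSE, row.names = NULL)
  out$length <- as.integer(out$length)
  if (strict) out <- out[out$nonanchor_genes_in_gap == 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate deletion intervals into a per-length profile
#'
#' Groups intervals by exact length L and reports the arithmetic mean DNA
#' span on each side, the plotted quantity of the bp-versus-L analysis. The
#' raw interval list is preserved for point-level regression.
#'
#' @param intervals data.frame from [scanDeletionIntervals()].
#' @return An `IntervalProfile`: list with `per_length` (columns `length`,
#'   `mean_bp_unfractionated`, `mean_bp_fractionated`, `n`) and `intervals`.
#' @export
aggregateProfile <- function(intervals) {
  if (nrow(intervals) == 0L) {
    per <- data.frame(length = integer(), mean_bp_unfractionated = numeric(),
                      mean_bp_fractionated = numeric(), n = integer())
  } else {
    sp <- split(seq_len(nrow(intervals)), intervals$length)
    per <- data.frame(
      length = as.integer(names(sp)),
      mean_bp_unfractionated = vapply(sp, function(i)
        mean(intervals$bp_unfractionated[i]), numeric(1L)),
      mean_bp_fractionated = vapply(sp, function(i)
        mean(intervals$bp_fractionated[i]), numeric(1L)),
      n = lengths(sp), row.names = NULL)
    per <- per[order(per$length), , drop = FALSE]
  }
  structure(list(per_length = per, intervals = intervals),
            class = "IntervalProfile")
}

#' @export
print.IntervalProfile <- function(x, ...) {
  cat(sprintf("IntervalProfile: %d interval(s), lengths %s\n",
              nrow(x$intervals),
              if (nrow(x$per_length)) paste0(min(x$per_length$length), "-",
                                             max(x$per_length$length)) else "-"))
  print(head(x$per_length, 10L), row.names = FALSE)
  invisible(x)
}

#' Pseudogene capacity of deletion intervals
#'
#' The residual DNA on the fractionated side, expressed per mean gene
#' length, bounds from above the number of full-length pseudogenes the gap
#' could hide; `bp_per_missing_gene` is the same residue per missing gene.
#' Under pure excision both stay near zero regardless of interval length;
#' under pseudogenization the capacity approaches L.
#'
#' @param intervals data.frame from [scanDeletionIntervals()].
#' @param meanGeneBp mean gene length in bp (> 0).
#' @return the intervals with `capacity` and `bp_per_missing_gene` added.
#' @export
pseudogeneCapacity <- function(intervals, meanGeneBp) {
  .checkScalarNum(meanGeneBp, "meanGeneBp")
  if (meanGeneBp <= 0) .stopf("meanGeneBp must be > 0")
  intervals$capacity <- intervals$bp_fractionated / meanGeneBp
  intervals$bp_per_missing_gene <- intervals$bp_fractionated / intervals$length
  intervals
}

#' Write deletion intervals as TSV
#' @param intervals data.frame from [scanDeletionIntervals()].
#' @param path output path.
#' @export
writeIntervalsTsv <- function(intervals, path) {
  cols <- c("block_id", "chrom_a", "chrom_b", "length", "bp_unfractionated",
            "bp_fractionated", "fractionated_genome", "nonanchor_genes_in_gap",
            "clamped")
  data.table::fwrite(intervals[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}
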