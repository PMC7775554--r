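# Translocation audit: did the "missing" genes move elsewhere instead of
# being excised? Block singletons (the surviving copies inside deletion
# intervals) are searched for partners anywhere in the genome, using the
# full anchor list (the minimum-block-size-1 view of the homology search)
# and requiring the partner's similarity to fall in the event cohort's
# window. A high paired-elsewhere rate would point at translocation; the
# rate is an upper bound, since some hits are pre-existing paralogs.

#' Collect the singleton genes of deletion intervals
#'
#' The union over intervals of the unfractionated-side genes strictly
#' between the bounding anchors, on the requested side.
#'
#' @param intervals data.frame from [scanDeletionIntervals()].
#' @param tableA,tableB [GeneTable-class] objects; `tableB` defaults to
#'   `tableA`.
#' @param side `"A"` or `"B"`: collect singletons annotated on this side
#'   (i.e. from intervals whose fractionated side is the other genome).
#' @return character vector of gene ids.
#' @export
collectSingletons <- function(intervals, tableA, tableB = tableA,
                              side = c("A", "B")) {
  side <- match.arg(side)
  other <- if (side == "A") "B" else "A"
  iv <- intervals[intervals$fractionated_genome == other, , drop = FALSE]
  if (nrow(iv) == 0L) return(character())
  tab <- if (side == "A") tableA else tableB
  g <- geneRecords(tab)
  key <- paste(g$chrom, g$rank)
  ids <- lapply(seq_len(nrow(iv)), function(i) {
    if (side == "A") {
      ranks <- seq(iv$rank_left_a[i] + 1L, iv$rank_right_a[i] - 1L)
      chrom <- iv$chrom_a[i]
    } else {
      ranks <- seq(iv$rank_lo_b[i] + 1L, iv$rank_hi_b[i] - 1L)
      chrom <- iv$chrom_b[i]
    }
    g$gene_id[match(paste(chrom, ranks), key)]
  })
  ids <- unique(unlist(ids))
  if (anyNA(ids)) .stopf("singleton rank without an annotated gene")
  ids
}

#' Audit block singletons for remote partners
#'
#' A singleton counts as remotely paired if any anchor pair links it to any
#' gene at a similarity inside the window -- "approximately the expected
#' similarity level" of the event cohort, made concrete as the same
#' similarity window used for block filtering. Duplicated anchor rows do not
#' change the result.
#'
#' @param singletons character vector of gene ids (see
#'   [collectSingletons()]); must be non-empty.
#' @param allPairs the full anchor-pair table (built with minimum block size
#'   1, i.e. the raw pair list).
#' @param window a [similarityWindow()].
#' @param genomeId label for the audited genome.
#' @return A `TranslocationAudit`: list with `genome_id`, `n_singletons`,
#'   `n_paired_remotely`, `percent_paired` (rounded to the nearest integer)
#'   and `similarity_window_used`.
#' @examples
#' w <- similarityWindow(85, 95)
#' pairs <- data.frame(gene_a = paste0("s", 1:429),
#'                     gene_b = paste0("p", 1:429), similarity = 92)
#' a <- findRemotePartners(paste0("s", 1:8307), pairs, w)
#' a$percent_paired  # 5
#' @export
findRemotePartners <- function(singletons, allPairs, window,
                               genomeId = NA_character_) {
  stopifnot(inherits(window, "SimilarityWindow"))
  singletons <- unique(as.character(singletons))
  if (length(singletons) == 0L)
    .stopf("empty singleton set: percent paired is undefined")
  inWin <- allPairs$similarity >= window$lower &
    allPairs$similarity <= window$upper
  partnered <- unique(c(allPairs$gene_a[inWin], allPairs$gene_b[inWin]))
  nPaired <- sum(singletons %in% partnered)
  structure(list(
    genome_id = genomeId,
    n_singletons = length(singletons),
    n_paired_remotely = nPaired,
    percent_paired = round(100 * nPaired / length(singletons)),
    similarity_window_used = window), class = "TranslocationAudit")
}

#' @export
print.TranslocationAudit <- function(x, ...) {
  cat(sprintf(
    "TranslocationAudit%s: %d of %d singletons (%d%%) paired elsewhere in [%g, %g]%%\n",
    if (is.na(x$genome_id)) "" else paste0(" '", x$genome_id, "'"),
    x$n_paired_remotely, x$n_singletons, x$percent_paired,
    x$similarity_window_used$lower, x$similarity_window_used$upper))
  invisible(x)
}
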