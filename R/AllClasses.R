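#' GeneTable: ordered gene annotations for one genome
#'
#' A `GeneTable` holds the gene-level annotation of one genome as a
#' coordinate-sorted table with a dense per-chromosome gene order ("rank").
#' Coordinates are 0-based half-open throughout the package; conversion from
#' 1-based formats (GFF3) happens at the I/O boundary only. Ranks run
#' `0..n-1` within each chromosome, ordered by start coordinate with ties
#' broken by end coordinate and then gene id, so that interval scanning has a
#' deterministic gene order even for overlapping gene models.
#'
#' @slot genomeId single character genome identifier.
#' @slot genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`+`, `-` or `unknown`) and `rank`, sorted by
#'   `(chrom, start, end, gene_id)`.
#'
#' @seealso [geneTable()], [readGff3()], [readBed()]
#' @export
setClass("GeneTable",
  representation(genomeId = "character", genes = "data.frame"))

setValidity("GeneTable", function(object) {
  g <- object@genes
  need <- c("gene_id", "chrom", "start", "end", "strand", "rank")
  if (!all(need %in% names(g)))
    return(paste("genes must have columns:", paste(need, collapse = ", ")))
  if (length(object@genomeId) != 1L || is.na(object@genomeId))
    return("genomeId must be a single string")
  if (nrow(g) == 0L) return(TRUE)
  if (anyDuplicated(g$gene_id)) return("duplicate gene_id")
  if (any(g$start < 0)) return("negative start coordinate")
  if (any(g$end <= g$start)) return("end <= start (zero/negative length gene)")
  if (!all(g$strand %in% c("+", "-", "unknown"))) return("bad strand value")
  for (ch in unique(g$chrom)) {
    i <- which(g$chrom == ch)
    if (!identical(g$rank[i], seq_along(i) - 1L))
      return(sprintf("ranks on %s are not 0..n-1 in table order", ch))
    if (is.unsorted(g$start[i]))
      return(sprintf("start coordinates on %s not sorted", ch))
  }
  TRUE
})

#' Construct a GeneTable from raw gene records
#'
#' Records are sorted by `(chrom, start, end, gene_id)` and per-chromosome
#' ranks `0..n-1` are assigned; input row order is irrelevant.
#'
#' @param genomeId genome identifier.
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `strand` (default `"unknown"`). Coordinates are 0-based
#'   half-open.
#' @return A [GeneTable-class] object.
#' @examples
#' gt <- geneTable("g", data.frame(gene_id = c("b", "a"), chrom = "chr1",
#'                                 start = c(500, 0), end = c(900, 300)))
#' geneRecords(gt)$rank   # 0 1, coordinate order
#' @export
geneTable <- function(genomeId, genes) {
  genes <- as.data.frame(genes)
  if (is.null(genes$strand)) genes$strand <- rep("unknown", nrow(genes))
  genes$strand <- .normStrand(genes$strand)
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  if (anyDuplicated(genes$gene_id))
    .stopf("duplicate gene_id in genome '%s': %s", genomeId,
           genes$gene_id[duplicated(genes$gene_id)][1L])
  o <- order(genes$chrom, genes$start, genes$end, genes$gene_id, method = "radix")
  genes <- genes[o, c("gene_id", "chrom", "start", "end", "strand"), drop = FALSE]
  rank <- integer(nrow(genes))
  if (nrow(genes)) {
    rank <- stats::ave(seq_len(nrow(genes)), genes$chrom,
                       FUN = seq_along) - 1L
    rank <- as.integer(rank)
  }
  genes$rank <- rank
  rownames(genes) <- NULL
  new("GeneTable", genomeId = as.character(genomeId), genes = genes)
}

#' @describeIn geneTable genome identifier accessor.
#' @param x a `GeneTable`.
#' @export
genomeId <- function(x) x@genomeId

#' @describeIn geneTable the sorted gene record data.frame.
#' @export
geneRecords <- function(x) x@genes

#' @describeIn geneTable number of genes.
#' @export
geneCount <- function(x) nrow(x@genes)

#' @describeIn geneTable chromosome names carrying at least one gene.
#' @export
chromosomes <- function(x) unique(x@genes$chrom)

#' Gene order lookup
#'
#' `geneRank()` maps gene ids to `(chrom, rank)`; `geneAt()` is the inverse,
#' mapping `(chrom, rank)` to a gene id. The two compose to the identity for
#' every annotated gene.
#'
#' @param table a [GeneTable-class].
#' @param geneIds character vector of gene ids.
#' @return `geneRank()`: data.frame with `gene_id`, `chrom`, `rank`;
#'   `geneAt()`: character vector of gene ids.
#' @export
geneRank <- function(table, geneIds) {
  i <- match(geneIds, table@genes$gene_id)
  if (anyNA(i))
    .stopf("gene id(s) not found in genome '%s': %s", table@genomeId,
           paste(head(geneIds[is.na(i)], 3L), collapse = ", "))
  data.frame(gene_id = geneIds, chrom = table@genes$chrom[i],
             rank = table@genes$rank[i], stringsAsFactors = FALSE)
}

#' @rdname geneRank
#' @param chrom chromosome name(s), recycled against `rank`.
#' @param rank integer rank(s), 0-based.
#' @export
geneAt <- function(table, chrom, rank) {
  key <- paste(table@genes$chrom, table@genes$rank)
  i <- match(paste(chrom, rank), key)
  if (anyNA(i)) .stopf("no gene at the requested (chrom, rank) position")
  table@genes$gene_id[i]
}

setMethod("show", "GeneTable", function(object) {
  cat(sprintf("GeneTable '%s': %d genes on %d chromosome(s)\n",
              object@genomeId, nrow(object@genes),
              length(unique(object@genes$chrom))))
})

#' Coerce a GeneTable to a GRanges
#'
#' Converts the internal 0-based half-open records to the 1-based inclusive
#' convention of [GenomicRanges::GRanges]. `unknown` strand maps to `*`.
#'
#' @param table a [GeneTable-class].
#' @return a `GRanges` with metadata columns `gene_id` and `rank`.
#' @export
asGRanges <- function(table) {
  g <- table@genes
  s <- g$strand
  s[s == "unknown"] <- "*"
  GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = s, gene_id = g$gene_id, rank = g$rank)
}

#' GenomeSummary: genome-wide gene density
#'
#' Total assembly size, gene count and their ratio (base pairs per gene, the
#' inverse of the gene density). The genome-wide bp-per-gene is the reference
#' quantity the conserved-interval regression slope is compared against and
#' the default basis of the genome-size normalization factor.
#'
#' @slot genomeId genome identifier.
#' @slot totalBp total assembly length in bp.
#' @slot geneCount number of annotated genes.
#' @slot bpPerGene `totalBp / geneCount`.
#' @seealso [summarizeGenome()], [genomeSizeFactor()], [densityComparison()]
#' @export
setClass("GenomeSummary",
  representation(genomeId = "character", totalBp = "numeric",
                 geneCount = "integer", bpPerGene = "numeric"))

setValidity("GenomeSummary", function(object) {
  if (object@geneCount <= 0L) return("geneCount must be positive")
  if (object@totalBp <= 0) return("totalBp must be positive")
  if (abs(object@bpPerGene - object@totalBp / object@geneCount) > 1e-8)
    return("bpPerGene != totalBp / geneCount")
  TRUE
})

#' @describeIn summarizeGenome bp-per-gene accessor.
#' @param x a `GenomeSummary`.
#' @export
bpPerGene <- function(x) x@bpPerGene

setMethod("show", "GenomeSummary", function(object) {
  cat(sprintf("GenomeSummary '%s': %.0f bp, %d genes, %.1f bp/gene\n",
              object@genomeId, object@totalBp, object@geneCount,
              object@bpPerGene))
})

#' SyntenyBlockSet: chained collinear anchor runs
#'
#' The result of [chainAnchors()]: a table of blocks (id, chromosome pair,
#' orientation, size, mean similarity) plus one row per anchor in chain
#' order. Within a block, side-A ranks strictly increase and side-B ranks
#' strictly increase (`same` orientation) or strictly decrease (`inverted`),
#' with consecutive anchors at most `max_gap` ranks apart on both sides.
#'
#' @slot blocks data.frame: `block_id`, `chrom_a`, `chrom_b`, `orientation`,
#'   `n_anchors`, `mean_similarity`.
#' @slot anchors data.frame: `block_id`, `gene_a`, `rank_a`, `gene_b`,
#'   `rank_b`, `similarity`, in chain order.
#' @slot params list of chaining parameters (`max_gap`, `min_block_size`,
#'   `self`).
#' @export
setClass("SyntenyBlockSet",
  representation(blocks = "data.frame", anchors = "data.frame",
                 params = "list"))

setValidity("SyntenyBlockSet", function(object) {
  b <- object@blocks; a <- object@anchors
  needB <- c("block_id", "chrom_a", "chrom_b", "orientation", "n_anchors",
             "mean_similarity")
  needA <- c("block_id", "gene_a", "rank_a", "gene_b", "rank_b", "similarity")
  if (!all(needB %in% names(b))) return("missing block columns")
  if (!all(needA %in% names(a))) return("missing anchor columns")
  if (nrow(b) == 0L) return(TRUE)
  if (anyDuplicated(b$block_id)) return("duplicate block_id")
  cnt <- table(a$block_id)
  if (!all(b$n_anchors == as.integer(cnt[as.character(b$block_id)])))
    return("n_anchors inconsistent with anchor rows")
  mg <- object@params$max_gap %||% Inf
  for (id in b$block_id) {
    ai <- a[a$block_id == id, ]
    da <- diff(ai$rank_a); db <- diff(ai$rank_b)
    if (nrow(ai) >= 2L) {
      if (any(da <= 0)) return(sprintf("block %d: side-A ranks not increasing", id))
      ori <- b$orientation[b$block_id == id]
      if (ori == "same" && any(db <= 0))
        return(sprintf("block %d: side-B ranks not increasing", id))
      if (ori == "inverted" && any(db >= 0))
        return(sprintf("block %d: side-B ranks not decreasing", id))
      if (any(da > mg) || any(abs(db) > mg))
        return(sprintf("block %d: gap exceeds max_gap", id))
    }
  }
  TRUE
})

#' @describeIn chainAnchors block-level table accessor.
#' @param x a `SyntenyBlockSet`.
#' @export
syntenyBlocks <- function(x) x@blocks

#' @describeIn chainAnchors per-anchor table accessor (chain order).
#' @export
blockAnchors <- function(x) x@anchors

#' @describeIn chainAnchors number of blocks.
#' @export
nBlocks <- function(x) nrow(x@blocks)

setMethod("show", "SyntenyBlockSet", function(object) {
  cat(sprintf(
    "SyntenyBlockSet: %d block(s), %d anchor(s) (max_gap=%s, min_block_size=%s)\n",
    nrow(object@blocks), nrow(object@anchors),
    object@params$max_gap %||% "?", object@params$min_block_size %||% "?"))
  if (nrow(object@blocks)) {
    cat(sprintf("  anchors/block: median %.0f, range %d-%d; mean similarity %.1f\n",
                stats::median(object@blocks$n_anchors),
                min(object@blocks$n_anchors), max(object@blocks$n_anchors),
                mean(object@blocks$mean_similarity)))
  }
})
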