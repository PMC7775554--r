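# Collinear chaining of anchor pairs into synteny blocks.
#
# Within one (chrom_a, chrom_b) pair, anchors are points (rank_a, rank_b) in
# gene-order space. A chain is a run of anchors strictly increasing in rank_a
# and strictly monotone in rank_b (increasing = "same" orientation,
# decreasing = "inverted"), with consecutive anchors at most max_gap ranks
# apart on both sides. Blocks are extracted by iterated best-chain peeling:
# the best remaining chain (most anchors; ties broken by the
# lexicographically smallest index sequence after sorting anchors by
# (rank_a, rank_b), which puts the leftmost start rank first; count-ties
# between orientations prefer "same") is emitted and its anchors removed,
# until the best chain falls below min_block_size. Peeling scores are
# non-increasing, so the block list at a higher threshold is a prefix of the
# list at a lower one.

.resolvePairs <- function(pairs, tableA, tableB) {
  ga <- geneRecords(tableA); gb <- geneRecords(tableB)
  ia <- match(pairs$gene_a, ga$gene_id)
  ib <- match(pairs$gene_b, gb$gene_id)
  if (anyNA(ia))
    .stopf("anchor gene not in genome '%s': %s", genomeId(tableA),
           pairs$gene_a[is.na(ia)][1L])
  if (anyNA(ib))
    .stopf("anchor gene not in genome '%s': %s", genomeId(tableB),
           pairs$gene_b[is.na(ib)][1L])
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
             similarity = pairs$similarity,
             chrom_a = ga$chrom[ia], rank_a = ga$rank[ia],
             chrom_b = gb$chrom[ib], rank_b = gb$rank[ib],
             stringsAsFactors = FALSE)
}

# Longest chain over alive anchors (vectors sorted by (ra, rb)); dir = +1
# for same orientation, -1 for inverted. Returns indices (into ra) of the
# maximum-count chain with the lexicographically smallest index sequence.
.bestChain <- function(ra, rb, maxGap, dir) {
  n <- length(ra)
  if (n == 0L) return(integer())
  f <- rep.int(1L, n)
  for (i in n:1L) {
    j <- i + 1L
    best <- 0L
    while (j <= n && ra[j] - ra[i] <= maxGap) {
      if (ra[j] > ra[i]) {
        db <- dir * (rb[j] - rb[i])
        if (db >= 1L && db <= maxGap && f[j] > best) best <- f[j]
      }
      j <- j + 1L
    }
    f[i] <- 1L + best
  }
  len <- max(f)
  cur <- which.max(f)                     # smallest index attaining max
  chain <- integer(len)
  chain[1L] <- cur
  k <- 1L
  while (f[cur] > 1L) {
    j <- cur + 1L
    while (j <= n) {
      if (ra[j] - ra[cur] > maxGap) { j <- 0L; break }
      db <- dir * (rb[j] - rb[cur])
      if (ra[j] > ra[cur] && db >= 1L && db <= maxGap && f[j] == f[cur] - 1L)
        break
      j <- j + 1L
    }
    stopifnot(j > 0L, j <= n)
    cur <- j
    k <- k + 1L
    chain[k] <- cur
  }
  chain
}

# canonical order for self-comparison: chrom_a <= chrom_b, ties by rank
.canonicalizeSelf <- function(rp) {
  swap <- (rp$chrom_b < rp$chrom_a) |
    (rp$chrom_b == rp$chrom_a & rp$rank_b < rp$rank_a)
  if (any(swap)) {
    tmp <- rp[swap, c("gene_a", "rank_a", "chrom_a")]
    rp[swap, c("gene_a", "rank_a", "chrom_a")] <-
      rp[swap, c("gene_b", "rank_b", "chrom_b")]
    rp[swap, c("gene_b", "rank_b", "chrom_b")] <- tmp
  }
  key <- paste(rp$gene_a, rp$gene_b, sep = "\r")
  o <- order(key, -rp$similarity, method = "radix")
  rp <- rp[o, , drop = FALSE][!duplicated(key[o]), , drop = FALSE]
  rp
}

#' Chain anchor pairs into collinear synteny blocks
#'
#' Builds maximal-score collinear chains of anchor pairs by dynamic
#' programming within every chromosome pair, in both orientations, and
#' discards chains with fewer than `minBlockSize` anchors (the classic
#' minimum-block-size threshold, default 5). The gap criterion is measured
#' in gene ranks (genes skipped) on each side, not base pairs. A gene can
#' appear in more than one block (via different anchor pairs); each anchor
#' pair is assigned to at most one block.
#'
#' For a self-comparison (`self = TRUE`, or `tableB` missing) the trivial
#' diagonal (a gene paired with itself) must not be present in `pairs`, and
#' mirror-duplicate anchors are canonicalized to `chrom_a <= chrom_b` (then
#' lower rank) so each homeologous region pair is chained once.
#'
#' @param pairs anchor pair data.frame (`gene_a`, `gene_b`, `similarity`).
#' @param tableA,tableB [GeneTable-class] objects for the two sides;
#'   `tableB` defaults to `tableA` (self-comparison).
#' @param maxGap maximum rank gap between consecutive anchors on either
#'   side, default 20.
#' @param minBlockSize minimum number of anchors per block, default 5.
#' @param self logical, self-comparison mode.
#' @return A [SyntenyBlockSet-class].
#' @export
chainAnchors <- function(pairs, tableA, tableB = tableA, maxGap = 20L,
                         minBlockSize = 5L, self = missing(tableB)) {
  .checkScalarNum(maxGap, "maxGap", 1)
  .checkScalarNum(minBlockSize, "minBlockSize", 1)
  rp <- .resolvePairs(pairs, tableA, tableB)
  if (self) {
    if (any(rp$gene_a == rp$gene_b))
      .stopf("self-comparison: trivial diagonal pair present (%s)",
             rp$gene_a[rp$gene_a == rp$gene_b][1L])
    rp <- .canonicalizeSelf(rp)
  }
  grp <- paste(rp$chrom_a, rp$chrom_b, sep = "\r")
  blockRows <- list(); anchorRows <- list()
  nextId <- 1L
  for (g in sort(unique(grp))) {
    sub <- rp[grp == g, , drop = FALSE]
    o <- order(sub$rank_a, sub$rank_b, method = "radix")
    sub <- sub[o, , drop = FALSE]
    alive <- rep.int(TRUE, nrow(sub))
    repeat {
      idx <- which(alive)
      if (length(idx) == 0L) break
      ra <- sub$rank_a[idx]; rb <- sub$rank_b[idx]
      cs <- .bestChain(ra, rb, maxGap, +1L)
      ci <- .bestChain(ra, rb, maxGap, -1L)
      pickSame <- length(cs) > length(ci) ||
        (length(cs) == length(ci) &&
           .lexLE(cs, ci))
      chain <- if (pickSame) cs else ci
      ori <- if (pickSame) "same" else "inverted"
      if (length(chain) < minBlockSize) break
      rows <- sub[idx[chain], , drop = FALSE]
      blockRows[[length(blockRows) + 1L]] <- data.frame(
        block_id = nextId, chrom_a = rows$chrom_a[1L],
        chrom_b = rows$chrom_b[1L], orientation = ori,
        n_anchors = nrow(rows), mean_similarity = mean(rows$similarity),
        stringsAsFactors = FALSE)
      anchorRows[[length(anchorRows) + 1L]] <- data.frame(
        block_id = nextId, gene_a = rows$gene_a, rank_a = rows$rank_a,
        gene_b = rows$gene_b, rank_b = rows$rank_b,
        similarity = rows$similarity, chrom_a = rows$chrom_a,
        chrom_b = rows$chrom_b, stringsAsFactors = FALSE)
      nextId <- nextId + 1L
      alive[idx[chain]] <- FALSE
    }
  }
  empty <- function(cols) as.data.frame(cols, stringsAsFactors = FALSE)
  blocks <- if (length(blockRows)) do.call(rbind, blockRows) else
    empty(list(block_id = integer(), chrom_a = character(),
               chrom_b = character(), orientation = character(),
               n_anchors = integer(), mean_similarity = numeric()))
  anchors <- if (length(anchorRows)) do.call(rbind, anchorRows) else
    empty(list(block_id = integer(), gene_a = character(), rank_a = integer(),
               gene_b = character(), rank_b = integer(),
               similarity = numeric(), chrom_a = character(),
               chrom_b = character()))
  rownames(blocks) <- rownames(anchors) <- NULL
  new("SyntenyBlockSet", blocks = blocks, anchors = anchors,
      params = list(max_gap = as.integer(maxGap),
                    min_block_size = as.integer(minBlockSize), self = self))
}

# TRUE if integer vector a is lexicographically <= b (same length)
.lexLE <- function(a, b) {
  d <- a - b
  nz <- which(d != 0L)
  if (length(nz) == 0L) TRUE else d[nz[1L]] < 0L
}

#' Filter blocks by mean similarity
#'
#' Retains blocks whose *mean* anchor similarity lies inside the window
#' (individual pairs are never dropped from a retained block). This is the
#' step that isolates blocks created at the most recent polyploidization or
#' speciation event from older duplication cohorts.
#'
#' @param blockSet a [SyntenyBlockSet-class].
#' @param window a [similarityWindow()].
#' @return the filtered `SyntenyBlockSet` (block ids preserved).
#' @export
filterBlocksBySimilarity <- function(blockSet, window) {
  stopifnot(inherits(window, "SimilarityWindow"))
  b <- syntenyBlocks(blockSet)
  keep <- b$mean_similarity >= window$lower & b$mean_similarity <= window$upper
  kept <- b$block_id[keep]
  a <- blockAnchors(blockSet)
  new("SyntenyBlockSet", blocks = b[keep, , drop = FALSE],
      anchors = a[a$block_id %in% kept, , drop = FALSE],
      params = c(blockSet@params, list(similarity_window = unlist(window))))
}

#' Minimum-block-size sensitivity sweep
#'
#' For each threshold, counts the distinct genes (both sides pooled)
#' belonging to at least one block of at least that many anchors. Because
#' chains are peeled in non-increasing score order, chaining once at the
#' smallest threshold and filtering by block size is exact. The count is
#' non-increasing in the threshold; lowering it to 3 starts to capture
#' coincidental neighboring pairs, which is the rationale for the default
#' minimum of 5.
#'
#' @inheritParams chainAnchors
#' @param thresholds integer vector of minimum block sizes, default 3:6.
#' @return data.frame with `threshold` and `genes_in_blocks`.
#' @export
blockSizeSensitivity <- function(pairs, tableA, tableB = tableA, maxGap = 20L,
                                 thresholds = c(3L, 4L, 5L, 6L),
                                 self = missing(tableB)) {
  if (length(thresholds) == 0L || any(thresholds < 1L))
    .stopf("thresholds must be positive block sizes")
  bs <- chainAnchors(pairs, tableA, tableB, maxGap = maxGap,
                     minBlockSize = min(thresholds), self = self)
  b <- syntenyBlocks(bs); a <- blockAnchors(bs)
  counts <- vapply(thresholds, function(t) {
    ids <- b$block_id[b$n_anchors >= t]
    ai <- a[a$block_id %in% ids, , drop = FALSE]
    if (nrow(ai) == 0L) return(0L)
    length(unique(c(paste0(genomeId(tableA), "\r", ai$gene_a),
                    paste0(genomeId(tableB), "\r", ai$gene_b))))
  }, integer(1L))
  data.frame(threshold = as.integer(thresholds), genes_in_blocks = counts)
}

#' Write a SyntenyBlockSet as a flat TSV
#'
#' One row per anchor, carrying its block's metadata columns
#' (`block_id, chrom_a, chrom_b, orientation, n_anchors, mean_similarity`)
#' followed by `gene_a, rank_a, gene_b, rank_b, similarity`.
#' @param blockSet a [SyntenyBlockSet-class].
#' @param path output path.
#' @export
writeBlocksTsv <- function(blockSet, path) {
  b <- syntenyBlocks(blockSet); a <- blockAnchors(blockSet)
  m <- merge(b, a[, c("block_id", "gene_a", "rank_a", "gene_b", "rank_b",
                      "similarity")], by = "block_id", sort = FALSE)
  m <- m[order(m$block_id, m$rank_a), , drop = FALSE]
  data.table::fwrite(m, path, sep = "\t", quote = FALSE)
  invisible(path)
}
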