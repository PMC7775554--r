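# Independent oracles and small fixture builders shared across test files.

# ---- tiny GeneTable builders ---------------------------------------------

# evenly spaced genes: gene k on chrom occupies [k*step, k*step + glen)
evenTable <- function(genomeId, nPerChrom, chroms = "chr1", step = 10000,
                      glen = 3000, prefix = genomeId) {
  rows <- do.call(rbind, lapply(chroms, function(ch) {
    k <- seq_len(nPerChrom) - 1L
    data.frame(gene_id = sprintf("%s_%s_g%03d", prefix, ch, k + 1L),
               chrom = ch, start = k * step + step,
               end = k * step + step + glen, stringsAsFactors = FALSE)
  }))
  geneTable(genomeId, rows)
}

# ---- exhaustive chaining oracle ------------------------------------------

# all chains via depth-first enumeration; returns the maximum-count chain
# with the lexicographically smallest index sequence (indices into the
# (ra, rb)-sorted anchor list), or integer() when there are no anchors.
oracleBestChain <- function(ra, rb, maxGap, dir) {
  n <- length(ra)
  if (n == 0L) return(integer())
  succ <- lapply(seq_len(n), function(i) {
    j <- setdiff(seq_len(n), i)
    j[ra[j] > ra[i] & ra[j] - ra[i] <= maxGap &
        dir * (rb[j] - rb[i]) >= 1 & dir * (rb[j] - rb[i]) <= maxGap]
  })
  best <- NULL
  consider <- function(chain) {
    if (is.null(best) || length(chain) > length(best)) {
      best <<- chain
    } else if (length(chain) == length(best)) {
      d <- chain - best
      nz <- which(d != 0L)
      if (length(nz) && d[nz[1L]] < 0L) best <<- chain
    }
  }
  dfs <- function(chain) {
    s <- succ[[chain[length(chain)]]]
    if (length(s) == 0L) { consider(chain); return(invisible()) }
    for (j in sort(s)) dfs(c(chain, j))
  }
  for (i in seq_len(n)) dfs(i)
  best
}

# same peeling contract as chainAnchors, driven by the exhaustive search
oracleChainBlocks <- function(pairs, tableA, tableB, maxGap, minBlockSize) {
  ga <- geneRecords(tableA); gb <- geneRecords(tableB)
  rp <- data.frame(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    similarity = pairs$similarity,
    chrom_a = ga$chrom[match(pairs$gene_a, ga$gene_id)],
    rank_a = ga$rank[match(pairs$gene_a, ga$gene_id)],
    chrom_b = gb$chrom[match(pairs$gene_b, gb$gene_id)],
    rank_b = gb$rank[match(pairs$gene_b, gb$gene_id)],
    stringsAsFactors = FALSE)
  out <- list()
  lexLE <- function(a, b) {
    d <- a - b; nz <- which(d != 0L)
    if (length(nz) == 0L) TRUE else d[nz[1L]] < 0L
  }
  for (g in sort(unique(paste(rp$chrom_a, rp$chrom_b, sep = "\r")))) {
    sub <- rp[paste(rp$chrom_a, rp$chrom_b, sep = "\r") == g, , drop = FALSE]
    sub <- sub[order(sub$rank_a, sub$rank_b), , drop = FALSE]
    alive <- rep(TRUE, nrow(sub))
    repeat {
      idx <- which(alive)
      if (length(idx) == 0L) break
      cs <- oracleBestChain(sub$rank_a[idx], sub$rank_b[idx], maxGap, +1)
      ci <- oracleBestChain(sub$rank_a[idx], sub$rank_b[idx], maxGap, -1)
      pickSame <- length(cs) > length(ci) ||
        (length(cs) == length(ci) && lexLE(cs, ci))
      chain <- if (pickSame) cs else ci
      if (length(chain) < minBlockSize) break
      out[[length(out) + 1L]] <- list(
        orientation = if (pickSame) "same" else "inverted",
        gene_a = sub$gene_a[idx[chain]], gene_b = sub$gene_b[idx[chain]])
      alive[idx[chain]] <- FALSE
    }
  }
  out
}

# canonical comparable form of a SyntenyBlockSet
blockSignature <- function(blockSet) {
  a <- blockAnchors(blockSet); b <- syntenyBlocks(blockSet)
  sig <- vapply(b$block_id, function(id) {
    ai <- a[a$block_id == id, ]
    paste(b$orientation[b$block_id == id],
          paste(ai$gene_a, ai$gene_b, sep = "~", collapse = "|"))
  }, character(1L))
  sort(sig)
}

oracleSignature <- function(oracleBlocks) {
  sort(vapply(oracleBlocks, function(x)
    paste(x$orientation, paste(x$gene_a, x$gene_b, sep = "~", collapse = "|")),
    character(1L)))
}

# ---- truth-log deletion-interval oracle ----------------------------------

# expected intervals from the simulator event log: maximal runs of
# consecutive ancestral genes lost on one uniform side, bounded by intact
# pairs that sit as consecutive anchors in one retained block. Only valid
# for fixtures without rearrangements or noise anchors.
truthIntervalOracle <- function(sim, blockSet) {
  truth <- sim$truth
  n <- length(truth$anc_chrom)
  lostSide <- integer(n)
  for (ev in truth$events) {
    if (ev$op %in% c("excision", "pseudogenization")) lostSide[ev$idx] <- ev$side
  }
  comb <- c(truth$id_to_idx[[1L]], truth$id_to_idx[[2L]])
  # consecutive anchor pairs per retained block, keyed by bounding idx
  a <- blockAnchors(blockSet)
  boundKey <- character(0)
  if (nrow(a) >= 2L) {
    i <- seq_len(nrow(a) - 1L)
    ok <- a$block_id[i] == a$block_id[i + 1L]
    li <- unname(comb[a$gene_a[i][ok]])
    ri <- unname(comb[a$gene_a[i + 1L][ok]])
    boundKey <- paste(pmin(li, ri), pmax(li, ri))
  }
  out <- list()
  pos <- 1L
  while (pos <= n) {
    if (lostSide[pos] == 0L) { pos <- pos + 1L; next }
    end <- pos
    while (end < n && lostSide[end + 1L] != 0L &&
           truth$anc_chrom[end + 1L] == truth$anc_chrom[pos]) end <- end + 1L
    sides <- unique(lostSide[pos:end])
    l <- pos - 1L; r <- end + 1L
    if (length(sides) == 1L && l >= 1L && r <= n &&
        truth$anc_chrom[l] == truth$anc_chrom[pos] &&
        truth$anc_chrom[r] == truth$anc_chrom[pos] &&
        lostSide[l] == 0L && lostSide[r] == 0L &&
        paste(l, r) %in% boundKey) {
      out[[length(out) + 1L]] <- c(l = l, r = r, L = end - pos + 1L,
                                   side = sides)
    }
    pos <- end + 1L
  }
  if (length(out) == 0L)
    return(data.frame(l = integer(), r = integer(), L = integer(),
                      side = integer()))
  as.data.frame(do.call(rbind, out))
}

# scan output mapped onto ancestral indices and simulator sides
scanIntervalSignature <- function(intervals, sim) {
  idx1 <- sim$truth$id_to_idx[[1L]]; idx2 <- sim$truth$id_to_idx[[2L]]
  toIdx <- function(id) {
    i <- idx1[id]
    i[is.na(i)] <- idx2[id[is.na(i)]]
    unname(i)
  }
  # fractionated side "A" means the gene_a side lost; find which simulator
  # side that is from the id map membership of the bounding gene
  fracSide <- ifelse(intervals$fractionated_genome == "A",
                     ifelse(intervals$left_gene_a %in% names(idx1), 1L, 2L),
                     ifelse(intervals$left_gene_b %in% names(idx1), 1L, 2L))
  li <- toIdx(intervals$left_gene_a)
  ri <- toIdx(intervals$right_gene_a)
  sort(paste(pmin(li, ri), pmax(li, ri), intervals$length, fracSide))
}

truthIntervalSignature <- function(oracle) {
  sort(paste(oracle$l, oracle$r, oracle$L, oracle$side))
}
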