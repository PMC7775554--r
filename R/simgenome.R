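# Forward simulator of a genome pair after whole-genome duplication or
# speciation, with a replayable ground-truth event log.
#
# An ancestor of n genes (lognormal gene and intergenic lengths laid
# head-to-tail) is duplicated -- either into two sister genomes (speciation)
# or into homeologous chromosome copies of one genome (WGD). Duplicate
# pairs then lose one member in runs of geometric length, by excision
# (the whole stretch between the surviving neighbour genes is removed and
# replaced by a single exponential residual per event -- this is what makes
# the fractionated span flat in the interval length) or by pseudogenization
# (the annotation and its anchor disappear, the DNA stays). Inversions and
# single-gene translocations erode collinearity; an older duplication
# cohort and uniform noise pairs can be mixed into the anchor list. Every
# mutation is executed by a parameter-explicit primitive and logged, so
# folding the log over the ancestor reproduces the emitted genomes exactly.

#' Simulation configuration
#'
#' Defaults mirror a mid-size plant genome: 10,000 genes of mean length
#' 3 kbp separated by mean 5 kbp intergenic stretches (lognormal, sigma on
#' the log scale), 30% of duplicate pairs losing one copy in runs of mean
#' length 2, and 400 bp of residual DNA left per excision event.
#'
#' @param n_genes number of ancestral genes (= duplicate pairs).
#' @param n_chromosomes chromosomes the ancestor is split across.
#' @param mean_gene_bp,mean_intergenic_bp arithmetic mean gene / intergenic
#'   length in bp.
#' @param sdlog_gene,sdlog_intergenic lognormal sigma of the two length
#'   distributions (0 = degenerate).
#' @param event `"speciation"` (two sister genomes) or `"wgd"` (one doubled
#'   genome, self-comparison).
#' @param loss_fraction proportion of duplicate pairs losing one member.
#' @param run_length_p geometric parameter of loss-run lengths (mean run
#'   `1/p`).
#' @param mechanism `"excision"`, `"pseudogenization"` or `"mixed"`.
#' @param mix_excision_prob probability that a `mixed` event is an excision.
#' @param residual_mean_bp mean of the exponential residual left per
#'   excision event.
#' @param n_translocations single genes jumped to a remote location.
#' @param n_inversions segments of reversed gene order.
#' @param inversion_len_range min/max genes per inverted segment.
#' @param similarity_recent,similarity_old `(mean, sd)` percent identity of
#'   the recent-event and older duplicate cohorts.
#' @param old_pair_fraction proportion of genes given an older-cohort
#'   (collinear, remote-segment) duplicate pair.
#' @param old_segment_len genes per older-cohort duplicated segment.
#' @param n_noise_anchors uniformly random anchor pairs added to the list.
#' @param intergenic_scale_b multiply genome B's intergenic stretches by
#'   this factor (models a partner genome bloated by repetitive DNA).
#' @param seed integer seed fixing all randomness end-to-end.
#' @return list of class `SimConfig`.
#' @export
simConfig <- function(n_genes = 10000L, n_chromosomes = 5L,
                      mean_gene_bp = 3000, mean_intergenic_bp = 5000,
                      sdlog_gene = 0.25, sdlog_intergenic = 0.25,
                      event = c("speciation", "wgd"),
                      loss_fraction = 0.3, run_length_p = 0.5,
                      mechanism = c("excision", "pseudogenization", "mixed"),
                      mix_excision_prob = 0.5, residual_mean_bp = 400,
                      n_translocations = 0L, n_inversions = 0L,
                      inversion_len_range = c(3L, 25L),
                      similarity_recent = c(92, 2), similarity_old = c(75, 3),
                      old_pair_fraction = 0, old_segment_len = 15L,
                      n_noise_anchors = 0L, intergenic_scale_b = 1,
                      seed = 1L) {
  event <- match.arg(event)
  mechanism <- match.arg(mechanism)
  .checkScalarNum(n_genes, "n_genes", 2)
  .checkScalarNum(n_chromosomes, "n_chromosomes", 1)
  .checkScalarNum(mean_gene_bp, "mean_gene_bp", 1)
  .checkScalarNum(mean_intergenic_bp, "mean_intergenic_bp", 1)
  .checkScalarNum(loss_fraction, "loss_fraction", 0, 1)
  .checkScalarNum(run_length_p, "run_length_p", 1e-6, 1)
  .checkScalarNum(mix_excision_prob, "mix_excision_prob", 0, 1)
  .checkScalarNum(residual_mean_bp, "residual_mean_bp", 0)
  .checkScalarNum(old_pair_fraction, "old_pair_fraction", 0, 1)
  .checkScalarNum(intergenic_scale_b, "intergenic_scale_b", 1e-6)
  .checkScalarNum(seed, "seed")
  structure(as.list(environment()), class = "SimConfig")
}

.rtruncsim <- function(n, ms) pmin(100, pmax(0, rnorm(n, ms[1L], ms[2L])))

#' Simulate the ancestral genome
#'
#' Lays `n_genes` genes head-to-tail (gap, gene, gap, gene, ..., gap) across
#' the configured chromosomes; sets the seed, so the whole downstream
#' simulation is reproducible from the config alone.
#'
#' @param config a [simConfig()].
#' @return list of class `SimAncestor` with `genes` (data.frame: `idx`,
#'   `gene_id`, `chrom`, `start`, `end`, `strand`, `len`) and `sizes`.
#' @export
simulateAncestor <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- as.integer(config$n_genes)
  nc <- as.integer(config$n_chromosomes)
  per <- diff(floor(seq(0, n, length.out = nc + 1L)))
  chromOf <- rep(seq_len(nc), times = per)
  mlg <- log(config$mean_gene_bp) - config$sdlog_gene^2 / 2
  mli <- log(config$mean_intergenic_bp) - config$sdlog_intergenic^2 / 2
  len <- pmax(1, round(rlnorm(n, mlg, config$sdlog_gene)))
  rows <- vector("list", nc)
  sizes <- numeric(nc)
  names(sizes) <- sprintf("chr%02d", seq_len(nc))
  for (c in seq_len(nc)) {
    i <- which(chromOf == c)
    m <- length(i)
    gap <- pmax(1, round(rlnorm(m + 1L, mli, config$sdlog_intergenic)))
    start <- cumsum(gap[seq_len(m)]) + c(0, cumsum(len[i])[-m])
    rows[[c]] <- data.frame(
      idx = i, gene_id = sprintf("g%05d", i), chrom = names(sizes)[c],
      start = start, end = start + len[i],
      strand = sample(c("+", "-"), m, replace = TRUE), len = len[i],
      stringsAsFactors = FALSE)
    sizes[c] <- sum(gap) + sum(len[i])
  }
  structure(list(genes = do.call(rbind, rows), sizes = sizes,
                 config = config), class = "SimAncestor")
}

# ---- deterministic, parameter-explicit mutation primitives ----------------

.sideGenes <- function(state, s) state$sides[[s]]$genes

.simExcise <- function(state, s, geneIds, residual) {
  g <- state$sides[[s]]$genes
  i <- match(geneIds, g$gene_id)
  chrom <- g$chrom[i[1L]]
  onChrom <- g$chrom == chrom & g$alive
  lo <- min(g$start[i]); hi <- max(g$end[i])
  prevEnd <- suppressWarnings(max(g$end[onChrom & g$end <= lo & !(g$gene_id %in% geneIds)]))
  nextStart <- suppressWarnings(min(g$start[onChrom & g$start >= hi & !(g$gene_id %in% geneIds)]))
  leftB <- if (is.finite(prevEnd)) prevEnd else 0
  rightB <- if (is.finite(nextStart)) nextStart else state$sides[[s]]$chromSizes[chrom]
  removed <- rightB - leftB
  residual <- min(residual, removed)
  delta <- removed - residual
  g$alive[i] <- FALSE
  shift <- g$chrom == chrom & g$start >= rightB
  g$start[shift] <- g$start[shift] - delta
  g$end[shift] <- g$end[shift] - delta
  state$sides[[s]]$genes <- g
  state$sides[[s]]$chromSizes[chrom] <-
    state$sides[[s]]$chromSizes[chrom] - delta
  state
}

.simPseudogenize <- function(state, s, geneIds) {
  g <- state$sides[[s]]$genes
  g$alive[match(geneIds, g$gene_id)] <- FALSE
  state$sides[[s]]$genes <- g
  state
}

.simInvert <- function(state, s, chrom, segStart, segEnd) {
  g <- state$sides[[s]]$genes
  w <- g$chrom == chrom & g$start >= segStart & g$end <= segEnd
  ns <- segStart + (segEnd - g$end[w])
  ne <- segStart + (segEnd - g$start[w])
  g$start[w] <- ns; g$end[w] <- ne
  flip <- c(`+` = "-", `-` = "+", unknown = "unknown")
  g$strand[w] <- unname(flip[g$strand[w]])
  state$sides[[s]]$genes <- g
  state
}

.simTranslocate <- function(state, s, geneId, destChrom, destAfterGene, gapOffset) {
  g <- state$sides[[s]]$genes
  i <- match(geneId, g$gene_id)
  len <- g$end[i] - g$start[i]
  srcChrom <- g$chrom[i]
  shift <- g$chrom == srcChrom & g$start >= g$end[i]
  g$start[shift] <- g$start[shift] - len
  g$end[shift] <- g$end[shift] - len
  state$sides[[s]]$chromSizes[srcChrom] <-
    state$sides[[s]]$chromSizes[srcChrom] - len
  g$chrom[i] <- NA_character_   # detached while we locate the destination
  j <- match(destAfterGene, g$gene_id)
  destPos <- g$end[j] + gapOffset
  shift2 <- !is.na(g$chrom) & g$chrom == destChrom & g$start >= destPos
  g$start[shift2] <- g$start[shift2] + len
  g$end[shift2] <- g$end[shift2] + len
  g$chrom[i] <- destChrom
  g$start[i] <- destPos
  g$end[i] <- destPos + len
  state$sides[[s]]$genes <- g
  state$sides[[s]]$chromSizes[destChrom] <-
    state$sides[[s]]$chromSizes[destChrom] + len
  state
}

# ---- state construction ---------------------------------------------------

# RNG-free: everything here is a deterministic function of ancestor + config
.initSides <- function(ancestor, config) {
  anc <- ancestor$genes
  mk <- function(prefix, idSuffix, chromSuffix) {
    g <- anc
    g$gene_id <- paste0(prefix, anc$gene_id, idSuffix)
    g$chrom <- paste0(anc$chrom, chromSuffix)
    g$alive <- TRUE
    sz <- ancestor$sizes
    names(sz) <- paste0(names(ancestor$sizes), chromSuffix)
    list(genes = g, chromSizes = sz)
  }
  if (config$event == "speciation") {
    sides <- list(mk("A_", "", ""), mk("B_", "", ""))
  } else {
    sides <- list(mk("", "a", "a"), mk("", "b", "b"))
  }
  if (config$intergenic_scale_b != 1) {
    s2 <- sides[[2L]]
    g <- s2$genes
    for (ch in unique(g$chrom)) {
      w <- which(g$chrom == ch)
      w <- w[order(g$start[w])]
      gap <- diff(c(0, g$start[w])) - c(0, g$end[w][-length(w)] - g$start[w][-length(w)])
      # gap[k] is the intergenic stretch before gene k
      gap <- round(gap * config$intergenic_scale_b)
      lens <- g$end[w] - g$start[w]
      newStart <- cumsum(gap) + c(0, cumsum(lens)[-length(w)])
      tailGap <- round((s2$chromSizes[ch] - max(g$end[w])) *
                         config$intergenic_scale_b)
      g$start[w] <- newStart
      g$end[w] <- newStart + lens
      s2$chromSizes[ch] <- max(g$end[w]) + tailGap
    }
    s2$genes <- g
    sides[[2L]] <- s2
  }
  list(mode = if (config$event == "wgd") "self" else "cross",
       sides = sides, ancChrom = anc$chrom, n = nrow(anc),
       pairStatus = integer(nrow(anc)), events = list(), config = config)
}

#' Duplicate the ancestor by speciation or WGD
#'
#' Creates the two sides of the comparison plus the anchor-pair truth: one
#' recent-cohort pair per ancestral gene, and optionally older-cohort pairs
#' linking remote duplicated segments at a lower similarity.
#'
#' @param ancestor a `SimAncestor` from [simulateAncestor()].
#' @param config the same [simConfig()].
#' @return list of class `SimState` (sides, pair table, event log).
#' @export
applyEvent <- function(ancestor, config = ancestor$config) {
  stopifnot(inherits(ancestor, "SimAncestor"))
  state <- .initSides(ancestor, config)
  n <- state$n
  id1 <- state$sides[[1L]]$genes$gene_id
  id2 <- state$sides[[2L]]$genes$gene_id
  pairs <- data.frame(idx = seq_len(n), gene_a = id1, gene_b = id2,
                      similarity = .rtruncsim(n, config$similarity_recent),
                      cohort = "recent", stringsAsFactors = FALSE)
  nOld <- round(config$old_pair_fraction * n)
  if (nOld > 0L) {
    segLen <- as.integer(config$old_segment_len)
    made <- 0L
    oldRows <- list()
    guard <- 0L
    while (made < nOld && guard < 50L * nOld) {
      guard <- guard + 1L
      i <- sample.int(n - segLen + 1L, 1L)
      j <- sample.int(n - segLen + 1L, 1L)
      ii <- i:(i + segLen - 1L); jj <- j:(j + segLen - 1L)
      if (abs(i - j) < 2L * segLen) next
      if (length(unique(state$ancChrom[ii])) > 1L) next
      if (length(unique(state$ancChrom[jj])) > 1L) next
      oldRows[[length(oldRows) + 1L]] <- data.frame(
        idx = NA_integer_, gene_a = id1[ii], gene_b = id2[jj],
        similarity = .rtruncsim(segLen, config$similarity_old),
        cohort = "old", stringsAsFactors = FALSE)
      made <- made + segLen
    }
    if (length(oldRows)) pairs <- rbind(pairs, do.call(rbind, oldRows))
  }
  state$pairs <- pairs
  state
}

#' Apply duplicate-gene loss with a ground-truth log
#'
#' Loss runs of geometric length are placed uniformly at random over intact
#' duplicate pairs (never overlapping previous losses, never deleting both
#' members of a pair) until `loss_fraction` of the pairs have lost one
#' member, alternating sides at random. Each run is excised or
#' pseudogenized according to the configured mechanism and appended to the
#' event log.
#'
#' @param state a `SimState` from [applyEvent()].
#' @param config the [simConfig()].
#' @return the mutated `SimState`.
#' @export
applyLoss <- function(state, config = state$config) {
  n <- state$n
  target <- floor(config$loss_fraction * n)
  lost <- 0L
  while (lost < target) {
    cand <- which(state$pairStatus == 0L)
    if (length(cand) == 0L)
      .stopf("loss_fraction too high: no intact duplicate pair left to lose")
    startIdx <- cand[sample.int(length(cand), 1L)]
    k <- min(rgeom(1L, config$run_length_p) + 1L, target - lost)
    run <- startIdx
    j <- startIdx + 1L
    while (length(run) < k && j <= n &&
           state$ancChrom[j] == state$ancChrom[startIdx] &&
           state$pairStatus[j] == 0L) {
      run <- c(run, j)
      j <- j + 1L
    }
    s <- sample.int(2L, 1L)
    mech <- switch(config$mechanism,
                   excision = "excision",
                   pseudogenization = "pseudogenization",
                   mixed = if (runif(1L) < config$mix_excision_prob)
                     "excision" else "pseudogenization")
    geneIds <- state$sides[[s]]$genes$gene_id[match(run, state$sides[[s]]$genes$idx)]
    if (mech == "excision") {
      residual <- round(rexp(1L, 1 / config$residual_mean_bp))
      state <- .simExcise(state, s, geneIds, residual)
    } else {
      residual <- NA_real_
      state <- .simPseudogenize(state, s, geneIds)
    }
    state$pairStatus[run] <- s
    state$events[[length(state$events) + 1L]] <- list(
      op = mech, side = s, idx = run, gene_ids = geneIds, residual = residual)
    lost <- lost + length(run)
  }
  state
}

#' Apply inversions and single-gene translocations
#'
#' Inversions reverse the gene order (and strand) of a random run of
#' contiguous genes; translocations move one member of an intact duplicate
#' pair to a random remote position, DNA included, leaving its anchor pair
#' in place. Both are logged.
#'
#' @param state a `SimState`.
#' @param nTranslocations,nInversions event counts (default from the
#'   config).
#' @return the mutated `SimState`.
#' @export
applyRearrangements <- function(state,
                                nTranslocations = state$config$n_translocations,
                                nInversions = state$config$n_inversions) {
  cfg <- state$config
  for (dummy in seq_len(nInversions)) {
    s <- sample.int(2L, 1L)
    g <- state$sides[[s]]$genes
    aliveIdx <- which(g$alive)
    pick <- aliveIdx[sample.int(length(aliveIdx), 1L)]
    chrom <- g$chrom[pick]
    onCh <- aliveIdx[g$chrom[aliveIdx] == chrom]
    onCh <- onCh[order(g$start[onCh])]
    p0 <- which(onCh == pick)
    lenOpts <- cfg$inversion_len_range[1L]:cfg$inversion_len_range[2L]
    segN <- lenOpts[sample.int(length(lenOpts), 1L)]
    seg <- onCh[p0:min(p0 + segN - 1L, length(onCh))]
    segStart <- min(g$start[seg]); segEnd <- max(g$end[seg])
    state <- .simInvert(state, s, chrom, segStart, segEnd)
    state$events[[length(state$events) + 1L]] <- list(
      op = "inversion", side = s, chrom = chrom,
      seg_start = segStart, seg_end = segEnd,
      gene_ids = g$gene_id[seg])
  }
  for (dummy in seq_len(nTranslocations)) {
    s <- sample.int(2L, 1L)
    g <- state$sides[[s]]$genes
    movable <- which(g$alive & g$idx %in% which(state$pairStatus == 0L))
    if (length(movable) == 0L) break
    i <- movable[sample.int(length(movable), 1L)]
    geneId <- g$gene_id[i]
    destChrom <- sample(names(state$sides[[s]]$chromSizes), 1L)
    anchors <- which(g$alive & g$chrom == destChrom & g$gene_id != geneId)
    if (length(anchors) == 0L) next
    after <- g$gene_id[anchors[sample.int(length(anchors), 1L)]]
    gap <- round(cfg$mean_intergenic_bp / 2)
    state <- .simTranslocate(state, s, geneId, destChrom, after, gap)
    state$events[[length(state$events) + 1L]] <- list(
      op = "translocation", side = s, gene_id = geneId,
      dest_chrom = destChrom, dest_after_gene = after, gap_offset = gap)
  }
  state
}

# Noise pairs model duplications created independently of the event that
# happen to land in nearby regions ("coincidentally neighboring"): they are
# drawn in small clusters of 2-4 pairs whose members sit within a few gene
# ranks of a random cluster center on each side. Such clusters are what a
# permissive block-size threshold of 3 starts to pick up.
.addNoiseAnchors <- function(state, config = state$config) {
  nn <- as.integer(config$n_noise_anchors)
  if (nn == 0L) return(state)
  g1 <- state$sides[[1L]]$genes; g2 <- state$sides[[2L]]$genes
  a1 <- which(g1$alive); a2 <- which(g2$alive)
  rows <- list()
  placed <- 0L
  while (placed < nn) {
    k <- min(sample(2:4, 1L), nn - placed)
    c1 <- sample.int(length(a1), 1L); c2 <- sample.int(length(a2), 1L)
    m1 <- pmin(pmax(c1 + sample(-8:8, k, replace = TRUE), 1L), length(a1))
    m2 <- pmin(pmax(c2 + sample(-8:8, k, replace = TRUE), 1L), length(a2))
    keep <- g1$chrom[a1[m1]] == g1$chrom[a1[c1]] &
      g2$chrom[a2[m2]] == g2$chrom[a2[c2]]
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      idx = NA_integer_,
      gene_a = g1$gene_id[a1[m1[keep]]],
      gene_b = g2$gene_id[a2[m2[keep]]],
      similarity = .rtruncsim(sum(keep), config$similarity_recent),
      cohort = "noise", stringsAsFactors = FALSE)
    placed <- placed + sum(keep)
  }
  state$pairs <- rbind(state$pairs, do.call(rbind, rows))
  state
}

.finalizeSim <- function(state) {
  cfg <- state$config
  aliveTab <- function(s, gid) {
    g <- state$sides[[s]]$genes
    g <- g[g$alive, c("gene_id", "chrom", "start", "end", "strand")]
    geneTable(gid, g)
  }
  alive1 <- state$sides[[1L]]$genes$gene_id[state$sides[[1L]]$genes$alive]
  alive2 <- state$sides[[2L]]$genes$gene_id[state$sides[[2L]]$genes$alive]
  pairs <- state$pairs
  pairs <- pairs[pairs$gene_a %in% alive1 & pairs$gene_b %in% alive2, ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  if (state$mode == "self") {
    g <- rbind(state$sides[[1L]]$genes, state$sides[[2L]]$genes)
    g <- g[g$alive, c("gene_id", "chrom", "start", "end", "strand")]
    tabA <- tabB <- geneTable("P", g)
    sizesA <- sizesB <- c(state$sides[[1L]]$chromSizes,
                          state$sides[[2L]]$chromSizes)
  } else {
    tabA <- aliveTab(1L, "A"); tabB <- aliveTab(2L, "B")
    sizesA <- state$sides[[1L]]$chromSizes
    sizesB <- state$sides[[2L]]$chromSizes
  }
  idMap <- function(s) {
    g <- state$sides[[s]]$genes
    stats::setNames(g$idx, g$gene_id)
  }
  structure(list(
    mode = state$mode, tableA = tabA, tableB = tabB,
    sizesA = sizesA, sizesB = sizesB, pairs = pairs,
    truth = list(events = state$events, config = cfg,
                 pair_status = state$pairStatus,
                 anc_chrom = state$ancChrom,
                 id_to_idx = list(idMap(1L), idMap(2L)))),
    class = "SimResult")
}

#' Simulate a complete genome pair with ground truth
#'
#' Runs [simulateAncestor()], [applyEvent()], [applyLoss()] and
#' [applyRearrangements()] under one seed, adds any configured noise
#' anchors, and packages the pipeline-ready inputs.
#'
#' @param config a [simConfig()].
#' @return list of class `SimResult` with `mode` (`"cross"`/`"self"`),
#'   `tableA`, `tableB` ([GeneTable-class]s; identical for `"self"`),
#'   `sizesA`, `sizesB`, `pairs` (anchor table with cohort labels) and
#'   `truth` (the event log and id maps).
#' @export
simulateGenomePair <- function(config) {
  anc <- simulateAncestor(config)
  state <- applyEvent(anc, config)
  state <- applyLoss(state, config)
  state <- applyRearrangements(state)
  state <- .addNoiseAnchors(state)
  res <- .finalizeSim(state)
  res$truth$ancestor <- anc
  res
}

#' @export
print.SimResult <- function(x, ...) {
  cat(sprintf(
    "SimResult (%s): %d + %d genes, %d anchor pairs, %d logged events\n",
    x$mode, geneCount(x$tableA), geneCount(x$tableB), nrow(x$pairs),
    length(x$truth$events)))
  invisible(x)
}

#' Replay a truth log against the ancestor
#'
#' Folds the logged mutation events over a freshly constructed duplicated
#' ancestor, without drawing any random numbers, and returns the resulting
#' gene tables and chromosome sizes. Matching the emitted genomes exactly is
#' the completeness check of the log.
#'
#' @param truth the `truth` element of a `SimResult`.
#' @return list with `tableA`, `tableB`, `sizesA`, `sizesB`.
#' @export
replayTruthLog <- function(truth) {
  state <- .initSides(truth$ancestor, truth$config)
  for (ev in truth$events) {
    state <- switch(ev$op,
      excision = .simExcise(state, ev$side, ev$gene_ids, ev$residual),
      pseudogenization = .simPseudogenize(state, ev$side, ev$gene_ids),
      inversion = .simInvert(state, ev$side, ev$chrom, ev$seg_start,
                             ev$seg_end),
      translocation = .simTranslocate(state, ev$side, ev$gene_id,
                                      ev$dest_chrom, ev$dest_after_gene,
                                      ev$gap_offset),
      .stopf("unknown event op '%s'", ev$op))
  }
  state$pairs <- data.frame(gene_a = character(), gene_b = character(),
                            similarity = numeric(), idx = integer(),
                            cohort = character())
  out <- .finalizeSim(state)
  list(tableA = out$tableA, tableB = out$tableB,
       sizesA = out$sizesA, sizesB = out$sizesB)
}

#' Write a simulated genome pair as pipeline input files
#'
#' Emits per-genome annotations (GFF3 or BED), assembly-size TSVs, the
#' anchor TSV and the truth log as JSON. Output is byte-stable for a fixed
#' config (seed included).
#'
#' @param sim a `SimResult`.
#' @param dir output directory (created if needed).
#' @param format `"gff3"` or `"bed"`.
#' @return invisibly, the named list of file paths.
#' @export
emitFixture <- function(sim, dir, format = c("gff3", "bed")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tab, stem) {
    p <- file.path(dir, paste0(stem, ".", if (format == "gff3") "gff3" else "bed"))
    if (format == "gff3") writeGff3(tab, p) else writeBed(tab, p)
    p
  }
  paths <- list()
  if (sim$mode == "self") {
    paths$genome <- wr(sim$tableA, "genome")
    paths$sizes <- writeAssemblySizes(sim$sizesA, file.path(dir, "genome.sizes.tsv"))
  } else {
    paths$genome_a <- wr(sim$tableA, "genome_A")
    paths$genome_b <- wr(sim$tableB, "genome_B")
    paths$sizes_a <- writeAssemblySizes(sim$sizesA, file.path(dir, "genome_A.sizes.tsv"))
    paths$sizes_b <- writeAssemblySizes(sim$sizesB, file.path(dir, "genome_B.sizes.tsv"))
  }
  paths$anchors <- writeAnchorPairs(sim$pairs, file.path(dir, "anchors.tsv"))
  truth <- list(config = unclass(sim$truth$config),
                events = sim$truth$events)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths$truth <- file.path(dir, "truth.json")
  invisible(paths)
}
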