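test_that("degenerate length parameters give an exact deterministic layout", {
  cfg <- simConfig(n_genes = 10, n_chromosomes = 1, mean_gene_bp = 3000,
                   mean_intergenic_bp = 5000, sdlog_gene = 0,
                   sdlog_intergenic = 0, seed = 5)
  anc <- simulateAncestor(cfg)
  expect_equal(unname(anc$sizes), 10 * 3000 + 11 * 5000)   # 85,000
  expect_equal(anc$genes$start[1], 5000)
  expect_equal(anc$genes$end - anc$genes$start, rep(3000, 10))
  anc2 <- simulateAncestor(cfg)
  expect_identical(anc$genes, anc2$genes)                  # same seed, same genome
})

test_that("ancestral length distributions hit their configured means", {
  cfg <- simConfig(n_genes = 10000, n_chromosomes = 4, seed = 6)
  anc <- simulateAncestor(cfg)
  expect_lt(abs(mean(anc$genes$len) - 3000) / 3000, 0.02)
  gaps <- sum(anc$sizes) - sum(anc$genes$len)
  expect_lt(abs(gaps / (10000 + 4) - 5000) / 5000, 0.02)
})

test_that("speciation and WGD events produce the right pair structure", {
  cfg <- simConfig(n_genes = 200, n_chromosomes = 2, loss_fraction = 0,
                   seed = 8)
  st <- applyEvent(simulateAncestor(cfg), cfg)
  expect_equal(sum(st$pairs$cohort == "recent"), 200L)
  expect_equal(st$mode, "cross")

  cfgW <- simConfig(n_genes = 200, n_chromosomes = 2, event = "wgd",
                    loss_fraction = 0, seed = 8)
  simW <- simulateGenomePair(cfgW)
  expect_equal(geneCount(simW$tableA), 400L)               # doubled complement
  expect_equal(simW$mode, "self")

  cfgO <- simConfig(n_genes = 1000, n_chromosomes = 2, loss_fraction = 0,
                    old_pair_fraction = 0.2, seed = 9)
  stO <- applyEvent(simulateAncestor(cfgO), cfgO)
  nOld <- sum(stO$pairs$cohort == "old")
  expect_gt(nOld, 0.15 * 1000)
  expect_lte(nOld, 0.25 * 1000)
  expect_lt(abs(mean(stO$pairs$similarity[stO$pairs$cohort == "old"]) - 75), 1)
})

test_that("zero loss leaves the genomes untouched with an empty log", {
  cfg <- simConfig(n_genes = 300, n_chromosomes = 1, loss_fraction = 0,
                   seed = 10)
  sim <- simulateGenomePair(cfg)
  expect_length(sim$truth$events, 0L)
  expect_equal(geneCount(sim$tableA), 300L)
  expect_equal(geneCount(sim$tableB), 300L)
  expect_equal(nrow(sim$pairs), 300L)
})

test_that("pseudogenization conserves chromosome lengths, excision shrinks them", {
  base <- simConfig(n_genes = 1000, n_chromosomes = 2, seed = 12,
                    mechanism = "pseudogenization")
  simP <- simulateGenomePair(base)
  anc <- simulateAncestor(base)
  expect_equal(unname(simP$sizesA), unname(anc$sizes))
  expect_equal(unname(simP$sizesB), unname(anc$sizes))
  expect_lt(geneCount(simP$tableA) + geneCount(simP$tableB), 2000L)

  cfgE <- simConfig(n_genes = 1000, n_chromosomes = 2, seed = 12)
  simE <- simulateGenomePair(cfgE)
  expect_lt(sum(simE$sizesA) + sum(simE$sizesB), 2 * sum(anc$sizes))
})

test_that("per-event excision residues average to the configured mean", {
  sim <- fixture("residuals", function()
    simulateGenomePair(simConfig(n_genes = 8000, n_chromosomes = 2,
                                 loss_fraction = 0.4, seed = 13)))
  res <- vapply(sim$truth$events, function(e)
    if (e$op == "excision") e$residual else NA_real_, numeric(1))
  res <- res[!is.na(res)]
  expect_gt(length(res), 1000L)
  expect_lt(abs(mean(res) - 400) / 400, 0.10)
})

test_that("loss never removes both members of a pair", {
  sim <- smallExcisionSim()
  lostSides <- lapply(sim$truth$events, function(e)
    if (e$op %in% c("excision", "pseudogenization"))
      data.frame(idx = e$idx, side = e$side) else NULL)
  lost <- do.call(rbind, lostSides)
  expect_equal(anyDuplicated(lost$idx), 0L)
  # every lost gene's partner is still annotated
  surv <- ifelse(lost$side == 1L, 2L, 1L)
  id1 <- sim$truth$id_to_idx[[1L]]; id2 <- sim$truth$id_to_idx[[2L]]
  partnerIds <- ifelse(surv == 1L,
                       names(id1)[match(lost$idx, id1)],
                       names(id2)[match(lost$idx, id2)])
  present <- c(geneRecords(sim$tableA)$gene_id, geneRecords(sim$tableB)$gene_id)
  expect_true(all(partnerIds %in% present))
})

test_that("inversions reverse a segment's order and are recovered by chaining", {
  cfg <- simConfig(n_genes = 400, n_chromosomes = 1, loss_fraction = 0,
                   n_inversions = 1, inversion_len_range = c(10L, 10L),
                   seed = 18)
  sim <- simulateGenomePair(cfg)
  ev <- sim$truth$events[[1L]]
  expect_equal(ev$op, "inversion")
  expect_length(ev$gene_ids, 10L)
  tab <- if (ev$side == 1L) sim$tableA else sim$tableB
  g <- geneRecords(tab)
  ranks <- g$rank[match(ev$gene_ids, g$gene_id)]
  expect_equal(ranks, rev(sort(ranks)))       # reversed order, same slots
  # everything outside the segment keeps its coordinates (the other genome
  # is an untouched copy here, so it serves as the reference layout)
  other <- if (ev$side == 1L) sim$tableB else sim$tableA
  og <- geneRecords(other)
  outside <- !g$gene_id %in% ev$gene_ids
  ref <- match(sub("^[AB]_", "", g$gene_id[outside]),
               sub("^[AB]_", "", og$gene_id))
  expect_equal(g$start[outside], og$start[ref])
  # the inverted segment occupies the same span, lengths preserved
  seg <- match(ev$gene_ids, g$gene_id)
  refSeg <- match(sub("^[AB]_", "", ev$gene_ids), sub("^[AB]_", "", og$gene_id))
  expect_equal(range(c(g$start[seg], g$end[seg])),
               range(c(og$start[refSeg], og$end[refSeg])))
  expect_setequal(g$end[seg] - g$start[seg], og$end[refSeg] - og$start[refSeg])

  simBig <- fixture("inverted20", function()
    simulateGenomePair(simConfig(n_genes = 8000, n_chromosomes = 2,
                                 loss_fraction = 0, n_inversions = 20,
                                 seed = 15)))
  bs <- chainAnchors(anchorPairs(simBig$pairs), simBig$tableA, simBig$tableB)
  expect_gte(nrow(blockAnchors(bs)) / nrow(simBig$pairs), 0.95)
})

test_that("replaying the truth log reconstructs the emitted genomes exactly", {
  for (sim in list(smallExcisionSim(), smallPseudoSim(),
                   fixture("messy", function()
                     simulateGenomePair(simConfig(n_genes = 1500,
                                                  n_chromosomes = 2,
                                                  mechanism = "mixed",
                                                  n_inversions = 5,
                                                  n_translocations = 5,
                                                  seed = 16))))) {
    rp <- replayTruthLog(sim$truth)
    expect_identical(geneRecords(rp$tableA), geneRecords(sim$tableA))
    expect_identical(geneRecords(rp$tableB), geneRecords(sim$tableB))
    expect_identical(rp$sizesA, sim$sizesA)
    expect_identical(rp$sizesB, sim$sizesB)
  }
})

test_that("fixture files round-trip and are byte-stable under the seed", {
  cfg <- simConfig(n_genes = 300, n_chromosomes = 2, seed = 17,
                   n_noise_anchors = 10)
  sim <- simulateGenomePair(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- emitFixture(sim, d1)
  p2 <- emitFixture(simulateGenomePair(cfg), d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     info = nm)
  }
  tabA <- readGff3(p1$genome_a, genomeId = "A")
  expect_equal(geneRecords(tabA), geneRecords(sim$tableA))
  prs <- readAnchorPairs(p1$anchors)
  expect_equal(nrow(prs), nrow(anchorPairs(sim$pairs)))
  sz <- readAssemblySizes(p1$sizes_a)
  expect_equal(sz[names(sim$sizesA)], sim$sizesA)

  simBed <- emitFixture(sim, withr::local_tempdir(), format = "bed")
  expect_equal(geneRecords(readBed(simBed$genome_a, genomeId = "A")),
               geneRecords(sim$tableA))
})

test_that("an impossible loss fraction is rejected rather than looping", {
  expect_error(simConfig(loss_fraction = 1.2), "loss_fraction")
})
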