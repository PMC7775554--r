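# a hand-built two-block scene:
# side A keeps all 12 genes; side B lost genes 4-6 (three singletons on A)
handScene <- function() {
  ta <- evenTable("A", 12, step = 10000, glen = 3000)
  idsB <- sprintf("B_g%02d", c(1:3, 7:12))
  k <- seq_along(idsB) - 1L
  tb <- geneTable("B", data.frame(gene_id = idsB, chrom = "chr1",
                                  start = k * 10000 + 10000,
                                  end = k * 10000 + 13000))
  p <- data.frame(gene_a = geneRecords(ta)$gene_id[c(1:3, 7:12)],
                  gene_b = idsB, similarity = 92)
  list(ta = ta, tb = tb, pairs = p)
}

test_that("a one-sided gap becomes a deletion interval with the right length", {
  sc <- handScene()
  bs <- chainAnchors(sc$pairs, sc$ta, sc$tb, maxGap = 10, minBlockSize = 5)
  iv <- scanDeletionIntervals(bs, sc$ta, sc$tb, allPairs = sc$pairs)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$length, 3L)
  expect_equal(iv$fractionated_genome, "B")
  expect_equal(iv$nonanchor_genes_in_gap, 0L)
  # unfractionated span: end of gene 3 (A) to start of gene 7 (A)
  ga <- geneRecords(sc$ta)
  expect_equal(iv$bp_unfractionated, ga$start[7] - ga$end[3])
  # fractionated span on B: consecutive genes, one intergenic stretch
  gb <- geneRecords(sc$tb)
  expect_equal(iv$bp_fractionated, gb$start[4] - gb$end[3])
})

test_that("gaps with genes on both sides or neither side emit nothing", {
  ta <- evenTable("A", 10); tb <- evenTable("B", 10)
  # anchors at 1:3 and 6:8 on both sides: both sides have genes 4,5 between
  p <- data.frame(gene_a = geneRecords(ta)$gene_id[c(1:3, 6:8)],
                  gene_b = geneRecords(tb)$gene_id[c(1:3, 6:8)],
                  similarity = 92)
  bs <- chainAnchors(p, ta, tb, maxGap = 10, minBlockSize = 6)
  expect_equal(nrow(scanDeletionIntervals(bs, ta, tb, allPairs = p)), 0L)
  # fully dense anchors: no gap at all
  p2 <- data.frame(gene_a = geneRecords(ta)$gene_id[1:6],
                   gene_b = geneRecords(tb)$gene_id[1:6], similarity = 92)
  bs2 <- chainAnchors(p2, ta, tb, maxGap = 10, minBlockSize = 6)
  expect_equal(nrow(scanDeletionIntervals(bs2, ta, tb, allPairs = p2)), 0L)
})

test_that("unpaired genes on the fractionated side are tallied, not fatal", {
  sc <- handScene()
  # add an annotated-but-unpaired gene on B inside the gap
  gb <- geneRecords(sc$tb)
  gb <- rbind(gb[, 1:5],
              data.frame(gene_id = "B_orphan", chrom = "chr1",
                         start = 31000, end = 31800, strand = "unknown"))
  tb2 <- geneTable("B", gb)
  # one A-side singleton is remotely paired, so side A is positively
  # visible to the homology screen while side B's gap gene is not
  pairs2 <- rbind(sc$pairs,
                  data.frame(gene_a = geneRecords(sc$ta)$gene_id[4],
                             gene_b = "B_g12", similarity = 76))
  bs <- chainAnchors(pairs2, sc$ta, tb2, maxGap = 10, minBlockSize = 5)
  iv <- scanDeletionIntervals(bs, sc$ta, tb2, allPairs = pairs2)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$nonanchor_genes_in_gap, 1L)
  ivStrict <- scanDeletionIntervals(bs, sc$ta, tb2, allPairs = pairs2,
                                    strict = TRUE)
  expect_equal(nrow(ivStrict), 0L)
})

test_that("span measurement handles plain, inverted and overlapping anchors", {
  mk <- function(s1, e1, s2, e2, id1 = "x1", id2 = "x2") {
    geneTable("T", data.frame(gene_id = c(id1, id2), chrom = "c",
                              start = c(s1, s2), end = c(e1, e2)))
  }
  tA <- mk(8000, 10000, 18500, 20000)
  sp <- measureSpans(tA, tA, "x1", "x2", "x1", "x2")
  expect_equal(sp$bp_a, 8500)

  # inverted orientation: the later-start gene comes first in the block
  tB <- mk(40000, 41500, 50000, 52000)
  sp2 <- measureSpans(tB, tB, "x2", "x1", "x2", "x1")
  expect_equal(sp2$bp_b, 8500)

  tC <- mk(1000, 5000, 4000, 9000)       # overlapping bounding genes
  sp3 <- measureSpans(tC, tC, "x1", "x2", "x1", "x2")
  expect_equal(sp3$bp_a, 0)
  expect_true(sp3$clamped_a)

  tD <- geneTable("T", data.frame(gene_id = c("x1", "x2"),
                                  chrom = c("c1", "c2"),
                                  start = c(0, 0), end = c(10, 10)))
  expect_error(measureSpans(tD, tD, "x1", "x2", "x1", "x2"),
               "different chromosomes")
})

test_that("profiles aggregate per exact length with preserved raw list", {
  iv <- data.frame(length = c(2L, 2L, 5L),
                   bp_unfractionated = c(16000, 20000, 40000),
                   bp_fractionated = c(100, 300, 50),
                   fractionated_genome = "B")
  pr <- aggregateProfile(iv)
  expect_equal(pr$per_length$mean_bp_fractionated[pr$per_length$length == 2],
               200)
  expect_equal(sum(pr$per_length$n), 3L)
  expect_identical(pr$intervals, iv)
  expect_equal(nrow(aggregateProfile(iv[0, ])$per_length), 0L)
})

test_that("pseudogene capacity is residual DNA per mean gene length", {
  iv <- data.frame(length = c(1L, 2L), bp_fractionated = c(300, 0),
                   bp_unfractionated = c(9000, 17000))
  pc <- pseudogeneCapacity(iv, 3000)
  expect_equal(pc$capacity, c(0.1, 0))
  expect_equal(pc$bp_per_missing_gene, c(300, 0))
  expect_error(pseudogeneCapacity(iv, 0), "> 0")
})

test_that("capacity approaches L under pseudogenization, stays low under excision", {
  simP <- smallPseudoSim()
  repP <- runSmallPipeline(simP)
  pcP <- pseudogeneCapacity(repP$intervals, simP$truth$config$mean_gene_bp)
  # DNA retained: room for roughly L full-length pseudogenes per interval,
  # plus the L+1 intergenic stretches between them
  scale <- (simP$truth$config$mean_gene_bp + simP$truth$config$mean_intergenic_bp) /
    simP$truth$config$mean_gene_bp
  byL <- tapply(pcP$capacity, pcP$length, mean)
  L <- as.numeric(names(byL))
  expect_true(all(abs(byL[L <= 5] / (scale * L[L <= 5] + 5/3) - 1) < 0.35))

  simE <- smallExcisionSim()
  repE <- runSmallPipeline(simE)
  pcE <- pseudogeneCapacity(repE$intervals, simE$truth$config$mean_gene_bp)
  expect_lt(mean(pcE$capacity), 0.5)
})

test_that("interval spans conserve at least the singleton gene lengths", {
  sim <- smallExcisionSim()
  rep <- runSmallPipeline(sim)
  iv <- rep$intervals
  # look the singleton genes up and compare their summed lengths to the span
  for (side in c("A", "B")) {
    sg <- collectSingletons(iv, sim$tableA, sim$tableB, side = side)
    tab <- if (side == "A") sim$tableA else sim$tableB
    g <- geneRecords(tab)
    lens <- stats::setNames(g$end - g$start, g$gene_id)
    sub <- iv[iv$fractionated_genome == (if (side == "A") "B" else "A"), ]
    rk <- g$rank; names(rk) <- g$gene_id
    for (i in seq_len(nrow(sub))) {
      if (side == "A") {
        ranks <- (sub$rank_left_a[i] + 1L):(sub$rank_right_a[i] - 1L)
        ids <- geneAt(tab, sub$chrom_a[i], ranks)
      } else {
        ranks <- (sub$rank_lo_b[i] + 1L):(sub$rank_hi_b[i] - 1L)
        ids <- geneAt(tab, sub$chrom_b[i], ranks)
      }
      expect_gte(sub$bp_unfractionated[i], sum(lens[ids]))
    }
  }
})

test_that("scan agrees with the simulator truth log on loss-only fixtures", {
  for (sim in list(smallExcisionSim(), smallPseudoSim(),
                   fixture("mixed_small", function()
                     simulateGenomePair(simConfig(n_genes = 2000,
                                                  n_chromosomes = 2,
                                                  mechanism = "mixed",
                                                  seed = 103))),
                   fixture("wgd_small", function()
                     simulateGenomePair(simConfig(n_genes = 2000,
                                                  n_chromosomes = 2,
                                                  event = "wgd",
                                                  seed = 104))))) {
    rep <- runSmallPipeline(sim)
    expect_identical(scanIntervalSignature(rep$intervals, sim),
                     truthIntervalSignature(truthIntervalOracle(sim, rep$blocks)))
  }
})

test_that("excision spans are flat in L while pseudogenized spans track the conserved side", {
  repE <- runSmallPipeline(smallExcisionSim())
  cfg <- smallExcisionSim()$truth$config
  unit <- cfg$mean_gene_bp + cfg$mean_intergenic_bp
  fitF <- fitLinear(intervalPoints(repE$intervals, "fractionated"))
  expect_lt(abs(fitF$slope), 0.05 * unit)
  perE <- aggregateProfile(repE$intervals)$per_length
  sub <- perE[perE$length <= 10 & perE$n >= 5, ]
  expect_lt(max(sub$mean_bp_fractionated), 2 * cfg$residual_mean_bp)

  repP <- runSmallPipeline(smallPseudoSim())
  perP <- aggregateProfile(repP$intervals)$per_length
  subP <- perP[perP$n >= 5, ]
  expect_true(all(abs(subP$mean_bp_fractionated /
                        subP$mean_bp_unfractionated - 1) < 0.15))
})
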