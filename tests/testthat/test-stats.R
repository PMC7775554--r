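test_that("OLS recovers exact lines and matches normal equations by hand", {
  f <- fitLinear(data.frame(L = 1:5, bp = 8000 * (1:5)))
  expect_equal(f$slope, 8000)
  expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)

  fc <- fitLinear(data.frame(L = c(1, 2, 3, 4), bp = c(400, 400, 400, 400)))
  expect_equal(fc$slope, 0)

  # five hand-listed points, slope/intercept from the closed-form normal
  # equations computed independently of lm()
  L <- c(1, 2, 4, 7, 9); bp <- c(9500, 17000, 33500, 60000, 70000)
  slopeHand <- (sum(L * bp) - length(L) * mean(L) * mean(bp)) /
    (sum(L^2) - length(L) * mean(L)^2)
  interceptHand <- mean(bp) - slopeHand * mean(L)
  f2 <- fitLinear(data.frame(L = L, bp = bp))
  expect_equal(f2$slope, slopeHand)
  expect_equal(f2$intercept, interceptHand)

  expect_error(fitLinear(data.frame(L = c(1, 2), bp = c(1, 2))), "3 points")
  expect_error(fitLinear(data.frame(L = c(2, 2, 2), bp = 1:3)), "identical")
})

test_that("length_means mode fits the per-L averages", {
  pts <- data.frame(L = c(1, 1, 2, 2, 3, 3),
                    bp = c(100, 300, 350, 450, 500, 700))
  f <- fitLinear(pts, mode = "length_means")
  fHand <- fitLinear(data.frame(L = 1:3, bp = c(200, 400, 600)))
  expect_equal(f$slope, fHand$slope)
  expect_equal(f$n, 3L)
  # the L cap excludes long intervals from the fit
  pts2 <- rbind(pts, data.frame(L = 50, bp = 1e6))
  expect_equal(fitLinear(pts2, lCap = 30)$slope, fitLinear(pts)$slope)
})

test_that("slope comparison follows the Welch formula and its symmetries", {
  mkFit <- function(slope, se, n = 100) {
    structure(list(slope = slope, intercept = 0, se_slope = se, n = n,
                   df_residual = n - 2, r_squared = 0.5, mode = "raw",
                   l_cap = 30), class = "RegressionFit")
  }
  same <- compareSlopes(mkFit(8000, 100), mkFit(8000, 100))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  cmp <- compareSlopes(mkFit(8000, 100), mkFit(0, 50))
  expect_equal(cmp$t_statistic, 8000 / sqrt(100^2 + 50^2), tolerance = 1e-12)
  expect_equal(cmp$t_statistic, 71.55, tolerance = 1e-3)

  rev <- compareSlopes(mkFit(0, 50), mkFit(8000, 100))
  expect_equal(rev$t_statistic, -cmp$t_statistic)
  expect_equal(rev$p_value, cmp$p_value)

  degSame <- compareSlopes(mkFit(5, 0), mkFit(5, 0))
  expect_equal(degSame$t_statistic, 0); expect_equal(degSame$p_value, 1)
  degDiff <- compareSlopes(mkFit(5, 0), mkFit(4, 0))
  expect_equal(degDiff$p_value, 0)
  expect_true(degDiff$degenerate)
})

test_that("slope recovery within 3 SEs under generated noise", {
  set.seed(1234)
  for (a in c(0, 8000)) {
    for (r in 1:5) {
      L <- sample(1:20, 400, replace = TRUE)
      bp <- a * L + rnorm(400, 0, 2000)
      f <- fitLinear(data.frame(L = L, bp = bp))
      expect_lt(abs(f$slope - a), 3 * f$se_slope + 1e-9)
    }
  }
})

test_that("excision fixtures give a very significant slope difference", {
  rep <- runSmallPipeline(smallExcisionSim())
  for (g in c("A", "B")) {
    expect_lt(rep$fits[[g]]$comparison$p_value, 1e-6)
    expect_gt(rep$fits[[g]]$comparison$t_statistic, 0)
  }
})

test_that("genome size factor is a plain ratio on the chosen basis", {
  sBig <- new("GenomeSummary", genomeId = "big", totalBp = 2e9,
              geneCount = 40000L, bpPerGene = 2e9 / 40000)
  sSmall <- new("GenomeSummary", genomeId = "small", totalBp = 5e8,
                geneCount = 30000L, bpPerGene = 5e8 / 30000)
  sEq <- new("GenomeSummary", genomeId = "eq", totalBp = 2e9,
             geneCount = 40000L, bpPerGene = 2e9 / 40000)
  expect_equal(genomeSizeFactor(sBig, sEq), 1)
  expect_equal(genomeSizeFactor(sBig, sSmall, basis = "total_bp"), 4)
  expect_equal(genomeSizeFactor(sBig, sSmall, basis = "bp_per_gene"), 3)
})

test_that("profile normalization scales spans and inverts exactly", {
  iv <- data.frame(length = c(1L, 2L, 2L),
                   bp_unfractionated = c(8000, 16000, 18000),
                   bp_fractionated = c(400, 100, 900),
                   fractionated_genome = "B")
  pr <- aggregateProfile(iv)
  expect_equal(normalizeProfile(pr, 1)$per_length, pr$per_length)
  q <- normalizeProfile(pr, 4)
  expect_equal(q$per_length$mean_bp_unfractionated,
               pr$per_length$mean_bp_unfractionated / 4)
  back <- normalizeProfile(q, 1 / 4)
  expect_equal(back$per_length, pr$per_length)
  expect_error(normalizeProfile(pr, 0), "> 0")
})

test_that("normalization reconciles a 4x intergenic genome pair", {
  sim <- fixture("bigB", function()
    simulateGenomePair(simConfig(n_genes = 3000, n_chromosomes = 2,
                                 intergenic_scale_b = 4, seed = 41)))
  rep <- runSmallPipeline(sim)
  slopeA <- rep$fits$B$unfractionated$slope   # conserved side of genome A
  slopeB <- rep$fits$A$unfractionated$slope   # conserved side of genome B
  f <- genomeSizeFactor(rep$summaryB, rep$summaryA, basis = "bp_per_gene")
  expect_gt(slopeB / slopeA, 2)               # before normalization: far apart
  expect_lt(abs(slopeB / f / slopeA - 1), 0.10)
})

test_that("density points sit on the diagonal for homogeneous genomes", {
  # spec'd single-interval arithmetic: the ratio estimator is exact
  iv <- data.frame(length = 4L, bp_unfractionated = 32000,
                   bp_fractionated = 0, fractionated_genome = "B")
  sA <- new("GenomeSummary", genomeId = "A", totalBp = 8e8,
            geneCount = 100000L, bpPerGene = 8000)
  d <- densityComparison(iv, sA, estimator = "ratio")
  expect_equal(d$bp_per_gene_in_blocks, d$bp_per_gene_genomewide)

  rep <- runSmallPipeline(smallExcisionSim())
  d2 <- densityComparison(rep$intervals, rep$summaryA, rep$summaryB)
  expect_true(all(abs(d2$bp_per_gene_in_blocks /
                        d2$bp_per_gene_genomewide - 1) < 0.10))
})

test_that("gene-dense block regions pull points off the diagonal upward in bp terms", {
  # conserved regions twice as gene-dense as the genome average: the
  # in-block bp/gene should fall clearly below the genome-wide value
  set.seed(77)
  nb <- 400
  L <- sample(1:10, nb, replace = TRUE)
  denseUnit <- 4000                       # bp per gene inside blocks
  iv <- data.frame(length = L,
                   bp_unfractionated = denseUnit * L + rnorm(nb, 0, 500),
                   bp_fractionated = 0, fractionated_genome = "B")
  sA <- new("GenomeSummary", genomeId = "A", totalBp = 8e8,
            geneCount = 100000L, bpPerGene = 8000)
  sB <- new("GenomeSummary", genomeId = "B", totalBp = 8e8,
            geneCount = 100000L, bpPerGene = 8000)
  d <- densityComparison(iv, sA, sB)
  dA <- d[d$genome_id == "A", ]
  expect_lt(dA$bp_per_gene_in_blocks, 0.7 * dA$bp_per_gene_genomewide)
})
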