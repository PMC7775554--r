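# Regressions of DNA span on interval length and their comparison.
#
# The unfractionated span of an interval of length L is expected to grow
# linearly in L with slope equal to the mean gene-plus-intergenic size (the
# inverse of the local gene density). Under excision the fractionated span
# is flat near the per-event residual; under pseudogenization it grows like
# the unfractionated one. Welch's unpooled t-test compares the two slopes.

#' Extract (L, bp) regression points from deletion intervals
#'
#' @param intervals data.frame from [scanDeletionIntervals()].
#' @param side which span to take: the conserved (`"unfractionated"`) or the
#'   reduced (`"fractionated"`) side.
#' @param fractionatedGenome optionally restrict to intervals whose
#'   fractionated side is `"A"` or `"B"` (i.e. analyze the losses of one
#'   genome of a cross-comparison separately).
#' @return data.frame with columns `L` and `bp`.
#' @export
intervalPoints <- function(intervals,
                           side = c("unfractionated", "fractionated"),
                           fractionatedGenome = NULL) {
  side <- match.arg(side)
  if (!is.null(fractionatedGenome))
    intervals <- intervals[intervals$fractionated_genome %in% fractionatedGenome, ,
                           drop = FALSE]
  data.frame(L = intervals$length,
             bp = if (side == "unfractionated") intervals$bp_unfractionated
                  else intervals$bp_fractionated)
}

#' Ordinary least squares fit of bp against interval length
#'
#' `mode = "raw"` (default) fits every interval as one point, giving honest
#' standard errors; `mode = "length_means"` first averages bp within each
#' exact length and fits the per-L means, the quantity shown in the classic
#' profile plots. Lengths beyond `lCap` (default 30) are excluded from the
#' fit because long intervals are few and their means fluctuate wildly; the
#' points remain available in the data.
#'
#' @param points data.frame with columns `L` and `bp` (see
#'   [intervalPoints()]), or an `IntervalProfile` whose raw intervals are
#'   used via the unfractionated side.
#' @param mode `"raw"` or `"length_means"`.
#' @param lCap maximum L included in the fit; `Inf` disables the cap.
#' @return A `RegressionFit`: list with `slope` (bp per gene), `intercept`
#'   (bp), `se_slope`, `n`, `df_residual`, `r_squared`, `mode`, `l_cap`.
#' @examples
#' fitLinear(data.frame(L = 1:5, bp = 8000 * (1:5)))$slope  # 8000
#' @export
fitLinear <- function(points, mode = c("raw", "length_means"), lCap = 30) {
  mode <- match.arg(mode)
  .checkScalarNum(lCap, "lCap", 1)
  pts <- as.data.frame(points)[, c("L", "bp")]
  pts <- pts[is.finite(pts$L) & is.finite(pts$bp) & pts$L <= lCap, , drop = FALSE]
  if (mode == "length_means") {
    sp <- split(pts$bp, pts$L)
    pts <- data.frame(L = as.numeric(names(sp)),
                      bp = vapply(sp, mean, numeric(1L)))
  }
  if (nrow(pts) < 3L) .stopf("need at least 3 points for a regression fit")
  if (length(unique(pts$L)) < 2L)
    .stopf("all interval lengths identical; slope undefined")
  fit <- lm(bp ~ L, data = pts)
  sm <- suppressWarnings(summary(fit))   # exact fits are valid input here
  structure(list(
    slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
    se_slope = unname(sm$coefficients[2L, 2L]),
    n = nrow(pts), df_residual = fit$df.residual,
    r_squared = sm$r.squared, mode = mode, l_cap = lCap),
    class = "RegressionFit")
}

#' @export
print.RegressionFit <- function(x, ...) {
  cat(sprintf(
    "RegressionFit (%s, L <= %g): slope %.1f +/- %.1f bp/gene, intercept %.1f bp, n = %d, R^2 = %.3f\n",
    x$mode, x$l_cap, x$slope, x$se_slope, x$intercept, x$n, x$r_squared))
  invisible(x)
}

#' Welch t-test for the difference of two regression slopes
#'
#' `t = (slope1 - slope2) / sqrt(se1^2 + se2^2)` with Welch-Satterthwaite
#' degrees of freedom from the two fits' residual degrees of freedom, and a
#' two-sided p-value. Variances are not pooled: the unfractionated and
#' fractionated spans have visibly unequal scatter.
#'
#' @param fit1,fit2 `RegressionFit` objects from [fitLinear()].
#' @return A `SlopeComparison`: list with `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `slope_difference` and a `degenerate`
#'   flag (set when both standard errors are zero).
#' @export
compareSlopes <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "RegressionFit"), inherits(fit2, "RegressionFit"))
  d <- fit1$slope - fit2$slope
  v1 <- fit1$se_slope^2; v2 <- fit2$se_slope^2
  degenerate <- FALSE
  if (v1 + v2 == 0) {
    degenerate <- d != 0
    t <- if (d == 0) 0 else Inf * sign(d)
    p <- if (d == 0) 1 else 0
    df <- fit1$df_residual + fit2$df_residual
  } else {
    t <- d / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / fit1$df_residual + v2^2 / fit2$df_residual)
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(t_statistic = t, degrees_of_freedom = df, p_value = p,
                 slope_difference = d, degenerate = degenerate),
            class = "SlopeComparison")
}

#' @export
print.SlopeComparison <- function(x, ...) {
  cat(sprintf("SlopeComparison: t = %.3f, df = %.1f, p = %.3g%s\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value,
              if (x$degenerate) " (degenerate: zero SEs, unequal slopes)" else ""))
  invisible(x)
}

#' Genome-size normalization factor
#'
#' Ratio of the larger to the smaller genome on the chosen basis. The
#' default basis is bp-per-gene, which corrects the span comparison of two
#' genomes whose intergenic spacing differs (a large genome's conserved
#' intervals carry proportionally more DNA per gene).
#'
#' @param summaryBig,summarySmall [GenomeSummary-class] objects.
#' @param basis `"bp_per_gene"` (default) or `"total_bp"`.
#' @return a single positive number.
#' @export
genomeSizeFactor <- function(summaryBig, summarySmall,
                             basis = c("bp_per_gene", "total_bp")) {
  basis <- match.arg(basis)
  if (basis == "total_bp") summaryBig@totalBp / summarySmall@totalBp
  else summaryBig@bpPerGene / summarySmall@bpPerGene
}

#' Rescale the DNA spans of an interval profile
#'
#' Divides bp values by `factor`, leaving interval lengths untouched; used
#' to bring a disproportionately large genome onto the scale of its partner
#' before comparing profiles. Applying `factor` and then `1/factor` is the
#' identity.
#'
#' @param profile an `IntervalProfile` from [aggregateProfile()].
#' @param factor positive scale factor.
#' @param side which spans to rescale (default both).
#' @return the rescaled `IntervalProfile`.
#' @export
normalizeProfile <- function(profile, factor,
                             side = c("both", "unfractionated", "fractionated")) {
  side <- match.arg(side)
  .checkScalarNum(factor, "factor")
  if (factor <= 0) .stopf("normalization factor must be > 0")
  iv <- profile$intervals
  if (side %in% c("both", "unfractionated")) {
    iv$bp_unfractionated <- iv$bp_unfractionated / factor
  }
  if (side %in% c("both", "fractionated")) {
    iv$bp_fractionated <- iv$bp_fractionated / factor
  }
  aggregateProfile(iv)
}

#' Compare in-block gene density with the genome-wide density
#'
#' For each genome, estimates bp-per-gene inside the conserved
#' (unfractionated) intervals and pairs it with the genome-wide bp-per-gene;
#' equal densities put a point on the diagonal. The default estimator is the
#' regression slope of bp against L, the inverse-density of the intervals;
#' `estimator = "ratio"` uses the raw total `sum(bp) / sum(L)`, which is
#' upward-biased by one boundary intergenic stretch per interval (an
#' interval of L genes spans L+1 intergenic gaps).
#'
#' @param intervals data.frame from [scanDeletionIntervals()].
#' @param summaryA [GenomeSummary-class] of side A.
#' @param summaryB optional [GenomeSummary-class] of side B; omit for a
#'   self-comparison, where both sides are the same genome.
#' @param estimator `"slope"` (default) or `"ratio"`.
#' @param lCap passed to [fitLinear()] for the slope estimator.
#' @return data.frame with `genome_id`, `bp_per_gene_in_blocks`,
#'   `bp_per_gene_genomewide`.
#' @export
densityComparison <- function(intervals, summaryA, summaryB = NULL,
                              estimator = c("slope", "ratio"), lCap = 30) {
  estimator <- match.arg(estimator)
  est <- function(iv) {
    if (nrow(iv) == 0L) return(NA_real_)
    if (estimator == "ratio") sum(iv$bp_unfractionated) / sum(iv$length)
    else fitLinear(data.frame(L = iv$length, bp = iv$bp_unfractionated),
                   mode = "raw", lCap = lCap)$slope
  }
  if (is.null(summaryB)) {
    return(data.frame(genome_id = summaryA@genomeId,
                      bp_per_gene_in_blocks = est(intervals),
                      bp_per_gene_genomewide = summaryA@bpPerGene,
                      stringsAsFactors = FALSE))
  }
  # a genome's conserved intervals are those where the *other* side lost
  rows <- list(
    data.frame(genome_id = summaryA@genomeId,
               bp_per_gene_in_blocks =
                 est(intervals[intervals$fractionated_genome == "B", , drop = FALSE]),
               bp_per_gene_genomewide = summaryA@bpPerGene,
               stringsAsFactors = FALSE),
    data.frame(genome_id = summaryB@genomeId,
               bp_per_gene_in_blocks =
                 est(intervals[intervals$fractionated_genome == "A", , drop = FALSE]),
               bp_per_gene_genomewide = summaryB@bpPerGene,
               stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
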