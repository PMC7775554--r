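# Optional ggplot2 figures; the package computes everything without them.

.needGgplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    .stopf("plotting requires the ggplot2 package")
}

#' Plot an interval profile (per-length mean spans and fits)
#'
#' Per-length mean DNA span on the unfractionated and fractionated sides
#' against interval length, with the fitted regression lines if supplied.
#'
#' @param profile an `IntervalProfile` from [aggregateProfile()].
#' @param fits optional list with `unfractionated` and `fractionated`
#'   `RegressionFit` objects.
#' @return a ggplot object.
#' @export
plotIntervalProfile <- function(profile, fits = NULL) {
  .needGgplot()
  per <- profile$per_length
  d <- rbind(
    data.frame(length = per$length, bp = per$mean_bp_unfractionated,
               side = "unfractionated"),
    data.frame(length = per$length, bp = per$mean_bp_fractionated,
               side = "fractionated"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$length, y = .data$bp,
                                       colour = .data$side)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "interval length (genes)", y = "mean DNA span (bp)")
  if (!is.null(fits)) {
    for (s in c("unfractionated", "fractionated")) {
      f <- fits[[s]]
      if (!is.null(f))
        p <- p + ggplot2::geom_abline(slope = f$slope, intercept = f$intercept,
                                      linetype = "dashed")
    }
  }
  p
}

#' Plot in-block versus genome-wide gene density
#'
#' One point per genome; the diagonal marks equality of the two densities.
#'
#' @param density data.frame from [densityComparison()].
#' @return a ggplot object.
#' @export
plotDensityComparison <- function(density) {
  .needGgplot()
  ggplot2::ggplot(density,
                  ggplot2::aes(x = .data$bp_per_gene_genomewide,
                               y = .data$bp_per_gene_in_blocks,
                               label = .data$genome_id)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8) +
    ggplot2::labs(x = "genome-wide bp per gene",
                  y = "bp per gene in conserved intervals")
}
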