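#' Read homologous anchor pairs
#'
#' Tab-separated dialect `gene_a<TAB>gene_b<TAB>similarity` with `#` comment
#' lines; an optional header row (`gene_a  gene_b  similarity`) is detected
#' and skipped. Similarity is percent identity in `[0, 100]`. Duplicate rows
#' for the same unordered pair are collapsed keeping the maximum similarity.
#'
#' @param path path to the anchor TSV.
#' @param self logical; in self-comparison mode a pair of a gene with itself
#'   is an error.
#' @return data.frame with columns `gene_a`, `gene_b`, `similarity`.
#' @export
readAnchorPairs <- function(path, self = FALSE) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & lines != ""]
  if (length(lines) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      similarity = numeric()))
  f1 <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(f1) >= 3L && is.na(suppressWarnings(as.numeric(f1[3L]))))
    lines <- lines[-1L]                 # header row
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    .stopf("anchor TSV: fewer than 3 columns at data line %d", which(nf < 3L)[1L])
  m <- matrix(unlist(lapply(parts, `[`, 1:3)), ncol = 3L, byrow = TRUE)
  sim <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(sim)) .stopf("anchor TSV: non-numeric similarity")
  if (any(sim < 0 | sim > 100)) .stopf("similarity outside [0, 100]")
  pairs <- data.frame(gene_a = m[, 1L], gene_b = m[, 2L], similarity = sim,
                      stringsAsFactors = FALSE)
  anchorPairs(pairs, self = self)
}

#' Validate and deduplicate an anchor pair table
#'
#' @param pairs data.frame with `gene_a`, `gene_b`, `similarity`.
#' @inheritParams readAnchorPairs
#' @return the validated data.frame (unordered duplicates collapsed, max
#'   similarity kept).
#' @export
anchorPairs <- function(pairs, self = FALSE) {
  pairs <- as.data.frame(pairs)[, c("gene_a", "gene_b", "similarity")]
  pairs$gene_a <- as.character(pairs$gene_a)
  pairs$gene_b <- as.character(pairs$gene_b)
  if (any(pairs$similarity < 0 | pairs$similarity > 100))
    .stopf("similarity outside [0, 100]")
  if (self && any(pairs$gene_a == pairs$gene_b))
    .stopf("self-comparison: gene paired with itself (%s)",
           pairs$gene_a[pairs$gene_a == pairs$gene_b][1L])
  key <- ifelse(pairs$gene_a <= pairs$gene_b,
                paste(pairs$gene_a, pairs$gene_b, sep = "\r"),
                paste(pairs$gene_b, pairs$gene_a, sep = "\r"))
  o <- order(key, -pairs$similarity, method = "radix")
  pairs <- pairs[o, , drop = FALSE][!duplicated(key[o]), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Write anchor pairs in the package TSV dialect
#' @param pairs anchor pair data.frame.
#' @param path output path.
#' @export
writeAnchorPairs <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# gene_a\tgene_b\tsimilarity", con)
  writeLines(sprintf("%s\t%s\t%g", pairs$gene_a, pairs$gene_b,
                     pairs$similarity), con)
  invisible(path)
}

#' Histogram of anchor-pair similarities
#'
#' Counts pairs into bins `[k*w, (k+1)*w)`. Bins between the occupied
#' extremes are kept (with zero counts) so that mode/minimum searches see a
#' contiguous axis.
#'
#' @param pairs anchor pair data.frame.
#' @param binWidth bin width in percent, default 1.
#' @return data.frame with `lower`, `upper`, `count`; the counts sum to
#'   `nrow(pairs)`.
#' @export
similarityHistogram <- function(pairs, binWidth = 1) {
  .checkScalarNum(binWidth, "binWidth")
  if (binWidth <= 0) .stopf("binWidth must be > 0")
  if (nrow(pairs) == 0L)
    return(data.frame(lower = numeric(), upper = numeric(), count = integer()))
  k <- floor(pairs$similarity / binWidth)
  kk <- seq(min(k), max(k))
  cnt <- tabulate(k - min(k) + 1L, nbins = length(kk))
  data.frame(lower = kk * binWidth, upper = (kk + 1) * binWidth, count = cnt)
}

#' A similarity window
#'
#' Percent-identity bounds `[lower, upper]` isolating one duplication/
#' speciation cohort; applied to block mean similarities, never to
#' individual pairs.
#'
#' @param lower,upper bounds in percent, `0 <= lower < upper <= 100`.
#' @return list of class `SimilarityWindow`.
#' @export
similarityWindow <- function(lower, upper) {
  .checkScalarNum(lower, "lower", 0, 100)
  .checkScalarNum(upper, "upper", 0, 100)
  if (lower >= upper) .stopf("similarity window requires lower < upper")
  structure(list(lower = lower, upper = upper), class = "SimilarityWindow")
}

#' @export
print.SimilarityWindow <- function(x, ...) {
  cat(sprintf("SimilarityWindow [%.3g, %.3g]%%\n", x$lower, x$upper))
  invisible(x)
}

#' Select the similarity window of the most recent event cohort
#'
#' With `policy = "highest_mode"` the histogram is smoothed with a centered
#' 3-bin moving average, the local mode at the *greatest similarity* (the
#' most recent cohort) is located, and the window extends from that mode to
#' the flanking local minima (or the histogram edges). `policy = "manual"`
#' returns the supplied bounds unchanged. The automatic rule is a
#' deterministic stand-in for reading the similarity distribution by eye;
#' manual bounds are the escape hatch when the distribution is not clearly
#' multimodal.
#'
#' @param hist histogram from [similarityHistogram()].
#' @param policy `"highest_mode"` or `"manual"`.
#' @param lower,upper manual bounds (required for `policy = "manual"`).
#' @return a [similarityWindow()].
#' @export
selectSimilarityWindow <- function(hist, policy = c("highest_mode", "manual"),
                                   lower = NULL, upper = NULL) {
  policy <- match.arg(policy)
  if (policy == "manual") {
    if (is.null(lower) || is.null(upper))
      .stopf("manual policy requires explicit lower and upper bounds")
    return(similarityWindow(lower, upper))
  }
  if (nrow(hist) == 0L) .stopf("cannot select a window from an empty histogram")
  n <- nrow(hist)
  cnt <- as.numeric(hist$count)
  s <- if (n >= 3L) {
    c(cnt[1L], (cnt[-c(1L, 2L)] + cnt[-c(1L, n)] + cnt[-c(n - 1L, n)]) / 3,
      cnt[n])
  } else cnt
  # only interior bins qualify as modes, so monotone histograms fail over
  # to the manual policy rather than returning a spurious edge "peak"
  modes <- integer()
  if (n >= 3L) {
    i <- 2:(n - 1L)
    isMode <- s[i] >= s[i - 1L] & s[i] >= s[i + 1L] &
      (s[i] > s[i - 1L] | s[i] > s[i + 1L])
    modes <- i[isMode]
  }
  if (length(modes) == 0L)
    .stopf(paste("no local mode detectable (monotone or flat histogram);",
                 "use policy = 'manual' with explicit bounds"))
  m <- max(modes)                       # mode at the greatest similarity
  lo <- m
  while (lo > 1L && s[lo - 1L] <= s[lo]) lo <- lo - 1L
  hi <- m
  while (hi < n && s[hi + 1L] <= s[hi]) hi <- hi + 1L
  similarityWindow(max(0, hist$lower[lo]), min(100, hist$upper[hi]))
}
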