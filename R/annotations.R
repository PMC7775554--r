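#' Read gene annotations from GFF3
#'
#' Imports gene-level features (via \pkg{rtracklayer}) and converts them from
#' GFF3's 1-based inclusive coordinates to the package-internal 0-based
#' half-open convention. Records are sorted by position and per-chromosome
#' ranks assigned; the file's row order is irrelevant.
#'
#' @param path path to a GFF3 file.
#' @param genomeId genome identifier for the resulting table; defaults to the
#'   file name without extension.
#' @param featureType feature type (column 3) to keep, default `"gene"`.
#' @return A [GeneTable-class].
#' @details Malformed lines (wrong column count, non-numeric coordinates,
#'   end before start) raise an error naming the offending line number.
#'   Gene ids are taken from the `ID` attribute, falling back to `Name`.
#' @export
readGff3 <- function(path, genomeId = NULL,  featureType = "gene") {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  genomeId <- genomeId %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  fasta <- which(lines == "##FASTA")
  if (length(fasta)) lines <- lines[seq_len(fasta[1L] - 1L)]
  body <- !(startsWith(lines, "#") | lines == "")
  for (i in which(body)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      .stopf("malformed GFF3 at line %d: expected 9 tab-separated fields", i)
    s <- suppressWarnings(as.numeric(f[4L])); e <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(s) || is.na(e))
      .stopf("malformed GFF3 at line %d: non-numeric coordinates", i)
    if (e < s)
      .stopf("malformed GFF3 at line %d: end < start", i)
  }
  if (!any(body))
    return(geneTable(genomeId, data.frame(gene_id = character(), chrom = character(),
                                          start = numeric(), end = numeric())))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == featureType]
  if (length(gr) == 0L)
    return(geneTable(genomeId, data.frame(gene_id = character(), chrom = character(),
                                          start = numeric(), end = numeric())))
  ids <- as.character(gr$ID)
  if (!is.null(gr$Name)) {
    nm <- as.character(gr$Name)
    ids[is.na(ids)] <- nm[is.na(ids)]
  }
  if (anyNA(ids)) .stopf("GFF3 %s feature without ID or Name attribute", featureType)
  strand <- as.character(GenomicRanges::strand(gr))
  geneTable(genomeId, data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,     # 1-based inclusive -> 0-based half-open
    end = as.numeric(GenomicRanges::end(gr)),
    strand = strand, stringsAsFactors = FALSE))
}

#' Read gene annotations from BED
#'
#' BED4 or BED6; BED's native 0-based half-open coordinates are kept
#' unchanged. A missing strand column (BED4) or `.` strand becomes
#' `"unknown"`. The same sorting/rank contract as [readGff3()] applies, so a
#' gene set encoded as GFF3 (1-based) or BED (0-based) yields identical
#' `GeneTable`s.
#'
#' @inheritParams readGff3
#' @export
readBed <- function(path, genomeId = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  genomeId <- genomeId %||% sub("\\.[^.]*$", "", basename(path))
  d <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE,
                         colClasses = "character", fill = TRUE)
  if (nrow(d) == 0L)
    return(geneTable(genomeId, data.frame(gene_id = character(), chrom = character(),
                                          start = numeric(), end = numeric())))
  if (ncol(d) < 4L)
    .stopf("BED parse error: fewer than 4 columns (got %d)", ncol(d))
  start <- suppressWarnings(as.numeric(d[[2L]]))
  end <- suppressWarnings(as.numeric(d[[3L]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) .stopf("malformed BED at line %d: non-numeric coordinates", bad[1L])
  if (any(start < 0)) .stopf("malformed BED: negative start at line %d",
                             which(start < 0)[1L])
  strand <- if (ncol(d) >= 6L) d[[6L]] else "unknown"
  geneTable(genomeId, data.frame(
    gene_id = d[[4L]], chrom = d[[1L]], start = start, end = end,
    strand = .normStrand(strand), stringsAsFactors = FALSE))
}

#' Write a GeneTable as BED6
#'
#' Inverse of [readBed()]: `readBed(writeBed(x, f))` reproduces `x` exactly.
#' @param table a [GeneTable-class].
#' @param path output path.
#' @export
writeBed <- function(table, path) {
  g <- geneRecords(table)
  s <- g$strand; s[s == "unknown"] <- "."
  out <- data.frame(g$chrom, format(g$start, scientific = FALSE, trim = TRUE),
                    format(g$end, scientific = FALSE, trim = TRUE),
                    g$gene_id, 0L, s)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a GeneTable as GFF3 (gene features)
#' @inheritParams writeBed
#' @param source value for the GFF3 source column.
#' @export
writeGff3 <- function(table, path, source = "fracsig") {
  g <- geneRecords(table)
  s <- g$strand; s[s == "unknown"] <- "."
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tgene\t%.0f\t%.0f\t.\t%s\t.\tID=%s",
                     g$chrom, source, g$start + 1, g$end, s, g$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read chromosome/assembly sizes
#'
#' Two-column TSV `chromosome<TAB>length`; a FASTA `.fai` index works too
#' (extra columns are ignored).
#'
#' @param path path to the sizes file.
#' @return named numeric vector of chromosome lengths (bp).
#' @export
readAssemblySizes <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  d <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  if (ncol(d) < 2L) .stopf("assembly sizes: need at least 2 columns")
  len <- as.numeric(d[[2L]])
  if (anyNA(len) || any(len <= 0)) .stopf("assembly sizes: non-positive or non-numeric length")
  stats::setNames(len, as.character(d[[1L]]))
}

#' Write assembly sizes TSV
#' @param sizes named numeric vector of chromosome lengths.
#' @param path output path.
#' @export
writeAssemblySizes <- function(sizes, path) {
  data.table::fwrite(
    data.frame(names(sizes), format(sizes, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Genome-wide gene density summary
#'
#' `bp_per_gene = total assembly bp / gene count`, the inverse of the
#' genome-wide gene density. This is the reference value against which the
#' conserved-interval density (regression slope) is compared, and the
#' default basis for cross-genome normalization.
#'
#' @param table a [GeneTable-class].
#' @param assemblySizes named numeric vector of chromosome lengths covering
#'   at least every chromosome that carries a gene.
#' @return A [GenomeSummary-class].
#' @examples
#' gt <- geneTable("g", data.frame(gene_id = paste0("g", 1:10), chrom = "chr1",
#'                                 start = (0:9) * 1e4, end = (0:9) * 1e4 + 3000))
#' bpPerGene(summarizeGenome(gt, c(chr1 = 1e5)))  # 10000
#' @export
summarizeGenome <- function(table, assemblySizes) {
  n <- geneCount(table)
  if (n == 0L) .stopf("cannot summarize a genome with zero genes")
  miss <- setdiff(chromosomes(table), names(assemblySizes))
  if (length(miss))
    .stopf("gene(s) on chromosome(s) absent from assembly sizes: %s",
           paste(miss, collapse = ", "))
  total <- sum(assemblySizes)
  new("GenomeSummary", genomeId = genomeId(table), totalBp = total,
      geneCount = n, bpPerGene = total / n)
}
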