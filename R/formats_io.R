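#' Read a bedGraph coverage file
#'
#' Coverage intervals are 0-based half-open on disk and returned as a
#' `GRanges` with a `score` metadata column (the package's interval-coverage
#' carrier; `GRanges` itself is 1-based closed).  Track/browser header lines,
#' comments and blank lines are skipped.  Records on a chromosome must be
#' non-overlapping; they are returned sorted.
#'
#' @param path path to a 4-column whitespace-separated bedGraph file.
#' @param layout optional [GenomeLayout-class]; when supplied, chromosomes are
#'   validated and ordered against it and intervals must lie within bounds.
#' @return `GRanges` with numeric `score`, sorted within chromosome.
#' @examples
#' tf <- tempfile(fileext = ".bedGraph")
#' writeLines("chr1\t0\t400\t2", tf)
#' readBedGraph(tf)
#' @export
readBedGraph <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*($|#|track\\b|browser\\b)", lines)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  for (j in seq_along(fields)) {
    if (length(fields[[j]]) != 4L)
      stop("bedGraph parse error at line ", which(keep)[j],
           ": expected 4 columns, got ", length(fields[[j]]))
  }
  chrom <- vapply(fields, `[`, character(1), 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  v <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 4L)))
  bad <- which(is.na(s) | is.na(e) | is.na(v))
  if (length(bad))
    stop("bedGraph parse error at line ", which(keep)[bad[1]],
         ": non-numeric field")
  bad <- which(s >= e)
  if (length(bad))
    stop("bedGraph parse error at line ", which(keep)[bad[1]],
         ": start >= end")
  bad <- which(v < 0)
  if (length(bad))
    stop("bedGraph parse error at line ", which(keep)[bad[1]],
         ": negative coverage value")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1, e), score = v)
  .validateCoverage(gr, layout)
}

# Shared validation: chromosome membership/bounds against a layout, per
# chromosome sorting, and the non-overlap invariant.
.validateCoverage <- function(gr, layout = NULL) {
  if (!is.null(layout)) {
    chr <- as.character(GenomicRanges::seqnames(gr))
    len <- .chromLength(layout, unique(chr))
    if (length(gr)) {
      lim <- setNames(len, unique(chr))[chr]
      if (any(.end0(gr) > lim))
        stop("coverage interval exceeds chromosome length")
    }
    GenomeInfoDb::seqlevels(gr) <- layout@chromNames
  }
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (length(gr) > 1L) {
    same <- as.character(GenomicRanges::seqnames(gr)[-1]) ==
      as.character(GenomicRanges::seqnames(gr)[-length(gr)])
    if (any(same & (GenomicRanges::start(gr)[-1] <=
                    GenomicRanges::end(gr)[-length(gr)])))
      stop("overlapping coverage records within a chromosome")
  }
  if (is.null(gr$score)) gr$score <- numeric(length(gr))
  gr$score <- as.numeric(gr$score)
  if (any(!is.finite(gr$score)) || any(gr$score < 0))
    stop("coverage values must be finite and non-negative")
  gr
}

#' Write interval coverage as bedGraph
#'
#' Coordinates are written 0-based half-open.  Values are formatted with 17
#' significant digits so that a read/write/read cycle reproduces the input
#' exactly; zero-value records are kept.  Records are emitted in the
#' chromosome order of the object's seqlevels.
#'
#' @param cov `GRanges` with a `score` column, as returned by [readBedGraph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(cov, path) {
  cov <- .validateCoverage(cov)
  cov <- cov[order(match(as.character(GenomicRanges::seqnames(cov)),
                         GenomeInfoDb::seqlevels(cov)),
                   GenomicRanges::start(cov))]
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(cov))
    writeLines(sprintf("%s\t%d\t%d\t%.17g",
                       as.character(GenomicRanges::seqnames(cov)),
                       .start0(cov), .end0(cov), cov$score), con)
  invisible(path)
}

#' Read a UCSC-table-browser-style gene table
#'
#' Tab-separated with a header; the columns `name`, `chrom`, `strand`,
#' `txStart`, `txEnd` are required (0-based half-open), extra columns are
#' ignored.  The TSS is `txStart` on the `+` strand and `txEnd` on the `-`
#' strand.  Rows sharing a `name` are kept as transcript variants and flagged
#' in the `hasVariants` column for later collapsing.
#'
#' @param path path to the gene table.
#' @return `GRanges` with metadata columns `name`, `tss` (0-based) and
#'   `hasVariants`.
#' @export
readGeneTable <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("name", "chrom", "strand", "txStart", "txEnd")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("gene table misses column(s): ",
                         paste(miss, collapse = ", "))
  .geneModel(tab$name, tab$chrom, tab$strand, tab$txStart, tab$txEnd)
}

# Build the gene GRanges from parallel vectors, enforcing the GeneModel
# invariants.
.geneModel <- function(name, chrom, strand, txStart, txEnd) {
  .checkStrand(strand)
  txStart <- as.numeric(txStart); txEnd <- as.numeric(txEnd)
  if (any(!is.finite(txStart)) || any(!is.finite(txEnd)))
    stop("non-numeric gene coordinates")
  if (any(txStart >= txEnd)) stop("txStart must be < txEnd")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(txStart + 1, txEnd),
                               strand = strand)
  gr$name <- as.character(name)
  gr$tss <- ifelse(strand == "+", txStart, txEnd)
  gr$hasVariants <- gr$name %in% gr$name[duplicated(gr$name)]
  gr
}

#' Read enhancer (or other) anchors from a BED file
#'
#' Accepts BED3 or BED6.  The anchor position of each interval is its
#' midpoint (floored); strand is taken from column 6 when present, otherwise
#' `defaultStrand`.
#'
#' @param path BED3/BED6 file.
#' @param defaultStrand strand assigned to strandless records.
#' @return A width-1 `GRanges` anchor set with an `id` metadata column.
#' @export
readBedAnchors <- function(path, defaultStrand = "+") {
  .checkStrand(defaultStrand)
  bed <- rtracklayer::import(path, format = "BED")
  mid0 <- (.start0(bed) + .end0(bed)) %/% 2
  strand <- as.character(GenomicRanges::strand(bed))
  strand[strand == "*"] <- defaultStrand
  ids <- if (!is.null(bed$name) && all(nzchar(bed$name))) bed$name
         else sprintf("anchor%04d", seq_along(bed))
  anchorSet(as.character(GenomicRanges::seqnames(bed)), mid0, strand, ids)
}

#' Build an anchor set from positions
#'
#' @param chrom,position,strand,id parallel vectors; `position` is 0-based.
#' @return width-1 `GRanges` with an `id` column.
#' @export
anchorSet <- function(chrom, position, strand, id) {
  .checkStrand(strand)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(position + 1, width = 1),
                               strand = strand)
  gr$id <- as.character(id)
  gr
}

#' TSS / TTS anchors of a gene set
#'
#' Strand-aware anchors at the transcription start (or termination) sites of
#' a gene `GRanges` from [readGeneTable()].  Genes on excluded chromosomes
#' (chromosome 8 by default, mirroring its exclusion from all analyses) are
#' dropped.
#'
#' @param genes gene `GRanges` with `name` and `tss` columns.
#' @param excludeChroms chromosomes to drop (default `"chr8"`).
#' @return width-1 anchor `GRanges` with `id`.
#' @export
tssAnchors <- function(genes, excludeChroms = "chr8") {
  genes <- genes[!as.character(GenomicRanges::seqnames(genes)) %in% excludeChroms]
  anchorSet(as.character(GenomicRanges::seqnames(genes)), genes$tss,
            as.character(GenomicRanges::strand(genes)), genes$name)
}

#' @rdname tssAnchors
#' @export
ttsAnchors <- function(genes, excludeChroms = "chr8") {
  genes <- genes[!as.character(GenomicRanges::seqnames(genes)) %in% excludeChroms]
  strand <- as.character(GenomicRanges::strand(genes))
  tts <- ifelse(strand == "+", .end0(genes), .start0(genes))
  anchorSet(as.character(GenomicRanges::seqnames(genes)), tts, strand,
            genes$name)
}

#' Read a genes x samples raw counts table with sample metadata
#'
#' The counts table is tab-separated with gene ids in the first column and
#' one column per sample; the metadata table maps `sample_id` to `line`,
#' `timepoint_h`, `state` and `replicate`.  The two sample sets must be
#' identical; counts must be non-negative integers.
#'
#' @param path counts table path.
#' @param metadataPath sample metadata table path.
#' @return `SummarizedExperiment` with a `counts` assay and the metadata as
#'   `colData`.
#' @export
readCountsTable <- function(path, metadataPath) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  meta <- utils::read.delim(metadataPath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(meta))
    stop("metadata table requires a sample_id column")
  if (!setequal(colnames(tab), meta$sample_id) ||
      anyDuplicated(meta$sample_id))
    stop("sample sets of counts table and metadata differ")
  counts <- as.matrix(tab)[, meta$sample_id, drop = FALSE]
  countsExperiment(counts, meta)
}

#' Assemble a counts SummarizedExperiment in memory
#'
#' @param counts genes x samples matrix of non-negative integer counts.
#' @param meta data.frame with a `sample_id` column matching `colnames(counts)`
#'   plus arbitrary annotation (`line`, `state`, `timepoint_h`, `replicate`).
#' @param chrom optional per-gene chromosome vector stored in `rowData`.
#' @return `SummarizedExperiment` with assay `counts`.
#' @export
countsExperiment <- function(counts, meta, chrom = NULL) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  cd <- S4Vectors::DataFrame(meta, row.names = meta$sample_id)
  rd <- if (is.null(chrom)) NULL else S4Vectors::DataFrame(chrom = chrom)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  if (!is.null(rd)) SummarizedExperiment::rowData(se) <- rd
  se
}
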