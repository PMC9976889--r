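# Expression-side pipeline: TPM, variant collapse, DE classification, gene
# group definition, group comparisons and stem-state retention correlations.

#' Select sample ids by annotation
#'
#' Convenience filter over the `colData` of a counts/TPM
#' `SummarizedExperiment` (columns `line`, `state`, `timepoint_h`,
#' `replicate`).  `NULL` arguments are not filtered on.
#'
#' @param expr a `SummarizedExperiment`.
#' @param line,state,timepoint,replicate values to keep.
#' @return character vector of sample ids.
#' @export
sampleSelect <- function(expr, line = NULL, state = NULL, timepoint = NULL,
                         replicate = NULL) {
  cd <- SummarizedExperiment::colData(expr)
  keep <- rep(TRUE, nrow(cd))
  if (!is.null(line)) keep <- keep & cd$line %in% line
  if (!is.null(state)) keep <- keep & cd$state %in% state
  if (!is.null(timepoint)) keep <- keep & cd$timepoint_h %in% timepoint
  if (!is.null(replicate)) keep <- keep & cd$replicate %in% replicate
  rownames(cd)[keep]
}

#' TPM normalization of raw counts
#'
#' Transcripts per million: counts are divided by gene length, and each
#' sample column is scaled so that length-normalized rates sum to 1e6.
#' Genes on excluded chromosomes (chromosome 8 by default) are removed
#' *before* normalization -- the exclusion applies to all analyses, so the
#' remaining genes renormalize over themselves.  Note that any later
#' subsetting of the result does NOT silently renormalize; column sums are
#' 1e6 only for the full returned matrix.
#'
#' @param counts counts `SummarizedExperiment` ([readCountsTable()],
#'   [countsExperiment()]); chromosome exclusion requires a `chrom` column in
#'   its `rowData`.
#' @param geneLengths named vector of gene lengths in bp (> 0), covering all
#'   retained genes.
#' @param excludeChroms chromosomes removed before normalization; `NULL` or
#'   `character(0)` disables the exclusion.
#' @return `SummarizedExperiment` with a `tpm` assay and the input `colData`.
#' @export
tpmNormalize <- function(counts, geneLengths, excludeChroms = "chr8") {
  x <- SummarizedExperiment::assay(counts, "counts")
  rd <- SummarizedExperiment::rowData(counts)
  if (length(excludeChroms)) {
    if (!"chrom" %in% colnames(rd))
      stop("chromosome exclusion requires a 'chrom' rowData column; ",
           "pass excludeChroms = NULL to skip it")
    keep <- !rd$chrom %in% excludeChroms
    counts <- counts[keep, ]
    x <- x[keep, , drop = FALSE]
  }
  len <- geneLengths[rownames(x)]
  if (anyNA(len) || any(len <= 0))
    stop("positive gene lengths required for every gene")
  rate <- x / len
  tot <- colSums(rate)
  if (any(tot <= 0)) stop("all-zero sample(s): ",
                          paste(colnames(x)[tot <= 0], collapse = ", "))
  tpm <- sweep(rate, 2, tot / 1e6, "/")
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = tpm),
    colData = SummarizedExperiment::colData(counts),
    rowData = SummarizedExperiment::rowData(counts))
  out
}

#' Collapse transcript variants to genes by maximal expression
#'
#' For genes quantified via several transcript variants, the gene-level
#' expression in every sample is the expression of the variant with the
#' maximal value in that sample (selection is per sample, so different
#' samples may pick different variants).
#'
#' @param expr TPM `SummarizedExperiment` whose rows are variant ids.
#' @param variantMap named character vector mapping every variant id to its
#'   gene id.
#' @return `SummarizedExperiment` with one row per gene.
#' @export
collapseVariants <- function(expr, variantMap) {
  x <- SummarizedExperiment::assay(expr, "tpm")
  miss <- setdiff(rownames(x), names(variantMap))
  if (length(miss))
    stop("unmapped variant(s): ", paste(head(miss, 5), collapse = ", "))
  gene <- variantMap[rownames(x)]
  groups <- split(seq_len(nrow(x)), gene)
  collapsed <- do.call(rbind, lapply(groups, function(i)
    apply(x[i, , drop = FALSE], 2, max)))
  rd <- SummarizedExperiment::rowData(expr)
  rdOut <- if ("chrom" %in% colnames(rd)) {
    S4Vectors::DataFrame(chrom = vapply(groups, function(i) rd$chrom[i[1]],
                                        character(1)))
  } else NULL
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = collapsed),
    colData = SummarizedExperiment::colData(expr))
  if (!is.null(rdOut)) SummarizedExperiment::rowData(out) <- rdOut
  out
}

#' Classify differentially expressed genes
#'
#' Fold change with a pseudocount of 1, `(mean(A)+1) / (mean(B)+1)`, and a
#' per-gene two-sample t-test on `log2(TPM+1)` with Benjamini-Hochberg
#' correction.  A gene is called `up` iff fold change > `fcHi` and q <
#' `alpha`, `down` iff fold change < `fcLo` and q < `alpha`, else `ns` --
#' both the fold-change and the significance condition are required.  The
#' internal test is an explicit simplified stand-in for a dedicated count
#' model (DESeq2 and friends are out of scope); externally computed p-values
#' can be supplied through `pValues` instead.
#'
#' @param expr TPM `SummarizedExperiment`.
#' @param groupA,groupB sample id vectors of the two groups (>= 2 replicates
#'   each for the internal test).
#' @param fcHi,fcLo,alpha classification thresholds (defaults 2, 0.5, 0.05).
#' @param pValues optional named per-gene raw p-values replacing the internal
#'   test.
#' @return data.frame with `gene`, `log2FC`, `pValue`, `qValue`, `call`.
#' @export
classifyDE <- function(expr, groupA, groupB, fcHi = 2, fcLo = 0.5,
                       alpha = 0.05, pValues = NULL) {
  tpm <- SummarizedExperiment::assay(expr, "tpm")
  miss <- setdiff(c(groupA, groupB), colnames(tpm))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  a <- tpm[, groupA, drop = FALSE]; b <- tpm[, groupB, drop = FALSE]
  fc <- (rowMeans(a) + 1) / (rowMeans(b) + 1)
  if (is.null(pValues)) {
    if (length(groupA) < 2L || length(groupB) < 2L)
      stop("internal test needs >= 2 replicates per group; ",
           "supply external p-values through pValues otherwise")
    la <- log2(a + 1); lb <- log2(b + 1)
    na <- ncol(la); nb <- ncol(lb)
    ma <- rowMeans(la); mb <- rowMeans(lb)
    va <- rowSums((la - ma)^2) / (na - 1)
    vb <- rowSums((lb - mb)^2) / (nb - 1)
    sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2) *
                 (1 / na + 1 / nb))
    tstat <- (ma - mb) / sp
    p <- 2 * stats::pt(-abs(tstat), df = na + nb - 2)
    # degenerate zero-variance genes: no evidence either way
    p[sp == 0 & ma == mb] <- 1
    p[sp == 0 & ma != mb] <- 0
  } else {
    p <- pValues[rownames(tpm)]
    if (anyNA(p)) stop("pValues must cover every gene")
  }
  q <- stats::p.adjust(p, method = "BH")
  call <- rep("ns", nrow(tpm))
  call[fc > fcHi & q < alpha] <- "up"
  call[fc < fcLo & q < alpha] <- "down"
  data.frame(gene = rownames(tpm), log2FC = log2(fc), pValue = unname(p),
             qValue = unname(q), call = call, row.names = NULL)
}

#' Gene groups defined by expression ratio between two lines
#'
#' Genes whose replicate-mean expression (pseudocount 1) in `lineA` exceeds
#' that in `lineB` by more than `cutoff`-fold within a state, and the
#' symmetric `B > A` group.  Swapping the lines swaps the groups exactly.
#'
#' @param expr TPM `SummarizedExperiment`.
#' @param state state in which the contrast is taken (e.g. `"RA"`).
#' @param lineA,lineB cell line labels.
#' @param cutoff fold-change cutoff (default 2; 1.5 gives supersets).
#' @return list of two gene groups (`aOverB`, `bOverA`), each a list with
#'   `name`, `genes` and `contrast`.
#' @export
genesHigherIn <- function(expr, state, lineA, lineB, cutoff = 2) {
  sa <- sampleSelect(expr, line = lineA, state = state)
  sb <- sampleSelect(expr, line = lineB, state = state)
  if (length(sa) == 0L || length(sb) == 0L)
    stop("line/state combination missing from the expression matrix")
  tpm <- SummarizedExperiment::assay(expr, "tpm")
  ra <- (rowMeans(tpm[, sa, drop = FALSE]) + 1) /
    (rowMeans(tpm[, sb, drop = FALSE]) + 1)
  contrast <- list(lineA = lineA, lineB = lineB, state = state,
                   cutoff = cutoff)
  list(aOverB = list(name = paste0(lineA, ">", lineB, "@", state),
                     genes = rownames(tpm)[ra > cutoff], contrast = contrast),
       bOverA = list(name = paste0(lineB, ">", lineA, "@", state),
                     genes = rownames(tpm)[ra < 1 / cutoff],
                     contrast = contrast))
}

#' Compare expression of a gene group against a background
#'
#' Mean expression of the group and of the background over the selected
#' samples, with a two-sided Mann-Whitney U p-value (the different-size
#' group convention).
#'
#' @param group gene id vector (or a group from [genesHigherIn()]).
#' @param background gene id vector, or `NULL` for all genes in `expr`.
#' @param expr TPM `SummarizedExperiment`.
#' @param samples sample ids whose mean expression is compared.
#' @return list with `meanGroup`, `meanBackground`, `statistic`, `pValue`.
#' @export
groupExpressionCompare <- function(group, background = NULL, expr, samples) {
  if (is.list(group)) group <- group$genes
  if (is.list(background)) background <- background$genes
  tpm <- SummarizedExperiment::assay(expr, "tpm")
  if (is.null(background)) background <- rownames(tpm)
  g <- intersect(group, rownames(tpm))
  bgd <- intersect(background, rownames(tpm))
  if (length(g) == 0L || length(bgd) == 0L)
    stop("empty group after intersection with the expression matrix")
  vg <- rowMeans(tpm[g, samples, drop = FALSE])
  vb <- rowMeans(tpm[bgd, samples, drop = FALSE])
  res <- compareGroupScores(vg, vb, test = "u")
  list(meanGroup = mean(vg), meanBackground = mean(vb),
       statistic = res$statistic, pValue = res$pValue)
}

#' Stem-state retention: expression correlation between two states
#'
#' Spearman correlation, across genes, between the replicate-mean expression
#' of a line in two states (undifferentiated ESC versus differentiated
#' RA/OPC by default).  All samples of a state are pooled -- for RA this
#' pools the 24 h and 72 h collections, which behave similarly.  An elevated
#' correlation in a mutant line relative to WT is the signature of retained
#' stem-state expression after differentiation.
#'
#' @param expr TPM `SummarizedExperiment`.
#' @param line cell line label.
#' @param statePair character vector of the two states.
#' @return list as [spearmanCorrelation()] plus `line` and `states`.
#' @export
stateRetentionCorrelation <- function(expr, line, statePair = c("ESC", "RA")) {
  s1 <- sampleSelect(expr, line = line, state = statePair[1])
  s2 <- sampleSelect(expr, line = line, state = statePair[2])
  if (length(s1) == 0L || length(s2) == 0L)
    stop("both states (", paste(statePair, collapse = ", "),
         ") must have samples for line ", line)
  tpm <- SummarizedExperiment::assay(expr, "tpm")
  out <- spearmanCorrelation(rowMeans(tpm[, s1, drop = FALSE]),
                             rowMeans(tpm[, s2, drop = FALSE]))
  out$line <- line
  out$states <- statePair
  out
}
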