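#' Gene-level H3.3 window score around the TSS
#'
#' The per-gene binding statistic used throughout the comparative analyses:
#' the mean bin signal over the TSS-flanking windows -1.2 kb..-200 b
#' (upstream) and +400 b..+1.2 kb (downstream), strand-oriented.  The TSS is
#' snapped to the start of its containing bin and bins are selected by their
#' midpoint offset, so with 200 bp bins the defaults select exactly 5
#' upstream + 4 downstream = 9 bins.  Genes on excluded chromosomes are
#' removed; genes whose window leaves the chromosome are dropped and counted
#' in the `nDropped` attribute.
#'
#' @param track a [BinnedTrack-class].
#' @param genes gene `GRanges` from [readGeneTable()].
#' @param upstream,downstream oriented half-open offset windows in bp.
#' @param excludeChroms chromosomes whose genes are removed (default
#'   `"chr8"`).
#' @return named numeric vector of scores (names are gene names) with
#'   attributes `upstream`, `downstream`, `sampleMeta`, `nDropped`.
#' @export
geneWindowScore <- function(track, genes,
                            upstream = c(-1200, -200),
                            downstream = c(400, 1200),
                            excludeChroms = "chr8") {
  lay <- track@layout
  bs <- lay@binSize
  half <- bs %/% 2
  # bin displacements whose midpoint offset d*bs + bs/2 falls in a window
  dFor <- function(w) {
    d <- seq(floor((w[1] - half) / bs), ceiling(w[2] / bs))
    d[d * bs + half >= w[1] & d * bs + half < w[2]]
  }
  dSet <- c(dFor(upstream), dFor(downstream))
  if (length(dSet) == 0L) stop("windows select no bins at this bin size")
  genes <- genes[!as.character(GenomicRanges::seqnames(genes)) %in% excludeChroms]
  if (length(genes) == 0L) stop("no genes left after chromosome exclusion")
  chrom <- as.character(GenomicRanges::seqnames(genes))
  strand <- as.character(GenomicRanges::strand(genes))
  tssBase <- ifelse(strand == "+", genes$tss, genes$tss - 1)
  tbin <- as.integer(tssBase %/% bs)        # 0-based bin of the TSS base
  sgn <- ifelse(strand == "+", 1L, -1L)
  nb <- nBins(lay)[chrom]
  binIdx <- outer(tbin, rep(1L, length(dSet))) + outer(sgn, dSet)  # 0-based
  inside <- rowSums(binIdx < 0 | binIdx >= nb) == 0 & chrom %in% names(track@values)
  nDropped <- sum(!inside)
  if (!any(inside)) stop("every gene's window leaves its chromosome")
  if (nDropped > 0)
    message(nDropped, " gene(s) dropped: score window exceeds chromosome bounds")
  scores <- numeric(sum(inside))
  keptChrom <- chrom[inside]
  bk <- binIdx[inside, , drop = FALSE] + 1L
  for (cn in unique(keptChrom)) {
    i <- keptChrom == cn
    scores[i] <- rowMeans(matrix(track@values[[cn]][bk[i, , drop = FALSE]],
                                 nrow = sum(i)))
  }
  structure(setNames(scores, genes$name[inside]),
            upstream = upstream, downstream = downstream,
            sampleMeta = track@sampleMeta, nDropped = nDropped)
}

#' Correlation between H3.3 binding and gene expression
#'
#' Spearman correlation, over the genes present in both inputs, between a
#' gene window score vector and the expression of the selected sample(s)
#' (mean TPM when several samples are given).  Genes missing on either side
#' are dropped and counted.
#'
#' @param scores named score vector from [geneWindowScore()].
#' @param expr TPM `SummarizedExperiment` from [tpmNormalize()].
#' @param samples sample id(s) selecting the expression column(s).
#' @return list as [spearmanCorrelation()] plus `nDropped`.
#' @export
bindingExpressionCorrelation <- function(scores, expr, samples) {
  tpm <- SummarizedExperiment::assay(expr, "tpm")
  miss <- setdiff(samples, colnames(tpm))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  e <- rowMeans(tpm[, samples, drop = FALSE])
  common <- intersect(names(scores), names(e))
  if (length(common) < 10L)
    stop("need at least 10 genes shared between scores and expression")
  out <- spearmanCorrelation(scores[common], e[common])
  out$nDropped <- (length(scores) - length(common)) +
    (length(e) - length(common))
  out
}

#' Pairwise Spearman matrix of gene score vectors
#'
#' Correlation of binding across samples or timepoints: all pairwise Spearman
#' coefficients over the common gene set of the supplied score vectors.
#'
#' @param scoreVectors named list of at least two named score vectors.
#' @return symmetric matrix of rho values with unit diagonal.
#' @export
correlationMatrix <- function(scoreVectors) {
  if (length(scoreVectors) < 2L) stop("need at least two score vectors")
  if (is.null(names(scoreVectors)))
    names(scoreVectors) <- sprintf("v%d", seq_along(scoreVectors))
  common <- Reduce(intersect, lapply(scoreVectors, names))
  if (length(common) < 10L) stop("fewer than 10 genes shared by all vectors")
  k <- length(scoreVectors)
  m <- diag(1, k)
  dimnames(m) <- list(names(scoreVectors), names(scoreVectors))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    rho <- spearmanCorrelation(scoreVectors[[i]][common],
                               scoreVectors[[j]][common])$rho
    m[i, j] <- m[j, i] <- rho
  }
  m
}
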