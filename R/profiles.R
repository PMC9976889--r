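#' Anchor-centered profile matrix (heatmap input)
#'
#' Extracts, for every anchor, the track bins covering oriented offsets
#' `-flank .. +flank` (10 kb by default, the window used for TSS heatmaps and
#' metagene profiles).  Column `j` holds the bin containing
#' `anchor + oriented(offset_j + binSize/2)`; minus-strand anchors are
#' orientation-flipped so that columns always run upstream to downstream in
#' the direction of transcription.  Anchors whose window would leave the
#' chromosome are dropped and counted (`anchorsDropped()`).
#'
#' @param track a [BinnedTrack-class].
#' @param anchors width-1 anchor `GRanges` with `id`
#'   ([tssAnchors()], [readBedAnchors()]).
#' @param flank half-window in bp; must be a multiple of the bin size.
#' @return A [ProfileMatrix-class].
#' @export
anchorMatrix <- function(track, anchors, flank = 10000) {
  lay <- track@layout
  bs <- lay@binSize
  if (flank %% bs != 0) stop("flank must be a multiple of the bin size")
  flank <- as.integer(flank)
  chrom <- as.character(GenomicRanges::seqnames(anchors))
  pos <- .start0(anchors)
  strand <- as.character(GenomicRanges::strand(anchors))
  .checkStrand(strand)
  len <- .chromLength(lay, chrom)
  keep <- pos - flank >= 0 & pos + flank <= len
  nDropped <- sum(!keep)
  if (nDropped > 0)
    message(nDropped, " anchor(s) dropped: profile window exceeds chromosome bounds")
  if (!any(keep)) stop("no anchors survive the chromosome-bound filter")
  chrom <- chrom[keep]; pos <- pos[keep]; strand <- strand[keep]
  ids <- anchors$id[keep]
  offsets <- as.integer(seq(-flank, flank - bs, by = bs))
  mids <- offsets + bs %/% 2
  sgn <- ifelse(strand == "+", 1L, -1L)
  base <- ifelse(strand == "+", pos, pos - 1L)     # offset-0 base per strand
  # genomic base of each (anchor, offset) cell, then its bin
  g <- outer(base, rep(1L, length(mids))) + outer(sgn, mids)
  b <- g %/% bs + 1L
  vals <- matrix(0, nrow = length(pos), ncol = length(mids),
                 dimnames = list(ids, mids))
  for (cn in unique(chrom)) {
    i <- chrom == cn
    vals[i, ] <- track@values[[cn]][b[i, , drop = FALSE]]
  }
  new("ProfileMatrix", values = vals, offsets = offsets, flank = flank,
      binSize = bs, sampleMeta = track@sampleMeta,
      nDropped = as.integer(nDropped))
}

#' Metagene profile: per-offset mean and twice the standard error
#'
#' Column means of a [ProfileMatrix-class] with `2 * SE` per offset, where
#' `SE` is the sample standard deviation across anchors over `sqrt(n)` --
#' the shading convention of the incorporation profiles.
#'
#' @param matrix a [ProfileMatrix-class] with at least two anchors.
#' @return data.frame with columns `offset`, `mean`, `se2`; the number of
#'   anchors is attached as attribute `nAnchors`.
#' @export
metageneProfile <- function(matrix) {
  x <- profileValues(matrix)
  n <- nrow(x)
  if (n < 2L) stop("metagene profile needs at least two anchors (SE undefined)")
  mu <- colMeans(x)
  sdv <- sqrt(colSums((x - rep(mu, each = n))^2) / (n - 1))
  structure(data.frame(offset = matrix@offsets, mean = unname(mu),
                       se2 = unname(2 * sdv / sqrt(n))),
            nAnchors = n)
}

#' Sort profile rows by an external score (heatmap ordering)
#'
#' Rows are reordered by decreasing score -- e.g. genes sorted by H3.3
#' binding in the WT line -- with ties broken deterministically by anchor id
#' (C-locale lexicographic).
#'
#' @param matrix a [ProfileMatrix-class].
#' @param sortScores named numeric scores covering every anchor id.
#' @return The reordered [ProfileMatrix-class].
#' @export
sortHeatmap <- function(matrix, sortScores) {
  ids <- rownames(profileValues(matrix))
  miss <- setdiff(ids, names(sortScores))
  if (length(miss))
    stop("sort scores missing for anchor(s): ", paste(head(miss, 5), collapse = ", "))
  s <- sortScores[ids]
  ord <- order(-s, ids, method = "radix")
  matrix@values <- matrix@values[ord, , drop = FALSE]
  matrix
}
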