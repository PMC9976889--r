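#' Bin interval coverage onto a fixed-width genome layout
#'
#' Each bin receives `sum(value * overlap_bp) / binSize` over the coverage
#' records that intersect it, i.e. the mean per-base coverage scaled by bin
#' occupancy; records need not be bin-aligned.  `totalMapped` of the
#' resulting track is the sum of all bin values before any normalization.
#'
#' @param cov coverage `GRanges` with `score` (see [readBedGraph()]).
#' @param layout [GenomeLayout-class] to bin on.
#' @param sampleMeta optional annotation list (antibody, line, timepoint_h,
#'   replicate) carried on the track.
#' @return A [BinnedTrack-class].
#' @examples
#' lay <- genomeLayout(c(chr1 = 1000))
#' cov <- readBedGraph(textConnectionPath <- {
#'   f <- tempfile(); writeLines("chr1\t100\t300\t1", f); f })
#' trackValues(binCoverage(cov, lay))$chr1[1:2]  # 0.5 0.5
#' @export
binCoverage <- function(cov, layout, sampleMeta = list()) {
  cov <- .validateCoverage(cov, layout)
  bs <- layout@binSize
  nb <- nBins(layout)
  values <- lapply(nb, numeric)
  chr <- as.character(GenomicRanges::seqnames(cov))
  s0 <- .start0(cov); e0 <- .end0(cov); v <- cov$score
  for (cn in unique(chr)) {
    i <- chr == cn
    values[[cn]] <- .binOne(s0[i], e0[i], v[i], bs, nb[[cn]])
  }
  new("BinnedTrack", layout = layout, values = values,
      sampleMeta = sampleMeta,
      totalMapped = sum(vapply(values, sum, numeric(1))),
      normalized = FALSE)
}

# Fractional-overlap accumulation of records (0-based half-open) into nb
# bins of width bs.  Interior full bins are added with a difference-array
# cumsum; partial first/last bins individually.
.binOne <- function(s0, e0, v, bs, nb) {
  out <- numeric(nb)
  bFirst <- as.integer(s0 %/% bs)      # 0-based bin indices
  bLast <- as.integer((e0 - 1) %/% bs)
  one <- bFirst == bLast
  if (any(one)) {
    w <- (e0[one] - s0[one]) / bs * v[one]
    acc <- rowsum(w, bFirst[one])
    out[as.integer(rownames(acc)) + 1L] <- out[as.integer(rownames(acc)) + 1L] + acc[, 1]
  }
  if (any(!one)) {
    bf <- bFirst[!one]; bl <- bLast[!one]
    vv <- v[!one]; ss <- s0[!one]; ee <- e0[!one]
    headW <- ((bf + 1) * bs - ss) / bs * vv
    accH <- rowsum(headW, bf)
    out[as.integer(rownames(accH)) + 1L] <- out[as.integer(rownames(accH)) + 1L] + accH[, 1]
    tailW <- (ee - bl * bs) / bs * vv
    accT <- rowsum(tailW, bl)
    out[as.integer(rownames(accT)) + 1L] <- out[as.integer(rownames(accT)) + 1L] + accT[, 1]
    body <- bl - bf > 1L
    if (any(body)) {
      delta <- numeric(nb + 1L)
      from <- bf[body] + 2L            # first interior bin, 1-based
      to <- bl[body] + 1L              # one past last interior bin, 1-based
      accF <- rowsum(vv[body], from)
      delta[as.integer(rownames(accF))] <-
        delta[as.integer(rownames(accF))] + accF[, 1]
      accU <- rowsum(vv[body], to)
      delta[as.integer(rownames(accU))] <-
        delta[as.integer(rownames(accU))] - accU[, 1]
      out <- out + cumsum(delta[seq_len(nb)])
    }
  }
  out
}

#' Reads-per-million normalization with chromosome exclusion
#'
#' Scales every bin by `1e6 / total`, where the total is taken over the
#' chromosomes *not* in `excludeChroms` only.  Chromosome 8 is excluded by
#' default: it carries a suspected duplication in the study system and never
#' contributes to the normalization denominator, but its bins remain in the
#' track (scaled by the same factor) for inspection.  After normalization the
#' summed signal over included chromosomes equals 1e6.
#'
#' @param track an un-normalized [BinnedTrack-class].
#' @param excludeChroms chromosomes excluded from the denominator.
#' @return The normalized [BinnedTrack-class].
#' @export
rpmNormalize <- function(track, excludeChroms = "chr8") {
  if (isNormalized(track)) stop("track is already normalized")
  included <- !names(track@values) %in% excludeChroms
  total <- sum(vapply(track@values[included], sum, numeric(1)))
  if (!is.finite(total) || total <= 0)
    stop("total signal over included chromosomes must be positive")
  track@values <- lapply(track@values, function(v) v * (1e6 / total))
  track@normalized <- TRUE
  track
}

#' Global change of a histone modification relative to a reference
#'
#' For each timepoint the ratio of total mapped signal between a modification
#' track (e.g. H3K27me3) and a reference track (H3, used for global
#' normalization in MINT-ChIP designs; H3.3 can be passed instead) is
#' computed; the reported change is the late ratio divided by the mean of the
#' early ratios.  A change of 0.5 at 72 h models the global H3K27me3 loss
#' seen under K27M.
#'
#' @param modTracks,refTracks named lists of [BinnedTrack-class], names are
#'   timepoints in hours (e.g. `"4"`, `"8"`, `"72"`).
#' @param early,late timepoints defining the early pool and the late point.
#' @return list with `ratioByTimepoint` (named numeric) and `change`.
#' @export
globalModificationChange <- function(modTracks, refTracks,
                                     early = c(4, 8), late = 72) {
  tps <- as.character(c(early, late))
  miss <- setdiff(tps, intersect(names(modTracks), names(refTracks)))
  if (length(miss))
    stop("timepoint(s) missing from tracks: ", paste(miss, collapse = ", "))
  ratio <- vapply(tps, function(t) {
    rt <- totalMapped(refTracks[[t]])
    if (rt <= 0) stop("zero reference total at timepoint ", t)
    totalMapped(modTracks[[t]]) / rt
  }, numeric(1))
  list(ratioByTimepoint = ratio,
       change = ratio[[as.character(late)]] /
         mean(ratio[as.character(early)]))
}

#' Genomic distribution of track signal over genic categories
#'
#' Each bin is assigned by its midpoint to exactly one of promoter, TTS,
#' gene body or intergenic, with precedence promoter > TTS > gene body.
#' Promoter and TTS windows are strand-oriented around the TSS/TTS (oriented
#' offsets, positive downstream).  Fractions are category signal over total
#' signal and sum to one.
#'
#' @param track a normalized [BinnedTrack-class].
#' @param genes gene `GRanges` from [readGeneTable()].
#' @param promoterWindow,ttsWindow oriented half-open offset windows in bp.
#' @return named numeric fractions over
#'   `c("promoter", "gene_body", "tts", "intergenic")`, with the windows as
#'   attributes.
#' @export
genicDistribution <- function(track, genes,
                              promoterWindow = c(-2000, 500),
                              ttsWindow = c(-1000, 1000)) {
  if (!isNormalized(track))
    stop("genicDistribution expects an RPM-normalized track")
  if (length(genes) == 0L) stop("empty gene list")
  lay <- track@layout
  bs <- lay@binSize
  nb <- nBins(lay)
  mask <- lapply(nb, function(n) integer(n))  # 0 intergenic 1 body 2 tts 3 prom
  strand <- as.character(GenomicRanges::strand(genes))
  chrom <- as.character(GenomicRanges::seqnames(genes))
  tss <- genes$tss
  tts <- ifelse(strand == "+", .end0(genes), .start0(genes))
  markLevel <- function(mask, chrom, lo, hi, level) {
    # bins whose midpoint m = b*bs + bs/2 satisfies lo <= m < hi
    n <- length(mask[[chrom]])
    half <- bs %/% 2
    bmin <- max(0, ceiling((lo - half) / bs))
    bmax <- min(n - 1, floor((hi - 1 - half) / bs))
    if (bmin <= bmax) {
      idx <- (bmin:bmax) + 1L
      mask[[chrom]][idx] <- pmax(mask[[chrom]][idx], level)
    }
    mask
  }
  orientedInterval <- function(a, s, w) {
    # genomic [lo, hi) of oriented offsets [w1, w2) around anchor a
    if (s == "+") c(a + w[1], a + w[2]) else c(a - w[2], a - w[1])
  }
  for (i in seq_along(genes)) {
    if (!chrom[i] %in% names(mask)) next
    pw <- orientedInterval(tss[i], strand[i], promoterWindow)
    tw <- orientedInterval(tts[i], strand[i], ttsWindow)
    mask <- markLevel(mask, chrom[i], pw[1], pw[2], 3L)
    mask <- markLevel(mask, chrom[i], tw[1], tw[2], 2L)
    mask <- markLevel(mask, chrom[i], .start0(genes)[i], .end0(genes)[i], 1L)
  }
  sums <- c(promoter = 0, gene_body = 0, tts = 0, intergenic = 0)
  for (cn in names(mask)) {
    v <- track@values[[cn]]; m <- mask[[cn]]
    sums["promoter"] <- sums["promoter"] + sum(v[m == 3L])
    sums["tts"] <- sums["tts"] + sum(v[m == 2L])
    sums["gene_body"] <- sums["gene_body"] + sum(v[m == 1L])
    sums["intergenic"] <- sums["intergenic"] + sum(v[m == 0L])
  }
  total <- sum(sums)
  if (total <= 0) stop("track carries no signal")
  structure(sums / total, promoterWindow = promoterWindow,
            ttsWindow = ttsWindow)
}
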