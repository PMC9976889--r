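# Synthetic-experiment generator: a small multi-chromosome genome with
# spaced genes and intergenic enhancers, expression programs shifting
# between an undifferentiated (ESC) and a differentiated (RA) state, and
# ChIP coverage with a double peak flanking each TSS whose amplitude scales
# with expression.  Mutant lines get a multiplicative TSS/enhancer
# incorporation boost, partial retention of the ESC program after
# differentiation, and a dependence of late expression on early binding.
# Every draw is a pure function of (config, seed).

#' Per-line simulation parameters
#'
#' @param tssBoost multiplicative H3.3 gain at the TSS-proximal component
#'   (>= 1; 1 for WT-like lines, 1.5 for the K27 mutants).
#' @param enhancerBoost same for the enhancer component.
#' @param retention fraction `r` in `[0, 1]` of ESC-program expression
#'   retained in the RA state.
#' @param coupling dependence `delta >= 0` of late (72 h) expression on the
#'   standardized early H3.3 amplitude.
#' @return named list of the four parameters.
#' @export
lineParams <- function(tssBoost = 1, enhancerBoost = 1, retention = 0,
                       coupling = 0) {
  if (tssBoost < 1 || enhancerBoost < 1) stop("boosts must be >= 1")
  if (retention < 0 || retention > 1) stop("retention must be in [0, 1]")
  if (coupling < 0) stop("coupling must be >= 0")
  list(tssBoost = tssBoost, enhancerBoost = enhancerBoost,
       retention = retention, coupling = coupling)
}

#' Simulation configuration
#'
#' The defaults are the stated experimental world: four lines (WT, K27M,
#' K27L, and the PRC2-inhibitor control GSK343), a 1.5x TSS/enhancer boost
#' and retention 0.6 / coupling 0.8 for the two mutants, 300 genes, two
#' replicates, timepoints 4/8/24/72 h with Dox-induction ramp
#' 0.4/0.6/0.85/1.0, 200 bp bins, and a double TSS peak at oriented offsets
#' -400/+600 bp.  See the methods vignette for the rationale behind the
#' noise and scale choices.
#'
#' @param seed master seed; every stream is derived from it.
#' @param nChroms number of chromosomes (2..8); the last one is named
#'   `"chr8"` to exercise the chromosome-8 exclusion.
#' @param chromLength chromosome length in bp.
#' @param nGenes,nEnhancers element counts.
#' @param binSize bin width in bp.
#' @param chr8Share fraction of genes placed on chr8.
#' @param lines named list of [lineParams()].
#' @param timepoints hours after Dox addition.
#' @param replicates biological replicates per condition.
#' @param expression,chip parameter lists; any supplied entries override the
#'   defaults printed by `str(simulationConfig()$expression)` /
#'   `...$chip`.
#' @return a validated config list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1,
                             nChroms = 4, chromLength = 3e6, nGenes = 300,
                             nEnhancers = 60, binSize = 200, chr8Share = 0.15,
                             lines = list(
                               WT = lineParams(),
                               K27M = lineParams(1.5, 1.5, 0.6, 0.8),
                               K27L = lineParams(1.5, 1.5, 0.6, 0.8),
                               GSK343 = lineParams()),
                             timepoints = c(4, 8, 24, 72),
                             replicates = 2,
                             expression = list(),
                             chip = list()) {
  exprDefaults <- list(nPluripotency = 50, nDifferentiation = 50,
                       logMean = 4, logSd = 1.5, programShift = 3,
                       dispersion = 0.05, libSize = 3e5)
  chipDefaults <- list(peakOffsets = c(-400, 600), peakWidths = c(250, 300),
                       gamma = 1, background = 1, backgroundLogSd = 0.25,
                       amplitude = 3, amplitudeLogSd = 1.2, depth = 30,
                       boostWindow = 1200, enhancerAmplitude = 2,
                       doxRamp = c("4" = 0.4, "8" = 0.6, "24" = 0.85,
                                   "72" = 1.0),
                       me3LossK27M = 0.5, acGainK27M = 1.3,
                       spacing = 30000, geneLengthRange = c(2000, 12000))
  expression <- utils::modifyList(exprDefaults, expression)
  chip <- utils::modifyList(chipDefaults, chip)
  cfg <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
              chromLength = chromLength, nGenes = as.integer(nGenes),
              nEnhancers = as.integer(nEnhancers),
              binSize = as.integer(binSize), chr8Share = chr8Share,
              lines = lines, timepoints = timepoints,
              replicates = as.integer(replicates),
              expression = expression, chip = chip)
  class(cfg) <- "SimulationConfig"
  .validateConfig(cfg)
  cfg
}

.validateConfig <- function(cfg) {
  with(cfg, {
    if (nChroms < 2 || nChroms > 8) stop("nChroms must be in 2..8")
    if (is.null(names(lines)) || any(!nzchar(names(lines))))
      stop("lines must be named")
    if (chr8Share < 0 || chr8Share >= 1) stop("chr8Share must be in [0, 1)")
    if (expression$nPluripotency + expression$nDifferentiation >
        nGenes - round(nGenes * chr8Share))
      stop("program sets do not fit among the non-chr8 genes")
    if (any(!timepoints %in% as.numeric(names(chip$doxRamp))))
      stop("every timepoint needs a doxRamp entry")
    if (expression$dispersion <= 0 || expression$libSize <= 0 ||
        chip$depth <= 0 || chip$background < 0 || chip$amplitude <= 0)
      stop("rates and sizes must be positive")
    for (l in lines) do.call(lineParams, l)  # re-validate
  })
  invisible(cfg)
}

#' Generate the synthetic genome: layout, gene table, enhancers
#'
#' Genes alternate strands and are placed on a 30 kb TSS grid, so no two
#' profile windows (+/-10 kb) overlap; gene bodies (2-12 kb) extend
#' downstream of their TSS.  One chromosome is named `chr8` and carries
#' `chr8Share` of the genes to exercise the exclusion logic.  Enhancers are
#' placed intergenically, halfway between adjacent TSS slots.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `layout` ([GenomeLayout-class]), `genes` (`GRanges`),
#'   `geneTable` (the UCSC-style data.frame), `enhancers` (width-1 anchor
#'   `GRanges`) and `enhancerTable` (BED6 data.frame).
#' @export
makeGenome <- function(cfg) {
  spacing <- cfg$chip$spacing
  margin <- 15000
  chroms <- c(paste0("chr", seq_len(cfg$nChroms - 1)), "chr8")
  nChr8 <- round(cfg$nGenes * cfg$chr8Share)
  nOther <- cfg$nGenes - nChr8
  per <- rep(nOther %/% (cfg$nChroms - 1), cfg$nChroms - 1)
  if (nOther %% (cfg$nChroms - 1) > 0)
    per[seq_len(nOther %% (cfg$nChroms - 1))] <-
      per[seq_len(nOther %% (cfg$nChroms - 1))] + 1L
  counts <- c(per, nChr8)
  maxSlot <- margin + (max(counts) - 1) * spacing
  if (maxSlot + margin > cfg$chromLength)
    stop("genome too small to place genes with the ", spacing,
         " bp TSS spacing guarantee")
  lens <- .withSeed(.subSeed(cfg$seed, "genome"), {
    round(runif(cfg$nGenes, cfg$chip$geneLengthRange[1],
                cfg$chip$geneLengthRange[2]))
  })
  rows <- list(); gi <- 0L
  enh <- list()
  for (ci in seq_along(chroms)) {
    k <- counts[ci]
    if (k == 0L) next
    slots <- margin + (seq_len(k) - 1) * spacing
    for (j in seq_len(k)) {
      gi <- gi + 1L
      strand <- if (gi %% 2L == 1L) "+" else "-"
      P <- slots[j]; L <- lens[gi]
      rows[[gi]] <- data.frame(
        name = sprintf("g%04d", gi), chrom = chroms[ci], strand = strand,
        txStart = if (strand == "+") P else P - L,
        txEnd = if (strand == "+") P + L else P)
    }
    if (k > 1L)
      enh[[ci]] <- data.frame(chrom = chroms[ci],
                              pos = slots[-k] + spacing %/% 2)
  }
  geneTable <- do.call(rbind, rows)
  enhAll <- do.call(rbind, enh)
  if (is.null(enhAll) || nrow(enhAll) < cfg$nEnhancers)
    stop("not enough intergenic slots for ", cfg$nEnhancers, " enhancers")
  enhAll <- enhAll[seq_len(cfg$nEnhancers), ]
  enhancerTable <- data.frame(chrom = enhAll$chrom, start = enhAll$pos - 100,
                              end = enhAll$pos + 100,
                              name = sprintf("e%04d", seq_len(cfg$nEnhancers)),
                              score = 0, strand = "+")
  layout <- genomeLayout(setNames(rep(cfg$chromLength, length(chroms)),
                                  chroms), cfg$binSize)
  genes <- .geneModel(geneTable$name, geneTable$chrom, geneTable$strand,
                      geneTable$txStart, geneTable$txEnd)
  enhancers <- anchorSet(enhancerTable$chrom, enhAll$pos,
                         enhancerTable$strand, enhancerTable$name)
  list(layout = layout, genes = genes, geneTable = geneTable,
       enhancers = enhancers, enhancerTable = enhancerTable)
}

#' Gene lengths (bp) from a gene GRanges
#'
#' @param genes gene `GRanges` with a `name` column.
#' @return named numeric vector of `txEnd - txStart`.
#' @export
geneLengths <- function(genes) {
  setNames(GenomicRanges::width(genes), genes$name)
}

# Pre-coupling linear mean expression of every gene for one (line, state).
# ESC: pluripotency program up by `shift` log2 units, differentiation
# program down; RA: the programs swap for WT, while a line with retention r
# keeps r * ESC-level + (1 - r) * WT-RA-level (linear mixture), symmetric
# for the differentiation program.
.stateMeanLin <- function(truth, cfg, line, state) {
  sh <- cfg$expression$programShift
  b <- truth$base
  up <- names(b) %in% truth$pluripotency
  dn <- names(b) %in% truth$differentiation
  esc <- 2^(b + sh * up - sh * dn)
  if (state == "ESC") return(esc)
  wtra <- 2^(b - sh * up + sh * dn)
  r <- cfg$lines[[line]]$retention
  r * esc + (1 - r) * wtra
}

# Binding amplitude of every gene for one (line-independent) state: the
# expression-percentile coupling pct^gamma times the gene's intrinsic
# log-normal binding propensity.  Returned in truth$amplitude[[line]][[state]].
.bindingAmplitude <- function(cfg, meanLin, eta) {
  pct <- rank(meanLin, ties.method = "average") / length(meanLin)
  cfg$chip$amplitude * pct^cfg$chip$gamma * 2^eta
}

#' Simulate the expression time course
#'
#' Negative-binomial counts around per-(line, state) mean profiles built
#' from a log-normal baseline and the two expression programs; the ESC
#' state exists at every timepoint, the RA state at 24 and 72 h.  At 72 h a
#' line's `coupling` adds `delta * z(log2 binding amplitude)` to the
#' log2-mean, tying late expression to early binding.  Deterministic under
#' the config seed.
#'
#' @param cfg a [simulationConfig()].
#' @param genome output of [makeGenome()].
#' @param lines,states,timepoints,replicates optional restrictions (defaults:
#'   everything in `cfg`).
#' @return list with `counts` (a counts `SummarizedExperiment` with `chrom`
#'   rowData) and `truth` (baseline, programs, binding propensity `eta`,
#'   per-line/state mean profiles and binding amplitudes).
#' @export
simulateExpression <- function(cfg, genome, lines = names(cfg$lines),
                               states = c("ESC", "RA"),
                               timepoints = cfg$timepoints,
                               replicates = seq_len(cfg$replicates)) {
  genes <- genome$geneTable$name
  nonChr8 <- genes[genome$geneTable$chrom != "chr8"]
  truth <- .withSeed(.subSeed(cfg$seed, "expression-truth"), {
    base <- setNames(rnorm(length(genes), cfg$expression$logMean,
                           cfg$expression$logSd), genes)
    picks <- sample(nonChr8, cfg$expression$nPluripotency +
                      cfg$expression$nDifferentiation)
    # the gene-intrinsic binding propensity is a property of the locus
    # (sequence, chromatin context) and therefore shared across the clonal
    # lines, like the baseline transcriptome
    eta <- setNames(rnorm(length(genes), 0, cfg$chip$amplitudeLogSd), genes)
    list(base = base,
         pluripotency = picks[seq_len(cfg$expression$nPluripotency)],
         differentiation = picks[-seq_len(cfg$expression$nPluripotency)],
         eta = eta)
  })
  truth$meanLin <- list(); truth$amplitude <- list(); truth$bindingZ <- list()
  for (ln in names(cfg$lines)) {
    truth$meanLin[[ln]] <- list(); truth$amplitude[[ln]] <- list()
    truth$bindingZ[[ln]] <- list()
    for (st in c("ESC", "RA")) {
      ml <- .stateMeanLin(truth, cfg, ln, st)
      A <- .bindingAmplitude(cfg, ml, truth$eta)
      truth$meanLin[[ln]][[st]] <- ml
      truth$amplitude[[ln]][[st]] <- A
      truth$bindingZ[[ln]][[st]] <- setNames(as.numeric(scale(log2(A))),
                                             names(A))
    }
  }
  samples <- list(); counts <- list()
  for (ln in lines) for (st in states) {
    tps <- if (st == "ESC") timepoints else intersect(timepoints, c(24, 72))
    for (tp in tps) for (rp in replicates) {
      mu <- truth$meanLin[[ln]][[st]]
      if (tp == 72 && cfg$lines[[ln]]$coupling > 0)
        mu <- mu * 2^(cfg$lines[[ln]]$coupling * truth$bindingZ[[ln]][[st]])
      p <- mu / sum(mu)
      id <- sprintf("%s_%s_%dh_r%d", ln, st, tp, rp)
      counts[[id]] <- .withSeed(
        .subSeed(cfg$seed, paste("expr", ln, st, tp, rp)),
        rnbinom(length(p), size = 1 / cfg$expression$dispersion,
                mu = p * cfg$expression$libSize))
      samples[[id]] <- data.frame(sample_id = id, line = ln, state = st,
                                  timepoint_h = tp, replicate = rp)
    }
  }
  if (length(counts) == 0L) stop("no samples selected")
  mat <- do.call(cbind, counts)
  rownames(mat) <- genes
  meta <- do.call(rbind, samples)
  list(counts = countsExperiment(mat, meta, chrom = genome$geneTable$chrom),
       truth = truth)
}

# Gaussian peak shape evaluated at oriented offsets.
.peakShape <- function(mids, offsets, widths) {
  s <- 0
  for (i in seq_along(offsets))
    s <- s + exp(-(mids - offsets[i])^2 / (2 * widths[i]^2))
  s
}

#' Simulate one ChIP coverage track
#'
#' H3.3 (HA) tracks carry a double peak at oriented offsets -400/+600 bp
#' from every TSS with amplitude proportional to the gene's expression
#' percentile (power `gamma`) times its intrinsic binding propensity, an
#' enhancer component, and a flat background with log-normal occupancy
#' noise; the line's `tssBoost` multiplies the peak component within
#' +/-1.2 kb of the TSS, ramping in with the Dox-induction kinetics
#' (0.4/0.6/0.85/1.0 of steady state at 4/8/24/72 h), which also scale the
#' overall tagged-histone amount.  H3 is flat occupancy; H3K27me3 loses and
#' H3K27ac gains total signal under K27M only.  Bin-level noise is Poisson
#' at `depth` reads per unit signal.  Deterministic under the config seed.
#'
#' @param cfg a [simulationConfig()].
#' @param genome output of [makeGenome()].
#' @param truth truth component of [simulateExpression()] (matching states).
#' @param line,timepoint,state,replicate sample coordinates.
#' @param antibody one of `"H3.3"`, `"H3"`, `"H3K27me3"`, `"H3K27ac"`.
#' @return coverage `GRanges` (`score` = simulated read counts per bin);
#'   zero-count bins are omitted.
#' @export
simulateChip <- function(cfg, genome, truth, line, timepoint, state = "ESC",
                         replicate = 1,
                         antibody = c("H3.3", "H3", "H3K27me3", "H3K27ac")) {
  antibody <- match.arg(antibody)
  if (!line %in% names(cfg$lines)) stop("unknown line: ", line)
  if (!as.character(timepoint) %in% names(cfg$chip$doxRamp))
    stop("unknown timepoint: ", timepoint)
  ramp <- unname(cfg$chip$doxRamp[as.character(timepoint)])
  ch <- cfg$chip
  bs <- cfg$binSize
  lay <- genome$layout
  nb <- nBins(lay)
  gt <- genome$geneTable
  # first transcribed base: tss on '+', tss - 1 on '-' (D1 convention)
  tssBase <- ifelse(gt$strand == "+", gt$txStart, gt$txEnd - 1)
  tbin <- as.integer(tssBase %/% bs)
  sgn <- ifelse(gt$strand == "+", 1L, -1L)
  seed <- .subSeed(cfg$seed, paste("chip", line, state, timepoint, replicate,
                                   antibody))
  etaE <- .withSeed(.subSeed(cfg$seed, "enhancer-truth"),
                    rnorm(nrow(genome$enhancerTable), 0, ch$amplitudeLogSd))
  .withSeed(seed, {
    signal <- lapply(nb, function(n)
      ch$background * 2^rnorm(n, 0, ch$backgroundLogSd))
    if (antibody %in% c("H3.3", "H3K27ac")) {
      dd <- -10:9
      mids <- dd * bs + bs %/% 2
      if (antibody == "H3.3") {
        shape <- .peakShape(mids, ch$peakOffsets, ch$peakWidths)
        beta <- cfg$lines[[line]]$tssBoost
        boost <- ifelse(abs(mids) <= ch$boostWindow,
                        1 + (beta - 1) * ramp, 1)
        A <- truth$amplitude[[line]][[state]][gt$name] * ramp
      } else {
        shape <- .peakShape(mids, 0, 500)
        boost <- rep(1, length(mids))
        pct <- rank(truth$meanLin[[line]][[state]][gt$name],
                    ties.method = "average") / nrow(gt)
        A <- 2 * pct
      }
      contrib <- outer(unname(A), shape * boost)
      bins <- outer(tbin, rep(1L, length(dd))) + outer(sgn, dd)
      for (cn in unique(gt$chrom)) {
        i <- gt$chrom == cn
        acc <- rowsum(as.vector(contrib[i, , drop = FALSE]),
                      as.vector(bins[i, , drop = FALSE]))
        idx <- as.integer(rownames(acc)) + 1L
        signal[[cn]][idx] <- signal[[cn]][idx] + acc[, 1]
      }
      if (antibody == "H3.3") {
        eBoost <- 1 + (cfg$lines[[line]]$enhancerBoost - 1) * ramp
        dd2 <- -5:4
        mids2 <- dd2 * bs + bs %/% 2
        shape2 <- .peakShape(mids2, 0, 300) *
          ifelse(abs(mids2) <= 600, eBoost, 1)
        Ae <- ch$enhancerAmplitude * 2^etaE * ramp
        ebin <- as.integer(genome$enhancerTable$start + 100) %/% bs
        binsE <- outer(ebin, rep(1L, length(dd2))) + outer(rep(1L, length(ebin)), dd2)
        contribE <- outer(Ae, shape2)
        for (cn in unique(genome$enhancerTable$chrom)) {
          i <- genome$enhancerTable$chrom == cn
          acc <- rowsum(as.vector(contribE[i, , drop = FALSE]),
                        as.vector(binsE[i, , drop = FALSE]))
          idx <- as.integer(rownames(acc)) + 1L
          signal[[cn]][idx] <- signal[[cn]][idx] + acc[, 1]
        }
      }
    }
    factor <- 1
    if (antibody == "H3K27me3" && line == "K27M")
      factor <- 1 - (1 - ch$me3LossK27M) * ramp
    if (antibody == "H3K27ac" && line == "K27M")
      factor <- 1 + (ch$acGainK27M - 1) * ramp
    si <- GenomeInfoDb::Seqinfo(lay@chromNames, lay@chromLengths)
    grs <- lapply(names(signal), function(cn) {
      counts <- rpois(nb[[cn]], ch$depth * factor * signal[[cn]])
      keep <- counts > 0
      if (!any(keep)) return(NULL)
      b0 <- which(keep) - 1L
      GenomicRanges::GRanges(cn,
        IRanges::IRanges(start = b0 * bs + 1,
                         end = pmin((b0 + 1) * bs, .chromLength(lay, cn))),
        score = as.numeric(counts[keep]), seqinfo = si)
    })
    do.call(c, grs[!vapply(grs, is.null, logical(1))])
  })
}
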