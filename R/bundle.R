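# On-disk synthetic bundles and the end-to-end pipeline over them.

#' Write a complete synthetic experiment bundle to disk
#'
#' Generates the genome (layout JSON, UCSC-style gene table, enhancer BED),
#' the expression time course (counts + sample metadata TSV), per-sample
#' ChIP bedGraph tracks, the ground-truth record and a manifest with MD5
#' checksums.  All files are plain text in exactly the dialects the package
#' readers accept, and re-running with the same config seed reproduces them
#' byte for byte.
#'
#' @param cfg a [simulationConfig()].
#' @param outDir output directory (created; must be empty unless `force`).
#' @param force overwrite a non-empty directory.
#' @param antibodies ChIP antibodies to emit per sample (default `"H3.3"`).
#' @param chipStates states in which ChIP tracks are generated (default
#'   `"ESC"`; RA-state tracks can be simulated in memory via
#'   [simulateChip()]).
#' @return invisibly, a list with `dir` and the `manifest`.
#' @export
generateBundle <- function(cfg, outDir, force = FALSE,
                           antibodies = "H3.3", chipStates = "ESC") {
  if (dir.exists(outDir) && length(dir(outDir, all.files = TRUE,
                                       no.. = TRUE)) > 0 && !force)
    stop("output directory exists and is not empty (use force = TRUE)")
  dir.create(file.path(outDir, "bedgraph"), recursive = TRUE,
             showWarnings = FALSE)
  genome <- makeGenome(cfg)
  sim <- simulateExpression(cfg, genome)
  files <- character()
  emit <- function(rel) { files <<- c(files, rel); file.path(outDir, rel) }

  jsonlite::write_json(
    list(binSize = cfg$binSize,
         chromLengths = as.list(chromLengths(genome$layout))),
    emit("layout.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(genome$geneTable, emit("genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(genome$enhancerTable, emit("enhancers.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  counts <- SummarizedExperiment::assay(sim$counts, "counts")
  utils::write.table(data.frame(gene = rownames(counts), counts,
                                check.names = FALSE),
                     emit("counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    as.data.frame(SummarizedExperiment::colData(sim$counts)),
    emit("samples.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(base = as.list(sim$truth$base),
         pluripotency = sim$truth$pluripotency,
         differentiation = sim$truth$differentiation,
         eta = as.list(sim$truth$eta),
         lines = cfg$lines),
    emit("truth.json"), auto_unbox = TRUE, digits = NA)

  for (ln in names(cfg$lines)) for (st in chipStates) {
    tps <- if (st == "ESC") cfg$timepoints else
      intersect(cfg$timepoints, c(24, 72))
    for (tp in tps) for (rp in seq_len(cfg$replicates)) for (ab in antibodies) {
      cov <- simulateChip(cfg, genome, sim$truth, ln, tp, state = st,
                          replicate = rp, antibody = ab)
      rel <- sprintf("bedgraph/%s_%s_%dh_r%d_%s.bedGraph", ln, st, tp, rp,
                     gsub("[^A-Za-z0-9]", "", ab))
      writeBedGraph(cov, emit(rel))
    }
  }
  manifest <- list(
    seed = cfg$seed,
    files = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(file.path(outDir, f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = outDir, manifest = manifest))
}

# Parse a bundle bedGraph file name back into its sample coordinates.
.parseTrackName <- function(rel) {
  m <- regmatches(rel, regexec(
    "([^/]+)_([^_]+)_(\\d+)h_r(\\d+)_([^.]+)\\.bedGraph$", rel))[[1]]
  if (length(m) == 0L) return(NULL)
  list(line = m[2], state = m[3], timepoint = as.numeric(m[4]),
       replicate = as.integer(m[5]), antibody = m[6])
}

#' Run the full downstream pipeline on a synthetic bundle
#'
#' Reads a [generateBundle()] directory back through the package's format
#' readers and executes the complete analysis: binning + RPM normalization
#' of every H3.3 track, replicate-averaged TSS window scores, 72 h metagene
#' profiles, the timepoint-stability correlation matrix, TPM normalization
#' (chromosome 8 excluded), binding-expression correlations, ESC-RA
#' state-retention correlations, and the early-binding to late-expression
#' retention-ratio procedure with Fisher tests.  All outputs are written as
#' deterministic TSV/JSON.
#'
#' @param bundleDir directory written by [generateBundle()].
#' @param outDir output directory for result files (created).
#' @param flank metagene half-window (bp).
#' @param bindingQuantile,exprQuantile thresholds of the retention-ratio
#'   procedure.
#' @return invisibly, the summary list written to `summary.json`.
#' @export
runPipeline <- function(bundleDir, outDir, flank = 10000,
                        bindingQuantile = 0.75, exprQuantile = 0.5) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  lay <- .readLayout(file.path(bundleDir, "layout.json"))
  genes <- readGeneTable(file.path(bundleDir, "genes.tsv"))
  counts <- readCountsTable(file.path(bundleDir, "counts.tsv"),
                            file.path(bundleDir, "samples.tsv"))
  # gene lengths + chromosomes from the gene table
  SummarizedExperiment::rowData(counts)$chrom <-
    as.character(GenomicRanges::seqnames(genes))[
      match(rownames(counts), genes$name)]
  expr <- tpmNormalize(counts, geneLengths(genes))
  anchors <- tssAnchors(genes)

  tracks <- list()
  for (f in dir(file.path(bundleDir, "bedgraph"), full.names = TRUE)) {
    info <- .parseTrackName(f)
    if (is.null(info) || info$antibody != "H33") next
    cov <- readBedGraph(f, lay)
    key <- sprintf("%s_%s_%gh", info$line, info$state, info$timepoint)
    tr <- rpmNormalize(binCoverage(cov, lay, sampleMeta = info))
    tracks[[key]] <- c(tracks[[key]], list(tr))
  }
  if (length(tracks) == 0L) stop("no H3.3 tracks found in the bundle")

  # replicate-averaged window scores per (line, timepoint)
  scores <- lapply(tracks, function(reps) {
    s <- lapply(reps, geneWindowScore, genes = genes)
    Reduce(`+`, s) / length(s)
  })
  scoreTab <- data.frame(gene = names(scores[[1]]),
                         vapply(scores, function(s) s[names(scores[[1]])],
                                numeric(length(scores[[1]]))),
                         check.names = FALSE)
  utils::write.table(.fmtNum(scoreTab), file.path(outDir, "window_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  lines <- unique(vapply(strsplit(names(tracks), "_"), `[`, character(1), 1))
  lateKey <- function(ln) grep(sprintf("^%s_ESC_72h$", ln), names(tracks),
                               value = TRUE)
  summary <- list()

  # 72 h metagene profiles per line
  for (ln in lines) {
    k <- lateKey(ln)
    if (length(k) != 1L) next
    pm <- lapply(tracks[[k]], anchorMatrix, anchors = anchors, flank = flank)
    avg <- pm[[1]]
    avg@values <- Reduce(`+`, lapply(pm, profileValues)) / length(pm)
    prof <- metageneProfile(avg)
    utils::write.table(.fmtNum(prof),
                       file.path(outDir, sprintf("metagene_%s.tsv", ln)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tssCols <- abs(avg@offsets + avg@binSize %/% 2) <= 1200
    summary$metageneTssMean[[ln]] <-
      mean(profileValues(avg)[, tssCols])
  }

  # timepoint stability (replicates as the two independent experiments)
  wtKeys <- grep("^WT_ESC_", names(tracks), value = TRUE)
  if (length(wtKeys) >= 2L) {
    tp <- sub("^WT_ESC_(\\d+)h$", "\\1", wtKeys)
    e1 <- lapply(tracks[wtKeys], function(r) geneWindowScore(r[[1]], genes))
    names(e1) <- tp
    e2 <- NULL
    if (all(vapply(tracks[wtKeys], length, integer(1)) >= 2L)) {
      e2 <- lapply(tracks[wtKeys], function(r) geneWindowScore(r[[2]], genes))
      names(e2) <- tp
    }
    stab <- timepointStability(e1, e2)
    utils::write.table(data.frame(sample = rownames(stab),
                                  .fmtNum(as.data.frame(stab))),
                       file.path(outDir, "stability_WT.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$stabilityMinOffDiag <- min(stab[upper.tri(stab)])
  }

  # binding-expression coupling at 72 h (ESC)
  for (ln in lines) {
    k <- lateKey(ln)
    esc72 <- sampleSelect(expr, line = ln, state = "ESC", timepoint = 72)
    if (length(k) == 1L && length(esc72) > 0)
      summary$bindingExpressionRho[[ln]] <-
        bindingExpressionCorrelation(scores[[k]], expr, esc72)$rho
  }

  # state retention (ESC vs RA expression)
  for (ln in lines) {
    ok <- length(sampleSelect(expr, line = ln, state = "RA")) > 0
    if (ok)
      summary$retentionRho[[ln]] <-
        stateRetentionCorrelation(expr, ln)$rho
  }

  # early binding -> late expression contingency
  early <- grep("_ESC_8h$", names(tracks), value = TRUE)
  if (length(early) >= 1L) {
    sets <- list()
    for (k in early) {
      ln <- sub("_ESC_8h$", "", k)
      esc72 <- sampleSelect(expr, line = ln, state = "ESC", timepoint = 72)
      if (length(esc72) == 0) next
      sets[[ln]] <- list(
        high = highBindingGeneSet(scores[[k]], bindingQuantile),
        late = expressedLateGeneSet(expr, esc72, exprQuantile),
        universe = rownames(expr))
    }
    if (length(sets) >= 1L) {
      rr <- retentionRatioTest(sets)
      utils::write.table(.fmtNum(rr$perLine),
                         file.path(outDir, "retention_ratio.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      summary$retentionRatio <- setNames(rr$perLine$ratio, rr$perLine$line)
      if (!is.null(rr$comparisons))
        summary$retentionFisherP <-
          setNames(rr$comparisons$pValue,
                   paste(rr$comparisons$lineA, rr$comparisons$lineB,
                         sep = "_vs_"))
    }
  }

  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

.readLayout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  genomeLayout(unlist(j$chromLengths), j$binSize)
}

# Format numeric columns with fixed 12 significant digits for byte-stable
# output files.
.fmtNum <- function(df) {
  for (i in seq_along(df))
    if (is.numeric(df[[i]])) df[[i]] <- sprintf("%.12g", df[[i]])
  df
}
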