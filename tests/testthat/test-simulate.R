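smallCfg <- function(seed = 1, ...) {
  simulationConfig(seed = seed, nGenes = 60, nChroms = 3, chromLength = 9e5,
                   nEnhancers = 5, replicates = 1,
                   expression = list(nPluripotency = 12,
                                     nDifferentiation = 12), ...)
}

test_that("configuration is validated", {
  expect_error(lineParams(tssBoost = 0.5), "boosts")
  expect_error(lineParams(retention = 1.2), "retention")
  expect_error(lineParams(coupling = -1), "coupling")
  expect_error(simulationConfig(nChroms = 1), "nChroms")
  expect_error(simulationConfig(nGenes = 20, expression =
                                  list(nPluripotency = 50)), "program sets")
  expect_error(simulationConfig(timepoints = c(4, 16)), "doxRamp")
})

test_that("makeGenome honours spacing, strand alternation and chr8 share", {
  cfg <- smallCfg()
  g <- makeGenome(cfg)
  expect_equal(sum(g$geneTable$chrom == "chr8"), round(60 * 0.15))
  expect_setequal(unique(g$geneTable$strand), c("-", "+"))

  # minimum pairwise TSS distance >= 30 kb within every chromosome
  tss <- ifelse(g$geneTable$strand == "+", g$geneTable$txStart,
                g$geneTable$txEnd)
  for (cn in unique(g$geneTable$chrom)) {
    d <- diff(sort(tss[g$geneTable$chrom == cn]))
    if (length(d)) expect_true(all(d >= 30000))
  }

  # outputs parse through the format readers
  gf <- tempfile(); ef <- tempfile()
  write.table(g$geneTable, gf, sep = "\t", quote = FALSE, row.names = FALSE)
  genes <- readGeneTable(gf)
  expect_equal(length(genes), 60L)
  expect_equal(genes$tss, tss)
  write.table(g$enhancerTable, ef, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  anc <- readBedAnchors(ef)
  expect_equal(length(anc), 5L)

  # enhancers are intergenic
  hits <- GenomicRanges::countOverlaps(anc, g$genes, ignore.strand = TRUE)
  expect_true(all(hits == 0))

  expect_error(makeGenome(simulationConfig(nGenes = 300, chromLength = 1e6)),
               "too small")
})

test_that("expression retention degenerate cases match their definitions", {
  cfg0 <- smallCfg(lines = list(WT = lineParams(),
                                M = lineParams(1.5, 1.5, 0, 0)))
  g <- makeGenome(cfg0)
  sim0 <- simulateExpression(cfg0, g)
  # r = 0: mutant RA means equal WT RA means
  expect_equal(sim0$truth$meanLin$M$RA, sim0$truth$meanLin$WT$RA)

  cfg1 <- smallCfg(lines = list(WT = lineParams(),
                                M = lineParams(1.5, 1.5, 1, 0)))
  sim1 <- simulateExpression(cfg1, makeGenome(cfg1))
  # r = 1: mutant RA means equal mutant ESC means
  expect_equal(sim1$truth$meanLin$M$RA, sim1$truth$meanLin$M$ESC)

  expect_error(smallCfg(lines = list(WT = lineParams(retention = 2))),
               "retention")
})

test_that("simulation is deterministic in the seed", {
  cfg <- smallCfg(seed = 7)
  g1 <- makeGenome(cfg); g2 <- makeGenome(cfg)
  expect_identical(g1$geneTable, g2$geneTable)
  s1 <- simulateExpression(cfg, g1); s2 <- simulateExpression(cfg, g2)
  expect_identical(SummarizedExperiment::assay(s1$counts),
                   SummarizedExperiment::assay(s2$counts))
  c1 <- simulateChip(cfg, g1, s1$truth, "WT", 8)
  c2 <- simulateChip(cfg, g2, s2$truth, "WT", 8)
  expect_identical(c1$score, c2$score)

  other <- smallCfg(seed = 8)
  s3 <- simulateExpression(other, makeGenome(other))
  expect_false(identical(SummarizedExperiment::assay(s1$counts),
                         SummarizedExperiment::assay(s3$counts)))
  expect_error(simulateChip(cfg, g1, s1$truth, "nope", 8), "unknown line")
  expect_error(simulateChip(cfg, g1, s1$truth, "WT", 11), "unknown timepoint")
})

test_that("the simulated double peak lands at the configured offsets", {
  cfg <- smallCfg(seed = 3)
  g <- makeGenome(cfg)
  sim <- simulateExpression(cfg, g)
  tr <- rpmNormalize(binCoverage(simulateChip(cfg, g, sim$truth, "WT", 72),
                                 g$layout))
  prof <- metageneProfile(anchorMatrix(tr, tssAnchors(g$genes)))
  top <- prof$offset[order(-prof$mean)[1:4]]
  # peaks at -400 and +600 live in offset bins [-600,-400,-200] / [400,600]
  expect_true(any(top %in% c(-600, -400)))
  expect_true(any(top %in% c(400, 600)))
})

test_that("TSS window gain is monotone in the incorporation boost", {
  gain <- sapply(c(1, 1.25, 1.5), function(beta) {
    mean(sapply(1:4, function(seed) {
      cfg <- smallCfg(seed = seed,
                      lines = list(WT = lineParams(),
                                   M = lineParams(beta, beta, 0, 0)))
      g <- makeGenome(cfg)
      sim <- simulateExpression(cfg, g, states = "ESC", timepoints = 72)
      sc <- lapply(c(WT = "WT", M = "M"), function(ln)
        geneWindowScore(rpmNormalize(binCoverage(
          simulateChip(cfg, g, sim$truth, ln, 72), g$layout)), g$genes))
      mean(sc$M) - mean(sc$WT)
    }))
  })
  expect_true(all(diff(gain) > 0))
})

test_that("bundles are byte-identical under one seed and parse end to end", {
  cfg <- smallCfg(seed = 5, timepoints = c(8, 72))
  d1 <- file.path(tempdir(), "bundle1"); d2 <- file.path(tempdir(), "bundle2")
  unlink(c(d1, d2), recursive = TRUE)
  b1 <- generateBundle(cfg, d1)
  b2 <- generateBundle(cfg, d2)
  expect_identical(b1$manifest$files, b2$manifest$files)
  expect_error(generateBundle(cfg, d1), "not empty")

  other <- generateBundle(smallCfg(seed = 6, timepoints = c(8, 72)), d2,
                          force = TRUE)
  expect_false(identical(b1$manifest$files[names(b1$manifest$files)],
                         other$manifest$files[names(other$manifest$files)]))

  out <- runPipeline(d1, file.path(d1, "out"))
  expect_true(all(c("window_scores.tsv", "stability_WT.tsv", "summary.json",
                    "retention_ratio.tsv") %in% dir(file.path(d1, "out"))))
  expect_true(all(unlist(out$bindingExpressionRho) > 0))
})
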