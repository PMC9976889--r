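# in-memory expression fixtures
makeExpr <- function(tpm, meta = NULL) {
  if (is.null(meta))
    meta <- data.frame(sample_id = colnames(tpm), line = "WT", state = "ESC",
                       timepoint_h = 72, replicate = seq_len(ncol(tpm)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = tpm),
    colData = S4Vectors::DataFrame(meta, row.names = meta$sample_id))
}

test_that("tpmNormalize matches hand arithmetic and excludes chr8 first", {
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  meta <- data.frame(sample_id = "s1", line = "WT", state = "ESC",
                     timepoint_h = 4, replicate = 1)
  se <- countsExperiment(counts, meta)
  out <- tpmNormalize(se, c(a = 100, b = 100), excludeChroms = NULL)
  expect_equal(unname(SummarizedExperiment::assay(out, "tpm")[, 1]),
               c(5e5, 5e5))

  out2 <- tpmNormalize(se, c(a = 100, b = 200), excludeChroms = NULL)
  expect_equal(unname(SummarizedExperiment::assay(out2, "tpm")[, 1]),
               c(2, 1) / 3 * 1e6)

  one <- countsExperiment(matrix(7, 1, 1, dimnames = list("a", "s1")), meta)
  expect_equal(unname(SummarizedExperiment::assay(
    tpmNormalize(one, c(a = 50), excludeChroms = NULL), "tpm")[, 1]), 1e6)

  # chr8 genes are removed before normalization: remaining columns sum to 1e6
  se8 <- countsExperiment(matrix(c(10, 10, 1000), 3, 1,
                                 dimnames = list(c("a", "b", "c8"), "s1")),
                          meta, chrom = c("chr1", "chr1", "chr8"))
  out8 <- tpmNormalize(se8, c(a = 100, b = 100, c8 = 100))
  expect_equal(rownames(out8), c("a", "b"))
  expect_equal(sum(SummarizedExperiment::assay(out8, "tpm")), 1e6)

  # subsetting afterwards must NOT silently renormalize
  sub <- out8[1, ]
  expect_lt(sum(SummarizedExperiment::assay(sub, "tpm")), 1e6)

  zero <- countsExperiment(matrix(0, 2, 1, dimnames = list(c("a", "b"), "s1")),
                           meta)
  expect_error(tpmNormalize(zero, c(a = 1, b = 1), excludeChroms = NULL),
               "all-zero")
  expect_error(tpmNormalize(se, c(a = 100), excludeChroms = NULL), "lengths")
})

test_that("tpm column sums are 1e6 on random counts", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(5:30, 1); m <- sample(2:5, 1)
    counts <- matrix(rpois(n * m, 40), n, m,
                     dimnames = list(sprintf("g%02d", 1:n),
                                     sprintf("s%d", 1:m)))
    meta <- data.frame(sample_id = colnames(counts), line = "WT",
                       state = "ESC", timepoint_h = 4, replicate = 1:m)
    out <- tpmNormalize(countsExperiment(counts, meta),
                        setNames(sample(100:5000, n), rownames(counts)),
                        excludeChroms = NULL)
    expect_equal(unname(colSums(SummarizedExperiment::assay(out, "tpm"))),
                 rep(1e6, m))
  }
})

test_that("collapseVariants takes the per-sample maximum", {
  tpm <- matrix(c(3, 7, 5,
                  6, 2, 5), 3, 2,
                dimnames = list(c("v1", "v2", "u1"), c("s1", "s2")))
  expr <- makeExpr(tpm)
  vm <- c(v1 = "gA", v2 = "gA", u1 = "gB")
  out <- collapseVariants(expr, vm)
  x <- SummarizedExperiment::assay(out, "tpm")
  expect_equal(x["gA", ], c(s1 = 7, s2 = 6))  # different variant per sample
  expect_equal(x["gB", ], c(s1 = 5, s2 = 5))  # single variant: identity
  expect_error(collapseVariants(expr, vm[1:2]), "unmapped")
})

test_that("classifyDE requires both fold-change and significance", {
  set.seed(17)
  n <- 40
  base <- matrix(rnorm(n * 6, 100, 5), n, 6,
                 dimnames = list(sprintf("g%02d", 1:n), sprintf("s%d", 1:6)))
  base[base < 0] <- 0
  meta <- data.frame(sample_id = colnames(base), line = "WT", state = "ESC",
                     timepoint_h = 72, replicate = 1:6)
  A <- paste0("s", 1:3); B <- paste0("s", 4:6)

  # identical groups: everything ns
  dup <- base; dup[, 4:6] <- base[, 1:3]
  de0 <- classifyDE(makeExpr(dup, meta), A, B)
  expect_true(all(de0$call == "ns"))

  # one strong gene: means ~300 vs ~100 with tight replicates -> up
  up <- base
  up["g01", A] <- c(300, 301, 299); up["g01", B] <- c(100, 101, 99)
  de1 <- classifyDE(makeExpr(up, meta), A, B)
  expect_equal(de1$call[de1$gene == "g01"], "up")
  expect_gt(2^de1$log2FC[de1$gene == "g01"], 2)

  # fold change 2.5 but q = 0.2 (external p) stays ns
  fc25 <- base
  fc25["g02", A] <- base["g02", B] * 2.5 + 1.5
  pv <- setNames(rep(0.5, n), rownames(base)); pv["g02"] <- 0.2
  de2 <- classifyDE(makeExpr(fc25, meta), A, B, pValues = pv)
  expect_gt(2^de2$log2FC[de2$gene == "g02"], 2)
  expect_equal(de2$call[de2$gene == "g02"], "ns")

  # calls invariant under sample permutation within groups
  de3 <- classifyDE(makeExpr(up, meta), A[c(3, 1, 2)], B[c(2, 3, 1)])
  expect_equal(de3$call, de1$call)

  expect_error(classifyDE(makeExpr(up, meta), "s1", B), ">= 2 replicates")
})

test_that("genesHigherIn is antisymmetric and monotone in the cutoff", {
  genes <- sprintf("g%02d", 1:30)
  set.seed(9)
  tpm <- cbind(matrix(rexp(60, 1 / 50), 30, 2), matrix(rexp(60, 1 / 50), 30, 2))
  dimnames(tpm) <- list(genes, c("a1", "a2", "b1", "b2"))
  meta <- data.frame(sample_id = colnames(tpm),
                     line = rep(c("K27M", "WT"), each = 2), state = "RA",
                     timepoint_h = 72, replicate = c(1, 2, 1, 2))
  expr <- makeExpr(tpm, meta)

  g2 <- genesHigherIn(expr, "RA", "K27M", "WT", cutoff = 2)
  g2r <- genesHigherIn(expr, "RA", "WT", "K27M", cutoff = 2)
  expect_equal(g2$aOverB$genes, g2r$bOverA$genes)
  expect_equal(g2$bOverA$genes, g2r$aOverB$genes)

  g15 <- genesHigherIn(expr, "RA", "K27M", "WT", cutoff = 1.5)
  expect_true(all(g2$aOverB$genes %in% g15$aOverB$genes))
  expect_true(all(g2$bOverA$genes %in% g15$bOverA$genes))
  expect_equal(length(intersect(g2$aOverB$genes, g2$bOverA$genes)), 0L)

  flat <- makeExpr(matrix(5, 30, 4, dimnames = dimnames(tpm)), meta)
  g0 <- genesHigherIn(flat, "RA", "K27M", "WT")
  expect_equal(length(g0$aOverB$genes), 0L)
  expect_equal(length(g0$bOverA$genes), 0L)
  expect_error(genesHigherIn(expr, "ESC", "K27M", "WT"), "missing")
})

test_that("groupExpressionCompare reports means and U-test p", {
  genes <- sprintf("g%03d", 1:500)
  set.seed(23)
  tpm <- matrix(rexp(1000, 1 / 100), 500, 2,
                dimnames = list(genes, c("s1", "s2")))
  expr <- makeExpr(tpm)

  same <- groupExpressionCompare(genes, genes, expr, c("s1", "s2"))
  expect_equal(same$pValue, 1)

  # group from the top expression decile separates strongly
  mv <- rowMeans(tpm)
  top <- names(sort(mv, decreasing = TRUE))[1:50]
  out <- groupExpressionCompare(top, NULL, expr, c("s1", "s2"))
  expect_lt(out$pValue, 1e-3)
  expect_gt(out$meanGroup, out$meanBackground)

  # singleton group against a small background uses the exact U path
  small <- makeExpr(tpm[1:9, , drop = FALSE])
  one <- groupExpressionCompare(genes[1], genes[1:9], small, "s1")
  expect_true(one$pValue >= 2 / 10 - 1e-12)  # exact enumeration granularity

  expect_error(groupExpressionCompare(c("nope"), NULL, expr, "s1"), "empty")
})

test_that("stateRetentionCorrelation pools states and correlates genes", {
  genes <- sprintf("g%02d", 1:40)
  set.seed(2)
  esc <- matrix(rexp(80, 1 / 100), 40, 2)
  meta <- data.frame(
    sample_id = c("e1", "e2", "r24", "r72"), line = "K27M",
    state = c("ESC", "ESC", "RA", "RA"), timepoint_h = c(4, 72, 24, 72),
    replicate = c(1, 2, 1, 1))

  # identical states: rho = 1
  tpm <- cbind(esc, esc)
  dimnames(tpm) <- list(genes, meta$sample_id)
  expr <- makeExpr(tpm, meta)
  expect_equal(stateRetentionCorrelation(expr, "K27M")$rho, 1)

  # independent states: rho near 0
  tpm2 <- cbind(esc, matrix(rexp(80, 1 / 100), 40, 2))
  dimnames(tpm2) <- list(genes, meta$sample_id)
  out <- stateRetentionCorrelation(makeExpr(tpm2, meta), "K27M")
  expect_lt(abs(out$rho), 0.45)
  expect_error(stateRetentionCorrelation(expr, "WT"), "must have samples")
})

test_that("retention correlation rises with the generator's r parameter", {
  rhos <- sapply(c(0, 0.5, 1), function(r) {
    mean(sapply(1:6, function(seed) {
      cfg <- simulationConfig(seed = seed, nGenes = 60, nChroms = 3,
                              chromLength = 9e5, nEnhancers = 5,
                              lines = list(WT = lineParams(),
                                           K27M = lineParams(1.5, 1.5, r, 0)),
                              replicates = 1, timepoints = c(24, 72),
                              expression = list(nPluripotency = 12,
                                                nDifferentiation = 12))
      g <- makeGenome(cfg)
      sim <- simulateExpression(cfg, g)
      expr <- tpmNormalize(sim$counts, geneLengths(g$genes))
      stateRetentionCorrelation(expr, "K27M")$rho
    }))
  })
  expect_true(all(diff(rhos) > 0))
})
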