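test_that("spearmanCorrelation matches the rank-Pearson oracle, with ties", {
  expect_equal(spearmanCorrelation(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearmanCorrelation(1:3, c(30, 20, 10))$rho, -1)

  x <- c(1, 1, 2, 3); y <- c(2, 1, 4, 3)
  expect_equal(spearmanCorrelation(x, y)$rho, oracleSpearmanRho(x, y))

  set.seed(5)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearmanCorrelation(x, y)$rho, oracleSpearmanRho(x, y))
  }
  expect_error(spearmanCorrelation(rep(1, 5), 1:5), "constant")
  expect_error(spearmanCorrelation(1:2, 1:2), "at least 3")
})

test_that("spearman p-values: exact enumeration below n = 10, t above", {
  set.seed(8)
  for (i in 1:5) {
    n <- sample(4:6, 1)
    x <- rnorm(n); y <- rnorm(n)
    out <- spearmanCorrelation(x, y)
    expect_equal(out$method, "exact permutation")
    expect_equal(out$pValue, oracleSpearmanPermP(x, y))
  }
  # invariance under strictly monotone transforms
  x <- rnorm(15); y <- rnorm(15)
  a <- spearmanCorrelation(x, y)
  b <- spearmanCorrelation(exp(x), 3 * y^3)  # y^3 monotone
  expect_equal(a$rho, b$rho)
  expect_equal(a$pValue, b$pValue)
  expect_equal(a$method, "t approximation")
  # cross-check the t approximation against stats::cor.test
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(a$rho, unname(ct$estimate))
})

test_that("compareGroupScores follows the t/U selection rule with oracles", {
  # identical groups under the U test: p = 1 (exact small-n path)
  out <- compareGroupScores(c(1, 2, 3), c(1, 2, 3), test = "u")
  expect_equal(out$pValue, 1)

  a <- c(1, 2, 3); b <- c(11, 12, 13)
  tt <- compareGroupScores(a, b, test = "t")
  or <- oracleTTest(a, b)
  expect_equal(tt$statistic, or$statistic)
  expect_equal(tt$pValue, or$pValue)

  # U on (1,2) vs (3,4,5): U = 0, exact two-sided p = 2/10
  uu <- compareGroupScores(c(1, 2), c(3, 4, 5))  # auto -> u (unequal sizes)
  expect_equal(uu$test, "u")
  expect_equal(uu$statistic, 0)
  expect_equal(uu$pValue, 2 / 10)

  # auto rule: equal sizes -> t
  expect_equal(compareGroupScores(a, b)$test, "t")
  expect_error(compareGroupScores(numeric(0), b), "empty")
  expect_error(compareGroupScores(c(1), c(2, 3), test = "t"), "at least two")

  # large-sample U path agrees with wilcox.test's corrected normal approx
  set.seed(2)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  mine <- compareGroupScores(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$pValue, ref$p.value, tolerance = 1e-10)
})

test_that("compareCorrelations implements the Fisher z difference test", {
  eq <- compareCorrelations(0.4, 100, 0.4, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$pValue, 1)

  out <- compareCorrelations(0.5, 500, 0.3, 500)
  zo <- (atanh(0.5) - atanh(0.3)) / sqrt(1 / 497 + 1 / 497)
  expect_equal(out$z, zo)
  expect_equal(out$pValue, 2 * pnorm(-abs(zo)))

  expect_error(compareCorrelations(1, 50, 0.2, 50), "< 1")
  expect_error(compareCorrelations(0.5, 5, 0.2, 50), ">= 10")

  rep <- compareCorrelations(0.5, 100, 0.3, 100,
                             replicateRhosA = c(0.45, 0.55),
                             replicateRhosB = c(0.25, 0.35))
  expect_true(is.numeric(rep$replicatePValue))
})

test_that("compareCorrelations keeps nominal type-I error under the null", {
  set.seed(1234)
  n <- 50; reps <- 2000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    x1 <- rnorm(n); y1 <- 0.3 * x1 + rnorm(n)
    x2 <- rnorm(n); y2 <- 0.3 * x2 + rnorm(n)
    rej[i] <- compareCorrelations(cor(x1, y1), n, cor(x2, y2), n)$pValue < 0.05
  }
  mcse <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), 2.5 * mcse + 0.01)
})

test_that("hypergeometric enrichment matches the combinatorial closed form", {
  uni <- sprintf("g%02d", 1:20)
  # category = set = universe: p = 1, fold = 1
  out <- hypergeometricEnrichment(uni, uni, list(all = uni))
  expect_equal(out$pValue, 1)
  expect_equal(out$fold, 1)

  # universe 20, category 5, set 5, overlap 5: p = 1 / C(20, 5)
  out2 <- hypergeometricEnrichment(uni[1:5], uni, list(cat = uni[1:5]))
  expect_equal(out2$pValue, 1 / choose(20, 5))
  expect_equal(out2$k, 5)

  set.seed(6)
  for (i in 1:10) {
    K <- sample(3:12, 1); n <- sample(3:12, 1)
    cat <- sample(uni, K); set <- sample(uni, n)
    out <- hypergeometricEnrichment(set, uni, list(c1 = cat))
    expect_equal(out$pValue,
                 oracleHyperP(length(intersect(cat, set)), K, n, 20))
  }
  expect_error(hypergeometricEnrichment("g01", character(0), list()), "empty")
  expect_error(hypergeometricEnrichment("x", uni, list()), "subset")
})

test_that("BH adjustment is correct and monotone", {
  uni <- sprintf("g%03d", 1:200)
  set.seed(3)
  cats <- lapply(1:8, function(i) sample(uni, sample(10:80, 1)))
  names(cats) <- paste0("c", 1:8)
  out <- hypergeometricEnrichment(sample(uni, 30), uni, cats)
  expect_equal(out$qValue, p.adjust(out$pValue, "BH"))
  expect_true(all(out$qValue >= out$pValue - 1e-12))
  ord <- order(out$pValue)
  expect_true(all(diff(out$qValue[ord]) >= -1e-12))
  # the textbook example: p = (.01, .02, .03, .04) -> q all 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("fisherExact2x2 equals enumeration (and fisher.test) exactly", {
  expect_equal(fisherExact2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisherExact2x2(matrix(c(5, 0, 0, 5), 2)), 2 / choose(10, 5))

  set.seed(12)
  for (i in 1:40) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (min(rowSums(tab)) == 0 || min(colSums(tab)) == 0) next
    p <- fisherExact2x2(tab)
    expect_equal(p, oracleFisherP(tab))
    expect_equal(p, fisher.test(tab)$p.value)
  }
  expect_error(fisherExact2x2(matrix(c(0, 0, 3, 4), 2)), "margins")
  expect_error(fisherExact2x2(matrix(c(1.5, 1, 1, 1), 2)), "integers")
})
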