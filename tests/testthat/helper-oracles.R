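# Independent oracles and fixture builders.  Everything here is brute force
# or closed form and deliberately avoids the code paths it checks.

# --- binning oracle: accumulate coverage on a base-resolution array, then
#     sum each bin / binSize.
oracleBinCoverage <- function(chrom, start0, end0, value, binSize, chromLen) {
  base <- numeric(chromLen)
  for (i in seq_along(start0))
    base[(start0[i] + 1):end0[i]] <- base[(start0[i] + 1):end0[i]] + value[i]
  nb <- ceiling(chromLen / binSize)
  vapply(seq_len(nb), function(b) {
    lo <- (b - 1) * binSize + 1
    hi <- min(b * binSize, chromLen)
    sum(base[lo:hi]) / binSize
  }, numeric(1))
}

# random non-overlapping coverage on one chromosome
randomCoverage <- function(chromLen, n = 10, maxVal = 10, chrom = "chr1") {
  cuts <- sort(sample(0:chromLen, 2 * n))
  s <- cuts[seq(1, 2 * n, 2)]; e <- cuts[seq(2, 2 * n, 2)]
  ok <- s < e
  s <- s[ok]; e <- e[ok]
  if (length(s) == 0) { s <- 0; e <- chromLen }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1, e),
                         score = round(runif(length(s), 0, maxVal), 3))
}

# --- average ranks computed from first principles (no rank())
oracleAvgRank <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
}

# Pearson of hand-computed average ranks, by the textbook formula
oracleSpearmanRho <- function(x, y) {
  rx <- oracleAvgRank(x); ry <- oracleAvgRank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exact two-sided permutation p for Spearman, recursive enumeration
oracleSpearmanPermP <- function(x, y) {
  n <- length(x)
  obs <- abs(oracleSpearmanRho(x, y))
  hits <- 0L; total <- 0L
  recur <- function(remaining, acc) {
    if (length(remaining) == 0L) {
      total <<- total + 1L
      if (abs(oracleSpearmanRho(x, y[acc])) >= obs - 1e-12)
        hits <<- hits + 1L
      return(invisible())
    }
    for (k in remaining) recur(setdiff(remaining, k), c(acc, k))
  }
  recur(seq_len(n), integer(0))
  hits / total
}

# --- pooled two-sample t-test, closed form
oracleTTest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t, pValue = 2 * pt(-abs(t), na + nb - 2))
}

# --- exact Mann-Whitney U by full enumeration; U computed by pairwise
#     comparison counting (not via ranks)
oracleUPairwise <- function(a, b) {
  sum(vapply(a, function(ai) sum(ai > b) + 0.5 * sum(ai == b), numeric(1)))
}
oracleUExactP <- function(a, b) {
  pool <- c(a, b); m <- length(a); N <- length(pool)
  obsDev <- abs(oracleUPairwise(a, b) - m * (N - m) / 2)
  sel <- utils::combn(N, m)
  devs <- apply(sel, 2, function(idx)
    abs(oracleUPairwise(pool[idx], pool[-idx]) - m * (N - m) / 2))
  mean(devs >= obsDev - 1e-9)
}

# --- hypergeometric upper tail from binomial coefficients
oracleHyperP <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# --- two-sided Fisher p by enumerating all tables with the observed margins,
#     probabilities from binomial coefficients
oracleFisherP <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  N <- r1 + r2
  xs <- max(0, c1 - r2):min(c1, r1)
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(N, c1)
  pObs <- choose(r1, tab[1, 1]) * choose(r2, c1 - tab[1, 1]) / choose(N, c1)
  sum(pr[pr <= pObs * (1 + 1e-7)])
}

# --- base-resolution gene window score oracle.  `values` is the per-bin
#     track vector for the gene's chromosome; windows are literal oriented
#     bp windows around `tssRef` (pass the snapped TSS for exact equality,
#     the true TSS for the one-bin-tolerance check).
oracleWindowScore <- function(values, binSize, chromLen, tssRef, strand,
                              upstream = c(-1200, -200),
                              downstream = c(400, 1200)) {
  base <- rep(values, each = binSize)[seq_len(chromLen)]
  offs <- if (strand == "+") (0:(chromLen - 1)) - tssRef
          else (tssRef - 1) - (0:(chromLen - 1))
  inWin <- (offs >= upstream[1] & offs < upstream[2]) |
    (offs >= downstream[1] & offs < downstream[2])
  mean(base[inWin])
}

# small helpers
toyLayout <- function(lens = c(chr1 = 2000), bs = 200) genomeLayout(lens, bs)
grCov <- function(chrom, s0, e0, v) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1, e0), score = v)
}
geneGR <- function(name, chrom, strand, txStart, txEnd) {
  h33dyn:::.geneModel(name, chrom, strand, txStart, txEnd)
}
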