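# Core statistical primitives: average-rank Spearman with small-n exact
# permutation p, two-sample t / Mann-Whitney U following the study's group
# test convention, Fisher-z correlation differences, hypergeometric
# over-representation with BH, and the two-sided Fisher exact test.

#' Spearman correlation with small-sample exact p-value
#'
#' Average-rank Spearman coefficient.  The p-value uses the large-sample t
#' approximation for `n >= 10` and an exact permutation enumeration (all
#' `n!` orderings) below, where the approximation is poor.  Constant input
#' is an error: rho is undefined.
#'
#' @param x,y numeric vectors of equal length `>= 3`; ties allowed.
#' @return list with `rho`, `n`, `pValue` and `method`.
#' @examples
#' spearmanCorrelation(1:5, c(2, 1, 4, 3, 5))
#' @export
spearmanCorrelation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 paired observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("Spearman correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n >= 10L) {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  } else {
    p <- .spearmanPermutationP(rx, ry)
    method <- "exact permutation"
  }
  list(rho = rho, n = n, pValue = min(p, 1), method = method)
}

# Exact two-sided permutation p for small n: proportion of the n!
# permutations of the y ranks whose |rho| >= |observed| (with a numerical
# fuzz for exact ties of the statistic).
.spearmanPermutationP <- function(rx, ry) {
  n <- length(rx)
  perms <- .allPermutations(n)
  rxc <- rx - mean(rx)
  denom <- sqrt(sum(rxc^2) * sum((ry - mean(ry))^2))
  rhoAll <- (matrix(ry[perms], nrow(perms), n) %*% rxc) / denom
  obs <- abs(sum(rxc * (ry - mean(ry))) / denom)
  mean(abs(rhoAll) >= obs - 1e-12)
}

# All permutations of 1..n as a matrix (n! x n), built by insertion.
.allPermutations <- function(n) {
  p <- matrix(1L, 1, 1)
  if (n == 1L) return(p)
  for (k in 2:n) {
    m <- nrow(p)
    out <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      rows <- ((pos - 1) * m + 1):(pos * m)
      if (pos > 1) out[rows, seq_len(pos - 1)] <- p[, seq_len(pos - 1), drop = FALSE]
      out[rows, pos] <- k
      if (pos < k) out[rows, (pos + 1):k] <- p[, pos:(k - 1), drop = FALSE]
    }
    p <- out
  }
  p
}

#' Two-sample location test following the study's convention
#'
#' Two-tailed Student's t-test for equal-sized groups, Mann-Whitney U test
#' when the group sizes differ (`test = "auto"`); either can be forced.  The
#' U test is exact (full enumeration of all assignments, valid under ties)
#' when `length(a) + length(b) <= 12`, and uses the tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param a,b numeric score vectors.
#' @param test `"auto"`, `"t"` or `"u"`.
#' @return list with `statistic`, `pValue` and `test` (`"t"` or `"u"`).
#' @export
compareGroupScores <- function(a, b, test = c("auto", "t", "u")) {
  test <- match.arg(test)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) stop("empty group")
  if (test == "auto") test <- if (length(a) != length(b)) "u" else "t"
  if (test == "t") {
    if (length(a) < 2L || length(b) < 2L)
      stop("t-test needs at least two observations per group")
    fit <- stats::t.test(a, b, var.equal = TRUE)
    list(statistic = unname(fit$statistic), pValue = fit$p.value, test = "t")
  } else {
    .mannWhitneyU(a, b)
  }
}

.mannWhitneyU <- function(a, b) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (m + n <= 12L) {
    pool <- c(a, b)
    N <- m + n
    dev <- abs(U - m * n / 2)
    hits <- 0L; total <- 0L
    sel <- utils::combn(N, m)
    rAll <- rank(pool)
    for (j in seq_len(ncol(sel))) {
      idx <- sel[, j]
      Uj <- sum(rAll[idx]) - m * (m + 1) / 2
      total <- total + 1L
      if (abs(Uj - m * n / 2) >= dev - 1e-9) hits <- hits + 1L
    }
    p <- hits / total
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- m * n / 12 * ((m + n + 1) -
      sum(ties^3 - ties) / ((m + n) * (m + n - 1)))
    z <- (abs(U - m * n / 2) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal approximation"
  }
  list(statistic = unname(U), pValue = p, test = "u", method = method)
}

#' Compare two correlation coefficients (Fisher z)
#'
#' Two-sided test of `rhoA = rhoB` from independent samples via the Fisher
#' z-transform.  When per-replicate correlations are available for both
#' groups, a two-sample t-test on the z-transformed replicate values is
#' reported in addition; the z test remains the primary result.
#'
#' @param rhoA,rhoB observed correlations, strictly inside (-1, 1).
#' @param nA,nB sample sizes behind each correlation, each at least 10.
#' @param replicateRhosA,replicateRhosB optional per-replicate correlation
#'   vectors (each of length `>= 2`) for the replicate-level t variant.
#' @return list with `z`, `pValue` and, when replicates are given,
#'   `replicateT` and `replicatePValue`.
#' @export
compareCorrelations <- function(rhoA, nA, rhoB, nB,
                                replicateRhosA = NULL, replicateRhosB = NULL) {
  if (nA < 10 || nB < 10) stop("need n >= 10 per group")
  if (abs(rhoA) >= 1 || abs(rhoB) >= 1)
    stop("|rho| must be < 1 for the Fisher z-transform")
  z <- (atanh(rhoA) - atanh(rhoB)) / sqrt(1 / (nA - 3) + 1 / (nB - 3))
  out <- list(z = z, pValue = min(1, 2 * stats::pnorm(-abs(z))))
  if (!is.null(replicateRhosA) && !is.null(replicateRhosB)) {
    if (length(replicateRhosA) < 2L || length(replicateRhosB) < 2L)
      stop("replicate-level t-test needs >= 2 correlations per group")
    fit <- stats::t.test(atanh(replicateRhosA), atanh(replicateRhosB),
                         var.equal = TRUE)
    out$replicateT <- unname(fit$statistic)
    out$replicatePValue <- fit$p.value
  }
  out
}

#' Hypergeometric over-representation of a gene set in categories
#'
#' Upper-tail hypergeometric p-value per category (the generic stand-in for
#' web-service GO over-representation), Benjamini-Hochberg adjusted across
#' categories.  Categories are intersected with the universe first.
#'
#' @param geneSet character vector, a subset of `universe`.
#' @param universe character vector of all considered genes.
#' @param categories named list mapping category name to gene vector.
#' @return data.frame with `category`, `k` (overlap), `K` (category size in
#'   universe), `n` (set size), `N` (universe size), `fold`, `pValue`,
#'   `qValue`.
#' @export
hypergeometricEnrichment <- function(geneSet, universe, categories) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  geneSet <- unique(geneSet)
  if (!all(geneSet %in% universe))
    stop("gene set must be a subset of the universe")
  N <- length(universe); n <- length(geneSet)
  rows <- lapply(names(categories), function(nm) {
    cat <- intersect(unique(categories[[nm]]), universe)
    K <- length(cat)
    k <- length(intersect(cat, geneSet))
    p <- if (K == 0L) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (K == 0L || n == 0L) NA_real_ else (k / n) / (K / N)
    data.frame(category = nm, k = k, K = K, n = n, N = N,
               fold = fold, pValue = p)
  })
  out <- do.call(rbind, rows)
  out$qValue <- stats::p.adjust(out$pValue, method = "BH")
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional hypergeometric test; the two-sided p-value sums the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (point-probability summation).
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return the two-sided p-value.
#' @examples
#' fisherExact2x2(matrix(c(5, 0, 0, 5), 2))  # 1/126
#' @export
fisherExact2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (min(r1, r2, c1, c2) == 0) stop("all margins must be positive")
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, r2, c1)
  pObs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}
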