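# Internal helpers shared across modules.

# 1-based index of the bin containing 0-based base position p.
.binIndex <- function(p, binSize) as.integer(p %/% binSize) + 1L

# Oriented offset of 0-based base p relative to anchor a: positive offsets
# are downstream in the direction of transcription (see coordinate contract
# in AllClasses.R).
.orientedOffset <- function(p, a, strand) {
  ifelse(strand == "+", p - a, (a - 1) - p)
}

.checkStrand <- function(strand) {
  if (any(!strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  invisible(strand)
}

# Deterministic 32-bit sub-seed from a base seed and a character key, so
# every (line, timepoint, replicate, antibody) simulation draw is an
# independent, reproducible stream.  Stays below 2^31.
.subSeed <- function(seed, key) {
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% 1000003
  as.integer((as.numeric(seed) %% 2147483 * 1000003 + h) %% 2147483647)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# chromosome lookup with a clear error
.chromLength <- function(layout, chrom) {
  i <- match(chrom, layout@chromNames)
  if (anyNA(i)) stop("unknown chromosome(s): ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  layout@chromLengths[i]
}

# GRanges coverage record accessors in the package's 0-based convention.
.start0 <- function(gr) GenomicRanges::start(gr) - 1L
.end0 <- function(gr) GenomicRanges::end(gr)
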