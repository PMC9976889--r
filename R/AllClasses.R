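#' @import methods
#' @importFrom stats sd quantile p.adjust phyper pnorm pt rnorm rpois rnbinom
#'   runif setNames cor t.test complete.cases
#' @importFrom utils combn head
NULL

## Coordinate contract used package-wide
##
## All on-disk coordinates (bedGraph, BED, gene tables) and every position
## argument are 0-based half-open.  GRanges objects used internally carry the
## usual 1-based closed convention; conversion happens only inside the
## readers/writers.  The transcription start site of a gene is txStart on the
## '+' strand and txEnd on the '-' strand, so the first transcribed base is
## tss on '+' and tss - 1 on '-'.  The oriented offset of a base p relative
## to an anchor a is p - a on '+' and (a - 1) - p on '-': positive offsets
## are always downstream in the direction of transcription.

#' GenomeLayout: chromosome names, lengths and the bin size of the analysis
#'
#' Fixed-width binning at `binSize` base pairs (200 bp by default, the
#' resolution at which the whole analysis operates) is defined per chromosome
#' as `ceiling(length / binSize)` bins, the last bin possibly truncated.
#'
#' @slot chromNames character vector of unique chromosome names, in order.
#' @slot chromLengths numeric vector of chromosome lengths (bp), parallel to
#'   `chromNames`; each at least `binSize`.
#' @slot binSize single positive integer bin width in bp.
#' @exportClass GenomeLayout
setClass("GenomeLayout",
  representation(chromNames = "character",
                 chromLengths = "numeric",
                 binSize = "integer"))

setValidity("GenomeLayout", function(object) {
  msg <- character()
  if (length(object@chromNames) == 0L)
    msg <- c(msg, "at least one chromosome required")
  if (anyDuplicated(object@chromNames))
    msg <- c(msg, "chromosome names must be unique")
  if (length(object@chromLengths) != length(object@chromNames))
    msg <- c(msg, "chromNames and chromLengths must be parallel")
  if (length(object@binSize) != 1L || is.na(object@binSize) || object@binSize < 1L)
    msg <- c(msg, "binSize must be a single positive integer")
  else if (any(!is.finite(object@chromLengths)) ||
           any(object@chromLengths < object@binSize))
    msg <- c(msg, "every chromosome length must be >= binSize")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeLayout
#'
#' @param chromLengths named numeric vector of chromosome lengths in bp.
#' @param binSize bin width in bp (default 200).
#' @return A [GenomeLayout-class] object.
#' @examples
#' genomeLayout(c(chr1 = 1e5, chr2 = 5e4))
#' @export
genomeLayout <- function(chromLengths, binSize = 200L) {
  if (is.null(names(chromLengths)) || any(!nzchar(names(chromLengths))))
    stop("chromLengths must be a named vector")
  new("GenomeLayout", chromNames = names(chromLengths),
      chromLengths = unname(as.numeric(chromLengths)),
      binSize = as.integer(binSize))
}

#' @describeIn genomeLayout chromosome names, in layout order.
#' @param x,object a `GenomeLayout`.
#' @export
chromNames <- function(x) x@chromNames

#' @describeIn genomeLayout named vector of chromosome lengths (bp).
#' @export
chromLengths <- function(x) setNames(x@chromLengths, x@chromNames)

#' @describeIn genomeLayout bin width in bp.
#' @export
binSize <- function(x) x@binSize

#' @describeIn genomeLayout named vector with the number of bins per
#'   chromosome (`ceiling(length / binSize)`).
#' @export
nBins <- function(x) setNames(as.integer(ceiling(x@chromLengths / x@binSize)),
                              x@chromNames)

setMethod("show", "GenomeLayout", function(object) {
  cat("GenomeLayout:", length(object@chromNames), "chromosome(s),",
      "binSize =", object@binSize, "bp\n")
  cat("  total", format(sum(object@chromLengths), big.mark = ","), "bp in",
      sum(nBins(object)), "bins\n")
})

#' BinnedTrack: fixed-bin coverage for one ChIP sample
#'
#' One numeric vector of non-negative bin values per chromosome, plus the
#' sample annotation (antibody, cell line, timepoint, replicate).
#' `totalMapped` is the total raw binned signal recorded before any
#' normalization; `normalized` flags whether [rpmNormalize()] was applied.
#'
#' @slot layout the [GenomeLayout-class] the track is binned on.
#' @slot values named list, one numeric vector per chromosome.
#' @slot sampleMeta named list: antibody, line, timepoint_h, replicate (any
#'   subset; free-form).
#' @slot totalMapped total raw binned signal.
#' @slot normalized logical flag.
#' @exportClass BinnedTrack
setClass("BinnedTrack",
  representation(layout = "GenomeLayout", values = "list",
                 sampleMeta = "list", totalMapped = "numeric",
                 normalized = "logical"))

setValidity("BinnedTrack", function(object) {
  msg <- character()
  nb <- nBins(object@layout)
  if (!identical(names(object@values), object@layout@chromNames))
    msg <- c(msg, "values must be named by the layout's chromosomes, in order")
  else {
    len <- vapply(object@values, length, integer(1))
    if (!all(len == nb))
      msg <- c(msg, "one value per bin required on every chromosome")
    bad <- vapply(object@values,
                  function(v) any(!is.finite(v)) || any(v < 0), logical(1))
    if (any(bad))
      msg <- c(msg, "bin values must be finite and non-negative")
  }
  if (length(object@normalized) != 1L || is.na(object@normalized))
    msg <- c(msg, "normalized must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' @describeIn binCoverage named list of per-chromosome bin value vectors.
#' @export
trackValues <- function(x) x@values

#' @describeIn binCoverage the sample annotation list.
#' @export
sampleMeta <- function(x) x@sampleMeta

#' @describeIn binCoverage total raw binned signal before normalization.
#' @export
totalMapped <- function(x) x@totalMapped

#' @describeIn binCoverage whether the track has been RPM-normalized.
#' @export
isNormalized <- function(x) x@normalized

#' @describeIn binCoverage the track's [GenomeLayout-class].
#' @export
trackLayout <- function(x) x@layout

setMethod("show", "BinnedTrack", function(object) {
  m <- object@sampleMeta
  lab <- if (length(m)) paste(unlist(m), collapse = "/") else "unannotated"
  cat("BinnedTrack [", lab, "] on ", length(object@values),
      " chromosome(s), binSize = ", object@layout@binSize, " bp\n", sep = "")
  cat("  totalMapped = ", format(object@totalMapped), ", normalized = ",
      object@normalized, "\n", sep = "")
})

#' ProfileMatrix: anchors x offset-bins signal matrix
#'
#' Row i, column j holds the track signal in the bin at oriented offset
#' `offsets[j] .. offsets[j] + binSize` from anchor i; minus-strand anchors
#' are orientation-flipped so positive offsets always point downstream in the
#' direction of transcription.
#'
#' @slot values numeric matrix, anchors x offset bins; rownames are anchor ids.
#' @slot offsets integer vector of oriented bin-start offsets in bp, from
#'   `-flank` to `flank - binSize`.
#' @slot flank half-window in bp.
#' @slot binSize bin width in bp.
#' @slot sampleMeta annotation of the source track.
#' @slot nDropped number of anchors dropped because their window exceeded
#'   chromosome bounds.
#' @exportClass ProfileMatrix
setClass("ProfileMatrix",
  representation(values = "matrix", offsets = "integer", flank = "integer",
                 binSize = "integer", sampleMeta = "list",
                 nDropped = "integer"))

setValidity("ProfileMatrix", function(object) {
  msg <- character()
  if (ncol(object@values) != length(object@offsets))
    msg <- c(msg, "one column per offset required")
  if (length(object@offsets) &&
      2L * object@flank != length(object@offsets) * object@binSize)
    msg <- c(msg, "offset count must equal 2*flank/binSize")
  if (is.null(rownames(object@values)))
    msg <- c(msg, "rownames (anchor ids) required")
  if (length(msg)) msg else TRUE
})

#' @describeIn anchorMatrix the anchors x offsets signal matrix.
#' @export
profileValues <- function(x) x@values

#' @describeIn anchorMatrix oriented bin-start offsets (bp).
#' @export
profileOffsets <- function(x) x@offsets

#' @describeIn anchorMatrix number of anchors dropped at chromosome bounds.
#' @export
anchorsDropped <- function(x) x@nDropped

setMethod("show", "ProfileMatrix", function(object) {
  cat("ProfileMatrix: ", nrow(object@values), " anchor(s) x ",
      ncol(object@values), " offset bins (flank ", object@flank, " bp, bin ",
      object@binSize, " bp)\n", sep = "")
  if (object@nDropped > 0L)
    cat("  ", object@nDropped, "anchor(s) dropped at chromosome bounds\n")
})

#' CytofMatrix: cells x markers mass-cytometry intensities
#'
#' Marker roles distinguish epigenetic readouts (to be normalized against the
#' core histones), core histone channels, and everything else.
#'
#' @slot intensities numeric matrix, cells x markers, with marker colnames.
#' @slot markerRoles character vector over markers, each one of
#'   `"epigenetic"`, `"core_histone"`, `"other"`.
#' @slot normalized logical, set by [cytofNormalize()].
#' @exportClass CytofMatrix
setClass("CytofMatrix",
  representation(intensities = "matrix", markerRoles = "character",
                 normalized = "logical"))

setValidity("CytofMatrix", function(object) {
  msg <- character()
  if (is.null(colnames(object@intensities)))
    msg <- c(msg, "marker names (colnames) required")
  if (length(object@markerRoles) != ncol(object@intensities))
    msg <- c(msg, "one role per marker required")
  if (!all(object@markerRoles %in% c("epigenetic", "core_histone", "other")))
    msg <- c(msg, "roles must be epigenetic, core_histone or other")
  if (length(msg)) msg else TRUE
})

#' Construct a CytofMatrix
#'
#' @param intensities cells x markers numeric matrix with marker colnames.
#' @param markerRoles character vector (or named vector over markers) of
#'   roles: `"epigenetic"`, `"core_histone"` or `"other"`.
#' @return A [CytofMatrix-class].
#' @export
cytofMatrix <- function(intensities, markerRoles) {
  intensities <- as.matrix(intensities)
  if (!is.null(names(markerRoles)))
    markerRoles <- markerRoles[colnames(intensities)]
  new("CytofMatrix", intensities = intensities,
      markerRoles = unname(markerRoles), normalized = FALSE)
}

#' @describeIn cytofMatrix the cells x markers matrix.
#' @param x a `CytofMatrix`.
#' @export
cytofIntensities <- function(x) x@intensities

#' @describeIn cytofMatrix named vector of marker roles.
#' @export
markerRoles <- function(x) setNames(x@markerRoles, colnames(x@intensities))

setMethod("show", "CytofMatrix", function(object) {
  cat("CytofMatrix: ", nrow(object@intensities), " cells x ",
      ncol(object@intensities), " markers (",
      sum(object@markerRoles == "epigenetic"), " epigenetic, ",
      sum(object@markerRoles == "core_histone"), " core histone); normalized = ",
      object@normalized, "\n", sep = "")
})
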