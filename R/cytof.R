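#' Normalize CyTOF marker intensities against core histones
#'
#' The three-step normalization used for mass-cytometry chromatin profiling:
#' (1) arcsinh transform with the field-standard cofactor 5,
#' `asinh(x / cofactor)`; (2) per-marker standardization to mean 0, sd 1;
#' (3) each epigenetic marker is corrected per cell by subtracting the mean
#' standardized core-histone level of that cell, removing cell-size /
#' staining-efficiency effects.  Non-epigenetic markers keep their
#' standardized values.
#'
#' @param m a [CytofMatrix-class] of raw intensities (non-negative).
#' @param cofactor arcsinh cofactor (default 5).
#' @return A normalized [CytofMatrix-class].
#' @export
cytofNormalize <- function(m, cofactor = 5) {
  if (m@normalized) stop("matrix is already normalized")
  x <- m@intensities
  if (any(x < 0)) stop("raw intensities must be non-negative")
  roles <- m@markerRoles
  if (!any(roles == "core_histone"))
    stop("at least one core_histone marker is required")
  z <- asinh(x / cofactor)
  mu <- colMeans(z)
  sdv <- apply(z, 2, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance marker(s): ",
         paste(colnames(x)[sdv == 0], collapse = ", "))
  z <- sweep(sweep(z, 2, mu), 2, sdv, "/")
  coreMean <- rowMeans(z[, roles == "core_histone", drop = FALSE])
  epi <- roles == "epigenetic"
  z[, epi] <- z[, epi, drop = FALSE] - coreMean
  m@intensities <- z
  m@normalized <- TRUE
  m
}
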