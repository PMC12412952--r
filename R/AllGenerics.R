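#' @importFrom BiocGenerics counts
NULL

#' Accessors for kelpcarbon classes
#'
#' Small accessor generics: \code{slope()} and \code{inverseCoefficient()}
#' for \linkS4class{CalibrationFit} and \linkS4class{QpcrCurve},
#' \code{efficiency()} for \linkS4class{QpcrCurve}, \code{profileSlices()},
#' \code{maxSampledDepth()} and \code{profileGaps()} for
#' \linkS4class{CoreProfile}, \code{taxonomy()} and \code{sampleData()} for
#' \linkS4class{TaxaTable}, and \code{permanovaResults()} for
#' \linkS4class{PermanovaTable}. \code{counts()} (from BiocGenerics) returns
#' the integer count assay of a \linkS4class{TaxaTable}.
#'
#' @param object an object of the documented class.
#' @return The slot contents (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("slope", function(object) standardGeneric("slope"))

#' @rdname accessors
#' @export
setGeneric("inverseCoefficient",
           function(object) standardGeneric("inverseCoefficient"))

#' @rdname accessors
#' @export
setGeneric("efficiency", function(object) standardGeneric("efficiency"))

#' @rdname accessors
#' @export
setGeneric("profileSlices", function(object) standardGeneric("profileSlices"))

#' @rdname accessors
#' @export
setGeneric("maxSampledDepth",
           function(object) standardGeneric("maxSampledDepth"))

#' @rdname accessors
#' @export
setGeneric("profileGaps", function(object) standardGeneric("profileGaps"))

#' @rdname accessors
#' @export
setGeneric("taxonomy", function(object) standardGeneric("taxonomy"))

#' @rdname accessors
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))

#' @rdname accessors
#' @export
setGeneric("permanovaResults",
           function(object) standardGeneric("permanovaResults"))

#' @rdname accessors
#' @export
setMethod("slope", "CalibrationFit", function(object) object@slope)

#' @rdname accessors
#' @export
setMethod("slope", "QpcrCurve", function(object) object@slope)

#' @rdname accessors
#' @export
setMethod("inverseCoefficient", "CalibrationFit",
          function(object) object@inverseCoefficient)

#' @rdname accessors
#' @export
setMethod("efficiency", "QpcrCurve", function(object) object@efficiency)

#' @rdname accessors
#' @export
setMethod("profileSlices", "CoreProfile", function(object) object@slices)

#' @rdname accessors
#' @export
setMethod("maxSampledDepth", "CoreProfile",
          function(object) object@maxSampledDepth)

#' @rdname accessors
#' @export
setMethod("profileGaps", "CoreProfile", function(object) object@gaps)

#' @rdname accessors
#' @export
setMethod("counts", "TaxaTable",
          function(object) SummarizedExperiment::assay(object, "counts"))

#' @rdname accessors
#' @export
setMethod("taxonomy", "TaxaTable", function(object)
  as.data.frame(SummarizedExperiment::rowData(object)[, TAXONOMY_RANKS,
                                                      drop = FALSE]))

#' @rdname accessors
#' @export
setMethod("sampleData", "TaxaTable", function(object)
  as.data.frame(SummarizedExperiment::colData(object)))

#' @rdname accessors
#' @export
setMethod("permanovaResults", "PermanovaTable", function(object) {
  r <- object@results
  r$partialOmega2 <- pmax(r$partialOmega2, 0)  # truncate for reporting
  r
})

#' @export
setMethod("show", "DpcrReaction", function(object) {
  cat("DpcrReaction with", length(object@positives), "well(s)\n")
  cat(sprintf("  partitions: %s valid; partition volume %g uL\n",
              paste(range(object@validPartitions), collapse = "-"),
              object@partitionVolume))
  cat(sprintf("  reaction %g uL (template %g uL)\n",
              object@reactionVolume, object@templateVolume))
  frac <- object@positives / object@validPartitions
  cat(sprintf("  positive fraction: %.4g-%.4g\n", min(frac), max(frac)))
})

#' @export
setMethod("show", "CalibrationFit", function(object) {
  cat("Through-origin biomass calibration\n")
  cat(sprintf("  slope: %.4g +/- %.3g copies g^-1 dry per %% dry kelp C\n",
              object@slope, object@slopeSe))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.3g, R2 = %.3f (adj. %.3f)\n",
              object@df[1], object@df[2], object@Fstat, object@pValue,
              object@r2, object@adjR2))
  cat(sprintf("  inverse: %.4g %% dry kelp C per copy g^-1 (fit over doses %.4g-%.4g, n = %d)\n",
              object@inverseCoefficient, object@fitRange[1],
              object@fitRange[2], object@nObs))
})

#' @export
setMethod("show", "QpcrCurve", function(object) {
  cat(sprintf("qPCR standard curve: Cq = %.4g x log10(copies) + %.4g\n",
              object@slope, object@intercept))
  cat(sprintf("  R2 = %.4g, efficiency = %.1f%% (n = %d)\n",
              object@r2, 100 * object@efficiency, object@n))
})

#' @export
setMethod("show", "CoreProfile", function(object) {
  cat(sprintf("CoreProfile %s (site %s, %s): %d slice(s), 0-%g cm\n",
              object@coreId, object@siteNumber, object@siteType,
              nrow(object@slices), object@maxSampledDepth))
  if (nrow(object@gaps))
    cat(sprintf("  unsampled gap(s): %s cm\n",
                paste(sprintf("%g-%g", object@gaps$top, object@gaps$bottom),
                      collapse = ", ")))
})

#' @export
setMethod("show", "TaxaTable", function(object) {
  cat(sprintf("TaxaTable: %d taxa x %d samples\n", nrow(object), ncol(object)))
  callNextMethod()
})

#' @export
setMethod("show", "PermanovaTable", function(object) {
  cat(sprintf("PERMANOVA (sequential SS, %d free permutations, seed %d)\n",
              object@permutations, object@seed))
  print(format(permanovaResults(object), digits = 4), row.names = FALSE)
})
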