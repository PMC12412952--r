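#' @import methods
#' @importFrom stats lm pf pchisq pnorm qnorm rnorm runif rbinom rgamma
#'   rmultinom coef vcov sd var qf shapiro.test p.adjust cor.test t.test
#'   kruskal.test model.matrix reformulate setNames complete.cases qchisq
#'   residuals relevel dist as.dist
#' @importFrom utils head tail read.csv write.csv read.delim packageVersion
#'   combn write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame
NULL

#' Digital PCR reactions
#'
#' Holds the partition-level readout and reaction geometry for one or more
#' digital PCR wells that share the same plate chemistry. The QIAcuity-style
#' nanoplate splits a reaction of \code{reactionVolume} microlitres (of which
#' \code{templateVolume} is template) into \code{validPartitions} partitions of
#' \code{partitionVolume} microlitres each; \code{positives} of them amplify.
#'
#' @slot wellId character, one label per well.
#' @slot positives integer, positive partitions per well.
#' @slot validPartitions integer, valid partitions per well.
#' @slot partitionVolume numeric(1), microlitres per partition. Instrument
#'   specific and therefore required: there is no safe default.
#' @slot reactionVolume numeric(1), total reaction volume in microlitres.
#' @slot templateVolume numeric(1), template volume per reaction in
#'   microlitres.
#' @slot dilutionFactor numeric, fold-dilution of the template before loading
#'   (1 = undiluted), recycled across wells.
#' @export
setClass("DpcrReaction",
  representation(
    wellId = "character",
    positives = "integer",
    validPartitions = "integer",
    partitionVolume = "numeric",
    reactionVolume = "numeric",
    templateVolume = "numeric",
    dilutionFactor = "numeric"
  )
)

setValidity("DpcrReaction", function(object) {
  n <- length(object@positives)
  msg <- character()
  if (length(object@validPartitions) != n || length(object@wellId) != n ||
      length(object@dilutionFactor) != n)
    msg <- c(msg, "wellId, positives, validPartitions and dilutionFactor must have equal length")
  if (any(object@positives < 0L)) msg <- c(msg, "positives must be >= 0")
  if (any(object@positives > object@validPartitions))
    msg <- c(msg, "positives cannot exceed validPartitions")
  if (any(object@validPartitions < 1L)) msg <- c(msg, "validPartitions must be >= 1")
  for (s in c("partitionVolume", "reactionVolume", "templateVolume"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)) || slot(object, s) <= 0)
      msg <- c(msg, paste(s, "must be a single positive number"))
  if (length(object@templateVolume) == 1L && length(object@reactionVolume) == 1L &&
      object@templateVolume > object@reactionVolume)
    msg <- c(msg, "templateVolume cannot exceed reactionVolume")
  if (any(object@dilutionFactor < 1)) msg <- c(msg, "dilutionFactor must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Through-origin biomass calibration fit
#'
#' Result of regressing gene copies per gram of dry sediment on added dry kelp
#' carbon (percent of slurry mass) with the intercept coerced to zero. The
#' reciprocal of the slope is the coefficient that converts field gene-copy
#' densities into derived kelp carbon.
#'
#' @slot slope copies per gram dry sediment per percent dry kelp carbon.
#' @slot slopeSe standard error of the slope.
#' @slot Fstat,df F statistic and its (numerator, denominator) degrees of
#'   freedom; for a one-parameter no-intercept fit df = (1, n - 1).
#' @slot r2,adjR2 uncentered R-squared and its no-intercept adjustment.
#' @slot pValue upper-tail F probability.
#' @slot inverseCoefficient percent dry kelp carbon per (copy per gram dry).
#' @slot fitRange range of doses retained in the fit.
#' @slot nObs number of points retained.
#' @slot shapiroW,shapiroP Shapiro-Wilk statistic on residuals (reported, not
#'   enforced).
#' @slot data data.frame of the retained (dose, response) points.
#' @export
setClass("CalibrationFit",
  representation(
    slope = "numeric", slopeSe = "numeric", Fstat = "numeric",
    df = "integer", r2 = "numeric", adjR2 = "numeric", pValue = "numeric",
    inverseCoefficient = "numeric", fitRange = "numeric", nObs = "integer",
    shapiroW = "numeric", shapiroP = "numeric", data = "data.frame"
  )
)

setValidity("CalibrationFit", function(object) {
  msg <- character()
  if (object@slope <= 0) msg <- c(msg, "slope must be positive")
  if (abs(object@inverseCoefficient * object@slope - 1) > 1e-8)
    msg <- c(msg, "inverseCoefficient must equal 1/slope")
  if (length(object@df) != 2L || any(object@df < 1L))
    msg <- c(msg, "df must be two positive integers")
  if (object@r2 < 0 || object@r2 > 1) msg <- c(msg, "r2 must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' qPCR standard curve
#'
#' Ordinary least-squares fit of quantification cycle (Cq) on log10 standard
#' copy number, with amplification efficiency derived from the slope as
#' 10^(-1/slope) - 1 (a slope of -3.3219 is perfect doubling).
#'
#' @slot slope Cq change per log10 copies (negative for a working assay).
#' @slot intercept Cq at one copy.
#' @slot r2 coefficient of determination.
#' @slot efficiency amplification efficiency as a fraction (1 = 100\%).
#' @slot n number of standards.
#' @export
setClass("QpcrCurve",
  representation(slope = "numeric", intercept = "numeric", r2 = "numeric",
                 efficiency = "numeric", n = "integer")
)

setValidity("QpcrCurve", function(object) {
  if (object@slope < 0 &&
      abs(object@efficiency - (10^(-1 / object@slope) - 1)) > 1e-8)
    return("efficiency must equal 10^(-1/slope) - 1 for a negative slope")
  TRUE
})

#' Depth profile of one sediment core
#'
#' Ordered, non-overlapping depth horizons of a single core, with per-slice
#' masses and (optionally) gene-copy measurements. Depths are cm below the
#' sediment-water interface; horizons are [top, bottom) and mid-depths are
#' used for regression and integration.
#'
#' @slot coreId single core label.
#' @slot siteNumber,siteType site the core came from.
#' @slot slices data.frame with one row per horizon (depth_top, depth_bottom,
#'   mid_depth, slice_wet_mass, slice_dry_mass, and measurement columns).
#' @slot innerDiameter core tube internal diameter, cm.
#' @slot maxSampledDepth deepest sampled horizon bottom, cm.
#' @slot gaps data.frame of unsampled [top, bottom) intervals between
#'   horizons.
#' @export
setClass("CoreProfile",
  representation(
    coreId = "character", siteNumber = "character", siteType = "character",
    slices = "data.frame", innerDiameter = "numeric",
    maxSampledDepth = "numeric", gaps = "data.frame"
  )
)

setValidity("CoreProfile", function(object) {
  s <- object@slices
  msg <- character()
  if (length(object@coreId) != 1L) msg <- c(msg, "coreId must be a single label")
  if (nrow(s)) {
    if (any(s$depth_top >= s$depth_bottom)) msg <- c(msg, "depth_top must be < depth_bottom")
    if (any(s$depth_top < 0)) msg <- c(msg, "depths must be >= 0")
    if (is.unsorted(s$depth_top, strictly = TRUE)) msg <- c(msg, "slices must be sorted by depth")
    if (nrow(s) > 1L && any(s$depth_bottom[-nrow(s)] > s$depth_top[-1L] + 1e-9))
      msg <- c(msg, "slices must not overlap")
    if (any(s$slice_dry_mass > s$slice_wet_mass))
      msg <- c(msg, "slice_dry_mass cannot exceed slice_wet_mass")
    if (any(s$slice_wet_mass <= 0) || any(s$slice_dry_mass <= 0))
      msg <- c(msg, "slice masses must be positive")
    if (abs(object@maxSampledDepth - max(s$depth_bottom)) > 1e-9)
      msg <- c(msg, "maxSampledDepth must equal the deepest sampled bottom")
  }
  if (object@innerDiameter <= 0) msg <- c(msg, "innerDiameter must be positive")
  if (length(msg)) msg else TRUE
})

#' Sample-by-taxon count table
#'
#' A \linkS4class{SummarizedExperiment} with taxa as rows and samples as
#' columns: a "counts" assay of non-negative integers, per-taxon ranked
#' taxonomy (domain ... genus) in \code{rowData}, and sample metadata
#' (site_type, site_number, depth, log10_coi, nutrients) in \code{colData}.
#'
#' @export
setClass("TaxaTable", contains = "SummarizedExperiment")

TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

setValidity("TaxaTable", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("a 'counts' assay is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (!isCount(m)) msg <- c(msg, "counts must be non-negative integers")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "taxon (row) names must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample (column) names must be present and unique")
  if (!all(TAXONOMY_RANKS %in%
           colnames(SummarizedExperiment::rowData(object))))
    msg <- c(msg, paste("rowData must carry taxonomy ranks:",
                        paste(TAXONOMY_RANKS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' PERMANOVA table with partial omega-squared effect sizes
#'
#' Sequential (type-I) partitioning of a distance matrix over model terms,
#' with permutation p-values and partial omega-squared per term.
#'
#' @slot results data.frame with one row per term plus Residual and Total
#'   rows (Df, SumOfSqs, R2, pseudoF, pPerm, partialOmega2).
#' @slot permutations number of permutations used.
#' @slot seed seed used for the permutation stream.
#' @export
setClass("PermanovaTable",
  representation(results = "data.frame", permutations = "integer",
                 seed = "integer")
)

setValidity("PermanovaTable", function(object) {
  r <- object@results
  terms <- !(r$term %in% c("Residual", "Total"))
  ssSum <- sum(r$SumOfSqs[terms]) + r$SumOfSqs[r$term == "Residual"]
  if (abs(ssSum - r$SumOfSqs[r$term == "Total"]) >
      1e-8 * max(1, abs(r$SumOfSqs[r$term == "Total"])))
    return("term + residual sums of squares must equal the total")
  p <- r$pPerm[terms]
  if (any(!is.na(p) & (p < 1 / (object@permutations + 1) - 1e-12 | p > 1)))
    return("permutation p-values must lie in [1/(m+1), 1]")
  TRUE
})
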