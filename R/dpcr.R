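#' Construct a set of digital PCR reactions
#'
#' @param positives integer vector, positive partitions per well.
#' @param validPartitions integer vector, valid partitions per well.
#' @param partitionVolume single numeric, microlitres per partition. This is
#'   instrument specific and must be supplied explicitly.
#' @param reactionVolume total reaction volume, microlitres.
#' @param templateVolume template loaded per reaction, microlitres.
#' @param dilutionFactor fold-dilution of the template before loading.
#' @param wellId optional well labels.
#' @return A \linkS4class{DpcrReaction}.
#' @examples
#' DpcrReaction(positives = 4250, validPartitions = 8500,
#'              partitionVolume = 0.0004)
#' @export
DpcrReaction <- function(positives, validPartitions, partitionVolume,
                         reactionVolume = 16, templateVolume = 4,
                         dilutionFactor = 1,
                         wellId = paste0("well", seq_along(positives))) {
  failIf(missing(partitionVolume) || is.null(partitionVolume),
         "partitionVolume is required (instrument specific, no default)")
  n <- length(positives)
  new("DpcrReaction",
      wellId = as.character(wellId),
      positives = as.integer(round(positives)),
      validPartitions = as.integer(rep_len(validPartitions, n)),
      partitionVolume = as.numeric(partitionVolume),
      reactionVolume = as.numeric(reactionVolume),
      templateVolume = as.numeric(templateVolume),
      dilutionFactor = as.numeric(rep_len(dilutionFactor, n)))
}

#' Per-sample extraction and mass bookkeeping
#'
#' Records how a sediment slice was taken through DNA extraction: the wet
#' mass loaded into the extraction, the elution volume, and the wet and dry
#' mass of the parent slice (whose dry:wet ratio converts the extracted wet
#' mass to a dry-mass basis).
#'
#' @param extractedWetMass grams of wet sediment extracted (about 0.25 g for
#'   a soil-kit column).
#' @param elutionVolume microlitres of eluate.
#' @param sliceWetMass,sliceDryMass grams, wet and dry mass of the slice.
#' @return A validated list of the four (vectorised) fields.
#' @export
extractionRecord <- function(extractedWetMass = 0.25, elutionVolume = 100,
                             sliceWetMass, sliceDryMass) {
  failIf(any(elutionVolume <= 0), "elutionVolume must be positive")
  failIf(any(extractedWetMass <= 0), "extractedWetMass must be positive")
  failIf(any(sliceDryMass <= 0), "sliceDryMass must be positive")
  failIf(any(sliceDryMass > sliceWetMass),
         "sliceDryMass cannot exceed sliceWetMass")
  structure(list(extractedWetMass = extractedWetMass,
                 elutionVolume = elutionVolume,
                 sliceWetMass = sliceWetMass,
                 sliceDryMass = sliceDryMass),
            class = "extractionRecord")
}

#' Poisson concentration estimate from partition counts
#'
#' The standard dPCR estimator: with a fraction p of positive partitions the
#' mean target occupancy per partition is lambda = -ln(1 - p), and the
#' concentration in the reaction mix is lambda divided by the partition
#' volume. Wells with zero positives return 0 and are flagged below the
#' limit of detection; fully saturated wells (p = 1) have no finite estimate
#' and raise an error.
#'
#' @param rxn a \linkS4class{DpcrReaction}.
#' @return data.frame with columns \code{well_id}, \code{lambda},
#'   \code{copies_per_ul_rxn} and \code{below_lod}.
#' @examples
#' rxn <- DpcrReaction(4250, 8500, partitionVolume = 0.0004)
#' poissonConcentration(rxn)  # lambda = ln 2, about 1733 copies/uL
#' @export
poissonConcentration <- function(rxn) {
  stopifnot(is(rxn, "DpcrReaction"))
  validObject(rxn)
  p <- rxn@positives / rxn@validPartitions
  failIf(any(p >= 1),
         "saturated well(s): all partitions positive, no finite estimate")
  lambda <- -log1p(-p)
  data.frame(well_id = rxn@wellId,
             lambda = lambda,
             copies_per_ul_rxn = lambda / rxn@partitionVolume,
             below_lod = rxn@positives == 0L,
             stringsAsFactors = FALSE)
}

#' Convert reaction-mix concentration to copies per gram of dry sediment
#'
#' Dimensional chain from the dPCR readout back to the sediment: copies per
#' microlitre of reaction, times reaction/template volume ratio and any
#' pre-dilution, gives copies per microlitre of eluate; times the elution
#' volume gives total copies recovered from the extracted wet mass; dividing
#' by the extracted mass on a dry basis (wet mass times the slice dry:wet
#' ratio) yields copies per gram of dry sediment. Every factor is carried
#' explicitly so any step can be overridden.
#'
#' @param concRxn numeric vector of copies per microlitre of reaction mix, or
#'   the data.frame returned by \code{\link{poissonConcentration}}.
#' @param rxn the \linkS4class{DpcrReaction} the concentrations came from.
#' @param ext an \code{\link{extractionRecord}} (vectorised over wells).
#' @return data.frame with \code{copies_per_g_dry}, \code{below_lod} and
#'   \code{saturated} columns.
#' @examples
#' rxn <- DpcrReaction(4250, 8500, partitionVolume = 0.0004)
#' ext <- extractionRecord(0.25, 100, sliceWetMass = 10, sliceDryMass = 4)
#' copiesPerGramDry(10, rxn, ext)  # 10 * 4 * 100 / (0.25 * 0.4) = 40000
#' @export
copiesPerGramDry <- function(concRxn, rxn, ext) {
  stopifnot(is(rxn, "DpcrReaction"), inherits(ext, "extractionRecord"))
  belowLod <- FALSE
  if (is.data.frame(concRxn)) {
    belowLod <- concRxn$below_lod
    concRxn <- concRxn$copies_per_ul_rxn
  }
  failIf(any(concRxn < 0), "concentration must be non-negative")
  dryWet <- ext$sliceDryMass / ext$sliceWetMass
  copies <- concRxn * (rxn@reactionVolume / rxn@templateVolume) *
    rxn@dilutionFactor * ext$elutionVolume /
    (ext$extractedWetMass * dryWet)
  data.frame(copies_per_g_dry = copies,
             below_lod = belowLod | concRxn == 0,
             saturated = FALSE)
}
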