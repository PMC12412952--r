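## Synthetic survey, lab and community generators. These emulate the
## statistical structure the downstream stages assume (log10-scale field
## variation, Poisson partition counts, linear-then-saturating spiking
## response, Dirichlet-multinomial communities) so the whole pipeline is
## testable without field data.

#' Survey design for a synthetic coring campaign
#'
#' Defaults describe a two-type survey of a kelp farm: three sites inside
#' and two outside, three cores per site, and the five eDNA depth horizons
#' 0-1, 1-2, 2-3, 4-5 and 6-7 cm (leaving a 3-4 and 5-6 cm gap, as when
#' only a subset of slices is assayed).
#'
#' @param sitesPerType named integer vector, sites per site type.
#' @param coresPerSite cores collected at each site.
#' @param horizons two-column matrix of (top, bottom) depth intervals in cm.
#' @param innerDiameter core tube internal diameter, cm.
#' @return A validated list of class \code{"surveyDesign"}.
#' @export
surveyDesign <- function(sitesPerType = c(inside = 3L, outside = 2L),
                         coresPerSite = 3L,
                         horizons = cbind(top = c(0, 1, 2, 4, 6),
                                          bottom = c(1, 2, 3, 5, 7)),
                         innerDiameter = 10) {
  failIf(is.null(names(sitesPerType)) || any(names(sitesPerType) == ""),
         "sitesPerType must be a named vector of site-type counts")
  failIf(any(sitesPerType < 1L), "at least one site per type")
  failIf(coresPerSite < 1L, "coresPerSite must be >= 1")
  horizons <- as.matrix(horizons)
  failIf(ncol(horizons) != 2L, "horizons must have two columns (top, bottom)")
  failIf(any(horizons[, 1] >= horizons[, 2]),
         "horizon top must be < bottom")
  failIf(any(horizons < 0), "horizon depths must be >= 0")
  o <- order(horizons[, 1])
  horizons <- horizons[o, , drop = FALSE]
  if (nrow(horizons) > 1L)
    failIf(any(horizons[-1L, 1] < horizons[-nrow(horizons), 2] - 1e-9),
           "horizons must not overlap")
  structure(list(sitesPerType = sitesPerType,
                 coresPerSite = as.integer(coresPerSite),
                 horizons = horizons,
                 innerDiameter = innerDiameter),
            class = "surveyDesign")
}

#' Field model for log10 gene-copy concentrations
#'
#' Per-slice true concentration (copies per gram dry sediment) is
#' 10^(mu_type + site_offset + depth_slope * mid_depth + eps) with
#' eps ~ Normal(0, residual_sd): log-normal field noise, matching a
#' log10-scale analysis. Defaults follow a surveyed farm contrast: aggregate
#' log10 means 4.816 inside / 4.506 outside, a depth decay of -0.06 per cm,
#' and one anomalously rich "hotspot" site inside the farm at +0.43.
#'
#' @param meanLog10Inside,meanLog10Outside type-level mean log10 copies/g.
#' @param depthSlope change in log10 copies/g per cm of depth.
#' @param hotspotSiteOffset extra log10 offset for the hotspot site.
#' @param hotspotSite index of the inside site receiving the offset (0 for
#'   none).
#' @param residualSd residual SD in log10 units (> 0).
#' @return A validated list of class \code{"coiFieldModel"}.
#' @export
coiFieldModel <- function(meanLog10Inside = 4.816, meanLog10Outside = 4.506,
                          depthSlope = -0.06, hotspotSiteOffset = 0.43,
                          hotspotSite = 2L, residualSd = 0.2) {
  failIf(residualSd < 0, "residualSd must be >= 0")  # 0 = noise-free limit
  structure(list(meanLog10Inside = meanLog10Inside,
                 meanLog10Outside = meanLog10Outside,
                 depthSlope = depthSlope,
                 hotspotSiteOffset = hotspotSiteOffset,
                 hotspotSite = as.integer(hotspotSite),
                 residualSd = residualSd),
            class = "coiFieldModel")
}

#' Simulate a coring survey with true gene-copy concentrations
#'
#' Generates one slice per core and horizon. Slice wet mass comes from a
#' wet bulk density drawn uniformly per slice (default 1.15-1.45 g/cm3,
#' fine marine mud) times the slice volume; dry mass applies a dry:wet
#' mass ratio drawn uniformly in \code{dryWetRange}. True concentrations
#' follow the field model; measurement (dPCR) noise is added separately by
#' \code{\link{simulateDpcrWell}}.
#'
#' @param design a \code{\link{surveyDesign}}.
#' @param model a \code{\link{coiFieldModel}}.
#' @param seed integer root seed.
#' @param dryWetRange range of the slice dry:wet mass ratio.
#' @param wetDensityRange range of wet bulk density, g/cm3.
#' @return data.frame with one row per slice: identifiers, depths, masses,
#'   \code{true_log10_copies} and \code{true_copies_per_g_dry}.
#' @export
simulateCoreSurvey <- function(design, model, seed = 1,
                               dryWetRange = c(0.3, 0.5),
                               wetDensityRange = c(1.15, 1.45)) {
  stopifnot(inherits(design, "surveyDesign"),
            inherits(model, "coiFieldModel"))
  set.seed(streamSeed(seed, 1L))
  types <- names(design$sitesPerType)
  rows <- list()
  siteCounter <- 0L
  for (ty in types) {
    for (si in seq_len(design$sitesPerType[[ty]])) {
      siteCounter <- siteCounter + 1L
      siteOffset <- 0
      if (ty == "inside" && si == model$hotspotSite)
        siteOffset <- model$hotspotSiteOffset
      for (co in seq_len(design$coresPerSite)) {
        h <- design$horizons
        mid <- (h[, 1] + h[, 2]) / 2
        thick <- h[, 2] - h[, 1]
        vol <- pi * (design$innerDiameter / 2)^2 * thick
        wetRho <- runif(nrow(h), wetDensityRange[1], wetDensityRange[2])
        dryWet <- runif(nrow(h), dryWetRange[1], dryWetRange[2])
        mu <- switch(ty, inside = model$meanLog10Inside,
                     model$meanLog10Outside)
        lg <- mu + siteOffset + model$depthSlope * mid +
          rnorm(nrow(h), 0, model$residualSd)
        coreId <- sprintf("%s_s%d_c%d", ty, siteCounter, co)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_d%g", coreId, mid),
          core_id = coreId,
          site_number = as.character(siteCounter),
          site_type = ty,
          depth_top = h[, 1], depth_bottom = h[, 2], mid_depth = mid,
          slice_wet_mass = wetRho * vol,
          slice_dry_mass = wetRho * vol * dryWet,
          true_log10_copies = lg,
          true_copies_per_g_dry = 10^lg,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate digital PCR wells for known concentrations
#'
#' Partition counts follow the dPCR generative model: each of
#' \code{nPartitions} partitions of volume \code{partitionVolume} amplifies
#' independently with probability 1 - exp(-conc * volume), so positives are
#' Binomial(nPartitions, 1 - exp(-lambda)).
#'
#' @param trueConc copies per microlitre of reaction mix (vectorised; one
#'   well per value).
#' @param nPartitions valid partitions per well.
#' @param partitionVolume microlitres per partition.
#' @param seed integer root seed.
#' @param ... further arguments (reactionVolume, templateVolume,
#'   dilutionFactor, wellId) passed to \code{\link{DpcrReaction}}.
#' @return A \linkS4class{DpcrReaction} with one well per concentration.
#' @export
simulateDpcrWell <- function(trueConc, nPartitions = 8500,
                             partitionVolume = 4e-4, seed = 1, ...) {
  failIf(any(trueConc < 0), "trueConc must be >= 0")
  failIf(nPartitions < 1, "nPartitions must be >= 1")
  failIf(partitionVolume <= 0, "partitionVolume must be > 0")
  set.seed(streamSeed(seed, 2L))
  pPos <- -expm1(-trueConc * partitionVolume)
  pos <- rbinom(length(trueConc), size = nPartitions, prob = pPos)
  DpcrReaction(positives = pos, validPartitions = nPartitions,
               partitionVolume = partitionVolume, ...)
}

#' Spiking-experiment design
#'
#' Defaults mirror a laboratory dose-response: wet kelp additions of 0,
#' 0.01, 0.05, 0.10, 0.50, 1.00, 2.00 and 5.00 percent by slurry mass,
#' three replicates per level, a true slope of 1.3e10 copies per gram dry
#' per percent dry kelp carbon, 30 percent multiplicative noise, and a
#' response that saturates above 0.08 percent dry kelp carbon (the top
#' level falls below the linear extrapolation).
#'
#' @param wetPctLevels wet-biomass addition levels, percent by mass.
#' @param replicates replicates per level.
#' @param trueSlope copies g^-1 dry per percent dry kelp carbon (> 0).
#' @param noiseCv coefficient of variation of the multiplicative response
#'   noise (>= 0).
#' @param plateauAbovePct percent dry kelp carbon beyond which the mean
#'   response stays at the plateau level.
#' @param dryWetRatio,carbonFrac wet-to-dry-carbon conversion factors (see
#'   \code{\link{wetToDryCarbon}}).
#' @return A validated list of class \code{"spikingDesign"}.
#' @export
spikingDesign <- function(wetPctLevels = c(0, 0.01, 0.05, 0.10, 0.50,
                                           1.00, 2.00, 5.00),
                          replicates = 3L, trueSlope = 1.3e10,
                          noiseCv = 0.3, plateauAbovePct = 0.0825,
                          dryWetRatio = 0.125, carbonFrac = 0.33) {
  failIf(any(wetPctLevels < 0), "wetPctLevels must be >= 0")
  failIf(trueSlope <= 0, "trueSlope must be > 0")
  failIf(noiseCv < 0, "noiseCv must be >= 0")
  failIf(replicates < 1L, "replicates must be >= 1")
  structure(list(wetPctLevels = wetPctLevels,
                 replicates = as.integer(replicates),
                 trueSlope = trueSlope, noiseCv = noiseCv,
                 plateauAbovePct = plateauAbovePct,
                 dryWetRatio = dryWetRatio, carbonFrac = carbonFrac),
            class = "spikingDesign")
}

#' Simulate the biomass spiking dose-response
#'
#' Mean response is linear in dry kelp carbon below the plateau
#' (slope * dose) and flat at slope * plateau above it. Noise is
#' multiplicative log-normal with the requested coefficient of variation,
#' mean-corrected so the expectation stays on the line.
#'
#' @param design a \code{\link{spikingDesign}}.
#' @param seed integer root seed.
#' @return data.frame: \code{level_wet_pct}, \code{replicate},
#'   \code{dry_carbon_pct}, \code{copies_per_g_dry}.
#' @export
simulateSpikingExperiment <- function(design, seed = 1) {
  stopifnot(inherits(design, "spikingDesign"))
  set.seed(streamSeed(seed, 3L))
  wet <- rep(design$wetPctLevels, each = design$replicates)
  dryC <- wetToDryCarbon(wet, design$dryWetRatio, design$carbonFrac)
  meanResp <- design$trueSlope * pmin(dryC, design$plateauAbovePct)
  if (design$noiseCv > 0) {
    sigma <- sqrt(log1p(design$noiseCv^2))
    resp <- meanResp * exp(rnorm(length(meanResp), -sigma^2 / 2, sigma))
  } else resp <- meanResp
  data.frame(level_wet_pct = wet,
             replicate = rep(seq_len(design$replicates),
                             times = length(design$wetPctLevels)),
             dry_carbon_pct = dryC,
             copies_per_g_dry = resp)
}

#' Simulate sediment nutrient measurements
#'
#' Total carbon is uniform over \code{tcRange} percent; total organic
#' carbon is \code{tocTcRatio} times TC plus optional Gaussian noise; total
#' nitrogen is Gaussian around \code{tnMean} with an optional additive
#' site-type effect applied to inside samples (default none).
#'
#' @param metadata data.frame with \code{sample_id} and \code{site_type}.
#' @param tcRange range of TC percent.
#' @param tocTcRatio TOC:TC ratio, in (0, 1].
#' @param noiseSd SD of the TOC noise (percent units).
#' @param tnMean,tnSd,tnInsideEffect total-nitrogen parameters (percent).
#' @param seed integer root seed.
#' @return data.frame: \code{sample_id}, \code{tc_pct}, \code{toc_pct},
#'   \code{tn_pct}.
#' @export
simulateNutrients <- function(metadata, tcRange = c(3.25, 3.6),
                              tocTcRatio = 0.939, noiseSd = 0,
                              tnMean = 0.35, tnSd = 0.03,
                              tnInsideEffect = 0, seed = 1) {
  failIf(tocTcRatio <= 0 || tocTcRatio > 1, "tocTcRatio must lie in (0, 1]")
  failIf(!all(c("sample_id", "site_type") %in% names(metadata)),
         "metadata needs sample_id and site_type columns")
  set.seed(streamSeed(seed, 5L))
  n <- nrow(metadata)
  tc <- runif(n, tcRange[1], tcRange[2])
  toc <- tocTcRatio * tc + rnorm(n, 0, noiseSd)
  tn <- rnorm(n, tnMean, tnSd) +
    ifelse(metadata$site_type == "inside", tnInsideEffect, 0)
  data.frame(sample_id = metadata$sample_id, tc_pct = tc, toc_pct = toc,
             tn_pct = tn, stringsAsFactors = FALSE)
}

#' Community model for synthetic taxa tables
#'
#' Log-linear Dirichlet-multinomial community: per-sample taxon weights are
#' softmax(baseline + site effect * inside + depth effect * depth + COI
#' effect * centred log10 copies); a Dirichlet draw with the given
#' concentration adds overdispersion and a multinomial draw with a uniform
#' random library size yields counts. Effect vectors are named by taxon
#' index; positive site effects enrich inside-farm samples. Taxonomy is
#' fabricated so that several "ASVs" share each family (three per family by
#' default), exercising rank aggregation.
#'
#' @param nTaxa number of taxa.
#' @param baselineLog baseline log abundances (length \code{nTaxa}); the
#'   default is a geometric decline spanning about e^6.
#' @param siteEffects named numeric: per-cm log effects applied to inside
#'   samples (names = taxon indices).
#' @param depthEffects named numeric: per-cm log effects of depth.
#' @param coiEffects named numeric: log effects per unit of centred log10
#'   gene copies.
#' @param dispersion Dirichlet concentration (larger = less overdispersed).
#' @param librarySizeRange reads per sample, drawn uniformly.
#' @param taxaPerFamily ASVs per fabricated family.
#' @return A validated list of class \code{"communityModel"}.
#' @export
communityModel <- function(nTaxa = 120L,
                           baselineLog = seq(3, -3, length.out = nTaxa),
                           siteEffects = c("1" = 1, "2" = 1, "3" = 1,
                                           "7" = -1, "8" = -1, "9" = -1),
                           depthEffects = c("13" = 0.25, "14" = 0.25,
                                            "19" = -0.25, "20" = -0.25),
                           coiEffects = c("25" = 0.8, "26" = 0.8,
                                          "31" = -0.8),
                           dispersion = 200,
                           librarySizeRange = c(5000L, 15000L),
                           taxaPerFamily = 3L) {
  failIf(length(baselineLog) != nTaxa,
         "baselineLog must have one entry per taxon")
  failIf(any(!is.finite(baselineLog)), "baselineLog must be finite")
  failIf(dispersion <= 0, "dispersion must be > 0")
  failIf(any(librarySizeRange < 1), "library sizes must be >= 1")
  for (eff in list(siteEffects, depthEffects, coiEffects)) {
    failIf(length(eff) > 0 && any(!is.finite(eff)),
           "effects must be finite")
    if (length(eff)) {
      idx <- suppressWarnings(as.integer(names(eff)))
      failIf(any(is.na(idx)) || any(idx < 1L) || any(idx > nTaxa),
             "effect names must be taxon indices within 1..nTaxa")
    }
  }
  structure(list(nTaxa = as.integer(nTaxa), baselineLog = baselineLog,
                 siteEffects = siteEffects, depthEffects = depthEffects,
                 coiEffects = coiEffects, dispersion = dispersion,
                 librarySizeRange = librarySizeRange,
                 taxaPerFamily = as.integer(taxaPerFamily)),
            class = "communityModel")
}

syntheticTaxonomy <- function(nTaxa, taxaPerFamily) {
  idx <- seq_len(nTaxa)
  fam <- (idx - 1L) %/% taxaPerFamily + 1L
  ord <- (fam - 1L) %/% 4L + 1L
  data.frame(domain = "Bacteria",
             phylum = sprintf("Phylum_%d", (ord - 1L) %/% 4L + 1L),
             class = sprintf("Class_%d", (ord - 1L) %/% 2L + 1L),
             order = sprintf("Order_%d", ord),
             family = sprintf("Family_%d", fam),
             genus = sprintf("Genus_%d", idx),
             row.names = sprintf("ASV_%03d", idx),
             stringsAsFactors = FALSE)
}

#' Simulate a sample-by-taxon count table
#'
#' @param model a \code{\link{communityModel}}.
#' @param metadata data.frame with one row per sample; required columns
#'   \code{sample_id}, \code{site_type}, \code{mid_depth} (or \code{depth})
#'   and \code{log10_coi}.
#' @param seed integer root seed.
#' @return A \linkS4class{TaxaTable} carrying \code{metadata} as sample
#'   data.
#' @export
simulateTaxaTable <- function(model, metadata, seed = 1) {
  stopifnot(inherits(model, "communityModel"))
  depthCol <- if ("mid_depth" %in% names(metadata)) "mid_depth" else "depth"
  req <- c("sample_id", "site_type", depthCol, "log10_coi")
  missingCols <- setdiff(req, names(metadata))
  failIf(length(missingCols) > 0,
         paste("metadata missing columns:",
               paste(missingCols, collapse = ", ")))
  set.seed(streamSeed(seed, 4L))
  n <- nrow(metadata)
  eta <- matrix(rep(model$baselineLog, n), ncol = n)  # taxa x samples
  addEffect <- function(eta, effects, x) {
    if (!length(effects)) return(eta)
    ti <- as.integer(names(effects))
    eta[ti, ] <- eta[ti, ] + outer(unname(effects), x)
    eta
  }
  coiCentered <- metadata$log10_coi - mean(metadata$log10_coi)
  eta <- addEffect(eta, model$siteEffects,
                   as.numeric(metadata$site_type == "inside"))
  eta <- addEffect(eta, model$depthEffects, metadata[[depthCol]])
  eta <- addEffect(eta, model$coiEffects, coiCentered)
  libs <- sample(model$librarySizeRange[1]:model$librarySizeRange[2], n,
                 replace = TRUE)
  m <- vapply(seq_len(n), function(j) {
    p <- exp(eta[, j] - max(eta[, j]))
    p <- p / sum(p)
    g <- rgamma(model$nTaxa, shape = model$dispersion * p)  # Dirichlet draw
    rmultinom(1, size = libs[j], prob = g / sum(g))[, 1]
  }, integer(model$nTaxa))
  tax <- syntheticTaxonomy(model$nTaxa, model$taxaPerFamily)
  dimnames(m) <- list(rownames(tax), metadata$sample_id)
  TaxaTable(m, tax, metadata)
}
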