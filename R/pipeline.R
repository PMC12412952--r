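#' Pipeline configuration
#'
#' Assembles (and validates) the full set of options driving
#' \code{\link{runPipeline}}, optionally seeded from a YAML file; arguments
#' given here override YAML values. Defaults run the built-in synthetic
#' scenario end to end.
#'
#' @param yaml optional path to a YAML file of options.
#' @param ... name = value overrides (see Details).
#' @details Options: \code{seed} (root seed), \code{out_dir} (NULL for no
#'   file output); dPCR geometry \code{partition_volume},
#'   \code{n_partitions}, \code{reaction_volume}, \code{template_volume},
#'   \code{dilution_factor}; extraction \code{extracted_wet_mass},
#'   \code{elution_volume}; calibration \code{dry_wet_ratio},
#'   \code{carbon_frac}, \code{exclude_above}; integration \code{z_max}
#'   (NULL = per-core maximum sampled depth), \code{interpolation}
#'   ("linear"/"nearest"); statistics \code{alpha}, \code{permutations},
#'   \code{pseudo_count} (NULL = automatic half-minimum rule); community
#'   \code{rarefaction_depth} ("min" or reads), \code{rank}, \code{top_k};
#'   input paths \code{slice_csv}, \code{dpcr_csv}, \code{spiking_csv},
#'   \code{taxa_tsv}, \code{metadata_csv} (all NULL = simulate instead).
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(yaml = NULL, ...) {
  cfg <- list(
    seed = 1L, out_dir = NULL,
    partition_volume = 4e-4, n_partitions = 8500L,
    reaction_volume = 16, template_volume = 4, dilution_factor = 1,
    extracted_wet_mass = 0.25, elution_volume = 100,
    dry_wet_ratio = 0.125, carbon_frac = 0.33, exclude_above = 0.0825,
    z_max = NULL, interpolation = "linear",
    alpha = 0.05, permutations = 999L, pseudo_count = NULL,
    rarefaction_depth = "min", rank = "family", top_k = 30L,
    slice_csv = NULL, dpcr_csv = NULL, spiking_csv = NULL,
    taxa_tsv = NULL, metadata_csv = NULL)
  if (!is.null(yaml)) {
    failIf(!file.exists(yaml), paste("config file not found:", yaml))
    fromYaml <- yaml::read_yaml(yaml)
    unknown <- setdiff(names(fromYaml), names(cfg))
    failIf(length(unknown) > 0,
           paste("unknown config option(s):", paste(unknown, collapse = ", ")))
    cfg[names(fromYaml)] <- fromYaml
  }
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    failIf(length(unknown) > 0,
           paste("unknown config option(s):", paste(unknown, collapse = ", ")))
    cfg[names(overrides)] <- overrides
  }
  failIf(cfg$partition_volume <= 0, "partition_volume must be > 0")
  failIf(cfg$permutations < 99, "permutations must be >= 99")
  failIf(!cfg$interpolation %in% c("linear", "nearest"),
         "interpolation must be 'linear' or 'nearest'")
  structure(cfg, class = "pipelineConfig")
}

#' Run the full eDNA-to-kelp-carbon analysis
#'
#' Executes the complete flow on either synthetic or file-based inputs:
#' spiking calibration (through-origin fit and inversion), dPCR
#' quantification to copies per gram dry sediment, per-core depth
#' integration to derived kelp carbon, site contrasts (nested OLS on log10
#' copies; Kruskal-Wallis and Dunn on integrated derived kelp carbon), and
#' the community layer (rarefaction, alpha diversity, Bray-Curtis, PCoA,
#' PERMANOVA with partial omega-squared, volcano and Spearman screens).
#' With no input paths configured, every input is simulated from the
#' package's generators under the config seed.
#'
#' @param config a \code{\link{pipelineConfig}} (default: the synthetic
#'   scenario).
#' @return list of class \code{"runReport"} with elements
#'   \code{calibration}, \code{slices}, \code{integrated},
#'   \code{ols}, \code{kruskal}, \code{dunn}, \code{alpha},
#'   \code{pcoa}, \code{permanova}, \code{volcano}, \code{spearman},
#'   \code{warnings}, \code{seed}, \code{config}, \code{version}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  seed <- config$seed
  warningsLog <- character()

  ## --- calibration ---------------------------------------------------
  spiking <- if (is.null(config$spiking_csv)) {
    simulateSpikingExperiment(
      spikingDesign(dryWetRatio = config$dry_wet_ratio,
                    carbonFrac = config$carbon_frac), seed = seed)
  } else readSpikingTable(config$spiking_csv)
  if (!"dry_carbon_pct" %in% names(spiking))
    spiking$dry_carbon_pct <- wetToDryCarbon(
      spiking$level_wet_pct, config$dry_wet_ratio, config$carbon_frac)
  calib <- fitThroughOrigin(spiking$dry_carbon_pct,
                            spiking$copies_per_g_dry,
                            excludeAbove = config$exclude_above)

  ## --- quantification ------------------------------------------------
  if (is.null(config$slice_csv)) {
    slices <- simulateCoreSurvey(surveyDesign(), coiFieldModel(),
                                 seed = seed)
    rxn <- simulateDpcrWell(
      trueConcReaction(slices$true_copies_per_g_dry, config,
                       dryWetRatio = slices$slice_dry_mass /
                         slices$slice_wet_mass),
      nPartitions = config$n_partitions,
      partitionVolume = config$partition_volume, seed = seed,
      reactionVolume = config$reaction_volume,
      templateVolume = config$template_volume,
      dilutionFactor = config$dilution_factor,
      wellId = slices$sample_id)
  } else {
    slices <- readSliceTable(config$slice_csv)
    dp <- readDpcrTable(config$dpcr_csv)
    idx <- match(slices$sample_id, dp$sample_id)
    failIf(any(is.na(idx)),
           "dPCR table lacks wells for some slice sample_ids")
    dp <- dp[idx, ]
    rxn <- DpcrReaction(dp$positives, dp$valid_partitions,
                        partitionVolume = config$partition_volume,
                        reactionVolume = config$reaction_volume,
                        templateVolume = config$template_volume,
                        dilutionFactor = config$dilution_factor,
                        wellId = dp$well_id)
  }
  conc <- poissonConcentration(rxn)
  ext <- extractionRecord(config$extracted_wet_mass, config$elution_volume,
                          sliceWetMass = slices$slice_wet_mass,
                          sliceDryMass = slices$slice_dry_mass)
  quant <- copiesPerGramDry(conc, rxn, ext)
  slices$copies_per_g_dry <- quant$copies_per_g_dry
  slices$below_lod <- quant$below_lod
  if (any(quant$below_lod))
    warningsLog <- c(warningsLog,
                     sprintf("%d well(s) below detection limit",
                             sum(quant$below_lod)))
  if (!"mid_depth" %in% names(slices))
    slices$mid_depth <- (slices$depth_top + slices$depth_bottom) / 2

  ## --- integration and site statistics --------------------------------
  integrated <- integrateCores(slices, calibration = calib,
                               zMax = config$z_max,
                               method = config$interpolation)
  slices$log10_coi <- logTransform(slices$copies_per_g_dry,
                                   pseudoCount = config$pseudo_count)
  ols <- fitNestedOls(slices, response = "log10_coi",
                      depth = "mid_depth")
  kw <- kruskalWallis(integrated$derived_kelp_carbon_per_cm3,
                      integrated$site_type)
  dunn <- dunnPosthoc(integrated$derived_kelp_carbon_per_cm3,
                      integrated$site_type)

  ## --- community layer -------------------------------------------------
  tt <- if (is.null(config$taxa_tsv)) {
    simulateTaxaTable(communityModel(), slices, seed = seed)
  } else readTaxaTableTsv(config$taxa_tsv, config$metadata_csv)
  rar <- rarefyTable(tt, depth = config$rarefaction_depth, seed = seed)
  dropped <- attr(rar, "dropped_samples")
  if (length(dropped))
    warningsLog <- c(warningsLog,
                     paste("rarefaction dropped:",
                           paste(dropped, collapse = ", ")))
  agg <- aggregateTaxa(rar, rank = config$rank, k = config$top_k)
  alpha <- alphaDiversity(rar)
  bc <- brayCurtis(rar)
  ord <- pcoaOrdination(bc)
  perm <- permanova(bc, sampleData(rar),
                    terms = c("site_type", "mid_depth", "log10_coi"),
                    permutations = config$permutations, seed = seed)
  volc <- volcanoScreen(rar, group = "site_type", reference = "inside")
  spear <- spearmanScreen(rar, covariate = "log10_coi")

  report <- structure(list(
    calibration = calib, slices = slices, integrated = integrated,
    ols = ols, kruskal = kw, dunn = dunn, aggregated = agg,
    alpha = alpha, pcoa = ord, permanova = perm, volcano = volc,
    spearman = spear, warnings = warningsLog, seed = seed,
    config = unclass(config),
    version = as.character(packageVersion("kelpcarbon"))),
    class = "runReport")

  if (!is.null(config$out_dir)) writeRunReport(report, config$out_dir)
  report
}

## Reaction-mix concentration implied by a copies/g-dry truth under the
## configured extraction and loading geometry (inverse of copiesPerGramDry);
## dryWetRatio is the slice's dry:wet mass ratio.
trueConcReaction <- function(copiesPerGDry, config, dryWetRatio) {
  copiesPerGDry * config$extracted_wet_mass * dryWetRatio /
    (config$elution_volume * config$dilution_factor *
     (config$reaction_volume / config$template_volume))
}

#' @export
print.runReport <- function(x, ...) {
  cat("kelpcarbon run report (version", x$version, ", seed", x$seed, ")\n\n")
  show(x$calibration)
  cat("\n")
  print(x$ols)
  cat("\nIntegrated derived kelp carbon, site contrast:\n  ")
  print(x$kruskal)
  cat("\n")
  show(x$permanova)
  if (length(x$warnings))
    cat("\nWarnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

writeRunReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeSliceTable(report$slices, file.path(outDir, "slices.csv"))
  write.csv(report$integrated, file.path(outDir, "integrated_cores.csv"),
            row.names = FALSE)
  write.csv(report$alpha, file.path(outDir, "alpha_diversity.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(report$pcoa$points),
            file.path(outDir, "pcoa_coordinates.csv"))
  write.csv(permanovaResults(report$permanova),
            file.path(outDir, "permanova.csv"), row.names = FALSE)
  write.csv(report$volcano, file.path(outDir, "volcano.csv"),
            row.names = FALSE)
  write.csv(report$spearman, file.path(outDir, "spearman.csv"),
            row.names = FALSE)
  summaryJson <- list(
    version = report$version, seed = report$seed,
    warnings = report$warnings,
    calibration = list(slope = report$calibration@slope,
                       inverse = report$calibration@inverseCoefficient,
                       adj_r2 = report$calibration@adjR2),
    ols = list(F = report$ols$F, df = report$ols$df, p = report$ols$p,
               adj_r2 = report$ols$adj_r2),
    kruskal = unclass(report$kruskal),
    config = report$config[!vapply(report$config, is.null, logical(1))])
  jsonlite::write_json(summaryJson, file.path(outDir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
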