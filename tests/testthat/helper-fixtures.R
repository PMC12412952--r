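## Small programmatic fixtures shared across test files.

## A slice table for one core with unit dry bulk density (dry mass equals
## the cylinder volume of each slice), so copies/g equals copies/cm3.
unitDensitySlices <- function(tops, bottoms, copies, coreId = "c1",
                              diameter = 10) {
  vol <- pi * (diameter / 2)^2 * (bottoms - tops)
  data.frame(core_id = coreId, site_number = "1", site_type = "inside",
             depth_top = tops, depth_bottom = bottoms,
             slice_wet_mass = 2 * vol, slice_dry_mass = vol,
             copies_per_g_dry = copies, stringsAsFactors = FALSE)
}

## Tiny deterministic TaxaTable: counts matrix taxa x samples plus minimal
## metadata (site_type alternating, depth increasing, log10_coi supplied).
toyTaxaTable <- function(m, siteType = NULL, depth = NULL,
                         log10Coi = NULL) {
  nT <- nrow(m); nS <- ncol(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("t%02d", seq_len(nT))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(nS))
  tax <- data.frame(domain = "Bacteria", phylum = "P1", class = "C1",
                    order = "O1",
                    family = sprintf("F%d", (seq_len(nT) - 1) %/% 2 + 1),
                    genus = sprintf("G%d", seq_len(nT)),
                    row.names = rownames(m), stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = colnames(m),
    site_type = if (is.null(siteType))
      rep(c("inside", "outside"), length.out = nS) else siteType,
    site_number = as.character(rep(1:2, length.out = nS)),
    mid_depth = if (is.null(depth)) seq_len(nS) else depth,
    log10_coi = if (is.null(log10Coi)) seq(4, 5, length.out = nS)
                else log10Coi,
    stringsAsFactors = FALSE)
  TaxaTable(m, tax, meta)
}

## Noiseless 2022-shaped survey frame: 2 types, 5 sites (3 in / 2 out),
## 3 cores per site, mid-depths of the five standard horizons.
noiselessSurveyFrame <- function(betaType = -0.31, betaSite2 = 0.43,
                                 betaDepth = -0.06, intercept = 4.816) {
  design <- expand.grid(depth = c(0.5, 1.5, 2.5, 4.5, 6.5),
                        core = 1:3, site = 1:5,
                        KEEP.OUT.ATTRS = FALSE)
  design$site_type <- ifelse(design$site <= 3, "inside", "outside")
  design$site_number <- as.character(design$site)
  design$log10_coi <- intercept +
    betaType * (design$site_type == "outside") +
    betaSite2 * (design$site == 2) +
    betaDepth * design$depth
  design
}
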