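## Plain-text readers and writers for the tables the pipeline consumes:
## CSV for dPCR partitions, slices, spiking and nutrients; TSV (taxa in
## rows, lineage column) and BIOM JSON for count tables. All writers emit
## UTF-8 with documented headers; all readers validate schemas and keys.

checkColumns <- function(df, cols, what) {
  missingCols <- setdiff(cols, names(df))
  failIf(length(missingCols) > 0,
         sprintf("%s: missing column(s) %s", what,
                 paste(missingCols, collapse = ", ")))
  invisible(df)
}

checkUniqueKey <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  failIf(length(dup) > 0,
         sprintf("%s: duplicate key(s) %s", what,
                 paste(head(dup, 5), collapse = ", ")))
  invisible(x)
}

#' Read a dPCR partition-count table
#'
#' CSV with columns \code{well_id}, \code{sample_id}, \code{positives},
#' \code{valid_partitions}.
#'
#' @param path CSV path.
#' @return data.frame, keyed by \code{well_id}.
#' @export
readDpcrTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  checkColumns(df, c("well_id", "sample_id", "positives",
                     "valid_partitions"), "dPCR table")
  checkUniqueKey(df$well_id, "dPCR table")
  failIf(!isCount(df$positives) || !isCount(df$valid_partitions),
         "dPCR table: counts must be non-negative integers")
  df
}

#' Read / write a sediment-slice table
#'
#' One row per slice: \code{sample_id}, \code{core_id}, \code{site_number},
#' \code{site_type}, \code{depth_top}, \code{depth_bottom},
#' \code{slice_wet_mass}, \code{slice_dry_mass}, plus any measurement
#' columns (e.g. \code{copies_per_g_dry}).
#'
#' @param path CSV path.
#' @return \code{readSliceTable}: data.frame keyed by \code{sample_id}.
#' @export
readSliceTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  checkColumns(df, c("sample_id", "core_id", "site_number", "site_type",
                     "depth_top", "depth_bottom", "slice_wet_mass",
                     "slice_dry_mass"), "slice table")
  checkUniqueKey(df$sample_id, "slice table")
  df$site_number <- as.character(df$site_number)
  df
}

#' @rdname readSliceTable
#' @param slices slice data.frame to write.
#' @export
writeSliceTable <- function(slices, path) {
  write.csv(slices, path, row.names = FALSE)
  invisible(path)
}

#' Read a spiking-experiment dose/response table
#'
#' CSV with columns \code{level_wet_pct}, \code{replicate},
#' \code{copies_per_g_dry} (an optional \code{dry_carbon_pct} column is
#' kept if present).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readSpikingTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  checkColumns(df, c("level_wet_pct", "replicate", "copies_per_g_dry"),
               "spiking table")
  df
}

#' Read a nutrient table
#'
#' CSV keyed by \code{sample_id} with \code{tc_pct} and optionally
#' \code{toc_pct}, \code{tn_pct}.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readNutrientTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  checkColumns(df, c("sample_id", "tc_pct"), "nutrient table")
  checkUniqueKey(df$sample_id, "nutrient table")
  df
}

#' Read / write taxa tables as TSV
#'
#' TSV layout: taxa in rows, samples in columns, first column \code{taxon},
#' last column \code{lineage} (semicolon-separated domain;phylum;class;
#' order;family;genus). Metadata is supplied separately (CSV keyed by
#' \code{sample_id}) and is checked one-to-one against the count columns.
#'
#' @param path TSV path.
#' @param metadata data.frame of sample metadata, or path to its CSV.
#' @return \code{readTaxaTableTsv}: a \linkS4class{TaxaTable}.
#' @export
readTaxaTableTsv <- function(path, metadata) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  checkColumns(df, c("taxon", "lineage"), "taxa TSV")
  checkUniqueKey(df$taxon, "taxa TSV")
  sampleCols <- setdiff(names(df), c("taxon", "lineage"))
  failIf(length(sampleCols) == 0, "taxa TSV: no sample columns")
  m <- as.matrix(df[, sampleCols, drop = FALSE])
  rownames(m) <- df$taxon
  storage.mode(m) <- "integer"
  lin <- strsplit(df$lineage, ";", fixed = TRUE)
  failIf(any(lengths(lin) != length(TAXONOMY_RANKS)),
         "taxa TSV: each lineage needs 6 ranks (domain;...;genus)")
  tax <- as.data.frame(do.call(rbind, lin), stringsAsFactors = FALSE)
  names(tax) <- TAXONOMY_RANKS
  rownames(tax) <- df$taxon
  meta <- alignMetadata(metadata, colnames(m))
  TaxaTable(m, tax, meta)
}

alignMetadata <- function(metadata, sampleIds) {
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- read.csv(metadata, stringsAsFactors = FALSE)
  checkColumns(metadata, "sample_id", "metadata")
  checkUniqueKey(metadata$sample_id, "metadata")
  orphanCounts <- setdiff(sampleIds, metadata$sample_id)
  failIf(length(orphanCounts) > 0,
         paste("metadata missing sample(s):",
               paste(head(orphanCounts, 5), collapse = ", ")))
  metadata[match(sampleIds, metadata$sample_id), , drop = FALSE]
}

lineageString <- function(tax) {
  apply(as.matrix(tax[, TAXONOMY_RANKS, drop = FALSE]), 1, paste,
        collapse = ";")
}

#' @rdname readTaxaTableTsv
#' @param tt a \linkS4class{TaxaTable} to write.
#' @export
writeTaxaTableTsv <- function(tt, path) {
  stopifnot(is(tt, "TaxaTable"))
  df <- data.frame(taxon = rownames(tt), counts(tt),
                   lineage = lineageString(taxonomy(tt)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write taxa tables as BIOM (JSON)
#'
#' BIOM format 1.0 JSON with per-observation taxonomy metadata, via the
#' biomformat package. Sample metadata is supplied separately as for
#' \code{\link{readTaxaTableTsv}}.
#'
#' @param path BIOM (JSON) path.
#' @param metadata sample metadata data.frame or CSV path.
#' @return \code{readTaxaTableBiom}: a \linkS4class{TaxaTable}.
#' @export
readTaxaTableBiom <- function(path, metadata) {
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  storage.mode(m) <- "integer"
  obs <- biomformat::observation_metadata(b)
  if (is.data.frame(obs)) {
    tax <- obs
  } else {
    tax <- as.data.frame(do.call(rbind, obs), stringsAsFactors = FALSE)
  }
  failIf(ncol(tax) < length(TAXONOMY_RANKS),
         "BIOM observation metadata must carry 6 taxonomy ranks")
  tax <- tax[, seq_along(TAXONOMY_RANKS), drop = FALSE]
  names(tax) <- TAXONOMY_RANKS
  rownames(tax) <- rownames(m)
  meta <- alignMetadata(metadata, colnames(m))
  TaxaTable(m, tax, meta)
}

#' @rdname readTaxaTableBiom
#' @param tt a \linkS4class{TaxaTable} to write.
#' @export
writeTaxaTableBiom <- function(tt, path) {
  stopifnot(is(tt, "TaxaTable"))
  tax <- taxonomy(tt)
  b <- biomformat::make_biom(counts(tt), observation_metadata = tax)
  biomformat::write_biom(b, path)
  invisible(path)
}
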