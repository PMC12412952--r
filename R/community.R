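#' Construct a TaxaTable
#'
#' @param counts integer matrix, taxa in rows, samples in columns, with row
#'   and column names.
#' @param taxonomy data.frame of ranked lineages (columns domain, phylum,
#'   class, order, family, genus), one row per taxon.
#' @param metadata data.frame of sample metadata, one row per sample
#'   (typically site_type, site_number, depth, log10_coi, tc_pct, tn_pct).
#' @return A \linkS4class{TaxaTable}.
#' @export
TaxaTable <- function(counts, taxonomy, metadata) {
  failIf(is.null(rownames(counts)) || is.null(colnames(counts)),
         "counts must have taxon rownames and sample colnames")
  failIf(nrow(taxonomy) != nrow(counts),
         "taxonomy must have one row per taxon")
  failIf(nrow(metadata) != ncol(counts),
         "metadata must have one row per sample")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(taxonomy, row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(metadata, row.names = colnames(counts)))
  new("TaxaTable", se)
}

relativeAbundance <- function(tt) {
  m <- counts(tt)
  sweep(m, 2, colSums(m), "/")
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly
#' \code{depth} reads (one fixed draw per seed, no repeated-rarefaction
#' averaging). Samples with fewer reads than \code{depth} are dropped and
#' reported via the \code{"dropped_samples"} attribute and a message.
#'
#' @param tt a \linkS4class{TaxaTable}.
#' @param depth target reads per sample; \code{"min"} uses the smallest
#'   sample total.
#' @param seed integer seed for the subsampling draw.
#' @return A rarefied \linkS4class{TaxaTable}.
#' @export
rarefyTable <- function(tt, depth = "min", seed = 1) {
  stopifnot(is(tt, "TaxaTable"))
  m <- counts(tt)
  totals <- colSums(m)
  if (identical(depth, "min")) depth <- min(totals)
  failIf(depth < 1, "depth must be >= 1")
  keep <- totals >= depth
  dropped <- colnames(m)[!keep]
  if (length(dropped))
    message("rarefyTable: dropping ", length(dropped), " sample(s) below ",
            depth, " reads: ", paste(dropped, collapse = ", "))
  failIf(!any(keep), "no sample reaches the rarefaction depth")
  m <- m[, keep, drop = FALSE]
  set.seed(streamSeed(seed, 6L))
  rar <- vapply(seq_len(ncol(m)), function(j) {
    drawn <- sample(rep.int(seq_len(nrow(m)), m[, j]), depth,
                    replace = FALSE)
    tabulate(drawn, nbins = nrow(m))
  }, integer(nrow(m)))
  dimnames(rar) <- dimnames(m)
  out <- TaxaTable(rar, taxonomy(tt),
                   sampleData(tt)[keep, , drop = FALSE])
  attr(out, "dropped_samples") <- dropped
  out
}

#' Observed richness and Shannon diversity per sample
#'
#' Observed diversity counts taxa with non-zero reads; the Shannon-Wiener
#' index is -sum p_i log(p_i) over the sample's relative abundances, natural
#' log by default (the convention of the common ecology stacks).
#'
#' @param tt a \linkS4class{TaxaTable} (or bare count matrix, taxa x
#'   samples).
#' @param base logarithm base for Shannon (default \code{exp(1)}).
#' @return data.frame: \code{sample_id}, \code{observed}, \code{shannon}.
#' @export
alphaDiversity <- function(tt, base = exp(1)) {
  m <- if (is(tt, "TaxaTable")) counts(tt) else tt
  p <- sweep(m, 2, colSums(m), "/")
  shannon <- apply(p, 2, function(q) {
    q <- q[q > 0]
    -sum(q * log(q, base = base))
  })
  data.frame(sample_id = colnames(m),
             observed = colSums(m > 0),
             shannon = shannon,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate to a taxonomy rank and pool minor taxa
#'
#' Sums counts by the lineage label at \code{rank} (families for 16S,
#' genera for 18S in a typical survey), ranks the aggregated taxa by overall
#' relative abundance, and pools everything beyond the top \code{k} into an
#' "Other" bucket. Taxa without an assignment at the rank are pooled into
#' "Unassigned" before ranking.
#'
#' @param tt a \linkS4class{TaxaTable}.
#' @param rank one of domain, phylum, class, order, family, genus.
#' @param k keep this many top taxa (default 30); \code{Inf} keeps all.
#' @return A \linkS4class{TaxaTable} whose rows are rank-level taxa, with a
#'   degenerate taxonomy (the rank label replicated across ranks at and
#'   below the aggregation level).
#' @export
aggregateTaxa <- function(tt, rank = "family", k = 30) {
  stopifnot(is(tt, "TaxaTable"))
  failIf(!rank %in% TAXONOMY_RANKS,
         paste("rank must be one of:", paste(TAXONOMY_RANKS, collapse = ", ")))
  lab <- as.character(taxonomy(tt)[[rank]])
  lab[is.na(lab) | lab == ""] <- "Unassigned"
  m <- rowsum(counts(tt), group = lab)
  ord <- order(rowSums(m), decreasing = TRUE)
  m <- m[ord, , drop = FALSE]
  if (is.finite(k) && nrow(m) > k) {
    other <- colSums(m[-seq_len(k), , drop = FALSE])
    m <- rbind(m[seq_len(k), , drop = FALSE], Other = other)
  }
  rankIdx <- match(rank, TAXONOMY_RANKS)
  tax <- as.data.frame(matrix(NA_character_, nrow(m), length(TAXONOMY_RANKS),
                              dimnames = list(rownames(m), TAXONOMY_RANKS)),
                       stringsAsFactors = FALSE)
  for (j in rankIdx:length(TAXONOMY_RANKS)) tax[[j]] <- rownames(m)
  TaxaTable(m, tax, sampleData(tt))
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i) over taxa; 0 for identical
#' samples, 1 for samples sharing no taxa.
#'
#' @param tt a \linkS4class{TaxaTable} or a taxa x samples matrix.
#' @return A \code{dist} over samples.
#' @export
brayCurtis <- function(tt) {
  m <- if (is(tt, "TaxaTable")) counts(tt) else tt
  failIf(ncol(m) < 2L, "need at least two samples")
  failIf(any(m < 0), "counts must be non-negative")
  x <- t(m)                                   # samples x taxa
  manhattan <- as.matrix(stats::dist(x, method = "manhattan"))
  tot <- rowSums(x)
  denom <- outer(tot, tot, "+")
  d <- manhattan / denom
  d[denom == 0] <- 0
  stats::as.dist(d)
}

## Gower-centered inner-product matrix of a distance matrix:
## G = -(1/2) C D^2 C with C the centering matrix. tr(G) is the total sum
## of squares of the configuration.
gowerCenter <- function(d) {
  a <- -0.5 * as.matrix(d)^2
  n <- nrow(a)
  rm <- rowMeans(a); gm <- mean(a)
  a - outer(rm, rm, "+") + gm
}

#' Principal coordinates analysis
#'
#' Classical metric ordination: Gower double-centering of the squared
#' distances followed by eigendecomposition. Axes are ordered by eigenvalue;
#' coordinates are returned for axes with positive eigenvalues, and the
#' proportion of variance explained uses the positive eigenvalues as the
#' denominator (negative eigenvalues, which arise for semi-metric
#' dissimilarities such as Bray-Curtis, are reported but excluded).
#'
#' @param d a \code{dist} or square symmetric distance matrix.
#' @param k number of axes to return (default all positive axes).
#' @return list with \code{points} (samples x axes), \code{eig} (all
#'   eigenvalues), \code{prop_explained} and \code{negative_eig}.
#' @export
pcoaOrdination <- function(d, k = NULL) {
  dm <- as.matrix(d)
  failIf(nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-8),
         "distance matrix must be square and symmetric")
  g <- gowerCenter(dm)
  e <- eigen(g, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  if (is.null(k)) k <- sum(pos) else k <- min(k, sum(pos))
  pts <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
  rownames(pts) <- rownames(dm)
  colnames(pts) <- paste0("PCo", seq_len(k))
  list(points = pts,
       eig = e$values,
       prop_explained = e$values[seq_len(k)] / sum(e$values[pos]),
       negative_eig = e$values[e$values < 0])
}

#' PERMANOVA with partial omega-squared effect sizes
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' (McArdle-Anderson): the Gower-centered inner-product matrix is
#' partitioned over the model terms with sequential (type-I) sums of squares
#' in the order given, pseudo-F per term, and p-values from free permutation
#' of sample rows. Effect sizes are partial omega-squared,
#' (SS_t - df_t MS_res) / (SS_total + MS_res), stored untruncated and
#' truncated at zero in summaries.
#'
#' @param d a \code{dist} or square symmetric distance matrix over samples.
#' @param metadata data.frame of sample covariates, rows aligned with
#'   \code{d}.
#' @param terms character vector of metadata columns, fitted sequentially in
#'   this order.
#' @param permutations number of permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @return A \linkS4class{PermanovaTable}.
#' @export
permanova <- function(d, metadata, terms, permutations = 999, seed = 1) {
  failIf(permutations < 99, "need at least 99 permutations")
  missingTerms <- setdiff(terms, names(metadata))
  failIf(length(missingTerms) > 0,
         paste("terms absent from metadata:",
               paste(missingTerms, collapse = ", ")))
  g <- gowerCenter(as.matrix(d))
  n <- nrow(g)
  failIf(nrow(metadata) != n, "metadata rows must match the distance matrix")
  for (tm in terms)
    failIf(length(unique(metadata[[tm]])) < 2L,
           paste("term has no variation:", tm))

  ## Sequential projection (hat) matrices, intercept first.
  hats <- vector("list", length(terms) + 1L)
  ranks <- integer(length(terms) + 1L)
  makeHat <- function(fml) {
    X <- model.matrix(fml, data = metadata)
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    list(H = tcrossprod(Q), rank = q$rank)
  }
  h0 <- makeHat(~1)
  hats[[1L]] <- h0$H; ranks[1L] <- h0$rank
  for (k in seq_along(terms)) {
    hk <- makeHat(reformulate(terms[seq_len(k)]))
    hats[[k + 1L]] <- hk$H; ranks[k + 1L] <- hk$rank
  }
  dfTerms <- diff(ranks)
  failIf(any(dfTerms == 0L),
         "aliased term contributes no degrees of freedom")
  dfRes <- n - ranks[length(ranks)]
  failIf(dfRes < 1L, "no residual degrees of freedom")

  ## Projector differences per term, and the residual projector.
  deltas <- lapply(seq_along(terms), function(k)
    hats[[k + 1L]] - hats[[k]])
  resProj <- diag(n) - hats[[length(hats)]]

  ssFor <- function(gmat) {
    ssT <- vapply(deltas, function(dl) sum(dl * gmat), numeric(1))
    c(ssT, sum(resProj * gmat))
  }
  ssObs <- ssFor(g)
  ssTerms <- ssObs[seq_along(terms)]
  ssRes <- ssObs[length(ssObs)]
  ssTotal <- sum(diag(g))
  msRes <- ssRes / dfRes
  fObs <- (ssTerms / dfTerms) / msRes

  set.seed(streamSeed(seed, 7L))
  exceed <- numeric(length(terms))
  for (i in seq_len(permutations)) {
    p <- sample.int(n)
    ssP <- ssFor(g[p, p])
    fP <- (ssP[seq_along(terms)] / dfTerms) / (ssP[length(ssP)] / dfRes)
    exceed <- exceed + (fP >= fObs - 1e-12)
  }
  pPerm <- (exceed + 1) / (permutations + 1)
  omega2 <- (ssTerms - dfTerms * msRes) / (ssTotal + msRes)

  res <- data.frame(
    term = c(terms, "Residual", "Total"),
    Df = c(dfTerms, dfRes, n - 1L),
    SumOfSqs = c(ssTerms, ssRes, ssTotal),
    R2 = c(ssTerms, ssRes, ssTotal) / ssTotal,
    pseudoF = c(fObs, NA, NA),
    pPerm = c(pPerm, NA, NA),
    partialOmega2 = c(omega2, NA, NA),
    stringsAsFactors = FALSE)
  new("PermanovaTable", results = res,
      permutations = as.integer(permutations),
      seed = as.integer(seed))
}

#' Volcano screen for indicator taxa between two groups
#'
#' Per-taxon differential relative abundance between two sample groups. The
#' coefficient is log2 of (mean relative abundance in the second group +
#' eps) over (mean in the first group + eps), with groups ordered so that a
#' negative coefficient means enrichment in the first (reference) group --
#' for an inside/outside farm contrast with reference "inside", negative =
#' enriched inside. p-values come from Welch's unequal-variance t test on
#' log(relative abundance + eps); eps is half the smallest non-zero relative
#' abundance in the table. BH-adjusted p-values, mean abundance across
#' samples where the taxon occurs, and prevalence are reported alongside.
#'
#' @param tt a \linkS4class{TaxaTable}.
#' @param group metadata column with exactly two levels.
#' @param reference level whose enrichment maps to negative coefficients;
#'   defaults to the first factor level.
#' @return data.frame, one row per taxon: \code{taxon}, \code{coefficient},
#'   \code{p_raw}, \code{p_adjusted}, \code{mean_abundance},
#'   \code{prevalence}.
#' @export
volcanoScreen <- function(tt, group = "site_type", reference = NULL) {
  stopifnot(is(tt, "TaxaTable"))
  meta <- sampleData(tt)
  failIf(!group %in% names(meta), paste("no metadata column", group))
  gf <- factor(meta[[group]])
  failIf(nlevels(gf) != 2L, "group must have exactly two levels")
  if (is.null(reference)) reference <- levels(gf)[1L]
  gf <- stats::relevel(gf, ref = reference)
  failIf(any(table(gf) < 2L), "each group needs at least 2 samples")
  rel <- relativeAbundance(tt)
  eps <- min(rel[rel > 0]) / 2
  inRef <- gf == levels(gf)[1L]
  coefs <- log2((rowMeans(rel[, !inRef, drop = FALSE]) + eps) /
                (rowMeans(rel[, inRef, drop = FALSE]) + eps))
  lrel <- log(rel + eps)
  pRaw <- apply(lrel, 1, function(v) {
    tryCatch(t.test(v[!inRef], v[inRef])$p.value,
             error = function(e) 1)  # constant taxon: no evidence
  })
  present <- rel > 0
  meanAb <- vapply(seq_len(nrow(rel)), function(i) {
    pi <- present[i, ]
    if (any(pi)) mean(rel[i, pi]) else 0
  }, numeric(1))
  data.frame(taxon = rownames(rel),
             coefficient = unname(coefs),
             p_raw = unname(pRaw),
             p_adjusted = bhAdjust(unname(pRaw)),
             mean_abundance = meanAb,
             prevalence = rowMeans(present),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman correlation screen against a continuous covariate
#'
#' Per-taxon rank correlation (midrank ties) between relative abundance and
#' a sample covariate such as log10 gene copies, with BH adjustment across
#' taxa. Optionally restricted to a subset of samples (e.g. one site type).
#'
#' @param tt a \linkS4class{TaxaTable}.
#' @param covariate metadata column name (finite for all retained samples).
#' @param subset optional logical vector over samples, or a site-type label
#'   to keep.
#' @return data.frame sorted by p: \code{taxon}, \code{rho}, \code{p_raw},
#'   \code{p_adjusted}, \code{prevalence}.
#' @export
spearmanScreen <- function(tt, covariate = "log10_coi", subset = NULL) {
  stopifnot(is(tt, "TaxaTable"))
  meta <- sampleData(tt)
  failIf(!covariate %in% names(meta), paste("no metadata column", covariate))
  keep <- rep(TRUE, ncol(tt))
  if (!is.null(subset)) {
    keep <- if (is.logical(subset)) subset
            else meta$site_type %in% subset
  }
  x <- meta[[covariate]][keep]
  failIf(any(!is.finite(x)), "covariate must be finite for all samples")
  failIf(sum(keep) < 4L, "need at least 4 samples")
  rel <- relativeAbundance(tt)[, keep, drop = FALSE]
  stats <- t(apply(rel, 1, function(v) {
    if (length(unique(v)) < 2L) return(c(NA_real_, 1))
    ct <- suppressWarnings(cor.test(v, x, method = "spearman",
                                    exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  }))
  out <- data.frame(taxon = rownames(rel),
                    rho = stats[, 1],
                    p_raw = stats[, 2],
                    p_adjusted = bhAdjust(stats[, 2]),
                    prevalence = rowMeans(rel > 0),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_raw), ]
}
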