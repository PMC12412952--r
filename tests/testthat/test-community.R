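test_that("rarefaction keeps identity, drops shallow samples, conserves depth", {
  m <- matrix(c(30, 20, 0,
                60, 30, 10,
                100, 60, 40), nrow = 3,
              dimnames = list(paste0("t", 1:3), paste0("s", 1:3)))
  tt <- toyTaxaTable(m)
  expect_message(rar <- rarefyTable(tt, depth = 100, seed = 1), "dropping")
  expect_equal(attr(rar, "dropped_samples"), "s1")
  expect_equal(ncol(rar), 2L)
  # a sample whose total equals the depth is returned unchanged
  expect_equal(counts(rar)[, "s2"], m[, "s2"])
  expect_true(all(colSums(counts(rar)) == 100))
  # subsampling never inflates a count
  expect_true(all(counts(rar) <= counts(tt)[, colnames(rar)]))
  # determinism under a fixed seed
  rar2 <- suppressMessages(rarefyTable(tt, depth = 100, seed = 1))
  expect_identical(counts(rar), counts(rar2))
})

test_that("alpha diversity matches closed forms and vegan", {
  m <- cbind(s1 = c(5, 0, 0), s2 = c(2, 2, 2), s3 = c(1, 1, 2))
  rownames(m) <- paste0("t", 1:3)
  a <- alphaDiversity(toyTaxaTable(m))
  expect_equal(a$observed, c(1L, 3L, 3L), ignore_attr = TRUE)
  expect_equal(a$shannon[1], 0)
  expect_equal(a$shannon[2], log(3), tolerance = 1e-12)
  expect_equal(a$shannon[3], 1.039721, tolerance = 1e-6)
  expect_equal(a$shannon,
               unname(vegan::diversity(t(m), index = "shannon")),
               tolerance = 1e-12)
  u <- alphaDiversity(toyTaxaTable(cbind(s1 = rep(3, 4))))
  expect_equal(u$shannon, log(4), tolerance = 1e-12)
})

test_that("rank aggregation merges lineages and pools minor taxa", {
  m <- matrix(1:8, nrow = 4,
              dimnames = list(paste0("t", 1:4), c("s1", "s2")))
  tt <- toyTaxaTable(m)   # families F1 (t1, t2) and F2 (t3, t4)
  agg <- aggregateTaxa(tt, "family", k = Inf)
  expect_equal(nrow(agg), 2L)
  expect_equal(counts(agg)["F1", ], m[1, ] + m[2, ])
  expect_equal(sum(counts(agg)), sum(m))        # reads conserved
  top1 <- aggregateTaxa(tt, "family", k = 1)
  expect_equal(rownames(top1), c("F2", "Other"))  # F2 has more reads
  expect_equal(sum(counts(top1)), sum(m))
  # unassigned lineages are pooled into a labelled bucket
  tax <- taxonomy(tt); tax$family[1] <- NA
  tt2 <- TaxaTable(counts(tt), tax, sampleData(tt))
  expect_true("Unassigned" %in% rownames(aggregateTaxa(tt2, "family",
                                                       k = Inf)))
  expect_error(aggregateTaxa(tt, "kingdom"), "rank")
})

test_that("Bray-Curtis matches hand values, bounds and vegan", {
  m <- cbind(a = c(2, 2), b = c(0, 4), c = c(2, 2))
  rownames(m) <- c("t1", "t2")
  d <- as.matrix(brayCurtis(m))
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 0)
  disjoint <- cbind(a = c(5, 0), b = c(0, 7))
  expect_equal(as.numeric(brayCurtis(disjoint)), 1)
  set.seed(14)
  big <- matrix(rpois(200, 5), nrow = 20)
  colnames(big) <- paste0("s", 1:10); rownames(big) <- paste0("t", 1:20)
  dbc <- brayCurtis(big)
  expect_true(all(dbc >= 0 & dbc <= 1))
  expect_equal(as.matrix(dbc),
               as.matrix(vegan::vegdist(t(big), method = "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
  # invariance to sample order
  perm <- sample(10)
  expect_equal(as.matrix(brayCurtis(big[, perm]))[colnames(big),
                                                  colnames(big)],
               as.matrix(dbc), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCoA embeds Euclidean configurations exactly", {
  two <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"),
                                                  c("a", "b")))
  ord <- pcoaOrdination(two)
  expect_equal(sort(ord$points[, 1]), c(-1.5, 1.5), ignore_attr = TRUE)
  set.seed(4)
  config <- matrix(rnorm(24), ncol = 2)
  d <- dist(config)
  rec <- pcoaOrdination(d)
  expect_equal(as.matrix(dist(rec$points)), as.matrix(d),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(rec$prop_explained) <= 1e-12))
  expect_lte(sum(rec$prop_explained), 1 + 1e-12)
})

test_that("PERMANOVA pseudo-F equals classical ANOVA F in 1D", {
  set.seed(31)
  x <- c(rnorm(8, 0), rnorm(8, 1.5))
  g <- rep(c("a", "b"), each = 8)
  meta <- data.frame(grp = g)
  pt <- permanova(dist(x), meta, terms = "grp", permutations = 99,
                  seed = 1)
  res <- pt@results
  classical <- anova(lm(x ~ g))
  expect_equal(res$pseudoF[1], classical$`F value`[1], tolerance = 1e-10)
  expect_equal(res$SumOfSqs[1], classical$`Sum Sq`[1], tolerance = 1e-10)
  # exact sum-of-squares conservation
  expect_equal(sum(res$SumOfSqs[1:2]), res$SumOfSqs[3], tolerance = 1e-10)
})

test_that("PERMANOVA matches vegan::adonis2 sequential partitioning", {
  set.seed(32)
  m <- matrix(rpois(300, 8), nrow = 15)
  colnames(m) <- paste0("s", 1:20); rownames(m) <- paste0("t", 1:15)
  meta <- data.frame(grp = rep(c("a", "b"), 10), cov = rnorm(20))
  d <- brayCurtis(m)
  mine <- permanova(d, meta, terms = c("grp", "cov"),
                    permutations = 99, seed = 2)@results
  ref <- vegan::adonis2(d ~ grp + cov, data = meta, permutations = 99,
                        by = "terms")
  expect_equal(mine$SumOfSqs[1:2], ref$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(mine$pseudoF[1:2], ref$F[1:2], tolerance = 1e-8)
  expect_equal(mine$Df[1:2], ref$Df[1:2])
})

test_that("PERMANOVA p-values reach the permutation floor and are reproducible", {
  x <- c(rnorm(10, 0, 0.01), rnorm(10, 100, 0.01))
  meta <- data.frame(grp = rep(c("a", "b"), each = 10))
  pt <- permanova(dist(x), meta, terms = "grp", permutations = 999,
                  seed = 5)
  expect_equal(pt@results$pPerm[1], 1 / 1000)
  pt2 <- permanova(dist(x), meta, terms = "grp", permutations = 999,
                   seed = 5)
  expect_identical(pt@results, pt2@results)
  expect_error(permanova(dist(x), data.frame(grp = rep("a", 20)),
                         terms = "grp", permutations = 99), "no variation")
  expect_error(permanova(dist(x), meta, terms = "grp", permutations = 10),
               "99")
})

test_that("volcano coefficients follow the inside-negative convention", {
  # 2 inside then 2 outside samples; taxon t1 is twice as abundant outside
  m <- cbind(s1 = c(1000, 1, 8999), s2 = c(1000, 0, 9000),
             s3 = c(2000, 0, 8000), s4 = c(2000, 1, 7999))
  rownames(m) <- c("t1", "t2", "t3")
  tt <- toyTaxaTable(m, siteType = c("inside", "inside", "outside",
                                     "outside"))
  v <- volcanoScreen(tt, reference = "inside")
  expect_equal(v$coefficient[v$taxon == "t1"], 1, tolerance = 1e-3)
  expect_true(all(v$prevalence >= 0 & v$prevalence <= 1))
  expect_true(all(v$p_adjusted >= v$p_raw - 1e-12))
  # identical groups give a zero coefficient
  mEq <- cbind(s1 = c(10, 90), s2 = c(20, 80), s3 = c(10, 90),
               s4 = c(20, 80))
  rownames(mEq) <- c("t1", "t2")
  vEq <- volcanoScreen(toyTaxaTable(mEq, siteType = c("inside", "inside",
                                                      "outside",
                                                      "outside")),
                       reference = "inside")
  expect_equal(vEq$coefficient, c(0, 0))
})

test_that("planted inside-enrichment yields negative volcano coefficients", {
  hits <- 0L; nSim <- 30L
  for (s in seq_len(nSim)) {
    meta <- data.frame(sample_id = sprintf("s%02d", 1:30),
                       site_type = rep(c("inside", "outside"), each = 15),
                       mid_depth = rep(1:5, 6),
                       log10_coi = rnorm(30, 4.6, 0.2))
    model <- communityModel(nTaxa = 60,
                            baselineLog = seq(2, -2, length.out = 60),
                            siteEffects = c("5" = 1),
                            depthEffects = numeric(),
                            coiEffects = numeric())
    tt <- simulateTaxaTable(model, meta, seed = 100 + s)
    v <- volcanoScreen(tt, reference = "inside")
    if (v$coefficient[v$taxon == "ASV_005"] < 0) hits <- hits + 1L
  }
  expect_gte(hits / nSim, 0.9)
})

test_that("Spearman screen matches rank-correlation hand values", {
  m <- cbind(s1 = c(10, 1, 89), s2 = c(20, 3, 77), s3 = c(30, 2, 68),
             s4 = c(40, 4, 56))
  rownames(m) <- c("up", "toy", "down")
  tt <- toyTaxaTable(m, log10Coi = 1:4)
  sc <- spearmanScreen(tt, covariate = "log10_coi")
  expect_equal(sc$rho[sc$taxon == "up"], 1)
  expect_equal(sc$rho[sc$taxon == "down"], -1)
  expect_equal(sc$rho[sc$taxon == "toy"], 0.8, tolerance = 1e-12)
  expect_true(all(sc$p_adjusted >= sc$p_raw - 1e-12))
})

test_that("a planted copy-number-correlated taxon is detected with power", {
  hits <- 0L; nSim <- 25L
  for (s in seq_len(nSim)) {
    meta <- data.frame(sample_id = sprintf("s%02d", 1:40),
                       site_type = rep(c("inside", "outside"), each = 20),
                       mid_depth = rep(1:5, 8),
                       log10_coi = rnorm(40, 4.6, 0.5))
    model <- communityModel(nTaxa = 60,
                            baselineLog = seq(2, -2, length.out = 60),
                            siteEffects = numeric(),
                            depthEffects = numeric(),
                            coiEffects = c("5" = 1.2))
    tt <- simulateTaxaTable(model, meta, seed = 500 + s)
    sc <- spearmanScreen(tt, covariate = "log10_coi")
    row <- sc[sc$taxon == "ASV_005", ]
    if (row$rho > 0 && row$p_adjusted < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / nSim, 0.8)
})
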