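test_that("survey designs validate their horizon geometry", {
  expect_error(surveyDesign(horizons = cbind(c(0, 0.5), c(1, 1.5))),
               "overlap")
  expect_error(surveyDesign(horizons = cbind(1, 0.5)), "top")
  expect_error(surveyDesign(horizons = cbind(-1, 1)), ">= 0")
  expect_error(surveyDesign(sitesPerType = c(inside = 0L, outside = 1L)),
               "at least one site")
  d <- surveyDesign()
  expect_equal(nrow(d$horizons), 5L)
})

test_that("noise-free surveys hit the generating means exactly", {
  model <- coiFieldModel(residualSd = 0, hotspotSiteOffset = 0,
                         depthSlope = 0)
  sv <- simulateCoreSurvey(surveyDesign(), model, seed = 1)
  inside <- sv$true_copies_per_g_dry[sv$site_type == "inside"]
  outside <- sv$true_copies_per_g_dry[sv$site_type == "outside"]
  expect_equal(inside, rep(10^4.816, length(inside)))
  expect_equal(outside, rep(10^4.506, length(outside)))
})

test_that("group means track the analytic generating means", {
  sv <- simulateCoreSurvey(surveyDesign(), coiFieldModel(), seed = 202)
  mids <- (sv$depth_top + sv$depth_bottom) / 2
  meanMid <- mean(unique(mids))
  m <- coiFieldModel()
  # inside: 3 sites, one carrying the hotspot offset
  muIn <- m$meanLog10Inside + m$hotspotSiteOffset / 3 +
    m$depthSlope * meanMid
  muOut <- m$meanLog10Outside + m$depthSlope * meanMid
  lg <- sv$true_log10_copies
  nIn <- sum(sv$site_type == "inside"); nOut <- sum(sv$site_type == "outside")
  expect_equal(nIn, 45L); expect_equal(nOut, 30L)
  semIn <- m$residualSd / sqrt(nIn); semOut <- m$residualSd / sqrt(nOut)
  expect_lt(abs(mean(lg[sv$site_type == "inside"]) - muIn), 3 * semIn)
  expect_lt(abs(mean(lg[sv$site_type == "outside"]) - muOut), 3 * semOut)
})

test_that("the planted depth slope is recovered within its 95% CI", {
  model <- coiFieldModel(hotspotSiteOffset = 0, meanLog10Outside = 4.816)
  sv <- simulateCoreSurvey(surveyDesign(), model, seed = 7)
  fit <- lm(true_log10_copies ~ mid_depth, data = sv)
  ci <- confint(fit)["mid_depth", ]
  expect_gt(-0.06, ci[1]); expect_lt(-0.06, ci[2])
})

test_that("survey masses respect the configured ranges and reproduce", {
  sv <- simulateCoreSurvey(surveyDesign(), coiFieldModel(), seed = 3)
  ratio <- sv$slice_dry_mass / sv$slice_wet_mass
  expect_true(all(ratio >= 0.3 & ratio <= 0.5))
  sv2 <- simulateCoreSurvey(surveyDesign(), coiFieldModel(), seed = 3)
  expect_identical(sv, sv2)
})

test_that("simulated dPCR wells follow the partition binomial model", {
  rxn0 <- simulateDpcrWell(rep(0, 20), seed = 1)
  expect_true(all(rxn0@positives == 0L))
  # lambda = ln 2 per partition: positive fraction 0.5 on average
  conc <- log(2) / 4e-4
  rxn <- simulateDpcrWell(rep(conc, 1000), seed = 2)
  frac <- mean(rxn@positives / rxn@validPartitions)
  se <- sqrt(0.25 / (1000 * 8500))
  expect_lt(abs(frac - 0.5), 4 * se)
  expect_error(simulateDpcrWell(-1), ">= 0")
})

test_that("noise-free spiking responses sit exactly on the line", {
  des <- spikingDesign(noiseCv = 0)
  sim <- simulateSpikingExperiment(des, seed = 1)
  lin <- sim$dry_carbon_pct <= des$plateauAbovePct
  expect_equal(sim$copies_per_g_dry[lin],
               des$trueSlope * sim$dry_carbon_pct[lin])
  # above the plateau the mean response stays at the plateau level
  expect_equal(unique(sim$copies_per_g_dry[!lin]),
               des$trueSlope * des$plateauAbovePct)
  expect_error(spikingDesign(trueSlope = -1), "> 0")
  expect_error(spikingDesign(noiseCv = -0.1), ">= 0")
})

test_that("taxa tables approach softmax weights at large library sizes", {
  base <- seq(2, -2, length.out = 30)
  model <- communityModel(nTaxa = 30, baselineLog = base,
                          siteEffects = numeric(),
                          depthEffects = numeric(),
                          coiEffects = numeric(),
                          dispersion = 1e6,
                          librarySizeRange = c(200000L, 200000L))
  meta <- data.frame(sample_id = paste0("s", 1:5),
                     site_type = "inside", mid_depth = 1,
                     log10_coi = 4.5)
  tt <- simulateTaxaTable(model, meta, seed = 5)
  rel <- rowMeans(sweep(counts(tt), 2, colSums(counts(tt)), "/"))
  expect_lt(max(abs(rel - exp(base) / sum(exp(base)))), 0.01)
})

test_that("taxa simulation validates metadata and reproduces under a seed", {
  model <- communityModel(nTaxa = 12, baselineLog = rep(0, 12),
                          siteEffects = c("3" = 1),
                          depthEffects = numeric(),
                          coiEffects = numeric())
  expect_error(simulateTaxaTable(model, data.frame(sample_id = "a")),
               "missing columns")
  expect_error(communityModel(nTaxa = 10, baselineLog = rep(0, 10),
                              siteEffects = c("40" = 1)),
               "taxon indices")
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     site_type = rep(c("inside", "outside"), 3),
                     mid_depth = 1:6, log10_coi = rnorm(6, 4.5))
  t1 <- simulateTaxaTable(model, meta, seed = 9)
  t2 <- simulateTaxaTable(model, meta, seed = 9)
  expect_identical(counts(t1), counts(t2))
  expect_equal(dim(t1), c(12L, 6L))
  # fabricated taxonomy supports family aggregation
  expect_lt(nrow(aggregateTaxa(t1, "family", k = Inf)), nrow(t1))
})

test_that("nutrient tables follow the TOC:TC ratio and TC range", {
  meta <- data.frame(sample_id = paste0("s", 1:50),
                     site_type = rep(c("inside", "outside"), 25))
  nut <- simulateNutrients(meta, seed = 4)
  expect_true(all(nut$tc_pct >= 3.25 & nut$tc_pct <= 3.6))
  expect_equal(nut$toc_pct / nut$tc_pct, rep(0.939, 50))
  one <- simulateNutrients(meta, tocTcRatio = 1, seed = 4)
  expect_equal(one$toc_pct, one$tc_pct)
  expect_error(simulateNutrients(meta, tocTcRatio = 1.5), "0, 1")
  expect_identical(simulateNutrients(meta, seed = 4), nut)
})
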