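test_that("log transform applies the half-minimum pseudo-count rule", {
  expect_equal(as.numeric(logTransform(10^4.816)), 4.816)
  clean <- logTransform(c(1, 10, 100))
  expect_equal(attr(clean, "pseudo_count"), 0)
  withZero <- logTransform(c(0, 10, 100))
  expect_equal(attr(withZero, "pseudo_count"), 5)
  expect_equal(as.numeric(withZero), log10(c(5, 15, 105)))
  expect_error(logTransform(c(-1, 2)), ">= 0")
  expect_error(logTransform(c(0, 0)), "undefined")
})

test_that("nested OLS recovers noiseless coefficients exactly", {
  d <- noiselessSurveyFrame()
  fit <- suppressWarnings(
    fitNestedOls(d, response = "log10_coi", depth = "depth"))
  expect_equal(fit$df, c(5L, 69L))
  cf <- fit$coefficients
  expect_equal(unname(cf["(Intercept)"]), 4.816, tolerance = 1e-10)
  expect_equal(unname(cf["typeoutside"]), -0.31, tolerance = 1e-10)
  expect_equal(unname(cf["depth"]), -0.06, tolerance = 1e-10)
  expect_equal(unname(cf["typeinside:site2"]), 0.43, tolerance = 1e-10)
  expect_equal(unname(cf["typeinside:site3"]), 0, tolerance = 1e-10)
})

test_that("one site per type drops the aliased nested term", {
  # two sites total: nesting is aliased with type, leaving type + depth
  d <- expand.grid(depth = c(0.25, 0.75, 1.25, 2.25, 3.25, 4.25, 4.75, 6.25),
                   core = 1:3, site = 1:2, KEEP.OUT.ATTRS = FALSE)
  d$site_type <- ifelse(d$site == 1, "inside", "outside")
  d$site_number <- as.character(d$site)
  set.seed(5)
  d$log10_coi <- 4.6 - 0.1 * (d$site_type == "outside") -
    0.05 * d$depth + rnorm(nrow(d), 0, 0.2)
  fit <- fitNestedOls(d, depth = "depth")
  expect_equal(fit$df, c(2L, 45L))
  expect_setequal(names(fit$coefficients),
                  c("(Intercept)", "typeoutside", "depth"))
})

test_that("standardised betas follow beta * sd(x) / sd(y)", {
  d <- noiselessSurveyFrame()
  set.seed(9)
  d$log10_coi <- d$log10_coi + rnorm(nrow(d), 0, 0.15)
  fit <- fitNestedOls(d, depth = "depth")
  x <- as.numeric(d$site_type == "outside")
  manual <- unname(fit$coefficients["typeoutside"]) * sd(x) / sd(d$log10_coi)
  expect_equal(unname(fit$std_beta["typeoutside"]), manual,
               tolerance = 1e-12)
  expect_true(is.na(fit$std_beta["(Intercept)"]))
})

test_that("nested OLS validates its inputs", {
  d <- noiselessSurveyFrame()
  expect_error(fitNestedOls(d[, -1], depth = "depth"), "missing columns")
  one <- d[d$site_type == "inside", ]
  expect_error(fitNestedOls(one, depth = "depth"), "two site types")
})

test_that("Kruskal-Wallis matches hand and enumeration oracles", {
  same <- kruskalWallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  hand <- kruskalWallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(hand$chi2, 2.4, tolerance = 1e-12)
  # enumeration oracle: all 3+3 splits of six distinct values
  vals <- c(1.2, 2.7, 3.1, 4.9, 5.5, 6.8)
  r <- rank(vals); n <- 6
  for (idx in utils::combn(6, 3, simplify = FALSE)) {
    g <- ifelse(seq_len(6) %in% idx, "a", "b")
    hDirect <- 12 / (n * (n + 1)) *
      sum(tapply(r, g, function(z) length(z) * (mean(z) - (n + 1) / 2)^2))
    expect_equal(kruskalWallis(vals, g)$chi2, hDirect, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  set.seed(21)
  v <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
  expect_equal(kruskalWallis(exp(v), g)$chi2, kruskalWallis(v, g)$chi2)
  expect_error(kruskalWallis(v, rep("a", 30)), "two groups")
})

test_that("Dunn post-hoc matches the mean-rank hand computation", {
  ident <- dunnPosthoc(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(abs(ident$z), 0)
  expect_equal(ident$p_raw, 1)
  sep <- dunnPosthoc(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(abs(sep$z), 1.963961, tolerance = 1e-6)
  set.seed(3)
  three <- dunnPosthoc(rnorm(18), rep(c("a", "b", "c"), each = 6))
  expect_equal(nrow(three), 3L)
  expect_true(all(three$p_adjusted >= three$p_raw - 1e-12))
  expect_equal(order(three$p_adjusted), order(three$p_raw))
})

test_that("BH adjustment matches its closed-form definition", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.005, 0.05, 0.5)), c(0.015, 0.075, 0.5))
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(8)
  p <- runif(25)
  o <- order(p); m <- length(p)
  stepUp <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  expect_equal(bhAdjust(p)[o], stepUp)
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("chi-square upper tail behaves at the boundaries", {
  expect_equal(chisqUpperTail(0, 1), 1)
  expect_error(chisqUpperTail(-1, 1), ">= 0")
  expect_error(chisqUpperTail(1, 0), ">= 1")
})

test_that("power analysis: Fisher-z sample sizes and monotonicity", {
  expect_equal(powerSampleSize(0.56)$n, 23L)
  expect_equal(powerSampleSize(0.999)$n, 4L)  # near-unit effect floor
  n80 <- powerSampleSize(0.4, power = 0.8)$n
  n90 <- powerSampleSize(0.4, power = 0.9)$n
  expect_gte(n90, n80)
  ftest <- powerSampleSize(0.56, method = "f-test")
  expect_equal(ftest$method, "f-test")
  expect_gte(ftest$n, 4L)
  expect_error(powerSampleSize(1.2), "0, 1")
})
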