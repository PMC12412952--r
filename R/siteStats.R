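#' Log10 transform with an automatic pseudo-count
#'
#' Gene-copy and nutrient data are analysed on the log10 scale. Zeros (e.g.
#' wells below the detection limit) would map to -Inf, so when any zero is
#' present a pseudo-count of half the smallest positive value is added to
#' every observation before transforming; with strictly positive data no
#' pseudo-count is applied.
#'
#' @param values non-negative numeric vector.
#' @param pseudoCount override the automatic rule; 0 forces no pseudo-count.
#' @return log10-transformed values, with the applied pseudo-count attached
#'   as attribute \code{"pseudo_count"}.
#' @examples
#' logTransform(c(0, 10, 100))  # log10 of 5, 15, 105
#' @export
logTransform <- function(values, pseudoCount = NULL) {
  failIf(any(values < 0), "values must be >= 0")
  if (is.null(pseudoCount)) {
    pseudoCount <- if (any(values == 0)) {
      failIf(all(values == 0), "all values zero: pseudo-count undefined")
      min(values[values > 0]) / 2
    } else 0
  }
  out <- log10(values + pseudoCount)
  attr(out, "pseudo_count") <- pseudoCount
  out
}

#' Nested ordinary least squares for a coring survey
#'
#' Fits log10 gene copies (or a nutrient) against site type, site number
#' nested within site type, and depth as a continuous covariate in cm:
#' \code{y ~ site_type + site_type:site_number + depth}, with "inside" as
#' the baseline type and depth 0 as the depth baseline. When a type has a
#' single site the nested dummies are aliased with the type effect and are
#' dropped automatically (a two-site survey then reduces to type + depth).
#' Standardised betas are beta * sd(x) / sd(y) computed on the model-matrix
#' columns, including dummies.
#'
#' @param data data.frame with the response and design columns.
#' @param response name of the response column (already log-transformed).
#' @param siteType,siteNumber,depth names of the design columns.
#' @param baselineType reference level for site type.
#' @return An object of class \code{"olsNestedFit"}: a list with
#'   \code{coefficients}, \code{std_beta}, \code{se}, \code{p_coef},
#'   \code{F}, \code{df}, \code{p}, \code{adj_r2}, \code{baselines} and the
#'   underlying \code{lm} fit.
#' @export
fitNestedOls <- function(data, response = "log10_coi",
                         siteType = "site_type", siteNumber = "site_number",
                         depth = "depth", baselineType = "inside") {
  req <- c(response, siteType, siteNumber, depth)
  missingCols <- setdiff(req, names(data))
  failIf(length(missingCols) > 0,
         paste("missing columns:", paste(missingCols, collapse = ", ")))
  d <- data.frame(y = data[[response]],
                  type = factor(data[[siteType]]),
                  site = factor(data[[siteNumber]]),
                  depth = as.numeric(data[[depth]]))
  failIf(nlevels(d$type) < 2L, "need at least two site types")
  failIf(any(!complete.cases(d)), "missing values in model columns")
  d$type <- stats::relevel(d$type, ref = baselineType)
  fit <- lm(y ~ type + type:site + depth, data = d)
  cf <- coef(fit)
  aliased <- is.na(cf)
  failIf(sum(!aliased) >= nrow(d),
         "singular design: more coefficients than observations")
  cf <- cf[!aliased]
  sm <- summary(fit)
  X <- model.matrix(fit)[, names(cf), drop = FALSE]
  sdY <- sd(d$y)
  stdBeta <- vapply(names(cf), function(nm)
    if (nm == "(Intercept)") NA_real_ else cf[[nm]] * sd(X[, nm]) / sdY,
    numeric(1))
  structure(list(
    coefficients = cf,
    std_beta = stdBeta,
    se = sm$coefficients[, 2],
    p_coef = sm$coefficients[, 4],
    F = unname(sm$fstatistic[1]),
    df = as.integer(unname(sm$fstatistic[2:3])),
    p = unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                  lower.tail = FALSE)),
    adj_r2 = sm$adj.r.squared,
    baselines = c(site_type = baselineType, depth = "0 cm"),
    lm = fit
  ), class = "olsNestedFit")
}

#' @export
print.olsNestedFit <- function(x, ...) {
  cat(sprintf("Nested OLS: F(%d, %d) = %.4g, p = %.3g, adj. R2 = %.3f\n",
              x$df[1], x$df[2], x$F, x$p, x$adj_r2))
  cat(sprintf("  baselines: site type = %s, depth = %s\n",
              x$baselines["site_type"], x$baselines["depth"]))
  tab <- data.frame(beta = x$coefficients, std_beta = x$std_beta,
                    se = x$se, p = x$p_coef)
  print(format(tab, digits = 3))
  invisible(x)
}

#' Kruskal-Wallis rank test
#'
#' Non-parametric contrast used where unequal variances between site types
#' rule out OLS. Thin wrapper over \code{stats::kruskal.test} that also
#' reports the tie-correction factor.
#'
#' @param values numeric observations.
#' @param groups group labels, same length.
#' @return list of class \code{"kruskalResult"}: \code{chi2}, \code{df},
#'   \code{p}, \code{tie_correction}.
#' @export
kruskalWallis <- function(values, groups) {
  groups <- factor(groups)
  failIf(nlevels(groups) < 2L, "need at least two groups")
  failIf(any(table(groups) == 0L), "empty group")
  kt <- kruskal.test(values, groups)
  tt <- table(values)
  n <- length(values)
  tieC <- 1 - sum(tt^3 - tt) / (n^3 - n)
  structure(list(chi2 = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value, tie_correction = tieC),
            class = "kruskalResult")
}

#' @export
print.kruskalResult <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4g, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Dunn's post-hoc test with Benjamini-Hochberg correction
#'
#' Pairwise follow-up to a significant Kruskal-Wallis test: z statistics
#' from mean-rank differences over the pooled ranking, with tie-corrected
#' variance, and BH adjustment across the pairs.
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @param adjust p-adjustment method passed to \code{stats::p.adjust}
#'   (default \code{"BH"}).
#' @return data.frame with one row per pair: \code{group_a}, \code{group_b},
#'   \code{z}, \code{p_raw}, \code{p_adjusted}.
#' @export
dunnPosthoc <- function(values, groups, adjust = "BH") {
  groups <- factor(groups)
  failIf(nlevels(groups) < 2L, "need at least two groups")
  n <- length(values)
  r <- rank(values)
  meanRank <- tapply(r, groups, mean)
  sizes <- table(groups)
  tt <- table(values)
  tieTerm <- sum(tt^3 - tt) / (12 * (n - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    sigma <- sqrt((n * (n + 1) / 12 - tieTerm) *
                  (1 / sizes[pr[1]] + 1 / sizes[pr[2]]))
    unname((meanRank[pr[1]] - meanRank[pr[2]]) / sigma)
  })
  pRaw <- 2 * pnorm(abs(z), lower.tail = FALSE)
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ], z = z,
             p_raw = pRaw, p_adjusted = p.adjust(pRaw, method = adjust),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wrapper over
#' \code{stats::p.adjust}).
#'
#' @param p vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bhAdjust <- function(p) {
  failIf(any(p < 0 | p > 1), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Chi-square upper tail
#'
#' Survival function of the chi-square distribution, the reference for
#' Kruskal-Wallis statistics.
#'
#' @param x statistic (>= 0).
#' @param df degrees of freedom.
#' @return Upper-tail probability.
#' @examples
#' chisqUpperTail(8, 1)      # 0.00468
#' chisqUpperTail(0.429, 1)  # 0.513
#' @export
chisqUpperTail <- function(x, df) {
  failIf(any(x < 0), "x must be >= 0")
  failIf(any(df < 1), "df must be >= 1")
  pchisq(x, df, lower.tail = FALSE)
}

#' Minimum sample size for detecting a standardised effect
#'
#' Smallest n reaching the target power for a correlation-scale effect size.
#' Two conventions are offered: the Fisher z approximation for a correlation
#' test, n = ((z_{1-alpha/2} + z_{power}) / atanh(r))^2 + 3, and an F-test
#' on f2 = r2/(1 - r2) with one numerator df (noncentrality f2 * n). The
#' method used is recorded in the result because the two can differ
#' materially at moderate effects.
#'
#' @param effect standardised effect size (|correlation|), in (0, 1).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param method \code{"fisher-z"} (default) or \code{"f-test"}.
#' @return list with \code{n}, \code{method}, \code{effect}, \code{alpha},
#'   \code{power}.
#' @examples
#' powerSampleSize(0.56)  # n = 23 under the Fisher-z convention
#' @export
powerSampleSize <- function(effect, alpha = 0.05, power = 0.8,
                            method = c("fisher-z", "f-test")) {
  method <- match.arg(method)
  failIf(effect <= 0 || effect >= 1, "effect must lie in (0, 1)")
  failIf(alpha <= 0 || alpha >= 1, "alpha must lie in (0, 1)")
  failIf(power <= 0 || power >= 1, "power must lie in (0, 1)")
  if (method == "fisher-z") {
    n <- ceiling(((qnorm(1 - alpha / 2) + qnorm(power)) / atanh(effect))^2 + 3)
    n <- max(n, 4L)
  } else {
    f2 <- effect^2 / (1 - effect^2)
    n <- NA_integer_
    for (cand in 4:100000) {
      v <- cand - 2
      pow <- pf(qf(1 - alpha, 1, v), 1, v, ncp = f2 * cand,
                lower.tail = FALSE)
      if (pow >= power) { n <- cand; break }
    }
    failIf(is.na(n), "target power unattainable within n <= 100000")
  }
  list(n = as.integer(n), method = method, effect = effect, alpha = alpha,
       power = power)
}
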