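#' Convert percent wet kelp biomass to percent dry kelp carbon
#'
#' Spiked kelp is weighed wet; the calibration is expressed in dry kelp
#' carbon. The conversion is the product of the wet-percent addition, the
#' kelp dry:wet mass ratio (about 12.5\% for blade tissue) and the carbon
#' fraction of the lyophilised powder (about 33\%).
#'
#' @param wetPct percent wet kelp biomass by slurry mass (vectorised).
#' @param dryWetRatio kelp dry mass / wet mass, in (0, 1].
#' @param carbonFrac carbon fraction of dry kelp mass, in (0, 1].
#' @return Percent dry kelp carbon by slurry mass.
#' @examples
#' wetToDryCarbon(5.00)  # 0.206 -> prints as 0.21 at two decimals
#' wetToDryCarbon(c(0, 0.01, 0.05, 0.10, 0.50, 1.00, 2.00, 5.00))
#' @export
wetToDryCarbon <- function(wetPct, dryWetRatio = 0.125, carbonFrac = 0.33) {
  failIf(any(wetPct < 0), "wetPct must be >= 0")
  failIf(any(dryWetRatio <= 0 | dryWetRatio > 1),
         "dryWetRatio must lie in (0, 1]")
  failIf(any(carbonFrac <= 0 | carbonFrac > 1),
         "carbonFrac must lie in (0, 1]")
  wetPct * dryWetRatio * carbonFrac
}

#' Fit the biomass spiking dose-response through the origin
#'
#' Least-squares regression of gene copies per gram dry sediment on added dry
#' kelp carbon with the intercept coerced to zero: a blank slurry should read
#' (near) zero. R-squared uses the uncentered total sum of squares, the
#' standard convention for no-intercept models, and the adjusted value is
#' 1 - (1 - R2) n / (n - 1). Doses above \code{excludeAbove} are dropped by
#' default because the gene-copy response saturates at high biomass loads
#' and would bias the slope low.
#'
#' @param doses percent dry kelp carbon per observation.
#' @param responses copies per gram dry sediment.
#' @param excludeAbove drop doses strictly above this value before fitting;
#'   the default 0.0825 is the 2.00 percent wet-biomass level (printed as
#'   0.08 percent dry C), the top of the linear range. \code{Inf} keeps all.
#' @return A \linkS4class{CalibrationFit}.
#' @examples
#' fitThroughOrigin(c(1, 2, 3), c(2, 4, 6))  # slope 2, R2 = 1
#' @export
fitThroughOrigin <- function(doses, responses, excludeAbove = 0.0825) {
  stopifnot(length(doses) == length(responses))
  failIf(any(doses < 0), "doses must be >= 0")
  keep <- doses <= excludeAbove & is.finite(responses)
  d <- doses[keep]; y <- responses[keep]
  failIf(length(d) < 3L, "need at least 3 points after exclusion")
  failIf(all(d == 0), "all doses zero: slope undefined")
  fit <- lm(y ~ 0 + d)
  sm <- summary(fit)
  sw <- tryCatch(shapiro.test(residuals(fit)),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
  slopeHat <- unname(coef(fit)[1])
  failIf(slopeHat <= 0, "fitted slope is not positive; calibration unusable")
  new("CalibrationFit",
      slope = slopeHat,
      slopeSe = unname(sm$coefficients[1, 2]),
      Fstat = unname(sm$fstatistic[1]),
      df = as.integer(sm$fstatistic[2:3]),
      r2 = sm$r.squared,
      adjR2 = sm$adj.r.squared,
      pValue = unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                         lower.tail = FALSE)),
      inverseCoefficient = 1 / slopeHat,
      fitRange = range(d),
      nObs = length(d),
      shapiroW = unname(sw$statistic),
      shapiroP = sw$p.value,
      data = data.frame(dose = d, response = y))
}

#' Invert the calibration to a copies-to-kelp-carbon converter
#'
#' The reciprocal of the through-origin slope converts a gene-copy density
#' (copies per gram dry sediment) into percent dry kelp carbon. Returned as
#' a coefficient plus a linear converter function.
#'
#' @param fit a \linkS4class{CalibrationFit}.
#' @return list with \code{inverse_coefficient} (percent dry kelp C per copy
#'   g^-1) and \code{kelp_carbon}, a function of copy numbers.
#' @export
invertCalibration <- function(fit) {
  stopifnot(is(fit, "CalibrationFit"))
  inv <- fit@inverseCoefficient
  list(inverse_coefficient = inv,
       kelp_carbon = function(copies) {
         failIf(any(copies < 0), "copies must be >= 0")
         inv * copies
       })
}

#' Recover regression summaries from an F statistic
#'
#' Back-calculates R-squared, adjusted R-squared and the p-value from a
#' reported F statistic and its degrees of freedom:
#' R2 = F df1 / (F df1 + df2), with the adjustment using (n - 1)/df2 for
#' models with an intercept and n/df2 for through-origin fits.
#'
#' @param Fstat the F statistic.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @param n number of observations; must satisfy n = df1 + df2 + 1 (with
#'   intercept) or n = df1 + df2 (through origin).
#' @param throughOrigin logical, no-intercept model?
#' @return list with \code{r2}, \code{adj_r2} and \code{p}.
#' @examples
#' regressionSummaryFromF(250.8, 1, 19, n = 20, throughOrigin = TRUE)
#' regressionSummaryFromF(14.51, 5, 69, n = 75)
#' @export
regressionSummaryFromF <- function(Fstat, df1, df2, n,
                                   throughOrigin = FALSE) {
  failIf(df1 < 1 || df2 < 1, "df1 and df2 must be >= 1")
  expected <- df1 + df2 + if (throughOrigin) 0L else 1L
  failIf(n != expected,
         sprintf("n = %d inconsistent with df (%d, %d): expected %d",
                 n, df1, df2, expected))
  r2 <- Fstat * df1 / (Fstat * df1 + df2)
  adj <- if (throughOrigin) 1 - (1 - r2) * n / df2
         else 1 - (1 - r2) * (n - 1) / df2
  list(r2 = r2, adj_r2 = adj,
       p = pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of quantification cycle on log10 standard copies.
#' Amplification efficiency follows from the slope as 10^(-1/slope) - 1,
#' so a slope of -3.3219 (= -1/log10(2)) is exactly 100\% (doubling per
#' cycle).
#'
#' @param log10Copies log10 copy number of each standard.
#' @param cq measured quantification cycles.
#' @return A \linkS4class{QpcrCurve}.
#' @examples
#' x <- rep(1:5, each = 3)
#' qpcrStandardCurve(x, 37.049 - 3.197 * x)
#' @export
qpcrStandardCurve <- function(log10Copies, cq) {
  stopifnot(length(log10Copies) == length(cq))
  failIf(length(unique(log10Copies)) < 3L,
         "need at least 3 distinct standard levels")
  fit <- lm(cq ~ log10Copies)
  sm <- summary(fit)
  b <- unname(coef(fit))
  eff <- if (b[2] < 0) 10^(-1 / b[2]) - 1 else NA_real_
  new("QpcrCurve", slope = b[2], intercept = b[1], r2 = sm$r.squared,
      efficiency = eff, n = length(cq))
}
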