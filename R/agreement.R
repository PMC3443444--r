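#' @include AllClasses.R calibration.R
NULL

#' Bland-Altman limits of agreement
#'
#' Differences are taken first-listed arm minus second. Bias is their
#' mean, the spread their sample standard deviation (n - 1 denominator),
#' and the 95\% limits of agreement are bias -/+ 1.96 x SD -- the 1.96
#' multiplier is fixed by convention, not a t quantile. Confidence
#' intervals use t quantiles with n - 1 degrees of freedom: the bias CI
#' half-width is t x SD / sqrt(n), each limit's CI half-width
#' t x SD x sqrt(3 / n).
#'
#' @param series a \code{\linkS4class{MeasurementSeries}} (n >= 3).
#' @return an \code{\linkS4class{AgreementReport}} with the Bland-Altman
#'   fields filled in (ICC, r and t remain NA).
#' @export
blandAltman <- function(series) {
  stopifnot(is(series, "MeasurementSeries"))
  d <- series@a - series@b
  n <- length(d)
  bias <- mean(d)
  sdD <- stats::sd(d)
  tq <- stats::qt(0.975, n - 1)
  half <- tq * sdD * sqrt(3 / n)
  new("AgreementReport", n = n, bias = bias, sdDiff = sdD,
      loaLower = bias - 1.96 * sdD, loaUpper = bias + 1.96 * sdD,
      biasCi = bias + c(-1, 1) * tq * sdD / sqrt(n),
      loaLowerCi = bias - 1.96 * sdD + c(-1, 1) * half,
      loaUpperCi = bias + 1.96 * sdD + c(-1, 1) * half,
      icc = NA_real_, iccCi = c(NA_real_, NA_real_), r = NA_real_,
      tStat = NA_real_, pValue = NA_real_, labels = series@labels)
}

#' Two-way intraclass correlation coefficient
#'
#' Single-measures ICC from the two-way mixed-effects model, by default
#' for absolute agreement -- the reproducibility default of the clinical
#' statistics packages this mirrors -- with \code{type = "consistency"}
#' available as the alternative. Mean squares come from the two-way ANOVA
#' decomposition (subjects x measurements); the 95\% confidence interval
#' uses the F-distribution bounds (Satterthwaite degrees of freedom for
#' the absolute-agreement form).
#'
#' @param series a \code{\linkS4class{MeasurementSeries}}.
#' @param type "agreement" (absolute agreement, default) or "consistency".
#' @return list with \code{icc} and \code{ci} (length-2 95\% interval).
#' @export
iccTwoWay <- function(series, type = c("agreement", "consistency")) {
  stopifnot(is(series, "MeasurementSeries"))
  type <- match.arg(type)
  x <- cbind(series@a, series@b)
  n <- nrow(x); k <- 2
  if (stats::var(as.vector(x)) < 1e-24)
    .octError("degenerate data: zero total variance, ICC undefined",
              "octgraft_degenerate_error")
  rowM <- rowMeans(x); colM <- colMeans(x); grand <- mean(x)
  MSR <- k * sum((rowM - grand)^2) / (n - 1)
  MSC <- n * sum((colM - grand)^2) / (k - 1)
  SSE <- sum((x - outer(rowM, rep(1, k)) - outer(rep(1, n), colM) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))

  if (type == "consistency") {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    if (MSE < 1e-24) return(list(icc = 1, ci = c(1, 1)))
    Fo <- MSR / MSE
    FL <- Fo / stats::qf(0.975, n - 1, (n - 1) * (k - 1))
    FU <- Fo * stats::qf(0.975, (n - 1) * (k - 1), n - 1)
    ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
    return(list(icc = icc, ci = ci))
  }

  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  if (MSE < 1e-24 && MSC < 1e-24) return(list(icc = 1, ci = c(1, 1)))
  r <- max(icc, 1e-12)
  a <- (k * r) / (n * (1 - r))
  b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(0.975, n - 1, v)
  FU <- stats::qf(0.975, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(icc = icc, ci = c(lower, upper))
}

#' Pearson correlation between the two arms
#'
#' @param series a \code{\linkS4class{MeasurementSeries}}.
#' @return the correlation coefficient.
#' @export
pearsonR <- function(series) {
  stopifnot(is(series, "MeasurementSeries"))
  if (stats::sd(series@a) < 1e-24 || stats::sd(series@b) < 1e-24)
    .octError("zero variance in one arm: correlation undefined",
              "octgraft_degenerate_error")
  stats::cor(series@a, series@b)
}

#' Paired t-test between the two arms
#'
#' Two-sided p from the t distribution with n - 1 degrees of freedom.
#'
#' @param series a \code{\linkS4class{MeasurementSeries}}.
#' @return list with \code{t} and \code{p}; both NA (flagged degenerate)
#'   when the differences are constant at zero.
#' @export
pairedT <- function(series) {
  stopifnot(is(series, "MeasurementSeries"))
  d <- series@a - series@b
  if (stats::sd(d) < 1e-24) {
    # identical arms: zero bias with zero spread; t is 0 by continuity,
    # the p value is undefined and flagged
    if (all(abs(d) < 1e-24)) return(list(t = 0, p = NA_real_, degenerate = TRUE))
    .octError("constant non-zero differences: paired t undefined",
              "octgraft_degenerate_error")
  }
  ht <- stats::t.test(series@a, series@b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
}

#' Full agreement report for one paired series
#'
#' Combines \code{\link{blandAltman}}, \code{\link{iccTwoWay}},
#' \code{\link{pearsonR}} and \code{\link{pairedT}}.
#'
#' @param series a \code{\linkS4class{MeasurementSeries}}.
#' @param iccType passed to \code{\link{iccTwoWay}}.
#' @return a fully populated \code{\linkS4class{AgreementReport}}.
#' @export
agreementReport <- function(series, iccType = "agreement") {
  rep <- blandAltman(series)
  icc <- tryCatch(iccTwoWay(series, iccType), octgraft_error = function(e) NULL)
  if (!is.null(icc)) { rep@icc <- icc$icc; rep@iccCi <- icc$ci }
  rep@r <- tryCatch(pearsonR(series), octgraft_error = function(e) NA_real_)
  tt <- pairedT(series)
  rep@tStat <- tt$t; rep@pValue <- tt$p
  rep
}

#' Tabulate agreement across several paired series
#'
#' One row per comparison, mirroring the standard published layout: mean
#' area (um^2) with SD for each arm, the paired-t p value, Pearson r, ICC
#' with its 95\% CI, the Bland-Altman bias with CI and the upper and lower
#' limits of agreement with CIs. Degenerate p values (identical arms) are
#' flagged NA.
#'
#' @param seriesList list of \code{\linkS4class{MeasurementSeries}}.
#' @param iccType passed to \code{\link{iccTwoWay}}.
#' @return a data.frame, one row per series.
#' @export
agreementTable <- function(seriesList, iccType = "agreement") {
  if (is(seriesList, "MeasurementSeries")) seriesList <- list(seriesList)
  rows <- lapply(seriesList, function(s) {
    rep <- agreementReport(s, iccType)
    data.frame(arm_a = s@labels[1], arm_b = s@labels[2], n = rep@n,
               mean_a = mean(s@a), sd_a = stats::sd(s@a),
               mean_b = mean(s@b), sd_b = stats::sd(s@b),
               p_value = rep@pValue, r = rep@r,
               icc = rep@icc, icc_lo = rep@iccCi[1], icc_hi = rep@iccCi[2],
               bias = rep@bias, bias_lo = rep@biasCi[1], bias_hi = rep@biasCi[2],
               loa_upper = rep@loaUpper, loa_upper_lo = rep@loaUpperCi[1],
               loa_upper_hi = rep@loaUpperCi[2],
               loa_lower = rep@loaLower, loa_lower_lo = rep@loaLowerCi[1],
               loa_lower_hi = rep@loaLowerCi[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
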