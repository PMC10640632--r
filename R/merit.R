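#' Recovery percentage
#'
#' `100 * predicted / actual`, the standard accuracy measure for a
#' quantitative assay.
#'
#' @param predicted Predicted concentration(s), ug/mL.
#' @param actual True concentration(s), ug/mL; all > 0.
#' @return Numeric vector of recoveries in percent.
#' @examples
#' recovery_percent(11.286, 11.0)
#' @export
recovery_percent <- function(predicted, actual) {
  if (any(actual <= 0)) stop("`actual` must be > 0.", call. = FALSE)
  100 * predicted / actual
}

#' Mean and standard deviation of recoveries
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of a
#' set of recovery percentages, as tabulated for a validation set.
#'
#' @param values Numeric vector of recoveries (%); at least 2 values.
#' @return Tibble with columns `n`, `mean`, `sd`.
#' @export
summarize_recoveries <- function(values) {
  if (length(values) < 2) stop("Need at least 2 recoveries.", call. = FALSE)
  tibble::tibble(n = length(values), mean = mean(values), sd = stats::sd(values))
}

#' Root mean squared error of prediction
#'
#' \eqn{\sqrt{\sum(\hat y - y)^2 / n}} over a validation set.
#'
#' @param predicted,actual Equal-length numeric vectors (ug/mL).
#' @return RMSEP in ug/mL.
#' @export
rmsep <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("`predicted` and `actual` must have equal length.", call. = FALSE)
  }
  sqrt(mean((predicted - actual)^2))
}

#' Standard error of prediction
#'
#' \eqn{\sqrt{\sum(\hat y - y)^2 / (n - 2)}} over the same residuals as
#' [rmsep()], so `sep / rmsep = sqrt(n / (n - 2))` exactly. The n - 2
#' denominator (no bias subtraction) is the convention consistent with the
#' published SEP/RMSEP pairs this package validates against; closeness of
#' SEP and RMSEP is the usual overfitting check.
#'
#' @param predicted,actual Equal-length numeric vectors, n >= 3.
#' @return SEP in ug/mL.
#' @export
sep <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("`predicted` and `actual` must have equal length.", call. = FALSE)
  }
  n <- length(predicted)
  if (n < 3) stop("SEP needs n >= 3.", call. = FALSE)
  sqrt(sum((predicted - actual)^2) / (n - 2))
}

#' Predicted-versus-actual regression
#'
#' Ordinary least squares of predicted on actual concentration, the
#' standard linearity check for a validation set: slope and intercept near
#' 1 and 0 and correlation near 1 indicate accurate, unbiased prediction.
#'
#' @param predicted,actual Numeric vectors, >= 3 points; `actual` must vary.
#' @return Tibble with `slope`, `intercept`, `r` (Pearson correlation) and
#'   `s_residual` (residual SD of the regression, df = n - 2).
#' @export
pred_actual_regression <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(actual) < 3) {
    stop("Need >= 3 paired points.", call. = FALSE)
  }
  if (stats::var(actual) == 0) {
    stop("`actual` is constant; regression is degenerate.", call. = FALSE)
  }
  fit <- stats::lm(predicted ~ actual)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = stats::cor(predicted, actual),
    s_residual = sqrt(sum(stats::residuals(fit)^2) / (length(actual) - 2))
  )
}

#' Limits of detection and quantification
#'
#' ICH-style limits from the predicted-versus-actual regression:
#' `lod = 3.3 * s / slope`, `loq = 10 * s / slope`, with `s` the residual
#' standard deviation of the regression, so `loq = lod * 10 / 3.3` always.
#'
#' @param s_residual Residual SD of the predicted-vs-actual regression.
#' @param slope Regression slope; must be > 0.
#' @return Tibble with `lod` and `loq` (ug/mL).
#' @export
lod_loq <- function(s_residual, slope) {
  if (slope <= 0) stop("`slope` must be > 0.", call. = FALSE)
  tibble::tibble(lod = 3.3 * s_residual / slope, loq = 10 * s_residual / slope)
}

#' Standard-addition evaluation
#'
#' Recovery of known spiked amounts on top of a dosage-form sample:
#' `recovery_i = 100 * (predicted_spiked_i - taken) / added_i`, computed on
#' the added amount only, then summarized over the spike levels.
#'
#' @param taken Concentration attributed to the unspiked sample (ug/mL).
#' @param spiked_predictions Predicted totals for each spiked solution.
#' @param added_levels Spiked amounts (ug/mL), all > 0.
#' @return Tibble of class `standard_addition` with per-level columns
#'   `added`, `predicted`, `recovery`, plus attributes `mean` and `sd`.
#' @export
standard_addition <- function(taken, spiked_predictions, added_levels) {
  if (any(added_levels <= 0)) stop("Added amounts must be > 0.", call. = FALSE)
  if (length(spiked_predictions) != length(added_levels)) {
    stop("One prediction per addition level is required.", call. = FALSE)
  }
  rec <- 100 * (spiked_predictions - taken) / added_levels
  out <- tibble::tibble(added = added_levels, predicted = spiked_predictions,
                        recovery = rec)
  attr(out, "mean") <- mean(rec)
  attr(out, "sd") <- stats::sd(rec)
  class(out) <- c("standard_addition", class(out))
  out
}

#' Compare two methods from summary statistics
#'
#' Pooled-variance two-sample Student t test (two-sided, df = n1 + n2 - 2)
#' and variance-ratio F test (larger variance in the numerator, one-tailed
#' upper critical value), both at significance level `alpha`. Used to
#' compare a proposed calibration against a reference method when only
#' summary statistics of the latter are available.
#'
#' @param mean1,sd1,n1 Summary of method 1.
#' @param mean2,sd2,n2 Summary of method 2.
#' @param alpha Significance level (default 0.05).
#' @return Tibble with `t_statistic`, `t_critical`, `t_df`, `f_statistic`,
#'   `f_critical`, `f_df1`, `f_df2`.
#' @examples
#' compare_methods(99.5, 1.82, 10, 99.6, 0.98, 5)
#' @export
compare_methods <- function(mean1, sd1, n1, mean2, sd2, n2, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) stop("Both n must be >= 2.", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("Both sd must be > 0.", call. = FALSE)
  df_t <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df_t
  t_stat <- abs(mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  if (sd1^2 >= sd2^2) {
    f_stat <- sd1^2 / sd2^2; f_df1 <- n1 - 1; f_df2 <- n2 - 1
  } else {
    f_stat <- sd2^2 / sd1^2; f_df1 <- n2 - 1; f_df2 <- n1 - 1
  }
  tibble::tibble(
    t_statistic = t_stat,
    t_critical = stats::qt(1 - alpha / 2, df_t),
    t_df = df_t,
    f_statistic = f_stat,
    f_critical = stats::qf(1 - alpha, f_df1, f_df2),
    f_df1 = f_df1, f_df2 = f_df2
  )
}

#' Full figures-of-merit report for a validation set
#'
#' Computes, per component: per-sample recoveries with mean and SD, RMSEP,
#' SEP, the predicted-versus-actual regression (slope, intercept, r) and
#' LOD/LOQ derived from its residual SD.
#'
#' @param predicted Matrix or data frame of predicted concentrations
#'   (validation samples x components).
#' @param actual Matching matrix or data frame of true concentrations.
#' @return A tibble of class `merit_report`, one row per component, with
#'   columns `component`, `n`, `mean_recovery`, `sd_recovery`, `slope`,
#'   `intercept`, `r`, `sep`, `rmsep`, `lod`, `loq`; the long per-sample
#'   recovery table is attached as attribute `"recoveries"` and retrievable
#'   with [tidy()][generics::tidy].
#' @export
merit_report <- function(predicted, actual) {
  P <- conc_to_matrix(predicted)
  A <- conc_to_matrix(actual)
  if (!all(dim(P) == dim(A))) {
    stop("`predicted` and `actual` must have identical dimensions.", call. = FALSE)
  }
  comp <- colnames(A) %||% colnames(P) %||% paste0("C", seq_len(ncol(A)))
  rows <- purrr::map_dfr(seq_len(ncol(A)), function(j) {
    rec <- recovery_percent(P[, j], A[, j])
    reg <- pred_actual_regression(P[, j], A[, j])
    lim <- lod_loq(reg$s_residual, reg$slope)
    tibble::tibble(
      component = comp[j], n = nrow(A),
      mean_recovery = mean(rec), sd_recovery = stats::sd(rec),
      slope = reg$slope, intercept = reg$intercept, r = reg$r,
      sep = sep(P[, j], A[, j]), rmsep = rmsep(P[, j], A[, j]),
      lod = lim$lod, loq = lim$loq
    )
  })
  recov <- tibble::tibble(
    sample = rep(seq_len(nrow(A)), times = ncol(A)),
    component = rep(comp, each = nrow(A)),
    actual = as.vector(A), predicted = as.vector(P),
    recovery = as.vector(100 * P / A)
  )
  attr(rows, "recoveries") <- recov
  class(rows) <- c("merit_report", class(rows))
  rows
}

#' Per-sample recoveries behind a merit report
#'
#' @param x A `merit_report`.
#' @param ... Unused.
#' @return Long tibble with `sample`, `component`, `actual`, `predicted`,
#'   `recovery`.
#' @method tidy merit_report
#' @export
tidy.merit_report <- function(x, ...) attr(x, "recoveries")

#' Plot predicted versus actual concentrations
#'
#' @param object A `merit_report`.
#' @param ... Unused.
#' @return A ggplot faceted by component with the identity line.
#' @method autoplot merit_report
#' @export
autoplot.merit_report <- function(object, ...) {
  df <- attr(object, "recoveries")
  ggplot2::ggplot(df, ggplot2::aes(.data$actual, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~component, scales = "free") +
    ggplot2::labs(x = "Actual (µg/mL)", y = "Predicted (µg/mL)") +
    ggplot2::theme_minimal()
}
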