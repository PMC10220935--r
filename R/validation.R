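#' Mean and SD of the prediction error
#'
#' Per-participant error is `predicted - measured`; the SD uses the sample
#' (n - 1) denominator.
#'
#' @param pred,meas numeric vectors of equal length (>= 2).
#' @return A list with `mean`, `sd` and `n`.
#' @examples
#' prediction_errors(c(1.7, 1.8), c(1.8, 1.9))
#' @export
prediction_errors <- function(pred, meas) {
  if (length(pred) != length(meas))
    stop("pred and meas must have the same length")
  if (length(pred) < 2) stop("need at least 2 paired values")
  if (anyNA(pred) || anyNA(meas)) stop("missing values in compared columns")
  err <- pred - meas
  list(mean = mean(err), sd = stats::sd(err), n = length(err))
}

#' Pearson correlation between predicted and measured values
#'
#' @param pred,meas numeric vectors of equal length (>= 3) with non-zero
#'   variance.
#' @return Pearson product-moment correlation coefficient.
#' @export
pal_correlation <- function(pred, meas) {
  if (length(pred) != length(meas))
    stop("pred and meas must have the same length")
  if (length(pred) < 3) stop("need at least 3 paired values")
  if (stats::sd(pred) == 0 || stats::sd(meas) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(pred, meas)
}

#' Compare two series with a t test
#'
#' Two-tailed t test at alpha = 0.05: paired for measured-versus-predicted
#' comparisons on the same participants, unpaired (Welch) for
#' between-group (e.g. sex) comparisons.
#'
#' @param a,b numeric series.
#' @param paired logical; paired design (default TRUE).
#' @return The `htest` object from [stats::t.test()].
#' @export
group_compare <- function(a, b, paired = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 observations per series")
  if (paired && length(a) != length(b))
    stop("paired series must have the same length")
  if (paired && stats::sd(a - b) == 0) {
    # degenerate but well-defined: identical series differ by a constant
    d <- mean(a - b)
    out <- list(statistic = c(t = if (d == 0) 0 else sign(d) * Inf),
                parameter = c(df = length(a) - 1),
                p.value = if (d == 0) 1 else 0,
                estimate = c(`mean difference` = d),
                method = "Paired t-test (degenerate: constant differences)",
                alternative = "two.sided",
                data.name = "a and b")
    class(out) <- "htest"
    return(out)
  }
  stats::t.test(a, b, paired = paired)
}

#' Full validation report for a cohort of predictions
#'
#' Reproduces the validation arithmetic of an accelerometer-against-
#' reference study on a results table: per sex and per method (unadjusted
#' device PAL, Nagayoshi-adjusted PAL, regression-corrected PAL) the mean
#' and SD of the PAL and TEE prediction errors, the Pearson correlation of
#' predicted with measured PAL, the fitted sex-specific correction
#' equations, and paired t tests of measured against predicted PAL.
#' Corrected TEE is reported with both the predicted and the measured BMR.
#'
#' @param results data.frame with one row per retained participant and
#'   columns `id`, `sex`, `bmr_pred`, `bmr_meas`, `tee_meas`, `pal_meas`,
#'   `pal_pred`, `pal_nagayoshi`.
#' @param calibration optional [pal_calibration()]; fitted on `results`
#'   when omitted (fitting sample = evaluation sample, as in a
#'   development-sample report).
#' @return A list of class `validation_report`: `n` per sex, `correlation`
#'   per sex, `calibration` (fit), and per-sex blocks `pal` / `tee` holding
#'   method-wise error summaries, plus `tests` of paired comparisons.
#' @export
validation_report <- function(results, calibration = NULL) {
  need <- c("sex", "bmr_pred", "bmr_meas", "tee_meas", "pal_meas",
            "pal_pred", "pal_nagayoshi")
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols))
    stop("results lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyNA(results[need[-1]])) stop("missing values in compared columns")
  if (is.null(calibration))
    calibration <- pal_calibration(pal_meas ~ pal_pred, results, sex = "sex")
  results$pal_corrected <- predict(calibration, results)
  results$tee_pred <- results$pal_pred * results$bmr_pred
  results$tee_nagayoshi <- results$pal_nagayoshi * results$bmr_pred
  results$tee_corr_predbmr <- corrected_tee(results$pal_corrected,
                                            results$bmr_pred)
  results$tee_corr_measbmr <- corrected_tee(results$pal_corrected,
                                            results$bmr_meas)

  per_sex <- lapply(split(results, results$sex), function(d) {
    pal <- list(
      unadjusted = prediction_errors(d$pal_pred, d$pal_meas),
      nagayoshi  = prediction_errors(d$pal_nagayoshi, d$pal_meas),
      regression = prediction_errors(d$pal_corrected, d$pal_meas))
    tee <- list(
      unadjusted = prediction_errors(d$tee_pred, d$tee_meas),
      nagayoshi  = prediction_errors(d$tee_nagayoshi, d$tee_meas),
      regression_predbmr = prediction_errors(d$tee_corr_predbmr, d$tee_meas),
      regression_measbmr = prediction_errors(d$tee_corr_measbmr, d$tee_meas))
    tests <- list(
      pal_unadjusted = group_compare(d$pal_meas, d$pal_pred, paired = TRUE),
      pal_nagayoshi = group_compare(d$pal_meas, d$pal_nagayoshi,
                                    paired = TRUE))
    list(n = nrow(d),
         correlation = pal_correlation(d$pal_pred, d$pal_meas),
         pal = pal, tee = tee, tests = tests)
  })

  structure(list(by_sex = per_sex, calibration = calibration,
                 results = results),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report\n")
  for (g in names(x$by_sex)) {
    b <- x$by_sex[[g]]
    cat(sprintf("\n%s (n = %d, r = %.3f)\n", g, b$n, b$correlation))
    for (m in names(b$pal))
      cat(sprintf("  PAL error, %-11s %6.2f (%.2f)\n", paste0(m, ":"),
                  b$pal[[m]]$mean, b$pal[[m]]$sd))
    for (m in names(b$tee))
      cat(sprintf("  TEE error, %-19s %6.0f (%.0f) kcal/day\n",
                  paste0(m, ":"), b$tee[[m]]$mean, b$tee[[m]]$sd))
  }
  cat("\n")
  print(x$calibration)
  invisible(x)
}

#' Flatten a validation report for JSON export
#'
#' Rounds as conventionally reported: PAL to 2 decimals, energies to whole
#' kcal/day, correlations to 3 decimals.  Full precision is kept
#' internally; rounding happens only here, at the reporting layer.
#'
#' @param report a [validation_report()].
#' @return A nested list of plain numbers suitable for
#'   [jsonlite::write_json()].
#' @export
report_to_list <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  cf <- coef(report$calibration)
  out <- list(correction = apply(cf, 1, function(r)
    list(slope = round(r[["slope"]], 3),
         intercept = round(r[["intercept"]], 3),
         resid_sd = round(r[["resid_sd"]], 2),
         n = r[["n"]]), simplify = FALSE))
  out$by_sex <- lapply(report$by_sex, function(b) list(
    n = b$n,
    r = round(b$correlation, 3),
    pal_error = lapply(b$pal, function(e)
      list(mean = round(e$mean, 2), sd = round(e$sd, 2))),
    tee_error = lapply(b$tee, function(e)
      list(mean = round(e$mean), sd = round(e$sd)))))
  out
}
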