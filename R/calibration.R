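#' Fit sex-specific PAL correction equations
#'
#' The central fit of the package: ordinary least squares of the reference
#' ("measured", doubly-labeled-water style) physical activity level on the
#' device-predicted PAL, fitted separately for each sex, never pooled.  The
#' fitted lines `Y = slope * X + intercept` are the correction equations
#' used by [correct_pal()]; the residual standard deviation (n - 1
#' denominator) summarizes the irreducible prediction error on the fitting
#' sample, on which the mean residual is exactly zero by construction.
#'
#' @param formula model formula, reference PAL on the left and predicted
#'   PAL on the right, e.g. `pal_meas ~ pal_pred`.
#' @param data data.frame holding both PAL columns and the grouping column.
#' @param sex name of the grouping column (default `"sex"`); use
#'   `sex = NULL` to fit one pooled model (labelled `"all"`).
#' @return An object of class `pal_calibration` with methods [print()],
#'   [summary()], [coef()], [predict()], [residuals()], [simulate()] and
#'   [plot()].
#' @examples
#' d <- data.frame(sex = rep(c("F", "M"), each = 25),
#'                 pal_pred = runif(50, 1.3, 2.0))
#' d$pal_meas <- 0.95 * d$pal_pred + 0.2 + rnorm(50, sd = 0.15)
#' fit <- pal_calibration(pal_meas ~ pal_pred, d)
#' coef(fit)
#' @export
pal_calibration <- function(formula, data, sex = "sex") {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  vars <- all.vars(formula)
  if (length(vars) != 2)
    stop("formula must be of the form measured ~ predicted")
  yname <- vars[1]; xname <- vars[2]
  if (!all(vars %in% names(data)))
    stop("data lacks column(s): ",
         paste(setdiff(vars, names(data)), collapse = ", "))
  if (anyNA(data[[yname]]) || anyNA(data[[xname]]))
    stop("missing values in the compared columns")
  grp <- if (is.null(sex)) rep("all", nrow(data)) else {
    if (!sex %in% names(data)) stop("data lacks grouping column '", sex, "'")
    as.character(data[[sex]])
  }

  fit_one <- function(d) {
    if (nrow(d) < 3) stop("need at least 3 observations per group")
    x <- d[[xname]]; y <- d[[yname]]
    if (stats::sd(x) == 0) stop("degenerate predictor: zero variance")
    m <- stats::lm(y ~ x)
    res <- stats::residuals(m)
    list(slope = unname(stats::coef(m)[2]),
         intercept = unname(stats::coef(m)[1]),
         resid_sd = stats::sd(res),
         r = stats::cor(x, y),
         n = nrow(d),
         residuals = res,
         x = x, y = y)
  }
  groups <- lapply(split(data, grp), fit_one)

  structure(list(models = groups, formula = formula,
                 xname = xname, yname = yname,
                 groupvar = if (is.null(sex)) NA_character_ else sex,
                 call = match.call()),
            class = "pal_calibration")
}

#' @describeIn pal_calibration coefficient matrix, one row per group with
#'   columns `slope`, `intercept`, `resid_sd`, `r`, `n`.
#' @param object,x a `pal_calibration` object.
#' @param ... unused.
#' @export
coef.pal_calibration <- function(object, ...) {
  out <- t(vapply(object$models, function(m)
    c(slope = m$slope, intercept = m$intercept, resid_sd = m$resid_sd,
      r = m$r, n = m$n), numeric(5)))
  out
}

#' @export
print.pal_calibration <- function(x, ...) {
  cat("Sex-specific PAL calibration (OLS of",
      x$yname, "on", x$xname, ")\n")
  cf <- coef(x)
  for (g in rownames(cf))
    cat(sprintf("  %s: Y = %.3f * X + %.3f  (resid SD %.2f, r = %.3f, n = %d)\n",
                g, cf[g, "slope"], cf[g, "intercept"], cf[g, "resid_sd"],
                cf[g, "r"], as.integer(cf[g, "n"])))
  invisible(x)
}

#' @export
summary.pal_calibration <- function(object, ...) {
  structure(list(coef = coef(object), call = object$call,
                 xname = object$xname, yname = object$yname),
            class = "summary.pal_calibration")
}

#' @export
print.summary.pal_calibration <- function(x, ...) {
  cat("PAL calibration:", x$yname, "~", x$xname, "\n\n")
  print(round(x$coef, 4))
  cat("\nMean residual is 0 within each group by OLS construction.\n")
  invisible(x)
}

#' @describeIn pal_calibration corrected PAL for new data.  `newdata` needs
#'   the predictor column and, for multi-group fits, the grouping column.
#'   With `newdata` missing, returns fitted values on the training sample.
#' @param newdata optional data.frame of new observations.
#' @export
predict.pal_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(unlist(lapply(object$models, function(m)
      m$intercept + m$slope * m$x), use.names = FALSE))
  }
  stopifnot(is.data.frame(newdata))
  if (!object$xname %in% names(newdata))
    stop("newdata lacks predictor column '", object$xname, "'")
  grp <- if (length(object$models) == 1L) {
    rep(names(object$models), nrow(newdata))
  } else {
    if (!object$groupvar %in% names(newdata))
      stop("newdata lacks grouping column '", object$groupvar, "'")
    as.character(newdata[[object$groupvar]])
  }
  missing_grp <- setdiff(unique(grp), names(object$models))
  if (length(missing_grp))
    stop("no fitted correction for group: ",
         paste(missing_grp, collapse = ", "))
  cf <- coef(object)
  unname(cf[grp, "intercept"] + cf[grp, "slope"] * newdata[[object$xname]])
}

#' @describeIn pal_calibration residuals of the fit, in the row order of
#'   the (group-split) fitting sample.
#' @export
residuals.pal_calibration <- function(object, ...) {
  unlist(lapply(object$models, `[[`, "residuals"), use.names = FALSE)
}

#' @describeIn pal_calibration draw `nsim` replicate response vectors from
#'   the fitted model at the training predictor values (Gaussian residuals
#'   with the fitted residual SD).
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @export
simulate.pal_calibration <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- unlist(lapply(object$models, function(m)
    m$intercept + m$slope * m$x), use.names = FALSE)
  sds <- unlist(lapply(object$models, function(m)
    rep(m$resid_sd, m$n)), use.names = FALSE)
  out <- as.data.frame(replicate(nsim, stats::rnorm(length(mu), mu, sds)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @describeIn pal_calibration scatter of measured against predicted PAL
#'   with the fitted correction lines and the identity line.
#' @export
plot.pal_calibration <- function(x, ...) {
  cols <- seq_along(x$models) + 1
  allx <- unlist(lapply(x$models, `[[`, "x"))
  ally <- unlist(lapply(x$models, `[[`, "y"))
  graphics::plot(allx, ally, type = "n", xlab = x$xname, ylab = x$yname, ...)
  graphics::abline(0, 1, lty = 3)
  for (i in seq_along(x$models)) {
    m <- x$models[[i]]
    graphics::points(m$x, m$y, col = cols[i], pch = i)
    graphics::abline(m$intercept, m$slope, col = cols[i], lty = 2)
  }
  graphics::legend("topleft", legend = names(x$models), col = cols,
                   pch = seq_along(x$models), bty = "n")
  invisible(x)
}

#' Extract fixed correction models from a calibration fit
#'
#' @param fit a [pal_calibration()].
#' @return Named list of [correction_model()] objects, one per group.
#' @export
as_correction_models <- function(fit) {
  stopifnot(inherits(fit, "pal_calibration"))
  cf <- coef(fit)
  out <- lapply(rownames(cf), function(g)
    correction_model(g, cf[g, "slope"], cf[g, "intercept"],
                     cf[g, "resid_sd"]))
  names(out) <- rownames(cf)
  out
}
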