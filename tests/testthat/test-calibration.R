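make_cal_data <- function(n = 40, seed = 8, sd = 0.15) {
  set.seed(seed)
  d <- data.frame(sex = rep(c("F", "M"), length.out = n),
                  pal_pred = runif(n, 1.3, 2.1))
  slope <- ifelse(d$sex == "F", 0.949, 0.899)
  icpt <- ifelse(d$sex == "F", 0.205, 0.371)
  d$pal_meas <- slope * d$pal_pred + icpt + rnorm(n, sd = sd)
  d
}

test_that("prediction errors are pred - meas with sample SD", {
  pe <- prediction_errors(c(1.7, 1.9, 1.8), c(1.8, 1.8, 1.8))
  expect_equal(pe$mean, mean(c(-0.1, 0.1, 0)))
  expect_equal(pe$sd, sd(c(-0.1, 0.1, 0)))
  same <- prediction_errors(c(1.5, 1.6), c(1.5, 1.6))
  expect_equal(same$mean, 0)
  expect_equal(same$sd, 0)
  expect_error(prediction_errors(1:3, 1:4), "length")
  expect_error(prediction_errors(1, 1), "at least 2")
})

test_that("calibration is OLS per sex with zero-mean residuals", {
  d <- make_cal_data()
  fit <- pal_calibration(pal_meas ~ pal_pred, d)
  cf <- coef(fit)
  expect_setequal(rownames(cf), c("F", "M"))

  for (g in c("F", "M")) {
    dg <- d[d$sex == g, ]
    ref <- lm(pal_meas ~ pal_pred, dg)
    expect_equal(cf[g, "slope"], unname(coef(ref)[2]), tolerance = 1e-12)
    expect_equal(cf[g, "intercept"], unname(coef(ref)[1]),
                 tolerance = 1e-12)
    # closed-form cross-check, independent of lm
    b <- cov(dg$pal_pred, dg$pal_meas) / var(dg$pal_pred)
    expect_equal(cf[g, "slope"], b, tolerance = 1e-12)
    expect_equal(cf[g, "intercept"],
                 mean(dg$pal_meas) - b * mean(dg$pal_pred),
                 tolerance = 1e-12)
  }
  # residual mean zero and orthogonal to X at machine precision
  res <- residuals(fit)
  expect_lt(abs(mean(res)), 1e-12)
  xs <- unlist(lapply(fit$models, `[[`, "x"))
  expect_lt(abs(sum(res * xs)) / length(res), 1e-10)

  expect_error(pal_calibration(pal_meas ~ pal_pred, d[1:4, ]),
               "at least 3")
  dd <- d; dd$pal_pred <- 1.5
  expect_error(pal_calibration(pal_meas ~ pal_pred, dd), "zero variance")
})

test_that("calibration methods predict, simulate and print coherently", {
  d <- make_cal_data(60, seed = 12)
  fit <- pal_calibration(pal_meas ~ pal_pred, d)
  # predict on new data uses the right sex-specific line
  nd <- data.frame(sex = c("F", "M"), pal_pred = c(1.71, 1.61))
  cf <- coef(fit)
  expect_equal(predict(fit, nd),
               unname(cf[c("F", "M"), "intercept"] +
                      cf[c("F", "M"), "slope"] * c(1.71, 1.61)))
  expect_error(predict(fit, data.frame(sex = "X", pal_pred = 1.5)),
               "no fitted correction")
  expect_error(predict(fit, data.frame(sex = "F")), "predictor")

  # correct_pal dispatches on the calibration object too
  expect_equal(correct_pal(1.71, fit, sex = "F"), predict(fit, nd)[1])

  # simulate returns nsim columns of the right length; seeded reproducibly
  s1 <- simulate(fit, nsim = 3, seed = 5)
  s2 <- simulate(fit, nsim = 3, seed = 5)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(nrow(d), 3L))

  expect_output(print(fit), "PAL calibration")
  expect_output(print(summary(fit)), "Mean residual")
  cm <- as_correction_models(fit)
  expect_equal(cm$F$slope, cf["F", "slope"])
})

test_that("correlation and t tests behave on canonical inputs", {
  x <- c(1.2, 1.5, 1.9, 2.2)
  expect_equal(pal_correlation(x, x), 1)
  expect_equal(pal_correlation(x, -x), -1)
  expect_error(pal_correlation(x, rep(1, 4)), "zero variance")
  expect_error(pal_correlation(1:2, 1:2), "at least 3")

  # identical paired series: t = 0, p = 1
  ht <- group_compare(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(unname(ht$statistic), 0)
  expect_equal(ht$p.value, 1)
  # hand-computed paired t: diffs (1, 2) -> t = 1.5 / (sqrt(0.5)/sqrt(2)) = 3
  ht2 <- group_compare(c(1, 2), c(0, 0), paired = TRUE)
  expect_equal(unname(ht2$statistic), 3, tolerance = 1e-12)
  expect_error(group_compare(1, 1), "at least 2")
})

test_that("validation report assembles errors, r and the fitted correction", {
  set.seed(99)
  n <- 30
  d <- data.frame(id = sprintf("P%02d", 1:n),
                  sex = rep(c("F", "M"), each = n / 2),
                  bmr_pred = runif(n, 900, 1300))
  d$bmr_meas <- d$bmr_pred * (1 + rnorm(n, 0, 0.05))
  d$pal_pred <- runif(n, 1.4, 1.9)
  d$pal_meas <- 0.95 * d$pal_pred + 0.25 + rnorm(n, 0, 0.1)
  d$pal_nagayoshi <- nagayoshi_adjust(1) * d$pal_pred  # stand-in column
  d$tee_meas <- d$pal_meas * d$bmr_meas

  rep_ <- validation_report(d)
  for (g in c("F", "M")) {
    b <- rep_$by_sex[[g]]
    expect_equal(b$n, n / 2)
    # regression-corrected errors have mean zero on the fitting sample
    expect_lt(abs(b$pal$regression$mean), 1e-12)
    expect_equal(b$correlation,
                 cor(d$pal_pred[d$sex == g], d$pal_meas[d$sex == g]))
    expect_true(all(c("unadjusted", "nagayoshi", "regression_predbmr",
                      "regression_measbmr") %in% names(b$tee)))
  }
  lst <- report_to_list(rep_)
  expect_true(all(c("correction", "by_sex") %in% names(lst)))
  expect_error(validation_report(d[, -3]), "lacks column")
})
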