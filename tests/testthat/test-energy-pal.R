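test_that("Ganpule BMR reproduces tabulated sex means and is linear", {
  # cohort mean anthropometry, women and men
  expect_lt(abs(ganpule_bmr("F", 74, 149.4, 52.5) - 962), 2)
  expect_lt(abs(ganpule_bmr("M", 75, 162.0, 62.7) - 1279), 2)
  # linearity: +1 kg weight adds 0.0481 MJ = 11.49 kcal/day
  d <- ganpule_bmr("F", 74, 149.4, 53.5) - ganpule_bmr("F", 74, 149.4, 52.5)
  expect_equal(d, 0.0481 * 1000 / 4.186, tolerance = 1e-10)
  d_age <- ganpule_bmr("M", 71, 162, 62.7) - ganpule_bmr("M", 70, 162, 62.7)
  expect_equal(d_age, -0.0138 * 1000 / 4.186, tolerance = 1e-10)
  # the sex term is -0.5473 MJ for men, doubled for women
  d_sex <- ganpule_bmr("M", 74, 149.4, 52.5) - ganpule_bmr("F", 74, 149.4, 52.5)
  expect_equal(d_sex, 0.5473 * 1000 / 4.186, tolerance = 1e-10)
  expect_error(ganpule_bmr("F", 74, 149.4, 20), "weight")
  expect_error(ganpule_bmr("F", 12, 149.4, 52.5), "age")
  expect_error(ganpule_bmr("X", 74, 149.4, 52.5), "sex")
})

test_that("daily AEE follows the (METs - 1) x 1.1 BMR convention", {
  expect_equal(daily_aee(rep(1, 1440), 1000), 0)
  expect_equal(daily_aee(rep(2, 1440), 1000), 1100)
  expect_equal(daily_aee(rep(0.9, 1440), 1000), -110)
  # mixed day: closed form on the minute mean
  m <- c(rep(0.9, 480), rep(1.4, 700), rep(3, 260))
  expect_equal(daily_aee(m, 1500),
               sum(m - 1) * 1.1 * 1500 / 1440)
  expect_error(daily_aee(rep(1, 100), 1000), "1440")
  expect_error(daily_aee(rep(1, 1440), 0), "positive")
})

test_that("TEE and PAL formulas and the DIT identity hold", {
  expect_equal(tee_and_pal(1000, 0)$pal, 10 / 9)
  tp <- tee_and_pal(1000, 530)
  expect_equal(tp$tee, 1700)
  expect_equal(tp$pal, 1.7)
  # identities over random inputs: pal * bmr = tee and DIT = TEE / 10
  set.seed(3)
  for (i in 1:25) {
    bmr <- runif(1, 800, 2000); aee <- runif(1, -200, 1500)
    tp <- tee_and_pal(bmr, aee)
    expect_equal(tp$pal * bmr, tp$tee, tolerance = 1e-12)
    expect_equal(tp$tee - (bmr + aee), tp$tee / 10, tolerance = 1e-12)
  }
  expect_error(tee_and_pal(-5, 100), "positive")
})

test_that("PAL correction maps cohort means to the corrected means", {
  w <- correction_model("F", 0.949, 0.205, 0.20)
  m <- correction_model("M", 0.899, 0.371, 0.17)
  expect_equal(round(correct_pal(1.71, w), 2), 1.83)
  expect_equal(round(correct_pal(1.61, m), 2), 1.82)
  # identity model
  expect_equal(correct_pal(1.5, correction_model("F", 1, 0)), 1.5)
  # strictly monotone in X
  x <- seq(1, 2.5, by = 0.1)
  expect_true(all(diff(correct_pal(x, w)) > 0))
  # corrected TEE is the plain product
  expect_equal(corrected_tee(1.828, 962.5), 1.828 * 962.5)
  expect_equal(corrected_tee(10 / 9, 900), 1000)
  expect_equal(corrected_tee(2, 1000), 2000)
  expect_error(corrected_tee(1.8, -10), "positive")
})

test_that("participant energy prediction matches the analytic PAL", {
  # noiseless constructed participant: 900 wear minutes at 1.8 METs/day
  mets_day <- c(rep(0.9, 540), rep(1.8, 900))
  wear_day <- c(rep(FALSE, 540), rep(TRUE, 900))
  minutes <- do.call(rbind, lapply(1:4, function(d)
    data.frame(day = d, minute_of_day = 0:1439, mets = mets_day,
               wear = wear_day)))
  anthro <- list(sex = "F", age_y = 74, stature_cm = 149.4, weight_kg = 52.5)
  pe <- participant_energy(minutes, anthro)
  expect_true(pe$retained)
  expect_equal(pe$n_valid, 4)
  mbar <- mean(mets_day)
  pal_analytic <- (10 / 9) * (1 + 1.1 * (mbar - 1))
  expect_lt(abs(pe$energy$pal_pred - pal_analytic), 0.01)
  expect_equal(pe$energy$bmr_pred, ganpule_bmr("F", 74, 149.4, 52.5))
  # adjusted PAL exceeds unadjusted (slope > 1, positive intercept)
  expect_gt(pe$energy$pal_nagayoshi, pe$energy$pal_pred)

  # wear below 600 min on every day -> participant excluded, no error
  short <- minutes
  short$wear <- rep(c(rep(FALSE, 900), rep(TRUE, 540)), 4)
  pe2 <- participant_energy(short, anthro)
  expect_false(pe2$retained)
  expect_null(pe2$energy)
})
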