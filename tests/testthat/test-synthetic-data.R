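test_that("schedules validate their inputs", {
  expect_error(activity_segment("swimming", 60), "unknown segment kind")
  expect_error(activity_segment("non_wear", 60, amplitude = 10), "amplitude")
  expect_error(gen_activity_signal(list(), seed = 1), "non-empty")
})

test_that("non-wear schedules give identically zero, reproducible signals", {
  s1 <- gen_activity_signal(list(activity_segment("non_wear", 3600)), seed = 4)
  expect_true(all(s1$axes == 0))
  # bit-identical reproduction under the same seed
  sched <- list(seg_min("sedentary", 2), seg_min("locomotive", 2))
  a <- gen_activity_signal(sched, seed = 9)
  b <- gen_activity_signal(sched, seed = 9)
  expect_identical(a$axes, b$axes)
  c_ <- gen_activity_signal(sched, seed = 10)
  expect_false(identical(a$axes, c_$axes))
  # quantized to the 3 mG grid
  expect_true(all(a$axes %% 3 == 0))
})

test_that("generated segments land on their designed side of the thresholds", {
  for (s in c(1, 2)) {
    for (kind in c("sedentary", "locomotive", "non_locomotive")) {
      sig <- gen_activity_signal(list(seg_min(kind, 5)), seed = s)
      ep <- process_signal(sig)
      expect_true(all(ep$activity_class == kind),
                  label = paste(kind, "seed", s))
    }
  }
  # the derived guarantee: one locomotive segment (200 mG, 2 Hz, 600 s)
  sig <- gen_activity_signal(
    list(activity_segment("locomotive", 600, amplitude = 200,
                          fundamental_freq = 2)), seed = 1)
  ep <- process_signal(sig)
  expect_equal(nrow(ep), 60L)
  expect_true(all(ep$activity_class == "locomotive"))
})

test_that("cohort generation is seeded, validated and respects truncation", {
  expect_error(cohort_spec(n_women = 0, n_men = 0), "at least 1")
  spec <- cohort_spec(n_women = 12, n_men = 6, n_days = 3, seed = 21)
  a <- gen_cohort(spec)
  b <- gen_cohort(spec)
  expect_identical(a$participants, b$participants)
  expect_identical(a$minutes, b$minutes)

  p <- a$participants
  expect_equal(nrow(p), 18L)
  expect_equal(sum(p$sex == "F"), 12L)
  w <- p[p$sex == "F", ]
  expect_true(all(abs(w$age_y - 74) <= 3 * 6))
  expect_true(all(abs(w$weight_kg - 52.5) <= 3 * 9.8 & w$weight_kg >= 25))
  # measured PAL = TEE / BMR by construction
  expect_equal(p$measured_tee_kcal_d / p$measured_bmr_kcal_d,
               a$truth$pal_meas, tolerance = 1e-12)
})

test_that("zero-SD women cohort reproduces the hand-computed Ganpule BMR", {
  spec <- cohort_spec(n_women = 5, n_men = 0, seed = 2,
                      women = list(age = c(74, 0), stature = c(149.4, 0),
                                   weight = c(52.5, 0)))
  coh <- gen_cohort(spec, keep_minutes = FALSE)
  hand <- (0.1238 + 0.0481 * 52.5 + 0.0234 * 149.4 - 0.0138 * 74 -
             0.5473 * 2) * 1000 / 4.186
  expect_equal(coh$truth$bmr_pred, rep(hand, 5), tolerance = 1e-12)
})

test_that("noiseless cohorts recover the generating line exactly", {
  spec <- cohort_spec(n_women = 20, n_men = 0, seed = 5, bmr_cv = 0,
                      women = list(resid_sd = 0))
  coh <- gen_cohort(spec, keep_minutes = FALSE)
  fit <- pal_calibration(pal_meas ~ pal_pred, coh$truth, sex = "sex")
  expect_equal(coef(fit)["F", "slope"], 0.949, tolerance = 1e-10)
  expect_equal(coef(fit)["F", "intercept"], 0.205, tolerance = 1e-10)
})

test_that("every generated day conserves wear + non-wear = 1440 minutes", {
  coh <- gen_cohort(cohort_spec(n_women = 3, n_men = 2, n_days = 4,
                                seed = 13))
  for (m in coh$minutes) {
    per_day <- table(m$day)
    expect_true(all(per_day == 1440))
    wear <- tapply(m$wear, m$day, sum)
    nonwear <- tapply(!m$wear, m$day, sum)
    expect_true(all(wear + nonwear == 1440))
    expect_true(all(wear >= 600))  # generated days are wearable days
  }
})

test_that("generator minute streams agree with the full pipeline PAL", {
  coh <- gen_cohort(cohort_spec(n_women = 3, n_men = 1, n_days = 3,
                                seed = 31))
  for (i in seq_len(nrow(coh$participants))) {
    p <- coh$participants[i, ]
    pe <- participant_energy(coh$minutes[[p$id]], p)
    expect_true(pe$retained)
    expect_equal(pe$energy$pal_pred, coh$truth$pal_pred[i],
                 tolerance = 1e-12)
  }
})
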