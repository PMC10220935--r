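#' Specification of a synthetic validation cohort
#'
#' Describes a cohort of older adults with sex-specific anthropometry
#' distributions and a known linear relation between the device-predicted
#' PAL and the "measured" (reference) PAL, used to generate ground-truth
#' data for every downstream stage.  Defaults mirror a community-dwelling
#' older Japanese cohort: 47 women (age 74 +/- 6 y, stature 149.4 +/- 6.6
#' cm, weight 52.5 +/- 9.8 kg) and 22 men (75 +/- 5 y, 162.0 +/- 4.8 cm,
#' 62.7 +/- 9.4 kg), with true correction lines Y = 0.949 X + 0.205
#' (residual SD 0.20) for women and Y = 0.899 X + 0.371 (residual SD 0.17)
#' for men, a 7% CV on measured BMR, and 14 monitored days per participant.
#'
#' @param n_women,n_men participant counts (n_women + n_men >= 1).
#' @param women,men optional named lists overriding the per-sex defaults;
#'   recognized elements: `age`, `stature`, `weight` (each `c(mean, sd)`),
#'   `slope`, `intercept`, `resid_sd`.
#' @param bmr_cv coefficient of variation of the multiplicative measured-
#'   BMR noise (default 0.07, typical indirect-calorimetry repeatability).
#' @param n_days monitored days per participant (default 14).
#' @param seed integer seed; all randomness in [gen_cohort()] flows from
#'   it.
#' @return A list of class `cohort_spec`.
#' @examples
#' cohort_spec(n_women = 10, n_men = 0, seed = 7)
#' @export
cohort_spec <- function(n_women = 47, n_men = 22,
                        women = list(), men = list(),
                        bmr_cv = 0.07, n_days = 14, seed = 1) {
  stopifnot(n_women >= 0, n_men >= 0, bmr_cv >= 0, n_days >= 1)
  if (n_women + n_men == 0) stop("cohort must contain at least 1 participant")
  def_w <- list(age = c(74, 6), stature = c(149.4, 6.6),
                weight = c(52.5, 9.8),
                slope = 0.949, intercept = 0.205, resid_sd = 0.20)
  def_m <- list(age = c(75, 5), stature = c(162.0, 4.8),
                weight = c(62.7, 9.4),
                slope = 0.899, intercept = 0.371, resid_sd = 0.17)
  women <- utils::modifyList(def_w, women)
  men <- utils::modifyList(def_m, men)
  for (s in list(women, men))
    stopifnot(s$age[2] >= 0, s$stature[2] >= 0, s$weight[2] >= 0,
              s$slope > 0, s$resid_sd >= 0)
  structure(list(n_women = n_women, n_men = n_men, women = women,
                 men = men, bmr_cv = bmr_cv, n_days = n_days,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# normal draw truncated at +/- 3 SD, intersected with a physiological
# range (rejection sampling; avoids nonphysical values)
.rnorm_trunc3 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  lo <- max(lo, mean - 3 * sd); hi <- min(hi, mean + 3 * sd)
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Minute-level activity schedule for one participant.
# A latent activity propensity z shifts the sedentary and MVPA fractions
# and the typical light-activity intensity, producing realistic
# between-participant dispersion of the predicted PAL (~0.19 SD); a
# contiguous sleep/off block at the start of each day supplies the
# non-wear time.
.gen_minute_days <- function(n_days, z) {
  wear_target <- .clip(stats::rnorm(1, 930, 60), 700, 1100)
  sed_frac <- .clip(0.63 - 0.12 * z, 0.30, 0.90)
  mvpa_frac <- .clip(0.05 + 0.04 * z, 0, 0.20)
  light_center <- .clip(2.25 + 0.15 * z, 1.7, 2.8)

  days <- lapply(seq_len(n_days), function(d) {
    wear_d <- as.integer(round(.clip(wear_target + stats::rnorm(1, 0, 40),
                                     620, 1200)))
    sf <- .clip(sed_frac + stats::rnorm(1, 0, 0.03), 0.20, 0.95)
    mf <- .clip(mvpa_frac + stats::rnorm(1, 0, 0.015), 0, 0.25)
    if (sf + mf > 0.98) mf <- 0.98 - sf
    n_sed <- as.integer(round(wear_d * sf))
    n_mvpa <- as.integer(round(wear_d * mf))
    n_light <- wear_d - n_sed - n_mvpa
    mets_wear <- c(stats::runif(n_sed, 0.9, 1.5),
                   stats::runif(n_light, light_center - 0.5,
                                light_center + 0.5),
                   stats::runif(n_mvpa, 3.0, 4.2))
    n_off <- 1440L - wear_d
    data.frame(day = d,
               minute_of_day = 0:1439,
               mets = c(rep(0.9, n_off), mets_wear),
               wear = c(rep(FALSE, n_off), rep(TRUE, wear_d)))
  })
  do.call(rbind, days)
}

# per-day PAL from a full minute stream; arithmetic identical to
# impute_nonwear + daily_aee + tee_and_pal (non-wear minutes already 0.9;
# BMR cancels out of PAL so it is not needed here)
.fast_pal <- function(minutes, energy = energy_params()) {
  daily_mean <- tapply(minutes$mets, minutes$day, mean)
  pal_day <- energy$dit_factor * (1 + energy$rmr_factor * (daily_mean - 1))
  mean(pal_day)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws anthropometry from sex-specific normal distributions truncated at
#' +/- 3 SD, builds each participant's minute-by-minute MET stream from a
#' random daily schedule, runs the energy model to obtain the
#' device-predicted PAL, and generates the "measured" quantities standing
#' in for calorimetry and doubly-labeled water: measured PAL =
#' `slope * pal_pred + intercept + N(0, resid_sd)`; measured BMR = the
#' Ganpule prediction perturbed by multiplicative noise (CV `bmr_cv`);
#' measured TEE = measured PAL x measured BMR exactly.
#'
#' @param spec a [cohort_spec()].
#' @param keep_minutes retain each participant's minute-level stream
#'   (default TRUE; set FALSE in large Monte-Carlo loops to save memory).
#' @return A list of class `synthetic_cohort`: `participants` (data.frame
#'   in the cohort CSV schema: `id`, `sex`, `age_y`, `stature_cm`,
#'   `weight_kg`, `measured_bmr_kcal_d`, `measured_tee_kcal_d`), `truth`
#'   (data.frame with the generating `pal_pred`, noise draw `eps`,
#'   `pal_meas`, `bmr_pred`), `minutes` (named list of per-participant
#'   minute data.frames, or NULL), and `spec`.
#' @examples
#' coh <- gen_cohort(cohort_spec(n_women = 5, n_men = 0, seed = 3))
#' coh$participants
#' @export
gen_cohort <- function(spec, keep_minutes = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  energy <- energy_params()

  gen_sex <- function(n, sex, pars, id0) {
    if (n == 0) return(NULL)
    age <- .rnorm_trunc3(n, pars$age[1], pars$age[2], 18, 110)
    stature <- .rnorm_trunc3(n, pars$stature[1], pars$stature[2], 100, 220)
    weight <- .rnorm_trunc3(n, pars$weight[1], pars$weight[2], 25, 200)
    bmr_pred <- ganpule_bmr(sex, age, stature, weight)
    z <- stats::rnorm(n)
    minutes <- vector("list", n)
    pal_pred <- numeric(n)
    for (i in seq_len(n)) {
      m <- .gen_minute_days(spec$n_days, z[i])
      pal_pred[i] <- .fast_pal(m, energy)
      if (keep_minutes) minutes[[i]] <- m
    }
    eps <- stats::rnorm(n, 0, pars$resid_sd)
    pal_meas <- pars$slope * pal_pred + pars$intercept + eps
    bmr_meas <- bmr_pred *
      (1 + .clip(stats::rnorm(n, 0, spec$bmr_cv), -3 * spec$bmr_cv,
                 3 * spec$bmr_cv))
    id <- sprintf("P%03d", id0 + seq_len(n))
    list(participants = data.frame(
           id = id, sex = sex, age_y = age, stature_cm = stature,
           weight_kg = weight,
           measured_bmr_kcal_d = bmr_meas,
           measured_tee_kcal_d = pal_meas * bmr_meas),
         truth = data.frame(id = id, sex = sex, z = z,
                            pal_pred = pal_pred, eps = eps,
                            pal_meas = pal_meas, bmr_pred = bmr_pred),
         minutes = stats::setNames(minutes, id))
  }

  w <- gen_sex(spec$n_women, "F", spec$women, 0L)
  m <- gen_sex(spec$n_men, "M", spec$men, spec$n_women)
  parts <- rbind(w$participants, m$participants)
  truth <- rbind(w$truth, m$truth)
  minutes <- if (keep_minutes) c(w$minutes, m$minutes) else NULL
  structure(list(participants = parts, truth = truth, minutes = minutes,
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d women, %d men, %d days each (seed %d)\n",
              x$spec$n_women, x$spec$n_men, x$spec$n_days, x$spec$seed))
  invisible(x)
}
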