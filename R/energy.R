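#' Predicted basal metabolic rate (Ganpule equation)
#'
#' Evaluates the Ganpule predictive equation for Japanese adults:
#' `BMR[MJ/day] = 0.1238 + 0.0481*weight(kg) + 0.0234*stature(cm)
#'  - 0.0138*age(y) - 0.5473*s`, with `s = 1` for men and `s = 2` for
#' women, converted to kcal/day by `* 1000 / 4.186`.
#'
#' @param sex `"F"` or `"M"` (vectorized with the other arguments).
#' @param age_y age in years (18-110).
#' @param stature_cm stature in cm (100-220).
#' @param weight_kg body weight in kg (25-200).
#' @return Predicted BMR in kcal/day.
#' @examples
#' ganpule_bmr("F", 74, 149.4, 52.5)  # about 962.5 kcal/day
#' @export
ganpule_bmr <- function(sex, age_y, stature_cm, weight_kg) {
  n <- max(length(sex), length(age_y), length(stature_cm), length(weight_kg))
  sex <- rep_len(sex, n); age_y <- rep_len(age_y, n)
  stature_cm <- rep_len(stature_cm, n); weight_kg <- rep_len(weight_kg, n)
  if (!all(sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (any(age_y < 18 | age_y > 110)) stop("age_y outside 18..110")
  if (any(stature_cm < 100 | stature_cm > 220))
    stop("stature_cm outside 100..220")
  if (any(weight_kg < 25 | weight_kg > 200))
    stop("weight_kg outside 25..200")
  s <- ifelse(sex == "M", 1, 2)
  mj <- 0.1238 + 0.0481 * weight_kg + 0.0234 * stature_cm -
    0.0138 * age_y - 0.5473 * s
  mj * 1000 / 4.186
}

#' Daily activity energy expenditure from minute METs
#'
#' `AEE = sum over the 1440 minutes of (METs - 1) * RMR_per_minute`, with
#' the resting metabolic rate `RMR = rmr_factor * BMR` (default 1.1).
#' Minutes below 1 MET (for instance imputed 0.9-MET non-wear minutes)
#' contribute negatively and are retained.
#'
#' @param mets numeric vector of exactly `minutes_per_day` (default 1440)
#'   minute METs for one imputed day.
#' @param bmr_pred predicted BMR in kcal/day (> 0).
#' @param p an [energy_params()].
#' @return AEE in kcal/day (may be negative for a near-resting day).
#' @examples
#' daily_aee(rep(2, 1440), 1000)  # 1100
#' @export
daily_aee <- function(mets, bmr_pred, p = energy_params()) {
  stopifnot(inherits(p, "energy_params"))
  if (length(mets) != p$minutes_per_day)
    stop("need exactly ", p$minutes_per_day, " minute METs, got ",
         length(mets))
  if (anyNA(mets)) stop("mets contains missing values")
  if (bmr_pred <= 0) stop("bmr_pred must be positive")
  sum(mets - 1) * p$rmr_factor * bmr_pred / p$minutes_per_day
}

#' Total energy expenditure and physical activity level
#'
#' `TEE = (BMR + AEE) * 10/9` (diet-induced thermogenesis is one tenth of
#' TEE) and `PAL = TEE / BMR`.
#'
#' @param bmr_pred predicted BMR, kcal/day (> 0).
#' @param aee_pred predicted AEE, kcal/day.
#' @param p an [energy_params()].
#' @return A list with `tee` (kcal/day) and `pal` (dimensionless).
#' @examples
#' tee_and_pal(1000, 530)  # tee 1700, pal 1.7
#' @export
tee_and_pal <- function(bmr_pred, aee_pred, p = energy_params()) {
  stopifnot(inherits(p, "energy_params"))
  if (any(bmr_pred <= 0)) stop("bmr_pred must be positive")
  tee <- (bmr_pred + aee_pred) * p$dit_factor
  list(tee = tee, pal = tee / bmr_pred)
}

#' Apply a sex-specific PAL correction
#'
#' Maps a device-predicted PAL to the corrected (reference-scale) PAL with
#' the linear model `Y = slope * X + intercept`.
#'
#' @param pal_pred device-predicted PAL (vectorized).
#' @param model a [correction_model()], or a fitted [pal_calibration()]
#'   together with `sex`.
#' @param sex participant sex, required when `model` is a
#'   `pal_calibration` holding several sex-specific fits.
#' @return Corrected PAL.
#' @examples
#' correct_pal(1.71, correction_model("F", 0.949, 0.205))  # 1.82779
#' @export
correct_pal <- function(pal_pred, model, sex = NULL) {
  if (inherits(model, "pal_calibration")) {
    if (is.null(sex)) stop("sex is required with a pal_calibration model")
    cf <- coef(model)
    sex <- rep_len(as.character(sex), length(pal_pred))
    missing_sex <- setdiff(unique(sex), rownames(cf))
    if (length(missing_sex))
      stop("no fitted correction for sex: ",
           paste(missing_sex, collapse = ", "))
    return(cf[sex, "intercept"] + cf[sex, "slope"] * pal_pred)
  }
  stopifnot(inherits(model, "correction_model"))
  if (!is.null(sex) && any(rep_len(as.character(sex),
                                   length(pal_pred)) != model$sex))
    stop("correction model is for sex ", model$sex)
  model$slope * pal_pred + model$intercept
}

#' TEE from a corrected PAL
#'
#' `TEE = PAL_corrected * BMR`; the caller chooses predicted or measured
#' BMR.
#'
#' @param pal_corrected corrected PAL.
#' @param bmr BMR in kcal/day (> 0).
#' @return TEE in kcal/day.
#' @export
corrected_tee <- function(pal_corrected, bmr) {
  if (any(bmr <= 0)) stop("bmr must be positive")
  pal_corrected * bmr
}

#' Predict the full energy stack for one participant
#'
#' Runs the per-participant half of the pipeline: minute METs are split by
#' day, non-wear detected and imputed, valid days selected
#' (wear >= 600 min; participant retained with >= 3 valid days), and AEE,
#' TEE and PAL computed per valid day and averaged with equal day weights.
#' A Nagayoshi-adjusted PAL is computed in parallel by adjusting observed
#' (wear) minute METs only — imputed non-wear minutes stay at the 0.9-MET
#' calibration constant.
#'
#' @param minutes data.frame with columns `day` (integer), `minute_of_day`,
#'   `mets`, and either `wear` (logical) or `zero` (zero-count flags from
#'   which wear is detected).
#' @param anthro one-row data.frame or list with `sex`, `age_y`,
#'   `stature_cm`, `weight_kg`.
#' @param params an [asp_params()] (unused here beyond defaults; kept for
#'   interface symmetry).
#' @param rules a [wear_rules()].
#' @param energy an [energy_params()].
#' @param nagayoshi a [nagayoshi_model()].
#' @param cutoffs an [intensity_cutoffs()].
#' @return A list: `retained` (logical), `n_valid`, `days` (per-day
#'   summaries), and when retained a one-row data.frame `energy` with
#'   `bmr_pred`, `aee_pred`, `tee_pred`, `pal_pred`, `pal_nagayoshi`.
#' @export
participant_energy <- function(minutes, anthro,
                               params = asp_params(),
                               rules = wear_rules(),
                               energy = energy_params(),
                               nagayoshi = nagayoshi_model(),
                               cutoffs = intensity_cutoffs()) {
  stopifnot(is.data.frame(minutes),
            all(c("day", "minute_of_day", "mets") %in% names(minutes)))
  if (!"wear" %in% names(minutes)) {
    if (!"zero" %in% names(minutes))
      stop("minutes needs a 'wear' or 'zero' column")
    minutes$wear <- unlist(lapply(split(minutes$zero, minutes$day),
                                  detect_nonwear, rules = rules),
                           use.names = FALSE)
  }
  bmr_pred <- ganpule_bmr(anthro$sex, anthro$age_y, anthro$stature_cm,
                          anthro$weight_kg)

  per_day <- lapply(split(minutes, minutes$day), function(d) {
    imp <- impute_nonwear(d[c("minute_of_day", "mets", "wear")], rules)
    smry <- day_summary(imp, rules, cutoffs)
    aee <- daily_aee(imp$mets, bmr_pred, energy)
    tp <- tee_and_pal(bmr_pred, aee, energy)
    adj <- imp$mets
    adj[imp$wear] <- nagayoshi_adjust(adj[imp$wear], nagayoshi)
    tp_adj <- tee_and_pal(bmr_pred, daily_aee(adj, bmr_pred, energy), energy)
    cbind(smry, aee = aee, tee = tp$tee, pal = tp$pal,
          pal_adj = tp_adj$pal)
  })
  days <- do.call(rbind, per_day)
  days$day <- as.integer(names(per_day))
  sel <- select_valid(days, rules)

  out <- list(retained = sel$retained, n_valid = sel$n_valid,
              days = sel$days)
  if (sel$retained) {
    vd <- sel$valid_days
    out$energy <- data.frame(
      bmr_pred = bmr_pred,
      aee_pred = mean(vd$aee),
      tee_pred = mean(vd$tee),
      pal_pred = mean(vd$pal),
      pal_nagayoshi = mean(vd$pal_adj))
  }
  out
}
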