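#' Device and algorithm parameters for the MET classification
#'
#' Constants of the epoch classification and MET assignment used by the
#' Active style Pro family of waist-worn triaxial accelerometers: the
#' sedentary threshold on the filtered synthesized acceleration, the
#' unfiltered/filtered ratio separating non-locomotive from locomotive
#' activity, and the three linear MET equations, together with the signal
#' settings (sampling rate, resolution, high-pass cutoff, epoch length).
#'
#' @param sed_threshold mG; epochs with filtered synthesized acceleration at
#'   or below this value are sedentary (default 29.9).
#' @param ratio_threshold dimensionless; unfiltered/filtered ratio at or
#'   above which a non-sedentary epoch is non-locomotive (default 1.16).
#' @param sed_coef,nonloc_coef,loc_coef numeric length 2, `c(intercept,
#'   slope)` of `MET = intercept + slope * ACfil` for the three activity
#'   classes (METs and METs/mG).
#' @param cutoff Hz; high-pass cutoff removing the gravitational component
#'   (default 0.7).
#' @param epoch_s seconds per epoch (default 10).
#' @param rate Hz; sampling rate (default 32).
#' @param resolution mG; quantization step of the device (default 3).
#' @return A list of class `asp_params`.
#' @examples
#' p <- asp_params()
#' p$sed_threshold
#' @export
asp_params <- function(sed_threshold = 29.9,
                       ratio_threshold = 1.16,
                       sed_coef = c(0.8823, 0.0351),
                       nonloc_coef = c(1.3435, 0.0196),
                       loc_coef = c(1.1128, 0.0086),
                       cutoff = 0.7,
                       epoch_s = 10,
                       rate = 32,
                       resolution = 3) {
  stopifnot(sed_threshold > 0, ratio_threshold > 0,
            length(sed_coef) == 2, length(nonloc_coef) == 2,
            length(loc_coef) == 2,
            sed_coef[2] > 0, nonloc_coef[2] > 0, loc_coef[2] > 0,
            cutoff > 0, epoch_s > 0, rate > 0, resolution >= 0,
            cutoff < rate / 2)
  structure(list(sed_threshold = sed_threshold,
                 ratio_threshold = ratio_threshold,
                 sed_coef = sed_coef, nonloc_coef = nonloc_coef,
                 loc_coef = loc_coef, cutoff = cutoff,
                 epoch_s = epoch_s, rate = rate, resolution = resolution),
            class = "asp_params")
}

#' Wear-time rules
#'
#' Rules for non-wear detection, valid-day selection and non-wear MET
#' imputation: at least `nonwear_run_min` consecutive zero-count minutes
#' define a non-wear period, a day needs `valid_day_min` minutes of wear to
#' be valid, a participant needs `min_valid_days` valid days to be retained,
#' and non-wear minutes are imputed at `nonwear_met` METs.
#'
#' @param nonwear_run_min minutes; minimum run of consecutive zero-count
#'   minutes counted as non-wear (default 60).
#' @param valid_day_min minutes of wear required for a valid day (default 600).
#' @param min_valid_days valid days required to retain a participant
#'   (default 3).
#' @param nonwear_met METs imputed to non-wear minutes (default 0.9).
#' @return A list of class `wear_rules`.
#' @export
wear_rules <- function(nonwear_run_min = 60, valid_day_min = 600,
                       min_valid_days = 3, nonwear_met = 0.9) {
  stopifnot(nonwear_run_min > 0, valid_day_min > 0,
            min_valid_days > 0, nonwear_met > 0)
  structure(list(nonwear_run_min = nonwear_run_min,
                 valid_day_min = valid_day_min,
                 min_valid_days = min_valid_days,
                 nonwear_met = nonwear_met),
            class = "wear_rules")
}

#' Energy-model parameters
#'
#' The resting-metabolic-rate factor (RMR = `rmr_factor` x predicted BMR),
#' the diet-induced-thermogenesis factor (TEE = (BMR + AEE) x `dit_factor`,
#' i.e. DIT is one tenth of TEE for the default 10/9), and the minutes in a
#' day.
#'
#' @param rmr_factor dimensionless multiplier from BMR to RMR (default 1.1).
#' @param dit_factor dimensionless TEE inflation factor (default 10/9).
#' @param minutes_per_day minutes in a full day (default 1440).
#' @return A list of class `energy_params`.
#' @export
energy_params <- function(rmr_factor = 1.1, dit_factor = 10 / 9,
                          minutes_per_day = 1440) {
  stopifnot(rmr_factor > 1, dit_factor > 1, minutes_per_day > 0)
  structure(list(rmr_factor = rmr_factor, dit_factor = dit_factor,
                 minutes_per_day = minutes_per_day),
            class = "energy_params")
}

#' Nagayoshi MET adjustment model
#'
#' Affine adjustment of device METs for older adults
#' (`adjusted = slope * METs + intercept`); defaults are the Model-1
#' coefficients of Nagayoshi et al.
#'
#' @param slope dimensionless (default 1.191).
#' @param intercept METs (default 0.106).
#' @return A list of class `nagayoshi_model`.
#' @export
nagayoshi_model <- function(slope = 1.191, intercept = 0.106) {
  stopifnot(slope > 0)
  structure(list(slope = slope, intercept = intercept),
            class = "nagayoshi_model")
}

#' Intensity cut-points
#'
#' MET cut-points partitioning activity into sedentary (METs <= 1.5), light
#' (1.5 < METs < 3) and moderate-to-vigorous (METs >= 3).
#'
#' @param sedentary_max METs; upper bound of sedentary behaviour
#'   (default 1.5).
#' @param mvpa_min METs; lower bound of moderate-to-vigorous activity
#'   (default 3.0).
#' @return A list of class `intensity_cutoffs`.
#' @export
intensity_cutoffs <- function(sedentary_max = 1.5, mvpa_min = 3.0) {
  stopifnot(sedentary_max > 0, mvpa_min > sedentary_max)
  structure(list(sedentary_max = sedentary_max, mvpa_min = mvpa_min),
            class = "intensity_cutoffs")
}

#' Fixed sex-specific PAL correction model
#'
#' A linear map from device-predicted PAL to reference PAL
#' (`Y = slope * X + intercept`) with the residual standard deviation of
#' its fitting sample.  Use [pal_calibration()] to estimate one from data;
#' use this constructor to hold published coefficients.
#'
#' @param sex group label, normally `"F"` or `"M"`.
#' @param slope,intercept coefficients of the linear map.
#' @param resid_sd residual SD of the fit (PAL units).
#' @return A list of class `correction_model`.
#' @examples
#' correction_model("F", 0.949, 0.205, 0.20)
#' @export
correction_model <- function(sex, slope, intercept, resid_sd = NA_real_) {
  stopifnot(is.character(sex), length(sex) == 1)
  stopifnot(is.numeric(slope), slope > 0, is.numeric(intercept),
            is.na(resid_sd) || resid_sd >= 0)
  structure(list(sex = sex, slope = slope, intercept = intercept,
                 resid_sd = resid_sd),
            class = "correction_model")
}
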