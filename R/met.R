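#' Classify an epoch as sedentary, locomotive or non-locomotive
#'
#' Deterministic, total classification of a 10-s epoch from its synthesized
#' filtered and unfiltered accelerations.  An epoch whose filtered
#' acceleration `ac_fil` does not exceed the sedentary threshold (29.9 mG)
#' is sedentary; otherwise the ratio `ac_unfil / ac_fil` at or above 1.16
#' marks non-locomotive (household/postural) activity and below 1.16 marks
#' locomotive (ambulatory) activity.
#'
#' Exactly 29.9 mG is assigned to sedentary: the boundary is not assigned by
#' the published conditionals ("< 29.9" / "> 29.9") and the sedentary and
#' non-locomotive equations differ by less than 0.01 METs there, so the
#' choice is immaterial but must be fixed.  When `ac_fil` is 0 the ratio is
#' undefined; such epochs are sedentary (0 <= 29.9) so the ratio is never
#' evaluated.
#'
#' @param ac_fil,ac_unfil non-negative synthesized accelerations in mG
#'   (vectorized).
#' @param params an [asp_params()].
#' @return A character vector, each element one of `"sedentary"`,
#'   `"locomotive"`, `"non_locomotive"`.
#' @examples
#' classify_epoch(c(10, 100, 100), c(50, 100, 150))
#' @export
classify_epoch <- function(ac_fil, ac_unfil, params = asp_params()) {
  stopifnot(inherits(params, "asp_params"))
  if (length(ac_fil) != length(ac_unfil))
    stop("ac_fil and ac_unfil must have the same length")
  if (anyNA(ac_fil) || anyNA(ac_unfil) || any(ac_fil < 0) || any(ac_unfil < 0))
    stop("accelerations must be non-negative and non-missing")
  out <- rep("non_locomotive", length(ac_fil))
  sed <- ac_fil <= params$sed_threshold
  out[sed] <- "sedentary"
  loco <- !sed & (ac_unfil / ac_fil < params$ratio_threshold)
  out[loco] <- "locomotive"
  out
}

#' MET value of an epoch
#'
#' Evaluates the linear MET equation of the epoch's activity class:
#' sedentary `0.8823 + 0.0351 * ACfil`, non-locomotive
#' `1.3435 + 0.0196 * ACfil`, locomotive `1.1128 + 0.0086 * ACfil`
#' (defaults; METs).
#'
#' @param activity_class character vector of classes from
#'   [classify_epoch()].
#' @param ac_fil filtered synthesized acceleration in mG (vectorized).
#' @param params an [asp_params()].
#' @return Numeric vector of METs, strictly increasing in `ac_fil` within
#'   each class.
#' @examples
#' met_value("sedentary", 0)      # 0.8823
#' met_value("locomotive", 100)   # 1.9728
#' @export
met_value <- function(activity_class, ac_fil, params = asp_params()) {
  stopifnot(inherits(params, "asp_params"))
  if (length(activity_class) == 1L && length(ac_fil) > 1L)
    activity_class <- rep(activity_class, length(ac_fil))
  if (length(activity_class) != length(ac_fil))
    stop("activity_class and ac_fil must have the same length")
  if (anyNA(ac_fil) || any(ac_fil < 0))
    stop("ac_fil must be non-negative and non-missing")
  bad <- !activity_class %in% c("sedentary", "locomotive", "non_locomotive")
  if (any(bad))
    stop("unknown activity class: ", paste(unique(activity_class[bad]),
                                           collapse = ", "))
  cf <- rbind(sedentary = params$sed_coef,
              locomotive = params$loc_coef,
              non_locomotive = params$nonloc_coef)
  unname(cf[activity_class, 1] + cf[activity_class, 2] * ac_fil)
}

#' Adjust METs for older adults (Nagayoshi Model 1)
#'
#' Applies the affine adjustment `adjusted = 1.191 * METs + 0.106`
#' (defaults) mapping device METs calibrated on young adults to older
#' adults.  Monotone (order-preserving) in its input.
#'
#' @param mets numeric vector of METs.
#' @param model a [nagayoshi_model()].
#' @return Numeric vector of adjusted METs.
#' @examples
#' nagayoshi_adjust(1.0)  # 1.297
#' @export
nagayoshi_adjust <- function(mets, model = nagayoshi_model()) {
  stopifnot(inherits(model, "nagayoshi_model"))
  if (anyNA(mets) || any(mets < 0))
    stop("mets must be non-negative and non-missing")
  model$slope * mets + model$intercept
}

#' Intensity category of a MET value
#'
#' Partitions the continuous MET scale into sedentary (METs <= 1.5), light
#' (1.5 < METs < 3) and moderate-to-vigorous (METs >= 3).  The conventional
#' discrete labels "1.6-2.9 METs" for light activity are read as the open
#' interval between the cut-points.
#'
#' @param mets numeric vector of METs (> 0).
#' @param cutoffs an [intensity_cutoffs()].
#' @return Character vector with values `"sedentary"`, `"light"`, `"mvpa"`.
#' @examples
#' intensity_category(c(0.9, 2.0, 3.0))
#' @export
intensity_category <- function(mets, cutoffs = intensity_cutoffs()) {
  stopifnot(inherits(cutoffs, "intensity_cutoffs"))
  if (anyNA(mets) || any(mets <= 0))
    stop("mets must be positive and non-missing")
  out <- rep("light", length(mets))
  out[mets <= cutoffs$sedentary_max] <- "sedentary"
  out[mets >= cutoffs$mvpa_min] <- "mvpa"
  out
}
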