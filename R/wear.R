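#' Aggregate epochs to minute-level METs
#'
#' Each complete minute's METs is the arithmetic mean of its six 10-s epochs
#' (more generally `60 / epoch_s` epochs); incomplete trailing minutes are
#' dropped.  A minute is a "zero-count" minute when every constituent epoch
#' recorded nothing — the `raw_zero` flag from [epochize()] when present
#' (raw samples all exactly zero; immune to filter-edge transients),
#' otherwise both synthesized accelerations exactly zero.  Zero-count
#' minutes are the raw material of non-wear detection.
#'
#' @param epochs data.frame from [process_signal()] (needs `ac_fil`,
#'   `ac_unfil`, `mets`), in temporal order.
#' @param epoch_s epoch length in seconds (default 10).
#' @param start_minute minute-of-day (0-1439) of the first epoch
#'   (default 0).
#' @return data.frame with columns `minute_of_day`, `mets`, `zero`
#'   (logical zero-count flag).
#' @examples
#' ep <- data.frame(ac_fil = rep(0, 12), ac_unfil = 0,
#'                  mets = rep(c(1, 2), each = 6))
#' minute_mets(ep)
#' @export
minute_mets <- function(epochs, epoch_s = 10, start_minute = 0) {
  stopifnot(is.data.frame(epochs),
            all(c("ac_fil", "ac_unfil", "mets") %in% names(epochs)))
  per_min <- 60L %/% as.integer(epoch_s)
  stopifnot(per_min * epoch_s == 60)
  n_min <- nrow(epochs) %/% per_min
  if (n_min == 0L)
    return(data.frame(minute_of_day = integer(), mets = numeric(),
                      zero = logical()))
  used <- seq_len(n_min * per_min)
  idx <- rep(seq_len(n_min), each = per_min)
  mets <- as.numeric(rowsum(epochs$mets[used], idx) / per_min)
  zero_ep <- if ("raw_zero" %in% names(epochs)) epochs$raw_zero[used]
             else epochs$ac_fil[used] == 0 & epochs$ac_unfil[used] == 0
  zero <- as.numeric(rowsum(as.numeric(zero_ep), idx)) == per_min
  data.frame(minute_of_day = start_minute + seq_len(n_min) - 1L,
             mets = mets, zero = zero)
}

#' Detect non-wear minutes
#'
#' Marks every maximal run of at least `nonwear_run_min` (default 60)
#' consecutive zero-count minutes as non-wear; shorter zero runs remain
#' wear.  Minutes must be contiguous within one day — runs are not carried
#' across days.
#'
#' @param zero logical vector of zero-count flags, one per contiguous
#'   minute (see [minute_mets()]).
#' @param rules a [wear_rules()].
#' @return Logical wear mask (`TRUE` = worn), same length as `zero`.
#' @examples
#' detect_nonwear(rep(TRUE, 59))  # all worn: run below threshold
#' @export
detect_nonwear <- function(zero, rules = wear_rules()) {
  stopifnot(inherits(rules, "wear_rules"), is.logical(zero), !anyNA(zero))
  wear <- rep(TRUE, length(zero))
  if (length(zero) == 0L) return(wear)
  r <- rle(zero)
  nonwear_run <- r$values & r$lengths >= rules$nonwear_run_min
  wear[rep(nonwear_run, r$lengths)] <- FALSE
  wear
}

#' Impute non-wear minutes over a full day
#'
#' Expands a day's observed minutes to the complete 1440-minute day:
#' minutes marked non-wear, and minutes with no observation at all, receive
#' the imputed non-wear MET value (default 0.9); wear minutes keep their
#' observed METs.
#'
#' @param minutes data.frame for one day with columns `minute_of_day`
#'   (0-1439, no duplicates), `mets`, and `wear` (logical).
#' @param rules a [wear_rules()].
#' @return data.frame of exactly 1440 rows with columns `minute_of_day`,
#'   `mets`, `wear`.
#' @export
impute_nonwear <- function(minutes, rules = wear_rules()) {
  stopifnot(inherits(rules, "wear_rules"), is.data.frame(minutes),
            all(c("minute_of_day", "mets", "wear") %in% names(minutes)))
  if (anyDuplicated(minutes$minute_of_day))
    stop("duplicated minute_of_day within a day")
  if (any(minutes$minute_of_day < 0 | minutes$minute_of_day > 1439))
    stop("minute_of_day must lie in 0..1439")
  full <- data.frame(minute_of_day = 0:1439,
                     mets = rules$nonwear_met, wear = FALSE)
  at <- minutes$minute_of_day + 1L
  full$wear[at] <- minutes$wear
  full$mets[at] <- ifelse(minutes$wear, minutes$mets, rules$nonwear_met)
  full
}

#' Summarize one imputed day
#'
#' Computes wear time, validity, mean METs over the full day, and intensity
#' minutes.  Intensity minutes are tallied over wear time only: imputed
#' non-wear minutes count toward energy but are not observed behaviour.
#'
#' @param minutes imputed 1440-minute data.frame from [impute_nonwear()].
#' @param rules a [wear_rules()].
#' @param cutoffs an [intensity_cutoffs()].
#' @return One-row data.frame: `wear_min`, `valid`, `mean_mets`, `sed_min`,
#'   `light_min`, `mvpa_min`.
#' @export
day_summary <- function(minutes, rules = wear_rules(),
                        cutoffs = intensity_cutoffs()) {
  stopifnot(nrow(minutes) == 1440)
  wear_min <- sum(minutes$wear)
  wm <- minutes$mets[minutes$wear]
  cat_ <- if (length(wm)) intensity_category(wm, cutoffs) else character()
  data.frame(wear_min = wear_min,
             valid = wear_min >= rules$valid_day_min,
             mean_mets = mean(minutes$mets),
             sed_min = sum(cat_ == "sedentary"),
             light_min = sum(cat_ == "light"),
             mvpa_min = sum(cat_ == "mvpa"))
}

#' Select valid days and decide participant retention
#'
#' A day is valid when its wear time reaches `valid_day_min` minutes
#' (default 600); a participant is retained when at least `min_valid_days`
#' (default 3) days are valid.
#'
#' @param days data.frame of day summaries (needs columns `wear_min` or
#'   `valid`).
#' @param rules a [wear_rules()].
#' @return A list: `days` (input with `valid` recomputed), `valid_days`
#'   (the valid subset), `n_valid`, and `retained` (logical).
#' @export
select_valid <- function(days, rules = wear_rules()) {
  stopifnot(inherits(rules, "wear_rules"), is.data.frame(days),
            nrow(days) >= 1, "wear_min" %in% names(days))
  days$valid <- days$wear_min >= rules$valid_day_min
  n_valid <- sum(days$valid)
  list(days = days, valid_days = days[days$valid, , drop = FALSE],
       n_valid = n_valid, retained = n_valid >= rules$min_valid_days)
}
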