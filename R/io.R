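# CSV interchange formats.  All files are headered UTF-8 CSV with a
# decimal point; readers validate the header and value ranges and report
# the offending line (1-based, counting the header as line 1).

.read_csv_checked <- function(path, required, numeric_cols,
                              colClasses = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = colClasses)
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("malformed header in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  for (cl in numeric_cols) {
    v <- d[[cl]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v))
      if (length(bad))
        stop("parse error in ", path, " line ", bad[1] + 1L,
             ": non-numeric value in column ", cl)
      d[[cl]] <- coerced
    }
    if (anyNA(d[[cl]]))
      stop("parse error in ", path, " line ",
           which(is.na(d[[cl]]))[1] + 1L, ": missing value in column ", cl)
  }
  d
}

#' Read and write raw-signal CSV files
#'
#' Schema: `time_s, ax_mg, ay_mg, az_mg` (header required).  The sampling
#' rate is inferred from the time column and checked for uniformity.
#' Write-then-read round-trips are lossless at the stored precision.
#'
#' @param path file path.
#' @param resolution device resolution metadata in mG (default 3).
#' @return [read_raw_signal()]: a [raw_signal()].
#' @export
read_raw_signal <- function(path, resolution = 3) {
  d <- .read_csv_checked(path, c("time_s", "ax_mg", "ay_mg", "az_mg"),
                         c("time_s", "ax_mg", "ay_mg", "az_mg"))
  if (nrow(d) < 2) stop("signal needs at least 2 samples")
  dt <- diff(d$time_s)
  if (any(abs(dt - dt[1]) > 1e-6))
    stop("non-uniform sampling in ", path)
  raw_signal(d$ax_mg, d$ay_mg, d$az_mg, rate = 1 / dt[1],
             resolution = resolution)
}

#' @rdname read_raw_signal
#' @param signal a [raw_signal()].
#' @export
write_raw_signal <- function(signal, path) {
  stopifnot(inherits(signal, "raw_signal"))
  n <- nrow(signal$axes)
  utils::write.csv(data.frame(time_s = (seq_len(n) - 1) / signal$rate,
                              ax_mg = signal$axes[, 1],
                              ay_mg = signal$axes[, 2],
                              az_mg = signal$axes[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and write epoch-level CSV files
#'
#' Schema: `epoch_index, ac_fil_mg, ac_unfil_mg`, plus any downstream
#' columns (`activity_class`, `mets`, ...) which are carried through.
#'
#' @param path file path.
#' @return [read_epochs()]: data.frame with columns `epoch`, `ac_fil`,
#'   `ac_unfil` (+ extras).
#' @export
read_epochs <- function(path) {
  d <- .read_csv_checked(path, c("epoch_index", "ac_fil_mg", "ac_unfil_mg"),
                         c("epoch_index", "ac_fil_mg", "ac_unfil_mg"))
  if (any(d$ac_fil_mg < 0) || any(d$ac_unfil_mg < 0))
    stop("validation error in ", path, ": negative acceleration at line ",
         which(d$ac_fil_mg < 0 | d$ac_unfil_mg < 0)[1] + 1L)
  out <- data.frame(epoch = d$epoch_index, ac_fil = d$ac_fil_mg,
                    ac_unfil = d$ac_unfil_mg)
  extras <- setdiff(names(d), c("epoch_index", "ac_fil_mg", "ac_unfil_mg"))
  for (cl in extras) out[[cl]] <- d[[cl]]
  out
}

#' @rdname read_epochs
#' @param epochs data.frame from [process_signal()] or [epochize()].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(all(c("epoch", "ac_fil", "ac_unfil") %in% names(epochs)))
  out <- data.frame(epoch_index = epochs$epoch, ac_fil_mg = epochs$ac_fil,
                    ac_unfil_mg = epochs$ac_unfil)
  for (cl in setdiff(names(epochs), c("epoch", "ac_fil", "ac_unfil")))
    out[[cl]] <- epochs[[cl]]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read and write cohort CSV files
#'
#' Schema: `id, sex, age_y, stature_cm, weight_kg, measured_bmr_kcal_d,
#' measured_tee_kcal_d` with `sex` in {F, M}.  Anthropometry is validated
#' against physiological ranges (age 18-110 y, stature 100-220 cm, weight
#' 25-200 kg, positive energies).
#'
#' @param path file path.
#' @return [read_cohort()]: validated data.frame.
#' @export
read_cohort <- function(path) {
  num <- c("age_y", "stature_cm", "weight_kg", "measured_bmr_kcal_d",
           "measured_tee_kcal_d")
  # sex read as character: read.csv would parse an all-"F" column as logical
  d <- .read_csv_checked(path, c("id", "sex", num), num,
                         colClasses = c(id = "character",
                                        sex = "character"))
  if (!all(d$sex %in% c("F", "M")))
    stop("validation error in ", path, " line ",
         which(!d$sex %in% c("F", "M"))[1] + 1L, ": sex must be F or M")
  checks <- list(age_y = c(18, 110), stature_cm = c(100, 220),
                 weight_kg = c(25, 200),
                 measured_bmr_kcal_d = c(1e-9, Inf),
                 measured_tee_kcal_d = c(1e-9, Inf))
  for (cl in names(checks)) {
    bad <- which(d[[cl]] < checks[[cl]][1] | d[[cl]] > checks[[cl]][2])
    if (length(bad))
      stop("validation error in ", path, " line ", bad[1] + 1L,
           ": ", cl, " out of range")
  }
  d
}

#' @rdname read_cohort
#' @param cohort data.frame in the cohort schema (e.g.
#'   `gen_cohort(...)$participants`).
#' @export
write_cohort <- function(cohort, path) {
  need <- c("id", "sex", "age_y", "stature_cm", "weight_kg",
            "measured_bmr_kcal_d", "measured_tee_kcal_d")
  stopifnot(all(need %in% names(cohort)))
  utils::write.csv(cohort[need], path, row.names = FALSE)
  invisible(path)
}
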