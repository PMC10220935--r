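#' One segment of a scripted activity schedule
#'
#' Building block of synthetic raw-signal schedules.  Four kinds are
#' supported, designed to land robustly on the intended side of the
#' classification thresholds:
#' * `sedentary` — white noise (default 5 mG SD), filtered magnitude well
#'   below the 29.9 mG sedentary threshold;
#' * `locomotive` — a sinusoid at `fundamental_freq` (default 2 Hz, above
#'   the 0.7 Hz cutoff) on the vertical axis, so the unfiltered/filtered
#'   ratio stays near 1, below the 1.16 threshold;
#' * `non_locomotive` — the amplitude split between the fundamental and a
#'   0.2 Hz sub-cutoff component (`low_freq_fraction`, default 0.5); the
#'   high-pass filter removes the 0.2 Hz part so the ratio exceeds 1.16;
#' * `non_wear` — exactly zero on all axes.
#'
#' @param kind one of `"sedentary"`, `"locomotive"`, `"non_locomotive"`,
#'   `"non_wear"`.
#' @param duration seconds (> 0).
#' @param amplitude mG; defaults by kind (5, 200, 150, 0).
#' @param fundamental_freq Hz of the periodic component (default 2).
#' @param low_freq_fraction fraction of amplitude in the 0.2 Hz component
#'   of non-locomotive segments (default 0.5).
#' @return A list of class `activity_segment`.
#' @examples
#' activity_segment("locomotive", duration = 600)
#' @export
activity_segment <- function(kind, duration,
                             amplitude = NULL,
                             fundamental_freq = 2,
                             low_freq_fraction = 0.5) {
  kinds <- c("sedentary", "locomotive", "non_locomotive", "non_wear")
  if (!is.character(kind) || length(kind) != 1 || !kind %in% kinds)
    stop("unknown segment kind: ", paste(kind, collapse = ", "))
  if (is.null(amplitude))
    amplitude <- switch(kind, sedentary = 5, locomotive = 200,
                        non_locomotive = 150, non_wear = 0)
  stopifnot(duration > 0, amplitude >= 0,
            fundamental_freq > 0,
            low_freq_fraction >= 0, low_freq_fraction <= 1)
  if (kind == "non_wear" && amplitude != 0)
    stop("non_wear segments must have amplitude 0")
  structure(list(kind = kind, duration = duration, amplitude = amplitude,
                 fundamental_freq = fundamental_freq,
                 low_freq_fraction = low_freq_fraction),
            class = "activity_segment")
}

#' Generate a raw triaxial signal from an activity schedule
#'
#' Synthesizes a 32 Hz three-axis stream in mG, quantized to the device
#' resolution (3 mG).  Worn segments carry a static 1 g gravity offset on
#' the vertical axis plus low-level white noise on all axes; non-wear
#' segments are exactly zero after quantization.  The periodic components
#' are placed on the vertical axis with a random phase.  Deterministic for
#' a fixed seed.
#'
#' @param schedule a list of [activity_segment()]s (non-empty).
#' @param params an [asp_params()] supplying rate and resolution.
#' @param seed integer seed.
#' @param gravity_mg static offset on the vertical axis during worn
#'   segments (default 1000 mG); removed downstream by the filter and the
#'   per-epoch DC subtraction.
#' @param noise_sd white-noise SD in mG on each axis of worn segments
#'   (default 5).
#' @return A [raw_signal()]; attribute `segment` gives each sample's
#'   1-based segment index.
#' @examples
#' sig <- gen_activity_signal(list(activity_segment("non_wear", 600)),
#'                            seed = 1)
#' all(sig$axes == 0)
#' @export
gen_activity_signal <- function(schedule, params = asp_params(), seed = 1,
                                gravity_mg = 1000, noise_sd = 5) {
  if (inherits(schedule, "activity_segment")) schedule <- list(schedule)
  if (!length(schedule)) stop("schedule must be non-empty")
  ok <- vapply(schedule, inherits, logical(1), "activity_segment")
  if (!all(ok)) stop("schedule must be a list of activity_segment objects")
  stopifnot(inherits(params, "asp_params"))
  set.seed(as.integer(seed))
  rate <- params$rate

  gen_seg <- function(seg) {
    n <- as.integer(round(seg$duration * rate))
    if (seg$kind == "non_wear")
      return(matrix(0, n, 3))
    t <- (seq_len(n) - 1) / rate
    ax <- stats::rnorm(n, 0, noise_sd)
    ay <- stats::rnorm(n, 0, noise_sd)
    az <- stats::rnorm(n, 0, noise_sd) + gravity_mg
    if (seg$kind == "locomotive") {
      az <- az + seg$amplitude *
        sin(2 * pi * seg$fundamental_freq * t + stats::runif(1, 0, 2 * pi))
    } else if (seg$kind == "non_locomotive") {
      hi <- seg$amplitude * (1 - seg$low_freq_fraction)
      lo <- seg$amplitude * seg$low_freq_fraction
      az <- az +
        hi * sin(2 * pi * seg$fundamental_freq * t +
                   stats::runif(1, 0, 2 * pi)) +
        lo * sin(2 * pi * 0.2 * t + stats::runif(1, 0, 2 * pi))
    }
    cbind(ax, ay, az)
  }

  mats <- lapply(schedule, gen_seg)
  axes <- do.call(rbind, mats)
  if (params$resolution > 0)
    axes <- round(axes / params$resolution) * params$resolution
  out <- raw_signal(axes[, 1], axes[, 2], axes[, 3], rate = rate,
                    resolution = params$resolution)
  attr(out, "segment") <- rep(seq_along(schedule),
                              vapply(mats, nrow, integer(1)))
  out
}

#' Map complete epochs to the schedule segment that contains them
#'
#' Utility for checking generated signals: returns, for each complete
#' epoch, the index of the segment it lies in, or `NA` when the epoch
#' straddles a segment boundary.
#'
#' @param signal output of [gen_activity_signal()] (carries the `segment`
#'   attribute).
#' @param epoch_s epoch length in seconds (default 10).
#' @return Integer vector, one element per complete epoch.
#' @export
epoch_segments <- function(signal, epoch_s = 10) {
  seg <- attr(signal, "segment")
  if (is.null(seg)) stop("signal carries no segment attribute")
  n_per <- as.integer(round(epoch_s * signal$rate))
  n_ep <- length(seg) %/% n_per
  vapply(seq_len(n_ep), function(i) {
    s <- seg[((i - 1) * n_per + 1):(i * n_per)]
    if (length(unique(s)) == 1L) s[1] else NA_integer_
  }, integer(1))
}
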