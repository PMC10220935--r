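#' Raw triaxial acceleration signal
#'
#' Container for a three-axis acceleration stream in mG sampled at a fixed
#' rate.  All three axes must have equal length.
#'
#' @param ax,ay,az numeric vectors of per-axis acceleration in mG.
#' @param rate sampling rate in Hz (default 32).
#' @param resolution device quantization step in mG (default 3); recorded as
#'   metadata, not applied.
#' @return A list of class `raw_signal` with elements `axes` (n x 3 matrix),
#'   `rate` and `resolution`.
#' @examples
#' s <- raw_signal(rnorm(64), rnorm(64), rnorm(64) + 1000)
#' nrow(s$axes)
#' @export
raw_signal <- function(ax, ay, az, rate = 32, resolution = 3) {
  if (length(ax) != length(ay) || length(ay) != length(az))
    stop("all three axes must have the same length")
  stopifnot(rate > 0, resolution >= 0)
  axes <- cbind(ax = as.numeric(ax), ay = as.numeric(ay),
                az = as.numeric(az))
  if (anyNA(axes)) stop("signal contains missing values")
  structure(list(axes = axes, rate = rate, resolution = resolution),
            class = "raw_signal")
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("raw triaxial signal: %d samples at %g Hz (%.1f s), %g mG resolution\n",
              nrow(x$axes), x$rate, nrow(x$axes) / x$rate, x$resolution))
  invisible(x)
}

#' Quantize a signal to the device resolution
#'
#' Rounds each sample to the nearest multiple of `resolution` mG, emulating
#' the device's analog-to-digital step.
#'
#' @param signal a [raw_signal()].
#' @param resolution mG; defaults to the signal's own resolution.
#' @return A `raw_signal` with quantized axes.
#' @export
quantize_signal <- function(signal, resolution = signal$resolution) {
  stopifnot(inherits(signal, "raw_signal"))
  if (resolution > 0)
    signal$axes <- round(signal$axes / resolution) * resolution
  signal
}

#' High-pass filter a triaxial signal
#'
#' Removes the gravitational (DC and very-low-frequency) component from each
#' axis with a 4th-order Butterworth high-pass filter applied
#' forward-backward (zero phase).  Zero-phase filtering avoids class-boundary
#' artifacts from phase lag when the filtered and unfiltered paths are later
#' compared epoch by epoch.
#'
#' Each maximal contiguous bout of recorded signal (samples where not all
#' three axes are zero) is filtered independently, with its mean removed
#' first: all-zero stretches are periods with nothing recorded, and
#' filtering across them would smear a spurious ~1 g step transient from
#' the wear boundaries into the zero region and the adjacent epochs.
#' Mean-removal before filtering is neutral for an ideal high-pass filter
#' and shrinks the start/end transients.  Bouts too short to filter
#' stably (under about one second) are only mean-centered.
#'
#' @param signal a [raw_signal()].
#' @param cutoff cutoff frequency in Hz (default 0.7); must lie strictly
#'   inside (0, rate/2).
#' @param order filter order (default 4).
#' @return A `raw_signal` containing the filtered axes.
#' @examples
#' s <- raw_signal(rep(500, 320), rep(0, 320), rep(1000, 320))
#' f <- highpass_filter(s)
#' max(abs(f$axes))  # DC removed
#' @export
highpass_filter <- function(signal, cutoff = 0.7, order = 4) {
  stopifnot(inherits(signal, "raw_signal"))
  if (!(cutoff > 0 && cutoff < signal$rate / 2))
    stop("cutoff must lie in (0, rate/2)")
  bf <- signal::butter(order, W = cutoff / (signal$rate / 2), type = "high")
  out <- signal
  recorded <- rowSums(signal$axes != 0) > 0
  r <- rle(recorded)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_len <- as.integer(ceiling(signal$rate))  # filtfilt needs some run-in
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next  # nothing recorded: stays exactly zero
    i <- starts[k]:ends[k]
    for (j in 1:3) {
      x <- signal$axes[i, j]
      xc <- x - mean(x)
      out$axes[i, j] <- if (length(i) >= min_len)
        as.numeric(signal::filtfilt(bf, xc)) else xc
    }
  }
  colnames(out$axes) <- colnames(signal$axes)
  out
}

#' Collapse raw and filtered signals into epochs
#'
#' For each complete epoch of `epoch_s` seconds, computes the per-axis mean
#' absolute acceleration and synthesizes the three axes into a single
#' magnitude (Euclidean norm of the three per-axis values).  The filtered
#' path gives `ac_fil`.  For the unfiltered path the per-epoch per-axis mean
#' (the static gravity component) is subtracted before taking absolute
#' values, leaving the 0 to cutoff band content that the
#' unfiltered/filtered ratio is designed to detect; this gives `ac_unfil`.
#' Trailing partial epochs are dropped.
#'
#' @param raw the unfiltered [raw_signal()].
#' @param filtered the high-pass-filtered signal, aligned sample-for-sample
#'   with `raw`.
#' @param epoch_s epoch length in seconds (default 10);
#'   `epoch_s * rate` must be a whole number of samples.
#' @return A data.frame with columns `epoch` (1-based ordinal), `ac_fil`,
#'   `ac_unfil` (mG) and `raw_zero` (TRUE when every raw sample of the
#'   epoch is exactly zero — the device recorded nothing; the raw path is
#'   used because the zero-phase filter bleeds transients from wear
#'   boundaries into adjacent zero epochs).
#' @export
epochize <- function(raw, filtered, epoch_s = 10) {
  stopifnot(inherits(raw, "raw_signal"), inherits(filtered, "raw_signal"))
  if (nrow(raw$axes) != nrow(filtered$axes) || raw$rate != filtered$rate)
    stop("raw and filtered signals are misaligned")
  n_per <- epoch_s * raw$rate
  if (abs(n_per - round(n_per)) > 1e-9)
    stop("epoch_s * rate must be a whole number of samples")
  n_per <- as.integer(round(n_per))
  n_ep <- nrow(raw$axes) %/% n_per
  if (n_ep == 0L)
    return(data.frame(epoch = integer(), ac_fil = numeric(),
                      ac_unfil = numeric(), raw_zero = logical()))
  used <- seq_len(n_ep * n_per)
  idx <- rep(seq_len(n_ep), each = n_per)

  mean_abs <- function(m) rowsum(abs(m[used, , drop = FALSE]), idx) / n_per
  norm3 <- function(m) sqrt(rowSums(m^2))

  ac_fil <- norm3(mean_abs(filtered$axes))
  # unfiltered path: remove the per-epoch DC (gravity) before |.|
  ep_mean <- rowsum(raw$axes[used, , drop = FALSE], idx) / n_per
  centered <- raw$axes[used, , drop = FALSE] - ep_mean[idx, , drop = FALSE]
  ac_unfil <- norm3(rowsum(abs(centered), idx) / n_per)

  raw_zero <- as.numeric(rowsum(as.numeric(
    rowSums(raw$axes[used, , drop = FALSE] != 0) > 0), idx)) == 0

  data.frame(epoch = seq_len(n_ep), ac_fil = as.numeric(ac_fil),
             ac_unfil = as.numeric(ac_unfil), raw_zero = raw_zero)
}

#' Run the full epoch engine on a raw signal
#'
#' Quantizes to the device resolution, high-pass filters, epochizes, then
#' classifies each epoch and assigns METs.
#'
#' @param signal a [raw_signal()].
#' @param params an [asp_params()].
#' @param quantize apply device quantization first (default TRUE).
#' @return A data.frame with columns `epoch`, `ac_fil`, `ac_unfil`,
#'   `activity_class` and `mets`.
#' @examples
#' seg <- activity_segment("locomotive", duration = 60)
#' sig <- gen_activity_signal(list(seg), seed = 1)
#' head(process_signal(sig))
#' @export
process_signal <- function(signal, params = asp_params(), quantize = TRUE) {
  stopifnot(inherits(params, "asp_params"))
  if (quantize) signal <- quantize_signal(signal, params$resolution)
  filt <- highpass_filter(signal, cutoff = params$cutoff)
  ep <- epochize(signal, filt, epoch_s = params$epoch_s)
  ep$activity_class <- classify_epoch(ep$ac_fil, ep$ac_unfil, params)
  ep$mets <- met_value(ep$activity_class, ep$ac_fil, params)
  ep
}
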