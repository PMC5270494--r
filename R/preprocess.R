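# Band-limiting and stimulus-locked segmentation of continuous recordings.

#' Continuous single-channel recording with stimulus markers
#'
#' Light container for a raw (or filtered) EEG trace plus the sample
#' indices of stimulus onsets. Markers are 0-based sample indices and a
#' sweep occupies the half-open range `[marker, marker + sweep_len)`.
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param markers Strictly increasing 0-based integer sample indices, all
#'   less than `length(signal)`.
#' @param channel,subject_id,state Metadata labels.
#' @param stim_rate Optional stimulus repetition rate in Hz.
#' @return An object of class `continuous_record`.
#' @export
as_continuous_record <- function(signal, fs, markers,
                                 channel = "Fz-A1A2", subject_id = "A",
                                 state = "W0", stim_rate = NA_real_) {
  signal <- as.numeric(signal)
  markers <- as.integer(markers)
  if (length(markers) > 0) {
    if (any(diff(markers) <= 0)) {
      stop_assr("`markers` must be strictly increasing.")
    }
    if (any(markers < 0) || any(markers >= length(signal))) {
      stop_assr("All markers must lie within the signal (0-based).")
    }
  }
  structure(list(signal = signal, fs = fs, markers = markers,
                 channel = channel, subject_id = subject_id,
                 state = state, stim_rate = stim_rate),
            class = "continuous_record")
}

#' @export
print.continuous_record <- function(x, ...) {
  cat(sprintf("<continuous_record> %d samples at %g Hz, %d markers | subject %s, channel %s, state %s\n",
              length(x$signal), x$fs, length(x$markers),
              x$subject_id, x$channel, x$state))
  invisible(x)
}

#' Zero-phase Butterworth band-limiting
#'
#' Applies a cascade of an order-`order` Butterworth high-pass at `low_hz`
#' followed by a low-pass at `high_hz`, each forward-backward (zero-phase)
#' so that the phase-locked ASSR component is not delayed. The default band
#' of 20-100 Hz brackets the 40-Hz response and its second harmonic.
#'
#' Because each filter runs forward and backward, the effective magnitude
#' response is the square of the single-pass Butterworth magnitude.
#'
#' @param record A [as_continuous_record()] object.
#' @param low_hz High-pass cutoff in Hz.
#' @param high_hz Low-pass cutoff in Hz; must be below the Nyquist rate.
#' @param order Butterworth order of each filter in the cascade.
#' @return The record with the filtered signal; metadata unchanged.
#' @export
bandpass_filter <- function(record, low_hz = 20, high_hz = 100, order = 3) {
  stopifnot(inherits(record, "continuous_record"))
  nyq <- record$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop_assr("Need 0 < low_hz < high_hz.", class = "assr_parameter_error")
  }
  if (high_hz >= nyq) {
    stop_assr(sprintf("high_hz (%g) must be below the Nyquist rate (%g Hz).",
                      high_hz, nyq), class = "assr_parameter_error")
  }
  hp <- signal::butter(order, low_hz / nyq, type = "high")
  lp <- signal::butter(order, high_hz / nyq, type = "low")
  # odd-reflection padding long enough to absorb the high-pass transient
  # (time constant ~ fs / (2 pi low_hz)), so edges do not leak into the
  # record; trimmed off after filtering
  x <- record$signal
  n <- length(x)
  pad <- min(n - 1, ceiling(3 * record$fs / low_hz))
  if (pad > 0) {
    x <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  }
  y <- signal::filtfilt(hp, x)
  y <- signal::filtfilt(lp, y)
  record$signal <- as.numeric(y[(pad + 1):(pad + n)])
  record
}

#' Cut a continuous record into stimulus-locked sweeps
#'
#' One row per marker whose full `sweep_len`-sample extent fits inside the
#' signal; markers whose sweep would overrun the end of the recording are
#' dropped, matching the acquisition rule of keeping only complete
#' 295-sample stimulus cycles. Rows appear in marker order.
#'
#' @param record A [as_continuous_record()] object.
#' @param sweep_len Sweep length in samples (default 295, one 40.68-Hz
#'   stimulus cycle at 12 kHz; see [sweep_samples()]).
#' @return A `sweep_matrix`; the number of dropped markers is available as
#'   attribute `"dropped"`.
#' @export
segment_sweeps <- function(record, sweep_len = 295) {
  stopifnot(inherits(record, "continuous_record"))
  if (sweep_len < 1) stop_assr("`sweep_len` must be >= 1.")
  sweep_len <- as.integer(sweep_len)
  n <- length(record$signal)
  keep <- record$markers[record$markers + sweep_len <= n]
  dropped <- length(record$markers) - length(keep)
  if (length(keep) == 0) {
    stop_assr(sprintf("No marker yields a complete %d-sample sweep (%d marker(s) dropped).",
                      sweep_len, dropped), class = "assr_empty_error")
  }
  data <- t(vapply(keep, function(m) record$signal[(m + 1):(m + sweep_len)],
                   numeric(sweep_len)))
  out <- new_sweep_matrix(data, record$fs, record$stim_rate,
                          record$subject_id, record$channel, record$state)
  attr(out, "dropped") <- dropped
  out
}
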