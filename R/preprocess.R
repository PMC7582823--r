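#' Derive the bipolar occipital channel
#'
#' Replaces the O1/O2 electrode pair by their difference O1 - O2, the montage
#' used for all decoding.  Subtraction cancels noise shared by the two
#' electrodes while retaining the (antisymmetric) stimulus response.
#'
#' @param stream an [eeg_stream()] containing channels `O1` and `O2`.
#' @return An [eeg_stream()] with the single channel `BIPOLAR`, same sampling
#'   rate and length.
#' @export
make_bipolar <- function(stream) {
  stopifnot(inherits(stream, "eeg_stream"))
  for (ch in c("O1", "O2"))
    if (!ch %in% stream$channels)
      stop("channel '", ch, "' is missing from the stream")
  o1 <- stream$samples[match("O1", stream$channels), ]
  o2 <- stream$samples[match("O2", stream$channels), ]
  eeg_stream(o1 - o2, stream$fs, "BIPOLAR", t0 = stream$t0)
}

# Shared zero-phase Butterworth band-pass core. `order` is the analogue
# prototype order of each pass; filtfilt squares the magnitude response.
iir_bandpass <- function(x, fs, low, high, order) {
  if (!(low > 0 && low < high && high < fs / 2))
    stop("invalid band [", low, ", ", high, "] Hz for fs = ", fs,
         " Hz (need 0 < low < high < fs/2)")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Acquisition band-pass filter (1–50 Hz)
#'
#' Zero-phase recursive (Butterworth) band-pass applied per channel,
#' emulating the acquisition-side analogue filtering of the recording device.
#' Length-preserving.
#'
#' @param stream an [eeg_stream()].
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth prototype order per pass (default 4); the filter
#'   is applied forward and backward, so the effective magnitude response is
#'   squared and the phase is zero.
#' @return The filtered [eeg_stream()].
#' @export
acquisition_bandpass <- function(stream, low = 1, high = 50, order = 4) {
  stopifnot(inherits(stream, "eeg_stream"))
  out <- stream
  for (i in seq_len(nrow(stream$samples)))
    out$samples[i, ] <- iir_bandpass(stream$samples[i, ], stream$fs, low, high, order)
  out
}

#' Analysis band-pass filter (5–30 Hz)
#'
#' The analysis-side IIR band-pass applied to a single epoch before feature
#' extraction; covers the stimulus fundamentals (6.6–12 Hz), their second
#' harmonics (up to 24 Hz) and the blink transient energy.
#'
#' @param epoch an [eeg_epoch()].
#' @inheritParams acquisition_bandpass
#' @return The filtered [eeg_epoch()].
#' @export
analysis_bandpass <- function(epoch, low = 5, high = 30, order = 4) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  epoch$samples <- iir_bandpass(epoch$samples, epoch$fs, low, high, order)
  epoch
}

#' Extract one epoch from a single-channel stream
#'
#' Returns the half-open window `[onset, onset + window_s)`: exactly
#' `round(fs * window_s)` samples starting at sample index
#' `round((onset - t0) * fs)` (0-based).  For the default 2 s window at
#' 500 Hz this is 1000 samples.
#'
#' @param stream a single-channel [eeg_stream()]; apply [make_bipolar()]
#'   first if it still carries the O1/O2 pair.
#' @param onset window start in seconds (same clock as `stream$t0`).
#' @param window_s window length in seconds.
#' @param label optional class label attached to the epoch.
#' @return An [eeg_epoch()].
#' @export
extract_epoch <- function(stream, onset, window_s = 2.0, label = NULL) {
  stopifnot(inherits(stream, "eeg_stream"))
  if (nrow(stream$samples) != 1L)
    stop("extract_epoch() needs a single-channel stream (got ",
         nrow(stream$samples), " channels); apply make_bipolar() first")
  n <- round(stream$fs * window_s)
  i0 <- round((onset - stream$t0) * stream$fs)       # 0-based start index
  if (i0 < 0 || i0 + n > ncol(stream$samples))
    stop("window [", onset, ", ", onset + window_s, ") s exceeds stream ",
         "bounds [", stream$t0, ", ",
         stream$t0 + ncol(stream$samples) / stream$fs, ") s")
  eeg_epoch(stream$samples[1, (i0 + 1L):(i0 + n)], stream$fs,
            label = label, onset = onset)
}
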