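#' Multi-channel EEG sample stream
#'
#' Lightweight container for a continuous multi-channel recording: a
#' channels-by-time numeric matrix in microvolts plus sampling rate, channel
#' labels and a start time.
#'
#' @param samples numeric matrix, channels x time, in uV. A vector is treated
#'   as a single channel.
#' @param fs sampling rate in Hz.
#' @param channels character vector of unique channel labels, typically a
#'   subset of `c("O1", "O2", "BIPOLAR")`.
#' @param t0 stream start time in seconds.
#' @return An object of class `eeg_stream`.
#' @export
eeg_stream <- function(samples, fs, channels, t0 = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (length(channels) != nrow(samples))
    stop("need one channel label per row: got ", length(channels),
         " labels for ", nrow(samples), " channels")
  if (anyDuplicated(channels))
    stop("channel labels must be unique")
  structure(list(samples = samples, fs = fs,
                 channels = as.character(channels), t0 = t0),
            class = "eeg_stream")
}

#' @export
print.eeg_stream <- function(x, ...) {
  cat(sprintf("<eeg_stream> %d channel(s) [%s], %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              nrow(x$samples), paste(x$channels, collapse = ", "),
              ncol(x$samples), x$fs, ncol(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' Single-channel labeled EEG epoch
#'
#' One fixed-length window of single-channel EEG, the unit of classification.
#' The default pipeline uses 2 s at 500 Hz, i.e. 1000 samples.
#'
#' @param samples numeric vector in uV.
#' @param fs sampling rate in Hz.
#' @param label optional class label (one of [class_labels()]).
#' @param onset onset in seconds relative to the task cue.
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(samples, fs, label = NULL, onset = 0) {
  stopifnot(is.numeric(samples), is.null(dim(samples)))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  structure(list(samples = as.numeric(samples), fs = fs,
                 label = label, onset = onset),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d samples @ %g Hz (%.2f s)%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.null(x$label)) "" else paste0(", label = ", x$label)))
  invisible(x)
}

#' @export
length.eeg_epoch <- function(x) length(x$samples)
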