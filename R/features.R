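# Cached DFT basis and Kaiser window per (window_len, fs, beta, band) so the
# per-epoch cost is two matrix products.
.stft_cache <- new.env(parent = emptyenv())

stft_basis <- function(window_len, fs, kaiser_beta, band) {
  key <- paste(window_len, fs, kaiser_beta,
               paste(band, collapse = "-"), sep = "|")
  hit <- get0(key, envir = .stft_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  k <- 0:(window_len - 1)                       # DFT bin indices
  freqs <- k * fs / window_len
  if (!is.null(band)) {
    keep <- freqs >= band[1] & freqs < band[2]  # half-open [low, high)
    k <- k[keep]; freqs <- freqs[keep]
  }
  m <- 0:(window_len - 1)
  ang <- 2 * pi * outer(k, m) / window_len
  w <- as.numeric(signal::kaiser(window_len, kaiser_beta))
  basis <- list(cosb = cos(ang) * rep(w, each = length(k)),
                sinb = sin(ang) * rep(w, each = length(k)),
                freqs = freqs, window = w)
  assign(key, basis, envir = .stft_cache)
  basis
}

#' Short-time Fourier transform power features
#'
#' Slides a Kaiser-tapered window over the epoch in steps of `step` samples
#' and computes, for each frame, the squared magnitude of the windowed DFT at
#' the bins falling inside `band`.  With the defaults (2 s epoch at 500 Hz,
#' 1 s / 500-sample window, step 1, band 5–30 Hz) the result is the canonical
#' 25 x 500 time-frequency map: 1 Hz bin spacing gives integer bins
#' 5–29 Hz (the half-open band keeps 25 rows), and the final frame of the 501
#' possible is dropped to keep 500 columns.
#'
#' @param epoch an [eeg_epoch()] (band-pass it with [analysis_bandpass()]
#'   first in the standard pipeline).
#' @param window_len frame length in samples.  Default: one second of samples
#'   (`round(fs)`), capped at half the epoch so shorter epochs still produce
#'   multi-frame maps.
#' @param step hop size in samples (default 1).
#' @param kaiser_beta Kaiser window shape parameter (default 0.5).
#' @param band two-element frequency band in Hz; bins are kept on the
#'   half-open interval `[band[1], band[2])`.  `NULL` keeps all bins.
#' @return A `feature_map`: list with `power` (bins x frames, non-negative),
#'   `freq_axis` (Hz), `time_axis` (frame start, s), and `normalized` flag.
#' @export
#' @examples
#' ep <- make_ssvep_epoch(10, signal_model_config(), seed = 1)
#' fm <- stft_feature(analysis_bandpass(ep))
#' dim(fm$power)  # 25 x 500
stft_feature <- function(epoch, window_len = NULL, step = 1,
                         kaiser_beta = 0.5, band = c(5, 30)) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  x <- epoch$samples
  L <- length(x)
  if (is.null(window_len))
    window_len <- min(round(epoch$fs), floor(L / 2))
  if (L < window_len)
    stop("epoch (", L, " samples) is shorter than the STFT window (",
         window_len, " samples)")
  n_frames <- floor((L - window_len) / step)   # final partial frame dropped
  if (n_frames < 1L)
    stop("epoch too short for even one full frame after the final-frame drop")
  b <- stft_basis(window_len, epoch$fs, kaiser_beta, band)
  starts <- (seq_len(n_frames) - 1L) * step
  frames <- matrix(x[outer(seq_len(window_len), starts, `+`)],
                   nrow = window_len)
  re <- b$cosb %*% frames
  im <- b$sinb %*% frames
  structure(list(power = re^2 + im^2,
                 freq_axis = b$freqs,
                 time_axis = starts / epoch$fs,
                 normalized = FALSE,
                 fs = epoch$fs, window_len = window_len, step = step,
                 label = epoch$label),
            class = "feature_map")
}

#' Min-max normalize a feature map
#'
#' Rescales the whole map linearly onto `[0, 1]`, so a non-degenerate map has
#' minimum 0 and maximum exactly 1.  Constant maps pass through unchanged
#' (all-zero) or collapse to all-ones (non-zero constant); idempotent.
#'
#' @param map a `feature_map` from [stft_feature()].
#' @return The normalized `feature_map` with `normalized = TRUE`.
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "feature_map"))
  if (isTRUE(map$normalized)) return(map)
  lo <- min(map$power); hi <- max(map$power)
  if (hi > lo) {
    map$power <- (map$power - lo) / (hi - lo)
  } else if (hi != 0) {
    map$power[] <- 1
  }
  map$normalized <- TRUE
  map
}

#' Per-frame dominant frequency
#'
#' For each time frame, the frequency of the highest-power bin; ties are
#' broken toward the lowest bin.  A direct diagnostic of the banded structure
#' of SSVEP spectrograms and of the broadband blink ridges.
#'
#' @param map a `feature_map`.
#' @return Data frame with columns `time` (s, frame start) and `freq` (Hz).
#' @export
peak_profile <- function(map) {
  stopifnot(inherits(map, "feature_map"))
  idx <- apply(map$power, 2L, which.max)
  data.frame(time = map$time_axis, freq = map$freq_axis[idx])
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> %d bins (%g-%g Hz) x %d frames%s\n",
              nrow(x$power), min(x$freq_axis), max(x$freq_axis),
              ncol(x$power), if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

#' @export
plot.feature_map <- function(x, ...) {
  graphics::image(x$time_axis, x$freq_axis, t(x$power),
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  main = if (is.null(x$label)) "STFT power" else x$label, ...)
  invisible(x)
}

#' Featurize a whole trial set
#'
#' Applies the standard per-epoch pipeline — [analysis_bandpass()] then
#' [stft_feature()] then [normalize_map()] — to every trial of a
#' [make_dataset()] result.
#'
#' @param trials a `trial_set`.
#' @param low,high analysis band edges in Hz.
#' @param filter_order Butterworth prototype order.
#' @param apply_filter set `FALSE` to skip the analysis band-pass.
#' @param ... passed to [stft_feature()].
#' @return A `feature_set`: list with `features` (bins x frames x trials
#'   array), `labels`, `subject`, `freq_axis`, `time_axis`, provenance.
#' @export
featurize_trials <- function(trials, low = 5, high = 30, filter_order = 4,
                             apply_filter = TRUE, ...) {
  stopifnot(inherits(trials, "trial_set"))
  n_tr <- nrow(trials$samples)
  fs <- trials$config$fs
  first <- NULL
  feats <- NULL
  for (i in seq_len(n_tr)) {
    ep <- eeg_epoch(trials$samples[i, ], fs)
    if (apply_filter) ep <- analysis_bandpass(ep, low, high, filter_order)
    fm <- normalize_map(stft_feature(ep, band = c(low, high), ...))
    if (is.null(feats)) {
      first <- fm
      feats <- array(NA_real_, c(nrow(fm$power), ncol(fm$power), n_tr))
    }
    feats[, , i] <- fm$power
  }
  structure(list(features = feats, labels = trials$labels,
                 subject = trials$subject,
                 freq_axis = first$freq_axis, time_axis = first$time_axis,
                 config = trials$config, seed = trials$seed,
                 channel = trials$channel),
            class = "feature_set")
}
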