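#' Signal-model configuration for the EEG simulator
#'
#' Bundles every tunable of the synthetic EEG generator.  The simulated
#' recording is a bipolar occipital montage: O1 and O2 carry the stimulus
#' response with opposite polarity (`+s/2` / `-s/2`) on top of a background
#' that mixes a noise source shared by both electrodes with per-electrode
#' independent noise, so the bipolar difference O1 - O2 recovers the response
#' and cancels the shared noise.  `snr_db` is defined on the bipolar trace.
#'
#' @param fs sampling rate in Hz.
#' @param duration epoch length in seconds; `fs * duration` must be a whole
#'   number of samples.
#' @param ssvep_freqs the six stimulus fundamentals in Hz, all distinct and
#'   below the Nyquist frequency.
#' @param n_harmonics number of harmonics (>= 1) in the SSVEP response,
#'   counting the fundamental.
#' @param harmonic_decay amplitude ratio between consecutive harmonics, in
#'   (0, 1].
#' @param snr_db SSVEP-to-background power ratio on the bipolar channel, dB.
#' @param noise_exponent spectral slope gamma of the 1/f^gamma background.
#' @param alpha_amp amplitude of an optional 10 Hz alpha component added to
#'   the background, as a fraction of background RMS.  Off (0) by default
#'   because it would collide with the 10 Hz stimulus class.
#' @param blink_amp_factor blink peak amplitude over bipolar background RMS.
#' @param blink_width_s blink pulse full width at half maximum, seconds.
#' @param blink_edge_s rise/fall scale of the pulse edges, seconds; sharper
#'   edges put more blink energy into the 5–30 Hz analysis band.
#' @param blink_cue_window_s blinks are cue-locked responses: pulse centres
#'   fall uniformly within the first `min(duration, blink_cue_window_s)`
#'   seconds of the epoch, so their timing spread does not grow with epoch
#'   length.
#' @param double_blink_gap_s centre-to-centre interval of the two pulses of a
#'   double blink, seconds.
#' @param subject_gain_sd relative standard deviation of the per-subject
#'   response amplitude.
#' @param shared_noise_frac fraction of the single-electrode background power
#'   contributed by the source shared between O1 and O2, in [0, 1).
#' @param noise_rms_uv background RMS per electrode in uV (sets the overall
#'   scale; downstream feature normalization makes results scale-free).
#' @param seed default integer seed used by the generators.
#' @return A validated list of class `signal_model_config`.
#' @export
#' @examples
#' cfg <- signal_model_config()
#' ep <- make_ssvep_epoch(10, cfg, seed = 1)
#' length(ep$samples)  # 1000
signal_model_config <- function(fs = 500,
                                duration = 2.0,
                                ssvep_freqs = c(6.6, 7.5, 8.57, 10, 11, 12),
                                n_harmonics = 2L,
                                harmonic_decay = 0.5,
                                snr_db = 10,
                                noise_exponent = 1,
                                alpha_amp = 0,
                                blink_amp_factor = 8,
                                blink_width_s = 0.3,
                                blink_edge_s = 0.01,
                                blink_cue_window_s = 2,
                                double_blink_gap_s = 0.5,
                                subject_gain_sd = 0.1,
                                shared_noise_frac = 0.5,
                                noise_rms_uv = 10,
                                seed = 1L) {
  cfg <- structure(list(fs = fs, duration = duration,
                        ssvep_freqs = ssvep_freqs,
                        n_harmonics = as.integer(n_harmonics),
                        harmonic_decay = harmonic_decay,
                        snr_db = snr_db, noise_exponent = noise_exponent,
                        alpha_amp = alpha_amp,
                        blink_amp_factor = blink_amp_factor,
                        blink_width_s = blink_width_s,
                        blink_edge_s = blink_edge_s,
                        blink_cue_window_s = blink_cue_window_s,
                        double_blink_gap_s = double_blink_gap_s,
                        subject_gain_sd = subject_gain_sd,
                        shared_noise_frac = shared_noise_frac,
                        noise_rms_uv = noise_rms_uv,
                        seed = as.integer(seed)),
                   class = "signal_model_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  n <- cfg$fs * cfg$duration
  if (abs(n - round(n)) > 1e-9)
    stop("fs * duration must be an integer sample count (got ", n, ")")
  if (any(cfg$ssvep_freqs >= cfg$fs / 2))
    stop("all ssvep_freqs must be below the Nyquist frequency ", cfg$fs / 2, " Hz")
  if (anyDuplicated(cfg$ssvep_freqs))
    stop("ssvep_freqs must be distinct")
  if (cfg$n_harmonics < 1L) stop("n_harmonics must be >= 1")
  if (cfg$harmonic_decay <= 0 || cfg$harmonic_decay > 1)
    stop("harmonic_decay must be in (0, 1]")
  if (cfg$shared_noise_frac < 0 || cfg$shared_noise_frac >= 1)
    stop("shared_noise_frac must be in [0, 1)")
  margin <- cfg$blink_width_s / 2 + 2 * cfg$blink_edge_s
  cue_win <- min(cfg$duration, cfg$blink_cue_window_s)
  if (2 * margin > cue_win)
    stop("a single blink pulse of width ", cfg$blink_width_s,
         " s does not fit inside the ", cue_win, " s cue window")
  if (2 * margin + cfg$double_blink_gap_s > cue_win)
    stop("a double blink (gap ", cfg$double_blink_gap_s,
         " s) does not fit inside the ", cue_win, " s cue window")
  invisible(cfg)
}

#' The eight class labels of the decoding task
#'
#' Six SSVEP frequency classes (in the order of `ssvep_freqs`) followed by the
#' single-blink and double-blink classes.
#'
#' @param config a [signal_model_config()].
#' @return Character vector of length 8.
#' @export
class_labels <- function(config = signal_model_config()) {
  c(paste0("ssvep_", vapply(config$ssvep_freqs, format, "")),
    "single_blink", "double_blink")
}

# 1/f^gamma Gaussian noise with unit RMS: shape a white spectrum by
# f^(-gamma/2) and invert. DC is zeroed.
one_over_f_noise <- function(n, gamma, fs) {
  x <- stats::rnorm(n)
  if (gamma == 0) return(x / stats::sd(x))
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * fs
  f[f > fs / 2] <- fs - f[f > fs / 2]        # mirror for negative frequencies
  shape <- c(0, f[-1]^(-gamma / 2))
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

# Background noise for one trial: O1/O2 share one source and add independent
# ones; optional alpha. Returns list(o1, o2) each with RMS ~ noise_rms_uv.
background_pair <- function(n, cfg) {
  sd_c <- sqrt(cfg$shared_noise_frac) * cfg$noise_rms_uv
  sd_i <- sqrt(1 - cfg$shared_noise_frac) * cfg$noise_rms_uv
  nc <- one_over_f_noise(n, cfg$noise_exponent, cfg$fs) * sd_c
  n1 <- one_over_f_noise(n, cfg$noise_exponent, cfg$fs) * sd_i
  n2 <- one_over_f_noise(n, cfg$noise_exponent, cfg$fs) * sd_i
  if (cfg$alpha_amp > 0) {
    t <- (seq_len(n) - 1) / cfg$fs
    alpha <- cfg$alpha_amp * cfg$noise_rms_uv *
      sin(2 * pi * 10 * t + stats::runif(1, 0, 2 * pi))
    nc <- nc + alpha
  }
  list(o1 = nc + n1, o2 = nc + n2)
}

# RMS of the independent (non-cancelling) part of the bipolar background.
bipolar_noise_rms <- function(cfg) {
  sqrt(2 * (1 - cfg$shared_noise_frac)) * cfg$noise_rms_uv
}

# Harmonic SSVEP waveform with random phases, scaled to the requested bipolar
# SNR. Harmonics at or above Nyquist are dropped.
ssvep_waveform <- function(freq, cfg, gain) {
  n <- round(cfg$fs * cfg$duration)
  t <- (seq_len(n) - 1) / cfg$fs
  w <- numeric(n)
  for (h in seq_len(cfg$n_harmonics)) {
    fh <- h * freq
    if (fh >= cfg$fs / 2) break
    w <- w + cfg$harmonic_decay^(h - 1) *
      sin(2 * pi * fh * t + stats::runif(1, 0, 2 * pi))
  }
  target_rms <- bipolar_noise_rms(cfg) * 10^(cfg$snr_db / 20)
  w * (target_rms / sqrt(mean(w^2))) * gain
}

# Smooth unipolar blink pulse(s): a plateau of width blink_width_s with erf
# edges of scale blink_edge_s. The edge sharpness sets the in-band (5-30 Hz)
# energy that makes blinks visible to the spectrogram decoder, mirroring the
# broadband transients real blinks leave after band-pass filtering.
blink_waveform <- function(centers, cfg, gain, n = round(cfg$fs * cfg$duration)) {
  t <- (seq_len(n) - 1) / cfg$fs
  peak <- cfg$blink_amp_factor * bipolar_noise_rms(cfg) * gain
  w <- numeric(n)
  for (c0 in centers) {
    half <- cfg$blink_width_s / 2
    w <- w + peak * (stats::pnorm((t - (c0 - half)) / cfg$blink_edge_s) -
                       stats::pnorm((t - (c0 + half)) / cfg$blink_edge_s))
  }
  w
}

# Compose one trial: antisymmetric signal over the background pair, then pick
# a channel view.
compose_trial <- function(sig, bg, cfg, channel) {
  switch(channel,
         O1      = sig / 2 + bg$o1,
         O2      = -sig / 2 + bg$o2,
         bipolar = sig + (bg$o1 - bg$o2),
         stop("unknown channel '", channel,
              "'; expected one of O1, O2, bipolar"))
}

#' Generate one synthetic SSVEP epoch
#'
#' Builds a harmonic sinusoid stack at `freq` (fundamental plus
#' `n_harmonics - 1` harmonics with geometric amplitude decay and random
#' phases), scales it to `snr_db` over the 1/f background, and returns the
#' requested channel view.
#'
#' @param freq stimulus fundamental in Hz; must be one of
#'   `config$ssvep_freqs`.
#' @param config a [signal_model_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param channel one of `"bipolar"` (default), `"O1"`, `"O2"`.
#' @param subject_gain multiplicative per-subject amplitude factor.
#' @return An [eeg_epoch()] labeled with the frequency class.
#' @export
make_ssvep_epoch <- function(freq, config = signal_model_config(),
                             seed = config$seed, channel = "bipolar",
                             subject_gain = 1) {
  k <- which(abs(config$ssvep_freqs - freq) < 1e-9)
  if (length(k) != 1L)
    stop("freq = ", freq, " Hz is not a configured stimulus frequency; ",
         "valid set: ", paste(config$ssvep_freqs, collapse = ", "), " Hz")
  n <- round(config$fs * config$duration)
  with_seed(seed, {
    bg <- background_pair(n, config)
    sig <- ssvep_waveform(freq, config, subject_gain)
    eeg_epoch(compose_trial(sig, bg, config, channel), config$fs,
              label = class_labels(config)[k])
  })
}

#' Generate one synthetic eye-blink epoch
#'
#' Background noise plus one (single) or two (double) smooth unipolar
#' Gaussian-windowed pulses of width `blink_width_s` and peak
#' `blink_amp_factor` times the bipolar background RMS.  Pulse centres are
#' placed uniformly at random so that each pulse fits inside the epoch.
#'
#' @param kind `"single"` or `"double"`.
#' @inheritParams make_ssvep_epoch
#' @return An [eeg_epoch()] labeled `"single_blink"` or `"double_blink"`.
#' @export
make_blink_epoch <- function(kind = c("single", "double"),
                             config = signal_model_config(),
                             seed = config$seed, channel = "bipolar",
                             subject_gain = 1) {
  kind <- match.arg(kind)
  margin <- config$blink_width_s / 2 + 2 * config$blink_edge_s
  cue_win <- min(config$duration, config$blink_cue_window_s)
  n <- round(config$fs * config$duration)
  with_seed(seed, {
    bg <- background_pair(n, config)
    centers <- if (kind == "single") {
      stats::runif(1, margin, cue_win - margin)
    } else {
      c1 <- stats::runif(1, margin,
                         cue_win - margin - config$double_blink_gap_s)
      c(c1, c1 + config$double_blink_gap_s)
    }
    if (any(centers < margin | centers > config$duration - margin))
      stop("blink pulse placement clips the epoch boundary")
    sig <- blink_waveform(centers, config, subject_gain)
    eeg_epoch(compose_trial(sig, bg, config, channel), config$fs,
              label = if (kind == "single") "single_blink" else "double_blink")
  })
}

#' Generate a balanced labeled trial set
#'
#' Simulates `n_subjects * 8 * n_trials_per_task` epochs, one eight-class task
#' block per subject, with a per-subject amplitude gain drawn once per subject
#' (`1 + subject_gain_sd * z`, truncated at 0.2).  The defaults reproduce the
#' canonical study size: 5 subjects x 8 tasks x 20 trials = 800 trials,
#' 100 per class.
#'
#' @param config a [signal_model_config()].
#' @param n_subjects number of simulated subjects (>= 1).
#' @param n_trials_per_task trials per subject and class (>= 1).
#' @param seed integer seed (defaults to `config$seed`).
#' @param channel channel view for every epoch: `"bipolar"`, `"O1"` or `"O2"`.
#' @return A `trial_set`: list with `samples` (trials x samples matrix),
#'   `labels` (factor over [class_labels()]), `subject` (integer vector),
#'   and provenance (`config`, `seed`, `channel`).
#' @export
make_dataset <- function(config = signal_model_config(), n_subjects = 5,
                         n_trials_per_task = 20, seed = config$seed,
                         channel = "bipolar") {
  if (n_subjects < 1 || n_trials_per_task < 1)
    stop("n_subjects and n_trials_per_task must be >= 1")
  classes <- class_labels(config)
  n <- round(config$fs * config$duration)
  n_trials <- n_subjects * length(classes) * n_trials_per_task
  gains <- with_seed(derive_seed(seed, 0), {
    pmax(0.2, 1 + config$subject_gain_sd * stats::rnorm(n_subjects))
  })
  samples <- matrix(NA_real_, n_trials, n)
  labels <- character(n_trials)
  subject <- integer(n_trials)
  i <- 0L
  for (s in seq_len(n_subjects)) {
    for (k in seq_along(classes)) {
      for (r in seq_len(n_trials_per_task)) {
        i <- i + 1L
        ep_seed <- derive_seed(seed, i)
        ep <- if (k <= length(config$ssvep_freqs)) {
          make_ssvep_epoch(config$ssvep_freqs[k], config, seed = ep_seed,
                           channel = channel, subject_gain = gains[s])
        } else {
          make_blink_epoch(if (classes[k] == "single_blink") "single" else "double",
                           config, seed = ep_seed, channel = channel,
                           subject_gain = gains[s])
        }
        samples[i, ] <- ep$samples
        labels[i] <- ep$label
        subject[i] <- s
      }
    }
  }
  structure(list(samples = samples,
                 labels = factor(labels, levels = classes),
                 subject = subject,
                 config = config, seed = as.integer(seed), channel = channel,
                 schema_version = DATASET_SCHEMA_VERSION),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials x %d samples @ %g Hz, channel %s\n",
              nrow(x$samples), ncol(x$samples), x$config$fs, x$channel))
  print(table(x$labels))
  invisible(x)
}

#' Synthesize a continuous closed-loop session stream
#'
#' Realizes a script of user intents (gaze at a stimulus, single blink,
#' double blink) as a continuous two-channel O1/O2 recording: background
#' noise everywhere, with each intent's signal injected into its time slot.
#' SSVEP slots ramp on and off over 0.1 s (raised cosine); blink pulses are
#' placed inside their slot with the same uniform jitter as the trial
#' generator.  The returned event log records the true slot of every intent.
#'
#' @param script data frame with columns `onset` (s), `duration` (s) and
#'   `intent` (a value of [class_labels()]).  Intervals must not overlap.
#' @param config a [signal_model_config()].
#' @param seed integer seed.
#' @param total_s total stream length; defaults to the end of the last intent.
#' @return List with `stream` (two-channel [eeg_stream()], O1 and O2) and
#'   `events` (the ground-truth log: `onset`, `duration`, `class`).
#' @export
make_session_stream <- function(script, config = signal_model_config(),
                                seed = config$seed, total_s = NULL) {
  if (is.null(script) || nrow(as.data.frame(script)) == 0L) {
    script <- data.frame(onset = numeric(0), duration = numeric(0),
                         intent = character(0))
  }
  script <- as.data.frame(script)
  stopifnot(all(c("onset", "duration", "intent") %in% names(script)))
  classes <- class_labels(config)
  bad <- setdiff(script$intent, classes)
  if (length(bad))
    stop("unknown intent(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(classes, collapse = ", "))
  if (nrow(script) > 1L) {
    o <- order(script$onset)
    ends <- script$onset[o] + script$duration[o]
    if (any(script$onset[o][-1] < ends[-length(ends)] - 1e-9))
      stop("intent intervals overlap")
  }
  if (is.null(total_s))
    total_s <- if (nrow(script)) max(script$onset + script$duration) else config$duration
  n <- round(config$fs * total_s)
  with_seed(seed, {
    bg <- background_pair(n, config)
    sig <- numeric(n)
    for (i in seq_len(nrow(script))) {
      i0 <- round(script$onset[i] * config$fs) + 1L
      ns <- round(script$duration[i] * config$fs)
      idx <- i0:(i0 + ns - 1L)
      intent <- script$intent[i]
      k <- match(intent, classes)
      slot <- if (k <= length(config$ssvep_freqs)) {
        cfg_i <- config
        cfg_i$duration <- script$duration[i]
        w <- ssvep_waveform(config$ssvep_freqs[k], cfg_i, 1)
        # raised-cosine onset/offset ramps: the steady-state response builds
        # up and decays smoothly, and a hard edge would ring through the
        # band-pass filter into a spurious broadband transient
        nr <- min(round(0.1 * config$fs), floor(ns / 2))
        if (nr > 0) {
          ramp <- (1 - cos(pi * seq_len(nr) / nr)) / 2
          w[seq_len(nr)] <- w[seq_len(nr)] * ramp
          w[(ns - nr + 1):ns] <- w[(ns - nr + 1):ns] * rev(ramp)
        }
        w
      } else {
        # place blinks with the same within-window jitter as the trial
        # generator (users blink with some latency after the prompt)
        margin <- config$blink_width_s / 2 + 2 * config$blink_edge_s
        dur <- script$duration[i]
        centers <- if (intent == "single_blink") {
          stats::runif(1, margin, dur - margin)
        } else {
          c1 <- stats::runif(1, margin, dur - margin - config$double_blink_gap_s)
          c(c1, c1 + config$double_blink_gap_s)
        }
        blink_waveform(centers, config, 1, n = ns)
      }
      sig[idx] <- sig[idx] + slot
    }
    stream <- eeg_stream(rbind(sig / 2 + bg$o1, -sig / 2 + bg$o2),
                         config$fs, c("O1", "O2"))
    events <- data.frame(onset = script$onset, duration = script$duration,
                         class = script$intent)
    list(stream = stream, events = events)
  })
}
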