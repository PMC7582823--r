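# Independent oracles used across the suite. These deliberately use naive
# loop/definition-level computations, not the package's vectorized paths.

# Brute-force sliding-window DFT power: loops over frames and computes every
# bin by direct summation.
naive_stft <- function(x, fs, window_len, step = 1, kaiser_beta = 0.5,
                       band = NULL) {
  w <- as.numeric(signal::kaiser(window_len, kaiser_beta))
  n_frames <- floor((length(x) - window_len) / step)
  k_all <- 0:(window_len - 1)
  freqs <- k_all * fs / window_len
  keep <- if (is.null(band)) rep(TRUE, window_len) else
    freqs >= band[1] & freqs < band[2]
  ks <- k_all[keep]
  P <- matrix(NA_real_, length(ks), n_frames)
  for (j in seq_len(n_frames)) {
    seg <- x[((j - 1) * step + 1):((j - 1) * step + window_len)] * w
    for (bi in seq_along(ks)) {
      ang <- -2 * pi * ks[bi] * (0:(window_len - 1)) / window_len
      P[bi, j] <- sum(seg * cos(ang))^2 + sum(seg * sin(ang))^2
    }
  }
  list(power = P, freqs = freqs[keep])
}

# Count well-separated threshold crossings: runs of |x| > thr, merging runs
# closer than merge_gap samples and dropping runs shorter than min_len.
count_pulses <- function(x, thr, min_len = 10L, merge_gap = 50L) {
  above <- abs(x) > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0L) return(list(n = 0L, centers = numeric(0)))
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] - merged$end[nrow(merged)] <= merge_gap)
      merged$end[nrow(merged)] <- runs$end[i]
    else merged <- rbind(merged, runs[i, ])
  }
  merged <- merged[merged$end - merged$start + 1L >= min_len, , drop = FALSE]
  list(n = nrow(merged), centers = (merged$start + merged$end) / 2)
}

# Direct 2x2 valid convolution by explicit loops.
conv2_valid_ref <- function(X, W, b = 0) {
  d1 <- nrow(X); d2 <- ncol(X)
  Z <- matrix(NA_real_, d1 - 1, d2 - 1)
  for (u in seq_len(d1 - 1))
    for (v in seq_len(d2 - 1))
      Z[u, v] <- b + sum(W * X[u:(u + 1), v:(v + 1)])
  Z
}

# 2x2/stride-2 max-pool by explicit loops (floors odd edges).
maxpool_ref <- function(A) {
  pu <- nrow(A) %/% 2; pv <- ncol(A) %/% 2
  P <- matrix(NA_real_, pu, pv)
  for (p in seq_len(pu))
    for (q in seq_len(pv))
      P[p, q] <- max(A[(2 * p - 1):(2 * p), (2 * q - 1):(2 * q)])
  P
}

# Magnitude response of a digital filter at frequency f (Hz): ratio of the
# numerator and denominator polynomials evaluated on the unit circle.
# filtfilt applies the filter twice, so its gain is this squared.
filter_gain <- function(bf, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  H <- sum(bf$b * z^(seq_along(bf$b) - 1)) / sum(bf$a * z^(seq_along(bf$a) - 1))
  Mod(H)
}

# Steady-state amplitude of a (roughly) sinusoidal signal from its middle
# third, via RMS * sqrt(2).
mid_amplitude <- function(x) {
  n <- length(x)
  mid <- x[floor(n / 3):ceiling(2 * n / 3)]
  sqrt(2 * mean(mid^2))
}

# Central-difference gradient of fn() with respect to every element of the
# numeric object at model[[name]].
numeric_grad <- function(model, name, fn, h = 1e-5) {
  par <- model[[name]]
  g <- par
  for (i in seq_along(par)) {
    m1 <- model; m1[[name]][i] <- par[i] + h
    m2 <- model; m2[[name]][i] <- par[i] - h
    g[i] <- (fn(m1) - fn(m2)) / (2 * h)
  }
  g
}

# Local maxima of a vector above a fraction of its peak (ridge detector for
# blink spectrogram column sums), with a minimum separation in samples.
find_ridges <- function(v, frac = 0.5, min_sep = 50L) {
  thr <- frac * max(v)
  peaks <- integer(0)
  for (i in seq_along(v)) {
    lo <- max(1L, i - min_sep); hi <- min(length(v), i + min_sep)
    if (v[i] >= thr && v[i] == max(v[lo:hi])) {
      if (length(peaks) == 0L || i - peaks[length(peaks)] > min_sep)
        peaks <- c(peaks, i)
    }
  }
  peaks
}

# Small lazily-built high-SNR fixture shared by closed-loop tests: a compact
# dataset and trained decoder. Cached in the helper environment so only the
# first test pays the training cost.
.fixture_env <- new.env(parent = emptyenv())

trained_fixture <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  cfg <- signal_model_config(snr_db = 15)
  ds <- make_dataset(cfg, n_subjects = 4, n_trials_per_task = 15, seed = 101)
  fs <- featurize_trials(ds)
  fit <- cnn_train(fs, config = train_config(epochs = 40, seed = 101))
  .fixture_env$fit <- list(fit = fit, features = fs, config = cfg)
  .fixture_env$fit
}
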