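#' Wolpaw bits per selection
#'
#' The classic information-transfer measure for an N-command interface with
#' per-selection accuracy P:
#' `psi = log2(N) + P*log2(P) + (1 - P)*log2((1 - P)/(N - 1))` bits.
#' At P = 1 the error term vanishes (the limit is taken, `psi = log2(N)`);
#' at or below chance (`P <= 1/N`) the rate is clamped to 0 with a warning.
#'
#' @param P probability of a correct selection, as a fraction in (0, 1].
#' @param N number of possible commands (>= 2).
#' @return Bits per selection (scalar).
#' @export
#' @examples
#' wolpaw_bits(1, 38)       # log2(38) = 5.2479
#' wolpaw_bits(0.9692, 38)  # 4.889 bits/selection
wolpaw_bits <- function(P, N) {
  if (N < 2) stop("N must be >= 2")
  if (P <= 0 || P > 1) stop("P must be in (0, 1]")
  if (P <= 1 / N + 1e-12) {
    if (P < 1 / N - 1e-12)
      warning("P = ", P, " is below chance (1/N = ", 1 / N, "); rate clamped to 0")
    return(0)
  }
  err <- if (P < 1) (1 - P) * log2((1 - P) / (N - 1)) else 0
  log2(N) + P * log2(P) + err
}

#' Information transfer rate in bits per minute
#'
#' Bits per selection ([wolpaw_bits()]) times selections per minute
#' (`60 / T`).
#'
#' @inheritParams wolpaw_bits
#' @param T seconds per selection (> 0).
#' @return Bits per minute.
#' @export
#' @examples
#' itr_bits_per_min(0.9692, 38, 2)  # 146.67
itr_bits_per_min <- function(P, N, T) {
  if (T <= 0) stop("T must be > 0")
  wolpaw_bits(P, N) * 60 / T
}

#' Per-class timing summary
#'
#' Arithmetic mean and n-1 sample standard deviation of response times,
#' grouped by event class.  Values are kept at full precision; round only
#' for display.
#'
#' @param values numeric vector of times in seconds.
#' @param by optional grouping vector (event classes); a single group when
#'   omitted.
#' @return Data frame with columns `class`, `n`, `mean`, `sd` (NA when
#'   n < 2).
#' @export
summarize_times <- function(values, by = NULL) {
  if (length(values) == 0L) stop("no timing values supplied")
  if (is.null(by)) by <- rep("all", length(values))
  stopifnot(length(by) == length(values))
  groups <- split(values, by)
  out <- data.frame(
    class = names(groups),
    n = vapply(groups, length, 0L),
    mean = vapply(groups, mean, 0),
    sd = vapply(groups, function(v) if (length(v) >= 2L) stats::sd(v) else NA_real_, 0)
  )
  rownames(out) <- NULL
  out
}

#' Tabulate evaluation reports across conditions
#'
#' Collects accuracy and error rate from several [cnn_evaluate()] reports
#' (e.g. per channel, or per time window) into one comparison table.  All
#' rows are tagged `synthetic`: the harness re-runs the channel and
#' time-window comparisons on simulated data.
#'
#' @param reports named list of `eval_report` objects; names label the
#'   conditions.
#' @return Data frame with columns `condition`, `accuracy`, `error_rate`,
#'   `n_test`, `data`.
#' @export
accuracy_table <- function(reports) {
  if (length(reports) == 0L) stop("need at least one report")
  if (is.null(names(reports)) || any(names(reports) == ""))
    names(reports) <- paste0("condition_", seq_along(reports))
  data.frame(
    condition = names(reports),
    accuracy = vapply(reports, function(r) r$accuracy, 0),
    error_rate = vapply(reports, function(r) r$error_rate, 0),
    n_test = vapply(reports, function(r) r$n, 0L),
    data = "synthetic",
    row.names = NULL
  )
}

#' Channel comparison study on synthetic data
#'
#' Simulates the same trials viewed as O1, O2 and bipolar, runs the full
#' featurize-train-evaluate pipeline per channel, and tabulates test
#' accuracies.  Because the simulator shares part of the background noise
#' between the electrodes while the response enters antisymmetrically, the
#' bipolar view has the highest SNR and is expected to score at least as
#' well as either single electrode.
#'
#' @param config a [signal_model_config()].
#' @param n_subjects,n_trials_per_task study size per channel.
#' @param train train-time settings, a [train_config()].
#' @param n_kernels,fc1_units CNN architecture sizes.
#' @param seed integer seed shared by all three simulations.
#' @return List with `table` (an [accuracy_table()]) and `reports`.
#' @export
channel_accuracy_study <- function(config = signal_model_config(snr_db = 5),
                                   n_subjects = 3, n_trials_per_task = 10,
                                   train = train_config(epochs = 25, seed = 7),
                                   n_kernels = 8L, fc1_units = 64L,
                                   seed = 7L) {
  reports <- list()
  for (ch in c("O1", "O2", "bipolar")) {
    ds <- make_dataset(config, n_subjects, n_trials_per_task,
                       seed = seed, channel = ch)
    fs <- featurize_trials(ds)
    fit <- cnn_train(fs, config = train, n_kernels = n_kernels,
                     fc1_units = fc1_units)
    reports[[ch]] <- cnn_evaluate(fit$model,
                                  fs$features[, , fit$test_idx, drop = FALSE],
                                  fs$labels[fit$test_idx])
  }
  list(table = accuracy_table(reports), reports = reports)
}

#' Time-window comparison study on synthetic data
#'
#' Re-runs the pipeline with epochs of different lengths and tabulates test
#' accuracies.  The STFT hop is scaled with the epoch so that maps keep a
#' (near-)constant number of frames: this holds the classifier architecture
#' and optimization identical across conditions, so the comparison isolates
#' the information carried by the window — more stimulus cycles and more
#' independent noise realizations — rather than conflating it with model
#' size.  Accuracy is expected to be non-decreasing in window length.
#'
#' @param windows epoch lengths in seconds.
#' @param config base [signal_model_config()]; `duration` is overridden per
#'   window.
#' @inheritParams channel_accuracy_study
#' @return List with `table` and `reports` (named by window).
#' @export
window_accuracy_study <- function(windows = c(1, 2, 3, 4),
                                  config = signal_model_config(snr_db = -5),
                                  n_subjects = 3, n_trials_per_task = 30,
                                  train = train_config(epochs = 30,
                                                       train_fraction = 0.5,
                                                       seed = 7),
                                  n_kernels = 8L, fc1_units = 64L,
                                  seed = 7L) {
  reports <- list()
  for (w in windows) {
    cfg <- config
    cfg$duration <- w
    validate_config(cfg)
    ds <- make_dataset(cfg, n_subjects, n_trials_per_task, seed = seed)
    L <- round(cfg$fs * w)
    win_len <- min(round(cfg$fs), floor(L / 2))
    fs <- featurize_trials(ds, step = max(1L, (L - win_len) %/% 500L))
    fit <- cnn_train(fs, config = train, n_kernels = n_kernels,
                     fc1_units = fc1_units)
    reports[[paste0(w, "s")]] <-
      cnn_evaluate(fit$model, fs$features[, , fit$test_idx, drop = FALSE],
                   fs$labels[fit$test_idx])
  }
  list(table = accuracy_table(reports), reports = reports)
}
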