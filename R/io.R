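DATASET_SCHEMA_VERSION <- "1.0"

# Write a numeric matrix as CSV with %.17g formatting, which round-trips
# IEEE doubles bit-exactly through fread().
write_matrix_csv <- function(m, path) {
  txt <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(txt, 1L, paste, collapse = ","), con)
}

read_matrix_csv <- function(path) {
  as.matrix(data.table::fread(path, header = FALSE, sep = ","))
}

config_to_list <- function(cfg) unclass(cfg)

config_from_list <- function(lst) {
  do.call(signal_model_config, lst)
}

#' Save a trial set to a plain-text container
#'
#' Writes `samples.csv` (trials x samples, full-precision text) and
#' `meta.json` (labels, subject ids, channel, schema version, seed and the
#' full generator config) into `dir`.  The round-trip through
#' [load_dataset()] is bit-exact.
#'
#' @param trials a `trial_set` from [make_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_dataset <- function(trials, dir) {
  stopifnot(inherits(trials, "trial_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_csv(trials$samples, file.path(dir, "samples.csv"))
  meta <- list(schema_version = DATASET_SCHEMA_VERSION,
               n_trials = nrow(trials$samples),
               n_samples = ncol(trials$samples),
               labels = as.character(trials$labels),
               classes = levels(trials$labels),
               subject = trials$subject,
               channel = trials$channel,
               seed = trials$seed,
               config = config_to_list(trials$config))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(dir)
}

#' Load a trial set saved by [save_dataset()]
#'
#' @param dir container directory.
#' @return The reconstructed `trial_set`.
#' @export
load_dataset <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  samp_path <- file.path(dir, "samples.csv")
  if (!file.exists(meta_path) || !file.exists(samp_path))
    stop("not a dataset container: missing meta.json or samples.csv in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$schema_version, DATASET_SCHEMA_VERSION))
    stop("dataset schema version mismatch: file has '", meta$schema_version,
         "', this package reads '", DATASET_SCHEMA_VERSION, "'")
  samples <- read_matrix_csv(samp_path)
  dimnames(samples) <- NULL
  if (nrow(samples) != meta$n_trials || ncol(samples) != meta$n_samples)
    stop("truncated or corrupt dataset: samples.csv is ",
         nrow(samples), "x", ncol(samples), " but meta.json declares ",
         meta$n_trials, "x", meta$n_samples)
  structure(list(samples = samples,
                 labels = factor(meta$labels, levels = meta$classes),
                 subject = as.integer(meta$subject),
                 config = config_from_list(meta$config),
                 seed = as.integer(meta$seed),
                 channel = meta$channel,
                 schema_version = meta$schema_version),
            class = "trial_set")
}

#' Save a trained CNN as JSON
#'
#' One self-describing JSON checkpoint: architecture, classes, featurization
#' pipeline, seed and all parameter arrays at 17 significant digits (the
#' round-trip through [load_model()] is bit-exact).
#'
#' @param model an `ssvep_cnn`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ssvep_cnn"))
  obj <- unclass(model)
  obj$schema_version <- DATASET_SCHEMA_VERSION
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a CNN checkpoint saved by [save_model()]
#'
#' @param path checkpoint path.
#' @return The reconstructed `ssvep_cnn`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema_version, DATASET_SCHEMA_VERSION))
    stop("model schema version mismatch: file has '", obj$schema_version, "'")
  obj$schema_version <- NULL
  obj$conv_w <- array(as.numeric(obj$conv_w), dim(obj$conv_w))
  obj$conv_b <- as.numeric(obj$conv_b)
  obj$fc1_w <- matrix(as.numeric(obj$fc1_w), nrow(obj$fc1_w))
  obj$fc2_w <- matrix(as.numeric(obj$fc2_w), nrow(obj$fc2_w))
  obj$input_shape <- as.integer(obj$input_shape)
  obj$pooled_shape <- as.integer(obj$pooled_shape)
  structure(obj, class = "ssvep_cnn")
}

#' Write a session log as JSON lines
#'
#' One JSON object per decoded epoch, plus a trailing summary object with the
#' issued commands and per-class response times.
#'
#' @param log a `session_log` from [run_closed_loop()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log$events)))
    writeLines(jsonlite::toJSON(as.list(log$events[i, ]), auto_unbox = TRUE,
                                digits = I(17)), con)
  summary <- list(issued_commands = log$issued_commands,
                  response_times = as.list(log$response_times))
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = I(17)), con)
  invisible(path)
}
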