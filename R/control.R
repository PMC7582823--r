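#' Specification of the 6x6 command menu
#'
#' Six main categories, each with six sub-options, give 36 leaf commands;
#' together with the two blink calibration events (confirm, undo) the
#' interface exposes 38 commands.  At both menu levels the on-screen targets
#' are tagged, in index order, with the six stimulus frequencies.
#'
#' @param main character vector of 6 category labels.
#' @param subs list of 6 character vectors of 6 option labels each (defaults
#'   to generic option names per category).
#' @param frequencies the six stimulus frequencies in Hz, mapped to menu
#'   indices 1..6 at both levels.
#' @return An object of class `menu_spec`.
#' @export
menu_spec <- function(main = c("daily life control", "calling",
                               "food ordering", "conversation control",
                               "wheelchair control", "entertainment"),
                      subs = NULL,
                      frequencies = c(6.6, 7.5, 8.57, 10, 11, 12)) {
  if (length(main) != 6L) stop("need exactly 6 main categories")
  if (length(frequencies) != 6L || anyDuplicated(frequencies))
    stop("stimulus_map must be a bijection onto 6 distinct frequencies")
  if (is.null(subs))
    subs <- lapply(main, function(m) paste0(m, ": option ", 1:6))
  if (length(subs) != 6L || any(lengths(subs) != 6L))
    stop("need 6 sub-options per category")
  structure(list(main = main, subs = subs, frequencies = frequencies),
            class = "menu_spec")
}

#' Initial menu state
#'
#' @return A `menu_state` in phase `MAIN_SELECT` with no pending selections.
#' @export
menu_state <- function() {
  structure(list(phase = "MAIN_SELECT", pending_main = NA_integer_,
                 pending_sub = NA_integer_),
            class = "menu_state")
}

menu_phases <- c("MAIN_SELECT", "MAIN_CONFIRM", "SUB_SELECT", "SUB_CONFIRM",
                 "DONE")
menu_events <- c(paste0("ssvep_", 1:6), "single_blink", "double_blink")

#' One transition of the menu state machine
#'
#' The control protocol: gaze selects (SSVEP event k proposes entry k), a
#' single blink confirms, a double blink undoes the pending selection.
#' Formally: `MAIN_SELECT + ssvep_k -> MAIN_CONFIRM(k)` (action `prompt`);
#' `MAIN_CONFIRM + single_blink -> SUB_SELECT` (`enter_submenu`);
#' `MAIN_CONFIRM + double_blink -> MAIN_SELECT` (`undo`);
#' `SUB_SELECT + ssvep_k -> SUB_CONFIRM(k)` (`prompt`);
#' `SUB_CONFIRM + single_blink -> DONE` (`issue_command`);
#' `SUB_CONFIRM + double_blink -> SUB_SELECT` (`undo`).
#' Blinks during selection phases, SSVEP events during confirm phases, and
#' anything in `DONE` are ignored with action `noop`.  The function is total
#' over state x event.
#'
#' @param state a `menu_state`.
#' @param event one of `"ssvep_1"` ... `"ssvep_6"`, `"single_blink"`,
#'   `"double_blink"` (menu-index events, not frequency labels).
#' @return List with the new `state` and an `action` list carrying `type`
#'   (`prompt`, `enter_submenu`, `undo`, `issue_command`, `noop`) and, for
#'   `issue_command`, the 1-based `command = c(main, sub)`.
#' @export
menu_step <- function(state, event) {
  stopifnot(inherits(state, "menu_state"))
  if (!event %in% menu_events)
    stop("unknown event '", event, "'; valid: ",
         paste(menu_events, collapse = ", "))
  k <- if (startsWith(event, "ssvep_")) as.integer(sub("ssvep_", "", event))
       else NA_integer_
  noop <- list(state = state, action = list(type = "noop"))
  switch(state$phase,
    MAIN_SELECT = {
      if (is.na(k)) return(noop)
      state$phase <- "MAIN_CONFIRM"; state$pending_main <- k
      list(state = state, action = list(type = "prompt", main = k))
    },
    MAIN_CONFIRM = {
      if (event == "single_blink") {
        state$phase <- "SUB_SELECT"
        list(state = state, action = list(type = "enter_submenu",
                                          main = state$pending_main))
      } else if (event == "double_blink") {
        list(state = menu_state(), action = list(type = "undo"))
      } else noop
    },
    SUB_SELECT = {
      if (is.na(k)) return(noop)
      state$phase <- "SUB_CONFIRM"; state$pending_sub <- k
      list(state = state, action = list(type = "prompt", sub = k))
    },
    SUB_CONFIRM = {
      if (event == "single_blink") {
        state$phase <- "DONE"
        list(state = state,
             action = list(type = "issue_command",
                           command = c(state$pending_main, state$pending_sub)))
      } else if (event == "double_blink") {
        state$phase <- "SUB_SELECT"; state$pending_sub <- NA_integer_
        list(state = state, action = list(type = "undo"))
      } else noop
    },
    DONE = noop)
}

#' Command inventory of a menu
#'
#' @param menu a [menu_spec()].
#' @return List with `n_leaf` (main x sub leaf commands), `n_blink` (the two
#'   blink calibration events) and `total`.
#' @export
command_inventory <- function(menu = menu_spec()) {
  n_leaf <- length(menu$main) * length(menu$subs[[1]])
  list(n_leaf = n_leaf, n_blink = 2L, total = n_leaf + 2L)
}

# Map a decoder class label to a menu event via the stimulus frequency order.
label_to_event <- function(label, menu, classes) {
  if (label %in% c("single_blink", "double_blink")) return(label)
  k <- match(label, classes[seq_len(6)])
  if (is.na(k)) stop("decoded label '", label, "' is not in the event space")
  paste0("ssvep_", k)
}

#' Run a closed-loop decoding session
#'
#' Consumes the stream in consecutive non-overlapping `epoch_s` windows,
#' decodes each window with [predict_epoch()], feeds the decoded events to
#' [menu_step()], and records every event with its action, latency (window
#' onset to action, i.e. `epoch_s` here since an action fires at the window
#' boundary) and — when a ground-truth event log is supplied — the true class
#' overlapping the window.  After a command is issued the menu resets to
#' `MAIN_SELECT`.
#'
#' @param stream an [eeg_stream()]; a two-channel O1/O2 stream is reduced
#'   with [make_bipolar()] first.
#' @param model a trained `ssvep_cnn` over the 8-class space.
#' @param menu a [menu_spec()].
#' @param epoch_s decoding window length in seconds.
#' @param truth optional ground-truth event log (`onset`, `duration`,
#'   `class`), e.g. from [make_session_stream()].
#' @return A `session_log`: `events` data frame (`time`, `decoded`, `true`,
#'   `action`), `issued_commands` data frame (`time`, `main`, `sub`,
#'   `main_label`, `sub_label`), and `response_times` (per decoded event
#'   class, seconds).
#' @export
run_closed_loop <- function(stream, model, menu = menu_spec(),
                            epoch_s = 2.0, truth = NULL) {
  stopifnot(inherits(stream, "eeg_stream"))
  if (all(c("O1", "O2") %in% stream$channels)) stream <- make_bipolar(stream)
  n_ep <- floor(ncol(stream$samples) / (stream$fs * epoch_s))
  if (n_ep < 1L)
    stop("stream (", ncol(stream$samples) / stream$fs,
         " s) is shorter than one ", epoch_s, " s epoch")
  state <- menu_state()
  events <- vector("list", n_ep)
  issued <- list()
  for (i in seq_len(n_ep)) {
    onset <- stream$t0 + (i - 1) * epoch_s
    ep <- extract_epoch(stream, onset, epoch_s)
    decoded <- predict_epoch(model, ep)
    event <- label_to_event(decoded, menu, model$classes)
    res <- menu_step(state, event)
    state <- res$state
    true_class <- NA_character_
    if (!is.null(truth)) {
      hit <- which(truth$onset < onset + epoch_s &
                     truth$onset + truth$duration > onset)
      if (length(hit)) true_class <- truth$class[hit[1]]
    }
    events[[i]] <- data.frame(time = onset + epoch_s, decoded = decoded,
                              true = true_class, action = res$action$type,
                              latency = epoch_s)
    if (res$action$type == "issue_command") {
      cmd <- res$action$command
      issued[[length(issued) + 1L]] <-
        data.frame(time = onset + epoch_s, main = cmd[1], sub = cmd[2],
                   main_label = menu$main[cmd[1]],
                   sub_label = menu$subs[[cmd[1]]][cmd[2]])
      state <- menu_state()
    }
  }
  events <- do.call(rbind, events)
  issued <- if (length(issued)) do.call(rbind, issued) else
    data.frame(time = numeric(0), main = integer(0), sub = integer(0),
               main_label = character(0), sub_label = character(0))
  rt <- tapply(events$latency, events$decoded, mean)
  structure(list(events = events, issued_commands = issued,
                 response_times = rt, final_state = state),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %d epochs decoded, %d command(s) issued\n",
              nrow(x$events), nrow(x$issued_commands)))
  if (nrow(x$issued_commands)) print(x$issued_commands)
  invisible(x)
}
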