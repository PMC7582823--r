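test_that("menu specification counts 36 leaf commands plus 2 blink commands", {
  menu <- menu_spec()
  inv <- command_inventory(menu)
  expect_equal(inv$n_leaf, 36L)
  expect_equal(inv$n_blink, 2L)
  expect_equal(inv$total, 38L)

  # the formula generalizes: a 2x2 toy menu gives 4 + 2 = 6
  toy <- structure(list(main = c("a", "b"),
                        subs = list(c("a1", "a2"), c("b1", "b2")),
                        frequencies = c(10, 12)),
                   class = "menu_spec")
  expect_equal(command_inventory(toy)$total, 6L)

  expect_error(menu_spec(main = c("a", "b")), "6 main categories")
  expect_error(menu_spec(frequencies = c(1, 1, 2, 3, 4, 5)), "bijection")
})

test_that("the transition table follows the select/confirm/undo protocol", {
  s0 <- menu_state()
  expect_equal(s0$phase, "MAIN_SELECT")

  r1 <- menu_step(s0, "ssvep_3")
  expect_equal(r1$state$phase, "MAIN_CONFIRM")
  expect_equal(r1$state$pending_main, 3L)
  expect_equal(r1$action$type, "prompt")

  # double blink in a confirm phase undoes the pending selection
  r2 <- menu_step(r1$state, "double_blink")
  expect_equal(r2$state$phase, "MAIN_SELECT")
  expect_true(is.na(r2$state$pending_main))
  expect_equal(r2$action$type, "undo")

  # single blink confirms into the submenu and a second select/confirm issues
  r3 <- menu_step(r1$state, "single_blink")
  expect_equal(r3$state$phase, "SUB_SELECT")
  expect_equal(r3$action$type, "enter_submenu")
  r4 <- menu_step(r3$state, "ssvep_6")
  expect_equal(r4$state$phase, "SUB_CONFIRM")
  r5 <- menu_step(r4$state, "single_blink")
  expect_equal(r5$state$phase, "DONE")
  expect_equal(r5$action$type, "issue_command")
  expect_equal(r5$action$command, c(3L, 6L))

  # undo from SUB_CONFIRM returns to SUB_SELECT, keeping the main selection
  r6 <- menu_step(r4$state, "double_blink")
  expect_equal(r6$state$phase, "SUB_SELECT")
  expect_equal(r6$state$pending_main, 3L)
  expect_true(is.na(r6$state$pending_sub))
})

test_that("every phase/event pair has a defined transition", {
  phases <- list(
    MAIN_SELECT = menu_state(),
    MAIN_CONFIRM = menu_step(menu_state(), "ssvep_1")$state,
    SUB_SELECT = menu_step(menu_step(menu_state(), "ssvep_1")$state,
                           "single_blink")$state,
    SUB_CONFIRM = menu_step(menu_step(menu_step(menu_state(), "ssvep_1")$state,
                                      "single_blink")$state, "ssvep_2")$state,
    DONE = menu_step(menu_step(menu_step(menu_step(menu_state(),
             "ssvep_1")$state, "single_blink")$state, "ssvep_2")$state,
             "single_blink")$state)
  events <- c(paste0("ssvep_", 1:6), "single_blink", "double_blink")
  for (ph in names(phases)) {
    expect_equal(phases[[ph]]$phase, ph)
    for (ev in events) {
      res <- menu_step(phases[[ph]], ev)
      expect_true(res$action$type %in%
                    c("prompt", "enter_submenu", "undo", "issue_command", "noop"),
                  label = paste(ph, "+", ev))
      expect_true(res$state$phase %in%
                    c("MAIN_SELECT", "MAIN_CONFIRM", "SUB_SELECT",
                      "SUB_CONFIRM", "DONE"))
    }
  }
  expect_error(menu_step(menu_state(), "wink"), "unknown event")
})

test_that("each of the 36 leaf commands is issued by its unique minimal script", {
  seen <- character(0)
  for (m in 1:6) for (s in 1:6) {
    st <- menu_state()
    script <- c(paste0("ssvep_", m), "single_blink",
                paste0("ssvep_", s), "single_blink")
    actions <- character(0)
    for (ev in script) {
      res <- menu_step(st, ev)
      st <- res$state
      actions <- c(actions, res$action$type)
    }
    expect_equal(actions, c("prompt", "enter_submenu", "prompt",
                            "issue_command"))
    seen <- c(seen, paste(m, s))
  }
  expect_length(unique(seen), 36L)
})

test_that("double-blink undo restores the phase preceding the selection", {
  # MAIN_CONFIRM -> MAIN_SELECT
  st <- menu_step(menu_state(), "ssvep_4")$state
  expect_equal(menu_step(st, "double_blink")$state$phase, "MAIN_SELECT")
  # SUB_CONFIRM -> SUB_SELECT for every pending pair
  for (m in 1:6) for (s in 1:6) {
    st <- menu_step(menu_step(menu_step(menu_state(), paste0("ssvep_", m))$state,
                              "single_blink")$state, paste0("ssvep_", s))$state
    back <- menu_step(st, "double_blink")$state
    expect_equal(back$phase, "SUB_SELECT")
    expect_equal(back$pending_main, m)
  }
})

test_that("closed-loop decoding issues exactly the scripted command", {
  fx <- trained_fixture()
  cfg_hi <- signal_model_config(snr_db = 40)

  script <- data.frame(onset = c(0, 2, 4, 6), duration = rep(2, 4),
                       intent = c("ssvep_8.57", "single_blink",
                                  "ssvep_11", "single_blink"))
  sess <- make_session_stream(script, cfg_hi, seed = 56)
  log <- run_closed_loop(sess$stream, fx$fit$model, truth = sess$events)
  expect_equal(nrow(log$issued_commands), 1L)
  # ssvep_8.57 is stimulus index 3, ssvep_11 is index 5
  expect_equal(log$issued_commands$main, 3L)
  expect_equal(log$issued_commands$sub, 5L)
  expect_equal(log$events$decoded, script$intent)
  expect_equal(log$events$true, script$intent)

  # gaze then double blink: selection undone, nothing issued
  script2 <- data.frame(onset = c(0, 2), duration = rep(2, 2),
                        intent = c("ssvep_8.57", "double_blink"))
  sess2 <- make_session_stream(script2, cfg_hi, seed = 56)
  log2 <- run_closed_loop(sess2$stream, fx$fit$model, truth = sess2$events)
  expect_equal(nrow(log2$issued_commands), 0L)
  expect_equal(log2$final_state$phase, "MAIN_SELECT")

  # per-class decoded-vs-truth accounting has one row per epoch
  expect_equal(nrow(log$events), 4L)
  expect_error(run_closed_loop(
    eeg_stream(rnorm(100), 500, "BIPOLAR"), fx$fit$model), "shorter than one")
})
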