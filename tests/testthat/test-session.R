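fixture_log <- function() {
  read_session_log(system.file("extdata", "session_log.jsonl",
                               package = "dresstrack"))
}

test_that("presence starts the session with the first drawer green", {
  res <- session_step(new_session(session_config()),
                      session_event(0, "presence"))
  expect_identical(res$prompts$prompt_id, "open_drawer_1")
  expect_identical(res$prompts$green_drawer, 1L)
})

test_that("events before presence are ignored with a logged warning", {
  st <- new_session(session_config())
  res <- session_step(st, session_event(1, "drawer_open", index = 1L))
  expect_identical(nrow(res$prompts), 0L)
  expect_match(res$state$warnings, "before presence")
})

test_that("wrong drawer triggers a redirect to the green drawer", {
  st <- session_step(new_session(session_config()),
                     session_event(0, "presence"))$state
  res <- session_step(st, session_event(2, "drawer_open", index = 3L))
  expect_identical(res$prompts$prompt_id, "redirect_to_drawer_1")
})

test_that("completion plus drawer close advances garments and finally completes", {
  cfg <- session_config(mode = "independent")
  st <- new_session(cfg)
  feed <- function(st, ...) session_step(st, session_event(...))
  st <- feed(st, 0, "presence")$state
  st <- feed(st, 1, "drawer_open", index = 1L)$state
  st <- feed(st, 2, "rfid_removed", drawer = 1L)$state
  res <- feed(st, 10, "detection", label = "C", garment = "shirt")
  expect_identical(res$prompts$prompt_id, "close_drawer_1")  # no praise
  res2 <- session_step(res$state, session_event(12, "drawer_close",
                                                index = 1L))
  expect_identical(res2$prompts$prompt_id, "open_drawer_2")
  expect_identical(res2$prompts$green_drawer, 2L)
  st <- res2$state
  st <- feed(st, 13, "drawer_open", index = 2L)$state
  st <- feed(st, 14, "rfid_removed", drawer = 2L)$state
  st <- feed(st, 20, "detection", label = "C", garment = "pants")$state
  res3 <- session_step(st, session_event(22, "drawer_close", index = 2L))
  expect_identical(res3$alerts$kind, "completed")
  expect_true(res3$state$completed)
  # a drawer close without prior C does not advance
  st4 <- feed(new_session(cfg), 0, "presence")$state
  res4 <- session_step(st4, session_event(1, "drawer_close", index = 1L))
  expect_identical(nrow(res4$prompts), 0L)
  expect_identical(res4$state$active, 1L)
})

test_that("detections before the garment leaves its drawer are ignored", {
  st <- session_step(new_session(session_config()),
                     session_event(0, "presence"))$state
  res <- session_step(st, session_event(3, "detection", label = "C",
                                        garment = "shirt"))
  expect_identical(nrow(res$prompts), 0L)
  expect_match(res$state$warnings, "ignored detection")
})

test_that("stress escalation follows the episode algebra", {
  cfg <- session_config(stress_soothe_level = 0.5, stress_alert_level = 0.8)
  series <- function(levels) data.frame(t = seq_along(levels), level = levels)
  expect_identical(escalate_stress(series(c(0.2, 0.6, 0.9)), cfg)$kind,
                   c("soothe", "caregiver_notify"))
  expect_identical(escalate_stress(series(c(0.2, 0.6, 0.3, 0.6)), cfg)$kind,
                   c("soothe", "soothe"))
  expect_identical(nrow(escalate_stress(series(c(0.1, 0.1, 0.1)), cfg)), 0L)
  # alert requires strictly exceeding the alert level, once per episode
  expect_identical(escalate_stress(series(c(0.6, 0.8, 0.8)), cfg)$kind,
                   "soothe")
  expect_identical(escalate_stress(series(c(0.6, 0.9, 0.95)), cfg)$kind,
                   c("soothe", "caregiver_notify"))
})

test_that("stuck detection combines stall, stress and repeated corrections", {
  cfg <- session_config(stall_s = 10, stress_soothe_level = 0.5,
                        max_corrections = 3)
  w <- rbind(session_event(0, "detection", label = "R", garment = "shirt"),
             session_event(11, "stress", level = 0.8),
             session_event(12, "stress", level = 0.8))
  expect_true(stuck_check(w, cfg))
  # steady progress resets the stall regardless of stress
  w2 <- rbind(session_event(0, "detection", label = "R", garment = "shirt"),
              session_event(11, "detection", label = "L", garment = "shirt"),
              session_event(12, "stress", level = 0.9))
  expect_false(stuck_check(w2, cfg))
  expect_false(stuck_check(w[0, ], cfg))
  # enough corrective detections alone suffice
  w3 <- do.call(rbind, lapply(1:3, function(i)
    session_event(i, "detection", label = "B", garment = "shirt")))
  expect_true(stuck_check(w3, cfg))
  # stalled but calm: not stuck
  w4 <- rbind(session_event(0, "detection", label = "R", garment = "shirt"),
              session_event(15, "stress", level = 0.2))
  expect_false(stuck_check(w4, cfg))
})

test_that("replaying the fixture log reproduces the golden transcript byte for byte", {
  golden <- c(
    '{"t": 0.0, "type": "prompt", "prompt_id": "open_drawer_1", "class": "navigation", "green_drawer": 1}',
    '{"t": 2.0, "type": "prompt", "prompt_id": "redirect_to_drawer_1", "class": "navigation", "green_drawer": 1}',
    '{"t": 4.0, "type": "prompt", "prompt_id": "take_out_shirt", "class": "progress", "green_drawer": 1}',
    '{"t": 6.0, "type": "prompt", "prompt_id": "don_shirt", "class": "progress", "green_drawer": 1}',
    '{"t": 10.0, "type": "prompt", "prompt_id": "correct_back_to_front", "class": "corrective", "green_drawer": 1}',
    '{"t": 15.0, "type": "prompt", "prompt_id": "progress_R", "class": "progress", "green_drawer": 1}',
    '{"t": 16, "type": "alert", "kind": "soothe"}',
    '{"t": 17, "type": "alert", "kind": "caregiver_notify"}',
    '{"t": 20.0, "type": "prompt", "prompt_id": "progress_L", "class": "progress", "green_drawer": 1}',
    '{"t": 20.5, "type": "prompt", "prompt_id": "progress_A", "class": "progress", "green_drawer": 1}',
    '{"t": 25.0, "type": "prompt", "prompt_id": "shirt_complete", "class": "progress", "green_drawer": 1}',
    '{"t": 25.0, "type": "prompt", "prompt_id": "close_drawer_1", "class": "navigation", "green_drawer": 1}',
    '{"t": 27.0, "type": "prompt", "prompt_id": "open_drawer_2", "class": "navigation", "green_drawer": 2}',
    '{"t": 29.0, "type": "prompt", "prompt_id": "take_out_pants", "class": "progress", "green_drawer": 2}',
    '{"t": 31.0, "type": "prompt", "prompt_id": "don_pants", "class": "progress", "green_drawer": 2}',
    '{"t": 35.0, "type": "prompt", "prompt_id": "progress_R", "class": "progress", "green_drawer": 2}',
    '{"t": 40.0, "type": "prompt", "prompt_id": "progress_L", "class": "progress", "green_drawer": 2}',
    '{"t": 45.0, "type": "prompt", "prompt_id": "pants_complete", "class": "progress", "green_drawer": 2}',
    '{"t": 45.0, "type": "prompt", "prompt_id": "close_drawer_2", "class": "navigation", "green_drawer": 2}',
    '{"t": 47, "type": "alert", "kind": "completed"}'
  )
  out <- run_session(fixture_log(), session_config(mode = "continuous"))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_session_transcript(out, path)
  expect_identical(readLines(path), golden)
})

test_that("session replay is deterministic and modes differ only in progress prompts", {
  for (seed in 1:10) {
    log <- fuzz_log(seed)
    cont1 <- run_session(log, session_config(mode = "continuous"))
    cont2 <- run_session(log, session_config(mode = "continuous"))
    expect_identical(format_transcript_lines(cont1),
                     format_transcript_lines(cont2))
    indep <- run_session(log, session_config(mode = "independent"))
    # corrective and navigation prompts identical across modes
    non_prog <- function(o) {
      d <- o$prompts[o$prompts$class != "progress", ]
      rownames(d) <- NULL
      d
    }
    expect_identical(non_prog(cont1), non_prog(indep))
    # independent mode emits no progress/praise prompts at all
    expect_identical(nrow(indep$prompts[indep$prompts$class == "progress", ]),
                     0L)
    # alerts (stress path) are mode-independent
    expect_identical(cont1$alerts, indep$alerts)
    # light exclusivity: each prompt has exactly one green drawer
    expect_true(all(cont1$prompts$green_drawer >= 1L &
                      cont1$prompts$green_drawer <= 5L))
  }
})
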