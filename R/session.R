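SESSION_KINDS <- c("presence", "drawer_open", "drawer_close", "rfid_removed",
                   "detection", "stress")

# Prompt catalog keys for corrective detections.  Prompt text itself is
# resolved outside the package (supporting recorded-caregiver-voice
# customization); the state machine deals only in prompt IDs.
CORRECTIVE_PROMPTS <- c(B = "correct_back_to_front",
                        I = "correct_inside_out",
                        M = "correct_misaligned",
                        p = "correct_partial")
PROGRESS_LABELS <- c("R", "L", "A", "C")

#' Construct one dressing-session event
#'
#' @param t Time in seconds.
#' @param kind One of `"presence"`, `"drawer_open"`, `"drawer_close"`,
#'   `"rfid_removed"`, `"detection"`, `"stress"`.
#' @param index Drawer index (for `drawer_open`/`drawer_close`).
#' @param drawer Drawer index (for `rfid_removed`).
#' @param label,garment Detection label and garment (for `detection`).
#' @param level Stress level, unitless `>= 0` (for `stress`).
#' @return One-row data frame of class `session_events`.
#' @export
session_event <- function(t, kind, index = NA_integer_, drawer = NA_integer_,
                          label = NA_character_, garment = NA_character_,
                          level = NA_real_) {
  kind <- match.arg(kind, SESSION_KINDS)
  df <- data.frame(t = as.numeric(t), kind = kind,
                   index = as.integer(index), drawer = as.integer(drawer),
                   label = as.character(label),
                   garment = as.character(garment),
                   level = as.numeric(level))
  class(df) <- c("session_events", "data.frame")
  df
}

validate_session_log <- function(log) {
  stopifnot(is.data.frame(log), all(log$kind %in% SESSION_KINDS))
  if (is.unsorted(log$t)) {
    stop("session log timestamps must be non-decreasing", call. = FALSE)
  }
  class(log) <- c("session_events", "data.frame")
  log
}

#' Dressing-session configuration
#'
#' @param mode `"continuous"` (step-by-step narration and praise) or
#'   `"independent"` (corrective and navigation prompts only; no audio when
#'   a garment is donned correctly).
#' @param garment_order Character vector: the garment in each drawer, in
#'   drawer order (default shirt in drawer 1, pants in drawer 2).
#' @param n_drawers Number of drawers on the dresser (default 5); drawers
#'   beyond the garment list stay red.
#' @param stress_soothe_level Stress level at which a soothing activity is
#'   started (default 0.5).
#' @param stress_alert_level Higher stress level at which the caregiver is
#'   notified if soothing did not help (default 0.8).
#' @param stall_s Seconds without progress before the wearer counts as
#'   stuck (default 10).
#' @param max_corrections Corrective prompts tolerated before escalation
#'   (default 3).
#' @return An object of class `session_config`.
#' @export
session_config <- function(mode = c("continuous", "independent"),
                           garment_order = c("shirt", "pants"),
                           n_drawers = 5L,
                           stress_soothe_level = 0.5,
                           stress_alert_level = 0.8,
                           stall_s = 10,
                           max_corrections = 3L) {
  mode <- match.arg(mode)
  garment_order <- vapply(garment_order, match_garment, character(1),
                          USE.NAMES = FALSE)
  stopifnot(n_drawers >= length(garment_order),
            stress_alert_level > stress_soothe_level,
            stall_s > 0, max_corrections >= 1)
  structure(list(mode = mode, garment_order = garment_order,
                 n_drawers = as.integer(n_drawers),
                 stress_soothe_level = stress_soothe_level,
                 stress_alert_level = stress_alert_level,
                 stall_s = stall_s,
                 max_corrections = as.integer(max_corrections)),
            class = "session_config")
}

#' Create a fresh dressing-session state
#'
#' @param config A [session_config()].
#' @return An opaque session state for [session_step()].
#' @export
new_session <- function(config = session_config()) {
  stopifnot(inherits(config, "session_config"))
  structure(
    list(config = config, clock = -Inf, started = FALSE, completed = FALSE,
         active = 0L, armed = FALSE, c_reached = FALSE, corrections = 0L,
         in_episode = FALSE, notified = FALSE, warnings = character()),
    class = "session_state"
  )
}

empty_prompts <- function() {
  data.frame(t = numeric(), prompt_id = character(), class = character(),
             green_drawer = integer())
}

empty_alerts <- function() {
  data.frame(t = numeric(), kind = character())
}

prompt_row <- function(t, prompt_id, class, green_drawer) {
  data.frame(t = t, prompt_id = prompt_id, class = class,
             green_drawer = as.integer(green_drawer))
}

#' Advance the session state machine by one event
#'
#' A pure transition: the same state and event always produce the same new
#' state and outputs.  Events arriving before presence confirmation are
#' ignored with a logged warning (hardware can misfire).
#'
#' @param state Session state from [new_session()] or a previous step.
#' @param event A one-row [session_event()].
#' @return A list with elements `state`, `prompts` (data frame `t`,
#'   `prompt_id`, `class`, `green_drawer`) and `alerts` (data frame `t`,
#'   `kind`).
#' @export
session_step <- function(state, event) {
  stopifnot(inherits(state, "session_state"), nrow(event) == 1L)
  t <- event$t
  if (t < state$clock) {
    stop(sprintf("event at t=%g precedes session clock t=%g", t, state$clock),
         call. = FALSE)
  }
  state$clock <- t
  cfg <- state$config
  prompts <- empty_prompts()
  alerts <- empty_alerts()
  continuous <- cfg$mode == "continuous"
  add_prompt <- function(id, class) {
    prompts <<- rbind(prompts, prompt_row(t, id, class, state$active))
  }
  add_alert <- function(kind) {
    alerts <<- rbind(alerts, data.frame(t = t, kind = kind))
  }

  if (!state$started) {
    if (event$kind == "presence") {
      state$started <- TRUE
      state$active <- 1L
      add_prompt(sprintf("open_drawer_%d", state$active), "navigation")
    } else {
      state$warnings <- c(state$warnings,
                          sprintf("ignored %s at t=%g before presence",
                                  event$kind, t))
    }
    return(list(state = state, prompts = prompts, alerts = alerts))
  }

  garment <- cfg$garment_order[state$active]
  switch(event$kind,
    presence = NULL,
    drawer_open = {
      if (!state$completed) {
        if (identical(event$index, state$active)) {
          if (continuous) add_prompt(paste0("take_out_", garment), "progress")
        } else {
          add_prompt(sprintf("redirect_to_drawer_%d", state$active),
                     "navigation")
        }
      }
    },
    drawer_close = {
      if (!state$completed && identical(event$index, state$active) &&
          state$c_reached) {
        if (state$active == length(cfg$garment_order)) {
          state$completed <- TRUE
          add_alert("completed")
        } else {
          state$active <- state$active + 1L
          state$armed <- FALSE
          state$c_reached <- FALSE
          state$corrections <- 0L
          add_prompt(sprintf("open_drawer_%d", state$active), "navigation")
        }
      }
    },
    rfid_removed = {
      if (!state$completed && identical(event$drawer, state$active)) {
        state$armed <- TRUE
        if (continuous) add_prompt(paste0("don_", garment), "progress")
      }
    },
    detection = {
      if (!state$armed || state$completed) {
        state$warnings <- c(state$warnings,
                            sprintf("ignored detection %s at t=%g (%s)",
                                    event$label, t,
                                    if (state$completed) "session complete"
                                    else "drawer not yet opened"))
      } else if (event$label == "C") {
        state$c_reached <- TRUE
        if (continuous) add_prompt(paste0(garment, "_complete"), "progress")
        add_prompt(sprintf("close_drawer_%d", state$active), "navigation")
      } else if (event$label %in% names(CORRECTIVE_PROMPTS)) {
        state$corrections <- state$corrections + 1L
        add_prompt(CORRECTIVE_PROMPTS[[event$label]], "corrective")
      } else if (event$label %in% c("R", "L", "A")) {
        if (continuous) add_prompt(paste0("progress_", event$label),
                                   "progress")
      }
    },
    stress = {
      lvl <- event$level
      if (lvl < cfg$stress_soothe_level) {
        state$in_episode <- FALSE
        state$notified <- FALSE
      } else {
        if (!state$in_episode) {
          state$in_episode <- TRUE
          state$notified <- FALSE
          add_alert("soothe")
        } else if (!state$notified && lvl > cfg$stress_alert_level) {
          state$notified <- TRUE
          add_alert("caregiver_notify")
        }
      }
    }
  )
  list(state = state, prompts = prompts, alerts = alerts)
}

#' Replay a session event log through the state machine
#'
#' @param log A `session_events` data frame (e.g. from
#'   [read_session_log()]), time-ordered.
#' @param config A [session_config()].
#' @return An object of class `session_output`: list with data frames
#'   `prompts` and `alerts`, plus `warnings` (character) and the final
#'   `state`.
#' @export
run_session <- function(log, config = session_config()) {
  log <- validate_session_log(log)
  state <- new_session(config)
  prompts <- list()
  alerts <- list()
  for (i in seq_len(nrow(log))) {
    res <- session_step(state, log[i, , drop = FALSE])
    state <- res$state
    if (nrow(res$prompts)) prompts[[length(prompts) + 1L]] <- res$prompts
    if (nrow(res$alerts)) alerts[[length(alerts) + 1L]] <- res$alerts
  }
  structure(
    list(prompts = do.call(rbind, c(prompts, list(empty_prompts()))),
         alerts = do.call(rbind, c(alerts, list(empty_alerts()))),
         warnings = state$warnings,
         state = state),
    class = "session_output"
  )
}

#' @export
print.session_output <- function(x, ...) {
  cat(sprintf("<session_output> %d prompt(s), %d alert(s)\n",
              nrow(x$prompts), nrow(x$alerts)))
  invisible(x)
}

#' Is the wearer stuck?
#'
#' TRUE iff either no progress-class detection (R, L, A or C) has occurred
#' for at least `stall_s` while the latest stress reading is at or above the
#' soothe threshold, or the number of corrective detections (B, I, M, p) in
#' the window has reached `max_corrections`.
#'
#' @param recent A time-ordered window of session events.
#' @param config A [session_config()].
#' @return Logical scalar.
#' @export
stuck_check <- function(recent, config = session_config()) {
  if (is.null(recent) || nrow(recent) == 0L) return(FALSE)
  recent <- validate_session_log(recent)
  t_end <- recent$t[nrow(recent)]
  is_det <- recent$kind == "detection"
  progress_t <- recent$t[is_det & recent$label %in% PROGRESS_LABELS]
  last_progress <- if (length(progress_t)) max(progress_t) else recent$t[1]
  stalled <- (t_end - last_progress) >= config$stall_s
  stress_lv <- recent$level[recent$kind == "stress"]
  latest_stress <- if (length(stress_lv)) stress_lv[length(stress_lv)] else 0
  corrections <- sum(is_det & recent$label %in% names(CORRECTIVE_PROMPTS))
  (stalled && latest_stress >= config$stress_soothe_level) ||
    corrections >= config$max_corrections
}

#' Stress-escalation over a stress sample series
#'
#' Crossing the soothe threshold starts an episode and emits a `soothe`
#' alert once; a later sample strictly above the alert threshold emits
#' `caregiver_notify` once; the episode resets when stress falls back below
#' the soothe threshold.
#'
#' @param stress_series Data frame with columns `t` and `level`,
#'   time-ordered.
#' @param config A [session_config()].
#' @return Data frame of alerts (`t`, `kind`).
#' @export
escalate_stress <- function(stress_series, config = session_config()) {
  stopifnot(all(c("t", "level") %in% names(stress_series)),
            !is.unsorted(stress_series$t))
  state <- new_session(config)
  state$started <- TRUE
  state$active <- 1L
  alerts <- list()
  for (i in seq_len(nrow(stress_series))) {
    res <- session_step(state, session_event(stress_series$t[i], "stress",
                                             level = stress_series$level[i]))
    state <- res$state
    if (nrow(res$alerts)) alerts[[length(alerts) + 1L]] <- res$alerts
  }
  do.call(rbind, c(alerts, list(empty_alerts())))
}
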