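ERROR_MODES <- c("correct", "back_to_front", "inside_out", "partial",
                 "misaligned")

#' Construct a dressing condition
#'
#' A condition pairs a garment with an acted error mode.  Misalignment is a
#' velcro-closure error and therefore shirt-only, giving 5 shirt + 4 pants
#' conditions.
#'
#' @param garment `"shirt"` or `"pants"`.
#' @param error_mode One of `"correct"`, `"back_to_front"`, `"inside_out"`,
#'   `"partial"`, `"misaligned"`.
#' @return An object of class `dressing_condition`.
#' @export
condition <- function(garment, error_mode) {
  garment <- match_garment(garment)
  error_mode <- match.arg(error_mode, ERROR_MODES)
  if (garment == "pants" && error_mode == "misaligned") {
    stop("misaligned is a shirt-only condition (pants have no velcro closure)",
         call. = FALSE)
  }
  structure(list(garment = garment, error_mode = error_mode),
            class = "dressing_condition")
}

#' @export
print.dressing_condition <- function(x, ...) {
  cat("<condition>", condition_id(x), "\n")
  invisible(x)
}

condition_id <- function(condition) {
  paste(condition$garment, condition$error_mode, sep = ":")
}

#' All nine study dressing conditions
#'
#' @return A list of 9 `dressing_condition` objects: 5 shirt conditions
#'   (correct, back-to-front, inside-out, partial, misaligned) and 4 pants
#'   conditions (the same minus misaligned).
#' @export
dressing_conditions <- function() {
  out <- list()
  for (g in GARMENTS) {
    modes <- if (g == "shirt") ERROR_MODES else setdiff(ERROR_MODES, "misaligned")
    for (m in modes) out[[length(out) + 1L]] <- condition(g, m)
  }
  out
}

phase_expectation <- function(phase, required = list(), optional = character()) {
  required <- lapply(required, as.character)
  optional <- as.character(optional)
  stopifnot(phase %in% 1:6,
            !any(unlist(required) %in% optional) || length(required) == 0L)
  list(phase = as.integer(phase), required = required, optional = optional)
}

#' Expected detections per dressing phase for a condition
#'
#' Transcribes the study's expectation table: for each of the six dressing
#' phases, the detections that must occur (`required`, a list of
#' alternative sets where any one member satisfies the requirement, e.g.
#' `c("R", "L")` for "either side first") and the detections that are
#' acceptable but not required (`optional`, e.g. transient back/inside
#' sightings while the garment is handled).
#'
#' @param condition A [condition()].
#' @return A list of six phase expectations, each with elements `phase`,
#'   `required` (list of character vectors) and `optional` (character).
#' @export
#' @examples
#' expected_for(condition("pants", "correct"))[[6]]
expected_for <- function(condition) {
  stopifnot(inherits(condition, "dressing_condition"))
  g <- condition$garment
  m <- condition$error_mode
  RL <- c("R", "L")
  LR <- c("L", "R")
  ph <- vector("list", 6)
  if (g == "pants") {
    ph[[2]] <- phase_expectation(2, required = list(RL))
    ph[[3]] <- phase_expectation(3)
    ph[[4]] <- phase_expectation(4, required = list(LR))
    ph[[5]] <- phase_expectation(5)
    ph[[6]] <- phase_expectation(6, required = list("C"))
    ph[[1]] <- switch(m,
      correct = phase_expectation(1, optional = "B"),
      back_to_front = phase_expectation(1, required = list("B")),
      inside_out = phase_expectation(1, required = list("I"), optional = "B"),
      partial = phase_expectation(1, optional = "B"))
  } else {
    ph[[2]] <- phase_expectation(2, required = list(RL))
    ph[[4]] <- phase_expectation(4, required = list(LR))
    ph[[6]] <- phase_expectation(6, required = list("C"))
    ph[[1]] <- switch(m,
      correct = ,
      misaligned = ,
      partial = phase_expectation(1, required = list("F"),
                                  optional = c("B", "I")),
      back_to_front = phase_expectation(1, required = list("F", "B"),
                                        optional = "I"),
      inside_out = phase_expectation(1, required = list("F", "I"),
                                     optional = "B"))
    ph[[3]] <- switch(m,
      inside_out = phase_expectation(3, optional = c("p", "R", "L")),
      partial = phase_expectation(3, required = list("p"),
                                  optional = c("I", "R", "L")),
      phase_expectation(3, optional = c("p", "I", "R", "L")))
    ph[[5]] <- switch(m,
      misaligned = phase_expectation(5, required = list("A", "M"),
                                     optional = "I"),
      inside_out = phase_expectation(5, required = list("A"),
                                     optional = c("M", "I")),
      phase_expectation(5, required = list("A"), optional = c("M", "I", "p")))
  }
  ph
}

#' Segment a detection sequence into the six dressing phases
#'
#' Milestone-based segmentation computable from the event stream alone:
#' phase 1 is everything before the first side (R or L) event; phase 2 is
#' that event; phase 3 everything strictly between it and the first event of
#' the opposite side; phase 4 that opposite-side event; phase 5 everything
#' between it and the first subsequent C; phase 6 the first C and everything
#' after.  Missing milestones leave later phases empty (their events remain
#' in the last open phase).
#'
#' @param events A time-ordered `detection_events` data frame.
#' @param condition The trial's [condition()] (carried for context; the
#'   segmentation itself depends only on the events).
#' @return A list of six `detection_events` data frames, named `"1"`..`"6"`.
#' @export
segment_phases <- function(events, condition = NULL) {
  n <- nrow(events)
  phase <- integer(n)
  if (n) {
    phase[] <- 1L
    i2 <- match(TRUE, events$label %in% c("R", "L"))
    if (!is.na(i2)) {
      phase[i2] <- 2L
      side1 <- events$label[i2]
      opp <- if (side1 == "R") "L" else "R"
      after2 <- seq_len(n) > i2
      phase[after2] <- 3L
      i4 <- match(TRUE, events$label == opp & after2)
      if (!is.na(i4)) {
        phase[i4] <- 4L
        after4 <- seq_len(n) > i4
        phase[after4] <- 5L
        i6 <- match(TRUE, events$label == "C" & after4)
        if (!is.na(i6)) phase[seq_len(n) >= i6] <- 6L
      }
    }
  }
  stats::setNames(
    lapply(1:6, function(k) events[phase == k, , drop = FALSE]),
    as.character(1:6)
  )
}

#' Score one trial's detections against its condition's expectations
#'
#' For each phase, every required alternative set with no matching event
#' contributes one missed entry, and every label observed in the phase that
#' is in neither the required nor the optional set contributes one
#' unexpected entry.  Repeated occurrences of the same label within one
#' phase count once toward requirements and are never unexpected; the
#' extras are tallied in a separate `repeats` diagnostic.
#'
#' @param events A `detection_events` data frame for one trial.
#' @param condition The trial's [condition()].
#' @return An object of class `trial_score`: list with elements `condition`,
#'   `missed` (data frame phase/label), `unexpected` (data frame
#'   phase/label), `repeats` (data frame phase/label/count) and
#'   `complete_detected`.
#' @export
score_trial <- function(events, condition) {
  expect <- expected_for(condition)
  phases <- segment_phases(events, condition)
  missed_phase <- integer(0); missed_label <- character(0)
  unexp_phase <- integer(0); unexp_label <- character(0)
  rep_phase <- integer(0); rep_label <- character(0); rep_count <- integer(0)
  for (k in 1:6) {
    labs <- phases[[k]]$label
    seen <- unique(labs)
    exp_k <- expect[[k]]
    allowed <- c(unlist(exp_k$required), exp_k$optional)
    for (alt in exp_k$required) {
      if (!any(alt %in% seen)) {
        missed_phase <- c(missed_phase, k)
        missed_label <- c(missed_label, paste(alt, collapse = "/"))
      }
    }
    for (lab in setdiff(seen, allowed)) {
      unexp_phase <- c(unexp_phase, k)
      unexp_label <- c(unexp_label, lab)
    }
    counts <- table(labs)
    extra <- counts[counts > 1L]
    if (length(extra)) {
      rep_phase <- c(rep_phase, rep(k, length(extra)))
      rep_label <- c(rep_label, names(extra))
      rep_count <- c(rep_count, as.integer(extra) - 1L)
    }
  }
  structure(
    list(condition = condition,
         missed = data.frame(phase = missed_phase, label = missed_label),
         unexpected = data.frame(phase = unexp_phase, label = unexp_label),
         repeats = data.frame(phase = rep_phase, label = rep_label,
                              count = rep_count),
         complete_detected = "C" %in% phases[["6"]]$label),
    class = "trial_score"
  )
}

#' @export
print.trial_score <- function(x, ...) {
  cat("<trial_score>", condition_id(x$condition),
      sprintf("missed=%d unexpected=%d complete=%s\n",
              nrow(x$missed), nrow(x$unexpected), x$complete_detected))
  invisible(x)
}

#' Aggregate trial scores into a condition-by-phase summary table
#'
#' Mirrors the study's reporting convention: per condition and phase, missed
#' expected detections are reported as negative counts and unexpected
#' detections as positive counts.
#'
#' @param scores List of `trial_score` objects.
#' @param exclude Integer indices of trials to drop before aggregation
#'   (models trials lost to recording failure).
#' @return A data frame with columns `garment`, `condition`, `phase`,
#'   `missed` (non-positive), `unexpected` (non-negative), `repeats`,
#'   `n_trials`, with attribute `totals` = c(missed, unexpected) across all
#'   cells.
#' @export
aggregate_scores <- function(scores, exclude = integer(0)) {
  stopifnot(all(vapply(scores, inherits, logical(1), "trial_score")))
  if (length(exclude)) scores <- scores[-exclude]
  cells <- list()
  for (sc in scores) {
    cid <- condition_id(sc$condition)
    if (is.null(cells[[cid]])) {
      cells[[cid]] <- list(condition = sc$condition,
                           missed = integer(6), unexpected = integer(6),
                           repeats = integer(6), n = 0L)
    }
    cell <- cells[[cid]]
    cell$n <- cell$n + 1L
    for (ph in sc$missed$phase) cell$missed[ph] <- cell$missed[ph] + 1L
    for (ph in sc$unexpected$phase) {
      cell$unexpected[ph] <- cell$unexpected[ph] + 1L
    }
    if (nrow(sc$repeats)) {
      for (i in seq_len(nrow(sc$repeats))) {
        ph <- sc$repeats$phase[i]
        cell$repeats[ph] <- cell$repeats[ph] + sc$repeats$count[i]
      }
    }
    cells[[cid]] <- cell
  }
  rows <- lapply(cells, function(cell) {
    data.frame(garment = cell$condition$garment,
               condition = cell$condition$error_mode,
               phase = 1:6,
               missed = -cell$missed,
               unexpected = cell$unexpected,
               repeats = cell$repeats,
               n_trials = cell$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "totals") <- c(missed = -sum(out$missed),
                           unexpected = sum(out$unexpected))
  out
}

#' Study trial roster
#'
#' @param n_participants Number of participants (study default 11).
#' @param repetitions Repetitions of each condition per participant
#'   (study default 2).
#' @param conditions List of [condition()]s (default all nine).
#' @return An object of class `trial_roster`.
#' @export
trial_roster <- function(n_participants = 11, repetitions = 2,
                         conditions = dressing_conditions()) {
  stopifnot(n_participants >= 1, repetitions >= 1, length(conditions) >= 1,
            all(vapply(conditions, inherits, logical(1),
                       "dressing_condition")))
  structure(list(n_participants = as.integer(n_participants),
                 repetitions = as.integer(repetitions),
                 conditions = conditions),
            class = "trial_roster")
}

#' Enumerate the trials of a randomized block design
#'
#' Every participant performs every condition exactly `repetitions` times;
#' within each participant the condition-by-repetition block is shuffled
#' uniformly (a complete randomized block design).  The caller's RNG state
#' is preserved.
#'
#' @param roster A [trial_roster()].
#' @param seed Integer seed for the block shuffles.
#' @return A data frame with one row per trial: `trial` (global index),
#'   `participant`, `garment`, `error_mode`, `repetition`.
#' @export
enumerate_trials <- function(roster, seed = 1L) {
  stopifnot(inherits(roster, "trial_roster"))
  block <- expand.grid(cond = seq_along(roster$conditions),
                       repetition = seq_len(roster$repetitions))
  with_seed(seed, {
    rows <- lapply(seq_len(roster$n_participants), function(pid) {
      ord <- sample.int(nrow(block))
      data.frame(participant = pid,
                 garment = vapply(roster$conditions[block$cond[ord]],
                                  function(cn) cn$garment, character(1)),
                 error_mode = vapply(roster$conditions[block$cond[ord]],
                                     function(cn) cn$error_mode, character(1)),
                 repetition = block$repetition[ord])
    })
    out <- do.call(rbind, rows)
    out <- cbind(trial = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  })
}

#' Count expected limb-worn detections over analyzed trials
#'
#' The number of required limb-worn detections (phases 2 and 4, one each) in
#' the expectation tables, summed over the trials of a roster after removing
#' an exclusion list — the denominator for the harness's limb-detection
#' reliability summary.
#'
#' @param trials Data frame from [enumerate_trials()].
#' @param exclude Integer trial indices excluded from analysis.
#' @return Integer count.
#' @export
count_expected_limb_detections <- function(trials, exclude = integer(0)) {
  if (length(exclude)) trials <- trials[-exclude, , drop = FALSE]
  total <- 0L
  for (i in seq_len(nrow(trials))) {
    expect <- expected_for(condition(trials$garment[i], trials$error_mode[i]))
    for (k in c(2L, 4L)) {
      limb <- vapply(expect[[k]]$required,
                     function(alt) all(alt %in% c("R", "L")), logical(1))
      total <- total + sum(limb)
    }
  }
  total
}
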