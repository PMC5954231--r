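#' Default phase durations for a dressing condition
#'
#' Per-condition durations (seconds) of the six dressing phases.  Acted-error
#' conditions get a longer phase 1 (handling and presenting the mis-oriented
#' garment) and the partial conditions a long phase 3 (the one-sided stall).
#'
#' @param condition A [condition()].
#' @return Numeric vector of six positive durations.
#' @export
default_phase_durations <- function(condition) {
  g <- condition$garment
  m <- condition$error_mode
  if (g == "shirt") {
    switch(m,
           correct = ,
           misaligned = c(4, 3, 2, 3, 6, 5),
           back_to_front = ,
           inside_out = c(6, 3, 2, 3, 6, 5),
           partial = c(4, 3, 8, 3, 6, 5))
  } else {
    switch(m,
           correct = c(3, 3, 2, 3, 4, 5),
           back_to_front = ,
           inside_out = c(4, 3, 2, 3, 4, 5),
           partial = c(3, 3, 8, 3, 4, 5))
  }
}

#' Scenario specification for one simulated dressing trial
#'
#' @param condition A [condition()].
#' @param phase_durations_s Six positive phase durations (seconds); defaults
#'   per condition, see [default_phase_durations()].
#' @param actor_distance Unitless camera-distance factor (>= 0); feeds the
#'   distance-dependent dropout of the noise model.
#' @param dressing_speed Speed multiplier (> 0); phase durations are divided
#'   by it, so values above ~2 make exposures shorter than the persistence
#'   window and reproduce the too-fast-donning failure mode.
#' @param terminal_hold_s Stillness at the end of the trial (the "DONE 1 2 3"
#'   hold in front of the camera, default 3 s); phase 6 never shrinks below
#'   this even at high dressing speed.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(condition,
                          phase_durations_s = default_phase_durations(condition),
                          actor_distance = 0,
                          dressing_speed = 1,
                          terminal_hold_s = 3.0) {
  stopifnot(inherits(condition, "dressing_condition"))
  if (length(phase_durations_s) != 6L || any(!is.finite(phase_durations_s)) ||
      any(phase_durations_s <= 0)) {
    stop("phase_durations_s must be six positive durations", call. = FALSE)
  }
  stopifnot(actor_distance >= 0, dressing_speed > 0, terminal_hold_s > 0)
  structure(list(condition = condition,
                 phase_durations_s = as.numeric(phase_durations_s),
                 actor_distance = actor_distance,
                 dressing_speed = dressing_speed,
                 terminal_hold_s = terminal_hold_s),
            class = "scenario_spec")
}

#' Noise model for simulated marker streams
#'
#' Emulates the failure modes observed with a live camera: per-frame marker
#' dropout that grows with actor distance (markers become effectively
#' smaller), transient glimpses of wrong-region markers while the garment is
#' handled during transition phases, and whole-region occlusion by cloth
#' folds.
#'
#' @param base_dropout_p Per-frame probability that a visible marker is not
#'   reported (default 0.05).
#' @param distance_dropout_coeff Added dropout per unit of actor distance
#'   (default 0.10).
#' @param glimpse_rate_hz Rate of transient back/inside glimpses during
#'   transition phases 3 and 5 (default 0.05 per second).
#' @param glimpse_duration_s Mean glimpse duration, exponentially distributed
#'   (default 0.5 s — mostly below the persistence window, occasionally
#'   long enough to fire a detection).
#' @param fold_occlusion_p Probability that a scripted region is occluded for
#'   an entire phase (default 0.02).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(base_dropout_p = 0.05,
                        distance_dropout_coeff = 0.10,
                        glimpse_rate_hz = 0.05,
                        glimpse_duration_s = 0.5,
                        fold_occlusion_p = 0.02) {
  stopifnot(base_dropout_p >= 0, base_dropout_p <= 1,
            fold_occlusion_p >= 0, fold_occlusion_p <= 1,
            distance_dropout_coeff >= 0, glimpse_rate_hz >= 0,
            glimpse_duration_s >= 0)
  structure(list(base_dropout_p = base_dropout_p,
                 distance_dropout_coeff = distance_dropout_coeff,
                 glimpse_rate_hz = glimpse_rate_hz,
                 glimpse_duration_s = glimpse_duration_s,
                 fold_occlusion_p = fold_occlusion_p),
            class = "noise_model")
}

#' A noise model with every noise source switched off
#'
#' @return A `noise_model` whose streams are fully deterministic region
#'   exposures (up to the seeded position jitter).
#' @export
noise_off <- function() {
  noise_model(base_dropout_p = 0, distance_dropout_coeff = 0,
              glimpse_rate_hz = 0, glimpse_duration_s = 0,
              fold_occlusion_p = 0)
}

#' Effective per-frame dropout probability at a camera distance
#'
#' `min(1, base_dropout_p + distance_dropout_coeff * actor_distance)`;
#' non-decreasing in distance.
#'
#' @param noise A [noise_model()].
#' @param actor_distance Unitless distance factor (>= 0).
#' @return Probability in `[0, 1]`.
#' @export
dropout_probability <- function(noise, actor_distance) {
  stopifnot(actor_distance >= 0)
  min(1, noise$base_dropout_p +
        noise$distance_dropout_coeff * actor_distance)
}

# Marker groups used by the condition scripts, with anchor positions
# (normalized camera coordinates, origin top-left, y downward).
sim_groups <- function(garment) {
  if (garment == "shirt") {
    list(
      fr = list(ids = c(5L, 10L, 11L), anchor = c(0.33, 0.45)),
      fl = list(ids = c(6L, 30L, 31L), anchor = c(0.62, 0.45)),
      fl_glimpse = list(ids = 6L, anchor = c(0.62, 0.45)),
      back = list(ids = 7L, anchor = c(0.50, 0.45)),
      inside = list(ids = 8L, anchor = c(0.50, 0.50)),
      velcro = list(ids = c(208L, 209L, 211L, 212L), anchor = NULL)
    )
  } else {
    list(
      back = list(ids = 22L, anchor = c(0.50, 0.50)),
      inside = list(ids = 17L, anchor = c(0.45, 0.50)),
      low_right = list(ids = c(25L, 26L), anchor = c(0.36, 0.80)),
      low_left = list(ids = c(28L, 29L), anchor = c(0.60, 0.80)),
      ll_glimpse = list(ids = 28L, anchor = c(0.60, 0.80)),
      upper = list(ids = c(15L, 16L, 24L, 27L), anchor = c(0.38, 0.35))
    )
  }
}

# Individual velcro anchors: pair members 0.05 apart in x and 0.02 in y,
# comfortably inside the 0.18/0.05 alignment thresholds; the misaligned
# script adds a 0.10 y offset to the left-side members (209, 212).
VELCRO_ANCHORS <- list(`208` = c(0.42, 0.40), `209` = c(0.47, 0.42),
                       `211` = c(0.42, 0.55), `212` = c(0.47, 0.57))

marker_anchor <- function(id, group) {
  v <- VELCRO_ANCHORS[[as.character(id)]]
  if (!is.null(v)) return(v)
  k <- match(id, group$ids) - 1L
  c(group$anchor[1] + 0.02 * k, group$anchor[2] + 0.015 * k)
}

# The condition script: piecewise region exposures, expressed per phase as
# fractional sub-intervals so trials scale with phase durations.  Columns:
# phase, group, f0, f1, dy (velcro vertical misalignment offset).
condition_script <- function(condition) {
  row <- function(phase, group, f0, f1, dy = 0) {
    data.frame(phase = phase, group = group, f0 = f0, f1 = f1, dy = dy)
  }
  g <- condition$garment
  m <- condition$error_mode
  if (g == "shirt") {
    tail_fr <- do.call(rbind, lapply(2:6, row, group = "fr", f0 = 0, f1 = 1))
    fl_on <- rbind(row(4, "fl", 0.0667, 1), row(5, "fl", 0, 1),
                   row(6, "fl", 0, 1))
    velcro <- rbind(row(5, "velcro", 1 / 3, 1), row(6, "velcro", 0, 1))
    # sub-persistence sightings of the dangling left front while the right
    # side is donned; spaced under the partial timeout so p never arms
    glimpses <- rbind(row(1, "fl_glimpse", 0.125, 0.375),
                      row(2, "fl_glimpse", 1 / 3, 0.6),
                      row(3, "fl_glimpse", 0.25, 0.65))
    head_rows <- switch(m,
      correct = ,
      misaligned = ,
      partial = row(1, "fr", 0.125, 1),
      back_to_front = rbind(row(1, "back", 0.0833, 0.5833),
                            row(1, "fr", 0.6, 1)),
      inside_out = rbind(row(1, "inside", 0.05, 0.55),
                         row(1, "fr", 0.6, 1)))
    if (m == "misaligned") {
      velcro <- rbind(row(5, "velcro", 0.45, 0.7, dy = 0.10),
                      row(5, "velcro", 0.7, 1), row(6, "velcro", 0, 1))
    }
    script <- rbind(head_rows, tail_fr, fl_on, velcro,
                    if (m != "partial") glimpses)
  } else {
    common <- rbind(row(2, "low_right", 1 / 6, 1),
                    do.call(rbind, lapply(3:6, row, group = "low_right",
                                          f0 = 0, f1 = 1)),
                    row(4, "low_left", 0.05, 1), row(5, "low_left", 0, 1),
                    row(6, "low_left", 0, 1),
                    row(5, "upper", 0.625, 1), row(6, "upper", 0, 1))
    head_rows <- switch(m,
      correct = NULL,
      back_to_front = row(1, "back", 0.075, 0.75),
      inside_out = row(1, "inside", 0.075, 0.75),
      # dangling second pant leg glimpsed sub-persistence during the stall,
      # and cloth folds keep breaking the worn side's run, so neither L nor
      # p ever qualifies during the one-sided interval
      partial = rbind(row(3, "ll_glimpse", 0.0625, 0.1625),
                      row(3, "ll_glimpse", 0.5, 0.6),
                      row(3, "ll_glimpse", 0.9, 0.9875)))
    script <- rbind(head_rows, common)
  }
  rownames(script) <- NULL
  script
}

# Bounded random walk: reflect an unbounded gaussian walk into [-amp, amp].
bounded_walk <- function(n, step_sd, amp) {
  w <- cumsum(rnorm(n, 0, step_sd))
  r <- (w + amp) %% (4 * amp)
  abs(r - 2 * amp) - amp
}

#' Simulate one dressing trial
#'
#' Generates a synthetic marker-observation stream for the condition's
#' scripted sequence of region exposures, with seeded position jitter and
#' the configured noise processes, plus the ground-truth phase annotation.
#' Deterministic given `(spec, noise, seed)`; the caller's RNG state is
#' preserved.
#'
#' @param spec A [scenario_spec()].
#' @param noise A [noise_model()] (use [noise_off()] for clean streams).
#' @param seed Integer seed.
#' @param frame_rate_hz Stream sampling rate (default 15).
#' @return An object of class `simulated_trial`: list with elements
#'   `stream` (marker observation data frame), `truth_phases` (data frame
#'   `phase`, `t_start`, `t_end`), `condition`, `seed`.
#' @export
simulate_trial <- function(spec, noise = noise_model(), seed = 1L,
                           frame_rate_hz = 15) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(noise, "noise_model"))
  condition <- spec$condition
  d <- spec$phase_durations_s / spec$dressing_speed
  d[6] <- max(d[6], spec$terminal_hold_s)
  bounds <- c(0, cumsum(d))
  total <- bounds[7]
  groups <- sim_groups(condition$garment)
  script <- condition_script(condition)

  with_seed(seed, {
    # fold occlusion: drop a whole (group, phase) block of the script
    if (noise$fold_occlusion_p > 0) {
      blocks <- unique(script[c("group", "phase")])
      occluded <- runif(nrow(blocks)) < noise$fold_occlusion_p
      for (b in which(occluded)) {
        script <- script[!(script$group == blocks$group[b] &
                             script$phase == blocks$phase[b]), , drop = FALSE]
      }
    }
    # transient wrong-region glimpses during transition phases
    if (noise$glimpse_rate_hz > 0 && noise$glimpse_duration_s > 0) {
      wrong <- if (condition$garment == "shirt") c("back", "inside")
               else c("back", "inside")
      for (ph in c(3L, 5L)) {
        n_g <- rpois(1, noise$glimpse_rate_hz * d[ph])
        if (n_g > 0) {
          for (i in seq_len(n_g)) {
            grp <- sample(wrong, 1)
            f0 <- runif(1)
            f1 <- min(1, f0 + rexp(1, 1 / noise$glimpse_duration_s) / d[ph])
            script <- rbind(script, data.frame(phase = ph, group = grp,
                                               f0 = f0, f1 = f1, dy = 0))
          }
        }
      }
    }

    tgrid <- seq(0, total, by = 1 / frame_rate_hz)
    n_frames <- length(tgrid)
    p_drop <- dropout_probability(noise, spec$actor_distance)

    all_ids <- sort(unique(unlist(lapply(groups, `[[`, "ids"))))
    rows <- vector("list", length(all_ids))
    for (j in seq_along(all_ids)) {
      id <- all_ids[j]
      visible <- rep(FALSE, n_frames)
      dy_off <- rep(0, n_frames)
      grp_of <- NULL
      for (r in seq_len(nrow(script))) {
        grp <- groups[[script$group[r]]]
        if (!id %in% grp$ids) next
        grp_of <- grp
        a <- bounds[script$phase[r]] + script$f0[r] * d[script$phase[r]]
        b <- bounds[script$phase[r]] + script$f1[r] * d[script$phase[r]]
        sel <- tgrid >= a & tgrid < b
        visible[sel] <- TRUE
        dy_off[sel] <- script$dy[r]
      }
      if (!any(visible)) next
      if (p_drop > 0) visible <- visible & (runif(n_frames) >= p_drop)
      if (!any(visible)) next
      anchor <- marker_anchor(id, grp_of)
      jx <- bounded_walk(n_frames, 0.002, 0.01)
      jy <- bounded_walk(n_frames, 0.002, 0.01)
      # left-side velcro members carry the scripted misalignment offset
      dy_use <- if (id %in% c(209L, 212L)) dy_off else rep(0, n_frames)
      rows[[j]] <- data.frame(
        t = tgrid[visible], id = id,
        x = pmin(1, pmax(0, anchor[1] + jx[visible])),
        y = pmin(1, pmax(0, anchor[2] + jy[visible] + dy_use[visible])),
        angle = (id * 37) %% 360
      )
    }
    stream <- validate_stream(do.call(rbind, c(rows, list(empty_stream()))))
    structure(
      list(stream = stream,
           truth_phases = data.frame(phase = 1:6, t_start = bounds[1:6],
                                     t_end = bounds[2:7]),
           condition = condition,
           seed = as.integer(seed)),
      class = "simulated_trial"
    )
  })
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat("<simulated_trial>", condition_id(x$condition),
      sprintf("seed=%d, %d observations over %.1f s\n", x$seed,
              nrow(x$stream), max(0, x$truth_phases$t_end[6])))
  invisible(x)
}

#' Simulate a full study roster
#'
#' One simulated trial per entry of [enumerate_trials()], with per-trial
#' seeds derived from the master seed as `seed + trial index`.
#'
#' @param roster A [trial_roster()].
#' @param noise A [noise_model()].
#' @param seed Master integer seed (also seeds the roster shuffle).
#' @param ... Passed to [scenario_spec()] (e.g. `actor_distance`).
#' @return A list of `simulated_trial` objects with attribute `trials`
#'   (the roster enumeration).
#' @export
simulate_study <- function(roster, noise = noise_model(), seed = 1L, ...) {
  trials <- enumerate_trials(roster, seed)
  sims <- lapply(seq_len(nrow(trials)), function(i) {
    spec <- scenario_spec(condition(trials$garment[i], trials$error_mode[i]),
                          ...)
    simulate_trial(spec, noise, seed = seed + i)
  })
  attr(sims, "trials") <- trials
  sims
}
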