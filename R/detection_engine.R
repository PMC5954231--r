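#' Construct a detection-event data frame
#'
#' @param t Numeric event times (seconds).
#' @param label Character detection labels (see [detection_labels()]).
#' @param garment Garment each event belongs to.
#' @param evidence List of integer vectors: the marker IDs satisfying the
#'   rule at the event time.
#' @return A data frame of class `detection_events` with columns `t`,
#'   `label`, `garment` and list column `evidence`.
#' @export
detection_events <- function(t = numeric(), label = character(),
                             garment = character(), evidence = list()) {
  stopifnot(all(label %in% DETECTION_LABELS))
  df <- data.frame(t = as.numeric(t), label = as.character(label),
                   garment = as.character(garment))
  df$evidence <- if (length(evidence)) evidence else
    rep(list(integer()), nrow(df))
  class(df) <- c("detection_events", "data.frame")
  df
}

#' @export
print.detection_events <- function(x, ...) {
  cat(sprintf("<detection_events> %d event(s)\n", nrow(x)))
  if (nrow(x)) {
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  %7.3f  %s  (%s)  [%s]\n", x$t[i], x$label[i],
                  x$garment[i], paste(x$evidence[[i]], collapse = ",")))
    }
  }
  invisible(x)
}

#' Create an empty marker visibility state
#'
#' Per-marker bookkeeping for the persistence (debounce) clock: when the
#' current unbroken visibility run began, when the marker was last sighted,
#' and its most recent position.
#'
#' @param marker_ids Integer vector of marker IDs to track.
#' @return An object of class `visibility_state`.
#' @export
visibility_state <- function(marker_ids) {
  n <- length(marker_ids)
  structure(
    list(ids = as.integer(marker_ids),
         continuous_since = rep(NA_real_, n),
         last_seen = rep(NA_real_, n),
         x = rep(NA_real_, n), y = rep(NA_real_, n),
         t = -Inf),
    class = "visibility_state"
  )
}

#' Absorb one frame of observations into a visibility state
#'
#' All observations in `frame` must share a single timestamp that is not
#' earlier than anything already absorbed.  A sighting whose gap from the
#' marker's previous sighting exceeds `gap_tolerance_s` restarts that
#' marker's visibility run; unsighted markers keep their state unchanged.
#'
#' @param state A `visibility_state`.
#' @param frame Data frame of observations at one timestamp (columns `t`,
#'   `id`, `x`, `y`).
#' @param gap_tolerance_s Maximum sighting gap for a run to stay unbroken.
#' @return The updated `visibility_state`.
#' @export
update_visibility <- function(state, frame, gap_tolerance_s = 2 / 15) {
  stopifnot(inherits(state, "visibility_state"))
  if (nrow(frame) == 0L) return(state)
  t <- unique(frame$t)
  if (length(t) != 1L) {
    stop("frame must contain observations at a single timestamp",
         call. = FALSE)
  }
  if (t < state$t) {
    stop(sprintf("time regression: frame at t=%g after state at t=%g",
                 t, state$t), call. = FALSE)
  }
  idx <- match(frame$id, state$ids)
  keep <- !is.na(idx)
  idx <- idx[keep]
  if (length(idx)) {
    broken <- is.na(state$last_seen[idx]) |
      (t - state$last_seen[idx] > gap_tolerance_s)
    state$continuous_since[idx[broken]] <- t
    state$last_seen[idx] <- t
    state$x[idx] <- frame$x[keep]
    state$y[idx] <- frame$y[keep]
  }
  state$t <- t
  state
}

# Qualification vector: marker is fresh (sighted within gap tolerance of t)
# and its unbroken run has lasted at least min_run_s.
qualified_markers <- function(state, t, min_run_s, gap_tolerance_s) {
  fresh <- !is.na(state$last_seen) & (t - state$last_seen <= gap_tolerance_s)
  out <- fresh
  out[fresh] <- (t - state$continuous_since[fresh]) >= min_run_s
  out
}

#' Is a region persistence-qualified visible?
#'
#' TRUE iff at least one marker of the region has an unbroken visibility run
#' of length at least `persist_s` ending within `gap_tolerance_s` of `t`.
#'
#' @param state A `visibility_state`.
#' @param region Region name from the layout.
#' @param layout A `marker_layout`.
#' @param t Evaluation time (seconds).
#' @param persist_s Required run length (seconds).
#' @param gap_tolerance_s Maximum sighting gap for a run to stay unbroken.
#' @return Logical scalar.
#' @export
region_visible <- function(state, region, layout, t, persist_s = 2.0,
                           gap_tolerance_s = 2 / 15) {
  stopifnot(region %in% names(layout$regions))
  idx <- match(layout$regions[[region]], state$ids)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return(FALSE)
  any(qualified_markers(state, t, persist_s, gap_tolerance_s)[idx])
}

# Pull the (x, y) of one marker from a positions mapping (named list of
# c(x, y), names = marker IDs).  NULL if absent.
position_of <- function(positions, id) {
  positions[[as.character(id)]]
}

velcro_differences <- function(positions,
                               pairs = list(c(208L, 209L), c(211L, 212L))) {
  dx <- dy <- numeric(length(pairs))
  for (k in seq_along(pairs)) {
    a <- position_of(positions, pairs[[k]][1])
    b <- position_of(positions, pairs[[k]][2])
    if (is.null(a) || is.null(b)) return(NULL)
    dx[k] <- abs(a[1] - b[1])
    dy[k] <- abs(a[2] - b[2])
  }
  list(dx = dx, dy = dy)
}

#' Velcro misalignment test
#'
#' TRUE iff any of the four absolute coordinate differences between the
#' matched velcro markers exceeds its threshold: vertical differences against
#' `y_align_max`, horizontal against `x_align_max`.  If any of the four
#' markers is missing from `positions` the rule is indeterminate and `NA` is
#' returned (the caller cannot assess alignment).
#'
#' @param positions Named list mapping marker IDs (as names) to `c(x, y)`.
#' @param config A [detection_config()].
#' @param pairs Velcro marker pairs (default the shirt's 208/209, 211/212).
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
#' @examples
#' pos <- list(`208` = c(0.40, 0.40), `209` = c(0.45, 0.47),
#'             `211` = c(0.40, 0.55), `212` = c(0.45, 0.55))
#' misaligned(pos)  # |y208 - y209| = 0.07 > 0.05
misaligned <- function(positions, config = detection_config(),
                       pairs = list(c(208L, 209L), c(211L, 212L))) {
  d <- velcro_differences(positions, pairs)
  if (is.null(d)) return(NA)
  any(d$dy > config$y_align_max) || any(d$dx > config$x_align_max)
}

#' Shirt completion (velcro alignment) test
#'
#' TRUE iff all four absolute velcro coordinate differences are within their
#' thresholds.  A difference exactly equal to its threshold counts as
#' aligned (the boundary is assigned to completion, eliminating the dead
#' zone between the strict inequalities of the misalignment and completion
#' rules).  `NA` if any velcro marker is missing.
#'
#' @inheritParams misaligned
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
shirt_complete <- function(positions, config = detection_config(),
                           pairs = list(c(208L, 209L), c(211L, 212L))) {
  d <- velcro_differences(positions, pairs)
  if (is.null(d)) return(NA)
  all(d$dy <= config$y_align_max) && all(d$dx <= config$x_align_max)
}

#' Pants completion test
#'
#' TRUE iff every upper-front marker of the pants individually satisfies the
#' persistence test at `t` (all markers, not any: the wearer must be
#' standing with the full waistband facing the camera).
#'
#' @param state A `visibility_state`.
#' @param layout The pants `marker_layout`.
#' @param t Evaluation time (seconds).
#' @param config A [detection_config()].
#' @return Logical scalar.
#' @export
pants_complete <- function(state, layout, t, config = detection_config()) {
  stopifnot(layout$garment == "pants")
  idx <- match(layout$regions$pants_upper_front, state$ids)
  if (anyNA(idx)) return(FALSE)
  all(qualified_markers(state, t, config$persist_s, config$gap_tolerance_s)[idx])
}

# Side region names used by the partial rule and by A.
side_regions <- function(garment) {
  if (garment == "shirt") {
    list(right = "shirt_front_right", left = "shirt_front_left")
  } else {
    list(right = "pants_low_right", left = "pants_low_left")
  }
}

#' Partial-dressing test
#'
#' TRUE iff one side region (left/right for the garment) has an unbroken
#' visibility run of at least `partial_timeout_s` while the opposite side has
#' had no sighting at all for at least `partial_timeout_s` (a side never
#' sighted counts as absent).
#'
#' @inheritParams pants_complete
#' @param layout A `marker_layout` for either garment.
#' @return Logical scalar.
#' @export
partial_check <- function(state, layout, t, config = detection_config()) {
  sides <- side_regions(layout$garment)
  long_run <- qualified_markers(state, t, config$partial_timeout_s,
                                config$gap_tolerance_s)
  side_idx <- lapply(sides, function(r) {
    i <- match(layout$regions[[r]], state$ids)
    i[!is.na(i)]
  })
  visible_long <- vapply(side_idx, function(i) any(long_run[i]), logical(1))
  absent <- vapply(side_idx, function(i) {
    seen <- state$last_seen[i]
    all(is.na(seen) | (t - seen >= config$partial_timeout_s))
  }, logical(1))
  (visible_long[["right"]] && absent[["left"]]) ||
    (visible_long[["left"]] && absent[["right"]])
}

#' Run the detection engine over an observation stream
#'
#' Applies the garment's identification rules frame by frame with temporal
#' persistence and emits a time-ordered sequence of detection events.  A
#' label is emitted at the first frame its rule becomes satisfied (a rising
#' edge); re-emission requires the rule to fall and rise again and at least
#' `refractory_s` since the previous emission of the same label.  Events
#' sharing a timestamp are ordered by the fixed precedence
#' F < B < I < R < L < A < M < p < C.  Marker IDs not in the layout are
#' ignored.
#'
#' @param stream Marker observation stream (validated internally).
#' @param garment `"shirt"` or `"pants"`.
#' @param config A [detection_config()].
#' @param layout Garment layout; defaults to the packaged one.
#' @return A `detection_events` data frame.
#' @export
run_detection <- function(stream, garment, config = detection_config(),
                          layout = load_layout(garment)) {
  garment <- match_garment(garment)
  stopifnot(layout$garment == garment)
  stream <- validate_stream(stream)
  ids <- layout_marker_ids(layout)
  stream <- stream[stream$id %in% ids, , drop = FALSE]
  labels <- detection_labels(garment)
  if (nrow(stream) == 0L) return(detection_events())

  regions <- layout$regions
  ridx <- function(region) match(regions[[region]], ids)
  if (garment == "shirt") {
    set_front <- ridx("shirt_front")
    set_back <- ridx("shirt_back")
    set_inside <- c(ridx("shirt_inside_center"), ridx("shirt_inside_side"))
    set_right <- ridx("shirt_front_right")
    set_left <- ridx("shirt_front_left")
    velcro_ids <- unlist(layout$velcro_pairs)
    set_velcro <- match(velcro_ids, ids)
  } else {
    set_back <- ridx("pants_back")
    set_inside <- c(ridx("pants_inside_front"), ridx("pants_inside_back"))
    set_right <- ridx("pants_low_right")
    set_left <- ridx("pants_low_left")
    set_upper <- ridx("pants_upper_front")
  }

  persist <- config$persist_s
  timeout <- config$partial_timeout_s
  gap_tol <- config$gap_tolerance_s
  refract <- config$refractory_s

  n_id <- length(ids)
  cont_since <- last_seen <- px <- py <- rep(NA_real_, n_id)

  # stream is sorted by t, so frames are contiguous row blocks
  starts <- which(!duplicated(stream$t))
  ends <- c(starts[-1] - 1L, nrow(stream))
  times <- stream$t[starts]
  frame_rows <- Map(seq.int, starts, ends)
  obs_idx <- match(stream$id, ids)
  obs_x <- stream$x
  obs_y <- stream$y

  prev_sat <- stats::setNames(rep(FALSE, length(labels)), labels)
  last_emit <- stats::setNames(rep(-Inf, length(labels)), labels)
  ev_t <- numeric(0)
  ev_label <- character(0)
  ev_evidence <- list()

  for (k in seq_along(times)) {
    t <- times[k]
    rows <- frame_rows[[k]]
    sidx <- obs_idx[rows]
    broken <- is.na(last_seen[sidx]) | (t - last_seen[sidx] > gap_tol)
    cont_since[sidx[broken]] <- t
    last_seen[sidx] <- t
    px[sidx] <- obs_x[rows]
    py[sidx] <- obs_y[rows]

    fresh <- !is.na(last_seen) & (t - last_seen <= gap_tol)
    run_len <- t - cont_since
    qual <- fresh & !is.na(run_len) & run_len >= persist
    long_run <- fresh & !is.na(run_len) & run_len >= timeout

    side_absent <- function(set) {
      seen <- last_seen[set]
      all(is.na(seen) | (t - seen >= timeout))
    }

    sat <- prev_sat
    sat[] <- FALSE
    evid <- list()
    sat["B"] <- any(qual[set_back])
    if (sat[["B"]]) evid$B <- ids[set_back][qual[set_back]]
    sat["I"] <- any(qual[set_inside])
    if (sat[["I"]]) evid$I <- ids[set_inside][qual[set_inside]]
    sat["R"] <- any(qual[set_right])
    if (sat[["R"]]) evid$R <- ids[set_right][qual[set_right]]
    sat["L"] <- any(qual[set_left])
    if (sat[["L"]]) evid$L <- ids[set_left][qual[set_left]]

    p_right <- any(long_run[set_right]) && side_absent(set_left)
    p_left <- any(long_run[set_left]) && side_absent(set_right)
    sat["p"] <- p_right || p_left
    if (sat[["p"]]) {
      evid$p <- c(if (p_right) ids[set_right][long_run[set_right]],
                  if (p_left) ids[set_left][long_run[set_left]])
    }

    if (garment == "shirt") {
      sat["F"] <- any(qual[set_front])
      if (sat[["F"]]) evid$F <- ids[set_front][qual[set_front]]
      sat["A"] <- sat[["R"]] && sat[["L"]]
      if (sat[["A"]]) evid$A <- c(evid$R, evid$L)
      if (all(fresh[set_velcro])) {
        dx1 <- abs(px[set_velcro[1]] - px[set_velcro[2]])
        dy1 <- abs(py[set_velcro[1]] - py[set_velcro[2]])
        dx2 <- abs(px[set_velcro[3]] - px[set_velcro[4]])
        dy2 <- abs(py[set_velcro[3]] - py[set_velcro[4]])
        geo_mis <- dy1 > config$y_align_max || dy2 > config$y_align_max ||
          dx1 > config$x_align_max || dx2 > config$x_align_max
        sat["M"] <- geo_mis
        sat["C"] <- !geo_mis && all(qual[set_velcro])
        if (sat[["M"]] || sat[["C"]]) evid$M <- evid$C <- velcro_ids
      }
    } else {
      sat["C"] <- all(qual[set_upper])
      if (sat[["C"]]) evid$C <- ids[set_upper]
    }

    rising <- sat & !prev_sat & (t - last_emit >= refract)
    if (any(rising)) {
      for (lab in labels[rising[labels]]) {
        ev_t <- c(ev_t, t)
        ev_label <- c(ev_label, lab)
        ev_evidence <- c(ev_evidence, list(sort(unique(evid[[lab]]))))
        last_emit[lab] <- t
      }
    }
    prev_sat <- sat
  }

  stopifnot(all(ev_label %in% labels))  # garment-illegal labels never emitted
  detection_events(t = ev_t, label = ev_label,
                   garment = rep(garment, length(ev_t)),
                   evidence = ev_evidence)
}
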