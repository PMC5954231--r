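# Brute-force reference detector.  Instead of maintaining incremental
# per-frame visibility state, it recomputes every marker's visibility runs
# globally from the whole stream (gap-splitting the sighting times) and, for
# each frame time, looks up last sighting / run start / last position by
# binary search.  Rule evaluation and rising-edge emission are re-written
# from the rule definitions.  Used to cross-check run_detection().
oracle_detect <- function(stream, garment, config = detection_config()) {
  layout <- load_layout(garment)
  stream <- validate_stream(stream)
  known <- layout_ids_oracle(layout)
  stream <- stream[stream$id %in% known, , drop = FALSE]
  labels <- detection_labels(garment)
  if (nrow(stream) == 0L) return(detection_events())

  gap <- config$gap_tolerance_s
  times <- sort(unique(stream$t))
  nT <- length(times)
  ids <- sort(unique(stream$id))
  nM <- length(ids)

  last_seen <- run_start <- posx <- posy <- matrix(NA_real_, nT, nM)
  for (j in seq_len(nM)) {
    obs <- stream[stream$id == ids[j], , drop = FALSE]
    tm <- obs$t
    run_id <- cumsum(c(TRUE, diff(tm) > gap))
    rstart <- tm[!duplicated(run_id)][run_id]
    idx <- findInterval(times, tm)
    has <- idx > 0L
    last_seen[has, j] <- tm[idx[has]]
    run_start[has, j] <- rstart[idx[has]]
    posx[has, j] <- obs$x[idx[has]]
    posy[has, j] <- obs$y[idx[has]]
  }

  reg <- function(name) which(ids %in% layout$regions[[name]])
  if (garment == "shirt") {
    sets <- list(Fr = reg("shirt_front"), B = reg("shirt_back"),
                 I = c(reg("shirt_inside_center"), reg("shirt_inside_side")),
                 R = reg("shirt_front_right"), L = reg("shirt_front_left"))
    vj <- match(c(208L, 209L, 211L, 212L), ids)
  } else {
    sets <- list(B = reg("pants_back"),
                 I = c(reg("pants_inside_front"), reg("pants_inside_back")),
                 R = reg("pants_low_right"), L = reg("pants_low_left"))
    uj <- reg("pants_upper_front")
  }

  prev <- stats::setNames(rep(FALSE, length(labels)), labels)
  last_emit <- stats::setNames(rep(-Inf, length(labels)), labels)
  ev <- list(t = numeric(0), label = character(0), evidence = list())

  for (i in seq_len(nT)) {
    t <- times[i]
    fresh <- !is.na(last_seen[i, ]) & (t - last_seen[i, ] <= gap)
    qual <- fresh & (t - run_start[i, ] >= config$persist_s)
    qual[is.na(qual)] <- FALSE
    long <- fresh & (t - run_start[i, ] >= config$partial_timeout_s)
    long[is.na(long)] <- FALSE
    absent <- function(set) {
      s <- last_seen[i, set]
      all(is.na(s) | (t - s >= config$partial_timeout_s))
    }

    sat <- prev; sat[] <- FALSE
    evid <- list()
    for (lab in c("B", "I", "R", "L")) {
      sat[lab] <- any(qual[sets[[lab]]])
      if (sat[[lab]]) evid[[lab]] <- ids[sets[[lab]]][qual[sets[[lab]]]]
    }
    pr <- any(long[sets$R]) && absent(sets$L)
    pl <- any(long[sets$L]) && absent(sets$R)
    sat["p"] <- pr || pl
    if (sat[["p"]]) {
      evid$p <- c(if (pr) ids[sets$R][long[sets$R]],
                  if (pl) ids[sets$L][long[sets$L]])
    }
    if (garment == "shirt") {
      sat["F"] <- any(qual[sets$Fr])
      if (sat[["F"]]) evid$F <- ids[sets$Fr][qual[sets$Fr]]
      sat["A"] <- sat[["R"]] && sat[["L"]]
      if (sat[["A"]]) evid$A <- c(evid$R, evid$L)
      if (!anyNA(vj) && all(fresh[vj])) {
        dys <- c(abs(posy[i, vj[1]] - posy[i, vj[2]]),
                 abs(posy[i, vj[3]] - posy[i, vj[4]]))
        dxs <- c(abs(posx[i, vj[1]] - posx[i, vj[2]]),
                 abs(posx[i, vj[3]] - posx[i, vj[4]]))
        mis <- any(dys > config$y_align_max) || any(dxs > config$x_align_max)
        sat["M"] <- mis
        sat["C"] <- !mis && all(qual[vj])
        if (sat[["M"]] || sat[["C"]]) evid$M <- evid$C <- ids[vj]
      }
    } else {
      sat["C"] <- length(uj) == 4L && all(qual[uj])
      if (sat[["C"]]) evid$C <- ids[uj]
    }

    fire <- sat & !prev & (t - last_emit >= config$refractory_s)
    for (lab in labels[fire[labels]]) {
      ev$t <- c(ev$t, t)
      ev$label <- c(ev$label, lab)
      ev$evidence <- c(ev$evidence, list(sort(unique(evid[[lab]]))))
      last_emit[lab] <- t
    }
    prev <- sat
  }
  detection_events(t = ev$t, label = ev$label,
                   garment = rep(garment, length(ev$t)),
                   evidence = ev$evidence)
}

layout_ids_oracle <- function(layout) {
  sort(unique(unlist(layout$regions, use.names = FALSE)))
}

events_equal <- function(a, b) {
  isTRUE(all.equal(a$t, b$t)) && identical(a$label, b$label) &&
    identical(lapply(a$evidence, as.integer), lapply(b$evidence, as.integer))
}
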