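# Stream builders used across the suite.  All times are seconds; the default
# frame rate matches the engine default (15 Hz).

FRAME <- 1 / 15

# Continuous sightings of one or more markers over [from, to) at frame_rate.
steady_stream <- function(ids, from, to, x = 0.5, y = 0.5,
                          frame_rate = 15) {
  ids <- unname(ids)
  t <- seq(from, to, by = 1 / frame_rate)
  t <- t[t < to | abs(t - to) < 1e-12]
  do.call(rbind, lapply(seq_along(ids), function(k) {
    data.frame(t = t, id = ids[k],
               x = rep_len(x, length(ids))[k],
               y = rep_len(y, length(ids))[k], angle = 0)
  }))
}

cat_streams <- function(...) {
  validate_stream(do.call(rbind, list(...)))
}

# Fixed velcro position mapping with exact pairwise differences: members of
# each pair sit at 0 and at (dx, dy), so the realized difference is the grid
# value itself (no binary representation error).
velcro_positions <- function(dx1 = 0, dy1 = 0, dx2 = 0, dy2 = 0) {
  list(`208` = c(0, 0), `209` = c(dx1, dy1),
       `211` = c(0, 0), `212` = c(dx2, dy2))
}

# Random stream over a garment's markers: per-marker two-state Markov
# visibility (runs long enough to cross the persistence threshold, gaps long
# enough to break runs), positions wandering around per-marker anchors with
# amplitude wide enough to flip the velcro alignment rules both ways.
random_garment_stream <- function(garment, n_frames = 1000, seed = 1,
                                  frame_rate = 15) {
  layout <- load_layout(garment)
  ids <- sort(unique(unlist(layout$regions)))
  set.seed(seed)
  tgrid <- (seq_len(n_frames) - 1L) / frame_rate
  rows <- lapply(ids, function(id) {
    visible <- logical(n_frames)
    state <- runif(1) < 0.3
    for (k in seq_len(n_frames)) {
      state <- if (state) runif(1) >= 0.03 else runif(1) < 0.05
      visible[k] <- state
    }
    if (!any(visible)) return(NULL)
    ax <- runif(1, 0.3, 0.7)
    ay <- runif(1, 0.3, 0.7)
    wx <- cumsum(rnorm(n_frames, 0, 0.01))
    wy <- cumsum(rnorm(n_frames, 0, 0.01))
    fold <- function(a, w, amp = 0.08) {
      r <- (w + amp) %% (4 * amp)
      pmin(1, pmax(0, a + abs(r - 2 * amp) - amp))
    }
    data.frame(t = tgrid[visible], id = id,
               x = fold(ax, wx)[visible], y = fold(ay, wy)[visible],
               angle = 0)
  })
  validate_stream(do.call(rbind, c(rows, list(
    data.frame(t = numeric(), id = integer(), x = numeric(), y = numeric(),
               angle = numeric())))))
}
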