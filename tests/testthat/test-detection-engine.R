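test_that("visibility runs start, extend and restart around the gap tolerance", {
  st <- visibility_state(c(7L, 8L))
  st <- update_visibility(st, data.frame(t = 0, id = 7L, x = 0.5, y = 0.5))
  expect_equal(st$continuous_since[1], 0)
  expect_equal(st$last_seen[1], 0)
  expect_true(is.na(st$last_seen[2]))

  # one frame period later: same run
  st <- update_visibility(st, data.frame(t = 1 / 15, id = 7L, x = 0.5, y = 0.5))
  expect_equal(st$continuous_since[1], 0)

  # a gap above tolerance restarts the run; last position updates
  st <- update_visibility(st, data.frame(t = 1.0, id = 7L, x = 0.7, y = 0.5),
                          gap_tolerance_s = 0.2)
  expect_equal(st$continuous_since[1], 1.0)
  expect_equal(st$x[1], 0.7)

  expect_error(update_visibility(st, data.frame(t = 0.5, id = 7L, x = 0, y = 0)),
               "regression")
  expect_error(update_visibility(st, data.frame(t = c(2, 3), id = c(7L, 8L),
                                                x = 0, y = 0)),
               "single timestamp")
})

test_that("region visibility requires the full persistence window", {
  layout <- load_layout("shirt")
  feed <- function(to) {
    st <- visibility_state(layout_marker_ids <- unlist(layout$regions))
    for (t in seq(0, to, by = FRAME)) {
      st <- update_visibility(st, data.frame(t = t, id = 7L, x = 0.5, y = 0.5))
    }
    st
  }
  st <- feed(2.5)
  expect_true(region_visible(st, "shirt_back", layout, 2.5, persist_s = 2))
  st <- feed(1.9)
  expect_false(region_visible(st, "shirt_back", layout, 1.9, persist_s = 2))
  # region whose markers were never sighted
  expect_false(region_visible(st, "shirt_front", layout, 1.9, persist_s = 2))
})

test_that("velcro alignment rules reproduce the threshold inequalities on a grid", {
  cfg <- detection_config()
  deltas_y <- c(0, 0.03, 0.05, 0.07, 0.2)
  deltas_x <- c(0, 0.1, 0.18, 0.2, 0.3)
  grid <- expand.grid(dy1 = deltas_y, dy2 = deltas_y,
                      dx1 = deltas_x, dx2 = deltas_x)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    pos <- velcro_positions(g$dx1, g$dy1, g$dx2, g$dy2)
    want_mis <- any(c(g$dy1, g$dy2) > 0.05) || any(c(g$dx1, g$dx2) > 0.18)
    m <- misaligned(pos, cfg)
    cpl <- shirt_complete(pos, cfg)
    expect_identical(m, want_mis)
    expect_identical(cpl, !want_mis)     # boundary values count as complete
    expect_false(isTRUE(m) && isTRUE(cpl))  # mutual exclusivity
  }
})

test_that("velcro rules are indeterminate when a marker is missing", {
  pos <- velcro_positions(0, 0.07, 0, 0)
  expect_true(misaligned(pos))
  pos$`212` <- NULL
  expect_identical(misaligned(pos), NA)
  expect_identical(shirt_complete(pos), NA)
})

test_that("pants completion needs all four upper-front markers qualified", {
  layout <- load_layout("pants")
  cfg <- detection_config()
  feed <- function(ids, to) {
    st <- visibility_state(unlist(layout$regions))
    for (t in seq(0, to, by = FRAME)) {
      st <- update_visibility(st, data.frame(t = t, id = ids, x = 0.5, y = 0.4))
    }
    list(st = st, t = max(seq(0, to, by = FRAME)))
  }
  r <- feed(c(15L, 16L, 24L, 27L), 2.2)
  expect_true(pants_complete(r$st, layout, r$t, cfg))
  r <- feed(c(15L, 16L, 24L), 2.2)        # universal quantifier
  expect_false(pants_complete(r$st, layout, r$t, cfg))
  r <- feed(c(15L, 16L, 24L, 27L), 1.0)   # below persistence
  expect_false(pants_complete(r$st, layout, r$t, cfg))
})

test_that("partial rule needs a long one-sided run and a truly absent other side", {
  layout <- load_layout("pants")
  cfg <- detection_config()
  run <- function(stream, t) {
    st <- visibility_state(unlist(layout$regions))
    for (tt in sort(unique(stream$t))) {
      st <- update_visibility(st, stream[stream$t == tt, , drop = FALSE])
    }
    partial_check(st, layout, t, cfg)
  }
  right55 <- steady_stream(25L, 0, 5.5)
  expect_true(run(right55, 5.5))
  # other side seen 2 s ago: not absent
  both <- cat_streams(right55, steady_stream(28L, 3.4, 3.5))
  expect_false(run(both, 5.5))
  # other side vanished more than the timeout ago: absent again
  old_left <- cat_streams(steady_stream(28L, 0, 0.2),
                          steady_stream(25L, 0, 5.6))
  expect_true(run(old_left, 5.6))
  # both sides visible throughout
  expect_false(run(cat_streams(steady_stream(25L, 0, 6),
                               steady_stream(28L, 0, 6)), 5.9))
})

test_that("run_detection handles empty and unknown-marker streams", {
  expect_identical(nrow(run_detection(empty <- data.frame(
    t = numeric(), id = integer(), x = numeric(), y = numeric()), "shirt")), 0L)
  junk <- steady_stream(999L, 0, 10)
  expect_identical(nrow(run_detection(junk, "shirt")), 0L)
})

test_that("a region must persist before its detection fires, at the right time", {
  # 1.9 s of back visibility: nothing; 2.5 s: B at +2 s
  short <- steady_stream(7L, 0, 1.9)
  expect_identical(nrow(run_detection(short, "shirt")), 0L)
  long <- steady_stream(7L, 0, 2.5)
  ev <- run_detection(long, "shirt")
  expect_identical(ev$label, "B")
  expect_lt(abs(ev$t - 2.0), FRAME + 1e-9)
  expect_identical(ev$evidence[[1]], 7L)
})

test_that("partial fires at the five-second boundary of one-sided visibility", {
  stream <- steady_stream(25L, 0, 6.5)
  ev <- run_detection(stream, "pants")
  expect_identical(ev$label, c("R", "p"))
  expect_lt(abs(ev$t[2] - 5.0), FRAME + 1e-9)
})

test_that("an interrupted run restarts the persistence clock", {
  # two 1.5 s exposures separated by a 1 s gap: neither crosses 2 s
  stream <- cat_streams(steady_stream(7L, 0, 1.5),
                        steady_stream(7L, 2.5, 4.0))
  expect_identical(nrow(run_detection(stream, "shirt")), 0L)
  # a single dropped frame does not break the run
  keep <- steady_stream(7L, 0, 2.5)
  keep <- keep[abs(keep$t - 1.0) > 1e-9, ]
  ev <- run_detection(keep, "shirt")
  expect_identical(ev$label, "B")
})

test_that("A fires only when both sides are simultaneously qualified", {
  stream <- cat_streams(steady_stream(5L, 0, 10, x = 0.3),
                        steady_stream(6L, 4, 10, x = 0.6))
  ev <- run_detection(stream, "shirt")
  expect_identical(ev$label, c("F", "R", "L", "A"))
  # L and A at the same instant, ordered by precedence
  expect_equal(ev$t[3], ev$t[4])
  a_row <- which(ev$label == "A")
  expect_setequal(ev$evidence[[a_row]], c(5L, 6L))
})

test_that("misaligned velcro yields M, corrected alignment then C", {
  mis <- do.call(rbind, lapply(list(
    c(208L, 0.40, 0.40), c(209L, 0.45, 0.52),   # dy = 0.12 > 0.05
    c(211L, 0.40, 0.55), c(212L, 0.45, 0.57)), function(r) {
      steady_stream(as.integer(r[1]), 0, 3, x = r[2], y = r[3])
    }))
  ok <- do.call(rbind, lapply(list(
    c(208L, 0.40, 0.40), c(209L, 0.45, 0.42),
    c(211L, 0.40, 0.55), c(212L, 0.45, 0.57)), function(r) {
      steady_stream(as.integer(r[1]), 3, 6, x = r[2], y = r[3])
    }))
  ev <- run_detection(cat_streams(mis, ok), "shirt")
  expect_identical(ev$label[1], "M")
  expect_lt(ev$t[1], 0.1)                   # M needs freshness, not persistence
  expect_true("C" %in% ev$label)
  tc <- ev$t[ev$label == "C"]
  expect_gte(tc, 3.0)                       # C only after realignment
  # F/R/L/A also fire from the velcro markers themselves
  expect_true(all(c("F", "R", "L", "A") %in% ev$label))
})

test_that("repeated labels are suppressed within the refractory gap", {
  # back flickers off for 0.4 s every second: each re-qualification is a new
  # rising edge, but edges closer than refractory_s to the last emission are
  # dropped
  pieces <- lapply(seq(0, 4), function(k) steady_stream(7L, k * 3, k * 3 + 2.4))
  ev <- run_detection(cat_streams(do.call(rbind, pieces)), "shirt")
  expect_true(all(ev$label == "B"))
  expect_identical(nrow(ev), 5L)
  expect_true(all(diff(ev$t) >= 1.0))
})

test_that("debounce soundness: sub-persistence markers never contribute", {
  set.seed(42)
  for (rep in 1:20) {
    # random exposures all strictly shorter than the persistence window,
    # one per distinct marker so runs can never merge
    n <- sample(3:5, 1)
    pieces <- lapply(sample(c(5L, 6L, 7L, 8L, 208L), n), function(id) {
      start <- runif(1, 0, 20)
      steady_stream(id, start, start + runif(1, 0.1, 1.8))
    })
    ev <- run_detection(cat_streams(do.call(rbind, pieces)), "shirt")
    expect_identical(nrow(ev), 0L)
  }
})

test_that("incremental engine matches the brute-force rescan oracle", {
  for (seed in 1:25) {
    garment <- if (seed %% 2) "shirt" else "pants"
    stream <- random_garment_stream(garment, n_frames = 400, seed = seed)
    a <- run_detection(stream, garment)
    b <- oracle_detect(stream, garment)
    expect_true(events_equal(a, b),
                label = sprintf("engine == oracle (garment=%s seed=%d)",
                                garment, seed))
  }
})

test_that("lengthening a visibility run never removes earlier events", {
  base <- steady_stream(25L, 0, 3.0)
  ev_base <- run_detection(base, "pants")
  longer <- steady_stream(25L, 0, 4.5)
  ev_long <- run_detection(longer, "pants")
  for (i in seq_len(nrow(ev_base))) {
    expect_true(any(ev_long$label == ev_base$label[i] &
                      abs(ev_long$t - ev_base$t[i]) < 1e-9))
  }
})

test_that("detections serialize to JSON lines and back", {
  ev <- run_detection(steady_stream(c(25L, 26L), 0, 3), "pants")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_detections(ev, path)
  back <- read_detections(path)
  expect_identical(back$label, ev$label)
  expect_equal(back$t, ev$t)
  expect_identical(back$evidence, lapply(ev$evidence, function(e) sort(e)))
})
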