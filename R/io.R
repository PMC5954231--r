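#' Read a marker observation stream from JSON Lines
#'
#' One observation per line with keys `t`, `id`, `x`, `y`, `angle`; lines
#' beginning with `#` are header comments and are skipped.  The result is
#' validated with [validate_stream()].
#'
#' @param path File path.
#' @return A marker observation stream data frame.
#' @export
read_marker_stream <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) return(empty_stream())
  recs <- lapply(lines, jsonlite::fromJSON)
  get_num <- function(key, default = NULL) {
    vapply(recs, function(r) {
      v <- r[[key]]
      if (is.null(v)) {
        if (is.null(default)) stop("missing key '", key, "' in stream record",
                                   call. = FALSE)
        v <- default
      }
      as.numeric(v)
    }, numeric(1))
  }
  validate_stream(data.frame(t = get_num("t"), id = get_num("id"),
                             x = get_num("x"), y = get_num("y"),
                             angle = get_num("angle", 0)))
}

#' Write a marker observation stream as JSON Lines
#'
#' Positions are written as 6-decimal fixed point; `t` and `angle` keep full
#' precision.
#'
#' @param stream Marker observation stream data frame.
#' @param path Output file path.
#' @param header Optional character vector of comment lines (written with a
#'   leading `#`).
#' @return `path`, invisibly.
#' @export
write_marker_stream <- function(stream, path, header = NULL) {
  stream <- validate_stream(stream)
  lines <- character(0)
  if (!is.null(header)) lines <- paste0("# ", header)
  if (nrow(stream)) {
    body <- sprintf('{"t": %s, "id": %d, "x": %.6f, "y": %.6f, "angle": %s}',
                    format(stream$t, digits = 12, trim = TRUE,
                           scientific = FALSE),
                    stream$id, stream$x, stream$y,
                    format(stream$angle, digits = 12, trim = TRUE,
                           scientific = FALSE))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write detection events as JSON Lines
#'
#' One event per line with keys `t`, `label`, `garment` and `evidence`
#' (array of marker IDs).
#'
#' @param events Detection event data frame from [run_detection()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(events, path) {
  lines <- vapply(seq_len(nrow(events)), function(i) {
    sprintf('{"t": %s, "label": "%s", "garment": "%s", "evidence": [%s]}',
            format(events$t[i], digits = 12, trim = TRUE, scientific = FALSE),
            events$label[i], events$garment[i],
            paste(sort(events$evidence[[i]]), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read detection events from JSON Lines
#'
#' @param path File written by [write_detections()].
#' @return Detection event data frame (`t`, `label`, `garment`, `evidence`).
#' @export
read_detections <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  recs <- lapply(lines, jsonlite::fromJSON)
  detection_events(
    t = vapply(recs, function(r) as.numeric(r$t), numeric(1)),
    label = vapply(recs, function(r) as.character(r$label), character(1)),
    garment = vapply(recs, function(r) as.character(r$garment), character(1)),
    evidence = lapply(recs, function(r) as.integer(r$evidence))
  )
}

#' Read a dressing-session event log from JSON Lines
#'
#' Each line is one session event with keys `t` and `kind`, plus
#' kind-specific keys: `index` (drawer_open/drawer_close), `drawer`
#' (rfid_removed), `label` and `garment` (detection), `level` (stress).
#'
#' @param path File path.
#' @return A data frame of session events ordered by time.
#' @export
read_session_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  recs <- lapply(lines, jsonlite::fromJSON)
  ev <- do.call(rbind, lapply(recs, function(r) {
    session_event(t = as.numeric(r$t), kind = as.character(r$kind),
                  index = if (!is.null(r$index)) as.integer(r$index) else NA_integer_,
                  drawer = if (!is.null(r$drawer)) as.integer(r$drawer) else NA_integer_,
                  label = if (!is.null(r$label)) as.character(r$label) else NA_character_,
                  garment = if (!is.null(r$garment)) as.character(r$garment) else NA_character_,
                  level = if (!is.null(r$level)) as.numeric(r$level) else NA_real_)
  }))
  validate_session_log(ev)
}

#' Write a session prompt/alert transcript as JSON Lines
#'
#' Serializes the output of [run_session()] deterministically: prompts then
#' alerts would lose interleaving, so rows are merged and ordered by time
#' (prompts before alerts at equal times).
#'
#' @param output A `session_output` from [run_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_transcript <- function(output, path) {
  writeLines(format_transcript(output), path)
  invisible(path)
}

format_transcript <- function(output) {
  pr <- output$prompts
  al <- output$alerts
  if (nrow(pr) + nrow(al) == 0L) return(character(0))
  rows <- c(
    if (nrow(pr)) sprintf(
      '{"t": %s, "type": "prompt", "prompt_id": "%s", "class": "%s", "green_drawer": %d}',
      format(pr$t, digits = 12, trim = TRUE, scientific = FALSE),
      pr$prompt_id, pr$class, pr$green_drawer),
    if (nrow(al)) sprintf('{"t": %s, "type": "alert", "kind": "%s"}',
                          format(al$t, digits = 12, trim = TRUE,
                                 scientific = FALSE), al$kind)
  )
  ts <- c(if (nrow(pr)) pr$t, if (nrow(al)) al$t)
  kind_rank <- c(rep(0L, nrow(pr)), rep(1L, nrow(al)))
  rows[order(ts, kind_rank)]
}
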