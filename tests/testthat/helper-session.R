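# Random but schema-valid session logs for determinism/mode properties.
fuzz_log <- function(seed, n = 40) {
  set.seed(seed)
  kinds <- sample(c("presence", "drawer_open", "drawer_close", "rfid_removed",
                    "detection", "stress"), n, replace = TRUE,
                  prob = c(0.08, 0.15, 0.15, 0.12, 0.35, 0.15))
  t <- sort(round(runif(n, 0, 120), 2))
  do.call(rbind, lapply(seq_len(n), function(i) {
    switch(kinds[i],
      presence = session_event(t[i], "presence"),
      drawer_open = session_event(t[i], "drawer_open",
                                  index = sample(1:3, 1)),
      drawer_close = session_event(t[i], "drawer_close",
                                   index = sample(1:3, 1)),
      rfid_removed = session_event(t[i], "rfid_removed",
                                   drawer = sample(1:3, 1)),
      detection = session_event(t[i], "detection",
                                label = sample(detection_labels(), 1),
                                garment = sample(c("shirt", "pants"), 1)),
      stress = session_event(t[i], "stress",
                             level = round(runif(1, 0, 1), 2)))
  }))
}

format_transcript_lines <- function(output) {
  path <- tempfile()
  on.exit(unlink(path))
  write_session_transcript(output, path)
  readLines(path)
}
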