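#' @importFrom stats rbinom rexp rnorm runif rpois
#' @importFrom utils head tail write.csv
NULL

# Detection labels in fixed precedence order.  At equal timestamps events are
# ordered by this precedence so that replays are reproducible.
DETECTION_LABELS <- c("F", "B", "I", "R", "L", "A", "M", "p", "C")

GARMENTS <- c("shirt", "pants")

# Labels that are legal for each garment.  F (front), A (both arms) and M
# (velcro misaligned) only exist for shirts.
GARMENT_LABELS <- list(
  shirt = DETECTION_LABELS,
  pants = c("B", "I", "R", "L", "p", "C")
)

#' Detection labels
#'
#' The nine dressing-state detection codes, in the fixed precedence order used
#' to break ties between events emitted at the same timestamp:
#' F (front), B (back), I (inside), R (right limb worn), L (left limb worn),
#' A (both arms worn), M (velcro misaligned), p (partial dressing),
#' C (worn correctly).
#'
#' @param garment Optional garment name; if given, only the labels legal for
#'   that garment are returned (F, A and M are shirt-only).
#' @return Character vector of label codes.
#' @export
#' @examples
#' detection_labels()
#' detection_labels("pants")
detection_labels <- function(garment = NULL) {
  if (is.null(garment)) return(DETECTION_LABELS)
  GARMENT_LABELS[[match_garment(garment)]]
}

match_garment <- function(garment) {
  if (length(garment) != 1L || !is.character(garment) || !garment %in% GARMENTS) {
    stop("unknown garment ", deparse(garment),
         "; legal values are: ", paste(GARMENTS, collapse = ", "),
         call. = FALSE)
  }
  garment
}

#' Load a garment marker layout
#'
#' Reads the packaged garment layout: the mapping from garment regions (front,
#' back, inside, left/right sides, velcro, ...) to the fiducial marker IDs
#' printed on them, plus the ordered velcro closure pairs for the shirt.
#'
#' @param garment `"shirt"` or `"pants"`.
#' @return An object of class `marker_layout`: a list with elements
#'   `garment`, `regions` (named list of integer marker-ID vectors) and
#'   `velcro_pairs` (list of length-2 integer vectors).
#' @export
#' @examples
#' load_layout("shirt")$regions$shirt_back
load_layout <- function(garment) {
  garment <- match_garment(garment)
  path <- system.file("extdata", "layouts.yaml", package = "dresstrack",
                      mustWork = TRUE)
  raw <- yaml::read_yaml(path)[[garment]]
  layout <- structure(
    list(
      garment = garment,
      regions = lapply(raw$regions, as.integer),
      velcro_pairs = lapply(raw$velcro_pairs, as.integer)
    ),
    class = "marker_layout"
  )
  validate_layout(layout)
  layout
}

# Internal consistency checks on a layout: front is the union of the two side
# sets, the velcro set matches the pairs, and regions belong to one garment.
validate_layout <- function(layout) {
  regions <- layout$regions
  if (layout$garment == "shirt") {
    front <- regions$shirt_front
    sides <- sort(c(regions$shirt_front_right, regions$shirt_front_left))
    stopifnot(
      setequal(front, sides),
      all(unlist(layout$velcro_pairs) %in% regions$shirt_velcro),
      length(intersect(regions$shirt_front_right,
                       regions$shirt_front_left)) == 0L
    )
  }
  prefix <- paste0(layout$garment, "_")
  stopifnot(all(startsWith(names(regions), prefix)))
  invisible(layout)
}

#' @export
print.marker_layout <- function(x, ...) {
  cat("<marker_layout>", x$garment, "\n")
  for (r in names(x$regions)) {
    cat(sprintf("  %-20s %s\n", r, paste(x$regions[[r]], collapse = ", ")))
  }
  if (length(x$velcro_pairs)) {
    cat("  velcro pairs:",
        paste(vapply(x$velcro_pairs, paste, "", collapse = "/"),
              collapse = ", "), "\n")
  }
  invisible(x)
}

layout_marker_ids <- function(layout) {
  sort(unique(unlist(layout$regions, use.names = FALSE)))
}

#' Regions containing a marker
#'
#' Inverse lookup of the layout tables: all regions of `layout` whose marker
#' set contains `marker_id`.  Unknown IDs yield an empty set (a live camera
#' sees spurious markers; they are ignored, never an error).
#'
#' @param marker_id Integer fiducial ID.
#' @param layout A `marker_layout` from [load_layout()].
#' @return Character vector of region names (possibly empty).
#' @export
#' @examples
#' regions_of(208, load_layout("shirt"))
regions_of <- function(marker_id, layout) {
  stopifnot(inherits(layout, "marker_layout"), length(marker_id) == 1L)
  names(layout$regions)[vapply(layout$regions,
                               function(ids) marker_id %in% ids, logical(1))]
}

#' Construct a marker observation stream
#'
#' A marker observation stream is a data frame with one row per sighting of
#' one fiducial marker: columns `t` (seconds from stream start), `id`
#' (integer marker ID), `x`, `y` (normalized camera coordinates in `[0, 1]`,
#' origin top-left, y downward) and `angle` (orientation in degrees
#' `[0, 360)`; carried but not used by any detection rule).
#'
#' @param t,id,x,y,angle Equal-length vectors of field values.
#' @return A validated stream (see [validate_stream()]).
#' @export
marker_stream <- function(t = numeric(), id = integer(), x = numeric(),
                          y = numeric(), angle = 0) {
  n <- length(t)
  df <- data.frame(t = as.numeric(t), id = as.integer(id),
                   x = as.numeric(x), y = as.numeric(y),
                   angle = rep_len(as.numeric(angle), n))
  validate_stream(df)
}

empty_stream <- function() {
  data.frame(t = numeric(), id = integer(), x = numeric(), y = numeric(),
             angle = numeric())
}

#' Validate and normalize a marker observation stream
#'
#' Checks field invariants (`0 <= x, y <= 1`, `t >= 0`, `id >= 0`,
#' `0 <= angle < 360`), sorts the stream by time (then marker ID), and
#' collapses duplicate `(t, id)` records to their first occurrence.  The
#' operation is idempotent.
#'
#' @param observations Data frame with columns `t`, `id`, `x`, `y` and
#'   optionally `angle` (defaults to 0).
#' @return The sorted, deduplicated stream.
#' @export
validate_stream <- function(observations) {
  stopifnot(is.data.frame(observations))
  if (!"angle" %in% names(observations)) {
    observations$angle <- rep(0, nrow(observations))
  }
  required <- c("t", "id", "x", "y", "angle")
  missing_cols <- setdiff(required, names(observations))
  if (length(missing_cols)) {
    stop("stream is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  observations <- observations[required]
  if (nrow(observations) == 0L) return(empty_stream())

  check_range <- function(v, lo, hi, field, hi_open = FALSE) {
    bad <- !is.finite(v) | v < lo | (if (hi_open) v >= hi else v > hi)
    if (any(bad)) {
      stop(sprintf("observation %d: %s = %s out of range [%s, %s%s",
                   which(bad)[1L], field, format(v[which(bad)[1L]]),
                   format(lo), format(hi), if (hi_open) ")" else "]"),
           call. = FALSE)
    }
  }
  check_range(observations$x, 0, 1, "x")
  check_range(observations$y, 0, 1, "y")
  check_range(observations$t, 0, Inf, "t")
  check_range(observations$id, 0, Inf, "id")
  check_range(observations$angle, 0, 360, "angle", hi_open = TRUE)
  observations$id <- as.integer(observations$id)

  ord <- order(observations$t, observations$id)
  observations <- observations[ord, , drop = FALSE]
  dup <- duplicated(observations[c("t", "id")])
  observations <- observations[!dup, , drop = FALSE]
  rownames(observations) <- NULL
  observations
}

#' Detection engine configuration
#'
#' Numeric constants of the detection rules.
#'
#' @param persist_s Seconds a region must be continuously visible before its
#'   detection fires (debounce; default 2).
#' @param partial_timeout_s Seconds of one-sided visibility before partial
#'   dressing (p) is raised (default 5).
#' @param y_align_max Velcro vertical alignment threshold (default 0.05,
#'   normalized coordinates).
#' @param x_align_max Velcro horizontal alignment threshold (default 0.18).
#' @param frame_rate_hz Sampling rate of the observation stream (default 15;
#'   a configuration default, not a property of the rules).
#' @param refractory_s Minimum gap between repeated emissions of the same
#'   label (default 1).
#' @param gap_tolerance_s Maximum gap between consecutive sightings for a
#'   visibility run to count as unbroken (default two frame periods, so a
#'   single dropped frame does not reset the persistence clock).
#' @param preset `"default"` or `"conservative"`; the conservative preset
#'   raises `persist_s` to 3 seconds, the longer debounce found adequate in
#'   preliminary testing against transient back/inside glimpses.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(persist_s = 2.0,
                             partial_timeout_s = 5.0,
                             y_align_max = 0.05,
                             x_align_max = 0.18,
                             frame_rate_hz = 15,
                             refractory_s = 1.0,
                             gap_tolerance_s = 2 / frame_rate_hz,
                             preset = c("default", "conservative")) {
  preset <- match.arg(preset)
  if (preset == "conservative" && missing(persist_s)) persist_s <- 3.0
  cfg <- list(persist_s = persist_s,
              partial_timeout_s = partial_timeout_s,
              y_align_max = y_align_max,
              x_align_max = x_align_max,
              frame_rate_hz = frame_rate_hz,
              refractory_s = refractory_s,
              gap_tolerance_s = gap_tolerance_s)
  bad <- names(cfg)[!vapply(cfg, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))]
  if (length(bad)) {
    stop("detection_config: ", paste(bad, collapse = ", "),
         " must be strictly positive numbers", call. = FALSE)
  }
  if (cfg$persist_s >= cfg$partial_timeout_s) {
    stop("detection_config: persist_s must be smaller than partial_timeout_s",
         call. = FALSE)
  }
  structure(cfg, class = "detection_config")
}

#' @export
print.detection_config <- function(x, ...) {
  cat("<detection_config>\n")
  for (nm in names(x)) cat(sprintf("  %-17s %g\n", nm, x[[nm]]))
  invisible(x)
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards so package functions never disturb user simulations.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
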