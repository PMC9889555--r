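ITEM_KINDS <- c("direct_observation", "choice", "number", "range",
                "four_quadrant", "text")
RECORDING_KINDS <- c("frequency", "duration", "interval")
INTERVAL_MODES <- c("partial", "whole", "momentary")

#' Build a measure item
#'
#' Items are the building blocks of a measure. Six kinds are supported:
#' `direct_observation` (carries a recording procedure: frequency, duration,
#' or interval recording), `choice` (closed list of options, single or
#' multiple), `number` (free numeric), `range` (bounded integer),
#' `four_quadrant` (a point on a labelled plane), and `text` (free text).
#'
#' @param kind One of the six item kinds.
#' @param prompt The question/prompt text shown to the observer.
#' @param recording For `direct_observation`: one of "frequency",
#'   "duration", "interval". Default "frequency".
#' @param interval_length For interval recording: bin length in seconds (> 0).
#' @param interval_mode For interval recording: "partial" (default), "whole"
#'   or "momentary".
#' @param options For `choice`: character vector of at least 2 options.
#' @param multiple_allowed For `choice`: may several options be selected?
#' @param min,max For `range`: integer bounds with `min < max`.
#' @param axes For `four_quadrant`: character vector of 2 axis labels.
#' @param axis_min,axis_max For `four_quadrant`: per-axis bounds (length 2).
#' @return An object of class `sced_item`.
#' @export
#' @examples
#' item("range", "How intense was the tantrum?", min = 0, max = 10)
#' item("direct_observation", "Mand emitted", recording = "frequency")
item <- function(kind, prompt,
                 recording = "frequency", interval_length = NULL,
                 interval_mode = "partial",
                 options = NULL, multiple_allowed = FALSE,
                 min = NULL, max = NULL,
                 axes = NULL, axis_min = NULL, axis_max = NULL) {
  kind <- match.arg(kind, ITEM_KINDS)
  if (!is.character(prompt) || length(prompt) != 1L || !nzchar(prompt))
    stop("'prompt' must be a non-empty string", call. = FALSE)
  x <- list(kind = kind, prompt = prompt)
  if (kind == "direct_observation") {
    x$recording <- match.arg(recording, RECORDING_KINDS)
    if (x$recording == "interval") {
      if (is.null(interval_length) || interval_length <= 0)
        stop("interval recording requires interval_length > 0", call. = FALSE)
      x$interval_length <- as.numeric(interval_length)
      x$interval_mode <- match.arg(interval_mode, INTERVAL_MODES)
    }
  } else if (kind == "choice") {
    if (is.null(options) || length(options) < 2L)
      stop("choice items need at least 2 options", call. = FALSE)
    if (anyDuplicated(options))
      stop("choice options must be unique", call. = FALSE)
    x$options <- as.character(options)
    x$multiple_allowed <- isTRUE(multiple_allowed)
  } else if (kind == "range") {
    if (is.null(min) || is.null(max) || !(min < max))
      stop("range items need integer bounds with min < max", call. = FALSE)
    x$min <- as.integer(min); x$max <- as.integer(max)
  } else if (kind == "four_quadrant") {
    if (is.null(axes) || length(axes) != 2L)
      stop("four_quadrant items need exactly 2 axis labels", call. = FALSE)
    if (is.null(axis_min)) axis_min <- c(-1, -1)
    if (is.null(axis_max)) axis_max <- c(1, 1)
    if (length(axis_min) != 2L || length(axis_max) != 2L ||
        any(axis_min >= axis_max))
      stop("four_quadrant axis bounds need axis_min < axis_max per axis",
           call. = FALSE)
    x$axes <- as.character(axes)
    x$axis_min <- as.numeric(axis_min); x$axis_max <- as.numeric(axis_max)
  }
  structure(x, class = "sced_item")
}

#' Build a measure
#'
#' A measure is a named, versioned, ordered collection of items that together
#' define one data-collection instrument. Measures can be exported to and
#' imported from JSON so practitioners can share them.
#'
#' @param name Measure name.
#' @param items List of [item()] objects (at least one); prompts must be
#'   unique within a measure.
#' @param version Free-form version tag.
#' @return An object of class `sced_measure`.
#' @export
measure <- function(name, items, version = "1") {
  if (!is.character(name) || !nzchar(name))
    stop("'name' must be a non-empty string", call. = FALSE)
  if (!is.list(items) || length(items) < 1L ||
      !all(vapply(items, inherits, logical(1), "sced_item")))
    stop("'items' must be a non-empty list of items", call. = FALSE)
  prompts <- vapply(items, `[[`, character(1), "prompt")
  if (anyDuplicated(prompts))
    stop("item prompts must be unique within a measure", call. = FALSE)
  structure(list(name = name, version = as.character(version), items = items),
            class = "sced_measure")
}

#' Build an event log
#'
#' The raw substrate for direct-observation recording: a session of known
#' duration plus a list of behavior events, each either an instant (onset
#' only) or an interval (onset and offset), in seconds from session start.
#'
#' @param duration Session duration in seconds (> 0).
#' @param onsets Numeric vector of event onsets (seconds).
#' @param offsets Numeric vector of event offsets; `NA` marks an instantaneous
#'   event. Recycled against `onsets`.
#' @return An object of class `event_log` with a data.frame `events`.
#' @export
#' @examples
#' event_log(600, onsets = c(10, 100), offsets = c(40, NA))
event_log <- function(duration, onsets = numeric(), offsets = NA_real_) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("'duration' must be a positive number of seconds", call. = FALSE)
  n <- length(onsets)
  offsets <- rep_len(as.numeric(offsets), if (n) n else 0L)
  ev <- data.frame(onset = as.numeric(onsets), offset = offsets)
  eff_off <- ifelse(is.na(ev$offset), ev$onset, ev$offset)
  if (any(ev$onset < 0) || any(eff_off > duration) || any(eff_off < ev$onset))
    stop("events must satisfy 0 <= onset <= offset <= duration", call. = FALSE)
  structure(list(duration = as.numeric(duration), events = ev),
            class = "event_log")
}

#' Frequency recording: count of events
#'
#' Each event counts once, whether instantaneous or an interval.
#'
#' @param log An [event_log()].
#' @return Non-negative integer count.
#' @export
summarize_frequency <- function(log) {
  stopifnot(inherits(log, "event_log"))
  nrow(log$events)
}

merge_intervals <- function(on, off) {
  # union of closed intervals; returns matrix with columns on, off
  if (length(on) == 0L) return(cbind(on = numeric(), off = numeric()))
  o <- order(on, off)
  on <- on[o]; off <- off[o]
  m_on <- on[1]; m_off <- off[1]
  res_on <- numeric(); res_off <- numeric()
  for (i in seq_along(on)[-1]) {
    if (on[i] <= m_off) {
      m_off <- max(m_off, off[i])
    } else {
      res_on <- c(res_on, m_on); res_off <- c(res_off, m_off)
      m_on <- on[i]; m_off <- off[i]
    }
  }
  cbind(on = c(res_on, m_on), off = c(res_off, m_off))
}

#' Duration recording: total seconds of behavior
#'
#' Interval events contribute their length; instantaneous events contribute
#' zero. Overlapping intervals are merged (union semantics) first, so a
#' behavior's duration is never double-counted and the result never exceeds
#' the session duration.
#'
#' @param log An [event_log()].
#' @return Total behavior duration in seconds.
#' @export
summarize_duration <- function(log) {
  stopifnot(inherits(log, "event_log"))
  ev <- log$events[!is.na(log$events$offset), , drop = FALSE]
  m <- merge_intervals(ev$onset, ev$offset)
  sum(m[, "off"] - m[, "on"])
}

#' Interval recording: proportion of occupied bins
#'
#' The session is divided into consecutive bins of `interval_length` seconds
#' (the last bin may be shorter). Three standard time-sampling modes:
#' \describe{
#'   \item{partial}{a bin scores if any behavior occurs anywhere in it;}
#'   \item{whole}{a bin scores only if behavior covers it entirely;}
#'   \item{momentary}{a bin scores if behavior is occurring at the instant
#'     the bin ends.}
#' }
#'
#' @param log An [event_log()].
#' @param interval_length Bin length in seconds (> 0).
#' @param mode "partial" (default), "whole" or "momentary".
#' @return Proportion of bins scored, in [0, 1].
#' @export
#' @examples
#' lg <- event_log(600, onsets = c(130, 310))
#' summarize_interval(lg, 60, "partial")  # 0.2
summarize_interval <- function(log, interval_length,
                               mode = c("partial", "whole", "momentary")) {
  stopifnot(inherits(log, "event_log"))
  mode <- match.arg(mode)
  if (!is.numeric(interval_length) || interval_length <= 0)
    stop("'interval_length' must be > 0", call. = FALSE)
  dur <- log$duration
  n_bins <- ceiling(dur / interval_length - 1e-9)
  starts <- (seq_len(n_bins) - 1) * interval_length
  ends <- pmin(starts + interval_length, dur)
  ev <- log$events
  inst <- ev$onset[is.na(ev$offset)]
  ints <- ev[!is.na(ev$offset), , drop = FALSE]
  merged <- merge_intervals(ints$onset, ints$offset)

  hit <- vapply(seq_along(starts), function(i) {
    s <- starts[i]; e <- ends[i]
    switch(mode,
      partial = {
        any(inst >= s & (inst < e | (e == dur & inst <= dur))) ||
          (nrow(merged) > 0 &&
             any(merged[, "on"] < e & merged[, "off"] > s))
      },
      whole = {
        nrow(merged) > 0 && any(merged[, "on"] <= s & merged[, "off"] >= e)
      },
      momentary = {
        any(abs(inst - e) < 1e-9) ||
          (nrow(merged) > 0 &&
             any(merged[, "on"] <= e & merged[, "off"] >= e))
      })
  }, logical(1))
  mean(hit)
}

#' Validate an observer response against an item
#'
#' Checks the response against the item variant's constraints and returns it
#' (possibly coerced); violations raise an error of class
#' `sceda_validation_error`.
#'
#' @param item An [item()].
#' @param value The raw response: a number for number/range, option string(s)
#'   for choice, a length-2 numeric for four_quadrant, a string for text, an
#'   [event_log()] or a count for direct_observation.
#' @return The validated value.
#' @export
validate_response <- function(item, value) {
  stopifnot(inherits(item, "sced_item"))
  fail <- function(msg) {
    stop(structure(class = c("sceda_validation_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  switch(item$kind,
    text = as.character(value),
    number = {
      if (!is.numeric(value) || length(value) != 1L || is.na(value))
        fail("number item requires a single numeric value")
      value
    },
    range = {
      if (!is.numeric(value) || length(value) != 1L || is.na(value))
        fail("range item requires a single numeric value")
      if (value < item$min || value > item$max)
        fail(sprintf("value %s outside range [%d, %d]",
                     format(value), item$min, item$max))
      as.integer(value)
    },
    choice = {
      value <- as.character(value)
      if (!item$multiple_allowed && length(value) != 1L)
        fail("single-choice item requires exactly one option")
      unknown <- setdiff(value, item$options)
      if (length(unknown))
        fail(sprintf("unknown option(s): %s", paste(unknown, collapse = ", ")))
      value
    },
    four_quadrant = {
      if (!is.numeric(value) || length(value) != 2L || anyNA(value))
        fail("four_quadrant item requires a numeric (x, y) pair")
      if (any(value < item$axis_min) || any(value > item$axis_max))
        fail("point outside the quadrant plane bounds")
      as.numeric(value)
    },
    direct_observation = {
      if (inherits(value, "event_log")) return(value)
      if (!is.numeric(value) || length(value) != 1L || value < 0)
        fail("direct_observation accepts an event_log or a non-negative summary value")
      value
    })
}

MEASURE_SCHEMA_VERSION <- "1.0"

item_to_list <- function(it) {
  unclass(it)
}

#' Export a measure to JSON
#'
#' Serializes a measure to a versioned JSON document (schema_version field)
#' suitable for sharing; [import_measure()] restores it exactly.
#'
#' @param m An [measure()].
#' @param path Optional file path; if `NULL` the JSON text is returned.
#' @return JSON text (invisibly, when written to a file).
#' @export
export_measure <- function(m, path = NULL) {
  stopifnot(inherits(m, "sced_measure"))
  doc <- list(schema_version = MEASURE_SCHEMA_VERSION,
              name = m$name, version = m$version,
              items = lapply(m$items, item_to_list))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}

#' Import a measure from JSON
#'
#' @param json JSON text, or a file path to a JSON document produced by
#'   [export_measure()].
#' @return A [measure()].
#' @export
import_measure <- function(json) {
  if (length(json) == 1L && file.exists(json))
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  required <- c("schema_version", "name", "version", "items")
  missing <- setdiff(required, names(doc))
  if (length(missing))
    stop(sprintf("measure JSON missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  items <- lapply(seq_along(doc$items), function(i) {
    raw <- doc$items[[i]]
    if (is.null(raw$kind))
      stop(sprintf("item %d missing field: kind", i), call. = FALSE)
    if (is.null(raw$prompt))
      stop(sprintf("item %d missing field: prompt", i), call. = FALSE)
    args <- raw
    args$options <- if (!is.null(raw$options)) unlist(raw$options)
    args$axes <- if (!is.null(raw$axes)) unlist(raw$axes)
    args$axis_min <- if (!is.null(raw$axis_min)) unlist(raw$axis_min)
    args$axis_max <- if (!is.null(raw$axis_max)) unlist(raw$axis_max)
    args <- args[!vapply(args, is.null, logical(1))]
    do.call(item, args)
  })
  measure(doc$name, items, version = doc$version)
}
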