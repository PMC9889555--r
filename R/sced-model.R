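#' Target behavior definition
#'
#' A target behavior pairs a short label with an operational definition and
#' the place/setting in which the behavior is observed, so that independent
#' observers record the same events.
#'
#' @param name Short label, non-empty.
#' @param operational_definition Free-text operational definition, non-empty.
#' @param place Free text, where observation happens (may be empty).
#' @param setting Free text, the broader setting (may be empty).
#' @return An object of class `target_behavior`.
#' @export
#' @examples
#' target_behavior("mand", "child requests a visible item within 5 s")
target_behavior <- function(name, operational_definition, place = "", setting = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name)))
    stop("'name' must be a non-empty string", call. = FALSE)
  if (!is.character(operational_definition) || length(operational_definition) != 1L ||
      !nzchar(trimws(operational_definition)))
    stop("'operational_definition' must be a non-empty string", call. = FALSE)
  structure(
    list(name = name, operational_definition = operational_definition,
         place = as.character(place), setting = as.character(setting)),
    class = "target_behavior"
  )
}

PHASE_LEVELS <- c("A", "B", "G")
CONTEXT_LEVELS <- c("clinic", "home", "school", "other")

#' Construct a single-case series
#'
#' The unit of analysis: one subject's ordered per-session scores with phase
#' labels. Session indexing is 1-based and global across phases (a 5-session
#' baseline followed by 30 intervention sessions spans indices 1--35, a
#' subsequent generalization phase continues at 36). Phases must appear in the
#' order A (baseline), B (intervention), then optionally G (generalization),
#' without interleaving.
#'
#' @param case_id Identifier for the case.
#' @param phase Character vector of per-session phase labels ("A", "B", "G").
#' @param score Integer vector of per-session scores (counts of correct
#'   responses).
#' @param max_score Positive integer, the score ceiling (number of trial
#'   opportunities per session); recycled to the series length.
#' @param session_index Optional explicit 1-based global session indices;
#'   defaults to `seq_along(score)`.
#' @param context Per-session context label ("clinic", "home", "school",
#'   "other"); recycled.
#' @param observer Per-session observer label; recycled.
#' @param date Optional per-session ISO-8601 date strings; recycled.
#' @param behavior Optional [target_behavior()].
#' @param design Design label; only "AB" (with optional G phase) is supported.
#' @return An object of class `case_series`: a list with `case_id`,
#'   `behavior`, `design`, and `sessions` (a data.frame).
#' @seealso [validate_series()], [phase_slice()]
#' @export
#' @examples
#' s <- case_series("child1", phase = rep(c("A", "B"), c(5, 30)),
#'                  score = c(rep(0, 5), seq_len(30)), max_score = 50)
#' nrow(s$sessions)
case_series <- function(case_id, phase, score, max_score = 50L,
                        session_index = seq_along(score),
                        context = "clinic", observer = "", date = NA_character_,
                        behavior = NULL, design = "AB") {
  n <- length(score)
  if (length(phase) != n)
    stop("'phase' and 'score' must have the same length", call. = FALSE)
  sessions <- data.frame(
    session_index = as.integer(session_index),
    phase = as.character(phase),
    score = as.integer(score),
    max_score = as.integer(rep_len(max_score, n)),
    context = as.character(rep_len(context, n)),
    observer = as.character(rep_len(observer, n)),
    date = as.character(rep_len(date, n)),
    stringsAsFactors = FALSE
  )
  if (!is.null(behavior) && !inherits(behavior, "target_behavior"))
    stop("'behavior' must be a target_behavior or NULL", call. = FALSE)
  structure(
    list(case_id = as.character(case_id), behavior = behavior,
         design = as.character(design), sessions = sessions),
    class = "case_series"
  )
}

#' @export
print.case_series <- function(x, ...) {
  ph <- table(factor(x$sessions$phase, levels = PHASE_LEVELS))
  cat(sprintf("<case_series> case '%s', design %s: %s\n", x$case_id, x$design,
              paste(sprintf("%d %s", as.integer(ph[ph > 0]),
                            names(ph)[ph > 0]), collapse = " + ")))
  invisible(x)
}

#' @export
as.data.frame.case_series <- function(x, ...) {
  out <- x$sessions
  out$case_id <- x$case_id
  out[, c("case_id", setdiff(names(out), "case_id"))]
}

violation <- function(rule, session_index, message) {
  data.frame(rule = rule, session_index = as.integer(session_index),
             message = message, stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(rule = character(), session_index = integer(),
             message = character(), stringsAsFactors = FALSE)
}

#' Validate a case series
#'
#' Checks every structural invariant of a [case_series()] and returns the
#' violations as data rather than raising: each row names the rule violated,
#' the offending global session index (NA for series-level rules) and a
#' human-readable message. An empty result means the series is valid.
#'
#' Rules checked: `index_consecutive` (session indices are 1, 2, ..., n),
#' `phase_label` (labels drawn from A/B/G), `phase_order` (A, then B, then
#' optionally G, no interleaving), `score_range` (0 <= score <= max_score),
#' `max_score_positive`, `context_label`.
#'
#' @param series A [case_series()].
#' @return A data.frame with columns `rule`, `session_index`, `message`;
#'   zero rows iff the series is valid.
#' @export
validate_series <- function(series) {
  stopifnot(inherits(series, "case_series"))
  s <- series$sessions
  out <- no_violations()
  n <- nrow(s)
  if (n == 0L)
    return(rbind(out, violation("empty_series", NA, "series has no sessions")))

  expect_idx <- seq_len(n)
  bad_idx <- which(s$session_index != expect_idx)
  for (i in bad_idx)
    out <- rbind(out, violation("index_consecutive", s$session_index[i],
                                sprintf("session %d should have index %d (1-based, consecutive)",
                                        s$session_index[i], expect_idx[i])))

  bad_ph <- which(!s$phase %in% PHASE_LEVELS)
  for (i in bad_ph)
    out <- rbind(out, violation("phase_label", s$session_index[i],
                                sprintf("unknown phase label '%s'", s$phase[i])))

  # phases must be non-interleaved and ordered A < B < G
  known <- s$phase %in% PHASE_LEVELS
  ranks <- match(s$phase[known], PHASE_LEVELS)
  if (length(ranks) > 1L) {
    drops <- which(diff(ranks) < 0L)
    idx_known <- s$session_index[known]
    for (i in drops)
      out <- rbind(out, violation("phase_order", idx_known[i + 1L],
                                  sprintf("phase '%s' follows phase '%s': phases must appear A, B, then G",
                                          s$phase[known][i + 1L], s$phase[known][i])))
  }

  bad_max <- which(s$max_score <= 0L)
  for (i in bad_max)
    out <- rbind(out, violation("max_score_positive", s$session_index[i],
                                sprintf("max_score %d is not positive", s$max_score[i])))

  bad_score <- which(s$score < 0L | s$score > s$max_score)
  for (i in bad_score)
    out <- rbind(out, violation("score_range", s$session_index[i],
                                sprintf("score %d outside [0, %d]", s$score[i], s$max_score[i])))

  bad_ctx <- which(!s$context %in% CONTEXT_LEVELS)
  for (i in bad_ctx)
    out <- rbind(out, violation("context_label", s$session_index[i],
                                sprintf("unknown context '%s'", s$context[i])))

  out
}

#' Extract one phase of a series as time/score vectors
#'
#' Returns the sessions belonging to one phase, preserving the global
#' session indices so that the time axis is continuous across phases.
#'
#' @param series A [case_series()].
#' @param phase One of "A", "B", "G"; must be present in the series.
#' @return A list with integer vector `t` (global session indices) and
#'   integer vector `y` (scores), plus `phase`.
#' @export
#' @examples
#' s <- case_series("c", rep(c("A", "B"), c(2, 3)), c(0, 0, 3, 5, 9))
#' phase_slice(s, "B")$t  # 3 4 5
phase_slice <- function(series, phase) {
  stopifnot(inherits(series, "case_series"))
  if (!phase %in% series$sessions$phase)
    stop(sprintf("phase '%s' not present in series '%s'", phase, series$case_id),
         call. = FALSE)
  keep <- series$sessions$phase == phase
  list(t = series$sessions$session_index[keep],
       y = series$sessions$score[keep],
       phase = phase)
}

#' Per-phase session counts
#'
#' @param series A [case_series()].
#' @return Named integer vector with counts for phases A, B, G.
#' @export
phase_lengths <- function(series) {
  stopifnot(inherits(series, "case_series"))
  tab <- table(factor(series$sessions$phase, levels = PHASE_LEVELS))
  stats::setNames(as.integer(tab), PHASE_LEVELS)
}
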