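CANONICAL_COLUMNS <- c("case_id", "session_index", "phase", "score",
                       "max_score", "context", "observer", "date")
REQUIRED_COLUMNS <- c("case_id", "session_index", "phase", "score")

#' Column mapping for session CSV files
#'
#' Maps canonical field names to the column names of a source CSV, and
#' normalizes arbitrary source phase vocabularies (e.g. "baseline",
#' "training", "generalization") to the internal A/B/G labels.
#'
#' @param ... Named canonical-field = source-column pairs overriding the
#'   identity mapping (e.g. `score = "correct_responses"`).
#' @param phase_labels Named character vector mapping source phase labels to
#'   "A", "B" or "G"; defaults to identity plus the common long names.
#' @return An object of class `column_mapping`.
#' @export
#' @examples
#' column_mapping(score = "n_correct",
#'                phase_labels = c(baseline = "A", training = "B"))
column_mapping <- function(..., phase_labels = NULL) {
  over <- list(...)
  map <- stats::setNames(as.list(CANONICAL_COLUMNS), CANONICAL_COLUMNS)
  for (nm in names(over)) {
    if (!nm %in% CANONICAL_COLUMNS)
      stop(sprintf("unknown canonical field '%s'", nm), call. = FALSE)
    map[[nm]] <- as.character(over[[nm]])
  }
  if (is.null(phase_labels))
    phase_labels <- c(A = "A", B = "B", G = "G",
                      baseline = "A", intervention = "B", training = "B",
                      generalization = "G")
  structure(list(map = map, phase_labels = phase_labels),
            class = "column_mapping")
}

#' Read session data from CSV
#'
#' Parses per-session observation records into validated [case_series()]
#' objects, one per `case_id`, with sessions sorted by session index. Scores
#' must be integers (the dependent variable is a count of correct responses);
#' fractional scores, duplicate session indices and missing mapped columns
#' are typed errors naming the offending row or column.
#'
#' @param path CSV file path.
#' @param mapping A [column_mapping()] (default: canonical layout).
#' @return Named list of [case_series()].
#' @export
read_sessions_csv <- function(path, mapping = column_mapping()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  stopifnot(inherits(mapping, "column_mapping"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  need <- unlist(mapping$map[REQUIRED_COLUMNS])
  absent <- setdiff(need, names(raw))
  if (length(absent))
    stop(sprintf("missing mapped column(s): %s", paste(absent, collapse = ", ")),
         call. = FALSE)
  get_col <- function(field, default = NA_character_) {
    src <- mapping$map[[field]]
    if (src %in% names(raw)) raw[[src]] else rep(default, nrow(raw))
  }
  as_int <- function(x, what) {
    suppress <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(suppress) | suppress != round(suppress))
    if (length(bad))
      stop(sprintf("non-integer %s at row(s) %s", what,
                   paste(bad, collapse = ", ")), call. = FALSE)
    as.integer(suppress)
  }
  df <- data.frame(
    case_id = get_col("case_id"),
    session_index = as_int(get_col("session_index"), "session_index"),
    phase = as.character(mapping$phase_labels[get_col("phase")]),
    score = as_int(get_col("score"), "score"),
    max_score = get_col("max_score", "50"),
    context = get_col("context", "clinic"),
    observer = get_col("observer", ""),
    date = get_col("date", NA_character_),
    stringsAsFactors = FALSE)
  df$date[!is.na(df$date) & df$date == ""] <- NA_character_
  unknown_phase <- which(is.na(df$phase))
  if (length(unknown_phase))
    stop(sprintf("unknown phase label at row(s) %s",
                 paste(unknown_phase, collapse = ", ")), call. = FALSE)
  df$max_score <- as_int(df$max_score, "max_score")

  out <- lapply(split(df, df$case_id), function(g) {
    dup <- g$session_index[duplicated(g$session_index)]
    if (length(dup))
      stop(sprintf("duplicate (case_id, session_index) for case '%s': %s",
                   g$case_id[1], paste(unique(dup), collapse = ", ")),
           call. = FALSE)
    g <- g[order(g$session_index), , drop = FALSE]
    s <- case_series(g$case_id[1], phase = g$phase, score = g$score,
                     max_score = g$max_score,
                     session_index = g$session_index,
                     context = g$context, observer = g$observer,
                     date = g$date)
    viol <- validate_series(s)
    if (nrow(viol))
      warning(sprintf("case '%s' has %d validation issue(s); see validate_series()",
                      g$case_id[1], nrow(viol)), call. = FALSE)
    s
  })
  out[order(names(out))]
}

#' Write session data to canonical CSV
#'
#' Canonical header order, UTF-8, LF line endings, RFC-4180 quoting;
#' `read_sessions_csv(write_sessions_csv(x))` reproduces the input.
#'
#' @param series_list A [case_series()] or list of them.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_sessions_csv <- function(series_list, path) {
  if (inherits(series_list, "case_series")) series_list <- list(series_list)
  rows <- lapply(series_list, as.data.frame)
  df <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(CANONICAL_COLUMNS))),
                    CANONICAL_COLUMNS)
  df <- df[, CANONICAL_COLUMNS, drop = FALSE]
  con <- file(path, open = "wb")  # LF endings on every platform
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

report_to_list <- function(report) {
  eff <- lapply(report$effects, function(e) {
    out <- unclass(e)
    out$trend <- if (!is.null(e$trend)) list(b0 = e$trend$b0, b1 = e$trend$b1)
    out[!vapply(out, is.null, logical(1))]
  })
  list(
    case_id = report$case_id,
    design = report$design,
    behavior = if (!is.null(report$behavior)) unclass(report$behavior),
    direction = report$direction,
    alpha = report$alpha,
    descriptives = report$descriptives,
    scatter = report$scatter,
    selection = unclass(report$selection),
    effects = eff,
    band = unclass(report$band),
    band_tables = report$band_tables,
    milestones = report$milestones,
    caveats = as.list(report$caveats)
  )
}

report_to_markdown <- function(report) {
  h <- report$effects[[report$selection$method]]
  est <- if (!is.null(h$estimate)) h$estimate else h$r
  lines <- c(
    sprintf("# Analysis report: case %s", report$case_id),
    "",
    sprintf("- design: %s, improvement direction: %s, alpha: %s",
            report$design, report$direction, format(report$alpha)),
    sprintf("- headline method: **%s** (selection rule: `%s`)",
            report$selection$method, report$selection$rule),
    sprintf("- headline estimate: **%.4f** — band **%s** (gauge position %.2f)",
            est, report$band$band, report$band$gauge_position),
    "",
    "## Phase descriptives",
    "",
    "| phase | n | mean | sd | median | min | max |",
    "|---|---|---|---|---|---|---|",
    apply(report$descriptives, 1, function(r)
      sprintf("| %s | %s | %s | %s | %s | %s | %s |",
              r[["phase"]], r[["n"]], r[["mean"]], r[["sd"]],
              r[["median"]], r[["min"]], r[["max"]])),
    "",
    "## Effect sizes",
    "")
  for (nm in names(report$effects)) {
    e <- report$effects[[nm]]
    if (nm == "parametric") {
      lines <- c(lines, sprintf(
        "- parametric detrended regression: r = %.4f, R^2 = %.4f, F(%d, %d) = %s, p = %s; level change c1 = %.4f, slope change c2 = %.4f; cov assumption %s",
        e$r, e$r_squared, e$df1, e$df2,
        if (is.finite(e$F)) sprintf("%.4f", e$F) else "Inf",
        format.pval(e$p), e$c1, e$c2,
        if (e$cov_assumption$ok) "respected" else "VIOLATED"))
    } else {
      lines <- c(lines, sprintf("- %s = %.4f%s", nm, e$estimate,
        if (isTRUE(e$out_of_range)) " (outside nominal range)" else ""))
    }
  }
  ms <- report$milestones
  fmt_ms <- function(x) if (is.na(x)) "never" else sprintf("session %d", x)
  lines <- c(lines, "",
    "## Milestones (global session index)",
    "",
    sprintf("- first positive score: %s", fmt_ms(ms$first_positive)),
    sprintf("- first score at threshold: %s", fmt_ms(ms$first_at_threshold)),
    sprintf("- first maximum score: %s", fmt_ms(ms$first_at_max)),
    sprintf("- mastery criterion reached: %s", fmt_ms(ms$mastery)))
  if (length(report$caveats)) {
    lines <- c(lines, "", "## Caveats", "",
               paste0("- ", report$caveats))
  }
  paste(c(lines, ""), collapse = "\n")
}

#' Serialize an analysis report
#'
#' JSON output uses a canonical key order and is byte-identical for identical
#' input; Markdown output is a human-readable render with descriptives,
#' method selection, effect sizes, interpretation band, milestones and
#' caveats.
#'
#' @param report A [build_report()] result.
#' @param path Output file path.
#' @param format "json" or "markdown".
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "markdown")) {
  stopifnot(inherits(report, "analysis_report"))
  format <- match.arg(format)
  txt <- if (format == "json") {
    as.character(jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                                  digits = NA, pretty = TRUE, na = "null"))
  } else {
    report_to_markdown(report)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a simulation config from YAML or JSON
#'
#' @param path File path (extension .yaml/.yml or .json).
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop(sprintf("unknown sim config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  do.call(sim_config, vals)
}

#' Write a simulation config to YAML
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
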