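#' Default interpretation band tables
#'
#' Cut points per method scale, with closed lower bounds: an estimate exactly
#' at a cut point falls in the higher band. Bands are named weak / medium /
#' large. Tau and the parametric r are banded on their absolute value. The
#' tables can be overridden through the `bands` element of a report config.
#'
#' @return Named list of per-method lists with `cuts` (two ascending cut
#'   points), `scale` (lower/upper bounds of the native scale) and `absolute`
#'   (band on |estimate|?).
#' @export
default_band_tables <- function() {
  list(
    NAP = list(cuts = c(0.66, 0.93), scale = c(0, 1), absolute = FALSE),
    PND = list(cuts = c(50, 90), scale = c(0, 100), absolute = FALSE),
    PEM = list(cuts = c(70, 90), scale = c(0, 100), absolute = FALSE),
    TAU_AB = list(cuts = c(0.2, 0.6), scale = c(-1, 1), absolute = TRUE),
    TAU_U = list(cuts = c(0.2, 0.6), scale = c(-1, 1), absolute = TRUE),
    parametric = list(cuts = c(0.3, 0.5), scale = c(-1, 1), absolute = TRUE)
  )
}

#' Choose the analysis method for an AB comparison
#'
#' Deterministic rule table driven by the phase sizes and assumption flags:
#' \enumerate{
#'   \item the detrended parametric regression when `n_A >= 3`, `n_B >= 5`,
#'     the baseline has positive time variance and the covariance assumption
#'     holds;
#'   \item otherwise Tau-U when `n_A >= 3` and the baseline shows a nonzero
#'     trend (Tau-U exists to absorb baseline trend);
#'   \item otherwise NAP, the assumption-light floor.
#' }
#' The fired rule is always recorded.
#'
#' @param n_A,n_B Phase sizes (>= 1).
#' @param flags List of assumption flags: `cov_ok` (covariance assumption
#'   holds), `baseline_trend_nonzero`, `baseline_time_variance_positive`.
#'   Missing flags default to `TRUE` for `baseline_time_variance_positive`
#'   and `FALSE` otherwise.
#' @return A `method_selection`: list with `method`, `rule`, `inputs`.
#' @export
#' @examples
#' select_method(5, 30, list(cov_ok = TRUE))$method  # "parametric"
select_method <- function(n_A, n_B, flags = list()) {
  stopifnot(n_A >= 1, n_B >= 1)
  cov_ok <- isTRUE(flags$cov_ok)
  trend_nz <- isTRUE(flags$baseline_trend_nonzero)
  tvar_pos <- !isFALSE(flags$baseline_time_variance_positive)
  if (n_A >= 3 && n_B >= 5 && tvar_pos && cov_ok) {
    method <- "parametric"; rule <- "parametric_regression_applicable"
  } else if (n_A >= 3 && trend_nz) {
    method <- "TAU_U"; rule <- "tau_u_absorbs_baseline_trend"
  } else {
    method <- "NAP"; rule <- "nap_assumption_light_floor"
  }
  structure(list(method = method, rule = rule,
                 inputs = list(n_A = as.integer(n_A), n_B = as.integer(n_B),
                               cov_ok = cov_ok,
                               baseline_trend_nonzero = trend_nz,
                               baseline_time_variance_positive = tvar_pos)),
            class = "method_selection")
}

#' Map an effect-size estimate to an interpretation band
#'
#' Places the estimate in the weak / medium / large band of its method's
#' threshold table (closed lower bounds: a value exactly at a cut point takes
#' the higher band) and computes a gauge position in [0, 1] — the estimate
#' linearly rescaled from its native scale — for speedometer-style rendering.
#'
#' @param result An effect-size result: a `nonoverlap_result` or
#'   `parametric_result`, or a list with `method` and `estimate`.
#' @param bands Band tables, see [default_band_tables()].
#' @return An `interpretation_band`: list with `band`, `thresholds`,
#'   `gauge_position`, `method`.
#' @export
#' @examples
#' interpret(nap(c(0, 0), c(5, 6)))$band  # "large"
interpret <- function(result, bands = default_band_tables()) {
  method <- result$method
  est <- if (!is.null(result$estimate)) result$estimate else result$r
  tab <- bands[[method]]
  if (is.null(tab))
    stop(sprintf("no band table for method '%s'", method), call. = FALSE)
  val <- if (isTRUE(tab$absolute)) abs(est) else est
  band <- if (val >= tab$cuts[2]) "large" else if (val >= tab$cuts[1]) "medium" else "weak"
  gauge <- (est - tab$scale[1]) / diff(tab$scale)
  structure(list(band = band, thresholds = tab$cuts,
                 gauge_position = min(max(gauge, 0), 1), method = method),
            class = "interpretation_band")
}

milestone_predicate <- function(predicate, fraction) {
  switch(predicate,
    positive = function(score, max_score) score > 0,
    fraction = function(score, max_score) score >= fraction * max_score,
    max      = function(score, max_score) score == max_score,
    stop(sprintf("unknown predicate '%s'", predicate), call. = FALSE))
}

#' First session meeting a scoring milestone
#'
#' Scans the series in global session order and returns the first session
#' index whose score satisfies the milestone predicate: `"positive"`
#' (score > 0), `"fraction"` (score >= fraction * max_score), or `"max"`
#' (score equals max_score).
#'
#' @param series A [case_series()].
#' @param predicate "positive", "fraction" or "max".
#' @param fraction Threshold fraction for `predicate = "fraction"`
#'   (default 0.8).
#' @param phases Phases to scan (default therapy phases A and B).
#' @return Global session index (integer) or `NA_integer_` if never met.
#' @export
first_session_meeting <- function(series, predicate = c("positive", "fraction", "max"),
                                  fraction = 0.8, phases = c("A", "B")) {
  predicate <- match.arg(predicate)
  stopifnot(inherits(series, "case_series"))
  s <- series$sessions[series$sessions$phase %in% phases, , drop = FALSE]
  f <- milestone_predicate(predicate, fraction)
  hit <- which(f(s$score, s$max_score))
  if (length(hit) == 0L) NA_integer_ else s$session_index[hit[1]]
}

#' Detect attainment of a mastery criterion
#'
#' Finds the first run of `consecutive` sessions whose scores all reach
#' `threshold_fraction * max_score`, and returns the global index of the LAST
#' session of that run — the session at which the criterion is reached (e.g.
#' 80% correct over 3 consecutive sessions marks the end of intervention).
#'
#' @param series A [case_series()].
#' @param threshold_fraction Fraction of `max_score` required, in (0, 1].
#' @param consecutive Number of consecutive qualifying sessions (>= 1).
#' @param phases Phases to scan (default A and B).
#' @return Global session index or `NA_integer_` if never attained.
#' @export
detect_mastery <- function(series, threshold_fraction = 0.8, consecutive = 3L,
                           phases = c("A", "B")) {
  stopifnot(inherits(series, "case_series"),
            threshold_fraction > 0, threshold_fraction <= 1, consecutive >= 1)
  s <- series$sessions[series$sessions$phase %in% phases, , drop = FALSE]
  ok <- s$score >= threshold_fraction * s$max_score
  run <- 0L
  for (i in seq_along(ok)) {
    run <- if (ok[i]) run + 1L else 0L
    if (run >= consecutive) return(s$session_index[i])
  }
  NA_integer_
}

#' Descriptive within-phase trend
#'
#' OLS slope of score on session index inside one phase, in score units per
#' session; used for the descriptive intervention-vs-generalization
#' comparison.
#'
#' @param series A [case_series()].
#' @param phase Phase label with at least 2 sessions.
#' @return Numeric slope.
#' @export
phase_trend <- function(series, phase) {
  sl <- phase_slice(series, phase)
  if (length(sl$t) < 2L)
    stop("phase trend needs at least 2 sessions", call. = FALSE)
  unname(stats::coef(stats::lm(sl$y ~ sl$t))[2])
}

phase_descriptives <- function(series) {
  s <- series$sessions
  do.call(rbind, lapply(intersect(PHASE_LEVELS, unique(s$phase)), function(ph) {
    y <- s$score[s$phase == ph]
    data.frame(phase = ph, n = length(y), mean = mean(y),
               sd = if (length(y) > 1) stats::sd(y) else NA_real_,
               median = stats::median(y), min = min(y), max = max(y),
               stringsAsFactors = FALSE)
  }))
}

ANTICONSERVATISM_CAVEAT <- paste(
  "Two-stage estimation (baseline trend, then treatment effects on de-trend",
  "scores) is known to be anti-conservative: baseline-trend uncertainty is",
  "not propagated into the F test.")

#' Assemble the full per-case analysis report
#'
#' Computes per-phase descriptives, scatter data, all applicable effect-size
#' indices (the parametric detrended regression and the five non-overlap
#' indices), selects the headline method by the rule table, attaches its
#' interpretation band, detects milestones and mastery, and collects caveats.
#' The report is deterministic given the series and config.
#'
#' @param series A [case_series()].
#' @param config List of options: `direction` ("increase"/"decrease"),
#'   `method` ("auto" or one of parametric/nap/pnd/pem/tau_ab/tau_u),
#'   `alpha` (test level, default 0.05), `bands` (see
#'   [default_band_tables()]), `mastery` (list with `threshold_fraction`,
#'   `consecutive`), `phases` (pair to compare, default A vs B).
#' @return An object of class `analysis_report`.
#' @export
build_report <- function(series, config = list()) {
  stopifnot(inherits(series, "case_series"))
  viol <- validate_series(series)
  if (nrow(viol) > 0L)
    stop(sprintf("series '%s' is invalid: %s", series$case_id,
                 paste(viol$message, collapse = "; ")), call. = FALSE)
  direction <- if (is.null(config$direction)) "increase" else config$direction
  method_req <- if (is.null(config$method)) "auto" else tolower(config$method)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  stopifnot(alpha > 0, alpha < 1)
  bands <- if (is.null(config$bands)) default_band_tables() else config$bands
  mastery_cfg <- if (is.null(config$mastery))
    list(threshold_fraction = 0.8, consecutive = 3L) else config$mastery
  phases <- if (is.null(config$phases)) c("A", "B") else config$phases

  A <- phase_slice(series, phases[1]); B <- phase_slice(series, phases[2])
  n_A <- length(A$y); n_B <- length(B$y)

  effects <- list()
  effects$NAP <- nap(A$y, B$y, direction)
  effects$PND <- pnd(A$y, B$y, direction)
  effects$PEM <- pem(A$y, B$y, direction)
  effects$TAU_AB <- tau_ab(A$y, B$y, direction)
  if (n_A >= 2L) effects$TAU_U <- tau_u(A$y, B$y, direction)

  par_res <- NULL
  flags <- list(cov_ok = FALSE, baseline_trend_nonzero = FALSE,
                baseline_time_variance_positive = n_A >= 2L)
  if (n_A >= 2L && n_B >= 2L && n_A + n_B >= 5L) {
    par_res <- tryCatch(analyze_parametric(series, phases, direction),
                        error = function(e) NULL)
    if (!is.null(par_res)) {
      effects$parametric <- par_res
      flags$cov_ok <- par_res$cov_assumption$ok
      flags$baseline_trend_nonzero <- par_res$trend$b1 != 0
    }
  }

  selection <- if (method_req == "auto") {
    sel <- select_method(n_A, n_B, flags)
    if (sel$method == "parametric" && is.null(par_res))
      sel <- select_method(n_A, n_B, modifyList(flags, list(cov_ok = FALSE)))
    sel
  } else {
    m <- toupper(method_req)
    if (method_req == "parametric") m <- "parametric"
    if (!m %in% names(effects))
      stop(sprintf("requested method '%s' not computable for this series",
                   method_req), call. = FALSE)
    structure(list(method = m, rule = "user_requested",
                   inputs = list(n_A = n_A, n_B = n_B)),
              class = "method_selection")
  }

  headline <- effects[[selection$method]]
  band <- interpret(headline, bands)

  milestones <- list(
    first_positive = first_session_meeting(series, "positive", phases = phases),
    first_at_threshold = first_session_meeting(series, "fraction",
                                               mastery_cfg$threshold_fraction,
                                               phases = phases),
    first_at_max = first_session_meeting(series, "max", phases = phases),
    mastery = detect_mastery(series, mastery_cfg$threshold_fraction,
                             mastery_cfg$consecutive, phases = phases)
  )

  caveats <- character()
  if (!is.null(par_res)) {
    caveats <- c(caveats, ANTICONSERVATISM_CAVEAT)
    if (!par_res$cov_assumption$ok)
      caveats <- c(caveats, "Covariance assumption violated: cov(phase, de-trend score) is not in the therapeutic direction.")
  }
  if (!is.null(effects$TAU_U) && isTRUE(effects$TAU_U$out_of_range))
    caveats <- c(caveats, "Tau-U exceeded its nominal [-1, 1] range (baseline trend opposes improvement); reported unclipped.")
  if (selection$rule == "nap_assumption_light_floor" && n_A < 3L)
    caveats <- c(caveats, "Baseline too short for trend-aware methods; non-overlap (NAP) used as the assumption-light fallback.")

  structure(
    list(case_id = series$case_id,
         behavior = series$behavior,
         design = series$design,
         direction = direction,
         alpha = alpha,
         descriptives = phase_descriptives(series),
         scatter = series$sessions[, c("session_index", "score", "phase", "context")],
         selection = selection,
         effects = effects,
         band = band,
         band_tables = bands,
         milestones = milestones,
         caveats = caveats),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Analysis report for case '%s' (%s design, direction = %s)\n",
              x$case_id, x$design, x$direction))
  cat(sprintf("  headline method: %s (rule: %s)\n",
              x$selection$method, x$selection$rule))
  h <- x$effects[[x$selection$method]]
  est <- if (!is.null(h$estimate)) h$estimate else h$r
  cat(sprintf("  headline estimate: %.4f, band: %s (gauge %.2f)\n",
              est, x$band$band, x$band$gauge_position))
  if (!is.null(x$effects$parametric)) print(x$effects$parametric)
  ms <- x$milestones
  cat(sprintf("  milestones: first>0 @%s, first>=threshold @%s, mastery @%s\n",
              ms$first_positive, ms$first_at_threshold, ms$mastery))
  for (cv in x$caveats) cat("  caveat:", cv, "\n")
  invisible(x)
}
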