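NONOVERLAP_METHODS <- c("NAP", "PND", "PEM", "TAU_AB", "TAU_U")

new_nonoverlap_result <- function(method, estimate, n_A, n_B, direction,
                                  out_of_range = FALSE) {
  structure(
    list(method = method, estimate = estimate,
         n_A = as.integer(n_A), n_B = as.integer(n_B),
         improvement_direction = direction, out_of_range = out_of_range),
    class = c("nonoverlap_result", "effect_size_result")
  )
}

#' @export
print.nonoverlap_result <- function(x, ...) {
  cat(sprintf("%s = %.4f (n_A = %d, n_B = %d, direction = %s)%s\n",
              x$method, x$estimate, x$n_A, x$n_B, x$improvement_direction,
              if (isTRUE(x$out_of_range)) " [outside nominal range]" else ""))
  invisible(x)
}

check_phases <- function(A, B, min_A = 1L) {
  if (length(A) < min_A)
    stop(sprintf("baseline phase needs at least %d observation(s)", min_A),
         call. = FALSE)
  if (length(B) < 1L)
    stop("intervention phase needs at least 1 observation", call. = FALSE)
}

# orient scores so that "improvement" always means "larger"
orient <- function(x, direction) if (direction == "decrease") -x else x

#' Exhaustive cross-phase pair outcomes
#'
#' Enumerates every (baseline, intervention) score pair and classifies it as
#' improved, tied, or deteriorated with respect to the improvement direction.
#' This is the slow, transparent reference from which NAP and Tau can be
#' recomputed; the fast implementations must agree with it exactly.
#'
#' @param A,B Numeric score vectors for the baseline and intervention phases.
#' @param direction "increase" (default) or "decrease": which way is better.
#' @return A data.frame with one row per pair: `a_index`, `b_index`, `a`, `b`,
#'   `outcome`.
#' @export
pairwise_oracle <- function(A, B, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  check_phases(A, B)
  g <- expand.grid(a_index = seq_along(A), b_index = seq_along(B))
  a <- orient(A[g$a_index], direction)
  b <- orient(B[g$b_index], direction)
  outcome <- ifelse(b > a, "improved", ifelse(b < a, "deteriorated", "tied"))
  data.frame(a_index = g$a_index, b_index = g$b_index,
             a = A[g$a_index], b = B[g$b_index],
             outcome = outcome, stringsAsFactors = FALSE)
}

#' Non-overlap of all pairs (NAP)
#'
#' The proportion of all baseline-vs-intervention score pairs showing
#' improvement, with ties weighted 0.5 — equivalently the Mann-Whitney U
#' statistic (mid-rank tie handling) divided by `n_A * n_B`. 0.5 is chance
#' level; 1 is complete separation in the therapeutic direction.
#'
#' The implementation is rank-based (midranks on the pooled sample); tests
#' verify exact agreement with [pairwise_oracle()].
#'
#' @inheritParams pairwise_oracle
#' @return A `nonoverlap_result` with estimate in [0, 1].
#' @export
#' @examples
#' nap(c(1, 3, 2), c(2, 4, 4))$estimate  # 0.8333
nap <- function(A, B, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  check_phases(A, B)
  a <- orient(A, direction); b <- orient(B, direction)
  r <- rank(c(a, b))  # midranks
  nA <- length(a); nB <- length(b)
  U <- sum(r[(nA + 1):(nA + nB)]) - nB * (nB + 1) / 2
  new_nonoverlap_result("NAP", U / (nA * nB), nA, nB, direction)
}

#' Percentage of non-overlapping data (PND)
#'
#' The percentage of intervention points strictly exceeding the most extreme
#' baseline point (the baseline maximum when improvement means increase, the
#' minimum when it means decrease). Scale 0--100.
#'
#' @inheritParams pairwise_oracle
#' @return A `nonoverlap_result` with estimate in [0, 100].
#' @export
pnd <- function(A, B, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  check_phases(A, B)
  a <- orient(A, direction); b <- orient(B, direction)
  new_nonoverlap_result("PND", 100 * sum(b > max(a)) / length(b),
                        length(a), length(b), direction)
}

#' Percentage of data exceeding the baseline median (PEM)
#'
#' Intervention points beyond the baseline median count fully; points exactly
#' at the median count half. Scale 0--100.
#'
#' @inheritParams pairwise_oracle
#' @return A `nonoverlap_result` with estimate in [0, 100].
#' @export
pem <- function(A, B, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  check_phases(A, B)
  a <- orient(A, direction); b <- orient(B, direction)
  med <- stats::median(a)
  new_nonoverlap_result("PEM",
                        100 * (sum(b > med) + 0.5 * sum(b == med)) / length(b),
                        length(a), length(b), direction)
}

#' Tau-AB: Kendall-type non-overlap between phases
#'
#' (improved pairs - deteriorated pairs) / (n_A * n_B) over all cross-phase
#' pairs; ties contribute zero. Satisfies `Tau_AB = 2 * NAP - 1` exactly.
#' Scale -1 to 1, with 0 at chance.
#'
#' @inheritParams pairwise_oracle
#' @return A `nonoverlap_result` with estimate in [-1, 1].
#' @export
tau_ab <- function(A, B, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  check_phases(A, B)
  a <- orient(A, direction); b <- orient(B, direction)
  r <- rank(c(a, b))
  nA <- length(a); nB <- length(b)
  U <- sum(r[(nA + 1):(nA + nB)]) - nB * (nB + 1) / 2
  # 2U - nA*nB = improved - deteriorated pairs (exact integer arithmetic)
  new_nonoverlap_result("TAU_AB", (2 * U - nA * nB) / (nA * nB),
                        nA, nB, direction)
}

#' Tau-U with baseline-trend correction
#'
#' `(S_AB - S_AA) / (n_A * n_B)`, where `S_AB` is the improved-minus-
#' deteriorated count over cross-phase pairs and `S_AA` the same count over
#' time-ordered within-baseline pairs. Subtracting `S_AA` discounts any
#' improving trend already present at baseline. The statistic can exceed the
#' nominal [-1, 1] range when the baseline trend opposes the improvement
#' direction; such values are reported unclipped with `out_of_range = TRUE`.
#'
#' @inheritParams pairwise_oracle
#' @return A `nonoverlap_result`; estimate usually in [-1, 1], unclipped.
#' @export
#' @examples
#' tau_u(c(1, 2, 3), c(4, 5, 6))$estimate  # 0.6667
tau_u <- function(A, B, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  check_phases(A, B, min_A = 2L)
  a <- orient(A, direction); b <- orient(B, direction)
  S_AB <- sum(sign(outer(a, b, function(x, y) y - x)))
  pairs_A <- utils::combn(length(a), 2)
  S_AA <- sum(sign(a[pairs_A[2, ]] - a[pairs_A[1, ]]))
  est <- (S_AB - S_AA) / (length(a) * length(b))
  new_nonoverlap_result("TAU_U", est, length(a), length(b), direction,
                        out_of_range = abs(est) > 1)
}

#' Recompute NAP and Tau-AB from a pairwise oracle table
#'
#' @param tab Output of [pairwise_oracle()].
#' @return List with `nap` and `tau_ab` estimates.
#' @export
oracle_indices <- function(tab) {
  n <- nrow(tab)
  imp <- sum(tab$outcome == "improved")
  tie <- sum(tab$outcome == "tied")
  det <- sum(tab$outcome == "deteriorated")
  list(nap = (imp + 0.5 * tie) / n, tau_ab = (imp - det) / n)
}
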