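test_that("method selection follows the documented rule table", {
  sel <- select_method(5, 30, list(cov_ok = TRUE, baseline_trend_nonzero = TRUE))
  expect_identical(sel$method, "parametric")
  expect_identical(sel$rule, "parametric_regression_applicable")

  sel2 <- select_method(5, 30, list(cov_ok = FALSE, baseline_trend_nonzero = TRUE))
  expect_identical(sel2$method, "TAU_U")

  expect_identical(select_method(2, 4, list(cov_ok = TRUE))$method, "NAP")
  expect_identical(select_method(1, 30, list(cov_ok = TRUE))$method, "NAP")
})

test_that("method selection is a pure function over the full flag grid", {
  for (n_A in 1:6) for (n_B in c(1, 4, 5, 30))
    for (cov_ok in c(TRUE, FALSE)) for (tr in c(TRUE, FALSE))
      for (tv in c(TRUE, FALSE)) {
        flags <- list(cov_ok = cov_ok, baseline_trend_nonzero = tr,
                      baseline_time_variance_positive = tv)
        s1 <- select_method(n_A, n_B, flags)
        s2 <- select_method(n_A, n_B, flags)
        expect_identical(s1, s2)
        expected <- if (n_A >= 3 && n_B >= 5 && tv && cov_ok) "parametric"
                    else if (n_A >= 3 && tr) "TAU_U" else "NAP"
        expect_identical(s1$method, expected)
        expect_true(nzchar(s1$rule))
      }
})

test_that("interpretation bands follow the threshold tables", {
  expect_identical(interpret(list(method = "parametric", r = 0.95))$band, "large")
  expect_identical(interpret(list(method = "parametric", r = 0.91))$band, "large")
  expect_identical(interpret(list(method = "NAP", estimate = 0.5))$band, "weak")
  expect_identical(interpret(list(method = "NAP", estimate = 0.80))$band, "medium")
  expect_identical(interpret(list(method = "TAU_U", estimate = -0.7))$band, "large")
  expect_error(interpret(list(method = "XYZ", estimate = 1)), "no band table")
})

test_that("a boundary estimate falls in the higher band at every cut point", {
  tabs <- default_band_tables()
  for (m in names(tabs)) {
    lo <- interpret(list(method = m, estimate = tabs[[m]]$cuts[1]), tabs)
    hi <- interpret(list(method = m, estimate = tabs[[m]]$cuts[2]), tabs)
    expect_identical(lo$band, "medium")
    expect_identical(hi$band, "large")
    eps <- diff(tabs[[m]]$scale) * 1e-9
    expect_identical(
      interpret(list(method = m, estimate = tabs[[m]]$cuts[1] - eps), tabs)$band,
      "weak")
  }
})

test_that("gauge position rescales the estimate to [0, 1]", {
  expect_equal(interpret(list(method = "NAP", estimate = 0.25))$gauge_position, 0.25)
  expect_equal(interpret(list(method = "PND", estimate = 80))$gauge_position, 0.8)
  expect_equal(interpret(list(method = "TAU_AB", estimate = 0))$gauge_position, 0.5)
})

test_that("milestone scan finds the first qualifying global session", {
  zeros <- make_ab_series(rep(0, 3), rep(0, 10))
  expect_identical(first_session_meeting(zeros, "positive"), NA_integer_)
  s <- make_ab_series(rep(0, 5), c(0, 0, 3, 5, 10, 40, 41, 43, 50, 50))
  expect_identical(first_session_meeting(s, "positive"), 8L)
  expect_identical(first_session_meeting(s, "fraction", 0.8), 11L)
  expect_identical(first_session_meeting(s, "max"), 14L)
})

test_that("mastery detection returns the last session of the first qualifying run", {
  sc <- c(rep(0, 5), c(10, 20, 39, 40, 41, 30, 40, 41, 43, 50))
  s <- make_ab_series(sc[1:5], sc[6:15])
  # runs of >= 40: positions 9-10 (len 2) then 12-15; first run of 3 ends at 14
  expect_identical(detect_mastery(s, 0.8, 3), 14L)
  expect_identical(detect_mastery(make_ab_series(rep(0, 3), rep(0, 5)), 0.8, 3),
                   NA_integer_)
  # consecutive = 1 degenerates to first_session_meeting
  set.seed(61)
  for (i in 1:15) {
    rs <- random_series()
    expect_identical(detect_mastery(rs, 0.8, 1L),
                     first_session_meeting(rs, "fraction", 0.8))
  }
})

test_that("descriptive phase trend equals the OLS slope", {
  s <- make_ab_series(rep(0, 2), c(5, 5), G = c(10, 20, 30))
  expect_equal(phase_trend(s, "G"), 10)
  expect_equal(phase_trend(s, "B"), 0)
  s2 <- make_ab_series(rep(0, 2), c(1, 1), G = c(5, 9, 8, 14))
  expect_equal(phase_trend(s2, "G"), 2.6)  # closed-form OLS: Sxy = 13, Sxx = 5
  expect_error(phase_trend(make_ab_series(0, c(1, 2), G = 5), "G"),
               "at least 2")
})

test_that("reports headline the selected method and downgrade gracefully", {
  s <- make_ab_series(rep(0, 5), pmin(50, cumsum(rpois(30, 3))))
  rep1 <- build_report(s, list(method = "auto"))
  expect_identical(rep1$selection$method, "parametric")
  expect_identical(rep1$band$method, "parametric")
  expect_true(all(c("NAP", "PND", "PEM", "TAU_AB", "TAU_U", "parametric")
                  %in% names(rep1$effects)))
  expect_true(any(grepl("anti-conservative", rep1$caveats)))

  short <- make_ab_series(0, c(5, 8, 7))
  rep2 <- build_report(short, list(method = "auto"))
  expect_identical(rep2$selection$method, "NAP")
  expect_true(any(grepl("fallback", rep2$caveats)))

  rep3 <- build_report(s, list(method = "nap"))
  expect_identical(rep3$selection$rule, "user_requested")
  expect_error(build_report(make_ab_series(c(0, 51), c(1, 2)), list()),
               "invalid")
})

test_that("reports are deterministic for identical input", {
  s <- make_ab_series(rep(0, 5), pmin(50, (1:30) + 3))
  r1 <- build_report(s, list(method = "auto"))
  r2 <- build_report(s, list(method = "auto"))
  expect_identical(r1, r2)
})
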