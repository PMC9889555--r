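test_that("baseline trend is the closed-form OLS line", {
  flat <- fit_baseline_trend(1:5, rep(0, 5))
  expect_equal(c(flat$b0, flat$b1), c(0, 0))
  exact <- fit_baseline_trend(1:3, c(1, 2, 3))
  expect_equal(c(exact$b0, exact$b1), c(0, 1))
  # Sxy = 1, Sxx = 2
  ols <- fit_baseline_trend(1:3, c(2, 1, 3))
  expect_equal(c(ols$b0, ols$b1), c(1, 0.5))
  # independent route: stats::lm on the same points
  fit <- stats::lm(y ~ t, data.frame(t = 1:4, y = c(3, 1, 4, 4)))
  ours <- fit_baseline_trend(1:4, c(3, 1, 4, 4))
  expect_equal(c(ours$b0, ours$b1), unname(coef(fit)))
  expect_error(fit_baseline_trend(1, 0), "at least 2")
  expect_error(fit_baseline_trend(c(1, 1), c(0, 0)), "strictly increasing")
})

test_that("detrending subtracts the extrapolated baseline line everywhere", {
  s <- make_ab_series(c(1, 2, 3), c(10, 11))
  d <- detrend(s, fit_baseline_trend(1:3, c(1, 2, 3)))
  expect_equal(d$d, c(0, 0, 0, 6, 6))
  # zero trend: de-trend scores equal raw scores
  zs <- make_ab_series(rep(0, 5), c(4, 9, 12, 20, 33))
  dz <- detrend(zs, fit_baseline_trend(1:5, rep(0, 5)))
  expect_equal(dz$d, dz$y)
  # baseline residuals always sum to zero (OLS property)
  set.seed(31)
  for (i in 1:20) {
    rs <- random_series()
    a <- phase_slice(rs, "A")
    dd <- detrend(rs, fit_baseline_trend(a$t, a$y))
    expect_equal(sum(dd$d[dd$P == 0]), 0, tolerance = 1e-9)
  }
})

test_that("effect model recovers exact separation and degenerate cases", {
  d <- detrend(make_ab_series(c(0, 0, 0), c(6, 6, 6)),
               structure(list(b0 = 0, b1 = 0, n_A = 3), class = "baseline_trend"))
  res <- fit_effect_model(d)
  expect_equal(res$c1, 6)
  expect_equal(res$c2, 0)
  expect_equal(res$r_squared, 1)
  expect_true(res$exact_fit)
  expect_lt(res$p, 1e-300)

  const <- detrend(make_ab_series(rep(3, 4), rep(3, 5)),
                   structure(list(b0 = 3, b1 = 0, n_A = 4), class = "baseline_trend"))
  res0 <- fit_effect_model(const)
  expect_equal(res0$r_squared, 0)
  expect_equal(res0$F, 0)
})

test_that("effect model agrees with stats::lm on a noisy series", {
  set.seed(99)
  s <- make_ab_series(c(0, 1, 0, 2, 1), pmin(50, rpois(30, 20)))
  res <- analyze_parametric(s)
  a <- phase_slice(s, "A")
  tr <- fit_baseline_trend(a$t, a$y)
  dd <- detrend(s, tr)
  fit <- stats::lm(d ~ P + I(P * (t - 6)), data = dd)
  sm <- summary(fit)
  expect_equal(unname(coef(fit)), c(res$c0, res$c1, res$c2))
  expect_equal(res$r_squared, sm$r.squared)
  expect_equal(res$F, unname(sm$fstatistic[1]))
  expect_equal(res$df2, 32L)
})

test_that("F satisfies the F-R^2 identity and is centering-invariant", {
  set.seed(42)
  for (i in 1:25) {
    s <- make_ab_series(sample(0:10, sample(3:6, 1), TRUE),
                        sample(0:50, sample(5:20, 1), TRUE))
    res <- analyze_parametric(s)
    n <- res$n_A + res$n_B
    if (!res$exact_fit) {
      expect_equal(res$F, (res$r_squared / 2) / ((1 - res$r_squared) / (n - 3)))
      # recentre the interaction: fit statistics must not move
      dd <- detrend(s, res$trend)
      tc <- mean(dd$t[dd$P == 1])
      fit <- stats::lm(d ~ P + I(P * (t - tc)), data = dd)
      sm <- summary(fit)
      expect_equal(sm$r.squared, res$r_squared, tolerance = 1e-10)
      expect_equal(unname(sm$fstatistic[1]), res$F, tolerance = 1e-8)
      expect_false(isTRUE(all.equal(unname(coef(fit)[2]), res$c1)) &&
                     res$c2 != 0)  # c1 moves when the slope effect is nonzero
    }
  }
})

test_that("R^2 = 0.83 at n = 35 gives F = 78.12 under the identity", {
  expect_equal((0.83 / 2) / ((1 - 0.83) / 32), 78.11765, tolerance = 1e-6)
})

test_that("covariance assumption flags the direction of mean separation", {
  up <- detrend(make_ab_series(c(0, 0, 0), c(6, 6, 6)),
                structure(list(b0 = 0, b1 = 0, n_A = 3), class = "baseline_trend"))
  expect_true(check_covariance_assumption(up)$ok)
  expect_gt(check_covariance_assumption(up)$value, 0)

  const <- detrend(make_ab_series(c(2, 2), c(2, 2)),
                   structure(list(b0 = 2, b1 = 0, n_A = 2), class = "baseline_trend"))
  chk <- check_covariance_assumption(const)
  expect_equal(chk$value, 0)
  expect_false(chk$ok)

  down <- detrend(make_ab_series(c(6, 6), c(0, 0)),
                  structure(list(b0 = 6, b1 = 0, n_A = 2), class = "baseline_trend"))
  expect_false(check_covariance_assumption(down)$ok)
  expect_true(check_covariance_assumption(down, "decrease")$ok)
})

test_that("full parametric pipeline carries trend, assumption flag and phases", {
  s <- make_ab_series(rep(0, 5), rep(c(10, 12), 15))
  res <- analyze_parametric(s)
  expect_equal(res$trend$b1, 0)
  expect_true(res$cov_assumption$ok)
  expect_equal(res$phases, c("A", "B"))
  expect_equal(sign(res$r), sign(res$c1))
  # assumption failure does not abort
  sdown <- make_ab_series(c(20, 21, 19, 20, 20), rep(c(1, 2), 15))
  resd <- analyze_parametric(sdown)
  expect_false(resd$cov_assumption$ok)
  expect_s3_class(resd, "parametric_result")
  expect_lt(resd$r, 0)
})

test_that("known trend bypasses baseline estimation", {
  s <- make_ab_series(c(0, 1, 2, 1, 0), c(8, 9, 10, 12, 11))
  res <- analyze_parametric(s, known_trend = list(b0 = 0, b1 = 0))
  expect_equal(res$trend$b0, 0)
  expect_equal(res$trend$b1, 0)
  d <- detrend(s, res$trend)
  expect_equal(d$d, d$y)
})
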