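test_that("frequency recording counts instants and intervals once each", {
  expect_identical(summarize_frequency(event_log(600)), 0L)
  expect_identical(summarize_frequency(event_log(600, onsets = (1:7) * 10)), 7L)
  lg <- event_log(600, onsets = c(5, 15, 25, 100, 300),
                  offsets = c(NA, NA, NA, 150, 360))
  expect_identical(summarize_frequency(lg), 5L)
})

test_that("duration recording sums interval lengths with union semantics", {
  expect_equal(summarize_duration(event_log(600)), 0)
  lg <- event_log(600, onsets = c(10, 100), offsets = c(40, 130))
  expect_equal(summarize_duration(lg), 60)
  overlap <- event_log(600, onsets = c(0, 10), offsets = c(20, 30))
  expect_equal(summarize_duration(overlap), 30)
  # instants contribute nothing
  mixed <- event_log(600, onsets = c(10, 50), offsets = c(40, NA))
  expect_equal(summarize_duration(mixed), 30)
})

test_that("duration is order-invariant and invariant under interval splitting", {
  set.seed(77)
  for (i in 1:25) {
    k <- sample(1:6, 1)
    on <- sort(runif(k, 0, 500))
    off <- pmin(on + runif(k, 0, 80), 600)
    base <- summarize_duration(event_log(600, on, off))
    perm <- sample(k)
    expect_equal(summarize_duration(event_log(600, on[perm], off[perm])), base)
    # split each interval at its midpoint
    mid <- (on + off) / 2
    split_lg <- event_log(600, c(on, mid), c(mid, off))
    expect_equal(summarize_duration(split_lg), base)
  }
})

test_that("interval recording modes match hand-computed bin occupancy", {
  # behavior covering the whole session
  full <- event_log(600, onsets = 0, offsets = 600)
  expect_equal(summarize_interval(full, 60, "partial"), 1)
  expect_equal(summarize_interval(full, 60, "whole"), 1)
  expect_equal(summarize_interval(full, 60, "momentary"), 1)
  # empty log
  empty <- event_log(600)
  for (m in c("partial", "whole", "momentary"))
    expect_equal(summarize_interval(empty, 60, m), 0)
  # two instants in 10 bins of 60 s
  inst <- event_log(600, onsets = c(130, 310))
  expect_equal(summarize_interval(inst, 60, "partial"), 0.2)
  expect_equal(summarize_interval(inst, 60, "whole"), 0)
  # interval (50, 130) touches bins 1-3, fully covers only bin 2 (60-120),
  # and covers the endpoints of bins 1 (60) and 2 (120)
  iv <- event_log(600, onsets = 50, offsets = 130)
  expect_equal(summarize_interval(iv, 60, "partial"), 0.3)
  expect_equal(summarize_interval(iv, 60, "whole"), 0.1)
  expect_equal(summarize_interval(iv, 60, "momentary"), 0.2)
  expect_error(summarize_interval(inst, 0), "> 0")
})

test_that("whole-interval proportion never exceeds partial-interval proportion", {
  set.seed(88)
  for (i in 1:30) {
    k <- sample(0:5, 1)
    on <- if (k) sort(runif(k, 0, 550)) else numeric()
    off <- if (k) pmin(on + runif(k, 0, 100), 600) else NA_real_
    lg <- event_log(600, on, off)
    len <- sample(c(30, 60, 90, 77), 1)
    expect_lte(summarize_interval(lg, len, "whole"),
               summarize_interval(lg, len, "partial"))
  }
})

test_that("responses validate against each item variant", {
  rng <- item("range", "intensity", min = 0, max = 50)
  expect_identical(validate_response(rng, 50), 50L)
  expect_error(validate_response(rng, 51), class = "sceda_validation_error")
  ch <- item("choice", "prompt", options = c("a", "b"))
  expect_identical(validate_response(ch, "b"), "b")
  expect_error(validate_response(ch, "c"), class = "sceda_validation_error")
  fq <- item("four_quadrant", "mood", axes = c("x", "y"))
  expect_equal(validate_response(fq, c(0.5, -0.5)), c(0.5, -0.5))
  expect_error(validate_response(fq, c(2, 0)), class = "sceda_validation_error")
  num <- item("number", "count")
  expect_error(validate_response(num, "x"), class = "sceda_validation_error")
  expect_identical(validate_response(item("text", "notes"), 12), "12")
})

test_that("measure JSON export/import is a field-for-field round trip", {
  m1 <- measure("freq", list(item("direct_observation", "mand",
                                  recording = "frequency")))
  expect_equal(import_measure(export_measure(m1)), m1)

  m6 <- all_items_measure()
  expect_equal(import_measure(export_measure(m6)), m6)

  tmp <- withr::local_tempfile(fileext = ".json")
  export_measure(m6, tmp)
  expect_equal(import_measure(tmp), m6)

  expect_error(import_measure('{"schema_version":"1.0","name":"x","version":"1",
    "items":[{"prompt":"p"}]}'), "missing field: kind")
  expect_error(import_measure('{"name":"x"}'), "missing field")
})

test_that("item and measure constructors enforce their invariants", {
  expect_error(item("range", "x", min = 5, max = 5), "min < max")
  expect_error(item("choice", "x", options = "only"), "at least 2")
  expect_error(item("direct_observation", "x", recording = "interval"),
               "interval_length")
  expect_error(measure("m", list()), "non-empty")
  it <- item("number", "same prompt")
  expect_error(measure("m", list(it, it)), "unique")
})
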