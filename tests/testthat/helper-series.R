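# shared fixtures built in code

make_ab_series <- function(A, B, G = integer(), case_id = "toy",
                           max_score = 50L, ...) {
  case_series(case_id,
              phase = rep(c("A", "B", "G"), c(length(A), length(B), length(G))),
              score = c(A, B, G), max_score = max_score, ...)
}

# random valid series under a caller-set seed
random_series <- function(case_id = "rand", max_score = 50L) {
  n_A <- sample(2:8, 1); n_B <- sample(5:15, 1)
  n_G <- sample(0:5, 1)
  make_ab_series(sample(0:max_score, n_A, replace = TRUE),
                 sample(0:max_score, n_B, replace = TRUE),
                 if (n_G) sample(0:max_score, n_G, replace = TRUE) else integer(),
                 case_id = case_id, max_score = max_score,
                 context = "clinic", observer = "obs",
                 date = "2022-01-01")
}

all_items_measure <- function() {
  measure("full", version = "2.1", items = list(
    item("direct_observation", "mand emitted?", recording = "frequency"),
    item("direct_observation", "on-task time", recording = "interval",
         interval_length = 30, interval_mode = "whole"),
    item("choice", "prompt level", options = c("vocal", "physical", "none"),
         multiple_allowed = TRUE),
    item("number", "session temperature"),
    item("range", "intensity", min = 0, max = 10),
    item("four_quadrant", "mood/energy", axes = c("valence", "arousal"),
         axis_min = c(-5, -5), axis_max = c(5, 5)),
    item("text", "notes")
  ))
}
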