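# Preprocessing: encoding, discretization, aggregation, scaling, assembly.

test_that("one-hot encoding is exhaustive and exclusive", {
  m <- one_hot_encode(c("female", "male", "female"),
                      c("female", "male", "non_binary"))
  expect_equal(m[1, ], c(female = 1, male = 0, non_binary = 0))
  expect_equal(unname(rowSums(m)), rep(1, 3))
  # degenerate single-row input keeps matrix shape
  m1 <- one_hot_encode("male", c("female", "male"))
  expect_equal(dim(m1), c(1, 2))
  expect_error(one_hot_encode("other", c("female", "male")),
               "other")
})

test_that("quantile discretization reproduces the standard age bands", {
  breaks <- c(-Inf, 19, 22, 25, 32, Inf)
  labels <- c("16-19", "20-22", "23-25", "26-32", "33+")
  qd <- quantile_discretize(c(21, 40, 19, 26), breaks = breaks,
                            labels = labels)
  pick <- function(i) labels[which(qd$indicators[i, ] == 1)]
  expect_equal(pick(1), "20-22")
  expect_equal(pick(2), "33+")
  expect_equal(pick(3), "16-19")
  expect_equal(pick(4), "26-32")
})

test_that("median split bins (1,2,3,4) into {1,2} and {3,4}", {
  qd <- quantile_discretize(c(1, 2, 3, 4), n_bins = 2)
  expect_equal(ncol(qd$indicators), 2)
  expect_equal(unname(qd$indicators[, 1]), c(1, 1, 0, 0))
  expect_equal(unname(qd$indicators[, 2]), c(0, 0, 1, 1))
})

test_that("an all-identical column collapses to one bin with a warning", {
  expect_warning(qd <- quantile_discretize(rep(5, 4), n_bins = 3),
                 "single distinct value")
  expect_equal(ncol(qd$indicators), 1)
  expect_equal(unname(qd$indicators[, 1]), rep(1, 4))
})

test_that("interaction aggregation averages, counts, and fills", {
  ev <- data.frame(
    participant_id = c("A", "A", "B"),
    event_kind = c("exercise_feedback", "exercise_feedback",
                   "ema_response"),
    usefulness = c(3, 4, NA),
    ema_value = c(NA, NA, 7))
  spec <- feature_spec("usefulness_mean", "interaction_aggregate",
                       aggregation = "mean",
                       event_kind = "exercise_feedback",
                       field = "usefulness", fill = 0)
  expect_equal(aggregate_interactions(ev, spec, c("A", "B", "C")),
               c(3.5, 0, 0))
  cnt <- feature_spec("n_ema", "interaction_aggregate",
                      aggregation = "count", event_kind = "ema_response")
  expect_equal(aggregate_interactions(ev, cnt, c("A", "B")), c(0, 1))
  expect_error(feature_spec("x", "interaction_aggregate",
                            aggregation = "mode", event_kind = "e"),
               "unknown aggregation")
})

test_that("a full response month yields the scheduled EMA response count", {
  cfg <- cohort_config(n_participants = 1, profile_sizes = 1,
                       trial_days = 30, prompts_per_day = 2,
                       response_rate = 1, seed = 10)
  co <- generate_cohort(cfg)
  ev <- simulate_sessions(co, config = cfg, seed = 11)
  spec <- feature_spec("n_resp", "interaction_aggregate",
                       aggregation = "count", event_kind = "ema_response")
  expect_equal(aggregate_interactions(ev, spec, co$participant_id), 60)
})

test_that("min-max scaling maps to [0,1] with fixed conventions", {
  expect_equal(min_max_scale(c(2, 4, 6))$values, c(0, 0.5, 1))
  expect_equal(min_max_scale(c(5, 5, 5))$values, c(0, 0, 0))
  expect_equal(min_max_scale(c(0, 1))$values, c(0, 1))
})

test_that("the default schema yields an 81 x 130 table within [0,1]", {
  cfg <- cohort_config()
  co <- generate_cohort(cfg)
  ev <- simulate_sessions(co, config = cfg, seed = 2)
  ft <- build_feature_table(co, ev)
  expect_equal(dim(ft$values), c(81, 130))
  expect_true(all(ft$values >= 0 & ft$values <= 1))
  expect_false(anyNA(ft$values))
  expect_equal(length(ft$weights), 130)
  expect_true(all(ft$weights > 0))
  # age contributes 5 indicator columns, gender 3
  expect_equal(sum(ft$column_feature == "age"), 5)
  expect_equal(sum(ft$column_feature == "gender"), 3)
  # one-hot/discretized blocks have unit row sums
  for (feat in c("gender", "occupation", "age")) {
    block <- ft$values[, ft$column_feature == feat, drop = FALSE]
    expect_equal(unname(rowSums(block)), rep(1, nrow(block)), info = feat)
  }
})

test_that("zero-weight features are dropped (expert feature selection)", {
  cfg <- small_config(seed = 3)
  co <- generate_cohort(cfg)
  schema <- default_feature_schema()
  for (i in seq_along(schema)) {
    if (schema[[i]]$name != "insomnia") schema[[i]]$weight <- 0
  }
  ft <- build_feature_table(co, NULL, schema)
  expect_equal(ncol(ft$values), 1)
  expect_equal(colnames(ft$values), "insomnia")
})

test_that("events referencing unknown participants are a consistency error", {
  cfg <- small_config(seed = 3)
  co <- generate_cohort(cfg)
  ev <- simulate_sessions(co, config = cfg, seed = 4)
  ev$participant_id[1] <- "P999"
  expect_error(build_feature_table(co, ev), "absent from the baseline")
})

test_that("feature table construction is deterministic and order-stable", {
  cfg <- small_config(seed = 5)
  co <- generate_cohort(cfg)
  ev <- simulate_sessions(co, config = cfg, seed = 6)
  ft1 <- build_feature_table(co, ev)
  ft2 <- build_feature_table(co, ev)
  expect_identical(colnames(ft1$values), colnames(ft2$values))
  expect_identical(ft1$values, ft2$values)
})

test_that("pipeline output satisfies table invariants on random cohorts", {
  for (s in 1:5) {
    cfg <- cohort_config(n_participants = 20,
                         profile_sizes = c(5, 5, 5, 5), trial_days = 3,
                         noise_sd = stats::runif(1, 0, 1.5), seed = s)
    co <- generate_cohort(cfg)
    ev <- simulate_sessions(co, config = cfg, seed = s + 50)
    ft <- build_feature_table(co, ev)
    expect_true(all(ft$values >= 0 & ft$values <= 1))
    expect_false(anyNA(ft$values))
    expect_true(all(ft$weights >= 0))
    expect_equal(nrow(ft$values), 20)
  }
})

test_that("feature tables round-trip through CSV plus sidecar", {
  cfg <- small_config(seed = 7)
  co <- generate_cohort(cfg)
  ev <- simulate_sessions(co, config = cfg, seed = 8)
  ft <- build_feature_table(co, ev)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(back$values, ft$values, tolerance = 1e-12)
  expect_equal(back$weights, ft$weights)
  expect_equal(back$column_feature, ft$column_feature)
})

test_that("a test participant embeds consistently into the fitted space", {
  cfg <- small_config(seed = 9)
  co <- generate_cohort(cfg)
  ev <- simulate_sessions(co, config = cfg, seed = 10)
  ft <- build_feature_table(co, ev)
  # embedding a training row with its own events reproduces its row
  i <- 3
  x <- encode_participant(ft, co[i, , drop = FALSE],
                          ev[ev$participant_id == co$participant_id[i], ])
  expect_equal(unname(x), unname(ft$values[i, ]), tolerance = 1e-12)
})
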