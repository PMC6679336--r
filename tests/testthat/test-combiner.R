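test_that("the literal rule table matches the published clauses", {
  rules <- default_rules()
  expect_equal(apply_rules(rules, "walking", "low"), "walking")
  expect_equal(apply_rules(rules, "walking", "medium"), "walking")
  expect_equal(apply_rules(rules, "walking", "high"), "walking")
  expect_equal(apply_rules(rules, "standing", "high"), "walking")
  expect_equal(apply_rules(rules, "standing", "medium"), "standing")
  expect_equal(apply_rules(rules, "standing", "low"), "standing")
  expect_equal(apply_rules(rules, "lying", "medium"), "lying")
  # documented policies for the two ambiguous cells
  expect_equal(apply_rules(rules, "lying", "low"), "lying")
  expect_equal(apply_rules(rules, "lying", "high"), "lying")  # KNN passthrough
  expect_equal(apply_rules(default_rules(conflict = "standing"),
                           "lying", "low"), "standing")
})

test_that("apply_rules enumerated over the grid matches the table and is pure", {
  rules <- default_rules()
  grid <- expand.grid(k = behaviour_labels(), l = activity_levels(),
                      stringsAsFactors = FALSE)
  out1 <- apply_rules(rules, grid$k, grid$l)
  out2 <- mapply(function(k, l) apply_rules(rules, k, l), grid$k, grid$l)
  expect_equal(out1, unname(out2))
  expect_true(all(out1 %in% behaviour_labels()))
  # fixed-label fallback
  fixed <- flockdrift:::new_rule_table(grid$k, grid$l,
                                       rep(NA_character_, 9),
                                       "standing", "literal")
  expect_equal(unique(apply_rules(fixed, grid$k, grid$l)), "standing")
})

test_that("learn_rules recovers a generating table and applies majority votes", {
  grid <- expand.grid(k = behaviour_labels(), l = activity_levels(),
                      stringsAsFactors = FALSE)
  set.seed(21)
  for (rep in 1:5) {
    truth_map <- sample(behaviour_labels(), 9, replace = TRUE)
    idx <- sample(9, 600, replace = TRUE)
    learned <- learn_rules(grid$k[idx], grid$l[idx], truth_map[idx])
    expect_equal(apply_rules(learned, grid$k, grid$l), truth_map)
  }
  # constant truth gives a constant table
  const <- learn_rules(grid$k[rep(1:9, 3)], grid$l[rep(1:9, 3)],
                       rep("standing", 27))
  expect_equal(unique(apply_rules(const, grid$k, grid$l)), "standing")
  # per-cell majority: 3 walking vs 2 standing
  maj <- learn_rules(rep("lying", 5), rep("high", 5),
                     c(rep("walking", 3), rep("standing", 2)))
  expect_equal(apply_rules(maj, "lying", "high"), "walking")
  # min_support sends sparse cells to the fallback policy
  sparse <- learn_rules("lying", "high", "walking", min_support = 2,
                        fallback = "knn")
  expect_equal(apply_rules(sparse, "lying", "high"), "lying")
  literal <- learn_rules("lying", "high", "walking", min_support = 2,
                         fallback = "literal")
  expect_equal(apply_rules(literal, "standing", "high"), "walking")
})

test_that("rule tables round-trip through their text format", {
  rules <- learn_rules(rep(c("walking", "standing"), 5),
                       rep(c("high", "low"), 5),
                       rep("walking", 10), fallback = "literal")
  path <- withr::local_tempfile(fileext = ".csv")
  write_rules(rules, path)
  back <- read_rules(path)
  expect_equal(back$mapping, rules$mapping)
  expect_equal(back$fallback, "literal")
  expect_equal(back$provenance, "learned")
})

test_that("run_combined emits one complete record per window", {
  cfg <- sim_config(duration_s = 120, seed = 31, start = "walking")
  log <- simulate_bouts(cfg)
  stream <- synthesise_imu(log, drift_schedule(0, list(dataset1_params())),
                           cfg)
  wins <- segment_windows(stream)
  ft <- feature_table(wins)
  truth <- align_labels(wins, log)
  # train on a longer stream so all classes are present
  cfg2 <- sim_config(duration_s = 1200, seed = 32)
  log2 <- simulate_bouts(cfg2)
  stream2 <- synthesise_imu(log2, drift_schedule(0, list(dataset1_params())),
                            cfg2)
  wins2 <- segment_windows(stream2)
  model <- fit_prototypes(feature_table(wins2), align_labels(wins2, log2),
                          seed = 31)
  res <- run_combined(stream, model, init_centroids(priors = c(12, 3, 0.5)),
                      default_rules())
  expect_equal(nrow(res$records), length(wins))
  expect_true(all(res$records$knn_label %in% behaviour_labels()))
  expect_true(all(res$records$level %in% activity_levels()))
  expect_true(all(res$records$combined %in% behaviour_labels()))
  expect_equal(res$records$timestamp,
               vapply(wins, function(w) w$start_t, numeric(1)))
  # deterministic rerun
  res2 <- run_combined(stream, model, init_centroids(priors = c(12, 3, 0.5)),
                       default_rules())
  expect_identical(res2$records, res$records)
  # fused output follows the rule table row by row
  expect_equal(res$records$combined,
               apply_rules(default_rules(), res$records$knn_label,
                           res$records$level))
})

test_that("a KNN stuck on standing is promoted to walking at high activity", {
  # model whose prototypes are all standing-labelled
  x <- matrix(rep(c(5, 1), each = 10 * 20 / 2), 10, 20)
  model <- suppressWarnings(
    structure(list(prototypes = quantise(x, fit_scaling(x)),
                   labels = rep("standing", 10), capacity = 128,
                   scaling = fit_scaling(x), metric = "L1", seed = 1),
              class = "pme_model"))
  stream <- make_stream(40, az = function(t) 1 + 3 * sin(4 * pi * t))
  state <- init_centroids(priors = c(9, 3, 0.5))
  res <- run_combined(stream, model, state, default_rules())
  expect_true(all(res$records$knn_label == "standing"))
  expect_true(all(res$records$level == "high"))
  expect_true(all(res$records$combined == "walking"))
})
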