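# End-to-end concept-drift experiment: train the offline prototype model
# and the decision rules under the first activity regime, then evaluate
# frozen-KNN-only, adaptive-k-means-only and the combined classifier on a
# drifted stream.

#' Run the concept-drift benchmark
#'
#' Simulates a training stream under the [dataset1_params()] regime and a
#' drifted evaluation stream under [dataset2_params()]; fits the
#' capacity-limited prototype model and learns the decision-rule table on
#' the training regime (under-supported cells fall back to the published
#' literal table); then scores three classifiers on the drifted stream:
#' the frozen nearest-prototype classifier alone, the adaptive online
#' k-means alone (levels read as behaviours by activity rank), and the
#' combined rule-fused classifier, with the online learner continuing
#' from its training-regime centroid state (a deployed system carries its
#' state across the drift). The frozen classifier is also scored on its
#' own training regime, to expose the drift-induced drop.
#'
#' The default capacity keeps roughly 3% of the training windows,
#' mirroring the aggressive compression of the emulated on-chip store
#' (128 prototypes for 8455 training windows in the original deployment);
#' the compression is what gives the prototype classifier its
#' characteristic, level-structured errors, which is precisely what the
#' learned decision rules can correct.
#'
#' @param seed Integer seed; all three streams derive their seeds from it.
#' @param train_duration_s,test_duration_s Simulated durations of the
#'   training and drifted evaluation streams, seconds.
#' @param capacity Prototype store capacity.
#' @param min_support Minimum per-cell support for rule learning; cells
#'   below it resolve through the literal rule table.
#' @param params_a,params_b Behaviour parameter sets of the two regimes.
#' @return List with `accuracy` (named vector: `knn_train_regime`,
#'   `knn_drifted`, `kmeans_drifted`, `combined_drifted`; macro overall
#'   accuracy in percent), the fitted `model` and `rules`, and the
#'   per-method drifted-set `metrics` tables.
#' @export
drift_experiment <- function(seed, train_duration_s = 7200,
                             test_duration_s = 10800, capacity = 24,
                             min_support = 5,
                             params_a = dataset1_params(),
                             params_b = dataset2_params()) {
  seed <- as.integer(seed)
  make_set <- function(s, duration, params) {
    cfg <- sim_config(duration_s = duration, seed = s)
    log <- simulate_bouts(cfg)
    stream <- synthesise_imu(log, drift_schedule(0, list(params)), cfg)
    windows <- segment_windows(stream)
    list(features = feature_table(windows),
         truth = align_labels(windows, log))
  }
  train <- make_set(seed, train_duration_s, params_a)
  test <- make_set(seed + 99991L, test_duration_s, params_b)

  model <- fit_prototypes(train$features, train$truth, capacity = capacity,
                          seed = seed)
  knn_train <- knn_predict(model, train$features)
  km_state <- init_centroids(points = train$features$mean_amag, seed = seed)
  res_train <- run_stream(km_state, train$features$mean_amag,
                          history = FALSE)
  rules <- learn_rules(knn_train, res_train$levels, train$truth,
                       min_support = min_support, fallback = "literal")

  # deployment: the frozen prototype model meets the drifted stream, and
  # the online learner restarts from the training-regime centres as priors
  # with unit mass, so it adapts quickly to the drifted distribution
  # instead of being pinned by its accumulated training-stream counts
  knn_test <- knn_predict(model, test$features)
  km_deploy <- init_centroids(priors = res_train$state$centres)
  res_test <- run_stream(km_deploy, test$features$mean_amag)
  combined <- apply_rules(rules, knn_test, res_test$levels)

  metrics <- list(
    knn_train_regime = metrics_table(train$truth, knn_train),
    knn_drifted = metrics_table(test$truth, knn_test),
    kmeans_drifted = metrics_table(test$truth,
                                   level_to_behaviour(res_test$levels)),
    combined_drifted = metrics_table(test$truth, combined))
  accuracy <- vapply(metrics, function(m) macro_average(m)[["accuracy"]],
                     numeric(1))
  list(accuracy = accuracy, model = model, rules = rules,
       metrics = metrics, centroid_state = res_test$state)
}
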