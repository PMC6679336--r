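test_that("simulate_bouts covers the duration and is seed-reproducible", {
  cfg <- sim_config(duration_s = 3000, seed = 41)
  log <- simulate_bouts(cfg)
  expect_equal(sum(log$end_t - log$start_t), 3000)
  expect_equal(log$start_t[1], 0)
  expect_equal(log$end_t[nrow(log)], 3000)
  expect_identical(simulate_bouts(cfg), log)
  cfg2 <- cfg
  cfg2$seed <- 42L
  expect_false(identical(simulate_bouts(cfg2), log))
  # absorbing transition weights give a single full-length bout
  single <- sim_config(duration_s = 500, seed = 1, start = "lying",
                       transitions = matrix(0, 3, 3,
                         dimnames = list(behaviour_labels(),
                                         behaviour_labels())))
  one <- simulate_bouts(single)
  expect_equal(nrow(one), 1)
  expect_equal(one$label, "lying")
  expect_equal(one$end_t - one$start_t, 500)
})

test_that("gamma calibration matches its closed-form oracle and Monte Carlo", {
  for (tg in list(c(5.74, 6.39), c(1.83, 1.57), c(0.60, 1.45),
                  c(0.20, 0.80))) {
    g <- calibrate_gamma(tg[1], tg[2])
    expect_equal(expected_discrete_mean(g$shape, g$scale), tg[1],
                 tolerance = 1e-6)
    set.seed(17)
    u <- rgamma(4e5, shape = g$shape, scale = g$scale)
    z <- pmin(pmax(floor(u + 0.5), 0), 20)
    expect_equal(mean(z), tg[1], tolerance = 0.03 * tg[1] + 0.01)
  }
})

test_that("a near-zero-activity regime yields gravity-only MeanAMag", {
  still <- list(lying = behaviour_params(0.011, 0.01, 0.5, 0, 0, 0),
                standing = behaviour_params(0.011, 0.01, 0.5, 0, 0, 0),
                walking = behaviour_params(0.011, 0.01, 0.5, 0, 0, 0))
  cfg <- sim_config(duration_s = 300, seed = 5, start = "lying",
                    transitions = matrix(0, 3, 3,
                      dimnames = list(behaviour_labels(),
                                      behaviour_labels())))
  stream <- synthesise_imu(simulate_bouts(cfg), drift_schedule(0, list(still)),
                           cfg)
  ft <- feature_table(segment_windows(stream))
  expect_true(all(ft$mean_amag_raw < 0.05))
  expect_true(all(ft$mean_amag == 0))
})

test_that("single-behaviour streams hit their calibrated targets", {
  trans0 <- matrix(0, 3, 3, dimnames = list(behaviour_labels(),
                                            behaviour_labels()))
  p <- dataset1_params()
  for (b in behaviour_labels()) {
    cfg <- sim_config(duration_s = 1800, seed = 43, start = b,
                      transitions = trans0)
    stream <- synthesise_imu(simulate_bouts(cfg), drift_schedule(0, list(p)),
                             cfg)
    z <- feature_table(segment_windows(stream))$mean_amag
    expect_equal(mean(z), p[[b]]$target_mean,
                 tolerance = 0.1 * p[[b]]$target_mean)
  }
})

test_that("a regime switch lowers the post-switch MeanAMag", {
  trans0 <- matrix(0, 3, 3, dimnames = list(behaviour_labels(),
                                            behaviour_labels()))
  cfg <- sim_config(duration_s = 3600, seed = 44, start = "walking",
                    transitions = trans0)
  sched <- drift_schedule(c(0, 1800),
                          list(dataset1_params(), dataset2_params()))
  stream <- synthesise_imu(simulate_bouts(cfg), sched, cfg)
  ft <- feature_table(segment_windows(stream))
  pre <- ft$mean_amag[ft$window_start_t < 1800]
  post <- ft$mean_amag[ft$window_start_t >= 1800]
  expect_true(mean(post) < mean(pre))
})

test_that("dataset_pair produces a drifted pair with all classes, reproducibly", {
  cfg <- sim_config(duration_s = 2400, seed = 45)
  pair <- dataset_pair(cfg)
  expect_setequal(unique(pair$train$truth), behaviour_labels())
  expect_setequal(unique(pair$test$truth), behaviour_labels())
  # activity decreases for every behaviour between the regimes
  for (b in behaviour_labels()) {
    expect_gt(mean(pair$train$features$mean_amag[pair$train$truth == b]),
              mean(pair$test$features$mean_amag[pair$test$truth == b]))
  }
  pair2 <- dataset_pair(cfg)
  expect_identical(pair2$train$features, pair$train$features)
  expect_identical(pair2$test$stream, pair$test$stream)
})

test_that("synthesised streams respect the bout labels", {
  cfg <- sim_config(duration_s = 1200, seed = 46)
  log <- simulate_bouts(cfg)
  stream <- synthesise_imu(log, drift_schedule(0, list(dataset1_params())),
                           cfg)
  expect_equal(nrow(stream), 1200 * 16)
  # windows fully inside walking bouts carry more dynamic acceleration on
  # average than windows fully inside lying bouts
  wins <- segment_windows(stream)
  truth <- align_labels(wins, log)
  z <- feature_table(wins)$mean_amag
  if (all(c("walking", "lying") %in% truth)) {
    expect_gt(mean(z[truth == "walking"]), mean(z[truth == "lying"]))
  }
  # schedule gaps are an error
  cfg_long <- cfg
  cfg_long$duration_s <- 2400
  expect_error(synthesise_imu(log, drift_schedule(0, list(dataset1_params())),
                              cfg_long),
               "not fully covered")
})
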