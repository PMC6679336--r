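# Small programmatic fixtures shared across the test files.

# a stream from per-axis generator functions of time (seconds)
make_stream <- function(duration_s, rate_hz = 16,
                        ax = function(t) 0 * t, ay = function(t) 0 * t,
                        az = function(t) 1 + 0 * t,
                        gx = function(t) 0 * t, gy = function(t) 0 * t,
                        gz = function(t) 0 * t) {
  t <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  imu_stream(data.frame(t = t, ax = ax(t), ay = ay(t), az = az(t),
                        gx = gx(t), gy = gy(t), gz = gz(t)),
             rate_hz = rate_hz)
}

# a single window with given constant axes (112 samples at 16 Hz)
make_window <- function(ax = 0, ay = 0, az = 1, gx = 0, gy = 0, gz = 0,
                        n = 112, rate_hz = 16) {
  stream <- make_stream(n / rate_hz, rate_hz,
                        ax = function(t) rep(ax, length(t))[seq_along(t)],
                        ay = function(t) rep(ay, length(t))[seq_along(t)],
                        az = function(t) rep(az, length(t))[seq_along(t)],
                        gx = function(t) rep(gx, length(t))[seq_along(t)],
                        gy = function(t) rep(gy, length(t))[seq_along(t)],
                        gz = function(t) rep(gz, length(t))[seq_along(t)])
  segment_windows(stream, window_s = n / rate_hz, cadence_s = n / rate_hz)[[1]]
}

# window whose acceleration-magnitude series is (approximately) a given
# series: put the series on the z axis with zero x/y
window_from_amag <- function(al, rate_hz = 16) {
  t <- seq(0, (length(al) - 1) / rate_hz, by = 1 / rate_hz)
  samples <- data.frame(t = t, ax = 0, ay = 0, az = al,
                        gx = 0, gy = 0, gz = 0)
  flockdrift:::new_window(samples, 0, rate_hz)
}

# random labelled byte-feature training sets for the prototype store
random_training_set <- function(n, seed) {
  set.seed(seed)
  labels <- sample(behaviour_labels(), n, replace = TRUE)
  shift <- c(walking = 4, standing = 0, lying = -4)[labels]
  x <- matrix(rnorm(n * 20), n, 20) + shift
  list(x = x, labels = labels)
}
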