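# Window-level feature extraction: the four signal variables, the 20
# summary feature characteristics, and the raw + discretised MeanAMag
# activity index.

# round-half-up; all inputs in this package are non-negative
round_half_up <- function(x) floor(x + 0.5)

#' Acceleration magnitude
#'
#' Euclidean norm of the tri-axial acceleration, in g:
#' \eqn{A_l = \sqrt{a_x^2 + a_y^2 + a_z^2}}. Vectorised over samples.
#'
#' @param ax,ay,az Per-axis acceleration in g.
#' @return Non-negative magnitude(s) in g.
#' @export
acceleration_magnitude <- function(ax, ay, az) sqrt(ax^2 + ay^2 + az^2)

#' Compute the four window variables
#'
#' For one window: acceleration magnitude, its signed first difference,
#' gyroscope magnitude, and its signed first difference. Magnitude series
#' have length n; difference series length n - 1.
#'
#' @param window An `imu_window` from [segment_windows()].
#' @return Named list `amag`, `amag_diff`, `gmag`, `gmag_diff`.
#' @export
window_variables <- function(window) {
  s <- window$samples
  if (nrow(s) < 2) stop("window must contain at least 2 samples")
  amag <- acceleration_magnitude(s$ax, s$ay, s$az)
  gmag <- sqrt(s$gx^2 + s$gy^2 + s$gz^2)
  list(amag = amag, amag_diff = diff(amag),
       gmag = gmag, gmag_diff = diff(gmag))
}

# population SD (divide by n)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# population (non-excess) Pearson kurtosis m4/m2^2; 0 for zero-variance
# series so vectors stay finite and quantisable
kurtosis_pop <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^4) / m2^2
}

feature_stat_names <- c("mean", "sd", "iqr", "kurt", "min")

summary_characteristics <- function(x) {
  c(mean = mean(x),
    sd = sd_pop(x),
    iqr = unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25)),
    kurt = kurtosis_pop(x),
    min = min(x))
}

#' Names of the 20 feature characteristics
#'
#' Variable-major, characteristic-minor order: for each of the four window
#' variables, the five statistics mean, SD (population), IQR
#' (linear-interpolation quantiles), kurtosis (population, non-excess) and
#' minimum.
#'
#' @return Character vector of length 20.
#' @export
feature_names <- function() {
  as.vector(t(outer(c("amag", "amag_diff", "gmag", "gmag_diff"),
                    feature_stat_names, paste, sep = "_")))
}

#' Extract the feature vector of one window
#'
#' Applies the five summary characteristics to the four window variables
#' (20 values), and also computes the raw and discretised MeanAMag activity
#' index. The first entry, `amag_mean`, is the source of MeanAMag.
#'
#' @param window An `imu_window`.
#' @param gravity Gravity magnitude subtracted from the mean acceleration
#'   magnitude, in g (default 1).
#' @param step Discretisation bin width in g (default 0.1, so bin 20 is
#'   about 2 g of dynamic acceleration).
#' @return A `feature_vector`: list with `values` (named numeric, length
#'   20), `mean_amag_raw` (g), `mean_amag` (integer in 0..20) and
#'   `window_start_t` (seconds).
#' @export
feature_vector <- function(window, gravity = 1, step = 0.1) {
  v <- window_variables(window)
  values <- c(summary_characteristics(v$amag),
              summary_characteristics(v$amag_diff),
              summary_characteristics(v$gmag),
              summary_characteristics(v$gmag_diff))
  names(values) <- feature_names()
  ma <- discretise_mean_amag(values[["amag_mean"]], gravity, step)
  structure(list(values = values, mean_amag_raw = ma$raw,
                 mean_amag = ma$discrete, window_start_t = window$start_t),
            class = "feature_vector")
}

discretise_mean_amag <- function(mean_al, gravity, step) {
  raw <- max(mean_al - gravity, 0)
  discrete <- min(max(round_half_up(raw / step), 0), 20)
  list(raw = raw, discrete = as.integer(discrete))
}

#' MeanAMag activity index of one window
#'
#' Mean of the per-sample acceleration magnitude, gravity-subtracted
#' (floored at 0) and discretised into integer bins of `step` g, saturating
#' at 20. The mean is taken first and the mean is discretised once.
#'
#' @inheritParams feature_vector
#' @return List with `raw` (g) and `discrete` (integer in 0..20).
#' @export
mean_amag <- function(window, gravity = 1, step = 0.1) {
  s <- window$samples
  al <- acceleration_magnitude(s$ax, s$ay, s$az)
  discretise_mean_amag(mean(al), gravity, step)
}

#' Feature table for a list of windows
#'
#' @param windows List of windows from [segment_windows()].
#' @inheritParams feature_vector
#' @return Data frame with `window_start_t`, the 20 named feature columns,
#'   `mean_amag_raw` and `mean_amag`; one row per window.
#' @export
feature_table <- function(windows, gravity = 1, step = 0.1) {
  rows <- lapply(windows, function(w) {
    fv <- feature_vector(w, gravity = gravity, step = step)
    c(window_start_t = fv$window_start_t, fv$values,
      mean_amag_raw = fv$mean_amag_raw, mean_amag = fv$mean_amag)
  })
  df <- as.data.frame(do.call(rbind, rows))
  df$mean_amag <- as.integer(df$mean_amag)
  df
}

#' Write a feature table to CSV
#'
#' @param features Data frame from [feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path Path written by [write_feature_csv()].
#' @return Feature data frame.
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("window_start_t", feature_names(), "mean_amag_raw", "mean_amag")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "))
  df$mean_amag <- as.integer(df$mean_amag)
  df
}
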