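# Data model for IMU sample streams, observation logs, window segmentation
# and ground-truth alignment at the device cadence (7 s window every 10 s).

#' Behaviour classes
#'
#' The closed set of behaviour labels the classifier distinguishes, in the
#' fixed priority order used for deterministic tie-breaking (majority-label
#' ties, rule-learning ties): walking > standing > lying.
#'
#' @return Character vector of the three behaviour labels.
#' @export
behaviour_labels <- function() c("walking", "standing", "lying")

#' Activity levels
#'
#' The closed set of activity levels produced by the online k-means over the
#' discretised mean acceleration magnitude, ordered from most to least
#' active.
#'
#' @return Character vector `c("high", "medium", "low")`.
#' @export
activity_levels <- function() c("high", "medium", "low")

imu_columns <- c("t", "ax", "ay", "az", "gx", "gy", "gz")

#' Construct an IMU sample stream
#'
#' A sample stream is a data frame with columns `t` (seconds), `ax,ay,az`
#' (acceleration per axis in g) and `gx,gy,gz` (angular rate per axis in
#' deg/s), carrying its nominal sampling rate as an attribute. Acceleration
#' is kept in g so that gravity subtraction is the constant 1.
#'
#' @param df Data frame holding the seven IMU columns.
#' @param rate_hz Nominal sampling rate in Hz (default 16, the device rate).
#' @return An object of class `imu_stream`.
#' @export
imu_stream <- function(df, rate_hz = 16) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(imu_columns, names(df))
  if (length(missing_cols) > 0)
    stop("missing IMU columns: ", paste(missing_cols, collapse = ", "))
  df <- df[imu_columns]
  for (col in imu_columns) {
    if (!is.numeric(df[[col]]))
      stop("non-numeric values in column '", col, "'")
    if (anyNA(df[[col]]) || any(!is.finite(df[[col]])))
      stop("non-finite values in column '", col, "'")
  }
  if (nrow(df) > 1) {
    dt <- diff(df$t)
    if (any(dt <= 0)) {
      bad <- which(dt <= 0)[1] + 1L
      stop("timestamps not strictly increasing at row ", bad,
           " (t = ", df$t[bad], ")")
    }
  }
  structure(df, rate_hz = rate_hz, class = c("imu_stream", "data.frame"))
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("IMU stream: %d samples at %g Hz, %.1f s\n",
              nrow(x), attr(x, "rate_hz"), stream_duration(x)))
  invisible(x)
}

stream_rate <- function(stream) {
  r <- attr(stream, "rate_hz")
  if (is.null(r)) 16 else r
}

stream_duration <- function(stream) nrow(stream) / stream_rate(stream)

#' Read an IMU stream from CSV
#'
#' Expects a header row declaring the columns `t,ax,ay,az,gx,gy,gz`
#' (comma-separated, '.' decimal). Rows must be numeric and timestamps
#' strictly increasing.
#'
#' @param path Path to the CSV file.
#' @param rate_hz Nominal sampling rate in Hz.
#' @return An [imu_stream()].
#' @export
read_imu_csv <- function(path, rate_hz = 16) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no samples in ", path)
  imu_stream(df, rate_hz = rate_hz)
}

#' Write an IMU stream to CSV
#'
#' @param stream An [imu_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(stream, path) {
  utils::write.csv(as.data.frame(stream)[imu_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a behaviour observation log
#'
#' An ethogram-style log of non-overlapping intervals, each carrying one of
#' the three behaviour labels.
#'
#' @param start_t,end_t Interval bounds in seconds, `end_t > start_t`.
#' @param label Behaviour label per interval.
#' @return An object of class `obs_log` (a data frame).
#' @export
obs_log <- function(start_t, end_t, label) {
  df <- data.frame(start_t = as.numeric(start_t), end_t = as.numeric(end_t),
                   label = as.character(label), stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty observation log")
  if (any(!df$label %in% behaviour_labels()))
    stop("unknown behaviour label(s): ",
         paste(unique(setdiff(df$label, behaviour_labels())), collapse = ", "))
  if (any(df$end_t <= df$start_t)) stop("intervals must have end_t > start_t")
  df <- df[order(df$start_t), , drop = FALSE]
  if (nrow(df) > 1 && any(df$start_t[-1] < df$end_t[-nrow(df)] - 1e-9))
    stop("observation intervals overlap")
  rownames(df) <- NULL
  structure(df, class = c("obs_log", "data.frame"))
}

#' Read an observation log from CSV
#'
#' Expects columns `start_t,end_t,label`.
#'
#' @param path Path to the CSV file.
#' @return An [obs_log()].
#' @export
read_obs_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  obs_log(df$start_t, df$end_t, df$label)
}

#' Write an observation log to CSV
#'
#' @param log An [obs_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obs_csv <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Split a stream at recording gaps (> gap_factor / rate_hz between samples);
# each contiguous segment is windowed independently.
split_on_gaps <- function(stream, gap_factor = 1.5) {
  n <- nrow(stream)
  if (n <= 1) return(list(stream))
  dt <- diff(stream$t)
  cuts <- which(dt > gap_factor / stream_rate(stream))
  if (length(cuts) == 0) return(list(stream))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  lapply(seq_along(starts), function(i) {
    seg <- as.data.frame(stream)[starts[i]:ends[i], , drop = FALSE]
    imu_stream(seg, rate_hz = stream_rate(stream))
  })
}

new_window <- function(samples, start_t, rate_hz) {
  structure(list(start_t = start_t, samples = samples, rate_hz = rate_hz),
            class = "imu_window")
}

#' @export
print.imu_window <- function(x, ...) {
  cat(sprintf("IMU window: start %g s, %d samples at %g Hz\n",
              x$start_t, nrow(x$samples), x$rate_hz))
  invisible(x)
}

#' Segment a stream into fixed-cadence windows
#'
#' Windows are anchored at the stream start and advance by exactly
#' `cadence_s` seconds (default: a 7 s sampling window every 10 s,
#' emulating the device's 3 s transmit delay between readings). Each window
#' holds exactly `window_s * rate_hz` samples; trailing partial windows are
#' dropped, and a stream shorter than one window yields an empty list.
#' Recording gaps larger than 1.5 sample periods split the stream into
#' segments that are windowed independently. Windows containing any
#' non-finite sample or a sample-count deficit are never produced
#' (non-finite samples are rejected at stream construction).
#'
#' @param stream An [imu_stream()].
#' @param window_s Window length in seconds (default 7).
#' @param cadence_s Window spacing in seconds (default 10); must be
#'   at least `window_s`.
#' @return List of `imu_window` objects.
#' @export
segment_windows <- function(stream, window_s = 7, cadence_s = 10) {
  if (cadence_s < window_s) stop("cadence_s must be >= window_s")
  rate <- stream_rate(stream)
  n_win <- as.integer(round(window_s * rate))
  n_cad <- as.integer(round(cadence_s * rate))
  segments <- split_on_gaps(stream)
  out <- list()
  for (seg in segments) {
    n <- nrow(seg)
    k <- 0L
    while (k * n_cad + n_win <= n) {
      idx <- seq.int(k * n_cad + 1L, k * n_cad + n_win)
      samples <- as.data.frame(seg)[idx, , drop = FALSE]
      rownames(samples) <- NULL
      out[[length(out) + 1L]] <- new_window(samples, samples$t[1], rate)
      k <- k + 1L
    }
  }
  out
}

#' Assign ground-truth labels to windows by majority overlap
#'
#' Each window's reporting interval `[start_t, start_t + cadence_s)` is
#' intersected with the observation log. If a single behaviour covers the
#' whole interval it becomes the ground truth; otherwise the behaviour with
#' the greatest overlap duration wins, with exact ties broken by the fixed
#' `priority` order.
#'
#' @param windows List of windows from [segment_windows()].
#' @param log An [obs_log()].
#' @param cadence_s Reporting cadence in seconds (default 10).
#' @param priority Label order used to break exact duration ties.
#' @return Character vector of behaviour labels, one per window.
#' @export
align_labels <- function(windows, log, cadence_s = 10,
                         priority = behaviour_labels()) {
  starts <- vapply(windows, function(w) w$start_t, numeric(1))
  align_starts(starts, log, cadence_s, priority)
}

#' Assign ground-truth labels to window start times
#'
#' The windowless core of [align_labels()], for feature tables that only
#' carry window start times.
#'
#' @param starts Window start times in seconds.
#' @inheritParams align_labels
#' @return Character vector of behaviour labels, one per start time.
#' @export
align_starts <- function(starts, log, cadence_s = 10,
                         priority = behaviour_labels()) {
  stopifnot(setequal(priority, behaviour_labels()))
  labs <- vapply(starts, function(a) {
    b <- a + cadence_s
    ov <- pmin(log$end_t, b) - pmax(log$start_t, a)
    ov[ov < 0] <- 0
    dur <- vapply(priority, function(lb) sum(ov[log$label == lb]), numeric(1))
    if (sum(dur) <= 0) return(NA_character_)
    priority[which.max(dur)]  # which.max takes the first max: priority order
  }, character(1))
  if (anyNA(labs)) {
    stop("windows with no observation coverage at start times: ",
         paste(format(starts[is.na(labs)]), collapse = ", "))
  }
  labs
}
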