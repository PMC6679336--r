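# Online unsupervised learner: three 1-D centroids over the discretised
# MeanAMag activity index, streamed predict-then-update, producing
# high/medium/low activity levels.

#' Initialise the online k-means centroid state
#'
#' Either from prior centre values (e.g. centres computed from previously
#' collected data) or from an initial subset of the stream (default the
#' first 100 points) clustered by batch k-means with multiple seeded
#' restarts.
#'
#' @param points Numeric stream prefix to cluster; at least 3 distinct
#'   values. Only the first `n_init` points are used.
#' @param priors Three prior centre values (used instead of `points`).
#' @param seed Integer seed for the batch k-means restarts.
#' @param n_init Number of leading points used when initialising from data
#'   (default 100).
#' @param prior_count Initial mass given to each prior centre (default 1).
#' @return A `centroid_state`: `centres` (length 3), `counts`, and an
#'   empty `history`.
#' @export
init_centroids <- function(points = NULL, priors = NULL, seed = 1,
                           n_init = 100, prior_count = 1) {
  if (!is.null(priors)) {
    stopifnot(length(priors) == 3, all(is.finite(priors)))
    return(new_centroid_state(as.numeric(priors),
                              rep(prior_count, 3)))
  }
  if (is.null(points)) stop("provide either points or priors")
  pts <- as.numeric(points)[seq_len(min(n_init, length(points)))]
  if (length(unique(pts)) < 3)
    stop("need at least 3 distinct values to initialise centroids")
  km <- with_seed(seed,
                  stats::kmeans(matrix(pts, ncol = 1), centers = 3,
                                nstart = 10, iter.max = 100))
  new_centroid_state(as.numeric(km$centers), as.numeric(km$size))
}

new_centroid_state <- function(centres, counts) {
  structure(list(centres = centres, counts = counts,
                 history = matrix(numeric(0), ncol = 3,
                                  dimnames = list(NULL, activity_levels()))),
            class = "centroid_state")
}

#' @export
print.centroid_state <- function(x, ...) {
  ord <- order(x$centres, decreasing = TRUE)
  cat(sprintf("centroid state: high %.3f (n=%g), medium %.3f (n=%g), low %.3f (n=%g)\n",
              x$centres[ord[1]], x$counts[ord[1]],
              x$centres[ord[2]], x$counts[ord[2]],
              x$centres[ord[3]], x$counts[ord[3]]))
  invisible(x)
}

# rank of each centre by descending value -> high/medium/low
centre_levels <- function(centres) {
  activity_levels()[match(seq_along(centres), order(centres, decreasing = TRUE))]
}

#' One predict-then-update step of the online k-means
#'
#' The activity level is predicted from the centroids as they stood before
#' this point (nearest centre by Euclidean distance on the 1-D activity
#' index; distance ties go to the higher-activity centre). The winning
#' centre then absorbs the point by an exact running mean,
#' `C <- C + (z - C) / (count + 1)`; the other centres are untouched.
#'
#' @param state A `centroid_state`.
#' @param z Activity index (discretised MeanAMag) of the new window.
#' @return List with `level` (`"high"`, `"medium"` or `"low"`) and the
#'   updated `state`.
#' @export
km_step <- function(state, z) {
  if (!is.finite(z)) stop("non-finite activity index")
  d <- abs(state$centres - z)
  cand <- which(d == min(d))
  winner <- cand[which.max(state$centres[cand])]
  level <- centre_levels(state$centres)[winner]
  state$centres[winner] <- state$centres[winner] +
    (z - state$centres[winner]) / (state$counts[winner] + 1)
  state$counts[winner] <- state$counts[winner] + 1
  list(level = level, state = state)
}

#' Run the online k-means over a stream of activity indices
#'
#' Applies [km_step()] sequentially. When `history = TRUE` the state's
#' history accumulates the centre values (sorted high/medium/low) after
#' each step, for drift diagnostics.
#'
#' @param state A `centroid_state`.
#' @param zs Numeric vector of activity indices.
#' @param history Record the centre trajectory (default `TRUE`).
#' @return List with `levels` (character, same length as `zs`) and the
#'   final `state`.
#' @export
run_stream <- function(state, zs, history = TRUE) {
  n <- length(zs)
  levels_out <- character(n)
  hist_rows <- if (history) matrix(NA_real_, n, 3) else NULL
  for (i in seq_len(n)) {
    step <- km_step(state, zs[i])
    state <- step$state
    levels_out[i] <- step$level
    if (history)
      hist_rows[i, ] <- sort(state$centres, decreasing = TRUE)
  }
  if (history) {
    colnames(hist_rows) <- activity_levels()
    state$history <- rbind(state$history, hist_rows)
  }
  list(levels = levels_out, state = state)
}

#' Write the centre trajectory to CSV
#'
#' Columns `step, C_high, C_medium, C_low`.
#'
#' @param state A `centroid_state` with recorded history.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(state, path) {
  h <- state$history
  df <- data.frame(step = seq_len(nrow(h)),
                   C_high = h[, "high"], C_medium = h[, "medium"],
                   C_low = h[, "low"])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map activity levels to behaviour labels
#'
#' The online clusters are read as behaviours by activity rank: high ->
#' walking, medium -> standing, low -> lying. This is the "online-only"
#' classifier used when benchmarking the fused algorithm.
#'
#' @param levels Character vector of activity levels.
#' @return Character vector of behaviour labels.
#' @export
level_to_behaviour <- function(levels) {
  behaviour_labels()[match(levels, activity_levels())]
}
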