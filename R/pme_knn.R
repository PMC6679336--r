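# Nearest-prototype classifier emulating an on-chip pattern matching
# engine: a capacity-limited store (default 128) of byte-quantised labelled
# feature vectors, classified by 1-nearest-neighbour.

# run expr with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Fit per-feature quantisation bounds
#'
#' Maps each feature's training range `[lo, hi]` onto the byte range 0-255.
#' Degenerate (constant) features get `hi = lo + eps` so they quantise to 0.
#'
#' @param x Numeric training matrix, one row per vector.
#' @return List with numeric vectors `lo` and `hi`.
#' @export
fit_scaling <- function(x) {
  lo <- unname(apply(x, 2, min))
  hi <- unname(apply(x, 2, max))
  deg <- hi <= lo
  # a representable epsilon: relative eps vanishes in floating point when
  # added to large lo values
  hi[deg] <- lo[deg] + pmax(abs(lo[deg]), 1) * 1e-9
  list(lo = lo, hi = hi)
}

#' Quantise a feature vector to bytes
#'
#' Each entry becomes `round(255 * (x - lo) / (hi - lo))` (half-up),
#' clipped into `[0, 255]` — out-of-range inputs saturate like hardware
#' bytes.
#'
#' @param x Numeric vector (length 20) or matrix (rows = vectors).
#' @param scaling Bounds from [fit_scaling()].
#' @return Integer vector or matrix with entries in 0..255.
#' @export
quantise <- function(x, scaling) {
  if (is.matrix(x)) {
    q <- round_half_up(sweep(sweep(x, 2, scaling$lo), 2,
                             scaling$hi - scaling$lo, "/") * 255)
    q[] <- pmin(pmax(q, 0), 255)
    storage.mode(q) <- "integer"
    return(q)
  }
  q <- round_half_up(255 * (x - scaling$lo) / (scaling$hi - scaling$lo))
  as.integer(pmin(pmax(q, 0), 255))
}

feature_matrix <- function(features) {
  if (is.data.frame(features)) features <- as.matrix(features[feature_names()])
  if (inherits(features, "feature_vector")) features <- rbind(features$values)
  as.matrix(features)
}

# deterministic k-medoids (PAM build + swap) on a precomputed distance
# matrix; returns medoid indices
k_medoids <- function(d, k, max_iter = 50) {
  n <- nrow(d)
  if (k >= n) return(seq_len(n))
  medoids <- which.min(colSums(d))
  while (length(medoids) < k) {
    best_cost <- Inf
    best <- NA_integer_
    nearest <- apply(d[, medoids, drop = FALSE], 1, min)
    for (cand in setdiff(seq_len(n), medoids)) {
      cost <- sum(pmin(nearest, d[, cand]))
      if (cost < best_cost) {
        best_cost <- cost
        best <- cand
      }
    }
    medoids <- c(medoids, best)
  }
  cost_of <- function(m) sum(apply(d[, m, drop = FALSE], 1, min))
  cost <- cost_of(medoids)
  for (iter in seq_len(max_iter)) {
    improved <- FALSE
    for (i in seq_along(medoids)) {
      for (cand in setdiff(seq_len(n), medoids)) {
        trial <- medoids
        trial[i] <- cand
        tc <- cost_of(trial)
        if (tc < cost - 1e-12) {
          medoids <- trial
          cost <- tc
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  sort(medoids)
}

byte_dist_matrix <- function(a, b, metric) {
  # a: n x p, b: m x p -> n x m
  out <- matrix(0, nrow(a), nrow(b))
  for (j in seq_len(nrow(b))) {
    diffs <- abs(sweep(a, 2, b[j, ]))
    out[, j] <- if (metric == "L1") rowSums(diffs) else sqrt(rowSums(diffs^2))
  }
  out
}

#' Fit a prototype model
#'
#' Quantisation bounds are fit on the training min/max. If the training set
#' fits within `capacity` every vector is stored; otherwise a
#' class-stratified k-medoids selection keeps a representative subset, with
#' per-class quotas proportional to class frequency (largest remainder, at
#' least 1 per class). Deterministic given `seed`.
#'
#' @param features Numeric matrix (rows = vectors of length 20) or a
#'   feature data frame from [feature_table()].
#' @param labels Behaviour label per training vector; every class must be
#'   present.
#' @param capacity Maximum number of stored prototypes (default 128).
#' @param metric Distance on byte vectors: `"L1"` (default) or
#'   `"euclidean"`.
#' @param seed Integer seed (selection is deterministic, the seed guards
#'   any future stochastic selection policy and is recorded in the model).
#' @return A `pme_model`: prototypes (integer matrix), labels, capacity,
#'   scaling and metric.
#' @export
fit_prototypes <- function(features, labels, capacity = 128,
                           metric = c("L1", "euclidean"), seed = 1) {
  metric <- match.arg(metric)
  x <- feature_matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  absent <- setdiff(behaviour_labels(), unique(labels))
  if (length(absent) > 0)
    stop("class(es) absent from training data: ",
         paste(absent, collapse = ", "))
  scaling <- fit_scaling(x)
  q <- quantise(x, scaling)
  if (nrow(q) > capacity) {
    counts <- table(factor(labels, levels = behaviour_labels()))
    quota <- largest_remainder_quota(as.numeric(counts), capacity, min_one = TRUE)
    keep <- integer(0)
    for (i in seq_along(behaviour_labels())) {
      cls <- behaviour_labels()[i]
      idx <- which(labels == cls)
      k <- min(quota[i], length(idx))
      d <- byte_dist_matrix(q[idx, , drop = FALSE], q[idx, , drop = FALSE],
                            metric)
      keep <- c(keep, idx[with_seed(seed, k_medoids(d, k))])
    }
    keep <- sort(keep)
    q <- q[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  structure(list(prototypes = q, labels = labels, capacity = capacity,
                 scaling = scaling, metric = metric, seed = seed),
            class = "pme_model")
}

# integer quotas summing to total, proportional to weights
largest_remainder_quota <- function(weights, total, min_one = FALSE) {
  share <- weights / sum(weights) * total
  quota <- floor(share)
  rem <- share - quota
  short <- total - sum(quota)
  if (short > 0) {
    ord <- order(rem, decreasing = TRUE)
    quota[ord[seq_len(short)]] <- quota[ord[seq_len(short)]] + 1
  }
  if (min_one) {
    while (any(quota == 0 & weights > 0)) {
      i <- which(quota == 0 & weights > 0)[1]
      j <- which.max(quota)
      quota[i] <- 1
      quota[j] <- quota[j] - 1
    }
  }
  as.integer(quota)
}

#' @export
print.pme_model <- function(x, ...) {
  cat(sprintf("PME prototype model: %d/%d prototypes, %s metric\n",
              nrow(x$prototypes), x$capacity, x$metric))
  print(table(x$labels))
  invisible(x)
}

#' Classify feature vectors by nearest prototype (1-NN)
#'
#' Queries are quantised with the model's scaling and matched against every
#' stored prototype under the model metric; the label of the
#' minimum-distance prototype is returned. Distance ties go to the
#' earliest-stored prototype.
#'
#' @param model A `pme_model` from [fit_prototypes()].
#' @param features One feature vector, a numeric matrix of query rows, or a
#'   feature data frame.
#' @return Character vector of predicted behaviour labels.
#' @export
knn_predict <- function(model, features) {
  if (nrow(model$prototypes) == 0) stop("empty prototype model")
  x <- feature_matrix(features)
  q <- quantise(x, model$scaling)
  d <- byte_dist_matrix(q, model$prototypes, model$metric)
  model$labels[apply(d, 1, which.min)]
}

#' Write a prototype model to a JSON file
#'
#' Plain-text serialisation with a bit-exact round-trip via
#' [read_pme_model()].
#'
#' @param model A `pme_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pme_model <- function(model, path) {
  obj <- list(format = "flockdrift-pme-1",
              capacity = model$capacity,
              metric = model$metric,
              seed = model$seed,
              scaling_lo = unname(model$scaling$lo),
              scaling_hi = unname(model$scaling$hi),
              labels = model$labels,
              prototypes = model$prototypes)
  # I(17) significant digits keeps the double-precision bounds bit-exact
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE), path)
  invisible(path)
}

#' Read a prototype model from a JSON file
#'
#' @param path Path written by [write_pme_model()].
#' @return A `pme_model`.
#' @export
read_pme_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "flockdrift-pme-1")
    stop("not a flockdrift PME model file: ", path)
  proto <- matrix(as.integer(obj$prototypes), nrow = length(obj$labels))
  structure(list(prototypes = proto,
                 labels = as.character(obj$labels),
                 capacity = as.integer(obj$capacity),
                 scaling = list(lo = as.numeric(obj$scaling_lo),
                                hi = as.numeric(obj$scaling_hi)),
                 metric = obj$metric,
                 seed = obj$seed),
            class = "pme_model")
}
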