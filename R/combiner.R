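# Decision-rule fusion of the offline nearest-prototype label and the
# online activity level, rule learning from labelled data, and the full
# streaming pipeline.

#' The published decision-rule table
#'
#' Maps every (KNN label, activity level) cell to a fused behaviour:
#' walking stays walking at any level; standing with high activity is
#' promoted to walking (the drift-rescue rule); standing with medium or low
#' activity stays standing; lying with medium or low activity stays lying.
#' Two cells are not pinned down by the published clauses: (lying, low) is
#' claimed by both the standing and the lying cluster — resolved by
#' `conflict` (default `"lying"`, keeping the low-activity behaviour
#' reachable) — and (lying, high) is never assigned — resolved by the
#' `fallback` policy (default: pass the KNN label through).
#'
#' @param conflict Output for the ambiguous (lying, low) cell: `"lying"`
#'   (default) or `"standing"`.
#' @param fallback Policy for unassigned cells: `"knn"` (pass the KNN
#'   label through, default) or a fixed behaviour label.
#' @return A `rule_table`.
#' @export
default_rules <- function(conflict = c("lying", "standing"),
                          fallback = "knn") {
  conflict <- match.arg(conflict)
  grid <- expand.grid(knn_label = behaviour_labels(),
                      level = activity_levels(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    k <- grid$knn_label[i]
    l <- grid$level[i]
    out[i] <-
      if (k == "walking") "walking"
      else if (k == "standing" && l == "high") "walking"
      else if (k == "standing") "standing"
      else if (k == "lying" && l == "medium") "lying"
      else if (k == "lying" && l == "low") conflict
      else NA_character_  # (lying, high): left to the fallback policy
  }
  new_rule_table(grid$knn_label, grid$level, out, fallback,
                 provenance = "literal")
}

new_rule_table <- function(knn_label, level, output, fallback, provenance) {
  stopifnot(fallback %in% c("knn", "literal", behaviour_labels()))
  mapping <- data.frame(knn_label = knn_label, level = level,
                        output = output, stringsAsFactors = FALSE)
  structure(list(mapping = mapping, fallback = fallback,
                 provenance = provenance),
            class = "rule_table")
}

#' @export
print.rule_table <- function(x, ...) {
  cat(sprintf("decision-rule table (%s), fallback = %s\n",
              x$provenance, x$fallback))
  m <- x$mapping
  m$output[is.na(m$output)] <- paste0("<", x$fallback, ">")
  print(m, row.names = FALSE)
  invisible(x)
}

#' Apply a decision-rule table
#'
#' Pure lookup of the fused behaviour for (KNN label, activity level)
#' pairs; cells the table leaves unassigned resolve through its fallback
#' policy. Vectorised.
#'
#' @param table A `rule_table`.
#' @param knn_label Behaviour label(s) from the offline classifier.
#' @param level Activity level(s) from the online k-means.
#' @return Fused behaviour label(s).
#' @export
apply_rules <- function(table, knn_label, level) {
  key <- paste(knn_label, level)
  map_key <- paste(table$mapping$knn_label, table$mapping$level)
  out <- table$mapping$output[match(key, map_key)]
  open <- is.na(out)
  if (any(open)) {
    out[open] <- if (table$fallback == "knn") {
      knn_label[open]
    } else if (table$fallback == "literal") {
      apply_rules(default_rules(), knn_label[open], level[open])
    } else {
      table$fallback
    }
  }
  out
}

#' Learn a decision-rule table from labelled pairs
#'
#' Per-cell majority vote of the ground-truth behaviour over all pairs
#' falling in that (KNN label, activity level) cell — the same partition a
#' fully grown decision tree on two 3-level categorical predictors induces.
#' Cells with fewer than `min_support` pairs stay unassigned and resolve
#' through the fallback policy; vote ties break by the fixed `priority`.
#'
#' @param knn_label,level,truth Equal-length vectors: offline label, online
#'   level, and observed behaviour per window.
#' @param min_support Minimum pair count for a cell to be learned
#'   (default 1).
#' @param fallback Policy for unlearned cells: `"knn"` (pass the KNN label
#'   through), `"literal"` (resolve by the published [default_rules()]
#'   table — prior knowledge for cells the training data never visits), or
#'   a fixed behaviour label.
#' @param priority Label order breaking majority ties.
#' @return A `rule_table` with provenance `"learned"`.
#' @export
learn_rules <- function(knn_label, level, truth, min_support = 1,
                        fallback = "knn", priority = behaviour_labels()) {
  stopifnot(length(knn_label) == length(level),
            length(level) == length(truth), length(truth) > 0)
  grid <- expand.grid(knn_label = behaviour_labels(),
                      level = activity_levels(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    in_cell <- knn_label == grid$knn_label[i] & level == grid$level[i]
    if (sum(in_cell) < min_support) {
      out[i] <- NA_character_
      next
    }
    votes <- vapply(priority, function(lb) sum(truth[in_cell] == lb),
                    numeric(1))
    out[i] <- priority[which.max(votes)]
  }
  new_rule_table(grid$knn_label, grid$level, out, fallback,
                 provenance = "learned")
}

#' Write a rule table to a text file
#'
#' Nine CSV rows (knn_label, level, output; unassigned cells written as
#' `NA`) preceded by comment lines recording fallback and provenance.
#'
#' @param table A `rule_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# fallback: ", table$fallback),
               paste0("# provenance: ", table$provenance),
               "knn_label,level,output"), con)
  m <- table$mapping
  writeLines(paste(m$knn_label, m$level,
                   ifelse(is.na(m$output), "NA", m$output), sep = ","), con)
  invisible(path)
}

#' Read a rule table written by [write_rules()]
#'
#' @param path Path to the rule file.
#' @return A `rule_table`.
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  fallback <- sub("^# fallback: ", "", grep("^# fallback:", meta, value = TRUE))
  provenance <- sub("^# provenance: ", "",
                    grep("^# provenance:", meta, value = TRUE))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE,
                        na.strings = "NA")
  if (nrow(df) != 9) stop("rule table must have exactly 9 cells")
  new_rule_table(df$knn_label, df$level, df$output,
                 if (length(fallback)) fallback else "knn",
                 if (length(provenance)) provenance else "literal")
}

#' Run the full combined pipeline over a sample stream
#'
#' Segments the stream at the device cadence, and per window: extracts the
#' 20-feature vector and activity index, classifies with the frozen
#' prototype model, steps the online k-means (predict-then-update on the
#' discretised MeanAMag) and fuses the two labels through the rule table.
#'
#' @param stream An [imu_stream()].
#' @param model A `pme_model` from [fit_prototypes()].
#' @param state A `centroid_state` from [init_centroids()].
#' @param table A `rule_table`.
#' @param window_s,cadence_s Windowing parameters as in
#'   [segment_windows()].
#' @param gravity,step MeanAMag parameters as in [feature_vector()].
#' @return List with `records` (data frame: `timestamp`, `knn_label`,
#'   `level`, `mean_amag`, `combined`) and the final `state`.
#' @export
run_combined <- function(stream, model, state, table,
                         window_s = 7, cadence_s = 10,
                         gravity = 1, step = 0.1) {
  windows <- segment_windows(stream, window_s = window_s,
                             cadence_s = cadence_s)
  n <- length(windows)
  records <- data.frame(timestamp = numeric(n), knn_label = character(n),
                        level = character(n), mean_amag = integer(n),
                        combined = character(n), stringsAsFactors = FALSE)
  hist_rows <- matrix(NA_real_, n, 3, dimnames = list(NULL, activity_levels()))
  for (i in seq_len(n)) {
    fv <- feature_vector(windows[[i]], gravity = gravity, step = step)
    x_i <- knn_predict(model, rbind(fv$values))
    s <- km_step(state, fv$mean_amag)
    state <- s$state
    hist_rows[i, ] <- sort(state$centres, decreasing = TRUE)
    records$timestamp[i] <- fv$window_start_t
    records$knn_label[i] <- x_i
    records$level[i] <- s$level
    records$mean_amag[i] <- fv$mean_amag
    records$combined[i] <- apply_rules(table, x_i, s$level)
  }
  state$history <- rbind(state$history, hist_rows)
  list(records = records, state = state)
}

#' Write pipeline records to CSV
#'
#' @param records Records data frame from [run_combined()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
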