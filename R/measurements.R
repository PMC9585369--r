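#' Canonical morphometric feature columns
#'
#' The three larval features used throughout the package, in canonical order:
#' head capsule length, head capsule width, mandible width, all in cm.
#' "Feature 1" (head capsule length) defines the canonical instar ordering of
#' cluster labels.
#'
#' @return Character vector of the three canonical column names.
#' @export
feature_columns <- function() {
  c("head_capsule_length_cm", "head_capsule_width_cm", "mandible_width_cm")
}

#' Construct a validated measurement table
#'
#' @param df data.frame with at least the three feature columns of
#'   [feature_columns()]; an optional `specimen_id` column (generated as
#'   `"s<row>"` when absent) and an optional integer `instar` column carrying
#'   true labels.
#' @return A `measurement_table`: a data.frame with columns `specimen_id`,
#'   the three feature columns, and `instar` (possibly all-`NA`).
#' @export
measurement_table <- function(df) {
  stopifnot(is.data.frame(df))
  feats <- feature_columns()
  missing_cols <- setdiff(feats, names(df))
  if (length(missing_cols) > 0) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(df)
  id <- if ("specimen_id" %in% names(df)) as.character(df$specimen_id) else
    if (n > 0) paste0("s", seq_len(n)) else character(0)
  if (anyDuplicated(id)) stop("duplicate specimen_id values")
  instar <- if ("instar" %in% names(df)) as.integer(df$instar) else
    rep(NA_integer_, n)
  out <- data.frame(specimen_id = id, stringsAsFactors = FALSE)
  for (f in feats) {
    v <- df[[f]]
    if (n == 0L) v <- numeric(0)
    if (!is.numeric(v)) stop("non-numeric values in column ", f)
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad) > 0) {
      stop("non-positive or non-finite measurement in column ", f,
           " at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    }
    out[[f]] <- as.numeric(v)
  }
  out$instar <- instar
  class(out) <- c("measurement_table", "data.frame")
  out
}

#' Read a morphometric measurement CSV
#'
#' Reads a comma-separated, headered, dot-decimal CSV of per-specimen larval
#' measurements and validates it: all three features must be present, numeric,
#' strictly positive and finite. A failed validation never returns a partial
#' table.
#'
#' @param path path to the CSV file.
#' @param column_map optional named character vector mapping canonical names
#'   (see [feature_columns()], plus optionally `specimen_id`, `instar`) to the
#'   column names used in the file.
#' @return A validated `measurement_table`.
#' @export
read_measurements <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) stop("mapped column not found: ", src)
      names(df)[names(df) == src] <- canon
    }
  }
  measurement_table(df)
}

#' Extract the feature matrix of a measurement table
#'
#' @param table a `measurement_table`.
#' @return Numeric matrix, one row per specimen, columns in canonical order.
#' @export
feature_matrix <- function(table) {
  m <- as.matrix(as.data.frame(table)[, feature_columns(), drop = FALSE])
  rownames(m) <- table$specimen_id
  m
}

#' Write a measurement table with cluster labels
#'
#' Appends the partition as a `cluster` column (noise encoded as 0) and writes
#' a CSV in the canonical column order. Feature values are serialized at full
#' double precision so a read/write round trip preserves them.
#'
#' @param table a `measurement_table`.
#' @param partition a `partition` of the same length (see [partition()]).
#' @param path output file path.
#' @return The output path, invisibly.
#' @export
write_partition <- function(table, partition, path) {
  labels <- partition_labels(partition)
  if (length(labels) != nrow(table)) {
    stop("partition length (", length(labels), ") does not match table rows (",
         nrow(table), ")")
  }
  out <- as.data.frame(table)
  out$cluster <- labels
  cols <- c("specimen_id", feature_columns(),
            if (!all(is.na(out$instar))) "instar", "cluster")
  utils::write.csv(out[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a measurement table as CSV
#'
#' @param table a `measurement_table`.
#' @param path output file path.
#' @return The output path, invisibly.
#' @export
write_measurements <- function(table, path) {
  out <- as.data.frame(table)
  cols <- c("specimen_id", feature_columns(),
            if (!all(is.na(out$instar))) "instar")
  utils::write.csv(out[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
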