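#' Construct a feature table
#'
#' A `feature_table` holds a samples-by-features numeric matrix together with
#' unique sample identifiers, unique feature names, a per-feature kind tag
#' (`"radiomics"` or `"clinical"`), and an optional binary outcome label per
#' sample (1 = event, e.g. locoregional recurrence; 0 = no event).
#'
#' @param values numeric matrix, one row per sample, one column per feature.
#' @param sample_ids character vector of unique sample identifiers.
#' @param feature_names character vector of unique feature names; defaults to
#'   the column names of `values`.
#' @param feature_kind character vector, one of `"radiomics"` or `"clinical"`
#'   per feature. Recycled if length 1.
#' @param labels optional integer vector in `{0, 1}`, one per sample.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, sample_ids, feature_names = colnames(values),
                          feature_kind = "radiomics", labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  d <- ncol(values)
  sample_ids <- as.character(sample_ids)
  feature_names <- as.character(feature_names)
  if (length(sample_ids) != n) stop("length(sample_ids) must equal nrow(values)")
  if (length(feature_names) != d) stop("length(feature_names) must equal ncol(values)")
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(feature_names)) {
    dup <- unique(feature_names[duplicated(feature_names)])
    stop("duplicate feature name(s): ", paste(dup, collapse = ", "))
  }
  if (length(feature_kind) == 1L) feature_kind <- rep(feature_kind, d)
  if (length(feature_kind) != d) stop("feature_kind must have one entry per feature")
  if (d > 0 && !all(feature_kind %in% c("radiomics", "clinical"))) {
    stop("feature_kind entries must be 'radiomics' or 'clinical'")
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at sample '%s', feature '%s'",
                 sample_ids[bad[1L]], feature_names[bad[2L]]))
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop("labels must have one entry per sample")
    if (any(is.na(labels)) || !all(labels %in% c(0L, 1L))) {
      stop("labels must be 0 or 1")
    }
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(
    list(values = values, sample_ids = sample_ids,
         feature_names = feature_names, feature_kind = feature_kind,
         labels = labels),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features (%d radiomics, %d clinical)\n",
              nrow(x$values), ncol(x$values),
              sum(x$feature_kind == "radiomics"), sum(x$feature_kind == "clinical")))
  if (!is.null(x$labels)) {
    cat(sprintf("labels: %d events / %d samples\n", sum(x$labels), length(x$labels)))
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset a feature table by samples and/or features
#'
#' @param x a `feature_table`.
#' @param samples sample indices, logical mask, or sample ids.
#' @param features feature indices, logical mask, or feature names.
#' @return a `feature_table` with the selected rows/columns.
#' @export
ft_subset <- function(x, samples = NULL, features = NULL) {
  si <- if (is.null(samples)) seq_along(x$sample_ids) else {
    if (is.character(samples)) match(samples, x$sample_ids) else
      seq_along(x$sample_ids)[samples]
  }
  if (any(is.na(si))) stop("unknown sample id(s)")
  fi <- if (is.null(features)) seq_along(x$feature_names) else {
    if (is.character(features)) match(features, x$feature_names) else
      seq_along(x$feature_names)[features]
  }
  if (any(is.na(fi))) {
    missing <- setdiff(as.character(features), x$feature_names)
    stop("unknown feature(s): ", paste(missing, collapse = ", "))
  }
  feature_table(x$values[si, fi, drop = FALSE], x$sample_ids[si],
                x$feature_names[fi], x$feature_kind[fi],
                labels = if (is.null(x$labels)) NULL else x$labels[si])
}

#' Read a feature table from CSV
#'
#' The CSV must be comma-separated with a header row; one column carries the
#' sample id, one (optional) column the binary outcome, and every remaining
#' column is parsed as a numeric feature. Values are never imputed or scaled
#' at ingestion; missing or non-numeric cells are hard errors unless
#' `drop_incomplete = TRUE`, which removes offending rows and reports how many.
#'
#' @param path path to a CSV file.
#' @param id_column name of the sample-id column.
#' @param label_column optional name of the binary outcome column.
#' @param feature_kind per-feature kind (`"radiomics"`/`"clinical"`), a single
#'   value recycled over all features, or a named vector keyed by feature name.
#' @param drop_incomplete drop rows with missing feature values instead of
#'   erroring (the number of dropped rows is messaged).
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, id_column = "sample_id",
                               label_column = NULL,
                               feature_kind = "radiomics",
                               drop_incomplete = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (!id_column %in% names(df)) stop("id column '", id_column, "' not found")
  if (!is.null(label_column) && !label_column %in% names(df)) {
    stop("label column '", label_column, "' not found")
  }
  ids <- df[[id_column]]
  feat_cols <- setdiff(names(df), c(id_column, label_column))
  if (length(feat_cols) == 0) stop("no feature columns in ", path)
  vals <- matrix(NA_real_, nrow(df), length(feat_cols),
                 dimnames = list(NULL, feat_cols))
  for (j in feat_cols) {
    raw <- trimws(df[[j]])
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !(raw == "" | raw == "NA" | is.na(raw)))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in feature '%s', row with id '%s'",
                   raw[bad[1L]], j, ids[bad[1L]]))
    }
    vals[, j] <- num
  }
  incomplete <- rowSums(is.na(vals)) > 0
  if (any(incomplete)) {
    if (drop_incomplete) {
      message(sprintf("dropped %d row(s) with missing feature values",
                      sum(incomplete)))
      keep <- !incomplete
      vals <- vals[keep, , drop = FALSE]
      ids <- ids[keep]
      df <- df[keep, , drop = FALSE]
    } else {
      first <- which(incomplete)[1L]
      stop(sprintf("missing feature value(s) in row with id '%s' (use drop_incomplete = TRUE to remove such rows)",
                   ids[first]))
    }
  }
  labels <- NULL
  if (!is.null(label_column)) {
    lraw <- suppressWarnings(as.numeric(df[[label_column]]))
    if (any(is.na(lraw)) || !all(lraw %in% c(0, 1))) {
      bad <- which(is.na(lraw) | !lraw %in% c(0, 1))[1L]
      stop(sprintf("label outside {0,1} for sample '%s'", ids[bad]))
    }
    labels <- as.integer(lraw)
  }
  kind <- if (length(feature_kind) == 1L) rep(feature_kind, length(feat_cols))
          else feature_kind[feat_cols]
  feature_table(vals, ids, feat_cols, kind, labels)
}

#' Write a feature table to CSV
#'
#' Inverse of [read_feature_table()]: emits the id column first, the label
#' column (when present) second, then all features at full precision.
#'
#' @param table a `feature_table`.
#' @param path output CSV path.
#' @param id_column,label_column column names to use in the file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, id_column = "sample_id",
                                label_column = "label") {
  df <- data.frame(table$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- id_column
  if (!is.null(table$labels)) df[[label_column]] <- table$labels
  vals <- table$values
  for (j in seq_len(ncol(vals))) {
    df[[table$feature_names[j]]] <- format(vals[, j], digits = 17, trim = TRUE,
                                           scientific = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
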