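#' Feature matrix container
#'
#' The single currency between pipeline stages: a numeric matrix of peptides
#' (rows, named by id) by descriptors (columns, named by the descriptor
#' naming scheme), with an optional aligned 0/1 label vector.
#'
#' @param x Numeric matrix with unique row and column names.
#' @param labels Optional integer 0/1 vector, one per row.
#' @return A `cpp_features` object.
#' @export
cpp_features <- function(x, labels = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) {
    cpp_stop("`x` must be a numeric matrix", "column_mismatch")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    cpp_stop("feature matrix must have row (id) and column (feature) names",
             "column_mismatch")
  }
  if (anyDuplicated(colnames(x))) {
    cpp_stop("feature names must be unique", "column_mismatch")
  }
  if (anyDuplicated(rownames(x))) {
    cpp_stop("row ids must be unique", "duplicate_id")
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(x) || anyNA(labels)) {
      cpp_stop("labels must be complete and aligned to rows", "length_mismatch")
    }
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) {
      cpp_stop("labels must be binary 0/1", "missing_label")
    }
  }
  structure(list(x = x, labels = labels), class = "cpp_features")
}

#' @export
print.cpp_features <- function(x, ...) {
  cat(sprintf("<cpp_features> %d peptide(s) x %d feature(s)%s\n",
              nrow(x$x), ncol(x$x),
              if (is.null(x$labels)) "" else ", labeled"))
  invisible(x)
}

#' @export
dim.cpp_features <- function(x) dim(x$x)

#' Feature names of a feature matrix
#' @param m A `cpp_features` object.
#' @return Character vector of descriptor names, in column order.
#' @export
feature_names <- function(m) colnames(m$x)

#' Restrict a feature matrix to a subset of features
#'
#' @param m A `cpp_features` object.
#' @param features Character vector of feature names to keep, in the order
#'   requested.
#' @return A `cpp_features` with the selected columns.
#' @export
select_features <- function(m, features) {
  missing <- setdiff(features, colnames(m$x))
  if (length(missing)) {
    cpp_stop(sprintf("unknown feature(s): %s",
                     paste(utils::head(missing, 5L), collapse = ", ")),
             "missing_feature")
  }
  cpp_features(m$x[, features, drop = FALSE], m$labels)
}

#' Write a feature matrix to TSV
#'
#' Layout: an `id` column, one column per feature (header = feature name),
#' and a trailing `label` column when labels are present. Values are written
#' with enough precision that a read/write round trip preserves them to at
#' least 12 significant digits.
#'
#' @param m A `cpp_features` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path) {
  dt <- data.table::as.data.table(m$x)
  dt <- cbind(data.table::data.table(id = rownames(m$x)), dt)
  if (!is.null(m$labels)) dt[["label"]] <- m$labels
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a feature matrix from TSV
#'
#' Inverse of [write_feature_matrix()]: expects an `id` first column,
#' numeric feature columns, and an optional trailing `label` column.
#'
#' @param path Path to a TSV written by [write_feature_matrix()].
#' @return A `cpp_features` object.
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) cpp_stop(sprintf("file not found: %s", path), "io")
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[1L] != "id") {
    cpp_stop("malformed feature matrix: first column must be 'id'",
             "unknown_header")
  }
  nf <- lengths(strsplit(readLines(path), "\t", fixed = TRUE))
  if (any(nf != length(header))) {
    cpp_stop(sprintf("ragged row(s) at line(s): %s",
                     paste(which(nf != length(header)), collapse = ", ")),
             "column_mismatch")
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "id"),
                          data.table = TRUE)
  has_label <- utils::tail(names(dt), 1L) == "label"
  feat_cols <- setdiff(names(dt), c("id", if (has_label) "label"))
  x <- as.matrix(dt[, feat_cols, with = FALSE])
  if (!is.numeric(x)) {
    cpp_stop("feature columns must be numeric", "unknown_header")
  }
  rownames(x) <- dt[["id"]]
  cpp_features(x, labels = if (has_label) dt[["label"]])
}
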