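#' Construct a decision table
#'
#' A decision table is a decision information system \eqn{(U, C \cup D)}:
#' a numeric matrix of \eqn{n} objects (samples) by \eqn{m} condition
#' attributes (e.g. genes), plus one categorical decision label per object.
#'
#' @param values Numeric matrix, objects in rows, attributes in columns.
#'   All values must be finite; missing values are an error.
#' @param labels Vector of decision labels, one per row of `values`.
#'   Coerced to a factor whose levels follow first appearance.
#' @param attribute_ids Optional character identifiers per attribute;
#'   defaults to `colnames(values)` or `"a1", "a2", ...`.
#' @param object_ids Optional identifiers per object; defaults to
#'   `rownames(values)` or `"s1", "s2", ...`.
#' @param normalize If `TRUE`, apply per-attribute min-max normalization
#'   to \eqn{[0,1]} (see [normalize_table()]).
#'
#' @return An object of class `decision_table`: a list with elements
#'   `values`, `labels`, `attribute_ids`, `object_ids`, and `normalized`.
#' @examples
#' dt <- decision_table(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5))
#' dt
#' @export
decision_table <- function(values, labels, attribute_ids = NULL,
                           object_ids = NULL, normalize = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("decision table values must be numeric")
  }
  n <- nrow(values)
  m <- ncol(values)
  if (n < 2L) stop("a decision table needs at least 2 objects")
  if (m < 1L) stop("a decision table needs at least 1 attribute")
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(is.na(values) | !is.finite(values), arr.ind = TRUE)
    stop("non-finite feature values at (row, col): ",
         paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = " "))
  }
  if (length(labels) != n) {
    stop("need exactly one label per object: got ", length(labels),
         " labels for ", n, " objects")
  }
  if (anyNA(labels)) stop("missing decision labels")
  labels <- factor(as.character(labels), levels = unique(as.character(labels)))

  if (is.null(attribute_ids)) attribute_ids <- colnames(values)
  if (is.null(attribute_ids)) attribute_ids <- paste0("a", seq_len(m))
  if (is.null(object_ids)) object_ids <- rownames(values)
  if (is.null(object_ids)) object_ids <- paste0("s", seq_len(n))
  stopifnot(length(attribute_ids) == m, length(object_ids) == n)
  dimnames(values) <- list(object_ids, attribute_ids)

  out <- structure(
    list(values = values, labels = labels,
         attribute_ids = as.character(attribute_ids),
         object_ids = as.character(object_ids),
         normalized = FALSE),
    class = "decision_table")
  if (normalize) out <- normalize_table(out) else out
}

#' @export
print.decision_table <- function(x, ...) {
  cat(sprintf("Decision table: %d objects x %d attributes, %d class(es)\n",
              nrow(x$values), ncol(x$values), nlevels(x$labels)))
  cat("Classes:", paste(sprintf("%s (%d)", levels(x$labels),
                                tabulate(x$labels)), collapse = ", "), "\n")
  cat("Normalized:", x$normalized, "\n")
  invisible(x)
}

#' Min-max normalize a decision table
#'
#' Rescales each attribute to \eqn{[0,1]} by `(x - min) / (max - min)`.
#' Constant attributes (zero range) map to all zeros rather than dividing
#' by zero. Normalization is idempotent; the `normalized` flag records it.
#' The Laplacian-kernel width grid \eqn{\sigma \in [0.05, 1]} is only
#' meaningful on normalized data, so selection normalizes by default.
#'
#' @param table A [decision_table()].
#' @return The table with normalized `values` and `normalized = TRUE`.
#' @export
normalize_table <- function(table) {
  stopifnot(inherits(table, "decision_table"))
  v <- table$values
  rng <- apply(v, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  for (j in seq_len(ncol(v))) {
    v[, j] <- if (span[j] > 0) (v[, j] - rng[1L, j]) / span[j] else 0
  }
  table$values <- v
  table$normalized <- TRUE
  table
}

#' Partition objects by decision label
#'
#' Returns the crisp partition \eqn{\{X_1, \ldots, X_k\}} of the universe
#' induced by the decision attribute: one class of object indices per
#' distinct label, ordered by first appearance of the label.
#'
#' @param table A [decision_table()].
#' @return An object of class `decision_partition`: list with `classes`
#'   (list of integer index vectors) and `class_labels`.
#' @examples
#' dt <- decision_table(matrix(1:6, 3, 2), c("a", "a", "b"))
#' decision_partition(dt)$classes
#' @export
decision_partition <- function(table) {
  stopifnot(inherits(table, "decision_table"))
  idx <- split(seq_along(table$labels), table$labels)
  structure(list(classes = unname(idx), class_labels = names(idx),
                 n = length(table$labels)),
            class = "decision_partition")
}

#' @export
print.decision_partition <- function(x, ...) {
  cat(sprintf("Decision partition: %d class(es) over %d objects\n",
              length(x$classes), x$n))
  invisible(x)
}

#' Load a decision table from a delimited file
#'
#' Reads a CSV/TSV matrix with attribute ids in the first row and object
#' ids in the first column. Labels come either from a designated column of
#' the matrix (`label_col`) or from a separate single-column file
#' (`label_file`).
#'
#' @param matrix_path Path to the CSV (`.csv`) or TSV (otherwise) file.
#' @param label_col Name of the label column inside the matrix.
#' @param label_file Path to a headerless single-column label file;
#'   exactly one of `label_col` / `label_file` must be given.
#' @param normalize Min-max normalize attributes after loading
#'   (default `TRUE`).
#' @param transpose If `TRUE` the file is gene-major (attributes in rows)
#'   and is transposed after reading. `label_col` then refers to a row.
#' @return A [decision_table()].
#' @export
load_decision_table <- function(matrix_path, label_col = NULL,
                                label_file = NULL, normalize = TRUE,
                                transpose = FALSE) {
  if (!file.exists(matrix_path)) stop("input file not found: ", matrix_path)
  if (is.null(label_col) == is.null(label_file)) {
    stop("give exactly one of label_col or label_file")
  }
  sep <- if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                          row.names = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (transpose) df <- as.data.frame(t(as.matrix(df)))

  if (!is.null(label_col)) {
    if (!label_col %in% colnames(df)) {
      stop("label column absent: '", label_col, "'")
    }
    labels <- as.character(df[[label_col]])
    df <- df[, setdiff(colnames(df), label_col), drop = FALSE]
  } else {
    if (!file.exists(label_file)) stop("label file not found: ", label_file)
    labels <- scan(label_file, what = character(), quiet = TRUE)
    if (length(labels) != nrow(df)) {
      stop("label file has ", length(labels), " entries for ",
           nrow(df), " objects")
    }
  }

  non_num <- names(df)[!vapply(df, is.numeric, logical(1L))]
  if (length(non_num)) {
    stop("non-numeric attribute(s): ", paste(non_num, collapse = ", "))
  }
  v <- as.matrix(df)
  if (anyNA(v)) {
    bad <- which(is.na(v), arr.ind = TRUE)
    stop("missing values at: ",
         paste(sprintf("row '%s' col '%s'", rownames(v)[bad[, 1]],
                       colnames(v)[bad[, 2]]), collapse = "; "))
  }
  decision_table(v, labels, normalize = normalize)
}

#' Write a decision table to CSV
#'
#' Inverse of [load_decision_table()]: writes object ids as the first
#' column and appends the labels as a designated column.
#'
#' @param table A [decision_table()].
#' @param path Output CSV path.
#' @param label_col Name for the label column (default `"class"`).
#' @return `path`, invisibly.
#' @export
write_decision_table <- function(table, path, label_col = "class") {
  stopifnot(inherits(table, "decision_table"))
  df <- as.data.frame(table$values, check.names = FALSE)
  df[[label_col]] <- as.character(table$labels)
  df <- cbind(id = table$object_ids, df)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
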