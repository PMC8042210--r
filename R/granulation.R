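#' Laplacian-kernel fuzzy relation matrix
#'
#' Builds the n x n fuzzy similarity relation \eqn{r_{ij} =
#' \exp(-\|x_i - x_j\| / \sigma)} over a subset of attributes, where
#' \eqn{\|\cdot\|} is the Euclidean distance restricted to that subset.
#' Entries lie in \eqn{(0, 1]}, the diagonal is exactly 1 and the matrix
#' is symmetric; row i is the fuzzy set describing how similar every
#' object is to object i. Distances are NOT rescaled by subset size, so
#' the effective granularity of a given sigma depends on how many
#' attributes are in play.
#'
#' @param table A [decision_table()].
#' @param subset Integer vector of attribute (column) indices; must be
#'   nonempty.
#' @param sigma Positive kernel width. On min-max normalized data the
#'   useful range is roughly \eqn{[0.05, 1]}.
#' @return An object of class `fuzzy_relation`: list with `entries`
#'   (n x n matrix), `sigma`, and `attribute_subset`.
#' @examples
#' dt <- decision_table(matrix(runif(15), 5, 3), rep(c("a", "b"), c(2, 3)))
#' R <- laplacian_relation(dt, 1:3, sigma = 0.5)
#' range(R$entries)
#' @export
laplacian_relation <- function(table, subset, sigma) {
  stopifnot(inherits(table, "decision_table"))
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("empty attribute subset")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("nonpositive kernel width")
  }
  if (any(subset < 1L | subset > ncol(table$values))) {
    stop("attribute index out of range")
  }
  d <- as.matrix(stats::dist(table$values[, subset, drop = FALSE]))
  structure(list(entries = exp(-d / sigma), sigma = sigma,
                 attribute_subset = subset),
            class = "fuzzy_relation")
}

#' @export
print.fuzzy_relation <- function(x, ...) {
  cat(sprintf("Fuzzy relation: %d x %d, sigma = %g, |subset| = %d\n",
              nrow(x$entries), ncol(x$entries), x$sigma,
              length(x$attribute_subset)))
  invisible(x)
}

#' Bin index of a membership value
#'
#' The approximately-equal relation compares membership degrees through k
#' equal-width bins of \eqn{[0,1]}: \eqn{[0, 1/k), [1/k, 2/k), \ldots,
#' [(k-1)/k, 1]} (the last interval is closed on the right). Returns the
#' 0-based bin index `floor(value * bins)`, with value 1 mapping to
#' `bins - 1`. Values infinitesimally below a bin boundary land in the
#' lower bin; no epsilon correction is applied.
#'
#' @param value Numeric vector of membership degrees in \eqn{[0,1]}.
#' @param bins Integer number of bins k, at least 2.
#' @return Integer vector of bin indices in `0:(bins - 1)`.
#' @examples
#' bin_index(c(0.49, 0.5, 1), bins = 2) # 0 1 1
#' @export
bin_index <- function(value, bins) {
  bins <- as.integer(bins)
  if (length(bins) != 1L || is.na(bins) || bins < 2L) {
    stop("bins must be >= 2")
  }
  if (any(!is.finite(value)) || any(value < 0 | value > 1)) {
    stop("membership out of range")
  }
  b <- as.integer(floor(value * bins))
  b[b >= bins] <- bins - 1L
  b
}

#' Approximate equality of two fuzzy-set rows
#'
#' Two fuzzy sets (relation rows) are approximately equal at threshold k
#' when their membership values fall in the same of the k bins at every
#' position.
#'
#' @param row_a,row_b Numeric vectors of equal length with entries in
#'   \eqn{[0,1]}.
#' @param bins Integer number of bins k, at least 2.
#' @return `TRUE` or `FALSE`.
#' @export
approx_equal <- function(row_a, row_b, bins) {
  if (length(row_a) != length(row_b)) {
    stop("rows have different lengths")
  }
  all(bin_index(row_a, bins) == bin_index(row_b, bins))
}

#' Granulate the universe by the approximately-equal relation
#'
#' Puts objects i and j in the same fuzzy information granule exactly when
#' their relation rows are approximately equal at threshold `bins`.
#' Because binning each entry induces an equivalence relation on rows, the
#' granules form a partition of the universe; every object is in its own
#' granule (the diagonal entry 1 is approximately equal to itself).
#' Objects are grouped by the signature of their discretized rows, O(n^2).
#'
#' @param R A [laplacian_relation()] result (or any `fuzzy_relation`).
#' @param bins Integer number of bins k, at least 2.
#' @return An object of class `granular_structure`: list with `granules`
#'   (list of integer index vectors, ordered by first member), `granule_of`
#'   (integer map object -> granule), `bins`, and `n`.
#' @examples
#' dt <- decision_table(matrix(runif(16), 8, 2), rep(c("a", "b"), 4))
#' G <- granulate(laplacian_relation(dt, 1:2, 0.5), bins = 3)
#' length(G$granules)
#' @export
granulate <- function(R, bins) {
  stopifnot(inherits(R, "fuzzy_relation"))
  granulate_rows(R$entries, bins)
}

# Shared core: granulation from a raw membership matrix.
granulate_rows <- function(entries, bins) {
  n <- nrow(entries)
  b <- matrix(bin_index(as.numeric(entries), bins), nrow = n)
  sig <- apply(b, 1L, paste, collapse = ",")
  f <- factor(sig, levels = unique(sig))
  granules <- unname(split(seq_len(n), f))
  structure(list(granules = granules,
                 granule_of = as.integer(f),
                 bins = as.integer(bins), n = n),
            class = "granular_structure")
}

# The degenerate granulation used for the empty attribute set: with no
# attributes there is no discernibility, so all objects share one granule.
universal_granulation <- function(n, bins = 2L) {
  structure(list(granules = list(seq_len(n)),
                 granule_of = rep(1L, n),
                 bins = as.integer(bins), n = as.integer(n)),
            class = "granular_structure")
}

#' @export
print.granular_structure <- function(x, ...) {
  sizes <- lengths(x$granules)
  cat(sprintf("Granular structure: %d granule(s) over %d objects (k = %d)\n",
              length(x$granules), x$n, x$bins))
  cat("Granule sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Serialize a granular structure to JSON
#'
#' @param G A [granulate()] result.
#' @param object_ids Optional ids substituted for object indices.
#' @return A JSON string: list of granules as arrays of object ids.
#' @export
granules_to_json <- function(G, object_ids = NULL) {
  stopifnot(inherits(G, "granular_structure"))
  gr <- if (is.null(object_ids)) G$granules
        else lapply(G$granules, function(g) object_ids[g])
  jsonlite::toJSON(list(bins = G$bins, granules = gr), auto_unbox = TRUE)
}
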