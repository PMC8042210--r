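#' Lower approximation of an object set
#'
#' Under a granular structure, the lower approximation of \eqn{X} is the
#' union of all granules entirely contained in \eqn{X}: the objects that
#' certainly belong to \eqn{X} given the available discernibility.
#'
#' @param G A [granulate()] result.
#' @param X Integer vector of object indices (a subset of `1:n`).
#' @return Sorted integer vector of object indices.
#' @export
lower_approximation <- function(G, X) {
  stopifnot(inherits(G, "granular_structure"))
  X <- as.integer(X)
  inside <- vapply(G$granules, function(g) all(g %in% X), logical(1L))
  as.integer(sort(unlist(G$granules[inside], use.names = FALSE)))
}

#' Upper approximation of an object set
#'
#' The union of all granules intersecting \eqn{X}: the objects that
#' possibly belong to \eqn{X}. Always a superset of the lower
#' approximation, and of \eqn{X} itself when \eqn{X} is nonempty.
#'
#' @inheritParams lower_approximation
#' @return Sorted integer vector of object indices.
#' @export
upper_approximation <- function(G, X) {
  stopifnot(inherits(G, "granular_structure"))
  X <- as.integer(X)
  hits <- vapply(G$granules, function(g) any(g %in% X), logical(1L))
  as.integer(sort(unlist(G$granules[hits], use.names = FALSE)))
}

#' Approximation accuracy of an object set
#'
#' The rough-set accuracy \eqn{a(X) = |lower(X)| / |upper(X)|}, in
#' \eqn{[0,1]}. It is 1 when \eqn{X} is crisp under the granulation and 0
#' when no granule fits inside \eqn{X}. Undefined (an error) for empty
#' \eqn{X}; for nonempty \eqn{X} the upper approximation contains \eqn{X},
#' so the denominator is never zero.
#'
#' @inheritParams lower_approximation
#' @return A number in \eqn{[0,1]}.
#' @examples
#' dt <- decision_table(matrix(seq(0, 1, length.out = 6)), rep(c("a", "b"), 3))
#' G <- granulate(laplacian_relation(dt, 1, 0.1), bins = 4)
#' approximate_accuracy(G, c(1, 4))
#' @export
approximate_accuracy <- function(G, X) {
  X <- as.integer(X)
  if (length(X) == 0L) stop("approximate accuracy undefined for empty set")
  length(lower_approximation(G, X)) / length(upper_approximation(G, X))
}

# granule x class contingency counts; the workhorse for both entropies.
granule_class_counts <- function(G, P) {
  stopifnot(inherits(G, "granular_structure"),
            inherits(P, "decision_partition"))
  if (G$n != P$n) stop("granulation and partition cover different universes")
  cls <- integer(P$n)
  for (j in seq_along(P$classes)) cls[P$classes[[j]]] <- j
  cnt <- matrix(0L, nrow = length(G$granules), ncol = length(P$classes))
  for (g in seq_along(G$granules)) {
    t <- tabulate(cls[G$granules[[g]]], nbins = length(P$classes))
    cnt[g, ] <- t
  }
  cnt
}

# Per-class approximation accuracy a_B(X_j), computed from the counts:
# a granule lies inside X_j iff all its members are in class j, and
# intersects X_j iff any member is.
class_accuracies <- function(G, P, cnt = granule_class_counts(G, P)) {
  sizes <- lengths(G$granules)
  vapply(seq_along(P$classes), function(j) {
    lower <- sum(sizes[cnt[, j] == sizes])
    upper <- sum(sizes[cnt[, j] > 0L])
    lower / upper # upper >= |X_j| > 0 since classes are nonempty
  }, numeric(1L))
}

#' Conditional entropy of the decision given a granulation
#'
#' The granule-based conditional entropy
#' \deqn{H(D/B) = -\sum_j \sum_{i=1}^{n}
#'   \frac{|[x_i] \cap X_j|}{n} \log_2 \frac{|[x_i] \cap X_j|}{|[x_i]|}}
#' where the inner sum runs over objects, so each granule is counted once
#' per member. Terms with an empty intersection contribute 0 (the
#' \eqn{0 \log 0 := 0} convention). The value is in bits and is bounded by
#' \eqn{n \log_2 n}, attained exactly when a single granule covers the
#' universe and every decision class is a singleton.
#'
#' @param G A [granulate()] result.
#' @param P A [decision_partition()] over the same objects.
#' @return Nonnegative entropy in bits.
#' @export
conditional_entropy <- function(G, P) {
  cnt <- granule_class_counts(G, P)
  unname(entropies_from_counts(G, P, cnt)["h_conditional"])
}

#' Approximate conditional entropy
#'
#' Like [conditional_entropy()], but every class-\eqn{j} term is damped by
#' the factor \eqn{\log_2(2 - a_B(X_j))}, where \eqn{a_B(X_j)} is the
#' class's approximation accuracy. The weight is 1 when the class has no
#' lower approximation (pure boundary) and 0 when the class is crisp, so
#' the measure blends boundary-region imprecision (algebra view) with
#' information granularity (information view). It is 0 exactly when every
#' granule lies inside a single decision class, and reaches the same
#' \eqn{n \log_2 n} maximum as the conditional entropy.
#'
#' @inheritParams conditional_entropy
#' @return Nonnegative entropy in bits; never exceeds
#'   [conditional_entropy()].
#' @export
approximate_conditional_entropy <- function(G, P) {
  cnt <- granule_class_counts(G, P)
  unname(entropies_from_counts(G, P, cnt)["h_ace"])
}

# Both entropies from one pass over the granule x class counts.
# Per granule g and class j the n_gj > 0 term, summed over the s_g
# members of g, is -s_g * (n_gj / n) * log2(n_gj / s_g).
entropies_from_counts <- function(G, P, cnt) {
  n <- G$n
  sizes <- lengths(G$granules)
  acc <- class_accuracies(G, P, cnt)
  w <- log2(2 - acc)
  h_cond <- 0
  h_ace <- 0
  for (j in seq_along(P$classes)) {
    nz <- cnt[, j] > 0L
    if (!any(nz)) next
    term <- -sum(sizes[nz] * (cnt[nz, j] / n) *
                   log2(cnt[nz, j] / sizes[nz]))
    h_cond <- h_cond + term
    h_ace <- h_ace + w[j] * term
  }
  c(h_conditional = h_cond, h_ace = h_ace)
}

#' Entropy report for a granulation and decision partition
#'
#' @inheritParams conditional_entropy
#' @return An object of class `entropy_report`: list with `h_conditional`,
#'   `h_ace` (both in bits) and `per_class_accuracy`.
#' @export
entropy_report <- function(G, P) {
  cnt <- granule_class_counts(G, P)
  h <- entropies_from_counts(G, P, cnt)
  structure(list(h_conditional = unname(h["h_conditional"]),
                 h_ace = unname(h["h_ace"]),
                 per_class_accuracy = class_accuracies(G, P, cnt)),
            class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  cat(sprintf("H(D/B)     = %.6f bits\nH_ace(D/B) = %.6f bits\n",
              x$h_conditional, x$h_ace))
  cat("Class accuracies:",
      paste(sprintf("%.3f", x$per_class_accuracy), collapse = " "), "\n")
  invisible(x)
}

#' Approximate conditional entropy of a table under an attribute subset
#'
#' Convenience pipeline: Laplacian relation over `subset`, granulation at
#' `bins`, then the approximate conditional entropy against the table's
#' decision partition. The empty subset is legal and uses the universal
#' granulation (a single granule covering all objects): with no attributes
#' there is no discernibility.
#'
#' @param table A [decision_table()].
#' @param subset Integer attribute indices; may be empty.
#' @param sigma Positive kernel width.
#' @param bins Bin count k of the approximately-equal relation.
#' @return Entropy in bits.
#' @export
ace_entropy <- function(table, subset, sigma, bins) {
  P <- decision_partition(table)
  G <- if (length(subset) == 0L) universal_granulation(nrow(table$values), bins)
       else granulate(laplacian_relation(table, subset, sigma), bins)
  unname(approximate_conditional_entropy(G, P))
}

#' Importance of an internal attribute (IIA)
#'
#' The entropy increase caused by removing attribute `c` from the full
#' condition set: \eqn{IIA(c) = H_{ace}(D/(C - \{c\})) - H_{ace}(D/C)}.
#' Attributes with positive IIA are core attributes: no reduct can do
#' without them.
#'
#' @param table A [decision_table()].
#' @param c A single attribute index.
#' @param sigma Kernel width.
#' @param bins Bin count of the approximately-equal relation.
#' @return A real number (0 for redundant attributes, e.g. duplicates).
#' @export
iia <- function(table, c, sigma, bins) {
  m <- ncol(table$values)
  if (m < 2L) stop("cannot remove the only attribute")
  c <- as.integer(c)
  stopifnot(length(c) == 1L, c >= 1L, c <= m)
  full <- seq_len(m)
  ace_entropy(table, setdiff(full, c), sigma, bins) -
    ace_entropy(table, full, sigma, bins)
}

#' Importance of an external attribute (IEA)
#'
#' The entropy drop from adding attribute `d` to the current subset `B`:
#' \eqn{IEA(d, B) = H_{ace}(D/B) - H_{ace}(D/(B \cup \{d\}))}. The greedy
#' forward search adds the attribute with maximal IEA at each step.
#' `B` may be empty (universal-granule convention).
#'
#' @param table A [decision_table()].
#' @param B Integer attribute indices already selected (possibly empty).
#' @param d A single candidate attribute index not in `B`.
#' @param sigma Kernel width.
#' @param bins Bin count of the approximately-equal relation.
#' @return A real number.
#' @export
iea <- function(table, B, d, sigma, bins) {
  d <- as.integer(d)
  B <- as.integer(B)
  stopifnot(length(d) == 1L, d >= 1L, d <= ncol(table$values))
  if (d %in% B) stop("attribute already selected")
  ace_entropy(table, B, sigma, bins) -
    ace_entropy(table, c(B, d), sigma, bins)
}

#' Test whether an attribute subset is a reduct
#'
#' `B` is a reduction of the condition set `C` relative to the decision
#' when (1) it preserves the approximate conditional entropy,
#' \eqn{|H_{ace}(D/B) - H_{ace}(D/C)| \le tol}, and (2) it has no
#' redundancy: removing any attribute of `B` strictly increases the
#' entropy beyond `tol`. For a single-attribute `B` the removal is checked
#' against the empty-set (universal granule) convention.
#'
#' @param table A [decision_table()].
#' @param B Nonempty integer attribute subset.
#' @param sigma Kernel width.
#' @param bins Bin count.
#' @param tol Absolute entropy tolerance (default `1e-10`).
#' @return `TRUE` or `FALSE`.
#' @export
is_reduction <- function(table, B, sigma, bins, tol = 1e-10) {
  B <- as.integer(B)
  stopifnot(length(B) >= 1L)
  full <- seq_len(ncol(table$values))
  h_full <- ace_entropy(table, full, sigma, bins)
  h_b <- ace_entropy(table, B, sigma, bins)
  if (abs(h_b - h_full) > tol) return(FALSE)
  for (b in B) {
    if (ace_entropy(table, setdiff(B, b), sigma, bins) <= h_full + tol) {
      return(FALSE)
    }
  }
  TRUE
}
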