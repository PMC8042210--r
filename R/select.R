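# Internal evaluation engine for repeated entropy queries on one table.
#
# The greedy search evaluates H_ace over many overlapping attribute
# subsets. Per attribute j we precompute the n x n squared-difference
# matrix once; a subset's Euclidean distance matrix is then the square
# root of a sum of cached matrices. An optional memo keyed by the
# discretized-row signature of the induced relation short-circuits
# repeated granulations — entropy depends on the granulation only, so
# results are identical with the cache disabled.
new_ace_engine <- function(table, sigma, bins, use_cache = TRUE) {
  v <- table$values
  e <- new.env(parent = emptyenv())
  e$dsq <- lapply(seq_len(ncol(v)), function(j) {
    d <- outer(v[, j], v[, j], "-")
    d * d
  })
  e$n <- nrow(v)
  e$partition <- decision_partition(table)
  e$sigma <- sigma
  e$bins <- as.integer(bins)
  e$cache <- if (use_cache) new.env(parent = emptyenv()) else NULL
  e$evals <- 0L
  e
}

engine_h_ace <- function(eng, subset) {
  eng$evals <- eng$evals + 1L
  if (length(subset) == 0L) {
    G <- universal_granulation(eng$n, eng$bins)
    return(unname(approximate_conditional_entropy(G, eng$partition)))
  }
  d2 <- eng$dsq[[subset[1L]]]
  for (j in subset[-1L]) d2 <- d2 + eng$dsq[[j]]
  entries <- exp(-sqrt(d2) / eng$sigma)
  G <- granulate_rows(entries, eng$bins)
  if (!is.null(eng$cache)) {
    key <- paste(G$granule_of, collapse = ",")
    hit <- get0(key, envir = eng$cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    h <- unname(approximate_conditional_entropy(G, eng$partition))
    assign(key, h, envir = eng$cache)
    h
  } else {
    unname(approximate_conditional_entropy(G, eng$partition))
  }
}

#' Core attributes of a decision table
#'
#' The core is the set of attributes whose removal from the full condition
#' set strictly increases the approximate conditional entropy, i.e.
#' \eqn{\{c : IIA(c, C, D) > tol\}}. Every reduct contains the core.
#'
#' @param table A [decision_table()].
#' @param sigma Kernel width.
#' @param bins Bin count of the approximately-equal relation.
#' @param tol Positivity threshold on IIA (default `1e-10`).
#' @return Sorted integer vector of core attribute indices (possibly
#'   empty).
#' @export
find_core <- function(table, sigma, bins, tol = 1e-10) {
  stopifnot(inherits(table, "decision_table"))
  m <- ncol(table$values)
  if (m < 2L) return(integer(0L)) # removal would leave nothing to compare
  eng <- new_ace_engine(table, sigma, bins)
  full <- seq_len(m)
  h_full <- engine_h_ace(eng, full)
  iia_vals <- vapply(full, function(c) {
    engine_h_ace(eng, setdiff(full, c)) - h_full
  }, numeric(1L))
  which(iia_vals > tol)
}

#' Greedy forward feature selection by approximate conditional entropy
#'
#' The FSACE search. Starting from the core (or the empty set), the
#' algorithm repeatedly adds the remaining attribute with maximal external
#' importance IEA until the selected subset's approximate conditional
#' entropy matches that of the full attribute set within `tol`. Ties in
#' the argmax go to the lowest attribute index, making the procedure fully
#' deterministic. Guarded termination protects against the cases where
#' exact entropy matching is unreachable: the search also stops when the
#' best IEA is no better than `tol` (once at least one attribute has been
#' selected), when `max_features` is reached, or when every attribute has
#' been taken; `stop_reason` records which.
#'
#' @param table A [decision_table()].
#' @param sigma Positive kernel width of the Laplacian relation.
#' @param bins Bin count k of the approximately-equal relation
#'   (default 4).
#' @param tol Absolute entropy tolerance used for the stopping rule and
#'   core test (default `1e-10`).
#' @param skip_core If `TRUE`, skip the O(n^2 m^2) core computation and
#'   start from the empty set (useful for very wide tables; deviates from
#'   the plain algorithm and is recorded in the result).
#' @param max_features Hard cap on the selected subset size (default: all
#'   attributes).
#' @param normalize Min-max normalize attributes first (default `TRUE`;
#'   a no-op if the table is already normalized).
#' @param prune If `TRUE`, run a backward pass after convergence that
#'   drops attributes whose removal keeps the entropy matched, enforcing
#'   the no-redundancy half of the reduct definition (default `FALSE`:
#'   the plain forward algorithm can return a superset of a reduct).
#' @param use_cache Memoize entropy values by granulation signature
#'   (default `TRUE`; results are identical either way).
#' @return An object of class `fsace_result` with elements `selected`
#'   (ordered attribute indices), `selected_ids`, `core`, `trace` (one row
#'   per greedy step: attribute, IEA, entropy after addition), `h_full`,
#'   `h_selected`, `converged`, `stop_reason` (one of `"entropy-matched"`,
#'   `"no-improvement"`, `"exhausted"`), and `config`.
#' @examples
#' syn <- generate_table(synthetic_spec(n_samples = 30, n_noise = 6, seed = 1))
#' res <- fsace_select(syn$table, sigma = 0.8)
#' res$selected
#' @export
fsace_select <- function(table, sigma, bins = 4L, tol = 1e-10,
                         skip_core = FALSE, max_features = NULL,
                         normalize = TRUE, prune = FALSE,
                         use_cache = TRUE) {
  stopifnot(inherits(table, "decision_table"))
  if (!is.numeric(sigma) || sigma <= 0) stop("nonpositive kernel width")
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be >= 2")
  m <- ncol(table$values)
  if (is.null(max_features)) max_features <- m
  if (max_features < 1L) stop("max_features must be >= 1")
  if (normalize && !table$normalized) table <- normalize_table(table)

  eng <- new_ace_engine(table, sigma, bins, use_cache = use_cache)
  full <- seq_len(m)
  h_full <- engine_h_ace(eng, full)

  # Step 3: the core seeds the subset unless skipped.
  core <- integer(0L)
  if (!skip_core && m >= 2L) {
    iia_vals <- vapply(full, function(c) {
      engine_h_ace(eng, setdiff(full, c)) - h_full
    }, numeric(1L))
    core <- which(iia_vals > tol)
  }

  B <- core
  trace <- list()
  h_b <- engine_h_ace(eng, B)
  converged <- FALSE
  stop_reason <- NULL

  repeat {
    # Step 4: entropy already matched? (an empty B goes straight to the
    # addition step, so at least one attribute is always selected)
    if (length(B) > 0L && abs(h_b - h_full) <= tol) {
      converged <- TRUE
      stop_reason <- "entropy-matched"
      break
    }
    M <- setdiff(full, B)
    if (length(M) == 0L || length(B) >= max_features) {
      stop_reason <- "exhausted"
      break
    }
    # Step 5: argmax of IEA over the remaining attributes.
    h_cand <- vapply(M, function(d) engine_h_ace(eng, c(B, d)), numeric(1L))
    ieas <- h_b - h_cand
    best <- which.max(ieas) # first max = lowest attribute index
    if (length(B) > 0L && ieas[best] <= tol) {
      stop_reason <- "no-improvement"
      break
    }
    B <- c(B, M[best])
    h_b <- h_cand[best]
    trace[[length(trace) + 1L]] <- data.frame(
      attribute = M[best], iea = ieas[best], h_ace = h_b)
  }

  if (prune && converged && length(B) > 1L) {
    # Backward pass: drop attributes whose removal keeps condition 1.
    repeat {
      dropped <- FALSE
      for (b in rev(B)) {
        if (length(B) == 1L) break
        h_wo <- engine_h_ace(eng, setdiff(B, b))
        if (abs(h_wo - h_full) <= tol) {
          B <- setdiff(B, b)
          h_b <- h_wo
          dropped <- TRUE
          break
        }
      }
      if (!dropped) break
    }
  }

  trace <- if (length(trace)) do.call(rbind, trace)
           else data.frame(attribute = integer(0L), iea = numeric(0L),
                           h_ace = numeric(0L))
  structure(list(
    selected = as.integer(B),
    selected_ids = table$attribute_ids[B],
    core = as.integer(core),
    trace = trace,
    h_full = h_full,
    h_selected = h_b,
    converged = converged,
    stop_reason = stop_reason,
    n_entropy_evals = eng$evals,
    config = list(sigma = sigma, bins = bins, tol = tol,
                  skip_core = skip_core, max_features = max_features,
                  normalize = normalize, prune = prune)),
    class = "fsace_result")
}

#' @export
print.fsace_result <- function(x, ...) {
  cat(sprintf("FSACE selection: %d attribute(s) [%s]\n",
              length(x$selected), paste(x$selected, collapse = ", ")))
  cat(sprintf("H_ace(D/C) = %.6g, H_ace(D/B) = %.6g\n",
              x$h_full, x$h_selected))
  cat(sprintf("converged = %s (%s); core = {%s}\n", x$converged,
              x$stop_reason, paste(x$core, collapse = ", ")))
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' Embeds the full run configuration and package version for provenance;
#' re-running with the embedded configuration reproduces the output.
#'
#' @param result An [fsace_select()] result.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly if `path` is given.
#' @export
selection_to_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "fsace_result"))
  payload <- list(
    package = "fsace",
    version = as.character(utils::packageVersion("fsace")),
    config = result$config,
    selected = result$selected,
    selected_ids = result$selected_ids,
    core = result$core,
    h_full = result$h_full,
    h_selected = result$h_selected,
    converged = result$converged,
    stop_reason = result$stop_reason,
    trace = result$trace)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns")
  if (!is.null(path)) {
    writeLines(json, path)
    invisible(json)
  } else {
    json
  }
}
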