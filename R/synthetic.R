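#' Specification for a synthetic decision table
#'
#' Describes a gene-expression-like classification problem: a few
#' class-informative attributes among many pure-noise attributes, tens of
#' samples, and a handful of classes. Defaults mirror the shape of small
#' tumour-subtype expression panels: 60 samples, 3 balanced classes, 2
#' informative attributes whose class means are separated by 6
#' within-class standard deviations, and 20 standard-normal noise
#' attributes.
#'
#' @param n_samples Number of objects (default 60).
#' @param n_classes Number of decision classes (default 3).
#' @param n_informative Number of class-informative attributes
#'   (default 2, must be >= 1).
#' @param n_noise Number of class-independent noise attributes
#'   (default 20).
#' @param effect Class-mean separation in within-class standard deviation
#'   units (default 6, must be > 0).
#' @param class_proportions Simplex vector of class proportions (default
#'   balanced).
#' @param seed Integer RNG seed (default 1).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 60L, n_classes = 3L,
                           n_informative = 2L, n_noise = 20L,
                           effect = 6, class_proportions = NULL,
                           seed = 1L) {
  if (n_informative < 1L) stop("need at least one informative attribute")
  if (!is.numeric(effect) || effect <= 0) stop("effect must be positive")
  if (n_classes < 1L) stop("need at least one class")
  if (is.null(class_proportions)) {
    class_proportions <- rep(1 / n_classes, n_classes)
  }
  if (length(class_proportions) != n_classes ||
      any(class_proportions <= 0) ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must be a positive vector summing to 1")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes),
                 n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise),
                 effect = effect,
                 class_proportions = class_proportions,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Largest-remainder apportionment of n samples to the proportions.
class_sizes <- function(n, proportions) {
  raw <- n * proportions
  sizes <- floor(raw)
  left <- n - sum(sizes)
  if (left > 0L) {
    order_frac <- order(raw - sizes, decreasing = TRUE)
    sizes[order_frac[seq_len(left)]] <- sizes[order_frac[seq_len(left)]] + 1L
  }
  as.integer(sizes)
}

#' Generate a synthetic decision table with known ground truth
#'
#' Informative attribute t shifts the class mean by `effect` within-class
#' standard deviations for every class above a threshold boundary
#' \eqn{p = ((t - 1) \bmod (K - 1)) + 1}: attribute t separates classes
#' \eqn{\{1..p\}} from \eqn{\{p+1..K\}}. With `n_informative <= K - 1`
#' each informative attribute resolves a different class boundary, so ALL
#' of them are needed to discriminate every class — a selection method
#' must recover the full set, not just one strong marker. Noise
#' attributes are standard normal and class-independent. Columns are
#' shuffled deterministically by the seed so ground-truth attributes do
#' not occupy privileged (low, tie-break-favoured) positions.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `table` (a [decision_table()], raw/unnormalized)
#'   and `ground_truth` (sorted indices of the informative attributes).
#' @examples
#' syn <- generate_table(synthetic_spec(seed = 42))
#' syn$ground_truth
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples
  K <- spec$n_classes
  sizes <- class_sizes(n, spec$class_proportions)
  if (any(sizes < 1L)) {
    stop("infeasible class proportions for ", n, " samples: ",
         "every class needs at least one sample")
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  labels <- rep(paste0("class", seq_len(K)), times = sizes)
  cls <- rep(seq_len(K), times = sizes)
  m <- spec$n_informative + spec$n_noise

  values <- matrix(stats::rnorm(n * m), nrow = n, ncol = m)
  for (t in seq_len(spec$n_informative)) {
    p <- if (K > 1L) ((t - 1L) %% (K - 1L)) + 1L else 1L
    shift <- ifelse(cls > p, spec$effect, 0)
    values[, t] <- values[, t] + shift
  }
  perm <- sample.int(m)
  values <- values[, perm, drop = FALSE]
  ground_truth <- sort(match(seq_len(spec$n_informative), perm))

  colnames(values) <- paste0("g", seq_len(m))
  table <- decision_table(values, labels)
  list(table = table, ground_truth = ground_truth)
}
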