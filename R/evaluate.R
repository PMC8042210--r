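# --- classifier backends -------------------------------------------------
#
# The harness mirrors the usual benchmarking trio for expression panels:
# kNN with 3 neighbours, a CART-style decision tree, and an RBF-kernel
# SVM. kNN is delegated to FNN. No CART or SVM package is available in
# the supported dependency set, so both are implemented here: the tree is
# a plain Gini-impurity recursive binary partitioner, and "svm-rbf" is a
# least-squares SVM (one-vs-rest kernel ridge with an RBF kernel, solved
# in closed form) — the LS-SVM variant rather than a hinge-loss QP.

predict_knn3 <- function(train_x, train_y, test_x) {
  k <- min(3L, nrow(train_x))
  FNN::knn(train_x, test_x, train_y, k = k)
}

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0L) return(0)
  1 - sum((counts / n)^2)
}

fit_gini_tree <- function(x, y, depth = 0L, max_depth = 10L,
                          min_split = 5L) {
  counts <- tabulate(y, nbins = nlevels(y))
  majority <- which.max(counts) # tie -> lowest class index
  if (depth >= max_depth || nrow(x) < min_split || gini_impurity(counts) == 0) {
    return(list(leaf = TRUE, class = majority))
  }
  n <- nrow(x)
  best <- list(gain = 0)
  parent <- gini_impurity(counts)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    uv <- sort(unique(v))
    if (length(uv) < 2L) next
    cuts <- (uv[-1L] + uv[-length(uv)]) / 2
    for (cut in cuts) {
      left <- v <= cut
      nl <- sum(left)
      if (nl == 0L || nl == n) next
      gl <- gini_impurity(tabulate(y[left], nbins = nlevels(y)))
      gr <- gini_impurity(tabulate(y[!left], nbins = nlevels(y)))
      gain <- parent - (nl * gl + (n - nl) * gr) / n
      if (gain > best$gain + 1e-12) {
        best <- list(gain = gain, feature = j, cut = cut)
      }
    }
  }
  if (best$gain <= 0) return(list(leaf = TRUE, class = majority))
  left <- x[, best$feature] <= best$cut
  list(leaf = FALSE, feature = best$feature, cut = best$cut,
       class = majority,
       left = fit_gini_tree(x[left, , drop = FALSE], y[left],
                            depth + 1L, max_depth, min_split),
       right = fit_gini_tree(x[!left, , drop = FALSE], y[!left],
                             depth + 1L, max_depth, min_split))
}

predict_gini_tree <- function(tree, x) {
  apply(x, 1L, function(row) {
    node <- tree
    while (!node$leaf) {
      node <- if (row[node$feature] <= node$cut) node$left else node$right
    }
    node$class
  })
}

predict_cart <- function(train_x, train_y, test_x) {
  tree <- fit_gini_tree(train_x, train_y)
  factor(levels(train_y)[predict_gini_tree(tree, test_x)],
         levels = levels(train_y))
}

# One-vs-rest least-squares SVM with RBF (Gaussian) kernel. gamma follows
# the common 1/m default; the ridge parameter trades margin for fit.
predict_lssvm_rbf <- function(train_x, train_y, test_x,
                              gamma = NULL, ridge = 0.1) {
  if (is.null(gamma)) gamma <- 1 / ncol(train_x)
  d2_tr <- as.matrix(stats::dist(train_x))^2
  K <- exp(-gamma * d2_tr)
  Y <- vapply(levels(train_y),
              function(l) ifelse(train_y == l, 1, -1), numeric(nrow(K)))
  alpha <- solve(K + diag(ridge, nrow(K)), Y)
  cross <- vapply(seq_len(nrow(test_x)), function(i) {
    colSums((t(train_x) - test_x[i, ])^2)
  }, numeric(nrow(train_x))) # n_train x n_test squared distances
  scores <- t(exp(-gamma * cross)) %*% alpha
  factor(levels(train_y)[max.col(scores, ties.method = "first")],
         levels = levels(train_y))
}

classifier_fun <- function(classifier) {
  switch(classifier,
         knn3 = predict_knn3,
         cart = predict_cart,
         `svm-rbf` = predict_lssvm_rbf,
         stop("unknown classifier: ", classifier))
}

# Stratified fold assignment: within each class, shuffled indices are
# dealt round-robin so every fold sees every class.
stratified_folds <- function(labels, folds, seed) {
  counts <- tabulate(labels)
  if (any(counts < folds)) {
    small <- levels(labels)[which.min(counts)]
    stop("class '", small, "' has ", min(counts), " sample(s), fewer than ",
         folds, " folds; reduce the number of folds")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  fold_of <- integer(length(labels))
  for (l in levels(labels)) {
    idx <- sample(which(labels == l))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_of
}

#' Stratified cross-validated accuracy of an attribute subset
#'
#' Evaluates how well a selected attribute subset supports classification:
#' stratified k-fold cross-validation, accuracy averaged over folds.
#' Classifiers: `"knn3"` (3-nearest-neighbour), `"cart"` (Gini decision
#' tree), `"svm-rbf"` (RBF-kernel least-squares SVM); all other settings
#' are the harness defaults documented in the backend code.
#'
#' @param table A [decision_table()].
#' @param subset Nonempty integer vector of attribute indices.
#' @param classifier One of `"knn3"`, `"cart"`, `"svm-rbf"`.
#' @param folds Number of folds (default 10); every class must have at
#'   least `folds` samples.
#' @param seed Integer seed for the fold assignment.
#' @return Mean accuracy in \eqn{[0,1]}.
#' @export
cross_validate <- function(table, subset, classifier = "knn3",
                           folds = 10L, seed = 1L) {
  stopifnot(inherits(table, "decision_table"))
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("empty attribute subset")
  if (folds < 2L) stop("folds must be >= 2")
  classifier <- match.arg(classifier, c("knn3", "cart", "svm-rbf"))
  fun <- classifier_fun(classifier)
  x <- table$values[, subset, drop = FALSE]
  y <- table$labels
  if (nlevels(y) == 1L) return(1) # degenerate: a constant rule is perfect
  fold_of <- stratified_folds(y, folds, seed)
  accs <- vapply(seq_len(folds), function(f) {
    test <- fold_of == f
    pred <- fun(x[!test, , drop = FALSE], y[!test], x[test, , drop = FALSE])
    mean(as.character(pred) == as.character(y[test]))
  }, numeric(1L))
  mean(accs)
}

#' Sigma sweep: selection plus evaluation over a kernel-width grid
#'
#' Runs [fsace_select()] at each kernel width in `grid` and scores every
#' selected subset by stratified cross-validation, producing the records
#' needed for accuracy-versus-sigma curves. The kernel width controls how
#' coarsely objects are granulated, and with it both the size and the
#' quality of the selected subset, so it is swept rather than fixed.
#'
#' @param table A [decision_table()].
#' @param grid Numeric vector of positive kernel widths.
#' @param bins Bin count (default 4).
#' @param tol Entropy tolerance (default `1e-10`).
#' @param classifiers Character vector out of `"knn3"`, `"cart"`,
#'   `"svm-rbf"` (default `"knn3"`).
#' @param folds Cross-validation folds (default 3; desk-scale tables are
#'   small).
#' @param seed Fold-assignment seed.
#' @param max_features Cap passed to [fsace_select()].
#' @return A data frame with one row per sigma: `sigma`, `n_selected`,
#'   `selected` (comma-separated indices), `converged`, and one
#'   `accuracy_<classifier>` column per classifier.
#' @export
sigma_sweep <- function(table, grid, bins = 4L, tol = 1e-10,
                        classifiers = "knn3", folds = 3L, seed = 1L,
                        max_features = NULL) {
  if (length(grid) == 0L || any(grid <= 0)) {
    stop("sigma grid must be nonempty and positive")
  }
  rows <- lapply(grid, function(sg) {
    res <- fsace_select(table, sigma = sg, bins = bins, tol = tol,
                        max_features = max_features)
    rec <- data.frame(sigma = sg, n_selected = length(res$selected),
                      selected = paste(res$selected, collapse = ","),
                      converged = res$converged)
    for (cl in classifiers) {
      rec[[paste0("accuracy_", gsub("-", "_", cl))]] <-
        cross_validate(table, res$selected, cl, folds = folds, seed = seed)
    }
    rec
  })
  do.call(rbind, rows)
}

#' Choose a kernel width by a coarse sweep
#'
#' Desk-scale version of the usual protocol: sweep a coarse sigma grid,
#' evaluate each selected subset by cross-validated kNN accuracy, and keep
#' the width with the highest accuracy (ties go to the smaller sigma,
#' which granulates more finely).
#'
#' @param table A [decision_table()].
#' The default grid is log-spaced rather than the linear experimental
#' grid used on full-scale expression matrices: because subset distances
#' are not rescaled by subset size, the width that granulates a single
#' normalized attribute coarsely (around 2-4) is far larger than the one
#' suited to many-attribute subsets, and a coarse sweep must span both
#' regimes.
#'
#' @param grid Candidate widths (default `c(0.25, 0.5, 1, 2, 4)`).
#' @param ... Passed to [sigma_sweep()].
#' @return The chosen sigma (a single number).
#' @export
choose_sigma <- function(table, grid = c(0.25, 0.5, 1, 2, 4), ...) {
  sweep <- sigma_sweep(table, sort(grid), ...)
  acc_col <- grep("^accuracy_", names(sweep), value = TRUE)[1L]
  sweep$sigma[which.max(sweep[[acc_col]])]
}
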