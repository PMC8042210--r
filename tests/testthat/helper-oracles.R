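# Independent brute-force oracles. These are literal transcriptions of the
# defining formulas, written against plain vectors/lists so they share no
# code path with the package implementations they check.

oracle_laplacian <- function(values, subset, sigma) {
  n <- nrow(values)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- sqrt(sum((values[i, subset] - values[j, subset])^2))
      out[i, j] <- exp(-d / sigma)
    }
  }
  out
}

oracle_bin <- function(v, k) {
  if (v >= 1) k - 1L else as.integer(floor(v * k))
}

oracle_rows_equal <- function(a, b, k) {
  for (t in seq_along(a)) {
    if (oracle_bin(a[t], k) != oracle_bin(b[t], k)) return(FALSE)
  }
  TRUE
}

# Pairwise closure: granule label per object, first-occurrence order.
oracle_granulate <- function(entries, k) {
  n <- nrow(entries)
  lab <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    hit <- 0L
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        if (oracle_rows_equal(entries[i, ], entries[j, ], k)) {
          hit <- lab[j]
          break
        }
      }
    }
    if (hit == 0L) {
      nxt <- nxt + 1L
      hit <- nxt
    }
    lab[i] <- hit
  }
  lab
}

# Per-object membership tests for the approximations.
oracle_lower <- function(granule_of, X) {
  n <- length(granule_of)
  which(vapply(seq_len(n), function(x) {
    all(which(granule_of == granule_of[x]) %in% X)
  }, logical(1L)))
}

oracle_upper <- function(granule_of, X) {
  n <- length(granule_of)
  which(vapply(seq_len(n), function(x) {
    any(which(granule_of == granule_of[x]) %in% X)
  }, logical(1L)))
}

oracle_accuracy <- function(granule_of, X) {
  length(oracle_lower(granule_of, X)) / length(oracle_upper(granule_of, X))
}

# Literal double loop over classes j and objects i.
oracle_h_cond <- function(granule_of, classes) {
  n <- length(granule_of)
  h <- 0
  for (j in seq_along(classes)) {
    for (i in seq_len(n)) {
      gi <- which(granule_of == granule_of[i])
      nij <- length(intersect(gi, classes[[j]]))
      if (nij > 0L) h <- h - (nij / n) * log2(nij / length(gi))
    }
  }
  h
}

# Composes the accuracy oracle with the per-term weight, term by term.
oracle_h_ace <- function(granule_of, classes) {
  n <- length(granule_of)
  h <- 0
  for (j in seq_along(classes)) {
    w <- log2(2 - oracle_accuracy(granule_of, classes[[j]]))
    for (i in seq_len(n)) {
      gi <- which(granule_of == granule_of[i])
      nij <- length(intersect(gi, classes[[j]]))
      if (nij > 0L) h <- h - w * (nij / n) * log2(nij / length(gi))
    }
  }
  h
}

# --- fixture builders ----------------------------------------------------

make_granulation <- function(granules, n = max(unlist(granules)),
                             bins = 2L) {
  granule_of <- integer(n)
  for (g in seq_along(granules)) granule_of[granules[[g]]] <- g
  structure(list(granules = lapply(granules, as.integer),
                 granule_of = granule_of, bins = as.integer(bins),
                 n = as.integer(n)),
            class = "granular_structure")
}

make_partition <- function(classes, n = max(unlist(classes))) {
  structure(list(classes = lapply(classes, as.integer),
                 class_labels = paste0("c", seq_along(classes)),
                 n = as.integer(n)),
            class = "decision_partition")
}

# Random set partition of 1:n into at most `blocks` nonempty parts.
random_blocks <- function(n, blocks) {
  lab <- sample.int(blocks, n, replace = TRUE)
  lab <- as.integer(factor(lab, levels = unique(lab)))
  split(seq_len(n), lab)
}

random_table <- function(n = 10L, m = 3L, n_classes = 2L) {
  labels <- sample(letters[seq_len(n_classes)], n, replace = TRUE)
  # guarantee every class appears
  labels[seq_len(n_classes)] <- letters[seq_len(n_classes)]
  decision_table(matrix(runif(n * m), n, m), labels)
}

# Canonical relabeling so two granulations compare as partitions.
canon <- function(granule_of) as.integer(factor(granule_of,
                                                levels = unique(granule_of)))
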