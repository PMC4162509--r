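# Test helpers: independent brute-force oracles and random-instance
# generators. The oracles deliberately recompute everything from first
# principles (no Lance-Williams updates, no dynamic programming) so they
# stay independent of the code paths they check.

# random monotone merge tree with random orientation
random_merge_tree <- function(n, seed) {
  set.seed(seed)
  ids <- seq_len(n)
  h <- sort(stats::runif(n - 1L, 0.1, 10))
  child_a <- integer(n - 1L); child_b <- integer(n - 1L)
  for (m in seq_len(n - 1L)) {
    pick <- sample(length(ids), 2L)
    child_a[m] <- ids[pick[1L]]; child_b[m] <- ids[pick[2L]]
    ids <- c(ids[-pick], n + m)
  }
  tb <- data.frame(child_a = child_a - 1L, child_b = child_b - 1L, height = h)
  from_merge_table(tb, labels = paste0("L", seq_len(n)))
}

# random symmetric distance matrix over given labels
random_distance_matrix <- function(labels, seed) {
  set.seed(seed)
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- stats::runif(n * (n - 1L) / 2L, 0.05, 5)
  m + t(m)
}

# multiset of (subtree leaf set, height) pairs: the part of a tree that
# ordering methods must never touch
tree_signature <- function(tree) {
  tb <- to_merge_table(tree)
  n <- length(attr(tb, "labels"))
  sets <- c(as.list(seq_len(n) - 1L), vector("list", n - 1L))
  sig <- character(n - 1L)
  for (m in seq_len(n - 1L)) {
    s <- sort(c(sets[[tb$child_a[m] + 1L]], sets[[tb$child_b[m] + 1L]]))
    sets[[n + m]] <- s
    sig[m] <- paste(format(tb$height[m], digits = 15),
                    paste(s, collapse = ","))
  }
  sort(sig)
}

# per-node integer leaf-id sequences, recomputed directly from the table
leaf_sequences_oracle <- function(tree) {
  tb <- to_merge_table(tree)
  n <- length(attr(tb, "labels"))
  seqs <- c(as.list(seq_len(n)), vector("list", n - 1L))
  for (m in seq_len(n - 1L)) {
    seqs[[n + m]] <- c(seqs[[tb$child_a[m] + 1L]], seqs[[tb$child_b[m] + 1L]])
  }
  seqs
}

# agglomerative clustering recomputing every cluster distance from scratch
# over the original pairwise matrix (O(n^3) per merge; oracle only)
naive_linkage <- function(d, linkage) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  ids <- seq_len(n)
  heights <- numeric(n - 1L)
  merge_sets <- vector("list", n - 1L)
  for (m in seq_len(n - 1L)) {
    k <- length(members)
    best <- Inf; besta <- Inf; bestb <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        pair <- d[members[[i]], members[[j]], drop = FALSE]
        v <- switch(linkage, single = min(pair), complete = max(pair),
                    average = mean(pair))
        a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
        if (v < best - 1e-12 ||
            (abs(v - best) <= 1e-12 && (a < besta ||
                                        (a == besta && b < bestb)))) {
          best <- v; besta <- a; bestb <- b; bi <- i; bj <- j
        }
      }
    }
    heights[m] <- best
    newset <- sort(c(members[[bi]], members[[bj]]))
    merge_sets[[m]] <- newset
    members <- c(members[-c(bi, bj)], list(newset))
    ids <- c(ids[-c(bi, bj)], n + m)
  }
  list(heights = heights, merge_sets = merge_sets)
}

# leaf sets of every merge of a tree, in merge order, as sorted leaf ids
merge_leaf_sets <- function(tree) {
  seqs <- leaf_sequences_oracle(tree)
  n <- tree$n
  lapply(seq_len(n - 1L), function(m) sort(seqs[[n + m]]))
}

# Hamiltonian path length computed straight from the definition
path_length_oracle <- function(d, order) {
  idx <- match(order, rownames(d))
  s <- 0
  for (i in seq_len(length(idx) - 1L)) s <- s + d[idx[i], idx[i + 1L]]
  s
}

# anti-Robinson events by literal triple scan
anti_robinson_oracle <- function(d, order) {
  idx <- match(order, rownames(d))
  D <- d[idx, idx]
  n <- nrow(D)
  ev <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && j < k) {
      if (D[i, j] > D[i, k]) ev <- ev + 1L
      if (D[j, k] > D[i, k]) ev <- ev + 1L
    }
  }
  ev
}
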