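# Leaf-ordering methods. Every method returns a tree with identical
# topology and heights; only the left/right orientation of internal nodes
# changes, selecting one of the 2^(n-1) admissible leaf orders.

# swap children at the rows where `swap` is TRUE
swap_rows <- function(tree, swap) {
  if (any(swap)) {
    tmp <- tree$left[swap]
    tree$left[swap] <- tree$right[swap]
    tree$right[swap] <- tmp
  }
  tree
}

#' Per-subtree merge-distance keys
#'
#' For each internal node, the statistic the modular ordering compares:
#' under `criterion = "min"` the smallest merge height anywhere in the
#' subtree (including the node's own), under `"avg"` the arithmetic mean of
#' all merge heights in the subtree. Leaves have no merges and carry the
#' sentinel `+Inf`, which is what pushes a lone leaf to the right of any
#' subtree it joins.
#'
#' @param tree a `merge_tree`.
#' @param criterion `"min"` or `"avg"`.
#' @return Numeric vector of length `2n-1` indexed by node id (leaves first,
#'   then internal nodes in merge order); leaf entries are `Inf`.
#' @export
subtree_keys <- function(tree, criterion = c("min", "avg")) {
  criterion <- match.arg(criterion)
  n <- tree$n
  key <- rep(Inf, 2L * n - 1L)
  if (criterion == "min") {
    for (m in seq_len(n - 1L)) {
      key[n + m] <- min(tree$height[m],
                        key[tree$left[m]], key[tree$right[m]])
    }
  } else {
    hsum <- numeric(2L * n - 1L)
    cnt <- integer(2L * n - 1L)
    for (m in seq_len(n - 1L)) {
      id <- n + m
      hsum[id] <- tree$height[m] + hsum[tree$left[m]] + hsum[tree$right[m]]
      cnt[id] <- 1L + cnt[tree$left[m]] + cnt[tree$right[m]]
      key[id] <- hsum[id] / cnt[id]
    }
  }
  key
}

#' Default dendrogram orientation
#'
#' Re-orients every merge according to the three conventional rules of
#' standard hierarchical-clustering dendrograms: (1) when two leaves merge,
#' the one earlier in the input data matrix goes left; (2) when a leaf
#' merges with a subtree, the leaf goes left; (3) when two subtrees merge,
#' the one whose own merge happened at the smaller distance goes left (ties
#' keep the current orientation). Topology and heights are untouched.
#'
#' @param tree a `merge_tree` (leaf ids are the input indices).
#' @return The re-oriented `merge_tree`.
#' @export
order_default <- function(tree) {
  stopifnot(is_merge_tree(tree))
  n <- tree$n
  swap <- logical(n - 1L)
  for (m in seq_len(n - 1L)) {
    l <- tree$left[m]; r <- tree$right[m]
    l_leaf <- l <= n; r_leaf <- r <= n
    if (l_leaf && r_leaf) {
      swap[m] <- l > r            # input order: smaller index left
    } else if (l_leaf || r_leaf) {
      swap[m] <- !l_leaf          # the leaf goes left
    } else {
      swap[m] <- tree$height[l - n] > tree$height[r - n]
    }
  }
  swap_rows(tree, swap)
}

#' Modular leaf ordering
#'
#' Re-orients every merge so that the subtree containing the smaller
#' preceding merge distance sits on the left: at each internal node the
#' children are swapped iff `key(left) > key(right)`, where the key is the
#' minimum (`criterion = "min"`) or mean (`"avg"`) of all merge heights in
#' the child's subtree and a bare leaf scores `+Inf`. The infinite leaf key
#' realizes the companion rule that a leaf joining a subtree is placed on
#' the right, and makes each subtree grow left-to-right in merge order,
#' giving the dendrogram its characteristic right-triangular silhouettes.
#' Ties (including leaf-leaf merges) keep the existing orientation, so the
#' operation is deterministic and idempotent.
#'
#' @param tree a `merge_tree`.
#' @param criterion `"min"` (smallest preceding merge distance) or `"avg"`
#'   (average of preceding merge distances, which prioritizes tight clusters
#'   over clusters that merely contain one tight pair).
#' @return The re-oriented `merge_tree`; afterwards every internal node
#'   satisfies `key(left) <= key(right)`.
#' @examples
#' tb <- data.frame(child_a = c(2, 0, 4), child_b = c(3, 1, 5),
#'                  height = c(2, 1, 5))
#' tree <- from_merge_table(tb, labels = c("A", "B", "C", "D"))
#' leaf_order(order_molo(tree))  # tightest pair A,B moves left
#' @export
order_molo <- function(tree, criterion = c("min", "avg")) {
  criterion <- match.arg(criterion)
  stopifnot(is_merge_tree(tree))
  key <- subtree_keys(tree, criterion)
  swap <- key[tree$left] > key[tree$right]
  swap[!is.finite(key[tree$left]) & !is.finite(key[tree$right])] <- FALSE
  swap_rows(tree, swap)
}

#' Endpoint-greedy leaf ordering (Gruvaeus-Wainer style)
#'
#' Bottom-up greedy orientation: each subtree exposes its leftmost and
#' rightmost leaves; at every internal node the four combinations of
#' mirroring either child are scored by the distance between the two leaves
#' that become adjacent across the join, and a combination with the smallest
#' inner-pair distance is kept. Ties prefer no mirror, then mirroring only
#' the left child, then only the right, then both.
#'
#' @param tree a `merge_tree`.
#' @param d distance matrix whose labels cover the tree's leaf labels.
#' @return The re-oriented `merge_tree`.
#' @export
order_gw <- function(tree, d) {
  stopifnot(is_merge_tree(tree))
  d <- as.matrix(d)
  idx <- dist_index(tree, d)
  n <- tree$n
  first <- integer(2L * n - 1L); last <- integer(2L * n - 1L)
  first[1:n] <- 1:n; last[1:n] <- 1:n
  fl <- logical(n - 1L); fr <- logical(n - 1L)  # mirror child subtree?
  for (m in seq_len(n - 1L)) {
    l <- tree$left[m]; r <- tree$right[m]
    # candidate (mirror_left, mirror_right) in tie-preference order
    combos <- list(c(FALSE, FALSE), c(TRUE, FALSE),
                   c(FALSE, TRUE), c(TRUE, TRUE))
    best <- Inf; choice <- combos[[1L]]
    for (cb in combos) {
      inner_l <- if (cb[1L]) first[l] else last[l]
      inner_r <- if (cb[2L]) last[r] else first[r]
      sc <- d[idx[inner_l], idx[inner_r]]
      if (sc < best) { best <- sc; choice <- cb }
    }
    fl[m] <- choice[1L]; fr[m] <- choice[2L]
    first[n + m] <- if (fl[m]) last[l] else first[l]
    last[n + m] <- if (fr[m]) first[r] else last[r]
  }
  # A mirrored subtree swaps the children of every node it contains; the
  # final swap state of a node is the XOR of the mirror flags on its
  # root path (including the flag on the edge into the node itself).
  s <- logical(2L * n - 1L)
  for (m in rev(seq_len(n - 1L))) {
    id <- n + m
    s[tree$left[m]] <- xor(s[id], fl[m])
    s[tree$right[m]] <- xor(s[id], fr[m])
  }
  swap_rows(tree, s[(n + 1L):(2L * n - 1L)])
}

#' Optimal leaf ordering
#'
#' Exact minimization of the Hamiltonian path length (sum of distances
#' between consecutive leaves) over all `2^(n-1)` orientations of the tree,
#' by the standard dynamic program over states (subtree, leftmost leaf,
#' rightmost leaf). The tree constraint is respected: only orders obtainable
#' by flipping merges are considered. Ties resolve toward the input
#' orientation.
#'
#' @param tree a `merge_tree`.
#' @param d distance matrix whose labels cover the tree's leaf labels.
#' @param max_leaves guard for the cubic dynamic program (default 2000).
#' @return The re-oriented `merge_tree`, with the achieved minimum path
#'   length in `attr(, "path_length")`.
#' @export
order_olo <- function(tree, d, max_leaves = 2000L) {
  stopifnot(is_merge_tree(tree))
  n <- tree$n
  if (n > max_leaves) {
    stop("optimal leaf ordering is cubic in n; n = ", n, " exceeds the cap ",
         max_leaves, " (consider the modular or endpoint-greedy methods)",
         call. = FALSE)
  }
  d <- as.matrix(d)
  idx <- dist_index(tree, d)
  D <- d[idx, idx, drop = FALSE]   # leaf-id indexed distances
  seqs <- subtree_sequences(tree)
  # per node: cross cost matrix C (rows = left-child leaves, cols =
  # right-child leaves) and argmin backpointers
  C <- vector("list", 2L * n - 1L)
  BM <- vector("list", 2L * n - 1L)  # chosen m (left child's right endpoint)
  BK <- vector("list", 2L * n - 1L)  # chosen k (right child's left endpoint)
  # full endpoint-cost matrix over a subtree's leaves
  full_cost <- function(id) {
    if (id <= n) return(matrix(0, 1L, 1L, dimnames = list(id, id)))
    m <- id - n
    A <- seqs[[tree$left[m]]]; B <- seqs[[tree$right[m]]]
    all <- c(A, B)
    FM <- matrix(Inf, length(all), length(all),
                 dimnames = list(all, all))
    FM[seq_along(A), length(A) + seq_along(B)] <- C[[id]]
    FM[length(A) + seq_along(B), seq_along(A)] <- t(C[[id]])
    if (length(all) == 1L) FM[1L, 1L] <- 0
    FM
  }
  for (m in seq_len(n - 1L)) {
    id <- n + m
    l <- tree$left[m]; r <- tree$right[m]
    A <- seqs[[l]]; B <- seqs[[r]]
    FL <- full_cost(l); FR <- full_cost(r)
    dAB <- D[A, B, drop = FALSE]
    na <- length(A); nb <- length(B)
    Cm <- matrix(0, na, nb)
    Bm <- matrix(0L, na, nb); Bk <- matrix(0L, na, nb)
    for (ai in seq_len(na)) {
      # best right endpoint m of the left block, per junction leaf k
      t1 <- FL[ai, ] + dAB                 # |A| x |B|: cost to m plus d(m,k)
      mstar <- max.col(-t(t1), ties.method = "first")   # per k, argmin over m
      u <- t1[cbind(mstar, seq_len(nb))]
      # best junction k, per final endpoint r of the right block
      t2 <- u + FR                          # |B| x |B|
      kstar <- max.col(-t(t2), ties.method = "first")
      Cm[ai, ] <- t2[cbind(kstar, seq_len(nb))]
      Bm[ai, ] <- A[mstar[kstar]]
      Bk[ai, ] <- B[kstar]
    }
    dimnames(Cm) <- list(A, B)
    C[[id]] <- Cm; BM[[id]] <- Bm; BK[[id]] <- Bk
  }
  root <- 2L * n - 1L
  Cr <- C[[root]]
  if (n == 1L) return(tree)
  best <- which(Cr == min(Cr), arr.ind = TRUE)[1L, ]
  lstar <- seqs[[tree$left[n - 1L]]][best[1L]]
  rstar <- seqs[[tree$right[n - 1L]]][best[2L]]
  realize <- function(id, a, b) {
    if (id <= n) return(id)
    m <- id - n
    A <- seqs[[tree$left[m]]]; B <- seqs[[tree$right[m]]]
    if (a %in% A) {
      ai <- match(a, A); bi <- match(b, B)
      mid <- BM[[id]][ai, bi]; kid <- BK[[id]][ai, bi]
      c(realize(tree$left[m], a, mid), realize(tree$right[m], kid, b))
    } else {
      rev(realize(id, b, a))
    }
  }
  target <- realize(root, lstar, rstar)
  out <- reorient_to_order(tree, target)
  attr(out, "path_length") <- min(Cr)
  out
}

# map leaf id -> row index into the distance matrix; errors on missing labels
dist_index <- function(tree, d) {
  labs <- rownames(d)
  if (is.null(labs)) stop("distance matrix must carry labels", call. = FALSE)
  idx <- match(tree$labels, labs)
  if (anyNA(idx)) {
    stop("labels missing from distance matrix: ",
         paste(tree$labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' Re-orient a tree to match a target leaf order
#'
#' Given a leaf order achievable by flipping merges, swaps children wherever
#' needed so that `leaf_order(result)` equals the target.
#'
#' @param tree a `merge_tree`.
#' @param target integer vector of leaf ids or character vector of labels.
#' @return The re-oriented `merge_tree`.
#' @export
reorient_to_order <- function(tree, target) {
  n <- tree$n
  if (is.character(target)) {
    target <- match(target, tree$labels)
    if (anyNA(target)) stop("target contains unknown labels", call. = FALSE)
  }
  if (!identical(sort(as.integer(target)), seq_len(n))) {
    stop("target is not a permutation of the leaves", call. = FALSE)
  }
  pos <- integer(n); pos[target] <- seq_len(n)
  minpos <- rep(Inf, 2L * n - 1L)
  minpos[1:n] <- pos
  swap <- logical(n - 1L)
  for (m in seq_len(n - 1L)) {
    l <- tree$left[m]; r <- tree$right[m]
    swap[m] <- minpos[l] > minpos[r]
    minpos[n + m] <- min(minpos[l], minpos[r])
  }
  out <- swap_rows(tree, swap)
  if (!identical(leaf_order_ids(out), as.integer(target))) {
    stop("target order is not achievable by flipping merges", call. = FALSE)
  }
  out
}

#' All leaf orders reachable by flipping merges
#'
#' Exhaustively enumerates the `2^(n-1)` orientation assignments of a tree.
#' Intended as a small-n oracle for the ordering heuristics.
#'
#' @param tree a `merge_tree` with at most `max_leaves` leaves.
#' @param max_leaves enumeration guard (default 16).
#' @return List of character vectors (leaf label orders).
#' @export
enumerate_flip_orders <- function(tree, max_leaves = 16L) {
  stopifnot(is_merge_tree(tree))
  n <- tree$n
  if (n > max_leaves) {
    stop("enumeration is exponential; n = ", n, " exceeds the cap ",
         max_leaves, call. = FALSE)
  }
  if (n == 1L) return(list(tree$labels))
  orders <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) orders[[i]] <- list(i)
  for (m in seq_len(n - 1L)) {
    lo <- orders[[tree$left[m]]]; ro <- orders[[tree$right[m]]]
    acc <- vector("list", 2L * length(lo) * length(ro))
    k <- 0L
    for (x in lo) for (y in ro) {
      acc[[k + 1L]] <- c(x, y)
      acc[[k + 2L]] <- c(y, x)
      k <- k + 2L
    }
    orders[[n + m]] <- acc
  }
  lapply(orders[[2L * n - 1L]], function(ids) tree$labels[ids])
}

#' Apply a leaf-ordering method by name
#'
#' Dispatcher used by the command-line interface and the benchmarking
#' helpers. Method names: `"default"`, `"molo-min"`, `"molo-avg"`, `"gw"`,
#' `"olo"`.
#'
#' @param tree a `merge_tree`.
#' @param method method name.
#' @param d distance matrix; required for `"gw"` and `"olo"`.
#' @return The re-oriented `merge_tree`.
#' @export
apply_ordering <- function(tree,
                           method = c("default", "molo-min", "molo-avg",
                                      "gw", "olo"),
                           d = NULL) {
  method <- match.arg(method)
  if (method %in% c("gw", "olo") && is.null(d)) {
    stop("method '", method, "' needs a distance matrix", call. = FALSE)
  }
  switch(method,
    "default" = order_default(tree),
    "molo-min" = order_molo(tree, "min"),
    "molo-avg" = order_molo(tree, "avg"),
    "gw" = order_gw(tree, d),
    "olo" = order_olo(tree, d)
  )
}
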