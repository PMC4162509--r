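# Merge-tree data model: a rooted, strictly binary tree recording the n-1
# merges of an agglomerative clustering, with heights on internal nodes.
#
# Node ids (1-based, internal representation):
#   leaves    1 .. n      -- in input-matrix order; the leaf id IS the input index
#   internal  n+1 .. 2n-1 -- in merge order; internal node n+m is described by
#                            row m of (left, right, height)
# Child order (left before right) is significant: it encodes the orientation
# of the dendrogram, which is what the ordering methods manipulate.
# The external merge-table serialization uses the common 0-based linkage
# convention (leaves 0..n-1, merges n..2n-3).

new_merge_tree <- function(labels, left, right, height) {
  structure(
    list(
      n = length(labels),
      labels = as.character(labels),
      left = as.integer(left),
      right = as.integer(right),
      height = as.numeric(height)
    ),
    class = "merge_tree"
  )
}

is_merge_tree <- function(x) inherits(x, "merge_tree")

#' Construct a merge tree from explicit merge rows
#'
#' Builds the binary merge tree of an agglomerative clustering from its
#' merge table: row m records that the clusters with ids `child_a[m]` and
#' `child_b[m]` were joined at dissimilarity `height[m]`. Ids follow the
#' common linkage convention: `0 ... n-1` are the leaves in input-matrix
#' order and `n ... 2n-3` refer to earlier rows (row m creates id `n+m-1`).
#' `child_a` becomes the left child and `child_b` the right child, so the
#' table fully determines the dendrogram's orientation.
#'
#' @param table data frame or matrix with columns `child_a`, `child_b`,
#'   `height` (0-based ids as above), rows in merge order, or an object
#'   returned by [to_merge_table()].
#' @param labels character vector of leaf labels, length n, in input order.
#'   Ignored (taken from the table) when `table` is a `merge_table`.
#' @return A `merge_tree` object.
#' @seealso [to_merge_table()], [leaf_order()], [from_newick()]
#' @examples
#' tb <- data.frame(child_a = c(0, 2, 4), child_b = c(1, 3, 5),
#'                  height = c(1, 2, 5))
#' tree <- from_merge_table(tb, labels = c("A", "B", "C", "D"))
#' leaf_order(tree)
#' @export
from_merge_table <- function(table, labels = attr(table, "labels")) {
  if (inherits(table, "merge_table")) labels <- attr(table, "labels")
  table <- as.data.frame(table)
  req <- c("child_a", "child_b", "height")
  if (!all(req %in% names(table))) {
    stop("merge table needs columns child_a, child_b, height", call. = FALSE)
  }
  if (is.null(labels)) stop("leaf labels are required", call. = FALSE)
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 2L) stop("need at least 2 leaves", call. = FALSE)
  if (nrow(table) != n - 1L) {
    stop(sprintf("expected %d merge rows for %d labels, got %d",
                 n - 1L, n, nrow(table)), call. = FALSE)
  }
  a <- as.integer(table$child_a)
  b <- as.integer(table$child_b)
  h <- as.numeric(table$height)
  for (m in seq_len(n - 1L)) {
    if (a[m] == b[m]) {
      stop(sprintf("row %d: duplicate child reference %d", m, a[m]),
           call. = FALSE)
    }
    for (id in c(a[m], b[m])) {
      if (is.na(id) || id < 0L || id > 2L * n - 3L) {
        stop(sprintf("row %d: id %s out of range", m, id), call. = FALSE)
      }
      if (id >= n && id - n + 1L >= m) {
        stop(sprintf("row %d: id %d refers to a later or same merge", m, id),
             call. = FALSE)
      }
    }
    if (!is.finite(h[m]) || h[m] < 0) {
      stop(sprintf("row %d: negative or non-finite height %s", m, h[m]),
           call. = FALSE)
    }
  }
  kids <- c(a, b)
  dup <- kids[duplicated(kids)]
  if (length(dup)) {
    m <- which(a %in% dup | b %in% dup)[1L]
    stop(sprintf("row %d: duplicate child reference %d", m, dup[1L]),
         call. = FALSE)
  }
  # every id except the final merge must appear exactly once as a child
  expected <- 0:(2L * n - 3L)
  missing_ids <- setdiff(expected, kids)
  if (length(missing_ids)) {
    stop(sprintf("dangling id(s) never merged: %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  }
  if (any(h == 0)) {
    warning("merge height 0 (duplicate observations?); tree kept as is",
            call. = FALSE)
  }
  # shift to 1-based: leaf id k -> k+1, merge id n+m-1 -> n+m
  new_merge_tree(labels, a + 1L, b + 1L, h)
}

#' Serialize a merge tree to its merge table
#'
#' Inverse of [from_merge_table()]: emits the n-1 merge rows in merge order
#' with 0-based ids, preserving child order (left child in `child_a`).
#'
#' @param tree a `merge_tree`.
#' @return A data frame of class `merge_table` with columns `child_a`,
#'   `child_b`, `height` and the leaf labels in `attr(, "labels")`.
#' @export
to_merge_table <- function(tree) {
  stopifnot(is_merge_tree(tree))
  tb <- data.frame(
    child_a = tree$left - 1L,
    child_b = tree$right - 1L,
    height = tree$height
  )
  attr(tb, "labels") <- tree$labels
  class(tb) <- c("merge_table", class(tb))
  tb
}

#' Read / write merge tables as TSV
#'
#' Text format: a TSV with header `child_a child_b height` (0-based linkage
#' ids) plus a label file with one leaf label per line, in input order.
#'
#' @param file path to the merge-table TSV.
#' @param label_file path to the label file.
#' @return `read_merge_table()` returns a `merge_tree`;
#'   `write_merge_table()` returns the input invisibly.
#' @export
read_merge_table <- function(file, label_file) {
  tb <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  labels <- readLines(label_file)
  from_merge_table(tb, labels = labels)
}

#' @rdname read_merge_table
#' @param tree a `merge_tree` to serialize.
#' @export
write_merge_table <- function(tree, file, label_file) {
  tb <- to_merge_table(tree)
  utils::write.table(as.data.frame(tb), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(attr(tb, "labels"), label_file)
  invisible(tree)
}

# child height: 0 for leaves, stored height for internal nodes
node_height <- function(tree, id) {
  h <- numeric(length(id))
  internal <- id > tree$n
  h[internal] <- tree$height[id[internal] - tree$n]
  h
}

# per-node integer leaf-id sequences (current orientation), bottom-up
subtree_sequences <- function(tree) {
  n <- tree$n
  seqs <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) seqs[[i]] <- i
  for (m in seq_len(n - 1L)) {
    seqs[[n + m]] <- c(seqs[[tree$left[m]]], seqs[[tree$right[m]]])
  }
  seqs
}

#' Leaf order of a dendrogram
#'
#' Depth-first, left-before-right traversal collecting leaf labels: the
#' linear order in which the leaves are drawn, and the permutation applied
#' to the rows or columns of a matrix in a cluster heat map.
#'
#' @param tree a `merge_tree`.
#' @return Character vector of leaf labels, a permutation of `tree$labels`.
#' @export
leaf_order <- function(tree) {
  stopifnot(is_merge_tree(tree))
  if (tree$n == 1L) return(tree$labels)
  tree$labels[leaf_order_ids(tree)]
}

# integer leaf ids in drawn order
leaf_order_ids <- function(tree) {
  n <- tree$n
  seqs <- subtree_sequences(tree)
  seqs[[2L * n - 1L]]
}

#' Structural validation report for a merge tree
#'
#' Diagnostic, not a gatekeeper: reports leaf/internal counts, the number of
#' parent-child pairs violating height monotonicity (a parent merged at a
#' smaller dissimilarity than a child), duplicate leaf labels, and
#' zero-height merges. Single-linkage ties and externally produced trees can
#' be legitimately non-monotone, so violations are counted rather than
#' rejected.
#'
#' @param tree a `merge_tree`.
#' @return A list of class `merge_tree_validation` with fields `n_leaves`,
#'   `n_internal`, `monotonicity_violations`, `duplicate_labels`,
#'   `zero_height_merges`, `ok`.
#' @export
validate_merge_tree <- function(tree) {
  stopifnot(is_merge_tree(tree))
  n <- tree$n
  viol <- 0L
  for (m in seq_len(n - 1L)) {
    for (child in c(tree$left[m], tree$right[m])) {
      if (child > n && tree$height[m] < tree$height[child - n]) {
        viol <- viol + 1L
      }
    }
  }
  dups <- unique(tree$labels[duplicated(tree$labels)])
  res <- list(
    n_leaves = n,
    n_internal = n - 1L,
    monotonicity_violations = viol,
    duplicate_labels = dups,
    zero_height_merges = sum(tree$height == 0),
    ok = viol == 0L && length(dups) == 0L
  )
  class(res) <- "merge_tree_validation"
  res
}

#' @export
print.merge_tree_validation <- function(x, ...) {
  cat(sprintf("Merge tree: %d leaves, %d internal nodes\n",
              x$n_leaves, x$n_internal))
  cat(sprintf("  height monotonicity violations: %d\n",
              x$monotonicity_violations))
  if (length(x$duplicate_labels)) {
    cat("  duplicate labels:", paste(x$duplicate_labels, collapse = ", "), "\n")
  }
  if (x$zero_height_merges > 0) {
    cat(sprintf("  zero-height merges: %d\n", x$zero_height_merges))
  }
  invisible(x)
}

#' @export
print.merge_tree <- function(x, ...) {
  ord <- leaf_order(x)
  shown <- paste(utils::head(ord, 8L), collapse = " ")
  if (x$n > 8L) shown <- paste(shown, "...")
  cat(sprintf("merge_tree: %d leaves, root height %.6g\n",
              x$n, max(x$height)))
  cat("  leaf order:", shown, "\n")
  invisible(x)
}

#' Convert foreign clusterings to a merge tree
#'
#' `as_merge_tree.hclust` converts a [stats::hclust] result, preserving its
#' merge order, heights and child orientation (`merge[, 1]` becomes the left
#' child).
#'
#' @param x object to convert.
#' @param ... passed to methods.
#' @return A `merge_tree`.
#' @export
as_merge_tree <- function(x, ...) UseMethod("as_merge_tree")

#' @rdname as_merge_tree
#' @param labels optional replacement leaf labels (input order).
#' @export
as_merge_tree.hclust <- function(x, labels = x$labels, ...) {
  n <- nrow(x$merge) + 1L
  if (is.null(labels)) labels <- as.character(seq_len(n))
  conv <- function(id) ifelse(id < 0L, -id, n + id)
  new_merge_tree(labels, conv(x$merge[, 1L]), conv(x$merge[, 2L]), x$height)
}

#' @export
as_merge_tree.merge_tree <- function(x, ...) x

# ---- Newick serialization (via ape) ---------------------------------------

# preorder edge list for the phylo conversion; returns matrix of (parent,
# child) in our ids, parents before children, left before right
preorder_edges <- function(tree) {
  n <- tree$n
  edges <- matrix(0L, nrow = 2L * (n - 1L), ncol = 2L)
  stack <- 2L * n - 1L
  k <- 0L
  while (length(stack)) {
    id <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (id > n) {
      m <- id - n
      edges[k + 1L, ] <- c(id, tree$left[m])
      edges[k + 2L, ] <- c(id, tree$right[m])
      k <- k + 2L
      # push right first so left is popped (and emitted deeper) first
      stack <- c(stack, tree$right[m], tree$left[m])
    }
  }
  edges
}

#' Newick serialization of a merge tree
#'
#' The branch length of a child is its parent's merge height minus the
#' child's own height (leaves sit at height 0), so the resulting tree is
#' ultrametric whenever the hierarchy is monotone. Child order is preserved,
#' which keeps the dendrogram orientation through a round trip.
#'
#' @param tree a `merge_tree`.
#' @param digits significant digits for branch lengths (default 15, well
#'   above the 10 needed for a faithful round trip).
#' @return A Newick string terminated by `";"`.
#' @export
to_newick <- function(tree, digits = 15L) {
  stopifnot(is_merge_tree(tree))
  n <- tree$n
  if (n < 2L) stop("Newick export needs at least 2 leaves", call. = FALSE)
  edges <- preorder_edges(tree)
  # phylo numbering: tips 1..n keep their ids; internal id n+m -> n + (n - m)
  # so that the root (m = n-1) becomes n+1 as ape requires
  renum <- function(id) ifelse(id <= n, id, n + (n - (id - n)))
  ph_edge <- cbind(renum(edges[, 1L]), renum(edges[, 2L]))
  elen <- node_height(tree, edges[, 1L]) - node_height(tree, edges[, 2L])
  phy <- structure(
    list(edge = ph_edge, tip.label = tree$labels, Nnode = n - 1L,
         edge.length = elen),
    class = "phylo"
  )
  ape::write.tree(phy, digits = digits)
}

#' Parse a Newick string into a merge tree
#'
#' Accepts rooted binary trees with branch lengths. Node heights are
#' recovered as (maximum root-to-leaf depth) minus the node's depth; if the
#' tree is not ultrametric the leaves are pinned to height 0 with a warning.
#' Internal node ids are assigned in merge order (non-decreasing height,
#' subject to children preceding parents). Leaf input indices follow the
#' order of appearance in the string.
#'
#' @param text a Newick string.
#' @return A `merge_tree`.
#' @export
from_newick <- function(text) {
  phy <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                  error = function(e) stop("Newick parse error: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("Newick parse error: unparseable text", call. = FALSE)
  n <- length(phy$tip.label)
  if (n < 2L) stop("need at least 2 leaves", call. = FALSE)
  if (phy$Nnode != n - 1L) {
    stop("non-binary tree: expected ", n - 1L, " internal nodes, found ",
         phy$Nnode, call. = FALSE)
  }
  if (is.null(phy$edge.length)) {
    stop("branch lengths are required", call. = FALSE)
  }
  if (any(phy$edge.length < 0)) {
    stop("negative branch length at edge ",
         which(phy$edge.length < 0)[1L], call. = FALSE)
  }
  # depths from the root (cladewise sweep visits parents before children)
  depth <- numeric(n + phy$Nnode)
  phy2 <- ape::reorder.phylo(phy, "cladewise")
  for (e in seq_len(nrow(phy2$edge))) {
    p <- phy2$edge[e, 1L]; ch <- phy2$edge[e, 2L]
    depth[ch] <- depth[p] + phy2$edge.length[e]
  }
  H <- max(depth[seq_len(n)])
  height_ape <- H - depth  # per ape node number
  if (any(abs(height_ape[seq_len(n)]) > 1e-8 * max(H, 1))) {
    warning("tree is not ultrametric; leaf heights pinned to 0",
            call. = FALSE)
  }
  # children per ape internal node, in edge (= child) order
  kids <- vector("list", n + phy$Nnode)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]
    kids[[p]] <- c(kids[[p]], phy$edge[e, 2L])
  }
  internal_ape <- (n + 1L):(2L * n - 1L)
  if (any(lengths(kids[internal_ape]) != 2L)) {
    stop("non-binary node found", call. = FALSE)
  }
  # assign merge order: repeatedly take the ready node of smallest height
  assigned <- integer(n + phy$Nnode)  # our id per ape number
  assigned[seq_len(n)] <- seq_len(n)
  remaining <- internal_ape
  left <- integer(n - 1L); right <- integer(n - 1L); height <- numeric(n - 1L)
  for (m in seq_len(n - 1L)) {
    ready <- remaining[vapply(remaining, function(v) {
      all(assigned[kids[[v]]] > 0L)
    }, logical(1L))]
    pick <- ready[order(height_ape[ready])][1L]
    assigned[pick] <- n + m
    left[m] <- assigned[kids[[pick]][1L]]
    right[m] <- assigned[kids[[pick]][2L]]
    height[m] <- height_ape[pick]
    remaining <- setdiff(remaining, pick)
  }
  new_merge_tree(phy$tip.label, left, right, height)
}
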