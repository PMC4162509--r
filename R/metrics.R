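# Evaluation metrics for leaf orderings: drawn line length / data-ink
# ratio, Hamiltonian path length, anti-Robinson events, and a per-method
# comparison table.

#' Total line length of a drawn dendrogram
#'
#' Layout convention: leaves sit at x = 1..n (unit spacing) in leaf order at
#' height 0; an internal node sits at the midpoint of its children's x
#' positions, at its merge height. Each internal node contributes one
#' horizontal connector spanning its children and two vertical risers from
#' the children's heights up to its own. The riser total depends only on
#' the heights, so it is identical across all orientations of the same
#' tree; orientation changes show up exclusively in the connector total.
#'
#' @param tree a `merge_tree`.
#' @return A list of class `line_length_report`: `height_direction_total`
#'   (risers, in distance units), `leaf_direction_total` (connectors, in
#'   leaf-index units) and `total`.
#' @examples
#' tb <- data.frame(child_a = 0, child_b = 1, height = 1)
#' line_length(from_merge_table(tb, labels = c("A", "B")))$total  # 3
#' @export
line_length <- function(tree) {
  stopifnot(is_merge_tree(tree))
  n <- tree$n
  ord <- leaf_order_ids(tree)
  x <- numeric(2L * n - 1L)
  x[ord] <- seq_len(n)
  risers <- 0
  spans <- 0
  for (m in seq_len(n - 1L)) {
    l <- tree$left[m]; r <- tree$right[m]
    h <- tree$height[m]
    risers <- risers + abs(h - node_height(tree, l)) +
      abs(h - node_height(tree, r))
    x[n + m] <- (x[l] + x[r]) / 2
    spans <- spans + abs(x[r] - x[l])
  }
  structure(
    list(height_direction_total = risers,
         leaf_direction_total = spans,
         total = risers + spans),
    class = "line_length_report"
  )
}

#' @export
print.line_length_report <- function(x, ...) {
  cat(sprintf("dendrogram ink: total %.4f (risers %.4f + connectors %.4f)\n",
              x$total, x$height_direction_total, x$leaf_direction_total))
  invisible(x)
}

#' Data-ink ratio of one dendrogram relative to a baseline
#'
#' Ratio of total drawn line length to that of a baseline drawing of the
#' same tree (conventionally the default orientation). Because both
#' drawings share the coordinate system, the ratio is invariant to uniform
#' rescaling of either axis.
#'
#' @param report,baseline `line_length_report` objects (see [line_length()]).
#' @return Numeric ratio `report$total / baseline$total`.
#' @export
data_ink_ratio <- function(report, baseline) {
  if (!is.finite(baseline$total) || baseline$total <= 0) {
    stop("baseline total must be positive", call. = FALSE)
  }
  report$total / baseline$total
}

# positions of `order` labels in the distance matrix, with checks
order_index <- function(d, order) {
  labs <- rownames(d)
  idx <- match(order, labs)
  if (anyNA(idx) || length(order) != nrow(d) || anyDuplicated(order)) {
    stop("order must be a permutation of the distance-matrix labels",
         call. = FALSE)
  }
  idx
}

#' Hamiltonian path length of a leaf order
#'
#' Sum of distances between consecutive items: the loss that optimal leaf
#' ordering minimizes subject to the tree constraint.
#'
#' @param d labeled distance matrix.
#' @param order character vector, a permutation of the labels of `d`.
#' @return Numeric path length (0 for a single item).
#' @export
path_length <- function(d, order) {
  d <- as.matrix(d)
  if (length(order) == 1L) return(0)
  idx <- order_index(d, order)
  sum(d[cbind(idx[-length(idx)], idx[-1L])])
}

#' Number of anti-Robinson events of a leaf order
#'
#' In a perfectly seriated (Robinson) matrix, distances within each row
#' never decrease moving away from the diagonal. This counts the
#' violations: over all position triples i < j < k, one event if
#' `d(i,j) > d(i,k)` and one if `d(j,k) > d(i,k)`. Unweighted, two-sided,
#' and invariant under reversal of the order.
#'
#' @param d labeled distance matrix.
#' @param order character vector, a permutation of the labels of `d`.
#' @return Number of events (integer-valued).
#' @export
anti_robinson_events <- function(d, order) {
  d <- as.matrix(d)
  idx <- order_index(d, order)
  D <- d[idx, idx, drop = FALSE]
  n <- nrow(D)
  if (n < 3L) return(0)
  events <- 0
  for (i in seq_len(n - 2L)) {
    for (j in (i + 1L):(n - 1L)) {
      ks <- (j + 1L):n
      events <- events + sum(D[i, j] > D[i, ks]) + sum(D[j, ks] > D[i, ks])
    }
  }
  events
}

#' Benchmark leaf-ordering methods on one clustering
#'
#' Runs each requested method on the same tree and tabulates, per method,
#' the total drawn line length with its riser/connector decomposition, the
#' ink ratio relative to the default orientation, the Hamiltonian path
#' length and the anti-Robinson event count.
#'
#' @param tree a `merge_tree`.
#' @param d labeled distance matrix covering the tree's leaves.
#' @param methods subset of `c("default", "molo-min", "molo-avg", "gw",
#'   "olo")`.
#' @return An `ordering_comparison`: list with `table` (data frame, one row
#'   per method) and `orders` (named list of leaf orders).
#' @export
compare_orderings <- function(tree, d,
                              methods = c("default", "molo-min", "molo-avg",
                                          "gw", "olo")) {
  stopifnot(is_merge_tree(tree))
  methods <- match.arg(methods, several.ok = TRUE)
  d <- as.matrix(d)
  baseline <- line_length(order_default(tree))
  rows <- vector("list", length(methods))
  orders <- vector("list", length(methods))
  for (i in seq_along(methods)) {
    ot <- apply_ordering(tree, methods[i], d = d)
    rp <- line_length(ot)
    ord <- leaf_order(ot)
    rows[[i]] <- data.frame(
      method = methods[i],
      total_length = rp$total,
      height_length = rp$height_direction_total,
      leaf_length = rp$leaf_direction_total,
      ratio_to_default = data_ink_ratio(rp, baseline),
      path_length = path_length(d, ord),
      anti_robinson = anti_robinson_events(d, ord),
      stringsAsFactors = FALSE
    )
    orders[[i]] <- ord
  }
  names(orders) <- methods
  structure(list(table = do.call(rbind, rows), orders = orders),
            class = "ordering_comparison")
}

#' @export
print.ordering_comparison <- function(x, digits = 4L, ...) {
  tb <- x$table
  tb$total_length <- round(tb$total_length, digits)
  tb$ratio_to_default <- round(tb$ratio_to_default, 2L)
  tb$path_length <- round(tb$path_length, digits)
  cat("Leaf-ordering comparison (", nrow(tb), " methods, ",
      length(x$orders[[1L]]), " leaves)\n", sep = "")
  print(tb[, c("method", "total_length", "ratio_to_default",
               "path_length", "anti_robinson")], row.names = FALSE)
  invisible(x)
}

#' Serialize an ordering comparison
#'
#' Writes the comparison as JSON (table plus leaf orders) and/or as a TSV of
#' the metric table (method, total length, ratio, path length, events).
#'
#' @param x an `ordering_comparison`.
#' @param json_file,tsv_file output paths (either may be `NULL`).
#' @return `x` invisibly.
#' @export
write_ordering_comparison <- function(x, json_file = NULL, tsv_file = NULL) {
  if (!is.null(json_file)) {
    jsonlite::write_json(
      list(table = x$table, orders = x$orders),
      json_file, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  if (!is.null(tsv_file)) {
    utils::write.table(x$table, tsv_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}
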