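# Distance computation and agglomerative clustering with the linkages the
# ordering methods are evaluated on (single, complete, average/UPGMA).

#' Pairwise distance matrix of a data matrix
#'
#' Rows are observations, columns attributes. `euclidean` is the usual root
#' sum of squared coordinate differences; `pearson` is a correlation-based
#' dissimilarity computed across attributes, by default `1 - r` (the
#' convention of most heat-map tools), optionally `(1 - r) / 2` so that
#' perfect anticorrelation maps to 1.
#'
#' @param data numeric matrix (n observations x p attributes) with unique
#'   row names used as labels; unlabeled rows are labeled `1..n`.
#' @param metric `"euclidean"` or `"pearson"`.
#' @param pearson_transform `"one_minus_r"` (default) or `"half_one_minus_r"`.
#' @return Symmetric n x n numeric matrix with zero diagonal and matching
#'   dimnames.
#' @examples
#' d <- compute_distance(rbind(a = c(0, 0), b = c(3, 4)))
#' d["a", "b"]  # 5
#' @export
compute_distance <- function(data,
                             metric = c("euclidean", "pearson"),
                             pearson_transform = c("one_minus_r",
                                                   "half_one_minus_r")) {
  metric <- match.arg(metric)
  pearson_transform <- match.arg(pearson_transform)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric", call. = FALSE)
  n <- nrow(data)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  labels <- rownames(data)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (anyDuplicated(labels)) stop("duplicate row labels", call. = FALSE)
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(data, method = "euclidean"))
  } else {
    if (ncol(data) < 2L) {
      stop("pearson distance needs at least 2 attributes", call. = FALSE)
    }
    v <- apply(data, 1L, stats::var)
    if (any(v == 0)) {
      stop("zero-variance row(s) under pearson: ",
           paste(labels[v == 0], collapse = ", "), call. = FALSE)
    }
    r <- stats::cor(t(data))
    d <- 1 - r
    if (pearson_transform == "half_one_minus_r") d <- d / 2
  }
  d <- (d + t(d)) / 2          # kill floating-point asymmetry
  d[d < 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  d
}

#' Validate a distance matrix
#'
#' Checks the contract every consumer in the package relies on: square,
#' labeled, symmetric to 1e-12, zero diagonal, finite and non-negative.
#'
#' @param d numeric matrix.
#' @return `d` invisibly (errors otherwise).
#' @export
validate_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(d)) || is.null(colnames(d))) {
    stop("distance matrix must carry row and column labels", call. = FALSE)
  }
  if (!identical(rownames(d), colnames(d))) {
    stop("row and column labels differ", call. = FALSE)
  }
  if (anyDuplicated(rownames(d))) stop("duplicate labels", call. = FALSE)
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  if (any(d < 0)) stop("negative distances", call. = FALSE)
  if (any(diag(d) != 0)) stop("diagonal must be exactly 0", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12) {
    stop("matrix not symmetric within 1e-12", call. = FALSE)
  }
  invisible(d)
}

#' Agglomerative hierarchical clustering
#'
#' Standard bottom-up clustering: starting from singleton clusters, the
#' closest pair of active clusters is merged at each step and the distances
#' to the new cluster updated by the linkage rule (single = minimum pair
#' distance, complete = maximum, average = unweighted mean over cross-cluster
#' pairs, i.e. UPGMA). Ties are broken deterministically by merging the
#' lexicographically smallest pair of node ids. The returned tree's child
#' orientation follows the default dendrogram rules (see [order_default()]),
#' so `order_default(agglomerate(...))` is a fixed point.
#'
#' @param d symmetric labeled distance matrix (see [compute_distance()]).
#' @param linkage `"complete"`, `"single"` or `"average"`.
#' @return A `merge_tree` whose heights are the inter-cluster dissimilarities
#'   at each merge.
#' @examples
#' d <- compute_distance(rbind(a = c(0, 0), b = c(0, 1), c = c(0, 4)))
#' agglomerate(d, "single")
#' @export
agglomerate <- function(d, linkage = c("complete", "single", "average")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  validate_distance_matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  if (any(d[upper.tri(d)] == 0)) {
    warning("zero distance between distinct observations; ",
            "expect zero-height merges", call. = FALSE)
  }
  ids <- seq_len(n)          # node id of each active cluster
  sizes <- rep(1L, n)
  D <- d
  diag(D) <- Inf
  left <- integer(n - 1L); right <- integer(n - 1L); height <- numeric(n - 1L)
  for (m in seq_len(n - 1L)) {
    k <- length(ids)
    best <- min(D)
    hits <- which(D == best, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    # lexicographically smallest (id_i, id_j) with id_i < id_j
    pi <- pmin(ids[hits[, 1L]], ids[hits[, 2L]])
    pj <- pmax(ids[hits[, 1L]], ids[hits[, 2L]])
    pick <- order(pi, pj)[1L]
    i <- hits[pick, 1L]; j <- hits[pick, 2L]
    if (j < i) { tmp <- i; i <- j; j <- tmp }
    left[m] <- min(ids[i], ids[j])
    right[m] <- max(ids[i], ids[j])
    height[m] <- best
    # Lance-Williams update of distances to the merged cluster
    others <- setdiff(seq_len(k), c(i, j))
    dnew <- switch(linkage,
      single = pmin(D[i, others], D[j, others]),
      complete = pmax(D[i, others], D[j, others]),
      average = (sizes[i] * D[i, others] + sizes[j] * D[j, others]) /
                (sizes[i] + sizes[j])
    )
    newsize <- sizes[i] + sizes[j]
    if (length(others)) {
      D <- D[-c(i, j), -c(i, j), drop = FALSE]
      D <- rbind(cbind(D, dnew), c(dnew, Inf))
    } else {
      D <- matrix(Inf, 1L, 1L)
    }
    ids <- c(ids[others], n + m)
    sizes <- c(sizes[others], newsize)
  }
  order_default(new_merge_tree(labels, left, right, height))
}

# ---- matrix I/O -----------------------------------------------------------

guess_sep <- function(file) {
  if (grepl("\\.(tsv|tab|txt)$", file, ignore.case = TRUE)) "\t" else ","
}

#' Read a data or distance matrix from CSV/TSV
#'
#' Expected layout: a header row of attribute names and a first column of
#' observation labels. `read_distance_matrix()` additionally requires the
#' matrix to be square with matching row/column labels and validates it.
#'
#' @param file path; the separator is inferred from the extension
#'   (`.tsv`/`.tab`/`.txt` = tab, otherwise comma) unless given.
#' @param sep field separator override.
#' @return Numeric matrix with dimnames.
#' @export
read_data_matrix <- function(file, sep = guess_sep(file)) {
  if (!file.exists(file)) stop("input file not found: ", file, call. = FALSE)
  df <- utils::read.table(file, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labels
  m
}

#' @rdname read_data_matrix
#' @export
read_distance_matrix <- function(file, sep = guess_sep(file)) {
  m <- read_data_matrix(file, sep = sep)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("not a square labeled distance matrix: ", file, call. = FALSE)
  }
  validate_distance_matrix(m)
  m
}

#' @rdname read_data_matrix
#' @param x numeric matrix with dimnames.
#' @export
write_data_matrix <- function(x, file, sep = guess_sep(file)) {
  df <- data.frame(label = rownames(x), x, check.names = FALSE)
  utils::write.table(df, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(x)
}
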