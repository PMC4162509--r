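# SVG rendering of dendrograms and cluster heat maps. The output is plain
# SVG 1.1 text assembled deterministically (fixed number formatting, stable
# element order, no timestamps), so identical inputs give byte-identical
# documents and drawings can be snapshot-tested.

fmt_num <- function(x) {
  out <- formatC(x, format = "f", digits = 2)
  sub("^-0\\.00$", "0.00", out)
}

svg_open <- function(width, height) {
  sprintf(paste0(
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
    'width="%s" height="%s" viewBox="0 0 %s %s">'),
    fmt_num(width), fmt_num(height), fmt_num(width), fmt_num(height))
}

#' Dendrogram drawing coordinates
#'
#' The geometry shared by [render_dendrogram()] and [line_length()]: leaves
#' at positions 1..n (unit spacing) in leaf order at height 0, internal
#' nodes at the midpoint of their children's positions at their merge
#' height.
#'
#' @param tree a `merge_tree`.
#' @return List with `leaf_pos` (named by label, in leaf order), `node_x`
#'   and `node_height` (length 2n-1, indexed by node id).
#' @export
dendrogram_layout <- function(tree) {
  stopifnot(is_merge_tree(tree))
  n <- tree$n
  ord <- leaf_order_ids(tree)
  x <- numeric(2L * n - 1L)
  x[ord] <- seq_len(n)
  for (m in seq_len(n - 1L)) {
    x[n + m] <- (x[tree$left[m]] + x[tree$right[m]]) / 2
  }
  h <- c(rep(0, n), tree$height)
  leaf_pos <- seq_len(n)
  names(leaf_pos) <- tree$labels[ord]
  list(leaf_pos = leaf_pos, node_x = x, node_height = h)
}

#' Render a dendrogram as SVG
#'
#' Draws one polyline per internal node (two vertical risers joined by the
#' horizontal connector), so a tree with n leaves yields exactly n-1
#' connectors and 2(n-1) risers. Leaf labels are dropped automatically when
#' the canvas allots fewer than `label_px_threshold` pixels per leaf, which
#' is how dense trees degrade in limited display space.
#'
#' @param tree a `merge_tree`.
#' @param file optional path; when given the SVG is also written there.
#' @param width,height canvas size in px (> 0).
#' @param orientation `"bottom"` (leaves at the bottom edge) or `"right"`
#'   (leaves at the right edge, root to the left).
#' @param labels draw leaf labels (subject to the pixel threshold).
#' @param highlight character vector of leaf labels to emphasize.
#' @param label_px_threshold minimum per-leaf pixels for labels (default 4).
#' @param margin canvas margin in px.
#' @return The SVG document as a single character string, invisibly when
#'   `file` is given.
#' @export
render_dendrogram <- function(tree, file = NULL, width = 600, height = 400,
                              orientation = c("bottom", "right"),
                              labels = TRUE, highlight = character(),
                              label_px_threshold = 4, margin = 20) {
  stopifnot(is_merge_tree(tree))
  orientation <- match.arg(orientation)
  if (width <= 0 || height <= 0) {
    stop("canvas dimensions must be positive", call. = FALSE)
  }
  n <- tree$n
  lay <- dendrogram_layout(tree)
  hmax <- max(lay$node_height)
  if (hmax <= 0) hmax <- 1
  label_space <- if (labels) 14 else 0
  # across = leaf axis, along = height axis, both in px from the margin
  across_px <- function(p) {
    extent <- if (orientation == "bottom") width else height
    margin + (p - 0.5) / n * (extent - 2 * margin)
  }
  along_px <- function(h) {
    extent <- if (orientation == "bottom") height else width
    # height 0 at the leaf edge, root towards the opposite edge
    (extent - margin - label_space) - h / hmax *
      (extent - 2 * margin - label_space)
  }
  pt <- function(p, h) {
    if (orientation == "bottom") c(across_px(p), along_px(h))
    else c(along_px(h), across_px(p))
  }
  per_leaf_px <- ((if (orientation == "bottom") width else height) -
                    2 * margin) / n
  draw_labels <- labels && per_leaf_px >= label_px_threshold
  out <- c(
    svg_open(width, height),
    '<style>.leaf{font:10px sans-serif;fill:#000000;}',
    '.leaf.highlight{fill:#cc0000;font-weight:bold;}',
    'polyline{fill:none;stroke:#000000;stroke-width:1;}</style>'
  )
  for (m in seq_len(n - 1L)) {
    l <- tree$left[m]; r <- tree$right[m]
    h <- tree$height[m]
    p1 <- pt(lay$node_x[l], lay$node_height[l])
    p2 <- pt(lay$node_x[l], h)
    p3 <- pt(lay$node_x[r], h)
    p4 <- pt(lay$node_x[r], lay$node_height[r])
    out <- c(out, sprintf('<polyline points="%s"/>', paste(
      paste(fmt_num(c(p1[1], p2[1], p3[1], p4[1])),
            fmt_num(c(p1[2], p2[2], p3[2], p4[2])), sep = ","),
      collapse = " ")))
  }
  if (draw_labels) {
    ord_labels <- names(lay$leaf_pos)
    for (i in seq_len(n)) {
      lb <- ord_labels[i]
      cls <- if (lb %in% highlight) "leaf highlight" else "leaf"
      p <- pt(i, 0)
      anchor <- if (orientation == "bottom") "middle" else "start"
      ypad <- if (orientation == "bottom") 12 else 3
      xpad <- if (orientation == "bottom") 0 else 4
      out <- c(out, sprintf(
        '<text class="%s" x="%s" y="%s" text-anchor="%s">%s</text>',
        cls, fmt_num(p[1] + xpad), fmt_num(p[2] + ypad), anchor,
        xml_escape(lb)))
    }
  }
  out <- c(out, "</svg>")
  doc <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Map values to a diverging color scale
#'
#' Linear blue-white-red ramp over `limits`, with the midpoint of the
#' limits mapped to white. Values outside the limits are clamped.
#'
#' @param values numeric vector.
#' @param limits length-2 numeric range (default the data range).
#' @param colors three ramp anchors (low, mid, high).
#' @return Character vector of hex colors.
#' @export
diverging_colors <- function(values, limits = range(values),
                             colors = c("#2166AC", "#FFFFFF", "#B2182B")) {
  if (limits[2L] <= limits[1L]) stop("invalid limits", call. = FALSE)
  t <- (values - limits[1L]) / (limits[2L] - limits[1L])
  t <- pmin(pmax(t, 0), 1)
  rgbm <- grDevices::colorRamp(colors)(t)
  grDevices::rgb(rgbm[, 1L], rgbm[, 2L], rgbm[, 3L], maxColorValue = 255)
}

# deterministic categorical fills for annotation strips
annotation_palette <- function(k) {
  base <- c("#1B9E77", "#D95F02", "#7570B3", "#E7298A", "#66A61E",
            "#E6AB02", "#A6761D", "#666666")
  rep_len(base, k)
}

#' Render a cluster heat map as SVG
#'
#' Draws the matrix with rows (and optionally columns) permuted by the leaf
#' orders of the given trees, the dendrograms in the margins, and an
#' optional categorical annotation strip between the row dendrogram and the
#' cells. With `symmetric = TRUE` a single tree orders both axes, the mode
#' used for distance-matrix heat maps.
#'
#' @param mat numeric matrix with row (and column) names.
#' @param row_tree `merge_tree` over the row labels, or `NULL`.
#' @param col_tree `merge_tree` over the column labels, or `NULL`.
#' @param annotations optional named vector (names = row labels) of
#'   categories shown as a color strip.
#' @param file optional output path.
#' @param width,height canvas size in px.
#' @param limits color-scale limits (e.g. `c(-1, 1)` for association
#'   scores); default the data range.
#' @param symmetric use `row_tree` for the columns as well (requires a
#'   square matrix with identical row/column labels).
#' @return The SVG document as a character string, invisibly when `file`
#'   is given.
#' @export
render_heatmap <- function(mat, row_tree = NULL, col_tree = NULL,
                           annotations = NULL, file = NULL,
                           width = 800, height = 600, limits = NULL,
                           symmetric = FALSE) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) {
    stop("matrix must have row names", call. = FALSE)
  }
  if (is.null(colnames(mat))) colnames(mat) <- as.character(seq_len(ncol(mat)))
  if (symmetric) {
    if (nrow(mat) != ncol(mat) || !identical(rownames(mat), colnames(mat))) {
      stop("symmetric mode needs a square matrix with matching labels",
           call. = FALSE)
    }
    col_tree <- row_tree
  }
  reorder_by <- function(tree, labs, axis) {
    if (is.null(tree)) return(seq_along(labs))
    ord <- leaf_order(tree)
    miss <- setdiff(ord, labs)
    if (length(miss) || length(ord) != length(labs)) {
      stop("tree labels do not match matrix ", axis, " labels; missing: ",
           paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
    }
    match(ord, labs)
  }
  ri <- reorder_by(row_tree, rownames(mat), "row")
  ci <- reorder_by(col_tree, colnames(mat), "column")
  M <- mat[ri, ci, drop = FALSE]
  if (is.null(limits)) limits <- range(M)
  if (limits[1L] == limits[2L]) limits <- limits + c(-0.5, 0.5)
  nr <- nrow(M); nc <- ncol(M)
  dend_w <- if (is.null(row_tree)) 0 else 120
  dend_h <- if (is.null(col_tree)) 0 else 120
  ann_w <- if (is.null(annotations)) 0 else 12
  pad <- 10
  cell_w <- (width - dend_w - ann_w - 2 * pad) / nc
  cell_h <- (height - dend_h - 2 * pad) / nr
  if (cell_w <= 0 || cell_h <= 0) stop("canvas too small", call. = FALSE)
  x0 <- pad + dend_w + ann_w
  y0 <- pad + dend_h
  out <- svg_open(width, height)
  # cells, row-major for stable output
  cols <- matrix(diverging_colors(as.vector(M), limits = limits), nr, nc)
  cells <- character(nr * nc)
  k <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      k <- k + 1L
      cells[k] <- sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
        fmt_num(x0 + (j - 1L) * cell_w), fmt_num(y0 + (i - 1L) * cell_h),
        fmt_num(cell_w), fmt_num(cell_h), cols[i, j])
    }
  }
  out <- c(out, cells)
  if (!is.null(annotations)) {
    ann <- annotations[rownames(M)]
    if (anyNA(ann)) {
      stop("annotations missing for rows: ",
           paste(utils::head(rownames(M)[is.na(ann)], 5L), collapse = ", "),
           call. = FALSE)
    }
    lev <- unique(as.character(ann))
    fills <- annotation_palette(length(lev))
    names(fills) <- lev
    for (i in seq_len(nr)) {
      out <- c(out, sprintf(
        '<rect class="annotation" x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
        fmt_num(pad + dend_w), fmt_num(y0 + (i - 1L) * cell_h),
        fmt_num(ann_w - 2), fmt_num(cell_h), fills[as.character(ann[i])]))
    }
  }
  # marginal dendrograms rendered as nested <svg> so coordinates stay local
  if (!is.null(row_tree)) {
    sub <- render_dendrogram(row_tree, width = dend_w, height = height -
                               dend_h - 2 * pad, orientation = "right",
                             labels = FALSE, margin = 0)
    out <- c(out, sprintf('<svg x="%s" y="%s">', fmt_num(pad), fmt_num(y0)),
             sub, "</svg>")
  }
  if (!is.null(col_tree)) {
    sub <- render_dendrogram(col_tree, width = width - x0 - pad,
                             height = dend_h, orientation = "bottom",
                             labels = FALSE, margin = 0)
    out <- c(out, sprintf('<svg x="%s" y="%s">', fmt_num(x0), fmt_num(pad)),
             sub, "</svg>")
  }
  out <- c(out, "</svg>")
  doc <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}
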