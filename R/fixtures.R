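# Bundled and generated datasets: a seeded Gaussian-cluster generator for
# simulation-style experiments, a fixed 10-point toy configuration that
# exercises every orientation rule in one tree, and Fisher's Iris
# measurements vendored as a plain-text file.

#' Seeded Gaussian cluster generator
#'
#' Draws `k` isotropic Gaussian clusters of `n_per` observations each, with
#' cluster centers placed on a grid of spacing `sep` (a square grid over the
#' first two attributes when `dim >= 2`, a line when `dim == 1`; any further
#' attributes carry noise around 0). Observations are labeled `1..k*n_per`
#' in input order, cluster by cluster. The caller's random-number state is
#' left untouched.
#'
#' @param k number of clusters (>= 1).
#' @param n_per observations per cluster (>= 1).
#' @param dim number of attributes (>= 1, default 2).
#' @param sep center grid spacing (default 10).
#' @param sd within-cluster standard deviation (> 0, default 1).
#' @param seed integer seed; the output is fully reproducible from it.
#' @return List with `data` (numeric `k*n_per` x `dim` matrix, rows labeled
#'   `1..k*n_per`, columns `attr1..attrdim`) and `cluster` (integer vector
#'   of true cluster memberships).
#' @export
make_gaussian_clusters <- function(k, n_per, dim = 2L, sep = 10, sd = 1,
                                   seed = 1L) {
  if (k < 1L || n_per < 1L || dim < 1L || sd <= 0 || sep < 0) {
    stop("invalid generator parameters", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  side <- if (dim >= 2L) ceiling(sqrt(k)) else k
  centers <- matrix(0, nrow = k, ncol = dim)
  for (ci in seq_len(k)) {
    if (dim >= 2L) {
      centers[ci, 1L] <- ((ci - 1L) %% side) * sep
      centers[ci, 2L] <- ((ci - 1L) %/% side) * sep
    } else {
      centers[ci, 1L] <- (ci - 1L) * sep
    }
  }
  n <- k * n_per
  cluster <- rep(seq_len(k), each = n_per)
  noise <- matrix(stats::rnorm(n * dim, sd = sd), nrow = n, ncol = dim)
  data <- centers[cluster, , drop = FALSE] + noise
  dimnames(data) <- list(as.character(seq_len(n)),
                         paste0("attr", seq_len(dim)))
  list(data = data, cluster = cluster)
}

#' Ten-point toy configuration
#'
#' A fixed two-dimensional arrangement of ten observations, labeled
#' `"1".."10"` in input order, engineered so that its complete-linkage
#' dendrogram contains all three merge types (leaf-leaf, leaf-subtree,
#' subtree-subtree) and therefore exercises every orientation rule of both
#' the default and the modular ordering in a single small tree. The
#' coordinates are this package's own; they are constants, so repeated
#' calls are identical.
#'
#' @return Numeric 10 x 2 matrix with row labels `"1".."10"`.
#' @export
fig2_toy <- function() {
  pts <- matrix(c(
     0.0, 0.0,   # 1  tight pair with 2
     0.5, 0.0,   # 2
     1.8, 0.4,   # 3  leaf joining the (1,2) pair
     6.0, 0.0,   # 4  pair with 5
     6.6, 0.1,   # 5
     7.9, 0.5,   # 6  leaf joining the (4,5) pair
    12.0, 5.0,   # 7  pair with 8
    12.4, 5.1,   # 8
    13.6, 5.4,   # 9  leaf joining the (7,8) pair
    20.0, 9.0    # 10 outlier, merges last
  ), ncol = 2L, byrow = TRUE)
  dimnames(pts) <- list(as.character(1:10), c("x", "y"))
  pts
}

#' Fisher's Iris measurements
#'
#' The classic 150-flower table: sepal length/width and petal length/width
#' (cm) for 50 observations of each of three species, bundled with the
#' package as a plain CSV so every example runs offline. Rows are labeled
#' `"1".."150"` in the canonical order (all setosa, then versicolor, then
#' virginica).
#'
#' @return List with `data` (150 x 4 numeric matrix) and `species` (factor
#'   of length 150).
#' @export
load_iris <- function() {
  path <- system.file("extdata", "iris.csv", package = "leaforder",
                      mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, c("sepal_length", "sepal_width",
                        "petal_length", "petal_width")])
  rownames(m) <- as.character(seq_len(nrow(df)))
  list(data = m, species = factor(df$species))
}
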