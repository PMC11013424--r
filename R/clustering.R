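#' Euclidean distance matrix over rows or columns of a logP table
#'
#' Pairwise Euclidean distances between compounds (`axis = "rows"`) or
#' between lipophilicity methods (`axis = "columns"`). All logP columns share
#' the log10 scale, so distances are computed on raw values by default; set
#' `standardize = TRUE` to z-score each variable first.
#'
#' @param x a [lipo_table()] or a plain numeric matrix with dimnames.
#' @param axis cluster compounds (`"rows"`) or methods (`"columns"`).
#' @param standardize z-score each variable before computing distances.
#' @return An object of class `distance_matrix`: list with `labels` and the
#'   symmetric matrix `d` (zero diagonal).
#' @examples
#' tab <- read_lipophilicity_table(
#'   system.file("extdata", "logp_calcd_table.csv", package = "rmzero"))
#' d <- euclidean_distances(tab, axis = "columns")
#' d$d["ClogP", "XLOGP2"]
#' @export
euclidean_distances <- function(x, axis = c("rows", "columns"),
                                standardize = FALSE) {
  axis <- match.arg(axis)
  m <- if (inherits(x, "lipo_table")) x$values else x
  if (!is.matrix(m) || !is.numeric(m)) {
    rmz_stop("'x' must be a lipo_table or numeric matrix", "rmzero_schema_error")
  }
  if (axis == "columns") m <- t(m)
  if (anyNA(m)) {
    rmz_stop("missing values among the selected vectors; impute or drop first",
             "rmzero_data_error")
  }
  if (standardize) {
    # per-variable z-score; constant variables would divide by zero
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      rmz_stop("cannot standardize: a variable has zero variance",
               "rmzero_data_error")
    }
    m <- scale(m)
  }
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  dimnames(d) <- list(rownames(m), rownames(m))
  distance_matrix(rownames(m), d)
}

#' Construct a distance matrix object
#'
#' @param labels character vector of item labels.
#' @param d symmetric numeric matrix of non-negative distances with zero
#'   diagonal, one row/column per label.
#' @return An object of class `distance_matrix`.
#' @export
distance_matrix <- function(labels, d) {
  labels <- as.character(labels)
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) != length(labels)) {
    rmz_stop("'d' must be a square matrix matching 'labels'",
             "rmzero_schema_error")
  }
  if (any(!is.finite(d))) {
    rmz_stop("distances must be finite", "rmzero_schema_error")
  }
  if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0) || any(d < 0)) {
    rmz_stop("'d' must be symmetric and non-negative with zero diagonal",
             "rmzero_schema_error")
  }
  d <- (d + t(d)) / 2
  dimnames(d) <- list(labels, labels)
  structure(list(labels = labels, d = d), class = "distance_matrix")
}

#' Single-linkage agglomerative clustering
#'
#' Classic bottom-up agglomeration: start from singleton clusters and
#' repeatedly merge the two clusters at minimum inter-cluster distance, where
#' the inter-cluster distance is the minimum pairwise distance between
#' members (single linkage). Ties are broken deterministically: the pair with
#' the lexicographically smallest (creation-order) indices merges first.
#' Single linkage is reducible, so merge heights are non-decreasing.
#'
#' The merge history uses the `stats::hclust` encoding (negative numbers are
#' leaves, positive numbers earlier merges), so the result converts cleanly
#' via [as.hclust.linkage_tree()].
#'
#' @param dist a [distance_matrix()] with at least two items.
#' @return An object of class `linkage_tree`: `merge` ((n-1) x 2 integer
#'   matrix), `height`, `new_size` (cluster size after each merge) and
#'   `labels`.
#' @examples
#' d <- distance_matrix(c("a", "b", "c"),
#'                      as.matrix(dist(c(0, 1, 3))))
#' single_linkage(d)$height  # 1, 2
#' @export
single_linkage <- function(dist) {
  stopifnot(inherits(dist, "distance_matrix"))
  n <- length(dist$labels)
  if (n < 2L) {
    rmz_stop("need at least 2 items to cluster", "rmzero_insufficient_data")
  }
  # active cluster bookkeeping: id in hclust encoding, creation order index
  active <- seq_len(n)            # positions into D
  ids <- -seq_len(n)              # hclust codes of active clusters
  sizes <- rep(1L, n)
  D <- dist$d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  new_size <- integer(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        dij <- D[active[i], active[j]]
        if (dij < best_d) {  # strict: first minimal pair wins the tie
          best_d <- dij
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    a <- ids[i]; b <- ids[j]
    # presentation order: singletons first by leaf index, then earlier merges
    key <- function(code) if (code < 0) -code else 1e9 + code
    merge[step, ] <- if (key(a) <= key(b)) c(a, b) else c(b, a)
    height[step] <- best_d
    new_size[step] <- sizes[i] + sizes[j]
    # single-linkage update: distance to merged cluster = min of the two
    pi <- active[i]; pj <- active[j]
    D[pi, ] <- pmin(D[pi, ], D[pj, ])
    D[, pi] <- D[pi, ]
    D[pi, pi] <- 0
    active <- active[-j]
    ids[i] <- step
    ids <- ids[-j]
    sizes[i] <- new_size[step]
    sizes <- sizes[-j]
  }
  structure(
    list(merge = merge, height = height, new_size = new_size,
         labels = dist$labels),
    class = "linkage_tree"
  )
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> %d leaves, %d merges, heights %.3g .. %.3g\n",
              length(x$labels), length(x$height),
              min(x$height), max(x$height)))
  invisible(x)
}

# Left-to-right leaf ordering of the merge history (for hclust conversion).
tree_leaf_order <- function(tree) {
  walk <- function(code) {
    if (code < 0) return(-code)
    c(walk(tree$merge[code, 1]), walk(tree$merge[code, 2]))
  }
  walk(nrow(tree$merge))
}

#' Convert a linkage tree to an hclust object
#'
#' @param x a `linkage_tree`.
#' @param ... unused.
#' @return A `stats::hclust` object (method `"single"`), e.g. for `plot()`.
#' @export
as.hclust.linkage_tree <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = tree_leaf_order(x),
         labels = x$labels, method = "single",
         dist.method = "euclidean", call = match.call()),
    class = "hclust"
  )
}

#' Cut a linkage tree into k clusters
#'
#' Cuts above the (n-k)-th merge: the first `n - k` merges define the
#' components. Cluster numbers are assigned by first appearance in leaf-index
#' order, so labellings are stable across runs.
#'
#' @param tree a `linkage_tree` over n leaves.
#' @param k desired number of clusters, between 1 and n.
#' @return A named integer vector: cluster membership (1..k) per leaf label.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "linkage_tree"))
  n <- length(tree$labels)
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1 || k > n) {
    rmz_stop(sprintf("'k' must be an integer in [1, %d]", n),
             "rmzero_parameter_error")
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  cluster_leaf <- integer(n - 1L)  # representative leaf of each merged cluster
  for (step in seq_len(n - k)) {
    leaf_of <- function(code) if (code < 0) -code else cluster_leaf[code]
    ra <- find(leaf_of(tree$merge[step, 1]))
    rb <- find(leaf_of(tree$merge[step, 2]))
    parent[max(ra, rb)] <- min(ra, rb)
    cluster_leaf[step] <- min(ra, rb)
  }
  if (n - k < n - 1L) {
    for (step in seq(n - k + 1L, n - 1L)) {
      code <- tree$merge[step, 1]
      cluster_leaf[step] <- if (code < 0) -code else cluster_leaf[code]
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- match(roots, unique(roots))  # numbered by first appearance
  names(groups) <- tree$labels
  groups
}

newick_safe <- function(label) {
  gsub("[ ,():;\\[\\]']", "_", label)
}

#' Export a linkage tree as a Newick string
#'
#' Writes the dendrogram in Newick format with ultrametric branch lengths
#' under the midpoint convention: a leaf under a merge at height h sits at
#' depth h/2, so a two-leaf tree at height 1 becomes `"(A:0.5,B:0.5);"`.
#'
#' @param tree a `linkage_tree`.
#' @return A single Newick string terminated by `";"`.
#' @export
export_dendrogram <- function(tree) {
  stopifnot(inherits(tree, "linkage_tree"))
  node_height <- function(code) if (code < 0) 0 else tree$height[code]
  render <- function(code, parent_h) {
    h <- node_height(code)
    len <- (parent_h - h) / 2
    if (code < 0) {
      sprintf("%s:%.10g", newick_safe(tree$labels[-code]), len)
    } else {
      sprintf("(%s,%s):%.10g",
              render(tree$merge[code, 1], h),
              render(tree$merge[code, 2], h),
              len)
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  paste0("(",
         render(tree$merge[root, 1], h), ",",
         render(tree$merge[root, 2], h),
         ");")
}
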