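fixture_path <- function(name) {
  system.file("extdata", name, package = "rmzero", mustWork = TRUE)
}

load_logp_table <- function() {
  read_lipophilicity_table(fixture_path("logp_calcd_table.csv"))
}

load_retention_fits <- function() {
  read_retention_fits(fixture_path("retention_fits_table.csv"))
}

load_standards <- function() {
  read_calibration_standards(fixture_path("calibration_standards.csv"))
}

load_adme <- function() {
  read_adme_table(fixture_path("adme_profiles.csv"))
}

# The combined compounds-by-methods table: eight calculated columns plus the
# experimental logP_TLC column.
load_combined_table <- function() {
  tab <- load_logp_table()
  fits <- load_retention_fits()
  stopifnot(identical(rownames(tab$values), fits$compound))
  lipo_table(cbind(tab$values, logP_TLC = fits$logp_tlc))
}

# Independent single-linkage oracle: exhaustive agglomeration over label
# sets, recomputing every inter-cluster distance from the original matrix at
# each step (no incremental update), with the same first-minimal-pair
# tie-break. Returns merge heights and the partition at every k.
brute_single_linkage <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  partitions[[n]] <- vapply(seq_len(n), function(i) {
    which(vapply(clusters, function(cl) i %in% cl, logical(1)))
  }, integer(1))
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- NULL; best_d <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        dij <- min(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d) { best_d <- dij; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    clusters <- clusters[order(vapply(clusters, min, integer(1)))]
    partitions[[length(clusters)]] <- vapply(seq_len(n), function(i) {
      which(vapply(clusters, function(cl) i %in% cl, logical(1)))
    }, integer(1))
  }
  list(heights = heights, partitions = partitions)
}

# Minimum-spanning-tree edge weights by Prim's algorithm (for the
# single-linkage = MST heights identity).
prim_mst_weights <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  weights <- numeric(0)
  while (sum(in_tree) < n) {
    sub <- d[in_tree, !in_tree, drop = FALSE]
    w <- min(sub)
    weights <- c(weights, w)
    j <- which(!in_tree)[which(apply(sub, 2, min) == w)[1]]
    in_tree[j] <- TRUE
  }
  weights
}

random_distance_matrix <- function(n) {
  m <- matrix(stats::runif(n * n), n, n)
  d <- as.matrix(stats::dist(m))
  distance_matrix(LETTERS[seq_len(n)], d)
}

# Do two clusterings define the same partition (up to label renumbering)?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
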