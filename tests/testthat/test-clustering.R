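test_that("euclidean distances match hand geometry and table relations", {
  m <- rbind(p = c(0, 0), q = c(3, 4))
  colnames(m) <- c("x", "y")
  d <- euclidean_distances(m, axis = "rows")
  expect_equal(d$d["p", "q"], 5)
  expect_equal(diag(d$d), c(p = 0, q = 0))

  tab <- load_logp_table()
  dc <- euclidean_distances(tab, axis = "columns")
  expect_lt(dc$d["ClogP", "XLOGP2"], dc$d["ClogP", "MLOGP"])

  withNA <- tab$values
  withNA[2, 3] <- NA
  expect_error(euclidean_distances(lipo_table(withNA), axis = "rows"),
               class = "rmzero_data_error")
})

test_that("single linkage agglomerates 1-D points as computed by hand", {
  d <- distance_matrix(c("A", "B", "C"), as.matrix(stats::dist(c(0, 1, 3))))
  tree <- single_linkage(d)
  expect_equal(tree$height, c(1, 2))
  expect_equal(tree$merge[1, ], c(-1L, -2L))  # A and B first
  expect_equal(tree$new_size, c(2L, 3L))

  two <- distance_matrix(c("A", "B"), matrix(c(0, 0.7, 0.7, 0), 2))
  t2 <- single_linkage(two)
  expect_equal(t2$height, 0.7)
  expect_error(single_linkage(distance_matrix("A", matrix(0, 1, 1))),
               class = "rmzero_insufficient_data")
})

test_that("merge heights are non-decreasing and match MST edge weights", {
  set.seed(9)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    dm <- random_distance_matrix(n)
    tree <- single_linkage(dm)
    expect_true(all(diff(tree$height) >= -1e-12))
    expect_equal(sort(tree$height), sort(prim_mst_weights(dm$d)),
                 tolerance = 1e-12)
  }
})

test_that("single linkage agrees with stats::hclust on random matrices", {
  set.seed(10)
  for (i in 1:25) {
    n <- sample(4:15, 1)
    dm <- random_distance_matrix(n)
    tree <- single_linkage(dm)
    ref <- stats::hclust(stats::as.dist(dm$d), method = "single")
    expect_equal(tree$height, ref$height, tolerance = 1e-12)
    for (k in c(2L, min(4L, n))) {
      expect_true(same_partition(cut_tree(tree, k),
                                 stats::cutree(ref, k)))
    }
  }
})

test_that("cut_tree spans the trivial cuts and keeps labels stable", {
  set.seed(12)
  dm <- random_distance_matrix(8)
  tree <- single_linkage(dm)
  expect_equal(unname(cut_tree(tree, 1)), rep(1L, 8))
  expect_equal(unname(cut_tree(tree, 8)), 1:8)
  expect_identical(names(cut_tree(tree, 3)), dm$labels)
  expect_identical(cut_tree(tree, 3), cut_tree(tree, 3))
  expect_error(cut_tree(tree, 0), class = "rmzero_parameter_error")
  expect_error(cut_tree(tree, 9), class = "rmzero_parameter_error")
})

test_that("permuting input labels permutes the output and nothing else", {
  set.seed(13)
  dm <- random_distance_matrix(7)
  perm <- sample(7)
  dperm <- distance_matrix(dm$labels[perm], dm$d[perm, perm])
  t1 <- single_linkage(dm)
  t2 <- single_linkage(dperm)
  expect_equal(sort(t1$height), sort(t2$height), tolerance = 1e-12)
  expect_true(same_partition(
    cut_tree(t1, 3)[dm$labels],
    cut_tree(t2, 3)[dm$labels]
  ))
})

test_that("Newick export uses midpoint heights and round-trips through ape", {
  skip_if_not_installed("ape")
  two <- single_linkage(
    distance_matrix(c("A", "B"), matrix(c(0, 1, 1, 0), 2)))
  expect_identical(export_dendrogram(two), "(A:0.5,B:0.5);")

  set.seed(14)
  for (i in 1:10) {
    dm <- random_distance_matrix(sample(3:9, 1))
    tree <- single_linkage(dm)
    phy <- ape::read.tree(text = export_dendrogram(tree))
    expect_setequal(phy$tip.label, dm$labels)
    # ultrametric under the midpoint convention: all leaves at depth h/2
    depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
    expect_equal(depths, rep(max(tree$height) / 2, length(depths)),
                 tolerance = 1e-8)
  }
})

test_that("method clustering isolates MLOGP and groups compounds as reported", {
  tab <- load_combined_table()
  mt <- single_linkage(euclidean_distances(tab, axis = "columns"))
  # the last merge joins MLOGP (alone) to everything else: soft structure
  # check on the methods dendrogram
  expect_equal(mt$merge[nrow(mt$merge), 1],
               -which(colnames(tab$values) == "MLOGP"))

  ct <- single_linkage(euclidean_distances(tab, axis = "rows"))
  groups <- cut_tree(ct, 3)
  allyl_naphtho <- groups[c("16", "17", "20", "21")]
  expect_equal(length(unique(allyl_naphtho)), 1L)
  # that group contains nothing else
  expect_equal(sum(groups == allyl_naphtho[1]), 4L)
})
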