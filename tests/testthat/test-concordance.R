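test_that("pearson_r reproduces exact closed-form cases", {
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2))$r, -1, tolerance = 1e-12)
  x <- c(0.4, 1.9, 3.5, 2.2)
  expect_equal(pearson_r(x, x)$r, 1, tolerance = 1e-12)
})

test_that("pearson_r uses pairwise deletion and refuses degenerate input", {
  set.seed(5)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20, 0, 0.3)
  full <- pearson_r(x, y)
  y2 <- y; y2[7] <- NA
  holed <- pearson_r(x, y2)
  expect_equal(holed$n, full$n - 1L)
  expect_false(is.na(holed$r))
  expect_error(pearson_r(x, rep(1, 20)),
               class = "rmzero_undefined_correlation")
  expect_error(pearson_r(1:2, 2:1), class = "rmzero_insufficient_data")
})

test_that("pearson_r is affine-invariant and flips sign under negation", {
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    r0 <- pearson_r(x, y)$r
    a <- stats::runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(pearson_r(a * x + b, y)$r, r0, tolerance = 1e-10)
    expect_equal(pearson_r(-x, y)$r, -r0, tolerance = 1e-10)
  }
})

test_that("the experimental column correlates best with AClogP", {
  tab <- load_combined_table()
  cm <- correlation_matrix(tab, "logP_TLC")
  expect_equal(nrow(cm), 8L)
  expect_identical(cm$method[which.max(cm$r)], "AClogP")
  expect_equal(cm$r[cm$method == "AClogP"], 0.6996, tolerance = 1e-3)
})

test_that("correlation_matrix handles degenerate shapes", {
  single <- lipo_table(matrix(1:5, ncol = 1,
                              dimnames = list(letters[1:5], "only")))
  expect_equal(nrow(correlation_matrix(single, "only")), 0L)

  tab <- load_logp_table()
  dup <- lipo_table(cbind(tab$values, copy = tab$values[, "AClogP"]))
  cm <- correlation_matrix(dup, "copy")
  expect_equal(cm$r[cm$method == "AClogP"], 1, tolerance = 1e-12)
  expect_error(correlation_matrix(tab, "nope"), class = "rmzero_lookup_error")
})

test_that("algorithm disagreement peaks at 2.59 log units for compound 4", {
  tab <- load_logp_table()
  sp <- spread_summary(tab)
  expect_equal(sp$max_range, 2.59, tolerance = 1e-12)
  expect_identical(sp$argmax_compound, "4")
  # brute-force two-loop scan over every compound and column pair
  v <- tab$values
  brute <- 0
  for (i in seq_len(nrow(v))) {
    for (j in seq_len(ncol(v))) {
      for (k in seq_len(ncol(v))) {
        brute <- max(brute, v[i, j] - v[i, k])
      }
    }
  }
  expect_equal(sp$max_range, brute)
})

test_that("spread obeys shift and constancy identities", {
  m <- matrix(rnorm(30), 10, 3,
              dimnames = list(letters[1:10], c("a", "b", "c")))
  same_m <- m[, c(1, 1, 1)]
  colnames(same_m) <- c("a", "b", "c")
  same <- lipo_table(same_m)
  expect_true(all(spread_summary(same)$per_compound$range == 0))

  two <- lipo_table(cbind(x = m[, 1], y = m[, 1] + 0.7))
  expect_equal(spread_summary(two)$per_compound$range, rep(0.7, 10),
               tolerance = 1e-12)
  expect_error(spread_summary(lipo_table(m), columns = "a"),
               class = "rmzero_parameter_error")
})

test_that("global extrema over the calculated columns match the stored table", {
  tab <- load_logp_table()
  rng <- range_summary(tab)
  expect_equal(rng$min, 2.78)
  expect_identical(unname(rng$argmin["method"]), "MLOGP")
  # the stored table's true global max (ClogP, compounds 16/20)
  expect_equal(rng$max, 6.90)
  expect_identical(unname(rng$argmax["method"]), "ClogP")
  # brute-force scan agreement
  expect_equal(c(rng$min, rng$max), range(tab$values))

  fits <- load_retention_fits()
  expect_equal(range(fits$rm0), c(3.15, 4.60))

  const <- lipo_table(matrix(2, 3, 2, dimnames = list(1:3, c("a", "b"))))
  cr <- range_summary(const)
  expect_equal(cr$min, cr$max)
})

test_that("the ADME screen reports ten parameters with HIA undefined", {
  tab <- load_combined_table()
  adme <- load_adme()
  scr <- adme_correlation_screen(tab, adme, "logP_TLC")
  expect_equal(nrow(scr), 10L)
  expect_true(is.na(scr$r[scr$parameter == "hia_pct"]))
  expect_match(scr$note[scr$parameter == "hia_pct"], "undefined")
  defined <- scr$r[!is.na(scr$r)]
  expect_true(all(abs(defined) <= 1))

  # permuting both inputs consistently leaves every r unchanged
  perm <- sample(nrow(adme))
  tab2 <- lipo_table(tab$values[perm, , drop = FALSE])
  scr2 <- adme_correlation_screen(tab2, adme, "logP_TLC")
  expect_equal(scr2$r, scr$r, tolerance = 1e-12)

  expect_error(
    adme_correlation_screen(tab, adme[-3, ], "logP_TLC"),
    class = "rmzero_join_error"
  )
})
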