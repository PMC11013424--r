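rec_full <- function(mw = 300, hbd = 1, hba = 3, logp = 4, atom_count = 40,
                     molar_refractivity = 80, rotatable_bonds = 2,
                     tpsa = 30) {
  list(mw = mw, hbd = hbd, hba = hba, logp = logp, atom_count = atom_count,
       molar_refractivity = molar_refractivity,
       rotatable_bonds = rotatable_bonds, tpsa = tpsa)
}

test_that("Lipinski evaluates four criteria under the 3-of-4 policy", {
  all_ok <- lipinski(rec_full())
  expect_true(all_ok$passes)
  expect_equal(sum(all_ok$criteria$satisfied), 4L)

  all_bad <- lipinski(rec_full(mw = 600, hbd = 6, hba = 11, logp = 6))
  expect_false(all_bad$passes)
  expect_equal(sum(all_bad$criteria$satisfied), 0L)

  one_violation <- lipinski(rec_full(mw = 400, hbd = 0, hba = 2, logp = 5.6))
  expect_true(one_violation$passes)
  expect_equal(sum(one_violation$criteria$satisfied), 3L)
  expect_false(one_violation$criteria$satisfied[
    one_violation$criteria$criterion == "logp <= 5"])
})

test_that("changing the Lipinski policy changes only the aggregate", {
  rec <- rec_full(mw = 400, hbd = 0, hba = 2, logp = 5.6)
  soft <- lipinski(rec, policy = "three_of_four")
  hard <- lipinski(rec, policy = "all")
  expect_identical(soft$criteria, hard$criteria)
  expect_true(soft$passes)
  expect_false(hard$passes)
})

test_that("Ghose bands are inclusive at both ends", {
  expect_true(ghose(rec_full())$passes)
  expect_false(ghose(rec_full(mw = 150))$passes)
  boundary <- ghose(rec_full(mw = 480, logp = 5.6, atom_count = 70,
                             molar_refractivity = 130))
  expect_true(boundary$passes)
  low_boundary <- ghose(rec_full(mw = 160, logp = 0.4, atom_count = 20,
                                 molar_refractivity = 40))
  expect_true(low_boundary$passes)
})

test_that("Veber and Egan bounds are inclusive and configurable", {
  expect_true(veber(rec_full(rotatable_bonds = 2, tpsa = 30))$passes)
  expect_false(veber(rec_full(rotatable_bonds = 11))$passes)
  expect_true(veber(rec_full(rotatable_bonds = 10, tpsa = 140))$passes)

  expect_true(egan(rec_full(tpsa = 60, logp = 2))$passes)
  expect_false(egan(rec_full(tpsa = 200, logp = 2))$passes)
  expect_true(egan(rec_full(tpsa = 131.6, logp = 5.88))$passes)
  expect_false(egan(rec_full(tpsa = 131.6, logp = 5.88),
                    psa_max = 100, logp_max = 5)$passes)
})

test_that("missing descriptors raise errors naming the field", {
  rec <- rec_full()
  rec$tpsa <- NULL
  err <- expect_error(veber(rec), class = "rmzero_incomplete_record")
  expect_match(conditionMessage(err), "tpsa")
  rec2 <- rec_full()
  rec2$molar_refractivity <- NA_real_
  expect_error(ghose(rec2), class = "rmzero_incomplete_record")
})

test_that("upper-bound rules are monotone: shrinking descriptors never fails a passer", {
  set.seed(21)
  for (i in 1:50) {
    rec <- rec_full(
      mw = stats::runif(1, 100, 700), hbd = sample(0:8, 1),
      hba = sample(0:14, 1), logp = stats::runif(1, -2, 8),
      rotatable_bonds = sample(0:14, 1), tpsa = stats::runif(1, 0, 220)
    )
    shrunk <- rec
    for (f in c("mw", "hbd", "hba", "logp", "rotatable_bonds", "tpsa")) {
      shrunk[[f]] <- max(0, rec[[f]] * stats::runif(1, 0, 1))
    }
    for (rule in list(lipinski, veber, egan)) {
      if (rule(rec)$passes) expect_true(rule(shrunk)$passes)
    }
  }
})

test_that("the batch screen counts failures per rule and ignores row order", {
  good <- do.call(rbind, lapply(1:19, function(i) {
    as.data.frame(rec_full(mw = 350 + i, logp = 4.5))
  }))
  # fails only the Ghose logP band: logP in (5.6, 5.88] passes Lipinski
  # (one violation), Veber and Egan, but not Ghose
  ghose_only <- do.call(rbind, lapply(1:2, function(i) {
    as.data.frame(rec_full(mw = 420, logp = 5.7))
  }))
  recs <- rbind(good, ghose_only)
  recs$compound <- as.character(seq_len(nrow(recs)))
  scr <- screen_rules(recs)
  expect_equal(unname(scr$failure_counts),
               c(0L, 2L, 0L, 0L))
  expect_identical(names(scr$failure_counts),
                   c("lipinski", "ghose", "veber", "egan"))

  shuffled <- recs[rev(seq_len(nrow(recs))), ]
  scr2 <- screen_rules(shuffled)
  expect_equal(scr2$failure_counts, scr$failure_counts)
  expect_identical(
    scr$table$ghose[match(recs$compound, scr$table$compound)],
    scr2$table$ghose[match(recs$compound, scr2$table$compound)]
  )
})
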