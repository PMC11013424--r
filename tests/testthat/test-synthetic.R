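test_that("noiseless plates invert every stage to numerical precision", {
  table3 <- load_retention_fits()
  params <- truth_params(table3$rm0, table3$b, compounds = table3$compound,
                         noise_sd = 0, replicates = 1, seed = 1)
  sim <- simulate_plate(params)
  for (i in seq_along(sim$series)) {
    fit <- fit_retention_line(sim$series[[i]])
    expect_equal(fit$r_m0, table3$rm0[i], tolerance = 1e-9)
    expect_equal(fit$b, table3$b[i], tolerance = 1e-9)
    expect_equal(abs(fit$r), 1, tolerance = 1e-9)
  }
})

test_that("simulation is deterministic in the seed and sensitive to it", {
  p <- truth_params(c(3.5, 4.2), c(-0.045, -0.055), noise_sd = 0.01,
                    seed = 99)
  s1 <- simulate_plate(p)
  s2 <- simulate_plate(p)
  expect_identical(s1, s2)
  p2 <- truth_params(c(3.5, 4.2), c(-0.045, -0.055), noise_sd = 0.01,
                     seed = 100)
  s3 <- simulate_plate(p2)
  expect_false(identical(s1$series[[1]]$rf, s3$series[[1]]$rf))
})

test_that("adding a compound leaves the other compounds' draws untouched", {
  p2 <- truth_params(c(3.5, 4.2), c(-0.045, -0.055), noise_sd = 0.01, seed = 5)
  p3 <- truth_params(c(3.5, 4.2, 3.8), c(-0.045, -0.055, -0.050),
                     noise_sd = 0.01, seed = 5)
  s2 <- simulate_plate(p2)
  s3 <- simulate_plate(p3)
  expect_identical(s2$series[[1]]$rf, s3$series[[1]]$rf)
  expect_identical(s2$series[[2]]$rf, s3$series[[2]]$rf)
})

test_that("infeasible designs are rejected with the offending points", {
  p <- truth_params(1000, -0.1, seed = 1)
  err <- expect_error(simulate_plate(p), class = "rmzero_infeasible_design")
  expect_match(conditionMessage(err), "50")
  expect_error(truth_params(3.5, 0.01), class = "rmzero_parameter_error")
  expect_error(truth_params(3.5, -0.04, noise_sd = -1),
               class = "rmzero_parameter_error")
})

test_that("noiseless standards reproduce the generating line exactly", {
  sim <- simulate_standards(1.2838, 0.2138,
                            r_m0_values = c(0.78, 1.16, 2.51, 3.33, 4.69),
                            noise_sd_logp = 0, seed = 1)
  m <- fit_calibration(sim$standards)
  expect_equal(m$slope, 1.2838, tolerance = 1e-9)
  expect_equal(m$intercept, 0.2138, tolerance = 1e-9)
  tiny <- simulate_standards(1, 0, r_m0_values = c(1, 2, 3))
  expect_equal(nrow(tiny$standards), 3L)
  expect_error(simulate_standards(1, 0, r_m0_values = c(1, 2)),
               class = "rmzero_parameter_error")
})

test_that("repeated noisy fits recover the calibration slope on average", {
  set.seed(31)
  slopes <- vapply(1:120, function(i) {
    sim <- simulate_standards(1.2838, 0.2138,
                              r_m0_values = c(0.78, 1.16, 2.51, 3.33, 4.69),
                              noise_sd_logp = 0.19, seed = 5000 + i)
    fit_calibration(sim$standards)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1.2838), 0.05)
})

test_that("R_M0 recovery error shrinks as plate noise shrinks", {
  mae_at <- function(noise) {
    set.seed(77)
    truth <- rmzero:::draw_truth(60)
    p <- truth_params(truth$r_m0, truth$b, noise_sd = noise, replicates = 3,
                      seed = 7700 + round(noise * 1000))
    sim <- simulate_plate(p)
    est <- vapply(sim$series, function(s) fit_retention_line(s)$r_m0,
                  numeric(1))
    mean(abs(est - truth$r_m0))
  }
  errs <- vapply(c(0.02, 0.01, 0.005), mae_at, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("the demo bundle is coherent, schema-valid and seed-stable", {
  d <- make_demo_dataset(seed = 42)
  expect_s3_class(d$lipophilicity, "lipo_table")
  expect_equal(dim(d$lipophilicity), c(21L, 8L))
  expect_true(all(d$lipophilicity$values >= 2.78 - 1e-9 &
                    d$lipophilicity$values <= 6.84 + 1e-9))
  expect_true(all(d$plates$truth$r_m0 >= 3.15 & d$plates$truth$r_m0 <= 4.60))
  expect_true(all(d$plates$truth$b < 0))
  expect_equal(d$seed, 42L)

  # standards/ADME/descriptors pass their validators via a file round trip
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d$adme, f, row.names = FALSE)
  expect_silent(read_adme_table(f))
  utils::write.csv(d$standards, f, row.names = FALSE)
  expect_silent(read_calibration_standards(f))
  expect_equal(nrow(screen_rules(d$descriptors)$table), 21L)

  d2 <- make_demo_dataset(seed = 43)
  expect_false(identical(d$plates$series[[1]]$rf, d2$plates$series[[1]]$rf))
  expect_identical(make_demo_dataset(seed = 42)$plates$series[[1]]$rf,
                   d$plates$series[[1]]$rf)
})
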