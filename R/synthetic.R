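#' Ground-truth parameters for a simulated plate experiment
#'
#' Describes the design of a simulated RP-TLC experiment: per-compound true
#' retention parameters (intercept `r_m0` and negative slope `b` of the
#' R_M-vs-concentration line), the modifier concentration levels, the
#' standard deviation of additive measurement noise on R_F, the number of
#' replicate chromatograms per level, and the random seed. Defaults mirror a
#' typical gradient design: eight acetone levels from 50 to 85% v/v in 5%
#' steps, three replicates, R_F noise of 0.01.
#'
#' @param r_m0 numeric vector of true intercepts, one per compound.
#' @param b numeric vector of true slopes (per % v/v), all negative.
#' @param compounds optional compound ids (default `"1"`, `"2"`, ...).
#' @param concentrations modifier levels, % v/v, distinct, within \[0, 100\].
#' @param noise_sd standard deviation of Gaussian noise added to R_F.
#' @param replicates replicate chromatograms per concentration (>= 1).
#' @param seed integer random seed.
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(r_m0, b, compounds = NULL,
                         concentrations = seq(50, 85, by = 5),
                         noise_sd = 0.01, replicates = 3, seed = 1) {
  if (length(r_m0) != length(b) || !length(r_m0)) {
    rmz_stop("'r_m0' and 'b' must be non-empty and the same length",
             "rmzero_parameter_error")
  }
  if (any(!is.finite(r_m0)) || any(!is.finite(b)) || any(b >= 0)) {
    rmz_stop("true slopes must be finite and negative", "rmzero_parameter_error")
  }
  if (any(concentrations < 0 | concentrations > 100) ||
      anyDuplicated(concentrations)) {
    rmz_stop("concentrations must be distinct and within [0, 100]",
             "rmzero_parameter_error")
  }
  if (noise_sd < 0) rmz_stop("'noise_sd' must be >= 0", "rmzero_parameter_error")
  if (replicates < 1 || replicates != round(replicates)) {
    rmz_stop("'replicates' must be a positive integer", "rmzero_parameter_error")
  }
  compounds <- compounds %||% as.character(seq_along(r_m0))
  if (anyDuplicated(compounds)) {
    rmz_stop("compound ids must be unique", "rmzero_parameter_error")
  }
  structure(
    list(compounds = as.character(compounds), r_m0 = r_m0, b = b,
         concentrations = sort(concentrations), noise_sd = noise_sd,
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "truth_params"
  )
}

# Derive an independent per-compound seed from the global seed, so adding a
# compound to a design never perturbs the draws of the others.
compound_seed <- function(seed, i) {
  (as.double(seed) * 48271 + i * 7919) %% 2147483647
}

#' Simulate RP-TLC plate measurements with known ground truth
#'
#' For each compound the true line `R_M = r_m0 + b * C` is inverted to true
#' retention factors `R_F = 1 / (1 + 10^R_M)`; Gaussian noise (sd
#' `noise_sd`) is added independently per replicate in R_F space — the
#' quantity actually read off a plate — the noisy values are clipped to
#' \[0.01, 0.99\], and replicates are averaged into one reported series per
#' compound. A design whose noise-free R_F falls outside (0, 1) is rejected
#' with the offending (compound, concentration) pairs. Identical seeds give
#' identical output.
#'
#' @param params a [truth_params()].
#' @return A list of class `plate_simulation`: `series` (named list of
#'   [retention_series()]), `truth` (data frame `compound`, `r_m0`, `b`) and
#'   `seed`.
#' @examples
#' p <- truth_params(r_m0 = 3.15, b = -0.0383, noise_sd = 0)
#' fit_retention_line(simulate_plate(p)$series[[1]])$r_m0  # 3.15
#' @export
simulate_plate <- function(params) {
  stopifnot(inherits(params, "truth_params"))
  cc <- params$concentrations
  rm_true <- outer(seq_along(params$r_m0), seq_along(cc),
                   function(i, j) params$r_m0[i] + params$b[i] * cc[j])
  rf_true <- 1 / (1 + 10^rm_true)
  bad <- which(rf_true <= 0 | rf_true >= 1, arr.ind = TRUE)
  if (nrow(bad)) {
    pairs <- apply(bad, 1, function(ij) {
      sprintf("(%s, %g%%)", params$compounds[ij[1]], cc[ij[2]])
    })
    rmz_stop(paste("design infeasible; noise-free R_F outside (0,1) at:",
                   paste(unique(pairs), collapse = ", ")),
             "rmzero_infeasible_design")
  }
  series <- vector("list", length(params$compounds))
  for (i in seq_along(params$compounds)) {
    set.seed(compound_seed(params$seed, i))
    obs <- vapply(seq_along(cc), function(j) {
      reps <- rf_true[i, j] + stats::rnorm(params$replicates, 0, params$noise_sd)
      mean(pmin(pmax(reps, 0.01), 0.99))
    }, numeric(1))
    series[[i]] <- retention_series(
      params$compounds[i], cc, obs,
      replicate_count = rep(params$replicates, length(cc))
    )
  }
  names(series) <- params$compounds
  structure(
    list(series = series,
         truth = data.frame(compound = params$compounds, r_m0 = params$r_m0,
                            b = params$b, stringsAsFactors = FALSE),
         seed = params$seed),
    class = "plate_simulation"
  )
}

#' Simulate calibration standards with known line coefficients
#'
#' Generates standards whose literature logP is `slope * r_m0 + intercept`
#' plus Gaussian noise, so a downstream [fit_calibration()] can be checked
#' against the generating truth.
#'
#' @param slope,intercept true calibration coefficients.
#' @param r_m0_values R_M0 values of the simulated standards (>= 3).
#' @param noise_sd_logp standard deviation of the noise on logP.
#' @param seed integer random seed.
#' @return A list: `standards` (data frame `compound`, `rm0`, `logp_lit`) and
#'   `truth` (slope, intercept, noise_sd_logp, seed).
#' @export
simulate_standards <- function(slope, intercept, r_m0_values,
                               noise_sd_logp = 0, seed = 1) {
  stopifnot_scalar_number(slope, "slope")
  stopifnot_scalar_number(intercept, "intercept")
  if (length(r_m0_values) < 3L) {
    rmz_stop("at least 3 standards required", "rmzero_parameter_error")
  }
  if (noise_sd_logp < 0) {
    rmz_stop("'noise_sd_logp' must be >= 0", "rmzero_parameter_error")
  }
  set.seed(as.integer(seed))
  logp <- slope * r_m0_values + intercept +
    stats::rnorm(length(r_m0_values), 0, noise_sd_logp)
  list(
    standards = data.frame(
      compound = as.character(as.roman(seq_along(r_m0_values))),
      rm0 = r_m0_values, logp_lit = logp, stringsAsFactors = FALSE
    ),
    truth = list(slope = slope, intercept = intercept,
                 noise_sd_logp = noise_sd_logp, seed = as.integer(seed))
  )
}

# Default truth ranges for this compound class (pentacyclic thiazines on
# RP-18 with an acetone gradient): R_M0 in [3.15, 4.60], slopes in
# [-0.0582, -0.0383], with slope steepening as R_M0 grows so that measured
# R_F stays on-plate across the 50-85% gradient.
draw_truth <- function(n) {
  r_m0 <- stats::runif(n, 3.15, 4.60)
  b_mid <- -(0.0383 + (r_m0 - 3.15) / (4.60 - 3.15) * (0.0582 - 0.0383))
  b <- b_mid + stats::runif(n, -0.001, 0.001)
  list(r_m0 = r_m0, b = b)
}

#' Generate a coherent synthetic analysis bundle
#'
#' Builds a complete 21-compound demonstration dataset with known ground
#' truth: plate series (with noise), calibration standards, a
#' compounds-by-methods logP matrix whose marginal range matches typical
#' calculated values for this compound class (2.78-6.84), a molecular
#' descriptor table, and a predicted ADME table. Deterministic in `seed`.
#'
#' @param seed integer random seed.
#' @param n_compounds number of compounds (default 21).
#' @param noise_sd R_F noise passed to the plate simulation.
#' @param replicates replicates per concentration.
#' @return A named list: `plates` (a `plate_simulation`), `standards`,
#'   `lipophilicity` (a [lipo_table()]), `descriptors`, `adme`, `seed`.
#' @export
make_demo_dataset <- function(seed = 1, n_compounds = 21,
                              noise_sd = 0.01, replicates = 3) {
  seed <- as.integer(seed)
  set.seed(seed)
  truth <- draw_truth(n_compounds)
  ids <- as.character(seq_len(n_compounds))
  params <- truth_params(truth$r_m0, truth$b, compounds = ids,
                         noise_sd = noise_sd, replicates = replicates,
                         seed = seed)
  plates <- simulate_plate(params)
  std <- simulate_standards(1.2838, 0.2138,
                            r_m0_values = c(0.78, 1.16, 2.51, 3.33, 4.69),
                            noise_sd_logp = 0.05, seed = seed + 101L)
  # logP matrix: per-method affine distortion of the true logP plus noise,
  # clamped into the realistic calculated range for this class
  methods <- c("ALOGPs", "AClogP", "ALOGP", "MLOGP", "XLOGP2", "XLOGP3",
               "LogP", "ClogP")
  set.seed(seed + 211L)
  logp_true <- 1.2838 * truth$r_m0 + 0.2138
  vals <- sapply(seq_along(methods), function(k) {
    bias <- stats::runif(1, -0.8, 0.4)
    scale <- stats::runif(1, 0.8, 1.1)
    pmin(pmax(scale * logp_true + bias + stats::rnorm(n_compounds, 0, 0.25),
              2.78), 6.84)
  })
  dimnames(vals) <- list(ids, methods)
  lipo <- lipo_table(vals)
  set.seed(seed + 307L)
  descriptors <- data.frame(
    compound = ids,
    mw = stats::runif(n_compounds, 330, 420),
    hbd = sample(0:1, n_compounds, replace = TRUE),
    hba = sample(3:4, n_compounds, replace = TRUE),
    logp = rowMeans(vals),
    atom_count = sample(40:60, n_compounds, replace = TRUE),
    molar_refractivity = stats::runif(n_compounds, 100, 125),
    rotatable_bonds = sample(0:2, n_compounds, replace = TRUE),
    tpsa = stats::runif(n_compounds, 20, 35),
    stringsAsFactors = FALSE
  )
  set.seed(seed + 401L)
  adme <- data.frame(
    compound = ids,
    caco2_pe = round(stats::runif(n_compounds, 94, 235)),
    ppb_pct = sample(99:100, n_compounds, replace = TRUE),
    cns = round(stats::runif(n_compounds, -4.3, -3.2), 2),
    hia_pct = rep(100, n_compounds),
    pgp_score = round(stats::runif(n_compounds, 0.28, 0.38), 2),
    cyp1a2 = round(stats::runif(n_compounds, 0.55, 0.71), 2),
    cyp2c9 = round(stats::runif(n_compounds, 0.26, 0.40), 2),
    cyp2c19 = round(stats::runif(n_compounds, 0.49, 0.57), 2),
    cyp2d6 = round(stats::runif(n_compounds, 0.37, 0.50), 2),
    cyp3a4 = round(stats::runif(n_compounds, 0.50, 0.58), 2),
    stringsAsFactors = FALSE
  )
  list(plates = plates, standards = std$standards, lipophilicity = lipo,
       descriptors = descriptors, adme = adme, seed = seed)
}
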