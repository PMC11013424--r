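#' Build a run configuration for the full analysis
#'
#' Collects every input path and analysis option into a validated named list.
#' Retention input may be either raw long-format plate measurements
#' (`retention_measurements`) or a precomputed per-compound fit table
#' (`retention_fits`); exactly one is required.
#'
#' @param lipophilicity path to the compounds-by-methods logP CSV.
#' @param standards path to the calibration standards CSV.
#' @param retention_fits path to a fitted-parameters CSV (`compound`, `rm0`,
#'   `b`, `r`), or `NULL`.
#' @param retention_measurements path to long-format plate measurements, or
#'   `NULL`.
#' @param adme optional path to a predicted-ADME CSV.
#' @param descriptors optional path to a molecular-descriptor CSV for the
#'   drug-likeness screen.
#' @param calibration `"refit"` (fit the line from the standards) or
#'   `"fixed"` (use `fixed_coefficients` as published).
#' @param fixed_coefficients numeric `c(slope, intercept)` used when
#'   `calibration = "fixed"`.
#' @param min_r,min_points QC thresholds for retention fits.
#' @param cluster_axis `"rows"`, `"columns"` or `"both"`.
#' @param k number of compound clusters to report.
#' @param standardize z-score variables before clustering.
#' @param rules drug-likeness rules to screen (when `descriptors` given).
#' @param out_dir optional report directory for [write_report()].
#' @param seed integer seed for any simulation steps.
#' @param decimals reported decimals for logP values (correlations always use
#'   three).
#' @return An object of class `run_config`.
#' @export
run_config <- function(lipophilicity,
                       standards,
                       retention_fits = NULL,
                       retention_measurements = NULL,
                       adme = NULL,
                       descriptors = NULL,
                       calibration = c("refit", "fixed"),
                       fixed_coefficients = c(1.2838, 0.2138),
                       min_r = 0.99, min_points = 3,
                       cluster_axis = "both", k = 3, standardize = FALSE,
                       rules = c("lipinski", "ghose", "veber", "egan"),
                       out_dir = NULL, seed = 1, decimals = 2) {
  structure(
    list(lipophilicity = lipophilicity, standards = standards,
         retention_fits = retention_fits,
         retention_measurements = retention_measurements,
         adme = adme, descriptors = descriptors,
         calibration = match.arg(calibration),
         fixed_coefficients = fixed_coefficients,
         min_r = min_r, min_points = min_points,
         cluster_axis = cluster_axis, k = k, standardize = standardize,
         rules = rules, out_dir = out_dir, seed = seed, decimals = decimals),
    class = "run_config"
  )
}

#' Validate a run configuration
#'
#' Checks every field and returns all violations at once (as data, never by
#' raising on the first problem).
#'
#' @param config a [run_config()].
#' @return A data frame with columns `field` and `message`; zero rows means
#'   the configuration is valid.
#' @export
validate_config <- function(config) {
  v <- list()
  flag <- function(field, message) {
    v[[length(v) + 1L]] <<- data.frame(field = field, message = message,
                                       stringsAsFactors = FALSE)
  }
  check_path <- function(field, required) {
    p <- config[[field]]
    if (is.null(p)) {
      if (required) flag(field, "required input path is missing")
      return()
    }
    if (!is.character(p) || length(p) != 1L || !file.exists(p)) {
      flag(field, sprintf("path does not exist: %s", as.character(p)[1]))
    }
  }
  check_path("lipophilicity", required = TRUE)
  check_path("standards", required = TRUE)
  if (is.null(config$retention_fits) && is.null(config$retention_measurements)) {
    flag("retention_fits",
         "provide retention_fits or retention_measurements")
  }
  check_path("retention_fits", required = FALSE)
  check_path("retention_measurements", required = FALSE)
  check_path("adme", required = FALSE)
  check_path("descriptors", required = FALSE)
  if (!config$calibration %in% c("refit", "fixed")) {
    flag("calibration", "must be 'refit' or 'fixed'")
  }
  if (config$calibration == "fixed" &&
      (!is.numeric(config$fixed_coefficients) ||
       length(config$fixed_coefficients) != 2L ||
       any(!is.finite(config$fixed_coefficients)))) {
    flag("fixed_coefficients", "must be numeric c(slope, intercept)")
  }
  if (!is.numeric(config$k) || length(config$k) != 1L || config$k < 1 ||
      config$k != round(config$k)) {
    flag("k", "must be an integer >= 1")
  }
  if (!is.numeric(config$decimals) || config$decimals < 0) {
    flag("decimals", "must be >= 0")
  }
  if (!is.numeric(config$min_r) || config$min_r < 0 || config$min_r > 1) {
    flag("min_r", "must be in [0, 1]")
  }
  if (!config$cluster_axis %in% c("rows", "columns", "both")) {
    flag("cluster_axis", "must be 'rows', 'columns' or 'both'")
  }
  bad_rules <- setdiff(config$rules, c("lipinski", "ghose", "veber", "egan"))
  if (length(bad_rules)) {
    flag("rules", paste("unknown rules:", paste(bad_rules, collapse = ", ")))
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(field = character(0), message = character(0))
}

stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full lipophilicity analysis
#'
#' Orchestrates the end-to-end workflow: read and validate inputs; obtain
#' per-compound R_M0 (from a fit table, or by fitting raw plate
#' measurements); QC the fits; fit (or fix) the calibration and convert R_M0
#' to logP_TLC; append the experimental column to the logP matrix; compute
#' concordance statistics (correlation of every method with logP_TLC,
#' per-compound spread, global range); correlate logP_TLC with ADME
#' parameters when supplied; cluster methods and/or compounds by
#' single-linkage on Euclidean distances; screen descriptors against
#' drug-likeness rules when supplied; and optionally write a report
#' directory. Reruns with identical inputs and configuration are
#' deterministic.
#'
#' @param config a [run_config()]; invalid configurations abort before any
#'   computation, listing every violation.
#' @param verbose log one line per stage.
#' @return A list of class `rmzero_analysis` with elements `calibration`
#'   (model summary), `logp_tlc` (per-compound table), `lipophilicity`
#'   (the augmented [lipo_table()]), `qc`, `method_correlations`, `spread`,
#'   `range`, `adme_correlations`, `method_tree`/`compound_tree` (Newick),
#'   `compound_clusters`, `rule_screen`, and `manifest` when a report was
#'   written.
#' @examples
#' cfg <- run_config(
#'   lipophilicity = system.file("extdata", "logp_calcd_table.csv",
#'                               package = "rmzero"),
#'   standards = system.file("extdata", "calibration_standards.csv",
#'                           package = "rmzero"),
#'   retention_fits = system.file("extdata", "retention_fits_table.csv",
#'                                package = "rmzero"))
#' res <- run_full_analysis(cfg, verbose = FALSE)
#' res$calibration$r
#' @export
run_full_analysis <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  violations <- validate_config(config)
  if (nrow(violations)) {
    rmz_stop(paste0("invalid configuration:\n",
                    paste(sprintf("  - %s: %s", violations$field,
                                  violations$message), collapse = "\n")),
             "rmzero_config_error")
  }
  out <- list()

  # --- retention -----------------------------------------------------------
  if (!is.null(config$retention_measurements)) {
    meas <- read_retention_measurements(config$retention_measurements)
    series <- average_replicates(meas)
    fits <- lapply(series, fit_retention_line)
    fit_tab <- data.frame(
      compound = vapply(fits, `[[`, character(1), "compound"),
      rm0 = vapply(fits, `[[`, numeric(1), "r_m0"),
      b = vapply(fits, `[[`, numeric(1), "b"),
      r = vapply(fits, `[[`, numeric(1), "r"),
      stringsAsFactors = FALSE
    )
    out$qc <- qc_retention_fits(fits, min_r = config$min_r,
                                min_points = config$min_points)
    stage_log(verbose, "retention", "fitted %d series from %d measurements",
              nrow(fit_tab), nrow(meas))
  } else {
    fit_tab <- read_retention_fits(config$retention_fits)
    pseudo <- lapply(seq_len(nrow(fit_tab)), function(i) {
      structure(list(compound = fit_tab$compound[i], r_m0 = fit_tab$rm0[i],
                     b = fit_tab$b[i], r = fit_tab$r[i], n = NA_integer_,
                     residual_sd = NA_real_, extrapolation_leverage = NA_real_,
                     degenerate = FALSE),
                class = "retention_fit")
    })
    out$qc <- qc_retention_fits(pseudo, min_r = config$min_r, min_points = 0)
    stage_log(verbose, "retention", "loaded %d precomputed fits",
              nrow(fit_tab))
  }
  rownames(fit_tab) <- NULL

  # --- calibration ---------------------------------------------------------
  standards <- read_calibration_standards(config$standards)
  model <- if (config$calibration == "fixed") {
    fixed_calibration(config$fixed_coefficients[1], config$fixed_coefficients[2])
  } else {
    fit_calibration(standards)
  }
  logp_tlc <- apply_calibration(model, fit_tab$rm0)
  out$calibration <- list(
    mode = config$calibration, slope = model$slope,
    intercept = model$intercept, r = model$r, s = model$s,
    f_stat = model$f_stat, n = model$n
  )
  out$logp_tlc <- data.frame(
    compound = fit_tab$compound, rm0 = fit_tab$rm0,
    logp_tlc = round_half_up(logp_tlc, config$decimals),
    stringsAsFactors = FALSE
  )
  if (config$calibration == "refit") {
    out$calibration_diagnostics <- calibration_diagnostics(model, standards)
  }
  stage_log(verbose, "calibration", "%s: logP_TLC = %.4f R_M0 + %.4f (n = %d)",
            config$calibration, model$slope, model$intercept, nrow(fit_tab))

  # --- concordance ---------------------------------------------------------
  lipo <- read_lipophilicity_table(config$lipophilicity)
  ids <- rownames(lipo$values)
  miss <- setdiff(ids, fit_tab$compound)
  if (length(miss)) {
    rmz_stop(paste("stage concordance: no R_M0 for compounds:",
                   paste(miss, collapse = ", ")), "rmzero_join_error")
  }
  aug <- cbind(lipo$values,
               logP_TLC = logp_tlc[match(ids, fit_tab$compound)])
  lipo_aug <- lipo_table(aug)
  out$lipophilicity <- lipo_aug
  out$method_correlations <- correlation_matrix(lipo_aug, "logP_TLC")
  out$method_correlations$r <- round(out$method_correlations$r, 3)
  out$spread <- spread_summary(lipo, columns = colnames(lipo$values))
  out$range <- range_summary(lipo)
  stage_log(verbose, "concordance",
            "%d methods vs logP_TLC; spread max %.2f (compound %s)",
            nrow(out$method_correlations), out$spread$max_range,
            out$spread$argmax_compound)

  # --- ADME ----------------------------------------------------------------
  if (!is.null(config$adme)) {
    adme <- read_adme_table(config$adme)
    out$adme_correlations <- adme_correlation_screen(lipo_aug, adme,
                                                     "logP_TLC")
    out$adme_correlations$r <- round(out$adme_correlations$r, 3)
    stage_log(verbose, "adme", "%d parameters screened (%d undefined)",
              nrow(out$adme_correlations),
              sum(is.na(out$adme_correlations$r)))
  }

  # --- clustering ----------------------------------------------------------
  if (config$cluster_axis %in% c("columns", "both")) {
    tree_m <- single_linkage(euclidean_distances(
      lipo_aug, axis = "columns", standardize = config$standardize))
    out$method_tree <- export_dendrogram(tree_m)
    stage_log(verbose, "clustering", "methods: %d leaves",
              length(tree_m$labels))
  }
  if (config$cluster_axis %in% c("rows", "both")) {
    tree_c <- single_linkage(euclidean_distances(
      lipo_aug, axis = "rows", standardize = config$standardize))
    out$compound_tree <- export_dendrogram(tree_c)
    cl <- cut_tree(tree_c, config$k)
    out$compound_clusters <- data.frame(compound = names(cl),
                                        cluster = unname(cl),
                                        stringsAsFactors = FALSE)
    stage_log(verbose, "clustering", "compounds: %d leaves cut at k = %d",
              length(cl), config$k)
  }

  # --- drug-likeness -------------------------------------------------------
  if (!is.null(config$descriptors)) {
    recs <- utils::read.csv(config$descriptors, stringsAsFactors = FALSE)
    recs$compound <- as.character(recs$compound)
    scr <- screen_rules(recs, rules = config$rules)
    out$rule_screen <- scr$table
    out$rule_failure_counts <- as.list(scr$failure_counts)
    stage_log(verbose, "rules", "%d compounds x %d rules; failures: %s",
              nrow(scr$table), length(config$rules),
              paste(names(scr$failure_counts), scr$failure_counts,
                    sep = "=", collapse = ", "))
  }

  # --- report --------------------------------------------------------------
  if (!is.null(config$out_dir)) {
    report <- list(
      logp_tlc = out$logp_tlc,
      method_correlations = out$method_correlations,
      spread = out$spread$per_compound,
      qc = out$qc,
      summary = list(calibration = out$calibration,
                     range = out$range, seed = config$seed)
    )
    if (!is.null(out$adme_correlations)) {
      report$adme_correlations <- out$adme_correlations
    }
    if (!is.null(out$method_tree)) report$method_tree <- out$method_tree
    if (!is.null(out$compound_tree)) report$compound_tree <- out$compound_tree
    if (!is.null(out$compound_clusters)) {
      report$compound_clusters <- out$compound_clusters
    }
    if (!is.null(out$rule_screen)) report$rule_screen <- out$rule_screen
    out$manifest <- write_report(report, config$out_dir)
    stage_log(verbose, "report", "wrote %d files to %s",
              nrow(out$manifest), config$out_dir)
  }

  structure(out, class = c("rmzero_analysis", "list"))
}

#' @export
print.rmzero_analysis <- function(x, ...) {
  cat("<rmzero_analysis>\n")
  cat(sprintf("  calibration (%s): logP_TLC = %.4f R_M0 + %.4f",
              x$calibration$mode, x$calibration$slope,
              x$calibration$intercept))
  if (!is.na(x$calibration$r)) {
    cat(sprintf(" (r = %.3f, s = %.3f, F = %.1f)",
                x$calibration$r, x$calibration$s, x$calibration$f_stat))
  }
  cat("\n")
  cat(sprintf("  %d compounds, logP_TLC %.2f .. %.2f\n",
              nrow(x$logp_tlc), min(x$logp_tlc$logp_tlc),
              max(x$logp_tlc$logp_tlc)))
  if (!is.null(x$method_correlations)) {
    best <- x$method_correlations[which.max(x$method_correlations$r), ]
    cat(sprintf("  best-agreeing method: %s (r = %.3f)\n",
                best$method, best$r))
  }
  invisible(x)
}
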