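#' Transform a retention factor to R_M
#'
#' In reversed-phase TLC the retention factor R_F (fraction of the solvent
#' front travelled by a spot) is converted to the chromatographic retention
#' parameter R_M = log10(1/R_F - 1), which is linear in the organic-modifier
#' concentration of the mobile phase. The transform is the base-10 logit of
#' (1 - R_F): strictly decreasing in R_F, zero at R_F = 0.5, and antisymmetric
#' about it.
#'
#' @param r_f numeric vector of retention factors, each strictly in (0, 1).
#' @return R_M values (dimensionless, log10 scale).
#' @seealso [rm_to_rf()] for the inverse.
#' @examples
#' rf_to_rm(0.5)   # 0
#' rf_to_rm(0.1)   # log10(9)
#' @export
rf_to_rm <- function(r_f) {
  if (!is.numeric(r_f) || any(!is.finite(r_f)) ||
      any(r_f <= 0) || any(r_f >= 1)) {
    rmz_stop("retention factors must lie strictly in (0, 1); values at 0 or 1 indicate a spot at the origin or the solvent front",
             "rmzero_domain_error")
  }
  log10(1 / r_f - 1)
}

#' Inverse of the R_F to R_M transform
#'
#' @param r_m numeric vector of R_M values.
#' @return Retention factors in (0, 1): `1 / (1 + 10^r_m)`.
#' @export
rm_to_rf <- function(r_m) {
  if (!is.numeric(r_m) || any(!is.finite(r_m))) {
    rmz_stop("R_M values must be finite", "rmzero_domain_error")
  }
  1 / (1 + 10^r_m)
}

#' Construct a retention series
#'
#' One compound's averaged plate measurements across the organic-modifier
#' gradient: pairs of concentration (% v/v) and retention factor. At least
#' three distinct concentrations are required for a line fit downstream.
#'
#' @param compound compound identifier (scalar character).
#' @param concentration numeric vector of modifier concentrations, % v/v,
#'   each in \[0, 100\], all distinct.
#' @param rf numeric vector of retention factors in (0, 1), same length.
#' @param replicate_count optional integer vector of replicates averaged into
#'   each point.
#' @return An object of class `retention_series`.
#' @export
retention_series <- function(compound, concentration, rf,
                             replicate_count = NULL) {
  compound <- as.character(compound)
  if (length(compound) != 1L || !nzchar(compound)) {
    rmz_stop("'compound' must be a single non-empty id", "rmzero_schema_error")
  }
  if (length(concentration) != length(rf)) {
    rmz_stop("'concentration' and 'rf' must have the same length",
             "rmzero_schema_error")
  }
  if (any(!is.finite(concentration)) || any(concentration < 0) ||
      any(concentration > 100)) {
    rmz_stop("concentrations must be finite and within [0, 100] % v/v",
             "rmzero_domain_error")
  }
  if (anyDuplicated(concentration)) {
    rmz_stop(sprintf("duplicate concentrations in series '%s'", compound),
             "rmzero_schema_error")
  }
  if (any(!is.finite(rf)) || any(rf <= 0) || any(rf >= 1)) {
    rmz_stop(sprintf("retention factors in series '%s' must lie in (0, 1)",
                     compound), "rmzero_domain_error")
  }
  if (!is.null(replicate_count)) {
    if (length(replicate_count) != length(rf) ||
        any(replicate_count < 1 | replicate_count != round(replicate_count))) {
      rmz_stop("'replicate_count' must be positive integers per point",
               "rmzero_schema_error")
    }
  }
  structure(
    list(compound = compound,
         concentration = as.numeric(concentration),
         rf = as.numeric(rf),
         replicate_count = replicate_count),
    class = "retention_series"
  )
}

#' @export
print.retention_series <- function(x, ...) {
  cat(sprintf("<retention_series> compound %s, %d concentrations (%g-%g%% v/v)\n",
              x$compound, length(x$concentration),
              min(x$concentration), max(x$concentration)))
  invisible(x)
}

#' Average replicate plate measurements into retention series
#'
#' Replicate R_F readings are averaged in R_F space (the quantity actually
#' measured on a plate) before the R_M transform, one averaged point per
#' (compound, concentration).
#'
#' @param measurements long-format data frame with columns `compound`,
#'   `concentration`, `rf` (see [read_retention_measurements()]).
#' @return A named list of [retention_series()], one per compound, in first
#'   appearance order.
#' @export
average_replicates <- function(measurements) {
  need <- c("compound", "concentration", "rf")
  if (!all(need %in% names(measurements))) {
    rmz_stop("measurements need columns compound, concentration, rf",
             "rmzero_schema_error")
  }
  ids <- unique(measurements$compound)
  out <- lapply(ids, function(id) {
    sub <- measurements[measurements$compound == id, , drop = FALSE]
    agg <- stats::aggregate(rf ~ concentration, data = sub, FUN = mean)
    cnt <- stats::aggregate(rf ~ concentration, data = sub, FUN = length)
    agg <- agg[order(agg$concentration), , drop = FALSE]
    cnt <- cnt[order(cnt$concentration), , drop = FALSE]
    retention_series(id, agg$concentration, agg$rf,
                     replicate_count = cnt$rf)
  })
  names(out) <- ids
  out
}

#' Fit the linear R_M extrapolation to zero modifier
#'
#' Transforms a series' retention factors to R_M and fits the line
#' `R_M = R_M0 + b * C` by ordinary least squares. The intercept R_M0 — the
#' retention parameter extrapolated to a purely aqueous mobile phase — is the
#' chromatographic lipophilicity index. Because the measured concentrations
#' (typically 50-85% v/v) sit far from C = 0, the fit also records the
#' leverage of the extrapolation point (`1/n + mean(C)^2 / Sxx`); high
#' leverage is reported, not rejected.
#'
#' A series whose R_M values are all equal yields a degenerate fit (`b = 0`,
#' `r = NA`) flagged via `degenerate = TRUE` rather than an error.
#'
#' @param series a [retention_series()], or a data frame with columns
#'   `concentration` and `rf` plus an optional `compound`.
#' @return An object of class `retention_fit` with fields `compound`, `r_m0`,
#'   `b`, `r` (Pearson correlation of C and R_M), `n`, `residual_sd`
#'   (`sqrt(SSE/(n-2))`), `extrapolation_leverage` and `degenerate`.
#' @examples
#' s <- retention_series("demo", seq(50, 85, 5),
#'                       rm_to_rf(3.15 - 0.0383 * seq(50, 85, 5)))
#' fit_retention_line(s)
#' @export
fit_retention_line <- function(series) {
  if (is.data.frame(series)) {
    id <- if ("compound" %in% names(series)) unique(series$compound) else "?"
    if (length(id) != 1L) {
      rmz_stop("data frame input must describe a single compound",
               "rmzero_schema_error")
    }
    series <- retention_series(id, series$concentration, series$rf)
  }
  stopifnot(inherits(series, "retention_series"))
  cc <- series$concentration
  n <- length(cc)
  if (n < 3L) {
    rmz_stop(sprintf("series '%s': at least 3 points required, got %d",
                     series$compound, n), "rmzero_insufficient_data")
  }
  if (stats::var(cc) == 0) {
    rmz_stop(sprintf("series '%s': zero variance in concentration",
                     series$compound), "rmzero_singular_fit")
  }
  rm_vals <- rf_to_rm(series$rf)
  sxx <- sum((cc - mean(cc))^2)
  leverage0 <- 1 / n + mean(cc)^2 / sxx
  if (stats::var(rm_vals) == 0) {
    fit <- list(compound = series$compound, r_m0 = rm_vals[1], b = 0,
                r = NA_real_, n = n, residual_sd = 0,
                extrapolation_leverage = leverage0, degenerate = TRUE)
    return(structure(fit, class = "retention_fit"))
  }
  b <- sum((cc - mean(cc)) * (rm_vals - mean(rm_vals))) / sxx
  r_m0 <- mean(rm_vals) - b * mean(cc)
  resid <- rm_vals - (r_m0 + b * cc)
  structure(
    list(compound = series$compound,
         r_m0 = r_m0,
         b = b,
         r = stats::cor(cc, rm_vals),
         n = n,
         residual_sd = sqrt(sum(resid^2) / (n - 2)),
         extrapolation_leverage = leverage0,
         degenerate = FALSE),
    class = "retention_fit"
  )
}

#' @export
print.retention_fit <- function(x, ...) {
  cat(sprintf("<retention_fit> %s: R_M0 = %.4f, b = %.5f, r = %.4f (n = %d)%s\n",
              x$compound, x$r_m0, x$b,
              if (is.na(x$r)) NA else x$r, x$n,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Predict R_M at a given modifier concentration
#'
#' Evaluates the fitted line `R_M0 + b * c`.
#'
#' @param fit a `retention_fit`.
#' @param c modifier concentration(s), % v/v.
#' @return Predicted R_M value(s).
#' @export
predict_rm <- function(fit, c) {
  stopifnot(inherits(fit, "retention_fit"))
  if (!is.numeric(c) || any(!is.finite(c))) {
    rmz_stop("'c' must be finite numeric", "rmzero_parameter_error")
  }
  fit$r_m0 + fit$b * c
}

#' Quality-control a batch of retention fits
#'
#' Flags fits whose correlation magnitude falls below `min_r`, whose slope is
#' non-negative (retention should decrease with modifier strength in a
#' reversed-phase system), or which use fewer than `min_points` levels. Every
#' input fit appears in the report; the inputs are never modified.
#'
#' @param fits a list of `retention_fit` objects.
#' @param min_r minimum acceptable `|r|` (default 0.99, a level comfortably
#'   below routinely achievable plate linearity).
#' @param min_points minimum number of concentration levels (default 3).
#' @return A data frame with one row per fit: `compound`, `r_m0`, `b`, `r`,
#'   `n`, `pass` and a semicolon-joined `reasons` string (empty when passing).
#' @export
qc_retention_fits <- function(fits, min_r = 0.99, min_points = 3) {
  if (inherits(fits, "retention_fit")) fits <- list(fits)
  if (!length(fits)) {
    rmz_stop("no fits supplied", "rmzero_parameter_error")
  }
  rows <- lapply(fits, function(f) {
    stopifnot(inherits(f, "retention_fit"))
    reasons <- character(0)
    if (is.na(f$r) || abs(f$r) < min_r) {
      reasons <- c(reasons, sprintf("|r| < %g", min_r))
    }
    if (f$b >= 0) reasons <- c(reasons, "non-negative slope")
    if (!is.na(f$n) && f$n < min_points) {
      reasons <- c(reasons, sprintf("n < %d", min_points))
    }
    if (isTRUE(f$degenerate)) reasons <- c(reasons, "degenerate fit")
    data.frame(compound = f$compound, r_m0 = f$r_m0, b = f$b, r = f$r,
               n = f$n, pass = !length(reasons),
               reasons = paste(reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
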