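#' Fit the R_M0 to logP calibration line
#'
#' Regresses the standards' literature logP on their chromatographic R_M0 by
#' ordinary least squares, producing the line used to convert relative
#' lipophilicity (R_M0) into absolute logP (logP_TLC). Alongside slope and
#' intercept the model carries the classical calibration statistics: the
#' Pearson correlation `r`, the standard error of estimate
#' `s = sqrt(SSE / (n - 2))`, and the regression F statistic
#' `F = r^2 (n - 2) / (1 - r^2)`.
#'
#' @param standards data frame of calibration standards with numeric columns
#'   `rm0` and `logp_lit` (see [read_calibration_standards()]); at least three
#'   standards with distinct `rm0`.
#' @return An object of class `calibration_model` with fields `slope`,
#'   `intercept`, `r`, `s`, `f_stat`, `n` and (for diagnostics) the fitted
#'   values and residuals.
#' @examples
#' std <- read_calibration_standards(
#'   system.file("extdata", "calibration_standards.csv", package = "rmzero"))
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards) {
  if (!is.data.frame(standards) ||
      !all(c("rm0", "logp_lit") %in% names(standards))) {
    rmz_stop("'standards' must be a data frame with columns rm0 and logp_lit",
             "rmzero_schema_error")
  }
  x <- standards$rm0
  y <- standards$logp_lit
  n <- length(x)
  if (n < 3L) {
    rmz_stop(sprintf("at least 3 standards required, got %d", n),
             "rmzero_insufficient_data")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    rmz_stop("rm0 and logp_lit must be finite", "rmzero_validation_error")
  }
  if (stats::var(x) == 0) {
    rmz_stop("standards share a single rm0 value; calibration line is singular",
             "rmzero_singular_fit")
  }
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  resid <- y - fitted
  sse <- sum(resid^2)
  r <- stats::cor(x, y)
  s <- sqrt(sse / (n - 2))
  f_stat <- if (1 - r^2 < .Machine$double.eps) Inf else r^2 * (n - 2) / (1 - r^2)
  structure(
    list(slope = slope, intercept = intercept, r = r, s = s, f_stat = f_stat,
         n = n, fitted = fitted, residuals = resid,
         compound = if ("compound" %in% names(standards)) standards$compound,
         fixed = FALSE),
    class = "calibration_model"
  )
}

#' Build a calibration model from externally supplied coefficients
#'
#' Wraps a known slope/intercept pair (for example coefficients reported in a
#' publication from data unavailable at full precision) into a
#' `calibration_model` usable with [apply_calibration()]. Regression
#' statistics are `NA` since no fit was performed here.
#'
#' @param slope,intercept calibration coefficients (logP per R_M0 unit and
#'   logP offset).
#' @return A `calibration_model` with `fixed = TRUE`.
#' @examples
#' fixed_calibration(1.2838, 0.2138)
#' @export
fixed_calibration <- function(slope, intercept) {
  stopifnot_scalar_number(slope, "slope")
  stopifnot_scalar_number(intercept, "intercept")
  structure(
    list(slope = slope, intercept = intercept, r = NA_real_, s = NA_real_,
         f_stat = NA_real_, n = 0L, fitted = NULL, residuals = NULL,
         compound = NULL, fixed = TRUE),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model>%s logP_TLC = %.4f * R_M0 + %.4f\n",
              if (isTRUE(x$fixed)) " [fixed coefficients]" else "",
              x$slope, x$intercept))
  if (!isTRUE(x$fixed)) {
    cat(sprintf("  n = %d, r = %.4f, s = %.4f, F = %.2f\n",
                x$n, x$r, x$s, x$f_stat))
  }
  invisible(x)
}

#' Convert R_M0 values to logP_TLC
#'
#' Maps chromatographic R_M0 values through a calibration line to absolute
#' logP. Full precision is returned; use [round_half_up()] (2 decimals) for
#' reporting, matching the convention of published lipophilicity tables.
#'
#' @param model a `calibration_model` from [fit_calibration()] or
#'   [fixed_calibration()].
#' @param r_m0 numeric vector of R_M0 values.
#' @return logP_TLC values at full precision.
#' @examples
#' std <- read_calibration_standards(
#'   system.file("extdata", "calibration_standards.csv", package = "rmzero"))
#' m <- fit_calibration(std)
#' round_half_up(apply_calibration(m, 3.15), 2)  # 4.26
#' @export
apply_calibration <- function(model, r_m0) {
  stopifnot(inherits(model, "calibration_model"))
  if (!is.numeric(r_m0) || any(!is.finite(r_m0))) {
    rmz_stop("'r_m0' must be finite numeric", "rmzero_parameter_error")
  }
  model$slope * r_m0 + model$intercept
}

#' Residual and leave-one-out diagnostics for a calibration
#'
#' Computes per-standard residuals from the fitted line and leave-one-out
#' (LOO) predictions, each obtained by refitting the calibration without that
#' standard. With only three standards the LOO refits are two-point lines and
#' the result is flagged low-power.
#'
#' @param model a fitted (non-fixed) `calibration_model`.
#' @param standards the data frame of standards the model was fitted on.
#' @return A data frame with columns `compound`, `rm0`, `logp_lit`, `fitted`,
#'   `residual`, `loo_pred`; attribute `low_power` is `TRUE` when `n == 3`.
#' @export
calibration_diagnostics <- function(model, standards) {
  stopifnot(inherits(model, "calibration_model"))
  if (isTRUE(model$fixed)) {
    rmz_stop("diagnostics require a model fitted on the supplied standards",
             "rmzero_parameter_error")
  }
  if (nrow(standards) != model$n) {
    rmz_stop("standards do not match the fitted model", "rmzero_parameter_error")
  }
  fitted <- apply_calibration(model, standards$rm0)
  resid <- standards$logp_lit - fitted
  loo <- vapply(seq_len(nrow(standards)), function(i) {
    rest <- standards[-i, , drop = FALSE]
    # 2-point refits are exact lines; valid, just low-power
    x <- rest$rm0; y <- rest$logp_lit
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a <- mean(y) - b * mean(x)
    a + b * standards$rm0[i]
  }, numeric(1))
  out <- data.frame(
    compound = if ("compound" %in% names(standards)) standards$compound
               else as.character(seq_len(nrow(standards))),
    rm0 = standards$rm0,
    logp_lit = standards$logp_lit,
    fitted = fitted,
    residual = resid,
    loo_pred = loo,
    stringsAsFactors = FALSE
  )
  attr(out, "low_power") <- model$n == 3L
  out
}
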