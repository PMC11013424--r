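#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used in
#' the chromatographic literature for reported logP values), unlike
#' [base::round()], which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals.
#' @examples
#' round_half_up(1.695, 2)  # 1.70, not 1.69
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Classed error constructor so callers can distinguish data problems from bugs.
rmz_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "rmzero_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Normalise typographic minus signs (U+2212, en dash) to ASCII "-" so numeric
# columns copied from typeset tables parse correctly.
normalize_minus <- function(x) {
  gsub("−|–", "-", x)
}

# Parse a character vector to numeric; empty strings become NA (missing),
# anything else non-numeric is an error located by row/column.
parse_numeric_column <- function(x, column, rows = seq_along(x)) {
  x <- trimws(normalize_minus(as.character(x)))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & nzchar(x) & is.na(out))
  if (length(bad)) {
    rmz_stop(
      sprintf(
        "non-numeric value %s in column '%s', row %d",
        dQuote(x[bad[1]]), column, rows[bad[1]]
      ),
      "rmzero_parse_error"
    )
  }
  out
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rmz_stop(sprintf("'%s' must be a single finite number", name),
             "rmzero_parameter_error")
  }
  invisible(x)
}
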