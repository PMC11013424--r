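#' Pearson correlation between two logP columns
#'
#' Product-moment correlation with pairwise deletion of missing values.
#' Fewer than three complete pairs, or zero variance in either vector (as
#' happens with a constant predicted-ADME column), raises a classed
#' undefined-correlation error; [adme_correlation_screen()] catches that
#' condition and reports it as data.
#'
#' @param x,y numeric vectors of equal length.
#' @param x_label,y_label column names carried into the result.
#' @param method `"pearson"` (default) or `"spearman"` for a rank-based
#'   robustness check.
#' @return An object of class `correlation_result`: a list with `x_label`,
#'   `y_label`, `r`, `n` (complete pairs used) and two-sided `p_value`.
#' @examples
#' pearson_r(c(1, 2, 3), c(6, 4, 2))$r  # -1
#' @export
pearson_r <- function(x, y, x_label = "x", y_label = "y",
                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) {
    rmz_stop("'x' and 'y' must have equal length", "rmzero_parameter_error")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    rmz_stop(sprintf("need at least 3 complete pairs (%s vs %s), got %d",
                     x_label, y_label, n), "rmzero_insufficient_data")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    rmz_stop(sprintf("correlation undefined: zero variance (%s vs %s)",
                     x_label, y_label), "rmzero_undefined_correlation")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  structure(
    list(x_label = x_label, y_label = y_label,
         r = unname(ct$estimate), n = n, p_value = ct$p.value,
         method = method),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s vs %s: r = %.3f (n = %d, p = %.3g)\n",
              x$x_label, x$y_label, x$r, x$n, x$p_value))
  invisible(x)
}

#' Correlate one column of a lipophilicity table against all others
#'
#' Typically used with `target = "logP_TLC"` to rank the calculation
#' algorithms by their agreement with the chromatographic measurement.
#'
#' @param table a [lipo_table()].
#' @param target the column to correlate against the rest.
#' @inheritParams pearson_r
#' @return A data frame with one row per non-target column: `method`, `r`,
#'   `n`, `p_value`, in the table's column order. Columns whose correlation is
#'   undefined appear with `r = NA` and a `note`.
#' @export
correlation_matrix <- function(table, target,
                               method = c("pearson", "spearman")) {
  stopifnot(inherits(table, "lipo_table"))
  method <- match.arg(method)
  cols <- colnames(table$values)
  if (!target %in% cols) {
    rmz_stop(sprintf("target column '%s' not in table (have: %s)", target,
                     paste(cols, collapse = ", ")), "rmzero_lookup_error")
  }
  others <- setdiff(cols, target)
  rows <- lapply(others, function(col) {
    res <- tryCatch(
      pearson_r(table$values[, target], table$values[, col],
                x_label = target, y_label = col, method = method),
      rmzero_undefined_correlation = function(e) NULL
    )
    if (is.null(res)) {
      data.frame(method = col, r = NA_real_, n = NA_integer_,
                 p_value = NA_real_, note = "undefined (zero variance)",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(method = col, r = res$r, n = res$n, p_value = res$p_value,
                 note = "", stringsAsFactors = FALSE)
    }
  })
  if (!length(rows)) {
    return(data.frame(method = character(0), r = numeric(0), n = integer(0),
                      p_value = numeric(0), note = character(0)))
  }
  do.call(rbind, rows)
}

resolve_columns <- function(table, columns) {
  cols <- colnames(table$values)
  if (is.null(columns)) return(cols)
  columns <- canonical_method(columns)
  missing_cols <- setdiff(columns, cols)
  if (length(missing_cols)) {
    rmz_stop(paste("columns not in table:", paste(missing_cols, collapse = ", ")),
             "rmzero_lookup_error")
  }
  columns
}

#' Per-compound spread across logP methods
#'
#' For each compound, the spread (max - min) of its logP values over the
#' selected method columns: a direct measure of how much the algorithms
#' disagree for that structure. The compound with the largest spread is
#' identified.
#'
#' @param table a [lipo_table()].
#' @param columns method columns to compare (default: all); at least two.
#' @return A list of class `spread_summary`: `per_compound` (data frame
#'   `compound`, `min`, `max`, `range`), `max_range` and `argmax_compound`.
#' @examples
#' tab <- read_lipophilicity_table(
#'   system.file("extdata", "logp_calcd_table.csv", package = "rmzero"))
#' spread_summary(tab)$max_range  # 2.59
#' @export
spread_summary <- function(table, columns = NULL) {
  stopifnot(inherits(table, "lipo_table"))
  columns <- resolve_columns(table, columns)
  if (length(columns) < 2L) {
    rmz_stop("at least two columns required for a spread", "rmzero_parameter_error")
  }
  v <- table$values[, columns, drop = FALSE]
  per <- data.frame(
    compound = rownames(v),
    min = apply(v, 1, min, na.rm = TRUE),
    max = apply(v, 1, max, na.rm = TRUE),
    stringsAsFactors = FALSE, row.names = NULL
  )
  per$range <- per$max - per$min
  structure(
    list(per_compound = per,
         max_range = max(per$range),
         argmax_compound = per$compound[which.max(per$range)]),
    class = "spread_summary"
  )
}

#' @export
print.spread_summary <- function(x, ...) {
  cat(sprintf("<spread_summary> largest per-compound range %.2f (compound %s)\n",
              x$max_range, x$argmax_compound))
  invisible(x)
}

#' Global extrema of a lipophilicity table
#'
#' Minimum and maximum over all selected cells, with the (compound, method)
#' coordinates of each extremum (first occurrence in row-major order).
#'
#' @param table a [lipo_table()].
#' @param columns columns to scan (default: all).
#' @return A list: `min`, `max`, `argmin` and `argmax` (each a named character
#'   vector `c(compound =, method =)`).
#' @export
range_summary <- function(table, columns = NULL) {
  stopifnot(inherits(table, "lipo_table"))
  columns <- resolve_columns(table, columns)
  v <- table$values[, columns, drop = FALSE]
  if (all(is.na(v))) {
    rmz_stop("selection contains no non-missing values", "rmzero_empty_data")
  }
  locate <- function(idx) {
    ij <- arrayInd(idx, dim(v))
    c(compound = rownames(v)[ij[1]], method = colnames(v)[ij[2]])
  }
  list(
    min = min(v, na.rm = TRUE),
    max = max(v, na.rm = TRUE),
    argmin = locate(which(v == min(v, na.rm = TRUE))[1]),
    argmax = locate(which(v == max(v, na.rm = TRUE))[1])
  )
}

#' Correlate a logP column against every predicted ADME parameter
#'
#' Joins a lipophilicity table with an ADME profile table on compound id and
#' correlates the target column with each of the ten ADME columns. Constant
#' columns (e.g. an intestinal-absorption column saturated at 100% for every
#' compound) give an undefined correlation, reported as a row with `r = NA`
#' and an explanatory note rather than an error.
#'
#' @param table a [lipo_table()] containing `target`.
#' @param adme data frame from [read_adme_table()].
#' @param target column of `table` to correlate (e.g. `"logP_TLC"`).
#' @inheritParams pearson_r
#' @return A data frame with one row per ADME parameter: `parameter`, `r`,
#'   `n`, `p_value`, `note`.
#' @export
adme_correlation_screen <- function(table, adme, target,
                                    method = c("pearson", "spearman")) {
  stopifnot(inherits(table, "lipo_table"))
  method <- match.arg(method)
  cols <- colnames(table$values)
  if (!target %in% cols) {
    rmz_stop(sprintf("target column '%s' not in table", target),
             "rmzero_lookup_error")
  }
  ids <- rownames(table$values)
  missing_ids <- setdiff(ids, adme$compound)
  if (length(missing_ids)) {
    rmz_stop(paste("compounds missing from ADME table:",
                   paste(missing_ids, collapse = ", ")), "rmzero_join_error")
  }
  adme <- adme[match(ids, adme$compound), , drop = FALSE]
  x <- table$values[, target]
  rows <- lapply(.adme_columns, function(col) {
    res <- tryCatch(
      pearson_r(x, adme[[col]], x_label = target, y_label = col,
                method = method),
      rmzero_undefined_correlation = function(e) NULL
    )
    if (is.null(res)) {
      data.frame(parameter = col, r = NA_real_, n = NA_integer_,
                 p_value = NA_real_, note = "undefined (zero variance)",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(parameter = col, r = res$r, n = res$n, p_value = res$p_value,
                 note = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
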