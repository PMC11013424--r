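#' Lipophilicity tables
#'
#' A `lipo_table` is the package's container for a compounds-by-methods matrix
#' of logP values: rows are compound identifiers, columns are lipophilicity
#' estimation methods (calculation algorithms and/or the experimental
#' `logP_TLC` column). Cells may be missing (`NA`); every non-missing cell
#' must be finite.
#'
#' @param values numeric matrix with row names (compound ids) and unique
#'   column names (method labels).
#' @return An object of class `lipo_table`.
#' @export
lipo_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    rmz_stop("'values' must be a numeric matrix", "rmzero_schema_error")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    rmz_stop("row names must be unique compound ids", "rmzero_schema_error")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    rmz_stop("column names must be unique method labels", "rmzero_schema_error")
  }
  if (any(!is.na(values) & !is.finite(values))) {
    rmz_stop("non-missing cells must be finite", "rmzero_schema_error")
  }
  structure(list(values = values), class = "lipo_table")
}

#' @export
print.lipo_table <- function(x, ...) {
  cat(sprintf(
    "<lipo_table> %d compounds x %d methods (%d missing cells)\n",
    nrow(x$values), ncol(x$values), sum(is.na(x$values))
  ))
  print(utils::head(x$values, 6))
  if (nrow(x$values) > 6) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.lipo_table <- function(x, ...) {
  data.frame(compound = rownames(x$values), x$values,
             check.names = FALSE, row.names = NULL)
}

#' @export
dim.lipo_table <- function(x) dim(x$values)

# Canonical spellings for method labels; the literature mixes case freely
# (AlogPs/ALOGPs, AclogP/AClogP, ...), so matching is case-insensitive.
.method_aliases <- c(
  "alogps" = "ALOGPs", "aclogp" = "AClogP", "alogp" = "ALOGP",
  "mlogp" = "MLOGP", "xlogp2" = "XLOGP2", "xlogp3" = "XLOGP3",
  "logp" = "LogP", "clogp" = "ClogP", "logp_tlc" = "logP_TLC",
  "logptlc" = "logP_TLC", "rm0" = "RM0", "r_m0" = "RM0"
)

canonical_method <- function(labels) {
  key <- tolower(trimws(labels))
  hit <- unname(.method_aliases[key])
  ifelse(is.na(hit), trimws(labels), hit)
}

read_checked_csv <- function(path) {
  if (!file.exists(path)) {
    rmz_stop(sprintf("file not found: %s", path), "rmzero_io_error")
  }
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "character",
                    fileEncoding = "UTF-8"),
    error = function(e) {
      rmz_stop(sprintf("cannot parse table %s: %s", path, conditionMessage(e)),
               "rmzero_schema_error")
    }
  )
  if (ncol(raw) < 1L || nrow(raw) == 0L) {
    rmz_stop(sprintf("empty table: %s", path), "rmzero_schema_error")
  }
  raw
}

#' Read a compounds-by-methods logP table
#'
#' Reads a comma-separated table whose header row names the methods and whose
#' first column holds compound identifiers. Empty cells become missing values;
#' any other non-numeric cell is an error located by row and column.
#' Typographic minus signs are accepted. Method labels are canonicalised
#' through a case-insensitive alias map.
#'
#' @param path path to a CSV file (UTF-8, `.` decimal separator).
#' @return A [lipo_table] preserving the file's row and column order.
#' @examples
#' path <- system.file("extdata", "logp_calcd_table.csv", package = "rmzero")
#' tab <- read_lipophilicity_table(path)
#' tab$values["1", "ALOGPs"]
#' @export
read_lipophilicity_table <- function(path) {
  raw <- read_checked_csv(path)
  if (ncol(raw) < 2L) {
    rmz_stop("expected a compound-id column plus at least one method column",
             "rmzero_schema_error")
  }
  ids <- trimws(raw[[1L]])
  if (any(!nzchar(ids)) || anyDuplicated(ids)) {
    rmz_stop("compound ids (first column) must be non-empty and unique",
             "rmzero_schema_error")
  }
  methods <- canonical_method(names(raw)[-1L])
  vals <- vapply(
    seq_along(methods),
    function(j) parse_numeric_column(raw[[j + 1L]], methods[j]),
    numeric(nrow(raw))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(ids, methods))
  lipo_table(vals)
}

#' Write a lipophilicity table to CSV
#'
#' Inverse of [read_lipophilicity_table()]; missing cells are written as empty
#' fields. Values are written at full precision so that write-then-read is the
#' identity.
#'
#' @param table a [lipo_table].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_lipophilicity_table <- function(table, path) {
  stopifnot(inherits(table, "lipo_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

.adme_columns <- c("caco2_pe", "ppb_pct", "cns", "hia_pct", "pgp_score",
                   "cyp1a2", "cyp2c9", "cyp2c19", "cyp2d6", "cyp3a4")

#' Read a predicted ADME profile table
#'
#' Expects columns `compound`, `caco2_pe` (Caco-2 permeability, 1e-6 cm/s),
#' `ppb_pct` (plasma protein binding, percent), `cns` (CNS score), `hia_pct`
#' (human intestinal absorption, percent), `pgp_score` (P-glycoprotein
#' substrate score in \[0,1\]) and the five cytochrome P450 inhibitor scores
#' `cyp1a2`, `cyp2c9`, `cyp2c19`, `cyp2d6`, `cyp3a4` (each in \[0,1\]).
#' Range invariants are enforced per row.
#'
#' @param path path to a CSV file.
#' @return A data frame with one validated profile per row.
#' @examples
#' path <- system.file("extdata", "adme_profiles.csv", package = "rmzero")
#' adme <- read_adme_table(path)
#' adme[adme$compound == "1", c("caco2_pe", "ppb_pct", "cns")]
#' @export
read_adme_table <- function(path) {
  raw <- read_checked_csv(path)
  names(raw) <- tolower(trimws(names(raw)))
  need <- c("compound", .adme_columns)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    rmz_stop(paste("missing ADME columns:", paste(missing_cols, collapse = ", ")),
             "rmzero_schema_error")
  }
  out <- data.frame(compound = trimws(raw$compound), stringsAsFactors = FALSE)
  for (col in .adme_columns) out[[col]] <- parse_numeric_column(raw[[col]], col)
  if (anyDuplicated(out$compound)) {
    rmz_stop("duplicate compound ids in ADME table", "rmzero_schema_error")
  }
  check_range <- function(col, lo, hi) {
    bad <- which(!is.na(out[[col]]) & (out[[col]] < lo | out[[col]] > hi))
    if (length(bad)) {
      rmz_stop(
        sprintf("%s = %g out of [%g, %g] for compound '%s'",
                col, out[[col]][bad[1]], lo, hi, out$compound[bad[1]]),
        "rmzero_validation_error"
      )
    }
  }
  check_range("ppb_pct", 0, 100)
  check_range("hia_pct", 0, 100)
  check_range("pgp_score", 0, 1)
  for (col in c("cyp1a2", "cyp2c9", "cyp2c19", "cyp2d6", "cyp3a4")) {
    check_range(col, 0, 1)
  }
  bad <- which(!is.na(out$caco2_pe) & out$caco2_pe <= 0)
  if (length(bad)) {
    rmz_stop(sprintf("caco2_pe must be positive (compound '%s')",
                     out$compound[bad[1]]), "rmzero_validation_error")
  }
  out
}

#' Read retention-line fit parameters
#'
#' Reads a per-compound table of fitted retention parameters: `compound`,
#' `rm0` (intercept at 0% modifier), `b` (slope per % v/v) and `r` (the
#' Pearson correlation of the fit). An optional `logp_tlc` column is kept if
#' present.
#'
#' @param path path to a CSV file.
#' @return A data frame with columns `compound`, `rm0`, `b`, `r` (and
#'   `logp_tlc` when present).
#' @export
read_retention_fits <- function(path) {
  raw <- read_checked_csv(path)
  names(raw) <- tolower(trimws(names(raw)))
  need <- c("compound", "rm0", "b", "r")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    rmz_stop(paste("missing columns:", paste(missing_cols, collapse = ", ")),
             "rmzero_schema_error")
  }
  out <- data.frame(compound = trimws(raw$compound), stringsAsFactors = FALSE)
  for (col in c("rm0", "b", "r")) out[[col]] <- parse_numeric_column(raw[[col]], col)
  if ("logp_tlc" %in% names(raw)) {
    out$logp_tlc <- parse_numeric_column(raw$logp_tlc, "logp_tlc")
  }
  out
}

#' Read calibration standards
#'
#' Reads the reference compounds used to anchor the R_M0 -> logP calibration:
#' columns `compound`, `rm0` and `logp_lit` (the accepted literature logP),
#' plus optional `name` and `source` metadata.
#'
#' @param path path to a CSV file.
#' @return A data frame of standards.
#' @examples
#' path <- system.file("extdata", "calibration_standards.csv", package = "rmzero")
#' read_calibration_standards(path)
#' @export
read_calibration_standards <- function(path) {
  raw <- read_checked_csv(path)
  names(raw) <- tolower(trimws(names(raw)))
  need <- c("compound", "rm0", "logp_lit")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    rmz_stop(paste("missing columns:", paste(missing_cols, collapse = ", ")),
             "rmzero_schema_error")
  }
  out <- data.frame(compound = trimws(raw$compound), stringsAsFactors = FALSE)
  if ("name" %in% names(raw)) out$name <- trimws(raw$name)
  out$rm0 <- parse_numeric_column(raw$rm0, "rm0")
  out$logp_lit <- parse_numeric_column(raw$logp_lit, "logp_lit")
  if ("source" %in% names(raw)) out$source <- trimws(raw$source)
  if (any(!is.finite(out$rm0)) || any(!is.finite(out$logp_lit))) {
    rmz_stop("rm0 and logp_lit must be finite for every standard",
             "rmzero_validation_error")
  }
  out
}

#' Read long-format plate measurements
#'
#' Reads raw plate measurements in long format: one row per (compound,
#' concentration) with columns `compound`, `concentration` (% v/v) and `rf`
#' (retention factor in (0,1)); an optional `replicate` column is preserved.
#'
#' @param path path to a CSV file.
#' @return A data frame of measurements.
#' @export
read_retention_measurements <- function(path) {
  raw <- read_checked_csv(path)
  names(raw) <- tolower(trimws(names(raw)))
  need <- c("compound", "concentration", "rf")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    rmz_stop(paste("missing columns:", paste(missing_cols, collapse = ", ")),
             "rmzero_schema_error")
  }
  out <- data.frame(compound = trimws(raw$compound), stringsAsFactors = FALSE)
  out$concentration <- parse_numeric_column(raw$concentration, "concentration")
  out$rf <- parse_numeric_column(raw$rf, "rf")
  if ("replicate" %in% names(raw)) {
    out$replicate <- parse_numeric_column(raw$replicate, "replicate")
  }
  out
}

#' Write an analysis bundle to a report directory
#'
#' Writes every tabular element of an analysis bundle (see
#' [run_full_analysis()]) as delimited text, dendrograms as Newick files, and
#' a machine-readable JSON summary, then returns a manifest listing each file
#' with an MD5 content checksum.
#'
#' @param results an analysis bundle (`rmzero_analysis`) or a plain named list
#'   of data frames / character scalars; an empty list writes nothing.
#' @param path output directory, created if absent.
#' @return A data frame manifest (`file`, `md5`); when any file was produced
#'   the manifest itself is also written as `manifest.json`.
#' @export
write_report <- function(results, path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rmz_stop(sprintf("cannot create directory: %s", path),
                      "rmzero_io_error")
  }
  files <- character(0)
  emit_csv <- function(df, name) {
    fp <- file.path(path, paste0(name, ".csv"))
    utils::write.csv(df, fp, row.names = FALSE, na = "")
    files <<- c(files, fp)
  }
  emit_text <- function(txt, name, ext) {
    fp <- file.path(path, paste0(name, ext))
    writeLines(txt, fp)
    files <<- c(files, fp)
  }
  for (name in names(results)) {
    el <- results[[name]]
    if (inherits(el, "lipo_table")) {
      emit_csv(as.data.frame(el), name)
    } else if (is.data.frame(el)) {
      emit_csv(el, name)
    } else if (is.character(el) && length(el) == 1L && grepl(";\\s*$", el)) {
      emit_text(el, name, ".nwk")  # Newick dendrogram
    } else if (is.list(el) || (is.atomic(el) && length(el) >= 1L)) {
      emit_text(jsonlite::toJSON(el, auto_unbox = TRUE, digits = NA,
                                 pretty = TRUE, force = TRUE),
                name, ".json")
    }
  }
  manifest <- data.frame(
    file = basename(files),
    md5 = if (length(files)) unname(tools::md5sum(files)) else character(0),
    stringsAsFactors = FALSE
  )
  if (length(files)) {
    jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                         dataframe = "rows", pretty = TRUE)
  }
  manifest
}
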