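.descriptor_fields <- c("mw", "hbd", "hba", "logp", "atom_count",
                        "molar_refractivity", "rotatable_bonds", "tpsa")

# Pull required descriptor fields out of a record (one-row data frame or
# named list), erroring with the first missing field's name.
need_fields <- function(rec, fields, rule) {
  if (is.data.frame(rec)) {
    if (nrow(rec) != 1L) {
      rmz_stop("descriptor record must be a single row", "rmzero_schema_error")
    }
    rec <- as.list(rec)
  }
  for (f in fields) {
    v <- rec[[f]]
    if (is.null(v) || length(v) != 1L || !is.finite(v)) {
      rmz_stop(sprintf("%s rule: descriptor '%s' missing or non-finite", rule, f),
               "rmzero_incomplete_record")
    }
  }
  rec
}

rule_result <- function(compound, rule, criteria, passes) {
  structure(
    list(compound = compound, rule = rule, criteria = criteria,
         passes = passes),
    class = "rule_result"
  )
}

#' @export
print.rule_result <- function(x, ...) {
  cat(sprintf("<rule_result> %s, compound %s: %s (%d/%d criteria)\n",
              x$rule, x$compound,
              if (x$passes) "PASS" else "FAIL",
              sum(x$criteria$satisfied), nrow(x$criteria)))
  invisible(x)
}

criterion_row <- function(label, value, bound, satisfied) {
  data.frame(criterion = label, value = value, bound = bound,
             satisfied = satisfied, stringsAsFactors = FALSE)
}

#' Lipinski rule of five
#'
#' Four criteria for oral drug-likeness: molecular weight at most 500 g/mol,
#' at most 5 hydrogen-bond donors, at most 10 hydrogen-bond acceptors, and
#' logP at most 5. Under the default `"three_of_four"` policy a compound
#' passes when at least three criteria hold (equivalently, at most one
#' violation — the classical formulation); `"all"` demands all four.
#'
#' @param rec descriptor record: one-row data frame or named list with `mw`,
#'   `hbd`, `hba`, `logp`.
#' @param compound compound id carried into the result (default taken from
#'   `rec$compound` if present).
#' @param policy aggregation policy, `"three_of_four"` or `"all"`.
#' @return A `rule_result` with four criteria rows and an overall `passes`.
#' @examples
#' lipinski(list(mw = 400, hbd = 0, hba = 2, logp = 5.6))$passes  # TRUE
#' @export
lipinski <- function(rec, compound = NULL,
                     policy = c("three_of_four", "all")) {
  policy <- match.arg(policy)
  rec <- need_fields(rec, c("mw", "hbd", "hba", "logp"), "lipinski")
  compound <- compound %||% as.character(rec$compound %||% "?")
  crit <- rbind(
    criterion_row("mw <= 500", rec$mw, 500, rec$mw <= 500),
    criterion_row("hbd <= 5", rec$hbd, 5, rec$hbd <= 5),
    criterion_row("hba <= 10", rec$hba, 10, rec$hba <= 10),
    criterion_row("logp <= 5", rec$logp, 5, rec$logp <= 5)
  )
  passes <- if (policy == "all") all(crit$satisfied)
            else sum(crit$satisfied) >= 3L
  rule_result(compound, "lipinski", crit, passes)
}

#' Ghose filter
#'
#' Four interval criteria, all required, bounds inclusive: molar mass in
#' \[160, 480\] g/mol, logP in \[0.4, 5.6\], atom count in \[20, 70\], molar
#' refractivity in \[40, 130\].
#'
#' @inheritParams lipinski
#' @return A `rule_result` with four criteria rows.
#' @export
ghose <- function(rec, compound = NULL) {
  rec <- need_fields(rec, c("mw", "logp", "atom_count", "molar_refractivity"),
                     "ghose")
  compound <- compound %||% as.character(rec$compound %||% "?")
  in_band <- function(v, lo, hi) v >= lo & v <= hi
  crit <- rbind(
    criterion_row("mw in [160, 480]", rec$mw, 480,
                  in_band(rec$mw, 160, 480)),
    criterion_row("logp in [0.4, 5.6]", rec$logp, 5.6,
                  in_band(rec$logp, 0.4, 5.6)),
    criterion_row("atom_count in [20, 70]", rec$atom_count, 70,
                  in_band(rec$atom_count, 20, 70)),
    criterion_row("molar_refractivity in [40, 130]", rec$molar_refractivity,
                  130, in_band(rec$molar_refractivity, 40, 130))
  )
  rule_result(compound, "ghose", crit, all(crit$satisfied))
}

#' Veber rule
#'
#' Two criteria, both required: at most 10 rotatable bonds and topological
#' polar surface area at most 140 A^2.
#'
#' @inheritParams lipinski
#' @return A `rule_result` with two criteria rows.
#' @export
veber <- function(rec, compound = NULL) {
  rec <- need_fields(rec, c("rotatable_bonds", "tpsa"), "veber")
  compound <- compound %||% as.character(rec$compound %||% "?")
  crit <- rbind(
    criterion_row("rotatable_bonds <= 10", rec$rotatable_bonds, 10,
                  rec$rotatable_bonds <= 10),
    criterion_row("tpsa <= 140", rec$tpsa, 140, rec$tpsa <= 140)
  )
  rule_result(compound, "veber", crit, all(crit$satisfied))
}

#' Egan passive-absorption filter
#'
#' Egan's model classifies passive intestinal absorption from polar surface
#' area and logP. The default bounds (PSA <= 131.6 A^2, logP <= 5.88) are the
#' axis extents of the published confidence region and match common screening
#' platforms; both are configurable.
#'
#' @inheritParams lipinski
#' @param psa_max upper bound on TPSA (A^2), default 131.6.
#' @param logp_max upper bound on logP, default 5.88.
#' @return A `rule_result` with two criteria rows.
#' @export
egan <- function(rec, compound = NULL, psa_max = 131.6, logp_max = 5.88) {
  rec <- need_fields(rec, c("tpsa", "logp"), "egan")
  compound <- compound %||% as.character(rec$compound %||% "?")
  crit <- rbind(
    criterion_row(sprintf("tpsa <= %g", psa_max), rec$tpsa, psa_max,
                  rec$tpsa <= psa_max),
    criterion_row(sprintf("logp <= %g", logp_max), rec$logp, logp_max,
                  rec$logp <= logp_max)
  )
  rule_result(compound, "egan", crit, all(crit$satisfied))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen a descriptor table against drug-likeness rules
#'
#' Applies the selected rules to every record and tabulates pass/fail per
#' compound plus failure counts per rule.
#'
#' @param records data frame of descriptor records, one compound per row,
#'   with a `compound` column and the fields each selected rule needs.
#' @param rules subset of `c("lipinski", "ghose", "veber", "egan")`.
#' @param lipinski_policy aggregation policy passed to [lipinski()].
#' @param egan_psa_max,egan_logp_max bounds passed to [egan()].
#' @return A list of class `rule_screen`: `table` (data frame compound x rule
#'   logical columns), `results` (nested list of `rule_result`), and
#'   `failure_counts` (named integer vector per rule).
#' @examples
#' recs <- data.frame(compound = "x", mw = 300, hbd = 1, hba = 3, logp = 4,
#'                    atom_count = 40, molar_refractivity = 80,
#'                    rotatable_bonds = 2, tpsa = 30)
#' screen_rules(recs)$failure_counts
#' @export
screen_rules <- function(records,
                         rules = c("lipinski", "ghose", "veber", "egan"),
                         lipinski_policy = "three_of_four",
                         egan_psa_max = 131.6, egan_logp_max = 5.88) {
  rules <- match.arg(rules, several.ok = TRUE)
  if (!is.data.frame(records) || nrow(records) == 0L) {
    rmz_stop("'records' must be a non-empty data frame", "rmzero_schema_error")
  }
  if (!"compound" %in% names(records)) {
    records$compound <- as.character(seq_len(nrow(records)))
  }
  apply_rule <- function(rule, rec) {
    switch(rule,
      lipinski = lipinski(rec, policy = lipinski_policy),
      ghose = ghose(rec),
      veber = veber(rec),
      egan = egan(rec, psa_max = egan_psa_max, logp_max = egan_logp_max)
    )
  }
  results <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    out <- lapply(rules, apply_rule, rec = rec)
    names(out) <- rules
    out
  })
  names(results) <- records$compound
  tab <- data.frame(compound = records$compound, stringsAsFactors = FALSE)
  for (rule in rules) {
    tab[[rule]] <- vapply(results, function(rr) rr[[rule]]$passes, logical(1))
  }
  failure_counts <- vapply(rules, function(rule) sum(!tab[[rule]]), integer(1))
  structure(
    list(table = tab, results = results, failure_counts = failure_counts),
    class = "rule_screen"
  )
}

#' @export
print.rule_screen <- function(x, ...) {
  cat(sprintf("<rule_screen> %d compounds x %d rules; failures: %s\n",
              nrow(x$table), length(x$failure_counts),
              paste(names(x$failure_counts), x$failure_counts,
                    sep = "=", collapse = ", ")))
  invisible(x)
}
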