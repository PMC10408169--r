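# Synthetic ADNI-shaped MMSE tables. Real ADNI downloads are
# access-restricted, so the generator emulates the table shape every stage
# consumes: a RID subject key, a visit code, the phase-dependent date dialect
# (early-phase rows populate EXAMDATE in US format, later-phase rows populate
# USERDATE in ISO format), and one 0/1 score column per MMSE item. Scores are
# drawn from a two-group mixture (control-like vs impaired-like subjects) so
# that queries over the loaded data return non-degenerate score
# distributions; no clinically realistic item correlations are simulated.

#' Fixture generator configuration
#'
#' @param n_subjects number of distinct subjects.
#' @param n_visits_per_subject visits (rows) per subject.
#' @param phase_mix length-2 proportions (must sum to 1) of early-phase rows
#'   (EXAMDATE populated, US date format) vs later-phase rows (USERDATE
#'   populated, ISO format).
#' @param missing_rate probability in `[0, 1)` that an item score cell is
#'   emitted as a missing code (empty string).
#' @param frac_impaired fraction of subjects drawn from the impaired-like
#'   score distribution (Bernoulli(0.4) per item; control-like subjects use
#'   Bernoulli(0.8)).
#' @param seed RNG seed; required, so the same configuration always yields a
#'   byte-identical table.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_subjects = 50, n_visits_per_subject = 3,
                           phase_mix = c(0.5, 0.5), missing_rate = 0.05,
                           frac_impaired = 0.5, seed = 1L) {
  stopifnot(n_subjects >= 1, n_visits_per_subject >= 1,
            length(phase_mix) == 2, abs(sum(phase_mix) - 1) < 1e-9,
            missing_rate >= 0, missing_rate < 1,
            frac_impaired >= 0, frac_impaired <= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_visits_per_subject = as.integer(n_visits_per_subject),
                 phase_mix = phase_mix, missing_rate = missing_rate,
                 frac_impaired = frac_impaired, seed = as.integer(seed)),
            class = "fixture_config")
}

# column name <-> MMSE item class correspondence. MMDATE is the one column
# name fixed by convention ("What is today's date?" = first orientation
# item); the remaining names are synthetic but follow the same per-scope
# pattern.
#' @keywords internal
mmse_columns <- function() {
  data.frame(
    column = c("MMDATE", paste0("MMORIENT", 2:10), paste0("MMREG", 1:3),
               paste0("MMATTN", 1:5), paste0("MMRECALL", 1:3),
               paste0("MMLANG", 1:9)),
    item = c(paste0("MMSE_OrientationItem_", 1:10),
             paste0("MMSE_RegistrationItem_", 1:3),
             paste0("MMSE_AttentionAndCalculationItem_", 1:5),
             paste0("MMSE_RecallItem_", 1:3),
             paste0("MMSE_LanguageAndPraxisItem_", 1:9)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic MMSE table
#'
#' Header: `RID, VISCODE, EXAMDATE, USERDATE, MMDATE, <29 more item columns>`.
#' Per row exactly one of `EXAMDATE`/`USERDATE` is populated according to the
#' phase mix; item scores are in `{0, 1}` with missing cells emitted as empty
#' strings. Deterministic given the seed.
#'
#' @param config a [fixture_config()].
#' @param path optional output file; when `NULL` the CSV text is returned.
#' @return Character vector of CSV lines (invisibly when `path` is given).
#' @export
generate_mmse_table <- function(config = fixture_config(), path = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  cols <- mmse_columns()
  n_sub <- config$n_subjects
  n_vis <- config$n_visits_per_subject
  rids <- 100L + seq_len(n_sub)
  impaired <- stats::runif(n_sub) < config$frac_impaired
  base_date <- as.Date("2005-06-01") + sample.int(2000L, n_sub, replace = TRUE)
  viscodes <- c("bl", sprintf("m%02d", 6L * seq_len(max(n_vis - 1L, 1L))))

  rows <- vector("list", n_sub * n_vis)
  r <- 0L
  for (i in seq_len(n_sub)) {
    p_item <- if (impaired[i]) 0.4 else 0.8
    for (v in seq_len(n_vis)) {
      r <- r + 1L
      d <- base_date[i] + 182L * (v - 1L)
      early <- stats::runif(1) < config$phase_mix[1]
      scores <- as.character(stats::rbinom(nrow(cols), 1L, p_item))
      scores[stats::runif(nrow(cols)) < config$missing_rate] <- ""
      rows[[r]] <- c(RID = as.character(rids[i]),
                     VISCODE = viscodes[v],
                     EXAMDATE = if (early) format(d, "%m/%d/%Y") else "",
                     USERDATE = if (early) "" else format(d, "%Y-%m-%d"),
                     stats::setNames(scores, cols$column))
    }
  }
  header <- c("RID", "VISCODE", "EXAMDATE", "USERDATE", cols$column)
  lines <- c(paste(header, collapse = ","),
             vapply(rows, function(x) paste(x[header], collapse = ","),
                    character(1)))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Generate the mapping-rule file for the synthetic MMSE table
#'
#' Emits one rule per generated data column: the `EXAMDATE`/`USERDATE`
#' dialect pair sharing the `Subject.undergoes.MMSE.hasDate.Date` path, a
#' `VISCODE` rule, and one binary-score rule per item column. `RID` carries
#' no rule: it is the subject key consumed directly by individual minting.
#' All emitted rules are validated against the schema before being returned.
#'
#' @param schema an `ontology_schema` (the shipped TBox).
#' @param path optional output file; when `NULL` the rule text is returned.
#' @param table table name on the rule left-hand sides.
#' @return Character vector of rule-file lines (invisibly when `path` is
#'   given).
#' @export
generate_rule_file <- function(schema, path = NULL, table = "MMSE") {
  cols <- mmse_columns()
  lines <- c(
    "# mapping rules for the synthetic MMSE table",
    paste0(table, ".EXAMDATE -> Subject.undergoes.MMSE.hasDate.Date"),
    paste0(table, ".USERDATE -> Subject.undergoes.MMSE.hasDate.Date"),
    paste0(table, ".VISCODE -> Subject.undergoes.MMSE.hasVisitCode.String"),
    paste0(table, ".", cols$column, " -> Subject.undergoes.MMSE.hasTestItem.",
           cols$item, ".0_1_score.Float"))
  parse_rules(lines, schema)   # validation; raises on any bad rule
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
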