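# Shared fixture builders. Everything is generated in code at test time; the
# schema build is cheap enough to share one instance per test file.

the_schema <- build_ad_onto()
ADO <- ado_namespace()

# the worked whole-path example used across the mapping and ETL tests
WHOLE_PATH <- "Subject.undergoes.MMSE.hasTestItem.MMSE_OrientationItem_1.0_1_score.Float"

# generate a table, load it, and hand back all the pieces
make_loaded_store <- function(config = fixture_config(n_subjects = 5,
                                                      n_visits_per_subject = 2,
                                                      seed = 42)) {
  csv <- tempfile(fileext = ".csv")
  generate_mmse_table(config, csv)
  rules <- parse_rules(generate_rule_file(the_schema), the_schema)
  registry <- individual_registry(ADO)
  res <- load_csv(triple_store(the_schema), csv, "MMSE", rules, registry,
                  the_schema)
  list(store = res$store, summary = res$summary, registry = registry,
       rules = rules, csv = csv, config = config)
}

write_csv_lines <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
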