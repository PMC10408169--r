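XSD <- "http://www.w3.org/2001/XMLSchema#"
RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

test_that("extract_rows yields one raw-string record per data line", {
  f <- write_csv_lines(c("RID,MMDATE", "134,1", "201,0"))
  rows <- extract_rows(f, "MMSE")
  expect_length(rows, 2)
  expect_equal(rows[[1]]$values, c(RID = "134", MMDATE = "1"))
  expect_equal(rows[[2]]$index, 2L)
  expect_equal(rows[[1]]$table, "MMSE")

  expect_length(extract_rows(write_csv_lines("RID,MMDATE"), "MMSE"), 0)
  expect_error(extract_rows(write_csv_lines(c("RID,MMDATE", "134,1,9")), "MMSE"),
               "line 2")
  empty <- tempfile(); file.create(empty)
  expect_error(extract_rows(empty, "MMSE"), "missing header")
})

test_that("coercion canonicalizes numbers and both date dialects", {
  expect_equal(coerce("1", "Float"), paste0('"1.0"^^<', XSD, 'float>'))
  expect_equal(coerce("0.25", "Float"), paste0('"0.25"^^<', XSD, 'float>'))
  expect_equal(coerce("2011-03-15", "Date"), coerce("03/15/2011", "Date"))
  expect_equal(term_text(coerce("03/15/2011", "Date")), "2011-03-15")
  expect_equal(term_text(coerce("bl", "String")), "bl")
  expect_error(coerce("abc", "Float"), "abc")
  expect_error(coerce("15/03/2011", "Date"), "Date")
  expect_error(coerce("1", "Integer"), "unknown base type")
})

test_that("the worked one-row example produces the full ABox path, triple by triple", {
  f <- write_csv_lines(c("RID,MMDATE", "134,1"))
  rules <- parse_rules(paste0("MMSE.MMDATE -> ", WHOLE_PATH), the_schema)
  reg <- individual_registry(ADO)
  tr <- transform_row(extract_rows(f, "MMSE")[[1]], rules, reg, the_schema)

  subj <- paste0(ADO, "Subject_134")
  ev <- paste0(ADO, "MMSE_1")
  item <- paste0(ADO, "MMSE_OrientationItem_1_1")
  has <- function(s, p, o) any(tr$s == s & tr$p == p & tr$o == o)
  expect_true(has(subj, RDF_TYPE, paste0(ADO, "Subject")))
  expect_true(has(ev, RDF_TYPE, paste0(ADO, "MMSE")))
  expect_true(has(item, RDF_TYPE, paste0(ADO, "MMSE_OrientationItem_1")))
  expect_true(has(subj, paste0(ADO, "undergoes"), ev))
  expect_true(has(ev, paste0(ADO, "hasTestItem"), item))
  expect_true(has(item, paste0(ADO, "0_1_score"),
                  paste0('"1.0"^^<', XSD, 'float>')))
  expect_equal(nrow(tr), 6)
})

test_that("subjects are reused across rows while each row mints its own event", {
  f <- write_csv_lines(c("RID,MMDATE", "134,1", "134,0"))
  rules <- parse_rules(paste0("MMSE.MMDATE -> ", WHOLE_PATH), the_schema)
  reg <- individual_registry(ADO)
  rows <- extract_rows(f, "MMSE")
  tr <- do.call(rbind, lapply(rows, transform_row, rules, reg, the_schema))
  types <- tr[tr$p == RDF_TYPE, , drop = FALSE]
  expect_length(unique(types$s[types$o == paste0(ADO, "Subject")]), 1)
  expect_setequal(unique(types$s[types$o == paste0(ADO, "MMSE")]),
                  paste0(ADO, c("MMSE_1", "MMSE_2")))
})

test_that("missing-coded values emit nothing and empty rows mint no event", {
  f <- write_csv_lines(c("RID,MMDATE", "7,", "8,-4", "9,1"))
  rules <- parse_rules(paste0("MMSE.MMDATE -> ", WHOLE_PATH), the_schema)
  reg <- individual_registry(ADO)
  rows <- extract_rows(f, "MMSE")
  trs <- lapply(rows, transform_row, rules, reg, the_schema)
  expect_equal(nrow(trs[[1]]), 0)
  expect_equal(nrow(trs[[2]]), 0)
  # ordinals stay dense: the first non-empty row is event 1
  expect_true(any(trs[[3]]$s == paste0(ADO, "MMSE_1")))
})

test_that("dialect groups consume one populated field and reject conflicts", {
  rules <- parse_rules(c("MMSE.EXAMDATE -> Subject.undergoes.MMSE.hasDate.Date",
                         "MMSE.USERDATE -> Subject.undergoes.MMSE.hasDate.Date"),
                       the_schema)
  run_one <- function(line) {
    f <- write_csv_lines(c("RID,EXAMDATE,USERDATE", line))
    transform_row(extract_rows(f, "MMSE")[[1]], rules,
                  individual_registry(ADO), the_schema)
  }
  iso_lit <- paste0('"2011-03-15"^^<', XSD, 'date>')
  tr1 <- run_one("134,03/15/2011,")
  tr2 <- run_one("134,,2011-03-15")
  expect_true(any(tr1$p == paste0(ADO, "hasDate") & tr1$o == iso_lit))
  expect_true(any(tr2$p == paste0(ADO, "hasDate") & tr2$o == iso_lit))
  # both populated, same value after normalization: consumed once, no error
  tr3 <- run_one("134,03/15/2011,2011-03-15")
  expect_equal(sum(tr3$p == paste0(ADO, "hasDate")), 1)
  expect_error(run_one("134,03/15/2011,2011-03-16"), "dialect conflict")
})

test_that("coercion failures carry table, row and field context", {
  rules <- parse_rules(paste0("MMSE.MMDATE -> ", WHOLE_PATH), the_schema)
  f <- write_csv_lines(c("RID,MMDATE", "134,banana"))
  expect_error(transform_row(extract_rows(f, "MMSE")[[1]], rules,
                             individual_registry(ADO), the_schema),
               "table MMSE row 1 field MMDATE.*banana")
})

test_that("a missing subject key is a hard error", {
  rules <- parse_rules(paste0("MMSE.MMDATE -> ", WHOLE_PATH), the_schema)
  f <- write_csv_lines(c("RID,MMDATE", ",1"))
  expect_error(transform_row(extract_rows(f, "MMSE")[[1]], rules,
                             individual_registry(ADO), the_schema),
               "missing subject key")
})

test_that("two identical loads produce byte-identical sorted stores", {
  paths <- vapply(1:2, function(i) {
    res <- make_loaded_store(fixture_config(n_subjects = 4,
                                            n_visits_per_subject = 2, seed = 9))
    p <- tempfile(fileext = ".ttl")
    write_store(res$store, p)
    p
  }, character(1))
  expect_identical(readLines(paths[1]), readLines(paths[2]))
})

test_that("re-loading the same file in a fresh load session is a no-op", {
  # ordinals are per-load, so a new session over the same file mints the
  # same individuals and the store (set semantics) is unchanged
  res <- make_loaded_store()
  n <- store_size(res$store)
  res2 <- load_csv(res$store, res$csv, "MMSE", res$rules,
                   individual_registry(ADO), the_schema)
  expect_equal(store_size(res2$store), n)
})

test_that("conservation: subjects equal distinct RIDs, events equal non-empty rows", {
  res <- make_loaded_store(fixture_config(n_subjects = 6,
                                          n_visits_per_subject = 3,
                                          missing_rate = 0.1, seed = 11))
  csv <- utils::read.csv(res$csv, colClasses = "character")
  # independent scan of emitted rdf:type triples
  tr <- res$store$triples
  types <- tr[tr$p == RDF_TYPE, , drop = FALSE]
  n_subj <- length(unique(types$s[types$o == paste0(ADO, "Subject")]))
  n_ev <- length(unique(types$s[types$o == paste0(ADO, "MMSE")]))
  mapped <- setdiff(names(csv), "RID")
  nonempty <- apply(csv[, mapped], 1, function(r) any(!r %in% c("", "-1", "-4", "NA")))
  expect_equal(n_subj, length(unique(csv$RID[nonempty])))
  expect_equal(n_ev, sum(nonempty))
  expect_equal(res$summary$rows_read, nrow(csv))
  expect_equal(res$summary$empty_rows, sum(!nonempty))
})

test_that("restriction validation flags exactly the injected foreign item", {
  res <- make_loaded_store(fixture_config(n_subjects = 3,
                                          n_visits_per_subject = 1, seed = 5))
  expect_equal(nrow(validate_abox(res$store, the_schema)), 0)

  bad <- bad_item_store(res$store)
  v <- validate_abox(bad, the_schema)
  expect_equal(nrow(v), 1)
  expect_match(v$reason, "MMSEItem")
  expect_equal(v$o, paste0(ADO, "GDSItem_99"))

  # independent full-scan oracle over all hasTestItem triples
  expect_equal(nrow(v), oracle_avf_violations(bad))
})

test_that("malformed datatype literals are reported as violations, not errors", {
  res <- make_loaded_store(fixture_config(n_subjects = 2,
                                          n_visits_per_subject = 1, seed = 3))
  st <- store_add(res$store,
                  data.frame(s = paste0(ADO, "MMSE_1"),
                             p = paste0(ADO, "hasDate"),
                             o = '"not-a-date"^^<http://www.w3.org/2001/XMLSchema#date>',
                             stringsAsFactors = FALSE))
  v <- validate_abox(st, the_schema)
  expect_equal(nrow(v), 1)
  expect_match(v$reason, "Date")
})
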