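RDFS <- "http://www.w3.org/2000/01/rdf-schema#"

# hand-built ABox with scored items typed directly under two memory
# sub-scopes (Registration, Learning) plus one non-memory item
scoped_item_store <- function() {
  st <- triple_store(the_schema)
  lit_date <- '"2011-03-15"^^<http://www.w3.org/2001/XMLSchema#date>'
  lit1 <- '"1.0"^^<http://www.w3.org/2001/XMLSchema#float>'
  lit0 <- '"0.0"^^<http://www.w3.org/2001/XMLSchema#float>'
  t <- function(s, p, o) data.frame(s = paste0(ADO, s),
                                    p = if (p == "a") RDF_TYPE_T else paste0(ADO, p),
                                    o = o, stringsAsFactors = FALSE)
  cls <- function(x) paste0(ADO, x)
  store_add(st, rbind(
    t("Subject_1", "a", cls("Subject")),
    t("NB_1", "a", cls("NeuropsychologicalBattery")),
    t("Subject_1", "undergoes", cls("NB_1")),
    t("NB_1", "hasDate", lit_date),
    t("item_reg", "a", cls("Registration")),
    t("item_learn", "a", cls("Learning")),
    t("item_lang", "a", cls("Naming")),
    t("NB_1", "hasTestItem", cls("item_reg")),
    t("NB_1", "hasTestItem", cls("item_learn")),
    t("NB_1", "hasTestItem", cls("item_lang")),
    t("item_reg", "itemScore", lit1),
    t("item_learn", "itemScore", lit0),
    t("item_lang", "itemScore", lit1)))
}

test_that("a SELECT over an empty ABox returns zero rows with the right columns", {
  st <- triple_store(the_schema)   # TBox only
  res <- run_query(st, memory_items_query())
  expect_equal(nrow(res), 0)
  expect_equal(names(res), c("subject", "date", "i_type", "score"))
})

test_that("the memory query returns items typed under memory sub-scopes by inference", {
  res <- run_query(scoped_item_store(), memory_items_query())
  expect_equal(nrow(res), 2)
  expect_setequal(res$i_type, paste0(ADO, c("Registration", "Learning")))
  expect_false(paste0(ADO, "Naming") %in% res$i_type)
  expect_setequal(term_text(res$score), c("1.0", "0.0"))
  expect_equal(unique(term_text(res$date)), "2011-03-15")
})

test_that("inference is monotone: exact typing returns a subset of the inferred result", {
  st <- scoped_item_store()
  exact <- sub("\\?i rdf:type \\?i_type \\.",
               "?i rdf:type ado:MemoryItem . ?i rdf:type ?i_type .",
               memory_items_query())
  exact <- sub("\\?i_type rdfs:subClassOf\\* ado:MemoryItem \\.", "", exact)
  res_exact <- run_query(st, exact)
  res_inf <- run_query(st, memory_items_query())
  expect_equal(nrow(res_exact), 0)   # nothing is a direct MemoryItem instance
  expect_true(nrow(res_exact) <= nrow(res_inf))

  # and with a direct MemoryItem-typed individual both queries grow by one
  st2 <- store_add(st, data.frame(
    s = c(paste0(ADO, "item_direct"), paste0(ADO, "NB_1"),
          paste0(ADO, "item_direct")),
    p = c(RDF_TYPE_T, paste0(ADO, "hasTestItem"), paste0(ADO, "itemScore")),
    o = c(paste0(ADO, "MemoryItem"), paste0(ADO, "item_direct"),
          '"1.0"^^<http://www.w3.org/2001/XMLSchema#float>'),
    stringsAsFactors = FALSE))
  res_exact2 <- run_query(st2, exact)
  res_inf2 <- run_query(st2, memory_items_query())
  expect_equal(nrow(res_exact2), 1)
  expect_equal(nrow(res_inf2), nrow(res_inf) + 1)
  merged <- merge(res_exact2, res_inf2)
  expect_equal(nrow(merged), nrow(res_exact2))
})

test_that("the inferred query equals the union of exact-type queries over the closure", {
  res <- make_loaded_store(fixture_config(n_subjects = 4,
                                          n_visits_per_subject = 2,
                                          missing_rate = 0.1, seed = 21))
  st <- res$store
  inferred <- run_query(st, memory_items_query())

  per_class <- lapply(subclass_closure(the_schema, "MemoryItem"), function(cl) {
    q <- paste0(
      "PREFIX ado: <", ADO, ">\n",
      "PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>\n",
      "SELECT ?subject ?date ?i_type ?score WHERE {\n",
      "  ?subject ado:undergoes ?test .\n",
      "  ?test ado:hasDate ?date .\n",
      "  ?test ado:hasTestItem ?i .\n",
      "  ?i rdf:type ?i_type .\n",
      "  ?i rdf:type <", cl, "> .\n",
      "  ?i ado:itemScore|ado:0_1_score ?score .\n}")
    as.data.frame(run_query(st, q))
  })
  union <- unique(do.call(rbind, per_class))
  # every fixture item has exactly one type, so the union is duplicate-free
  # and must match the inferred result as a multiset
  expect_equal(sorted_rows(as.data.frame(inferred)), sorted_rows(union))
})

test_that("run_query agrees with a naive nested-loop evaluator on fixture stores", {
  for (seed in c(13, 29)) {
    res <- make_loaded_store(fixture_config(n_subjects = 3,
                                            n_visits_per_subject = 2,
                                            missing_rate = 0.15, seed = seed))
    expect_lte(store_size(res$store), 1000)
    got <- sorted_rows(as.data.frame(run_query(res$store, memory_items_query())))
    want <- sorted_rows(oracle_memory_rows(res$store))
    expect_equal(got, want, info = paste("seed", seed))
  }
  # and on the hand-built scoped store
  st <- scoped_item_store()
  expect_equal(sorted_rows(as.data.frame(run_query(st, memory_items_query()))),
               sorted_rows(oracle_memory_rows(st)))
})

test_that("the memory-query row count equals the scored memory items in the store", {
  res <- make_loaded_store(fixture_config(n_subjects = 5,
                                          n_visits_per_subject = 2,
                                          missing_rate = 0.2, seed = 31))
  tr <- res$store$triples
  mem_classes <- subclass_closure(the_schema, "MemoryItem")
  item_inds <- tr$s[tr$p == RDF_TYPE_T & tr$o %in% mem_classes]
  scored <- tr$s[tr$p == paste0(ADO, "0_1_score")]
  expect_equal(nrow(run_query(res$store, memory_items_query())),
               length(intersect(item_inds, scored)))
})

test_that("general SELECT queries work: projection, constants, property paths", {
  st <- scoped_item_store()
  q1 <- paste0("PREFIX ado: <", ADO, ">\n",
               "SELECT ?s WHERE { ?s ado:undergoes ?t . }")
  expect_equal(as.data.frame(run_query(st, q1))$s, paste0(ADO, "Subject_1"))

  # sequence path: subject to item in one pattern
  q2 <- paste0("PREFIX ado: <", ADO, ">\n",
               "SELECT ?i WHERE { ?s ado:undergoes/ado:hasTestItem ?i . }")
  expect_setequal(as.data.frame(run_query(st, q2))$i,
                  paste0(ADO, c("item_reg", "item_learn", "item_lang")))

  # SELECT * binds every pattern variable
  q3 <- paste0("PREFIX ado: <", ADO, ">\n",
               "SELECT * WHERE { ?s ado:undergoes ?t . }")
  expect_setequal(names(run_query(st, q3)), c("s", "t"))

  # projection keeps duplicates (multiset semantics): three items share one test
  q4 <- paste0("PREFIX ado: <", ADO, ">\n",
               "SELECT ?t WHERE { ?t ado:hasTestItem ?i . }")
  expect_equal(nrow(run_query(st, q4)), 3)
})

test_that("syntax errors report a position; unknown selected variables are caught", {
  st <- triple_store(the_schema)
  expect_error(run_query(st, "SELECT ?x WHERE { ?x }"), "character")
  expect_error(run_query(st, "SELECT WHERE { ?x ?p ?y }"), "at least one")
  expect_error(run_query(st, "SELECT ?z WHERE { ?x a ?y . }"), "\\?z")
  expect_error(run_query(st, paste0("PREFIX ado: <", ADO, ">\n",
                                    "SELECT ?x WHERE { ?x foo:bar ?y . }")),
               "undeclared prefix")
})
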