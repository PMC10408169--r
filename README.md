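# adonto

Ontology-based integration of Alzheimer's-disease clinical tables.

Longitudinal AD studies such as ADNI publish their clinical data as flat
CSV tables with terse, phase-dependent column names (`MMDATE` is an MMSE
item score, not a date; the exam date lives in `EXAMDATE` or `USERDATE`
depending on the study phase). `adonto` is for researchers and data
engineers who want to query such data semantically instead of by column
name. It provides:

* **A TBox** for the domain (`build_ad_onto()`): the study model
  (`Subject` —`undergoes`→ `Event`, visits, exams, sites, diagnoses), the
  neuropsychological test taxonomy (behavioural / cognitive / functional,
  with GDS, NPI, NPI-Q, ADAS, CCI, CDR, MMSE, MoCA, FAQ, FCI-SF and the
  neuropsychological battery as leaves), a scope taxonomy of the
  psychological sub-domains items evaluate, and all 30 MMSE item classes,
  each classified under both its item family (`MMSEItem`) and its scope.
  Per-instrument `owl:allValuesFrom` restrictions confine `hasTestItem` to
  the instrument's own items, and `MMSE` is `owl:sameAs`-aligned to the NCI
  Thesaurus OBO term `NCIT_C74982`. Serializes to Turtle or RDF/XML and
  parses back losslessly.
* **A mapping-rule language** (`parse_rules()`): lines of the form
  `TABLE.FIELD -> Class.property. ... .BaseType`, validated against the
  schema with subclass substitutability. Rules sharing a path declare
  field dialects (e.g. `EXAMDATE`/`USERDATE`), of which the loader
  consumes exactly one per row.
* **An ETL engine** (`load_csv()`): lifts CSV rows into ABox triples with
  deterministic individual minting (`Subject_134`, `MMSE_1`, ...), missing-code
  handling, date normalization, set-semantics loading and
  `allValuesFrom`/datatype validation (`validate_abox()`).
* **A SPARQL SELECT evaluator** (`run_query()`) with property paths, so
  class-typed queries get `rdfs:subClassOf` inference by rewriting
  (`rdf:type/rdfs:subClassOf*`); `memory_items_query()` is the canned query
  returning every subject's memory-related item scores with their dates.
* **A fixture generator** (`generate_mmse_table()`) emulating ADNI-shaped
  MMSE tables — phase-dependent date dialects included — since the real
  download is access-restricted.
* **A CLI** (`inst/cli/ontoloader.R`, or `ontoloader_main()` in-process)
  with `build-tbox`, `load`, `query` and `fixtures` subcommands.

## Worked example

```r
library(adonto)

schema <- build_ad_onto()
schema
#> <ontology_schema> 114 classes, 9 properties, 11 restrictions, 1 alignments
#> namespace: http://www.modiag.it#

length(subclass_closure(schema, "MMSEItem")) - 1   # the 30 MMSE item classes
#> [1] 30
table(mmse_item_groups(schema)$group)
#> attention_calculation       language_praxis           orientation
#>                     5                     9                    10
#>                recall          registration
#>                     3                     3

# synthetic ADNI-shaped table -> rules -> loaded store
dir.create("demo")
generate_mmse_table(fixture_config(n_subjects = 3, n_visits_per_subject = 2,
                                   seed = 42), "demo/MMSE.csv")
rules <- parse_rules(generate_rule_file(schema), schema)
res <- load_csv(triple_store(schema), "demo/MMSE.csv", "MMSE",
                rules, individual_registry(), schema)
res$summary[c("rows_read", "triples_emitted", "empty_rows")]
#> $rows_read      [1] 6
#> $triples_emitted [1] 534
#> $empty_rows     [1] 0
nrow(validate_abox(res$store, schema))   # no restriction violations
#> [1] 0

# all memory-related item scores, via subclass inference
mem <- run_query(res$store, memory_items_query())
nrow(mem)
#> [1] 33
head(mem, 4)
#>                            subject       date                                 i_type score
#> 1 http://www.modiag.it#Subject_101 2008-08-21 http://www.modiag.it#MMSE_RecallItem_1   1.0
#> 2 http://www.modiag.it#Subject_102 2008-06-03 http://www.modiag.it#MMSE_RecallItem_1   0.0
#> 3 http://www.modiag.it#Subject_102 2008-12-02 http://www.modiag.it#MMSE_RecallItem_1   1.0
#> 4 http://www.modiag.it#Subject_103 2009-05-05 http://www.modiag.it#MMSE_RecallItem_1   1.0
```

The 33 rows are the recall and registration item scores of the six test
sessions (3 subjects × 2 visits × 6 memory-scoped items, minus three
missing cells): recall items are subclasses of the memory scope class and
registration items of its `Registration` sub-scope, so the single
`rdfs:subClassOf*`-constrained query retrieves both without naming either.

The same pipeline from a shell:

```sh
Rscript inst/cli/ontoloader.R fixtures --out demo --seed 42 --n-subjects 3 --n-visits 2
Rscript inst/cli/ontoloader.R build-tbox --out demo/tbox.ttl
Rscript inst/cli/ontoloader.R load --tbox demo/tbox.ttl --rules demo/mmse.map \
        --csv demo/MMSE.csv --store demo/store.ttl
Rscript inst/cli/ontoloader.R query --store demo/store.ttl --memory true
```

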