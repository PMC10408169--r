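---
title: "From clinical tables to a queryable knowledge graph: the adonto model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From clinical tables to a queryable knowledge graph: the adonto model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adonto)
```

## The problem

Longitudinal Alzheimer's-disease studies such as ADNI distribute their
clinical data as dozens of flat CSV tables whose column names are terse,
phase-dependent and semantically opaque: the same piece of information may
live in `EXAMDATE` for early-phase rows and `USERDATE` later, and a column
like `MMDATE` is not a date at all but the score of the "What is today's
date?" question of the Mini-Mental State Exam (MMSE). Selecting, say, "all
memory-related item scores" across such tables requires knowing every
column's meaning by heart.

`adonto` addresses this by (i) shipping a computational ontology (a TBox)
that models subjects, study events, neuropsychological tests, their items
and the cognitive scopes those items evaluate; (ii) lifting the CSV tables
into an RDF assertion box (ABox) through declarative mapping rules; and
(iii) answering SPARQL queries over the result with `rdfs:subClassOf`
inference, so that a query about memory items automatically retrieves
registration and learning items too.

## The terminology

`build_ad_onto()` constructs the schema. Three strands matter:

* **The study model.** `Subject` `undergoes` `Event`; events specialize
  into `Visit` and `Exam`, and exams into biospecimen, imaging, clinical
  and neuropsychological kinds. Events carry a `hasDate` attribute (type
  Date) and a `hasVisitCode` attribute (type String), and take place in a
  `Site`. A `Diagnosis` is `supportedBy` exams.
* **The test taxonomy.** `NeuropsychologicalTest` splits into behavioural
  (GDS, NPI, NPI-Q), cognitive (ADAS, CCI, CDR, MMSE, MoCA, the
  neuropsychological battery) and functional (FAQ, FCI-SF) instruments.
  Each instrument has an item family (`MMSEItem`, `GDSItem`, ...) under the
  generic `TestItem` class, and an `owl:allValuesFrom` restriction confining
  `hasTestItem` to its own family — an MMSE session cannot be linked to a
  GDS item. Items carry a `verbatimAnswer` (String) and an `itemScore`
  (Float); `0_1_score` is a subproperty of `itemScore` for binary-scored
  items.
* **The scope taxonomy.** Every item is classified a second time by the
  psychological sub-domain it evaluates: daily functioning, executive
  function, language, memory, orientation, the psychiatric domain, social
  functioning and visuo-spatial ability, each with its sub-scopes. The
  memory scope class is named `MemoryItem` (with `Memory` as a label
  synonym) and its sub-scopes include `Registration` and `Learning`; this
  is the naming the shipped memory query relies on. Scope names that are
  conventionally written with a slash (e.g. *Apathy/Indifference*) use an
  underscore in their IRI, keeping the slashed form as a label, because a
  slash is not legal in a Turtle local name or in the dotted path
  language.

Only the MMSE's 30 items are modelled individually; the other instruments'
item families are extension points. The 30 items split across five groups —
10 orientation, 3 registration, 5 attention and calculation, 3 recall, 9
language and praxis. Three placement decisions were genuinely open and were
resolved once:

* Orientation items 1–5 sit under `TimeOrientation` and 6–10 under
  `PlaceOrientation`, following the instrument's conventional five
  time-orientation plus five place-orientation questions.
* The attention-and-calculation group has no verbatim class in the printed
  scope list; an `AttentionAndCalculation` sub-scope was introduced under
  `ExecutiveFunction` rather than forcing those items into
  `ProcessionSpeed`, whose meaning is narrower.
* Recall items are direct subclasses of `MemoryItem`, while registration
  items sit under the `Registration` sub-scope; language-and-praxis items
  sit directly under `Language`. This keeps every group recoverable from
  the graph alone, which is how `mmse_item_groups()` counts them.

```{r}
schema <- build_ad_onto()
schema
table(mmse_item_groups(schema)$group)
```

The schema serializes to Turtle or RDF/XML and parses back losslessly
(`serialize_tbox()` / `parse_tbox()`); `MMSE` is aligned by `owl:sameAs` to
the NCI Thesaurus OBO term `NCIT_C74982`. External ontologies are linked,
never imported: only the alignment triple is shipped.

## Mapping rules and the ETL

A mapping rule ties a table column to a dotted **TBox path**, e.g.

```
MMSE.MMDATE -> Subject.undergoes.MMSE.hasTestItem.MMSE_OrientationItem_1.0_1_score.Float
```

Paths alternate classes and properties and end in a base type (`String`,
`Float`, `Date`). Validation applies subclass substitutability — a property
declared on `Subject`→`Event` is usable towards `MMSE` — and enforces the
`allValuesFrom` restrictions, reporting the leftmost failing step. Several
rules may share one path: that is how the `EXAMDATE`/`USERDATE` phase
dialect is declared, and the loader consumes exactly one populated field
per such group per row, failing hard if two populated fields disagree.

Loading a row instantiates each rule's path as an ABox path. Individual
minting is deterministic and mirrors the conceptual local names:

* the subject individual is keyed by the row's `RID` (`Subject_134`) and
  reused across rows and tables — `RID` itself therefore carries no
  mapping rule;
* each row that yields at least one value mints one event individual per
  event class, keyed by a per-class load ordinal (`MMSE_1`); ordinals
  start at 1 per load session, so re-loading a file in a fresh session
  reproduces the same individuals and the store, which has set semantics,
  is unchanged;
* item individuals are keyed by their event's ordinal
  (`MMSE_OrientationItem_1_1`), the class IRI disambiguating items within
  a row.

Raw values equal to one of the missing codes (`""`, `-1`, `-4`, `NA` by
default) emit nothing; dates are accepted in ISO and US form and
normalized to ISO; scores are canonicalized floats. `validate_abox()`
re-checks the loaded graph against every range restriction and literal
type, returning violations as data.

## Querying with subclass inference

`run_query()` evaluates SPARQL SELECT over the store. The supported
fragment — `PREFIX`, variable or `*` projection, basic graph patterns with
property paths (`/`, `|`, `*`) — is exactly what inference-aware clinical
queries need: instead of materializing the subclass closure into the
store, the shipped memory query (`memory_items_query()`) constrains the
item's type with `rdfs:subClassOf* ado:MemoryItem`, so items typed under
any memory sub-scope are retrieved. Scores resolve through
`ado:itemScore|ado:0_1_score`, honouring the subproperty decision.
Evaluation computes distinct solution mappings over the pattern variables
and then projects, preserving projection-induced duplicates (standard
multiset semantics). The test suite pins this evaluator to two independent
oracles: a hand-written nested-loop join over the raw triple table, and
the union of exact-type queries over the closure computed by brute-force
reachability.

No OWL-DL reasoning is attempted: `owl:sameAs` is recorded, not smushed;
inference is is-a closure only.

## The synthetic fixture generator

Real ADNI tables are access-restricted, so `generate_mmse_table()` emulates
their shape: a `RID` key, ADNI-style visit codes (`bl`, `m06`, ...), the
phase-dependent date dialect (early-phase rows populate `EXAMDATE` in US
format, later rows `USERDATE` in ISO format, mixed 50/50 by default), and
one 0/1 column per MMSE item with a configurable missing rate (default
5%). Scores come from a two-group mixture — control-like subjects answer
each item correctly with probability 0.8, impaired-like with 0.4, half the
cohort each — chosen once so that queries return non-degenerate score
distributions. The generator is seeded and byte-reproducible.

What it does **not** emulate: item–item correlations, per-phase visit
schedules, attrition, site effects, or any clinically calibrated score
distribution. Passing tests therefore demonstrate the correctness of the
modelling, mapping, loading and querying machinery on structurally
faithful inputs — not clinical validity of the synthetic scores.

Default problem sizes used in the tests are deliberately desk-scale (a few
subjects and visits, stores of a few hundred to a couple of thousand
triples; 10,080 cells for the missing-rate check), which keeps every
property checkable against brute-force oracles.

## Numerical and degenerate-input choices

* Float canonicalization prints whole numbers with one decimal (`1.0`), so
  dialect comparison and set-semantics de-duplication operate on canonical
  lexical forms.
* Date parsing requires a format round-trip, so `03/15/2011` cannot be
  mis-read by the ISO branch.
* A row whose mapped fields are all missing mints no individuals at all;
  event ordinals stay dense.
* A missing subject key on a row that would emit triples is a hard error,
  not a skip.
* Unmapped columns are skipped and listed in the load summary;
  administrative ADNI columns make this the common case.
* The `TestItem`/`NeuropsychologicalItem` terminology is one class with
  two labels.

## Command-line surface

The installed script `inst/cli/ontoloader.R` exposes `build-tbox`, `load`,
`query` (with `--memory` for the canned query) and `fixtures`
subcommands, returning non-zero with a one-line diagnostic on any
validation error; `ontoloader_main()` is the same entry point callable
in-process. The store is a sorted Turtle file rather than a server-backed
triple store: at desk scale an embedded graph preserves the same contract.

## Known limitations

* The Turtle reader covers the profile the package emits (prefixed names,
  predicate–object lists, string literals, non-nested blank-node
  brackets), not full Turtle.
* The SPARQL fragment omits `OPTIONAL`, `FILTER`, `UNION` and aggregation.
* Only is-a closure, `allValuesFrom` checking and `sameAs` recording are
  computed; no consistency checking or classification.
* Item taxonomies for instruments other than the MMSE are extension
  points, so scope-based queries only see MMSE items unless callers add
  their own item classes.
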