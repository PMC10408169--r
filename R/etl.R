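# The ETL core: extract CSV rows, transform them under the mapping rules
# into ABox triples with deterministic individual minting, and load them into
# the triple store. Minting mirrors the conceptual local names: the subject
# individual is keyed by its RID (Subject_134), each non-empty row mints one
# event individual keyed by a per-class load ordinal (MMSE_1), and item
# individuals are keyed by their event's ordinal.

#' ETL configuration
#'
#' @param namespace IRI prefix for minted individuals.
#' @param subject_field CSV column holding the subject key (default `RID`).
#' @param missing_codes raw values treated as absent; no triple is emitted
#'   for them.
#' @param date_formats accepted input date formats, tried in order; values
#'   are normalized to ISO `YYYY-MM-DD`.
#' @return A list of class `etl_config`.
#' @export
etl_config <- function(namespace = ado_namespace(),
                       subject_field = "RID",
                       missing_codes = c("", "-1", "-4", "NA"),
                       date_formats = c("%Y-%m-%d", "%m/%d/%Y")) {
  structure(list(namespace = namespace, subject_field = subject_field,
                 missing_codes = missing_codes, date_formats = date_formats),
            class = "etl_config")
}

#' Extract rows from a header-first CSV file
#'
#' Values are kept as raw, unmodified strings. Ragged rows are rejected with
#' the offending line number.
#'
#' @param file path to a CSV file (RFC 4180, header row).
#' @param table logical table name the rows belong to.
#' @return A list of `row_record`s: `list(table, index, values)` with `index`
#'   the 1-based data-row ordinal and `values` a named character vector.
#' @export
extract_rows <- function(file, table) {
  nf <- utils::count.fields(file, sep = ",", quote = "\"", blank.lines.skip = FALSE)
  if (length(nf) == 0) stop("missing header: ", file, " is empty")
  bad <- which(nf != nf[1])
  if (length(bad))
    stop("ragged row in ", file, " at line ", bad[1], ": ", nf[bad[1]],
         " fields, expected ", nf[1])
  df <- utils::read.csv(file, colClasses = "character", check.names = FALSE,
                        na.strings = NULL)
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(table = table, index = i,
                   values = stats::setNames(as.character(df[i, ]), names(df))),
              class = "row_record")
  })
}

#' Coerce a raw CSV string to a typed literal
#'
#' `Date` accepts ISO (`YYYY-MM-DD`) and US (`MM/DD/YYYY`) dialects and
#' normalizes both to ISO. `Float` requires a parseable number and is
#' canonicalized (`"1"` becomes `1.0`). Missing-coded values are handled
#' upstream; here an unparseable value is an error.
#'
#' @param raw the raw string.
#' @param base_type `"String"`, `"Float"` or `"Date"`.
#' @param config an [etl_config()] (supplies the date dialects).
#' @return An encoded typed literal term.
#' @export
coerce <- function(raw, base_type, config = etl_config()) {
  if (!base_type %in% names(BASE_TYPES))
    stop("unknown base type: ", base_type)
  if (base_type == "String")
    return(make_literal(raw, BASE_TYPES[["String"]]))
  if (base_type == "Float") {
    x <- suppressWarnings(as.numeric(raw))
    if (is.na(x)) stop("cannot coerce '", raw, "' to Float")
    lex <- if (x == floor(x) && abs(x) < 1e15) sprintf("%.1f", x) else
      format(x, scientific = FALSE, trim = TRUE)
    return(make_literal(lex, BASE_TYPES[["Float"]]))
  }
  for (fmt in config$date_formats) {
    d <- as.Date(raw, format = fmt)
    # as.Date is lenient about e.g. "03/15/2011" under %Y-%m-%d; require a
    # round-trip to the same lexical form
    if (!is.na(d) && format(d, fmt) == raw)
      return(make_literal(format(d, "%Y-%m-%d"), BASE_TYPES[["Date"]]))
  }
  stop("cannot coerce '", raw, "' to Date (expected one of: ",
       paste(config$date_formats, collapse = ", "), ")")
}

# ---- individual registry ---------------------------------------------------

#' Deterministic individual registry
#'
#' Mints ABox individuals as `<namespace><ClassName>_<key>` and guarantees
#' one individual per (class, key): looking the same pair up twice returns
#' the same IRI. Per-class counters provide the load ordinals used as event
#' keys.
#'
#' @param namespace IRI prefix for minted individuals.
#' @return An `individual_registry` (environment-backed, mutated in place).
#' @export
individual_registry <- function(namespace = ado_namespace()) {
  env <- new.env(parent = emptyenv())
  env$map <- list()        # "classIRI|key" -> uri
  env$counters <- list()   # classIRI -> last ordinal
  structure(list(env = env, namespace = namespace),
            class = "individual_registry")
}

#' Look up or mint an individual
#' @param registry an [individual_registry()].
#' @param class_uri full class IRI.
#' @param key the human-readable key (e.g. a subject's RID).
#' @return The individual's IRI.
#' @export
mint_individual <- function(registry, class_uri, key) {
  mkey <- paste0(class_uri, "|", key)
  uri <- registry$env$map[[mkey]]
  if (is.null(uri)) {
    uri <- paste0(registry$namespace, iri_local(class_uri), "_", key)
    registry$env$map[[mkey]] <- uri
  }
  uri
}

#' @keywords internal
next_ordinal <- function(registry, class_uri) {
  k <- registry$env$counters[[class_uri]]
  k <- if (is.null(k)) 1L else k + 1L
  registry$env$counters[[class_uri]] <- k
  k
}

#' Individuals minted so far
#' @param registry an [individual_registry()].
#' @return data.frame with columns `class`, `key`, `uri`.
#' @export
registry_individuals <- function(registry) {
  keys <- names(registry$env$map)
  if (!length(keys))
    return(data.frame(class = character(), key = character(), uri = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(class = vapply(parts, `[[`, character(1), 1),
             key = vapply(parts, function(p) paste(p[-1], collapse = "|"), character(1)),
             uri = unlist(registry$env$map, use.names = FALSE),
             stringsAsFactors = FALSE)
}

# ---- transformation --------------------------------------------------------

#' Transform one CSV row into ABox triples
#'
#' Each applicable mapping rule instantiates its TBox path as an ABox path:
#' the subject individual is keyed by the row's subject field and reused
#' across rows and tables; one event individual is minted per non-empty row
#' (lazily, on the first rule that produces a value); item individuals are
#' minted per (row, item class). `rdf:type` triples are emitted for every
#' minted individual, object-property triples along the path, and the
#' terminal datatype triple. Missing-coded values emit nothing. Within a
#' dialect group (rules sharing one path) exactly one populated field is
#' consumed; two populated fields with different values are a hard error.
#'
#' @param row a `row_record` from [extract_rows()].
#' @param rules a `mapping_rules` list (from [parse_rules()]).
#' @param registry an [individual_registry()], mutated in place.
#' @param schema the `ontology_schema` the rules were validated against.
#' @param config an [etl_config()].
#' @return A triple data.frame (possibly empty).
#' @export
transform_row <- function(row, rules, registry, schema, config = etl_config()) {
  rules <- rules[vapply(rules, function(r) r$table == row$table, logical(1))]
  if (!length(rules)) return(triple_df())
  groups <- dialect_groups(structure(rules, class = "mapping_rules"))

  out <- list()
  add <- function(s, p, o) out[[length(out) + 1L]] <<- c(s, p, o)
  row_events <- list()   # event class IRI -> individual IRI, lazily minted

  subject_key <- row$values[[config$subject_field]]

  event_for <- function(class_uri) {
    uri <- row_events[[class_uri]]
    if (is.null(uri)) {
      uri <- mint_individual(registry, class_uri,
                             next_ordinal(registry, class_uri))
      row_events[[class_uri]] <<- uri
      add(uri, IRI_RDF_TYPE, class_uri)
    }
    uri
  }

  for (group in groups) {
    vals <- vapply(group, function(r) {
      v <- row$values[[r$field]]
      if (is.null(v) || is.na(v)) "" else v
    }, character(1))
    populated <- !(vals %in% config$missing_codes)
    if (!any(populated)) next
    path <- group[[1]]$path
    lits <- vapply(which(populated), function(j) {
      tryCatch(coerce(vals[j], path$terminal, config),
               error = function(e) stop("table ", row$table, " row ", row$index,
                                        " field ", group[[j]]$field, ": ",
                                        conditionMessage(e), call. = FALSE))
    }, character(1))
    if (length(unique(lits)) > 1)
      stop("dialect conflict in table ", row$table, " row ", row$index,
           ": fields ", paste(vapply(group[which(populated)], `[[`,
                                     character(1), "field"), collapse = ", "),
           " map to the same path but hold different values")
    lit <- lits[[1]]

    if (is.null(subject_key) || is.na(subject_key) ||
        subject_key %in% config$missing_codes)
      stop("table ", row$table, " row ", row$index, ": missing subject key ('",
           config$subject_field, "')")

    # walk the path: Subject -> event -> (items ...) -> literal
    subj_uri <- mint_individual(registry, path$classes[1], subject_key)
    add(subj_uri, IRI_RDF_TYPE, path$classes[1])
    ev_uri <- event_for(path$classes[2])
    add(subj_uri, path$properties[1], ev_uri)
    cur <- ev_uri
    k <- 3L
    while (k <= length(path$classes)) {
      ev_ord <- sub("^.*_", "", ev_uri)
      item_uri <- mint_individual(registry, path$classes[k], ev_ord)
      add(item_uri, IRI_RDF_TYPE, path$classes[k])
      add(cur, path$properties[k - 1], item_uri)
      cur <- item_uri
      k <- k + 1L
    }
    add(cur, path$properties[length(path$properties)], lit)
  }

  if (!length(out)) return(triple_df())
  m <- do.call(rbind, out)
  unique(triple_df(m[, 1], m[, 2], m[, 3]))
}

#' Load a CSV table into a store
#'
#' Runs extract → transform → load for one table and returns the updated
#' store plus a load summary. Unmapped columns are skipped (and listed in
#' the summary), not errors.
#'
#' @param store a `triple_store`, already holding the TBox.
#' @param file CSV file path.
#' @param table table name the rules refer to.
#' @param rules validated `mapping_rules`.
#' @param registry an [individual_registry()] (reuse one registry across
#'   tables so subjects are shared).
#' @param schema the `ontology_schema`.
#' @param config an [etl_config()].
#' @return A list: `store` (updated), `summary` (rows read, triples added,
#'   skipped fields, empty rows).
#' @export
load_csv <- function(store, file, table, rules, registry, schema,
                     config = etl_config()) {
  rows <- extract_rows(file, table)
  mapped_fields <- vapply(Filter(function(r) r$table == table, rules),
                          `[[`, character(1), "field")
  header <- if (length(rows)) names(rows[[1]]$values) else character()
  skipped <- setdiff(header, c(mapped_fields, config$subject_field))

  added <- 0L
  empty_rows <- 0L
  for (row in rows) {
    tr <- transform_row(row, rules, registry, schema, config)
    if (nrow(tr) == 0L) { empty_rows <- empty_rows + 1L; next }
    added <- added + nrow(tr)
    store <- store_add(store, tr)
  }
  list(store = store,
       summary = list(table = table, rows_read = length(rows),
                      triples_emitted = added, empty_rows = empty_rows,
                      skipped_fields = skipped))
}

# ---- validation ------------------------------------------------------------

#' Validate the ABox against the schema's restrictions
#'
#' Reports every triple whose object violates an `allValuesFrom` range
#' restriction (the object individual's types, taken with subclass
#' semantics, do not fall inside the restriction class), and every datatype
#' literal whose lexical form does not conform to the declared base type.
#' Violations are returned as data, not raised.
#'
#' @param store a `triple_store` holding TBox and ABox.
#' @param schema the `ontology_schema`.
#' @return A data.frame with columns `s`, `p`, `o`, `reason` (zero rows when
#'   the ABox conforms).
#' @export
validate_abox <- function(store, schema) {
  tr <- store$triples
  types <- tr[tr$p == IRI_RDF_TYPE & !is_literal_term(tr$o), , drop = FALSE]
  type_map <- split(types$o, types$s)
  viol <- list()
  flag <- function(s, p, o, reason)
    viol[[length(viol) + 1L]] <<- data.frame(s = s, p = p, o = o, reason = reason,
                                             stringsAsFactors = FALSE)

  r <- schema$restrictions
  for (i in seq_len(nrow(r))) {
    on_cls <- subclass_closure(schema, r$on_class[i])
    allowed <- subclass_closure(schema, r$all_values_from[i])
    inds <- names(type_map)[vapply(type_map, function(tt) any(tt %in% on_cls),
                                   logical(1))]
    sub <- tr[tr$p == r$on_property[i] & tr$s %in% inds, , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      o <- sub$o[j]
      ok <- !is_literal_term(o) && any(type_map[[o]] %in% allowed)
      if (!ok)
        flag(sub$s[j], sub$p[j], o,
             paste0("allValuesFrom violation: value not an instance of ",
                    iri_local(r$all_values_from[i])))
    }
  }

  for (p in schema$properties) {
    if (p$kind != "datatype") next
    sub <- tr[tr$p == p$uri, , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      o <- sub$o[j]
      if (!is_literal_term(o)) {
        flag(sub$s[j], p$uri, o, "datatype property with non-literal value")
        next
      }
      lex <- term_text(o)
      ok <- switch(p$range,
                   String = TRUE,
                   Float = !is.na(suppressWarnings(as.numeric(lex))),
                   Date = !is.na(as.Date(lex, format = "%Y-%m-%d")))
      if (!ok)
        flag(sub$s[j], p$uri, o,
             paste0("literal does not conform to base type ", p$range))
    }
  }

  if (!length(viol))
    return(data.frame(s = character(), p = character(), o = character(),
                      reason = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, viol)
  rownames(out) <- NULL
  out
}
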