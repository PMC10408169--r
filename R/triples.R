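# A triple table is a data.frame with character columns s, p, o holding
# encoded terms (see terms.R). The triple store wraps one such table plus a
# prefix map, with set semantics on load.

#' @keywords internal
triple_df <- function(s = character(), p = character(), o = character()) {
  data.frame(s = as.character(s), p = as.character(p), o = as.character(o),
             stringsAsFactors = FALSE)
}

#' @keywords internal
bind_triples <- function(...) {
  do.call(rbind, Filter(function(d) nrow(d) > 0, list(triple_df(), ...)))
}

#' @keywords internal
sort_triples <- function(tr) {
  tr <- unique(tr)
  tr[order(tr$s, tr$p, tr$o), , drop = FALSE]
}

#' Create a triple store
#'
#' An in-memory RDF graph with set semantics. When a schema is supplied its
#' serialized terminology (classes, is-a edges, properties, restrictions,
#' alignments) is preloaded so that queries can exploit `rdfs:subClassOf`
#' closure over the terminology.
#'
#' @param schema optionally, an `ontology_schema` whose triples seed the store.
#' @return An object of class `triple_store`.
#' @export
triple_store <- function(schema = NULL) {
  st <- structure(list(triples = triple_df(),
                       prefixes = default_prefixes()),
                  class = "triple_store")
  if (!is.null(schema)) {
    st$prefixes <- default_prefixes(schema$namespace)
    st <- store_add(st, schema_triples(schema))
  }
  st
}

#' Add triples to a store
#'
#' Idempotent set-insert: loading the same triples twice leaves the store
#' unchanged.
#'
#' @param store a `triple_store`.
#' @param triples a triple data.frame (columns `s`, `p`, `o`).
#' @return The updated store.
#' @export
store_add <- function(store, triples) {
  stopifnot(inherits(store, "triple_store"))
  store$triples <- unique(rbind(store$triples, triples[, c("s", "p", "o")]))
  rownames(store$triples) <- NULL
  store
}

#' @export
print.triple_store <- function(x, ...) {
  cat("<triple_store> ", nrow(x$triples), " triples\n", sep = "")
  invisible(x)
}

#' Number of triples in a store
#' @param store a `triple_store`.
#' @return integer count.
#' @export
store_size <- function(store) nrow(store$triples)

#' Write a store to a Turtle file
#'
#' Triples are emitted in a canonical sorted order, so two stores holding the
#' same triple set serialize byte-identically.
#'
#' @param store a `triple_store`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_store <- function(store, path) {
  writeLines(write_turtle(sort_triples(store$triples), store$prefixes), path)
  invisible(path)
}

#' Read a Turtle file into a store
#'
#' @param path a Turtle file previously produced by [write_store()] or
#'   [serialize_tbox()], or any document within the supported Turtle profile.
#' @return A `triple_store`.
#' @export
read_store <- function(path) {
  parsed <- parse_turtle(paste(readLines(path, warn = FALSE), collapse = "\n"))
  st <- triple_store()
  st$prefixes <- utils::modifyList(as.list(st$prefixes), as.list(parsed$prefixes))
  st$prefixes <- unlist(st$prefixes)
  store_add(st, parsed$triples)
}
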