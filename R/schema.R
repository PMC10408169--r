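# The ontology schema (the terminology, or TBox): classes with is-a edges and
# label synonyms, object/datatype properties with domain and range,
# allValuesFrom range restrictions, and sameAs alignments to external
# ontologies. Stored as plain named lists keyed by full IRI; the is-a graph
# must be acyclic and closed under reference.

#' Construct an ontology schema
#'
#' Low-level constructor; most users want [build_ad_onto()]. Validation checks
#' reference closure (no dangling IRIs) and acyclicity of the is-a graph.
#'
#' @param namespace IRI prefix for locally defined terms.
#' @param classes list of class records `list(uri, labels, parents)`.
#' @param properties list of property records
#'   `list(uri, kind, domain, range, subproperty_of)` where `kind` is
#'   `"object"` or `"datatype"` and a datatype range is one of
#'   `"String"`, `"Float"`, `"Date"`.
#' @param restrictions data.frame with columns `on_class`, `on_property`,
#'   `all_values_from` (full IRIs).
#' @param alignments data.frame with columns `local_uri`, `external_uri`.
#' @return An object of class `ontology_schema`.
#' @export
ontology_schema <- function(namespace = ado_namespace(),
                            classes = list(), properties = list(),
                            restrictions = NULL, alignments = NULL) {
  if (is.null(restrictions))
    restrictions <- data.frame(on_class = character(), on_property = character(),
                               all_values_from = character(), stringsAsFactors = FALSE)
  if (is.null(alignments))
    alignments <- data.frame(local_uri = character(), external_uri = character(),
                             stringsAsFactors = FALSE)
  names(classes) <- vapply(classes, `[[`, character(1), "uri")
  names(properties) <- vapply(properties, `[[`, character(1), "uri")
  schema <- structure(list(namespace = namespace, classes = classes,
                           properties = properties, restrictions = restrictions,
                           alignments = alignments),
                      class = "ontology_schema")
  validate_schema(schema)
  schema
}

#' @keywords internal
validate_schema <- function(schema) {
  cls <- names(schema$classes)
  if (anyDuplicated(cls)) stop("duplicate class URI in schema")
  for (c in schema$classes) {
    bad <- setdiff(c$parents, cls)
    if (length(bad)) stop("class ", c$uri, " has undefined parent ", bad[1])
  }
  for (p in schema$properties) {
    if (!p$domain %in% cls) stop("property ", p$uri, " has undefined domain ", p$domain)
    if (p$kind == "object" && !p$range %in% cls)
      stop("object property ", p$uri, " has undefined range ", p$range)
    if (p$kind == "datatype" && !p$range %in% names(BASE_TYPES))
      stop("datatype property ", p$uri, " has non-base-type range ", p$range)
    if (!is.na(p$subproperty_of) && !p$subproperty_of %in% names(schema$properties))
      stop("property ", p$uri, " has undefined superproperty ", p$subproperty_of)
  }
  r <- schema$restrictions
  for (col in c("on_class", "all_values_from")) {
    bad <- setdiff(r[[col]], cls)
    if (length(bad)) stop("restriction references undefined class ", bad[1])
  }
  bad <- setdiff(r$on_property, names(schema$properties))
  if (length(bad)) stop("restriction references undefined property ", bad[1])
  bad <- setdiff(schema$alignments$local_uri, cls)
  if (length(bad)) stop("alignment references undefined class ", bad[1])
  assert_acyclic(schema)
  invisible(schema)
}

# topological sort over is-a edges; stops on a cycle
#' @keywords internal
assert_acyclic <- function(schema) {
  indeg <- stats::setNames(integer(length(schema$classes)), names(schema$classes))
  children <- child_index(schema)
  for (c in schema$classes) for (p in c$parents) indeg[[c$uri]] <- indeg[[c$uri]] + 0L
  # count edges parent -> child: child indegree = number of parents
  for (c in schema$classes) indeg[[c$uri]] <- length(c$parents)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[u]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(indeg)) stop("is-a graph contains a cycle")
  invisible(TRUE)
}

# parent -> children adjacency over is-a edges
#' @keywords internal
child_index <- function(schema) {
  idx <- stats::setNames(vector("list", length(schema$classes)), names(schema$classes))
  for (c in schema$classes) for (p in c$parents) idx[[p]] <- c(idx[[p]], c$uri)
  idx
}

#' @export
print.ontology_schema <- function(x, ...) {
  cat("<ontology_schema> ", length(x$classes), " classes, ",
      length(x$properties), " properties, ",
      nrow(x$restrictions), " restrictions, ",
      nrow(x$alignments), " alignments\n", sep = "")
  cat("namespace: ", x$namespace, "\n", sep = "")
  invisible(x)
}

#' Transitive subclass closure
#'
#' The set containing `root` and every class reachable from it by following
#' is-a edges downwards. This is the semantics that `rdfs:subClassOf`
#' inference gives to class-typed queries: an instance of any member of the
#' closure counts as an instance of `root`.
#'
#' @param schema an `ontology_schema`.
#' @param root a class IRI, or a bare local name resolved against the schema
#'   namespace.
#' @return Character vector of full class IRIs (including `root`).
#' @export
subclass_closure <- function(schema, root) {
  root <- expand_iri(root, schema$namespace)
  if (!root %in% names(schema$classes))
    stop("unknown class IRI: ", root)
  children <- child_index(schema)
  seen <- character()
  stack <- root
  while (length(stack)) {
    u <- stack[[1]]; stack <- stack[-1]
    if (u %in% seen) next
    seen <- c(seen, u)
    stack <- c(stack, children[[u]])
  }
  sort(seen)
}

# upward closure (class and all ancestors); used for property applicability
#' @keywords internal
superclass_closure <- function(schema, class_uri) {
  seen <- character()
  stack <- class_uri
  while (length(stack)) {
    u <- stack[[1]]; stack <- stack[-1]
    if (u %in% seen) next
    seen <- c(seen, u)
    stack <- c(stack, schema$classes[[u]]$parents)
  }
  seen
}

# ---- schema <-> triples ----------------------------------------------------

#' @keywords internal
schema_triples <- function(schema) {
  out <- list()
  add <- function(s, p, o) out[[length(out) + 1L]] <<- c(s, p, o)
  for (c in schema$classes) {
    add(c$uri, IRI_RDF_TYPE, IRI_OWL_CLASS)
    for (l in c$labels) add(c$uri, IRI_LABEL, make_literal(l))
    for (p in c$parents) add(c$uri, IRI_SUBCLASS, p)
  }
  for (p in schema$properties) {
    add(p$uri, IRI_RDF_TYPE, if (p$kind == "object") IRI_OBJ_PROP else IRI_DT_PROP)
    add(p$uri, IRI_DOMAIN, p$domain)
    add(p$uri, IRI_RANGE, if (p$kind == "object") p$range else BASE_TYPES[[p$range]])
    if (!is.na(p$subproperty_of)) add(p$uri, IRI_SUBPROP, p$subproperty_of)
  }
  r <- schema$restrictions
  for (i in seq_len(nrow(r))) {
    bn <- paste0("_:r", i)
    add(r$on_class[i], IRI_SUBCLASS, bn)
    add(bn, IRI_RDF_TYPE, IRI_RESTRICTION)
    add(bn, IRI_ON_PROPERTY, r$on_property[i])
    add(bn, IRI_ALL_VALUES, r$all_values_from[i])
  }
  a <- schema$alignments
  for (i in seq_len(nrow(a))) add(a$local_uri[i], IRI_SAME_AS, a$external_uri[i])
  if (!length(out)) return(triple_df())
  m <- do.call(rbind, out)
  triple_df(m[, 1], m[, 2], m[, 3])
}

#' Serialize a schema to an OWL document
#'
#' Emits `rdfs:subClassOf`, `rdfs:label`, `owl:Restriction`/`owl:allValuesFrom`
#' and `owl:sameAs` statements for everything the schema defines.
#'
#' @param schema an `ontology_schema`.
#' @param format `"turtle"` or `"rdfxml"`.
#' @return A character vector of document lines.
#' @seealso [parse_tbox()] for the inverse.
#' @export
serialize_tbox <- function(schema, format = c("turtle", "rdfxml")) {
  format <- match.arg(format)
  tr <- sort_triples(schema_triples(schema))
  prefixes <- default_prefixes(schema$namespace)
  switch(format,
         turtle = write_turtle(tr, prefixes),
         rdfxml = write_rdfxml(tr, prefixes))
}

#' Parse an OWL document back into a schema
#'
#' Inverse of [serialize_tbox()] up to triple order: the class, is-a edge,
#' property, restriction and alignment sets round-trip exactly.
#'
#' @param text document text (character vector of lines or a single string),
#'   or a file path to read.
#' @param format `"turtle"` or `"rdfxml"`.
#' @param namespace namespace recorded on the resulting schema.
#' @return An `ontology_schema`.
#' @export
parse_tbox <- function(text, format = c("turtle", "rdfxml"),
                       namespace = ado_namespace()) {
  format <- match.arg(format)
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  doc <- paste(text, collapse = "\n")
  tr <- switch(format,
               turtle = parse_turtle(doc)$triples,
               rdfxml = parse_rdfxml(doc))
  triples_to_schema(tr, namespace)
}

#' @keywords internal
triples_to_schema <- function(tr, namespace) {
  type_of <- function(t) tr$s[tr$p == IRI_RDF_TYPE & tr$o == t]
  class_uris <- sort(type_of(IRI_OWL_CLASS))
  bnodes <- unique(tr$s[is_blank_term(tr$s)])

  classes <- lapply(class_uris, function(u) {
    rows <- tr[tr$s == u, , drop = FALSE]
    list(uri = u,
         labels = term_text(sort(rows$o[rows$p == IRI_LABEL])),
         parents = sort(rows$o[rows$p == IRI_SUBCLASS & !is_blank_term(rows$o)]))
  })

  prop_uris <- sort(c(type_of(IRI_OBJ_PROP), type_of(IRI_DT_PROP)))
  properties <- lapply(prop_uris, function(u) {
    rows <- tr[tr$s == u, , drop = FALSE]
    kind <- if (u %in% type_of(IRI_OBJ_PROP)) "object" else "datatype"
    range <- rows$o[rows$p == IRI_RANGE][1]
    if (kind == "datatype") {
      bt <- names(BASE_TYPES)[BASE_TYPES == range]
      if (!length(bt)) stop("unknown base type in range of ", u, ": ", range)
      range <- bt
    }
    sup <- rows$o[rows$p == IRI_SUBPROP]
    list(uri = u, kind = kind,
         domain = rows$o[rows$p == IRI_DOMAIN][1],
         range = range,
         subproperty_of = if (length(sup)) sup[1] else NA_character_)
  })

  restr <- lapply(bnodes, function(b) {
    rows <- tr[tr$s == b, , drop = FALSE]
    if (!IRI_RESTRICTION %in% rows$o[rows$p == IRI_RDF_TYPE]) return(NULL)
    on_cls <- tr$s[tr$p == IRI_SUBCLASS & tr$o == b]
    data.frame(on_class = on_cls,
               on_property = rows$o[rows$p == IRI_ON_PROPERTY][1],
               all_values_from = rows$o[rows$p == IRI_ALL_VALUES][1],
               stringsAsFactors = FALSE)
  })
  restr <- do.call(rbind, c(list(data.frame(on_class = character(),
                                            on_property = character(),
                                            all_values_from = character(),
                                            stringsAsFactors = FALSE)),
                            Filter(Negate(is.null), restr)))
  restr <- restr[order(restr$on_class, restr$on_property, restr$all_values_from), ,
                 drop = FALSE]
  rownames(restr) <- NULL

  al <- tr[tr$p == IRI_SAME_AS, , drop = FALSE]
  alignments <- data.frame(local_uri = al$s, external_uri = al$o,
                           stringsAsFactors = FALSE)
  alignments <- alignments[order(alignments$local_uri, alignments$external_uri), ,
                           drop = FALSE]
  rownames(alignments) <- NULL

  ontology_schema(namespace = namespace, classes = classes,
                  properties = properties, restrictions = restr,
                  alignments = alignments)
}
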