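# RDF/XML reader/writer over the same triple tables, built on xml2. Output
# uses one rdf:Description element per subject; blank nodes are linked by
# rdf:nodeID. The reader accepts this generic shape.

#' @keywords internal
write_rdfxml <- function(triples, prefixes) {
  qname <- function(iri) {
    for (pfx in names(prefixes)) {
      ns <- prefixes[[pfx]]
      if (startsWith(iri, ns)) {
        local <- substring(iri, nchar(ns) + 1L)
        # XML element names may not start with a digit (0_1_score)
        if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local)) return(paste0(pfx, ":", local))
      }
    }
    stop("cannot emit RDF/XML for predicate outside declared namespaces: ", iri)
  }
  root <- xml2::xml_new_root("rdf:RDF")
  for (pfx in names(prefixes))
    xml2::xml_set_attr(root, paste0("xmlns:", pfx), prefixes[[pfx]])
  for (subj in unique(triples$s)) {
    d <- xml2::xml_add_child(root, "rdf:Description")
    if (is_blank_term(subj)) {
      xml2::xml_set_attr(d, "rdf:nodeID", substring(subj, 3))
    } else {
      xml2::xml_set_attr(d, "rdf:about", subj)
    }
    sub <- triples[triples$s == subj, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      el <- xml2::xml_add_child(d, qname(sub$p[i]))
      o <- sub$o[i]
      if (is_literal_term(o)) {
        dt <- term_datatype(o)
        if (!is.na(dt)) xml2::xml_set_attr(el, "rdf:datatype", dt)
        xml2::xml_set_text(el, term_text(o))
      } else if (is_blank_term(o)) {
        xml2::xml_set_attr(el, "rdf:nodeID", substring(o, 3))
      } else {
        xml2::xml_set_attr(el, "rdf:resource", o)
      }
    }
  }
  strsplit(as.character(root), "\n")[[1]]
}

# numeric-leading predicates (0_1_score) cannot be XML element names; they are
# never needed in the TBox document, which is the only RDF/XML surface.

#' @keywords internal
parse_rdfxml <- function(text) {
  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e) stop("RDF/XML parse error: ", conditionMessage(e),
                                           call. = FALSE))
  nsmap <- xml2::xml_ns(doc)
  expand_qname <- function(q) {
    parts <- strsplit(q, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("RDF/XML parse error: unprefixed element ", q)
    key <- parts[1]
    if (!key %in% names(nsmap)) stop("RDF/XML parse error: unknown prefix ", key)
    paste0(nsmap[[key]], parts[2])
  }
  out <- list()
  for (d in xml2::xml_find_all(doc, "./*")) {
    about <- xml2::xml_attr(d, "about")
    nid <- xml2::xml_attr(d, "nodeID")
    subj <- if (!is.na(about)) about else paste0("_:", nid)
    for (el in xml2::xml_find_all(d, "./*")) {
      pred <- expand_qname(xml2::xml_name(el, ns = nsmap))
      res <- xml2::xml_attr(el, "resource")
      onid <- xml2::xml_attr(el, "nodeID")
      if (!is.na(res)) {
        obj <- res
      } else if (!is.na(onid)) {
        obj <- paste0("_:", onid)
      } else {
        dt <- xml2::xml_attr(el, "datatype")
        obj <- make_literal(xml2::xml_text(el), if (is.na(dt)) NULL else dt)
      }
      out[[length(out) + 1L]] <- c(subj, pred, obj)
    }
  }
  if (!length(out)) return(triple_df())
  m <- do.call(rbind, out)
  triple_df(m[, 1], m[, 2], m[, 3])
}
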