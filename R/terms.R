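# RDF terms are plain character scalars:
#   IRI      -> the full IRI text ("http://www.modiag.it#MMSE")
#   blank    -> "_:" followed by a label
#   literal  -> N-Triples-style: "\"lex\"" optionally followed by ^^<datatype-IRI>
# Keeping terms as strings makes triple tables ordinary data.frames that sort,
# merge and unique() cheaply.

RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"
XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"
OBO_NS  <- "http://purl.obolibrary.org/obo/"

#' Default ontology namespace
#'
#' The IRI prefix under which all locally defined classes, properties and
#' minted individuals live.
#'
#' @return A length-one character IRI prefix ending in `#`.
#' @export
ado_namespace <- function() "http://www.modiag.it#"

#' @keywords internal
default_prefixes <- function(namespace = ado_namespace()) {
  c(ado  = namespace,
    owl  = OWL_NS,
    rdfs = RDFS_NS,
    rdf  = RDF_NS,
    xsd  = XSD_NS,
    obo  = OBO_NS)
}

IRI_RDF_TYPE     <- paste0(RDF_NS, "type")
IRI_SUBCLASS     <- paste0(RDFS_NS, "subClassOf")
IRI_SUBPROP      <- paste0(RDFS_NS, "subPropertyOf")
IRI_LABEL        <- paste0(RDFS_NS, "label")
IRI_DOMAIN       <- paste0(RDFS_NS, "domain")
IRI_RANGE        <- paste0(RDFS_NS, "range")
IRI_OWL_CLASS    <- paste0(OWL_NS, "Class")
IRI_OBJ_PROP     <- paste0(OWL_NS, "ObjectProperty")
IRI_DT_PROP      <- paste0(OWL_NS, "DatatypeProperty")
IRI_RESTRICTION  <- paste0(OWL_NS, "Restriction")
IRI_ON_PROPERTY  <- paste0(OWL_NS, "onProperty")
IRI_ALL_VALUES   <- paste0(OWL_NS, "allValuesFrom")
IRI_SAME_AS      <- paste0(OWL_NS, "sameAs")

# base types of the conceptual model and their XSD realizations
BASE_TYPES <- c(String = paste0(XSD_NS, "string"),
                Float  = paste0(XSD_NS, "float"),
                Date   = paste0(XSD_NS, "date"))

#' @keywords internal
is_literal_term <- function(x) startsWith(x, "\"")

#' @keywords internal
is_blank_term <- function(x) startsWith(x, "_:")

# Build an encoded literal term from a lexical form (and optional datatype IRI).
#' @keywords internal
make_literal <- function(lex, datatype = NULL) {
  esc <- gsub("\"", "\\\"", gsub("\\", "\\\\", lex, fixed = TRUE), fixed = TRUE)
  out <- paste0("\"", esc, "\"")
  if (!is.null(datatype) && !is.na(datatype)) out <- paste0(out, "^^<", datatype, ">")
  out
}

#' Lexical form of an RDF term
#'
#' For a literal term, the unescaped lexical value; for an IRI or blank node,
#' the term itself. Vectorised; convenient when turning query results into
#' plain tables.
#'
#' @param x character vector of encoded terms.
#' @return character vector of the same length.
#' @export
term_text <- function(x) {
  vapply(x, function(t) {
    if (is.na(t) || !is_literal_term(t)) return(t)
    lex <- sub("\\^\\^<[^>]*>$", "", t)
    lex <- substr(lex, 2, nchar(lex) - 1L)
    gsub("\\\\", "\\", gsub("\\\"", "\"", lex, fixed = TRUE), fixed = TRUE)
  }, character(1), USE.NAMES = FALSE)
}

#' @keywords internal
term_datatype <- function(x) {
  m <- regmatches(x, regexpr("\\^\\^<[^>]*>$", x))
  if (length(m) == 0) return(NA_character_)
  substr(m, 4, nchar(m) - 1L)
}

# local name under a hash namespace
#' @keywords internal
iri_local <- function(iri) sub("^.*#", "", iri)

# expand a bare local name against a namespace unless it already looks absolute
#' @keywords internal
expand_iri <- function(x, namespace) {
  ifelse(grepl("^[A-Za-z][A-Za-z0-9+.-]*://", x) | grepl("#", x),
         x, paste0(namespace, x))
}
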