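# A SPARQL SELECT evaluator covering the fragment the query manager needs:
# PREFIX declarations, SELECT with a variable list or *, and a basic graph
# pattern whose predicates may be property-path expressions built from IRIs
# with '/' (sequence), '|' (alternation) and '*' (reflexive-transitive
# closure). That is exactly the fragment required for inference-aware
# querying via the rdf:type/rdfs:subClassOf* idiom; the evaluator computes
# distinct solution mappings over the pattern variables and then projects,
# so projection-induced duplicates are preserved (standard multiset
# semantics).

#' @keywords internal
sparql_tokenize <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, at) tokens[[length(tokens) + 1L]] <<-
    list(type = type, value = value, at = at)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[ \t\r\n]$", ch)) { i <- i + 1L; next }
    if (ch == "#") { while (i <= n && substr(text, i, i) != "\n") i <- i + 1L; next }
    rest <- substring(text, i)
    if (ch == "<") {
      m <- regmatches(rest, regexpr("^<[^>]*>", rest))
      if (!length(m)) stop("SPARQL syntax error at character ", i, ": unterminated IRI")
      push("iri", substr(m, 2, nchar(m) - 1L), i); i <- i + nchar(m); next
    }
    if (ch == "?") {
      m <- regmatches(rest, regexpr("^\\?[A-Za-z_][A-Za-z0-9_]*", rest))
      if (!length(m)) stop("SPARQL syntax error at character ", i, ": bad variable name")
      push("var", substring(m, 2), i); i <- i + nchar(m); next
    }
    if (ch == "\"") {
      m <- regmatches(rest, regexpr("^\"(\\\\.|[^\"\\\\])*\"", rest))
      if (!length(m)) stop("SPARQL syntax error at character ", i, ": unterminated string")
      push("string", substr(m, 2, nchar(m) - 1L), i); i <- i + nchar(m); next
    }
    if (startsWith(rest, "^^")) { push("dcaret", "^^", i); i <- i + 2L; next }
    if (ch %in% c(".", "{", "}", "/", "|", "*", "(", ")")) {
      push(ch, ch, i); i <- i + 1L; next
    }
    m <- regmatches(rest, regexpr("^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_][A-Za-z0-9_-]*", rest))
    if (length(m)) { push("pname", m, i); i <- i + nchar(m); next }
    m <- regmatches(rest, regexpr("^[A-Za-z][A-Za-z0-9_.-]*:", rest))
    if (length(m)) { push("pnamens", sub(":$", "", m), i); i <- i + nchar(m); next }
    m <- regmatches(rest, regexpr("^[A-Za-z][A-Za-z0-9_]*", rest))
    if (length(m)) {
      kw <- toupper(m)
      if (kw %in% c("PREFIX", "SELECT", "WHERE")) push(kw, m, i)
      else if (m == "a") push("a", "a", i)
      else stop("SPARQL syntax error at character ", i, ": unexpected word '", m, "'")
      i <- i + nchar(m); next
    }
    stop("SPARQL syntax error at character ", i, ": unexpected '", ch, "'")
  }
  tokens
}

# Parsed query: list(vars, patterns); pattern = list(s, p, o) where s/o are
# list(type, value) terms and p is a path: list of alternatives, each a list
# of elements list(iri, star).
#' @keywords internal
sparql_parse <- function(text) {
  toks <- sparql_tokenize(text)
  pos <- 1L
  prefixes <- character()
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  fail <- function(msg, tok = peek()) {
    where <- if (is.null(tok)) "end of query" else paste0("character ", tok$at)
    stop("SPARQL syntax error at ", where, ": ", msg, call. = FALSE)
  }
  expect <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type) fail(paste0("expected '", type, "'"), t)
    advance()
  }
  resolve <- function(tok) {
    parts <- regmatches(tok$value, regexpr(":", tok$value), invert = TRUE)[[1]]
    if (!parts[1] %in% names(prefixes)) fail(paste0("undeclared prefix '", parts[1], ":'"), tok)
    paste0(prefixes[[parts[1]]], parts[2])
  }

  while (!is.null(peek()) && peek()$type == "PREFIX") {
    advance()
    t <- expect("pnamens")
    it <- expect("iri")
    prefixes[[t$value]] <- it$value
  }

  expect("SELECT")
  vars <- character()
  star <- FALSE
  repeat {
    t <- peek()
    if (is.null(t)) fail("expected WHERE")
    if (t$type == "var") { vars <- c(vars, t$value); advance() }
    else if (t$type == "*" && !length(vars)) { star <- TRUE; advance() }
    else break
  }
  if (!star && !length(vars)) fail("SELECT needs at least one variable")
  expect("WHERE")
  expect("{")

  parse_term <- function() {
    t <- peek()
    if (is.null(t)) fail("expected a term")
    if (t$type == "var") { advance(); return(list(type = "var", value = t$value)) }
    if (t$type == "iri") { advance(); return(list(type = "term", value = t$value)) }
    if (t$type == "pname") { advance(); return(list(type = "term", value = resolve(t))) }
    if (t$type == "string") {
      advance()
      dt <- NULL
      if (!is.null(peek()) && peek()$type == "dcaret") {
        advance()
        dtok <- peek()
        if (is.null(dtok) || !dtok$type %in% c("iri", "pname")) fail("expected datatype")
        advance()
        dt <- if (dtok$type == "iri") dtok$value else resolve(dtok)
      }
      return(list(type = "term",
                  value = paste0("\"", t$value, "\"",
                                 if (!is.null(dt)) paste0("^^<", dt, ">") else "")))
    }
    fail(paste0("unexpected token '", t$value, "'"), t)
  }

  parse_path_primary <- function() {
    t <- peek()
    if (is.null(t)) fail("expected a predicate")
    if (t$type == "a") { advance(); return(IRI_RDF_TYPE) }
    if (t$type == "iri") { advance(); return(t$value) }
    if (t$type == "pname") { advance(); return(resolve(t)) }
    fail(paste0("expected a predicate, got '", t$value, "'"), t)
  }
  parse_path_elt <- function() {
    iri <- parse_path_primary()
    star <- FALSE
    if (!is.null(peek()) && peek()$type == "*") { advance(); star <- TRUE }
    list(iri = iri, star = star)
  }
  parse_path_seq <- function() {
    elts <- list(parse_path_elt())
    while (!is.null(peek()) && peek()$type == "/") {
      advance()
      elts[[length(elts) + 1L]] <- parse_path_elt()
    }
    elts
  }
  parse_path_expr <- function() {
    alts <- list(parse_path_seq())
    while (!is.null(peek()) && peek()$type == "|") {
      advance()
      alts[[length(alts) + 1L]] <- parse_path_seq()
    }
    alts
  }

  patterns <- list()
  repeat {
    t <- peek()
    if (is.null(t)) fail("unterminated WHERE block")
    if (t$type == "}") { advance(); break }
    s <- parse_term()
    p <- if (!is.null(peek()) && peek()$type == "var") {
      v <- advance()
      list(var = v$value)                 # predicate variable
    } else {
      list(path = parse_path_expr())
    }
    o <- parse_term()
    patterns[[length(patterns) + 1L]] <- list(s = s, p = p, o = o)
    if (!is.null(peek()) && peek()$type == ".") advance()
  }
  if (!length(patterns)) fail("empty graph pattern")

  pat_vars <- unique(unlist(lapply(patterns, function(pt) {
    c(if (pt$s$type == "var") pt$s$value,
      if (!is.null(pt$p$var)) pt$p$var,
      if (pt$o$type == "var") pt$o$value)
  })))
  if (star) vars <- pat_vars
  missing <- setdiff(vars, pat_vars)
  if (length(missing))
    stop("SPARQL error: selected variable ?", missing[1],
         " does not occur in the pattern")
  list(vars = vars, patterns = patterns)
}

# ---- evaluation ------------------------------------------------------------

# relation (from,to) for one path element over the triple table
#' @keywords internal
path_elt_relation <- function(tr, elt, nodes) {
  edges <- tr[tr$p == elt$iri, c("s", "o"), drop = FALSE]
  names(edges) <- c("from", "to")
  if (!elt$star) return(unique(edges))
  # reflexive-transitive closure: BFS from every node
  adj <- split(edges$to, edges$from)
  out <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    start <- nodes[i]
    seen <- character()
    stack <- start
    while (length(stack)) {
      u <- stack[[1]]; stack <- stack[-1]
      if (u %in% seen) next
      seen <- c(seen, u)
      stack <- c(stack, adj[[u]])
    }
    out[[i]] <- data.frame(from = start, to = seen, stringsAsFactors = FALSE)
  }
  unique(do.call(rbind, out))
}

#' @keywords internal
path_relation <- function(tr, path, nodes) {
  alt_rel <- lapply(path, function(seqelts) {
    rel <- NULL
    for (elt in seqelts) {
      r <- path_elt_relation(tr, elt, nodes)
      rel <- if (is.null(rel)) r else {
        joined <- merge(rel, r, by.x = "to", by.y = "from")
        unique(data.frame(from = joined$from, to = joined$to.y,
                          stringsAsFactors = FALSE))
      }
    }
    rel
  })
  unique(do.call(rbind, alt_rel))
}

#' Run a SPARQL SELECT query over a store
#'
#' Supports the fragment needed for inference-aware clinical queries:
#' `PREFIX`, `SELECT` (variables or `*`), and basic graph patterns whose
#' predicates may be property paths with `/`, `|` and `*`. Subclass
#' inference is obtained by query rewriting with
#' `rdf:type/rdfs:subClassOf*` rather than by materializing the closure.
#'
#' @param store a `triple_store`.
#' @param sparql query text (single string or lines).
#' @return A data.frame of class `sparql_result` whose columns are the
#'   selected variables; cells hold encoded terms (IRIs, or literals in
#'   N-Triples form). Use [term_text()] for bare lexical values.
#' @export
run_query <- function(store, sparql) {
  q <- sparql_parse(paste(sparql, collapse = "\n"))
  tr <- store$triples
  nodes <- unique(c(tr$s, tr$o))

  sol <- data.frame(row.names = 1)   # one empty solution
  for (pt in q$patterns) {
    if (!is.null(pt$p$var)) {
      psol <- stats::setNames(tr, c(".s", pt$p$var, ".o"))
    } else {
      rel <- path_relation(tr, pt$p$path, nodes)
      psol <- data.frame(.s = rel$from, .o = rel$to, stringsAsFactors = FALSE)
    }
    # constrain / rename endpoints
    for (end in c("s", "o")) {
      col <- paste0(".", end)
      term <- pt[[end]]
      if (term$type == "var") {
        names(psol)[names(psol) == col] <- term$value
      } else {
        psol <- psol[psol[[col]] == term$value, , drop = FALSE]
        psol[[col]] <- NULL
      }
    }
    psol <- unique(psol)
    shared <- intersect(names(sol), names(psol))
    sol <- if (ncol(sol) == 0) {
      psol
    } else if (length(shared)) {
      merge(sol, psol, by = shared)
    } else {
      merge(sol, psol, by = NULL)      # cross join
    }
    sol <- unique(sol)
    if (nrow(sol) == 0) break
  }

  res <- if (nrow(sol) == 0) {
    as.data.frame(stats::setNames(rep(list(character()), length(q$vars)), q$vars),
                  optional = TRUE)
  } else {
    sol[, q$vars, drop = FALSE]        # projection keeps duplicates
  }
  rownames(res) <- NULL
  class(res) <- c("sparql_result", "data.frame")
  res
}

#' @export
print.sparql_result <- function(x, ...) {
  y <- as.data.frame(lapply(x, term_text), optional = TRUE,
                     stringsAsFactors = FALSE)
  print(y, ...)
  invisible(x)
}

#' The canned memory query
#'
#' Returns the SPARQL text of the query that searches for neuropsychological
#' test items pertaining to memory-related topics: the subject identifier,
#' the date the test was performed, the item's type and its score. The item
#' type is constrained to the memory scope class with `rdfs:subClassOf*`
#' semantics, so items typed by any subclass of the memory scope (e.g.
#' registration or learning items) are returned alongside direct instances.
#' The score resolves through `itemScore` or its binary-score subproperty.
#'
#' @param namespace ontology namespace the store was built under.
#' @return A character scalar of SPARQL text, ready for [run_query()].
#' @export
memory_items_query <- function(namespace = ado_namespace()) {
  paste0(
    "PREFIX ado: <", namespace, ">\n",
    "PREFIX rdf: <", RDF_NS, ">\n",
    "PREFIX rdfs: <", RDFS_NS, ">\n",
    "SELECT ?subject ?date ?i_type ?score\n",
    "WHERE {\n",
    "  ?subject ado:undergoes ?test .\n",
    "  ?test ado:hasDate ?date .\n",
    "  ?test ado:hasTestItem ?i .\n",
    "  ?i rdf:type ?i_type .\n",
    "  ?i_type rdfs:subClassOf* ado:MemoryItem .\n",
    "  ?i ado:itemScore|ado:0_1_score ?score .\n",
    "}\n")
}
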