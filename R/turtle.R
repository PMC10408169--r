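# Turtle reader/writer for the profile this package emits: prefix directives,
# IRI subjects, predicate-object lists with ';' and ',', string literals with
# optional ^^datatype, and non-nested bracketed blank nodes (used for OWL
# restrictions). Blank node trees are inlined on output when they are the
# object of exactly one triple.

#' @keywords internal
shorten_iri <- function(iri, prefixes) {
  for (pfx in names(prefixes)) {
    ns <- prefixes[[pfx]]
    if (startsWith(iri, ns)) {
      local <- substring(iri, nchar(ns) + 1L)
      # PN_LOCAL subset: no dots, no slashes; fall back to <> otherwise
      if (grepl("^[A-Za-z0-9_][A-Za-z0-9_-]*$", local)) {
        return(paste0(pfx, ":", local))
      }
    }
  }
  paste0("<", iri, ">")
}

#' @keywords internal
turtle_term <- function(term, prefixes) {
  if (is_literal_term(term)) {
    dt <- term_datatype(term)
    lex <- sub("\\^\\^<[^>]*>$", "", term)
    if (is.na(dt)) lex else paste0(lex, "^^", shorten_iri(dt, prefixes))
  } else if (is_blank_term(term)) {
    term
  } else {
    shorten_iri(term, prefixes)
  }
}

#' @keywords internal
write_turtle <- function(triples, prefixes) {
  out <- c(sprintf("@prefix %s: <%s> .", names(prefixes), unname(prefixes)), "")

  # blank nodes inlinable as [ ... ]: appear exactly once as an object and
  # have their own description
  bn_obj <- triples$o[is_blank_term(triples$o)]
  inlinable <- names(which(table(bn_obj) == 1L))
  inlinable <- inlinable[inlinable %in% triples$s]

  fmt_object <- function(o) {
    if (is_blank_term(o) && o %in% inlinable) {
      sub <- triples[triples$s == o, , drop = FALSE]
      inner <- vapply(seq_len(nrow(sub)), function(i) {
        paste(turtle_term(sub$p[i], prefixes), fmt_object(sub$o[i]))
      }, character(1))
      paste0("[ ", paste(inner, collapse = " ; "), " ]")
    } else {
      turtle_term(o, prefixes)
    }
  }

  top <- triples[!(triples$s %in% inlinable), , drop = FALSE]
  for (subj in unique(top$s)) {
    sub <- top[top$s == subj, , drop = FALSE]
    # rdf:type first, then alphabetical: stable, readable output
    ord <- order(sub$p != IRI_RDF_TYPE, sub$p, sub$o)
    sub <- sub[ord, , drop = FALSE]
    lines <- character()
    for (pred in unique(sub$p)) {
      objs <- vapply(sub$o[sub$p == pred], fmt_object, character(1))
      pterm <- if (pred == IRI_RDF_TYPE) "a" else turtle_term(pred, prefixes)
      lines <- c(lines, paste(pterm, paste(objs, collapse = " , ")))
    }
    out <- c(out,
             paste0(turtle_term(subj, prefixes), " ",
                    paste(lines, collapse = " ;\n    "), " ."),
             "")
  }
  out
}

# ---- tokenizer -------------------------------------------------------------

#' @keywords internal
turtle_tokenize <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  line <- 1L
  push <- function(type, value) tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, line = line)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (grepl("^[ \t\r]$", ch)) { i <- i + 1L; next }
    if (ch == "#") {                       # comment to end of line
      while (i <= n && substr(text, i, i) != "\n") i <- i + 1L
      next
    }
    rest <- substring(text, i)
    if (ch == "<") {
      m <- regmatches(rest, regexpr("^<[^>]*>", rest))
      if (length(m) == 0) stop("Turtle parse error at line ", line, ": unterminated IRI")
      push("iri", substr(m, 2, nchar(m) - 1L)); i <- i + nchar(m); next
    }
    if (ch == "\"") {
      j <- i + 1L
      lex <- character()
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\") { lex <- c(lex, substr(text, j, j + 1L)); j <- j + 2L; next }
        if (cj == "\"") break
        lex <- c(lex, cj); j <- j + 1L
      }
      if (j > n) stop("Turtle parse error at line ", line, ": unterminated string")
      push("string", paste(lex, collapse = "")); i <- j + 1L; next
    }
    if (startsWith(rest, "^^")) { push("dcaret", "^^"); i <- i + 2L; next }
    if (startsWith(rest, "@prefix")) { push("atprefix", "@prefix"); i <- i + 7L; next }
    if (ch %in% c(".", ";", ",", "[", "]")) { push(ch, ch); i <- i + 1L; next }
    m <- regmatches(rest, regexpr("^_:[A-Za-z0-9_]+", rest))
    if (length(m) == 1) { push("bnode", m); i <- i + nchar(m); next }
    m <- regmatches(rest, regexpr("^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_][A-Za-z0-9_-]*", rest))
    if (length(m) == 1) { push("pname", m); i <- i + nchar(m); next }
    m <- regmatches(rest, regexpr("^[A-Za-z][A-Za-z0-9_.-]*:", rest))  # prefix decl
    if (length(m) == 1) { push("pnamens", substr(m, 1, nchar(m) - 1L)); i <- i + nchar(m); next }
    if (grepl("^a[ \t\r\n]", rest) || rest == "a") { push("a", "a"); i <- i + 1L; next }
    stop("Turtle parse error at line ", line, ": unexpected character '", ch, "'")
  }
  tokens
}

# ---- parser ----------------------------------------------------------------

# Returns list(triples = data.frame(s,p,o), prefixes = named character)
#' @keywords internal
parse_turtle <- function(text) {
  toks <- turtle_tokenize(text)
  pos <- 1L
  prefixes <- character()
  triples <- list()
  bn_count <- 0L

  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  fail <- function(msg, tok = peek()) {
    where <- if (is.null(tok)) "end of input" else paste0("line ", tok$line)
    stop("Turtle parse error at ", where, ": ", msg, call. = FALSE)
  }
  expect <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type) fail(paste0("expected '", type, "'"), t)
    advance()
  }
  emit <- function(s, p, o) triples[[length(triples) + 1L]] <<- c(s, p, o)

  resolve_pname <- function(tok) {
    parts <- regmatches(tok$value, regexpr(":", tok$value), invert = TRUE)[[1]]
    pfx <- parts[1]
    if (!pfx %in% names(prefixes)) fail(paste0("undeclared prefix '", pfx, ":'"), tok)
    paste0(prefixes[[pfx]], parts[2])
  }

  parse_term <- function() {
    t <- peek()
    if (is.null(t)) fail("expected a term")
    if (t$type == "iri") { advance(); return(t$value) }
    if (t$type == "pname") { advance(); return(resolve_pname(t)) }
    if (t$type == "a") { advance(); return(IRI_RDF_TYPE) }
    if (t$type == "bnode") { advance(); return(t$value) }
    if (t$type == "string") {
      advance()
      dt <- NULL
      if (!is.null(peek()) && peek()$type == "dcaret") {
        advance()
        dtok <- peek()
        if (is.null(dtok) || !dtok$type %in% c("iri", "pname")) fail("expected datatype IRI")
        advance()
        dt <- if (dtok$type == "iri") dtok$value else resolve_pname(dtok)
      }
      return(paste0("\"", t$value, "\"", if (!is.null(dt)) paste0("^^<", dt, ">") else ""))
    }
    if (t$type == "[") return(parse_bnode())
    fail(paste0("unexpected token '", t$value, "'"), t)
  }

  parse_bnode <- function() {
    expect("[")
    bn_count <<- bn_count + 1L
    id <- paste0("_:b", bn_count)
    if (!is.null(peek()) && peek()$type != "]") parse_polist(id)
    expect("]")
    id
  }

  parse_polist <- function(subj) {
    repeat {
      pred <- parse_term()
      if (is_literal_term(pred) || is_blank_term(pred)) fail("predicate must be an IRI")
      repeat {
        emit(subj, pred, parse_term())
        if (!is.null(peek()) && peek()$type == ",") advance() else break
      }
      if (!is.null(peek()) && peek()$type == ";") {
        advance()
        if (!is.null(peek()) && peek()$type %in% c(".", "]")) break  # trailing ';'
      } else break
    }
  }

  while (!is.null(peek())) {
    if (peek()$type == "atprefix") {
      advance()
      pt <- expect("pnamens")
      it <- expect("iri")
      expect(".")
      prefixes[[pt$value]] <- it$value
      next
    }
    subj <- parse_term()
    if (is_literal_term(subj)) fail("subject must be an IRI or blank node")
    parse_polist(subj)
    expect(".")
  }

  tr <- if (length(triples)) {
    m <- do.call(rbind, triples)
    triple_df(m[, 1], m[, 2], m[, 3])
  } else triple_df()
  list(triples = tr, prefixes = prefixes)
}
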