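# The mapping-rule language: dotted TBox paths
# (Class.property.Class. ... .property.BaseType) and rule files of lines
# "TABLE.FIELD -> path". A path step sequence must be licensed by the
# schema's domain/range declarations, with subclass substitutability: a
# property declared on a general class is usable from any of its subclasses.
# allValuesFrom restrictions (inherited from ancestors) further narrow the
# admissible next class.

#' Parse and validate a dotted TBox path
#'
#' A TBox path alternates classes and properties, starting at a class and
#' ending in one of the base types `String`, `Float`, `Date`, e.g.
#' `Subject.undergoes.MMSE.hasTestItem.MMSE_OrientationItem_1.0_1_score.Float`.
#' Each (class, property, next) triple is checked against the schema's
#' domain/range declarations; a class may use any property declared on one of
#' its ancestors, and the next class may specialize the property's range.
#'
#' @param text the dotted path.
#' @param schema an `ontology_schema`.
#' @return An object of class `tbox_path` with elements `steps` (local
#'   names), `classes`/`properties` (full IRIs) and `terminal` (base type).
#' @export
parse_path <- function(text, schema) {
  steps <- strsplit(text, ".", fixed = TRUE)[[1]]
  if (!all(grepl("^[A-Za-z0-9_-]+$", steps)))
    stop("invalid path '", text, "': identifiers must match [A-Za-z0-9_-]+")
  n <- length(steps)
  if (n %% 2 == 0)
    stop("invalid path '", text, "': even number of steps")
  if (n < 3)
    stop("invalid path '", text, "': path must end in a base type ",
         "(expected Class.property. ... .BaseType)")
  ns <- schema$namespace
  class_pos <- seq(1, n - 2, by = 2)
  prop_pos <- seq(2, n - 1, by = 2)

  # single left-to-right walk so the leftmost failing step is the one reported
  if (!paste0(ns, steps[1]) %in% names(schema$classes))
    stop("invalid path '", text, "' at step 1: unknown class '", steps[1], "'")
  for (i in prop_pos) {
    cur <- paste0(ns, steps[i - 1])
    puri <- paste0(ns, steps[i])
    if (!puri %in% names(schema$properties))
      stop("invalid path '", text, "' at step ", i, ": unknown property '",
           steps[i], "'")
    prop <- schema$properties[[puri]]
    if (!prop$domain %in% superclass_closure(schema, cur))
      stop("invalid path '", text, "' at step ", i, ": property '", steps[i],
           "' not applicable from '", steps[i - 1], "' (domain is '",
           iri_local(prop$domain), "')")
    last <- i == n - 1
    if (last) {
      if (!steps[n] %in% names(BASE_TYPES))
        stop("invalid path '", text, "' at step ", n, ": terminal step '",
             steps[n], "' is not a base type (String, Float, Date)")
      if (prop$kind != "datatype")
        stop("invalid path '", text, "' at step ", i, ": object property '",
             steps[i], "' cannot end a path")
      if (prop$range != steps[n])
        stop("invalid path '", text, "' at step ", i + 1,
             ": base type mismatch, property '", steps[i], "' has range ",
             prop$range)
    } else {
      if (prop$kind != "object")
        stop("invalid path '", text, "' at step ", i, ": datatype property '",
             steps[i], "' must be followed by its base type")
      nxt <- paste0(ns, steps[i + 1])
      if (!nxt %in% names(schema$classes))
        stop("invalid path '", text, "' at step ", i + 1, ": unknown class '",
             steps[i + 1], "'")
      if (!prop$range %in% superclass_closure(schema, nxt))
        stop("invalid path '", text, "' at step ", i + 1, ": '", steps[i + 1],
             "' is outside the range of '", steps[i], "' ('",
             iri_local(prop$range), "')")
      # restrictions declared on the current class or any ancestor
      anc <- superclass_closure(schema, cur)
      r <- schema$restrictions
      r <- r[r$on_class %in% anc & r$on_property == prop$uri, , drop = FALSE]
      for (v in r$all_values_from) {
        if (!v %in% superclass_closure(schema, nxt))
          stop("invalid path '", text, "' at step ", i + 1, ": '",
               steps[i + 1], "' violates the allValuesFrom restriction to '",
               iri_local(v), "'")
      }
    }
  }

  structure(list(steps = steps,
                 classes = paste0(ns, steps[class_pos]),
                 properties = paste0(ns, steps[prop_pos]),
                 terminal = steps[n]),
            class = "tbox_path")
}

#' Render a TBox path back to dot notation
#' @param path a `tbox_path`.
#' @return The dotted string.
#' @export
render_path <- function(path) paste(path$steps, collapse = ".")

#' @export
print.tbox_path <- function(x, ...) {
  cat("<tbox_path> ", render_path(x), "\n", sep = "")
  invisible(x)
}

#' Parse a mapping-rule file
#'
#' One rule per non-comment line, in the form `TABLE.FIELD -> path`, where
#' `path` is a dotted TBox path (see [parse_path()]). `#` starts a comment;
#' blank lines are ignored. Every rule's path is validated against the
#' schema, `(table, field)` pairs must be unique, and several rules may share
#' one path — that is how field dialects from different study phases are
#' declared.
#'
#' @param text rule file path, or the rule text itself (lines or a single
#'   string).
#' @param schema an `ontology_schema`.
#' @return A list of `mapping_rule` objects (fields `table`, `field`, `path`,
#'   `line`), in file order, with class `mapping_rules`.
#' @export
parse_rules <- function(text, schema) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  rules <- list()
  seen <- character()
  for (i in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[i])
    if (!grepl("\\S", raw)) next
    m <- regmatches(raw, regexec(
      "^\\s*([A-Za-z0-9_-]+)\\.([A-Za-z0-9_-]+)\\s*->\\s*([A-Za-z0-9_.-]+)\\s*$", raw))[[1]]
    if (length(m) == 0)
      stop("rule syntax error at line ", i, ": '", trimws(raw), "'")
    key <- paste0(m[2], ".", m[3])
    if (key %in% seen)
      stop("duplicate rule for ", key, " at line ", i)
    seen <- c(seen, key)
    path <- tryCatch(parse_path(m[4], schema),
                     error = function(e) stop("line ", i, ": ",
                                              conditionMessage(e), call. = FALSE))
    rules[[length(rules) + 1L]] <-
      structure(list(table = m[2], field = m[3], path = path, line = i),
                class = "mapping_rule")
  }
  structure(rules, class = "mapping_rules")
}

#' Group rules that share the same TBox path
#'
#' Rules with step-wise identical paths are field dialects for the same piece
#' of information (e.g. `EXAMDATE` in early study phases vs `USERDATE`
#' later). The ETL consumes exactly one populated field per group per row.
#'
#' @param rules a `mapping_rules` list.
#' @return A list of rule groups (each a list of `mapping_rule`), keyed by
#'   the rendered path, in order of first appearance.
#' @export
dialect_groups <- function(rules) {
  keys <- vapply(rules, function(r) render_path(r$path), character(1))
  groups <- list()
  for (i in seq_along(rules)) {
    groups[[keys[i]]] <- c(groups[[keys[i]]], list(rules[[i]]))
  }
  groups
}
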