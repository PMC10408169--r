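# Independent oracles, deliberately written against the raw data structures
# (class records, triple tables) rather than the package's own traversal or
# query code.

# is-a edge list (parent, child) straight off the schema's class records
schema_isa_edges <- function(schema) {
  do.call(rbind, c(list(data.frame(parent = character(), child = character(),
                                   stringsAsFactors = FALSE)),
                   lapply(schema$classes, function(cl) {
                     if (!length(cl$parents)) return(NULL)
                     data.frame(parent = cl$parents, child = cl$uri,
                                stringsAsFactors = FALSE)
                   })))
}

# brute-force reachability: grow the set by whole-edge-list sweeps until fixed
# point (no DFS, no recursion)
oracle_reachable <- function(edges, root) {
  reach <- root
  repeat {
    nxt <- unique(c(reach, edges$child[edges$parent %in% reach]))
    if (length(nxt) == length(reach)) return(sort(reach))
    reach <- nxt
  }
}

# topological order must exist (acyclicity oracle): repeatedly peel nodes
# with no unpeeled parent
oracle_is_acyclic <- function(edges, nodes) {
  left <- nodes
  repeat {
    peel <- left[!left %in% edges$child[edges$parent %in% left]]
    if (!length(peel)) return(length(left) == 0)
    left <- setdiff(left, peel)
    if (!length(left)) return(TRUE)
  }
}

# Naive nested-loop evaluation of the memory query over a raw triple table:
# joins written out by hand, with the subclass closure recomputed from the
# store's own rdfs:subClassOf triples by sweep (not by the package).
RDF_TYPE_T <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
SUBCLASS_T <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"

oracle_memory_rows <- function(store, ns = ado_namespace()) {
  tr <- store$triples
  sub_edges <- data.frame(parent = tr$o[tr$p == SUBCLASS_T],
                          child = tr$s[tr$p == SUBCLASS_T],
                          stringsAsFactors = FALSE)
  sub_edges <- sub_edges[!startsWith(sub_edges$parent, "_:"), , drop = FALSE]
  memory_classes <- oracle_reachable(sub_edges, paste0(ns, "MemoryItem"))

  undergoes <- tr[tr$p == paste0(ns, "undergoes"), , drop = FALSE]
  hasdate <- tr[tr$p == paste0(ns, "hasDate"), , drop = FALSE]
  hasitem <- tr[tr$p == paste0(ns, "hasTestItem"), , drop = FALSE]
  types <- tr[tr$p == RDF_TYPE_T, , drop = FALSE]
  scores <- tr[tr$p %in% paste0(ns, c("itemScore", "0_1_score")), , drop = FALSE]

  out <- list()
  for (i in seq_len(nrow(undergoes))) {
    test <- undergoes$o[i]
    for (date in hasdate$o[hasdate$s == test]) {
      for (item in hasitem$o[hasitem$s == test]) {
        for (itype in types$o[types$s == item]) {
          if (!itype %in% memory_classes) next
          for (score in scores$o[scores$s == item]) {
            out[[length(out) + 1L]] <- data.frame(
              subject = undergoes$s[i], date = date, i_type = itype,
              score = score, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(subject = character(), date = character(),
                      i_type = character(), score = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# inject one foreign item triple (a GDS item attached to an MMSE session)
bad_item_store <- function(store, ns = ado_namespace()) {
  store_add(store, data.frame(
    s = c(paste0(ns, "GDSItem_99"), paste0(ns, "MMSE_1")),
    p = c(RDF_TYPE_T, paste0(ns, "hasTestItem")),
    o = c(paste0(ns, "GDSItem"), paste0(ns, "GDSItem_99")),
    stringsAsFactors = FALSE))
}

# full-scan allValuesFrom oracle: for every restriction row in the schema,
# sweep-compute both closures from the store's subClassOf triples and check
# every triple of the restricted property on every individual typed under the
# restricted class
oracle_avf_violations <- function(store, schema = the_schema) {
  tr <- store$triples
  sub_edges <- data.frame(parent = tr$o[tr$p == SUBCLASS_T],
                          child = tr$s[tr$p == SUBCLASS_T],
                          stringsAsFactors = FALSE)
  sub_edges <- sub_edges[!startsWith(sub_edges$parent, "_:"), , drop = FALSE]
  types <- tr[tr$p == RDF_TYPE_T, , drop = FALSE]
  n_bad <- 0L
  for (i in seq_len(nrow(schema$restrictions))) {
    r <- schema$restrictions[i, ]
    on_cls <- oracle_reachable(sub_edges, r$on_class)
    allowed <- oracle_reachable(sub_edges, r$all_values_from)
    subjects <- unique(types$s[types$o %in% on_cls])
    vals <- tr[tr$p == r$on_property & tr$s %in% subjects, , drop = FALSE]
    for (o in vals$o) {
      o_types <- types$o[types$s == o]
      if (!any(o_types %in% allowed)) n_bad <- n_bad + 1L
    }
  }
  n_bad
}

# canonical multiset comparison of result tables
sorted_rows <- function(df) {
  df <- as.data.frame(lapply(df, as.character), optional = TRUE,
                      stringsAsFactors = FALSE)
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}
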