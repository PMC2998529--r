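# An ontology_dag stores one GO namespace as child->parent adjacency lists.
# Edges follow the OBO orientation (is_a points from the more specific term
# to the more general one), so "ancestors" are reached by following stored
# edges and the namespace root is the unique term with no parents.

new_ontology_dag <- function(namespace, ids, parents, reltypes,
                             term_names, alt_ids) {
  stopifnot(is.character(ids), !anyDuplicated(ids))
  children <- rep(list(character(0)), length(ids))
  names(children) <- ids
  for (id in ids) {
    for (p in parents[[id]]) {
      children[[p]] <- c(children[[p]], id)
    }
  }
  roots <- ids[vapply(parents[ids], length, 1L) == 0L]
  if (length(roots) != 1L) {
    stop("ontology must have exactly one root term, found ",
         length(roots), ": ", paste(utils::head(roots, 5), collapse = ", "))
  }
  dag <- structure(list(
    namespace  = namespace,
    ids        = ids,
    parents    = parents,
    children   = children,
    reltypes   = reltypes,
    term_names = term_names,
    alt_ids    = alt_ids,
    root       = roots,
    cache      = new.env(parent = emptyenv())
  ), class = "ontology_dag")
  dag$topo <- topological_order(dag)
  dag
}

# Kahn's algorithm; errors on cycles. Returned order lists parents before
# children.
topological_order <- function(dag) {
  indeg <- vapply(dag$parents[dag$ids], length, 1L)
  names(indeg) <- dag$ids
  queue <- dag$ids[indeg == 0L]
  order <- character(0)
  while (length(queue)) {
    queue <- sort(queue)  # deterministic order
    v <- queue[1L]
    queue <- queue[-1L]
    order <- c(order, v)
    for (ch in dag$children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) != length(dag$ids)) {
    stop("cycle detected in ontology graph involving terms: ",
         paste(setdiff(dag$ids, order), collapse = ", "))
  }
  order
}

#' Parse an OBO 1.2 ontology file into a DAG
#'
#' Reads `[Term]` stanzas of an OBO 1.2 flat file and returns the directed
#' acyclic graph of one namespace. Obsolete terms are dropped, `alt_id`
#' values are recorded as aliases resolving to their canonical id, and all
#' relationship types present in the file (`is_a`, `part_of`, `regulates`,
#' ...) are kept as edges and treated equally unless restricted via
#' `relations`. Terms of other namespaces, and edges crossing into them,
#' are discarded so that each ontology is analysed separately.
#'
#' @param file Path to an OBO file, or a character scalar containing OBO
#'   text (detected by embedded newlines).
#' @param namespace One of `"cellular_component"`, `"biological_process"`,
#'   `"molecular_function"`, or an abbreviation `"CC"`/`"BP"`/`"MF"`.
#' @param relations Optional character vector of relationship types to
#'   keep; default keeps every type found.
#' @return An object of class `ontology_dag` with fields `ids`, `parents`,
#'   `children`, `root`, `term_names`, `alt_ids`, `namespace`.
#' @examples
#' obo <- c("format-version: 1.2",
#'          "[Term]", "id: GO:0000001", "name: root",
#'          "namespace: cellular_component",
#'          "[Term]", "id: GO:0000002", "name: child",
#'          "namespace: cellular_component", "is_a: GO:0000001 ! root")
#' dag <- parse_obo(paste(obo, collapse = "\n"), "CC")
#' dag$root
#' @export
parse_obo <- function(file, namespace, relations = NULL) {
  namespace <- normalize_namespace(namespace)
  lines <- read_input_lines(file)

  stanza <- NULL       # NULL outside [Term] blocks
  in_other <- FALSE    # inside a non-Term stanza (e.g. [Typedef])
  terms <- list()
  flush <- function(st) if (!is.null(st)) terms[[length(terms) + 1L]] <<- st

  for (i in seq_along(lines)) {
    line <- strip_obo_comment(lines[[i]])
    if (line == "") next
    if (grepl("^\\[", line)) {
      flush(stanza)
      stanza <- NULL
      if (identical(line, "[Term]")) {
        stanza <- list(line = i, alt_id = character(0),
                       parents = character(0), reltype = character(0),
                       obsolete = FALSE)
        in_other <- FALSE
      } else {
        in_other <- TRUE
      }
      next
    }
    if (in_other || (is.null(stanza) && !grepl("^\\[", line))) next
    m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1L]]
    if (length(m) != 3L) {
      stop("malformed OBO stanza line ", i, ": '", lines[[i]], "'")
    }
    tag <- m[[2L]]; val <- trimws(m[[3L]])
    if (tag == "id") stanza$id <- val
    else if (tag == "name") stanza$name <- val
    else if (tag == "namespace") stanza$namespace <- val
    else if (tag == "is_obsolete") stanza$obsolete <- identical(val, "true")
    else if (tag == "alt_id") stanza$alt_id <- c(stanza$alt_id, val)
    else if (tag == "is_a") {
      stanza$parents <- c(stanza$parents, val)
      stanza$reltype <- c(stanza$reltype, "is_a")
    } else if (tag == "relationship") {
      parts <- strsplit(val, "\\s+")[[1L]]
      if (length(parts) < 2L) {
        stop("malformed relationship on line ", i, ": '", lines[[i]], "'")
      }
      stanza$parents <- c(stanza$parents, parts[[2L]])
      stanza$reltype <- c(stanza$reltype, parts[[1L]])
    }
    # unknown tags tolerated
  }
  flush(stanza)

  for (st in terms) {
    if (is.null(st$id)) {
      stop("OBO [Term] stanza starting at line ", st$line, " has no id")
    }
  }
  all_ids <- vapply(terms, `[[`, "", "id")
  ns_of <- vapply(terms, function(s) s$namespace %||% NA_character_, "")
  names(ns_of) <- all_ids
  obsolete <- vapply(terms, `[[`, TRUE, "obsolete")

  keep <- !obsolete & !is.na(ns_of) & ns_of == namespace
  kept <- terms[keep]
  ids <- vapply(kept, `[[`, "", "id")
  if (!length(ids)) stop("no terms found for namespace '", namespace, "'")
  if (anyDuplicated(ids)) {
    stop("duplicate term ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }

  parents <- list(); reltypes <- list()
  term_names <- character(0); alt_vec <- character(0)
  for (st in kept) {
    p <- st$parents; r <- st$reltype
    if (!is.null(relations)) {
      sel <- r %in% relations
      p <- p[sel]; r <- r[sel]
    }
    dangling <- setdiff(p, all_ids)
    if (length(dangling)) {
      stop("term ", st$id, " references undefined parent(s): ",
           paste(dangling, collapse = ", "))
    }
    # drop edges to obsolete/other-namespace parents
    sel <- p %in% ids
    dup <- duplicated(paste(p, r))
    sel <- sel & !dup
    parents[[st$id]] <- p[sel]
    reltypes[[st$id]] <- r[sel]
    term_names[[st$id]] <- st$name %||% st$id
    if (length(st$alt_id)) {
      a <- rep(st$id, length(st$alt_id)); names(a) <- st$alt_id
      alt_vec <- c(alt_vec, a)
    }
  }
  new_ontology_dag(namespace, ids, parents, reltypes, term_names, alt_vec)
}

strip_obo_comment <- function(line) {
  # trailing comments start at an unescaped '!'
  trimws(sub("(?<!\\\\)!.*$", "", line, perl = TRUE))
}

normalize_namespace <- function(namespace) {
  full <- c(CC = "cellular_component", BP = "biological_process",
            MF = "molecular_function")
  if (toupper(namespace) %in% names(full)) {
    return(unname(full[[toupper(namespace)]]))
  }
  if (!namespace %in% full) {
    stop("unknown namespace '", namespace, "'; expected one of ",
         paste(c(full, names(full)), collapse = ", "))
  }
  namespace
}

read_input_lines <- function(file) {
  if (length(file) > 1L) return(file)
  if (grepl("\n", file, fixed = TRUE)) {
    return(strsplit(file, "\n", fixed = TRUE)[[1L]])
  }
  readLines(file, warn = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve a term id, following alt_id aliases
#'
#' @param dag An `ontology_dag`.
#' @param ids Character vector of GO ids (canonical or alt).
#' @param error If `TRUE` (default), unknown ids raise an error; otherwise
#'   they map to `NA`.
#' @return Character vector of canonical ids.
#' @export
resolve_term <- function(dag, ids, error = TRUE) {
  out <- ids
  is_alt <- out %in% names(dag$alt_ids)
  out[is_alt] <- unname(dag$alt_ids[out[is_alt]])
  bad <- !(out %in% dag$ids)
  if (any(bad)) {
    if (error) {
      stop("unknown term id(s): ", paste(unique(ids[bad]), collapse = ", "))
    }
    out[bad] <- NA_character_
  }
  out
}

# Full ancestor closure for every term, cached on the dag. Named list
# id -> character vector of strict ancestors.
ancestor_sets <- function(dag) {
  if (!is.null(dag$cache$anc)) return(dag$cache$anc)
  anc <- rep(list(character(0)), length(dag$ids))
  names(anc) <- dag$ids
  for (id in dag$topo) {   # parents visited before children
    ps <- dag$parents[[id]]
    if (length(ps)) {
      anc[[id]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
    }
  }
  dag$cache$anc <- anc
  anc
}

descendant_sets <- function(dag) {
  if (!is.null(dag$cache$desc)) return(dag$cache$desc)
  desc <- rep(list(character(0)), length(dag$ids))
  names(desc) <- dag$ids
  for (id in rev(dag$topo)) {
    ch <- dag$children[[id]]
    if (length(ch)) {
      desc[[id]] <- unique(c(ch, unlist(desc[ch], use.names = FALSE)))
    }
  }
  dag$cache$desc <- desc
  desc
}

#' Ancestors and descendants of a term
#'
#' `ancestors()` returns every term reachable from `t` by repeatedly
#' following parent links (excluding `t` itself); `descendants()` is the
#' mirror query over child links.
#'
#' @param dag An `ontology_dag`.
#' @param t A single term id.
#' @return Character vector of term ids (possibly empty for the root /
#'   a leaf).
#' @export
ancestors <- function(dag, t) {
  t <- resolve_term(dag, t)
  ancestor_sets(dag)[[t]]
}

#' @rdname ancestors
#' @export
descendants <- function(dag, t) {
  t <- resolve_term(dag, t)
  descendant_sets(dag)[[t]]
}

#' Transitive reduction of an ontology DAG
#'
#' Removes every edge (u, v) for which another directed path from u to v
#' exists, yielding the unique minimal graph with the same transitive
#' closure as the input. On GO this collapses shortcut edges such as
#' a -> c alongside a -> b -> c, which reduces the chance that a term
#' falls into two sub-graphs during clustering.
#'
#' @param dag An `ontology_dag`.
#' @return An `ontology_dag` with redundant edges removed.
#' @export
transitive_reduction <- function(dag) {
  anc <- ancestor_sets(dag)
  parents <- dag$parents
  reltypes <- dag$reltypes
  for (id in dag$ids) {
    ps <- parents[[id]]
    if (length(ps) < 2L) next
    # parent p is redundant iff it is an ancestor of another parent q
    redundant <- vapply(ps, function(p) {
      any(vapply(ps, function(q) !identical(p, q) && p %in% anc[[q]], TRUE))
    }, TRUE)
    parents[[id]] <- ps[!redundant]
    reltypes[[id]] <- reltypes[[id]][!redundant]
  }
  new_ontology_dag(dag$namespace, dag$ids, parents, reltypes,
                   dag$term_names, dag$alt_ids)
}

#' Serialize an ontology DAG back to OBO 1.2 text
#'
#' @param dag An `ontology_dag`.
#' @param file Optional path; when `NULL` the OBO text is returned as a
#'   character vector of lines.
#' @return Invisibly, the OBO lines.
#' @export
write_obo <- function(dag, file = NULL) {
  out <- c("format-version: 1.2", "")
  for (id in dag$ids) {
    out <- c(out, "[Term]",
             paste0("id: ", id),
             paste0("name: ", dag$term_names[[id]]),
             paste0("namespace: ", dag$namespace))
    alts <- names(dag$alt_ids)[dag$alt_ids == id]
    for (a in alts) out <- c(out, paste0("alt_id: ", a))
    ps <- dag$parents[[id]]; rs <- dag$reltypes[[id]]
    for (k in seq_along(ps)) {
      out <- c(out, if (rs[[k]] == "is_a") paste0("is_a: ", ps[[k]])
               else paste0("relationship: ", rs[[k]], " ", ps[[k]]))
    }
    out <- c(out, "")
  }
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' @export
print.ontology_dag <- function(x, ...) {
  n_edges <- sum(vapply(x$parents, length, 1L))
  cat("ontology_dag:", x$namespace, "\n",
      length(x$ids), "terms,", n_edges, "edges, root", x$root, "\n")
  invisible(x)
}

# number of edges, used by tests and reports
n_edges <- function(dag) sum(vapply(dag$parents, length, 1L))
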