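# Topological clustering: ICT, sub-graph root selection and merging,
# term-to-sub-graph assignment (with duplication), and the meta-graph
# with normalized ICS/ICM tables.

#' Topological information content (ICT)
#'
#' `ICT(t) = -ln((|descendants(t)| + 1) / |O|)`, where `|O|` is the number
#' of terms in the namespace. General terms near the root cover most of
#' the ontology and get ICT near 0; leaves get `ln|O|`. The descendant
#' count includes the term itself so that leaves have a finite value.
#'
#' @param dag An `ontology_dag`.
#' @param t A single term id (for `ict()`).
#' @return `ict()`: a single non-negative value. `ict_values()`: named
#'   numeric vector over all terms.
#' @export
ict_values <- function(dag) {
  desc <- descendant_sets(dag)
  n <- length(dag$ids)
  v <- -log((vapply(desc, length, 1L) + 1) / n)
  names(v) <- dag$ids
  v
}

#' @rdname ict_values
#' @export
ict <- function(dag, t) {
  t <- resolve_term(dag, t)
  ict_values(dag)[[t]]
}

#' Select sub-graph root candidates at a topology cutoff
#'
#' Returns every term whose ICT does not exceed `cutoff`. These general
#' terms are the candidate sub-graph roots; the namespace root (ICT 0) is
#' always selected. If the cutoff admits every term the clustering is
#' degenerate and a warning is raised.
#'
#' @param dag An `ontology_dag`.
#' @param cutoff Positive ICT threshold (the "topology cutoff").
#' @param ict_vals Optional precomputed `ict_values(dag)`.
#' @return Character vector of selected term ids, sorted.
#' @export
select_roots <- function(dag, cutoff, ict_vals = NULL) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  if (is.null(ict_vals)) ict_vals <- ict_values(dag)
  roots <- sort(names(ict_vals)[ict_vals <= cutoff])
  if (length(roots) == length(dag$ids)) {
    warning("topology cutoff ", cutoff, " selects every term; ",
            "clustering is degenerate")
  }
  roots
}

#' Merge nested sub-graph roots with similar ICT
#'
#' Roots are processed in ascending ICT order (ties broken by term id).
#' A root that descends from an already-kept root and whose ICT lies
#' within +/-20% of the kept root's ICT is removed, so its would-be
#' sub-graph merges into the ancestor's. Merging near-duplicate nested
#' roots increases the dissimilarity between the remaining sub-graphs.
#' Because ICT is monotone along descent, only the upper bound
#' (`ICT(descendant) <= (1 + tolerance) * ICT(ancestor)`) can bind.
#'
#' @param dag An `ontology_dag`.
#' @param roots Character vector of candidate roots from [select_roots()].
#' @param ict_vals Precomputed `ict_values(dag)` (optional).
#' @param tolerance Relative ICT window, default 0.2.
#' @return Character vector of surviving roots, sorted.
#' @export
merge_similar_roots <- function(dag, roots, ict_vals = NULL,
                                tolerance = 0.2) {
  if (is.null(ict_vals)) ict_vals <- ict_values(dag)
  anc <- ancestor_sets(dag)
  ord <- roots[order(ict_vals[roots], roots)]
  removed <- character(0)
  for (r in ord) {
    if (r %in% removed) next
    lo <- (1 - tolerance) * ict_vals[[r]]
    hi <- (1 + tolerance) * ict_vals[[r]]
    for (s in ord) {
      if (s == r || s %in% removed) next
      if (r %in% anc[[s]] &&
          ict_vals[[s]] >= lo && ict_vals[[s]] <= hi) {
        removed <- c(removed, s)
      }
    }
  }
  sort(setdiff(roots, removed))
}

#' Assign terms to sub-graphs and compute ICS tables
#'
#' Every term is assigned to the sub-graph(s) of its most specific root
#' ancestor(s): among the roots that are ancestors of (or equal to) the
#' term, those with maximal ICT. When several incomparable roots tie, the
#' term (and consequently its descendants) is duplicated into each
#' sub-graph. Each root belongs to its own sub-graph. Within each
#' sub-graph the annotation information content is renormalized:
#' `ICS(t) = ICA(t) / max ICA` over the sub-graph's annotated members, so
#' the most informative term of every sub-graph scores exactly 1.
#'
#' @param dag An `ontology_dag`, ideally transitively reduced.
#' @param roots Character vector of sub-graph roots (after merging).
#' @param ica_tab Result of [ica_table()].
#' @param warn Warn about sub-graphs with no annotated member (they are
#'   excluded from scoring). Default `TRUE`.
#' @return A `subgraph_index`: list with `roots`, `membership` (term ->
#'   roots), `members` (root -> terms), `max_ica`, and `ics` (root ->
#'   named numeric over members).
#' @export
build_subgraphs <- function(dag, roots, ica_tab, warn = TRUE) {
  if (!length(roots)) stop("no sub-graph roots supplied")
  ict_vals <- ict_values(dag)
  anc <- ancestor_sets(dag)
  membership <- vector("list", length(dag$ids))
  names(membership) <- dag$ids
  for (id in dag$ids) {
    cand <- intersect(c(id, anc[[id]]), roots)
    v <- ict_vals[cand]
    membership[[id]] <- sort(cand[v == max(v)])
  }
  members <- split(
    rep(dag$ids, lengths(membership)),
    unlist(membership, use.names = FALSE)
  )
  members <- lapply(members, sort)

  max_ica <- ics <- stats::setNames(vector("list", length(members)),
                                    names(members))
  empty <- character(0)
  for (r in names(members)) {
    m <- members[[r]]
    vals <- ica_tab$ica[m]
    if (all(is.na(vals))) {
      empty <- c(empty, r)
      max_ica[[r]] <- NA_real_
      ics[[r]] <- stats::setNames(rep(NA_real_, length(m)), m)
    } else {
      mx <- max(vals, na.rm = TRUE)
      max_ica[[r]] <- mx
      ics[[r]] <- if (mx > 0) vals / mx else ifelse(is.na(vals), NA_real_, 1)
      names(ics[[r]]) <- m
    }
  }
  if (warn && length(empty)) {
    warning(length(empty), " sub-graph(s) contain no annotated term and ",
            "are excluded from scoring: ",
            paste(utils::head(empty, 5), collapse = ", "))
  }
  structure(list(
    roots = sort(names(members)),
    membership = membership,
    members = members,
    max_ica = unlist(max_ica),
    ics = ics,
    unannotated_subgraphs = empty
  ), class = "subgraph_index")
}

#' Build the meta-graph over sub-graph roots
#'
#' The meta-graph's nodes are the sub-graph roots together with all of
#' their ancestors; its edges are the transitive reduction of the
#' reachability relation among those nodes. Node information content is
#' renormalized over the meta level: `ICM(t) = ICA(t) / max ICA` over
#' meta nodes, so the namespace root always has ICM 0.
#'
#' @param dag An `ontology_dag`.
#' @param roots Character vector of sub-graph roots (after merging).
#' @param ica_tab Result of [ica_table()].
#' @return A `meta_graph`: list with `nodes`, `parents` (node -> minimal
#'   meta ancestors), `icm` (named numeric), `max_ica`.
#' @export
build_metagraph <- function(dag, roots, ica_tab) {
  anc <- ancestor_sets(dag)
  nodes <- sort(unique(c(roots, unlist(anc[roots], use.names = FALSE))))
  parents <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) {
    p <- intersect(anc[[v]], nodes)
    if (length(p) > 1L) {
      # keep only minimal ancestors: drop any that is an ancestor of another
      keep <- vapply(p, function(x) !any(x %in% unlist(anc[setdiff(p, x)],
                                                       use.names = FALSE)), TRUE)
      p <- p[keep]
    }
    parents[[v]] <- sort(p)
  }
  vals <- ica_tab$ica[nodes]
  mx <- suppressWarnings(max(vals, na.rm = TRUE))
  if (!is.finite(mx)) mx <- NA_real_
  icm <- if (is.na(mx)) stats::setNames(rep(NA_real_, length(nodes)), nodes)
         else if (mx > 0) stats::setNames(vals / mx, nodes)
         else stats::setNames(ifelse(is.na(vals), NA_real_, 0), nodes)
  structure(list(nodes = nodes, parents = parents, icm = icm,
                 max_ica = mx), class = "meta_graph")
}

#' Build the full TCSS index for one corpus and cutoff
#'
#' Convenience pipeline: transitively reduces the ontology, computes ICT,
#' selects and merges sub-graph roots at the topology cutoff, assigns
#' terms to sub-graphs, and builds the meta-graph, together with the ICA
#' table of the annotation corpus. The returned index is all that
#' [gene_pair_similarity()] and [score_gene_pairs()] need.
#'
#' @param dag An `ontology_dag` (reduced internally; pass
#'   `reduce = FALSE` if already reduced).
#' @param ann An `annotation_set` (most-specific filtering is applied
#'   unless `most_specific = FALSE`).
#' @param cutoff Topology cutoff on ICT. Published yeast-style defaults
#'   are 2.4 (CC), 3.6 (BP) and 3.2 (MF); see [default_topology_cutoff()].
#' @param merge_tolerance Relative ICT window for root merging.
#' @param reduce,most_specific Logical switches for the two
#'   pre-processing steps.
#' @param warn Passed to [build_subgraphs()].
#' @return A `tcss_index` bundling the reduced dag, annotation set, ICA
#'   table, roots, `subgraph_index` and `meta_graph`.
#' @export
tcss_index <- function(dag, ann, cutoff, merge_tolerance = 0.2,
                       reduce = TRUE, most_specific = TRUE, warn = TRUE) {
  if (reduce) dag <- transitive_reduction(dag)
  if (most_specific) ann <- reduce_to_most_specific(ann, dag)
  ica_tab <- ica_table(dag, ann)
  ict_vals <- ict_values(dag)
  roots <- select_roots(dag, cutoff, ict_vals)
  roots <- merge_similar_roots(dag, roots, ict_vals,
                               tolerance = merge_tolerance)
  idx <- build_subgraphs(dag, roots, ica_tab, warn = warn)
  meta <- build_metagraph(dag, roots, ica_tab)
  structure(list(dag = dag, ann = ann, cutoff = cutoff,
                 ict = ict_vals, roots = roots, ica_tab = ica_tab,
                 subgraphs = idx, meta = meta),
            class = "tcss_index")
}

#' Default topology cutoffs for yeast-style corpora
#'
#' @param namespace Namespace name or `"CC"`/`"BP"`/`"MF"` abbreviation.
#' @return The default ICT cutoff: 2.4 for cellular component, 3.6 for
#'   biological process, 3.2 for molecular function.
#' @export
default_topology_cutoff <- function(namespace) {
  ns <- normalize_namespace(namespace)
  c(cellular_component = 2.4, biological_process = 3.6,
    molecular_function = 3.2)[[ns]]
}

#' @export
print.tcss_index <- function(x, ...) {
  cat("tcss_index:", x$dag$namespace, "\n",
      " topology cutoff", x$cutoff, "->", length(x$roots),
      "sub-graph roots,", length(x$meta$nodes), "meta nodes\n",
      " corpus:", x$ica_tab$corpus_size, "genes\n")
  invisible(x)
}
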