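# Shared fixture builders and brute-force oracles. The oracles are
# deliberately naive (matrix closure, exhaustive enumeration) and
# independent of the package's graph code.

# Build OBO text from a child->parent edge list (and optional extras).
obo_text <- function(edges, namespace = "cellular_component",
                     obsolete = character(0), alt = list()) {
  ids <- unique(c(edges$child, edges$parent, obsolete, names(alt)))
  lines <- c("format-version: 1.2")
  for (id in sort(ids)) {
    lines <- c(lines, "[Term]", paste0("id: ", id),
               paste0("name: term ", id),
               paste0("namespace: ", namespace))
    if (id %in% obsolete) lines <- c(lines, "is_obsolete: true")
    if (id %in% names(alt)) {
      lines <- c(lines, paste0("alt_id: ", alt[[id]]))
    }
    sel <- edges$child == id
    for (k in which(sel)) {
      rel <- if (is.null(edges$rel)) "is_a" else edges$rel[[k]]
      lines <- c(lines,
                 if (rel == "is_a") paste0("is_a: ", edges$parent[[k]])
                 else paste0("relationship: ", rel, " ", edges$parent[[k]]))
    }
  }
  paste(lines, collapse = "\n")
}

edge_df <- function(child, parent, rel = NULL) {
  data.frame(child = child, parent = parent,
             rel = if (is.null(rel)) rep("is_a", length(child)) else rel,
             stringsAsFactors = FALSE)
}

# Random single-rooted DAG: node i (>= 2) draws 1-2 parents among 1..i-1.
random_dag_edges <- function(n, seed, max_parents = 2L) {
  set.seed(seed)
  child <- character(0); parent <- character(0)
  ids <- sprintf("GO:%07d", seq_len(n))
  for (i in 2:n) {
    k <- sample(seq_len(max_parents), 1L)
    ps <- sample(seq_len(i - 1L), min(k, i - 1L))
    child <- c(child, rep(ids[[i]], length(ps)))
    parent <- c(parent, ids[ps])
  }
  edge_df(child, parent)
}

# Boolean reachability closure by iterated expansion (brute force).
closure_matrix <- function(ids, edges) {
  n <- length(ids)
  m <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(edges))) {
    m[edges$child[[k]], edges$parent[[k]]] <- TRUE
  }
  repeat {
    m2 <- m | ((m %*% m) > 0)
    if (identical(m2, m)) break
    m <- m2
  }
  m
}

# Unique transitive reduction of a DAG from its closure: keep (u,v) iff
# reachable and no intermediate w with u ~> w ~> v.
reduction_edges_oracle <- function(ids, edges) {
  cl <- closure_matrix(ids, edges)
  keep <- character(0)
  for (u in ids) {
    for (v in ids) {
      if (!cl[u, v]) next
      has_mid <- any(cl[u, ] & cl[, v])
      if (!has_mid) keep <- c(keep, paste(u, v))
    }
  }
  sort(keep)
}

dag_edge_keys <- function(dag) {
  out <- character(0)
  for (id in dag$ids) {
    for (p in dag$parents[[id]]) out <- c(out, paste(id, p))
  }
  sort(out)
}

# GAF text from a gene -> terms list.
gaf_text <- function(gene_terms, aspect = "C", evidence = "IDA",
                     qualifier = "") {
  lines <- "!gaf-version: 2.1"
  for (g in names(gene_terms)) {
    for (t in gene_terms[[g]]) {
      lines <- c(lines, paste("SYN", g, toupper(g), qualifier, t,
                              "SYN:1", evidence, "", aspect, g, "",
                              "protein", "taxon:4932", "20100101", "SYN",
                              sep = "\t"))
    }
  }
  paste(lines, collapse = "\n")
}

# Naive TCSS MAX scorer: enumerates every common ancestor through the
# index's ICS/ICM tables, without calling term_pair_score()/lca().
naive_tcss_max <- function(index, a, b) {
  anc_self <- function(t) c(t, ancestors(index$dag, t))
  S <- setdiff(index$ann$gene_terms[[a]], index$dag$root)
  T_ <- setdiff(index$ann$gene_terms[[b]], index$dag$root)
  best <- -Inf
  for (s in S) {
    for (t in T_) {
      shared <- intersect(index$subgraphs$membership[[s]],
                          index$subgraphs$membership[[t]])
      scores <- numeric(0)
      for (r in shared) {
        common <- intersect(intersect(anc_self(s), anc_self(t)),
                            index$subgraphs$members[[r]])
        ica_c <- index$ica_tab$ica[common]
        common <- common[!is.na(ica_c)]
        if (!length(common)) next
        top <- common[which.max(index$ica_tab$ica[common])]
        scores <- c(scores, index$subgraphs$ics[[r]][[top]])
      }
      if (!length(scores)) {
        common <- intersect(intersect(anc_self(s), anc_self(t)),
                            index$meta$nodes)
        ica_c <- index$ica_tab$ica[common]
        common <- common[!is.na(ica_c)]
        top <- common[which.max(index$ica_tab$ica[common])]
        scores <- index$meta$icm[[top]]
      }
      best <- max(best, max(scores))
    }
  }
  best
}

# Two-branch imbalance fixture: one deep branch (chain of depth 7 with
# side leaves) and one shallow branch (single leaf below its root),
# mirroring a deep intracellular vs shallow extracellular contrast.
imbalance_fixture <- function() {
  edges <- edge_df(
    c("GO:0000002", "GO:0000003",                       # branch roots
      "GO:0000010", "GO:0000011", "GO:0000012", "GO:0000013",
      "GO:0000014", "GO:0000015",                       # deep chain
      "GO:0000020", "GO:0000021", "GO:0000022", "GO:0000023",
      "GO:0000024", "GO:0000025",                       # side leaves
      "GO:0000030"),                                    # shallow leaf
    c("GO:0000001", "GO:0000001",
      "GO:0000002", "GO:0000010", "GO:0000011", "GO:0000012",
      "GO:0000013", "GO:0000014",
      "GO:0000010", "GO:0000011", "GO:0000012", "GO:0000013",
      "GO:0000014", "GO:0000015",
      "GO:0000003"))
  dag <- parse_obo(obo_text(edges), "CC")
  gene_terms <- list(
    # pair annotated to the shallow branch's most specific term
    pA = "GO:0000030", pB = "GO:0000030",
    # genes spread over the deep branch
    d1 = "GO:0000020", d2 = "GO:0000021", d3 = "GO:0000022",
    d4 = "GO:0000023", d5 = "GO:0000024", d6 = "GO:0000025",
    d7 = "GO:0000015", d8 = "GO:0000014")
  ann <- parse_gaf(gaf_text(gene_terms), dag)
  list(dag = dag, ann = ann)
}
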