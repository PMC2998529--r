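# Two-level TCSS scoring: term-pair scores through the sub-graph / meta
# levels, combined over gene annotation sets by MAX or best-match average.

anc_or_self <- function(dag, t) c(t, ancestor_sets(dag)[[t]])

#' Lowest common ancestor by information content
#'
#' Returns the common ancestor-or-self of `s` and `t` (optionally
#' restricted to a set of terms, e.g. one sub-graph's members or the meta
#' nodes) with maximal ICA; ties are broken by term id.
#'
#' @param dag An `ontology_dag`.
#' @param s,t Term ids.
#' @param ica_vals Named numeric ICA vector (`ica_table()$ica`).
#' @param within Optional character vector restricting the candidate
#'   ancestors (a sub-graph's members or meta nodes).
#' @return A term id, or `NA_character_` when no common ancestor exists
#'   within the restriction.
#' @export
lca <- function(dag, s, t, ica_vals, within = NULL) {
  common <- intersect(anc_or_self(dag, s), anc_or_self(dag, t))
  if (!is.null(within)) common <- intersect(common, within)
  common <- common[!is.na(ica_vals[common])]
  if (!length(common)) return(NA_character_)
  v <- ica_vals[common]
  sort(common[v == max(v)])[[1L]]
}

#' Score a term pair on the TCSS two-level scheme
#'
#' If `s` and `t` share at least one sub-graph, the score is the maximal
#' ICS (over the shared sub-graphs) of their lowest common ancestor
#' within that sub-graph; otherwise the pair is scored at the meta level
#' as the ICM of their lowest common ancestor among meta nodes. A term
#' that is itself a sub-graph root counts as belonging to that root's
#' sub-graph, so meta-level scoring only applies when no shared sub-graph
#' exists.
#'
#' @param index A `tcss_index`.
#' @param s,t Term ids.
#' @return List with `score` (in \[0, 1\]), `level` (`"meta"` or the
#'   shared sub-graph's root id) and `lca`.
#' @export
term_pair_score <- function(index, s, t) {
  sg <- index$subgraphs
  if (is.null(sg$membership[[s]]) || is.null(sg$membership[[t]])) {
    stop("term outside clustering: ",
         paste(setdiff(c(s, t), names(sg$membership)), collapse = ", "))
  }
  shared <- intersect(sg$membership[[s]], sg$membership[[t]])
  shared <- setdiff(shared, sg$unannotated_subgraphs)
  if (length(shared)) {
    best <- -Inf; best_root <- NA_character_; best_lca <- NA_character_
    for (r in shared) {
      a <- lca(index$dag, s, t, index$ica_tab$ica, within = sg$members[[r]])
      if (is.na(a)) next
      val <- sg$ics[[r]][[a]]
      if (!is.na(val) && val > best) {
        best <- val; best_root <- r; best_lca <- a
      }
    }
    if (is.finite(best)) {
      return(list(score = best, level = best_root, lca = best_lca))
    }
  }
  a <- lca(index$dag, s, t, index$ica_tab$ica, within = index$meta$nodes)
  if (is.na(a)) stop("no common meta ancestor for ", s, " and ", t)
  list(score = unname(index$meta$icm[[a]]), level = "meta", lca = a)
}

# usable (non-root) annotation terms of a gene, NULL when unscorable
usable_terms <- function(index, gene) {
  terms <- index$ann$gene_terms[[gene]]
  if (is.null(terms)) return(NULL)
  terms <- setdiff(terms, index$dag$root)
  if (!length(terms)) return(NULL)
  terms
}

#' TCSS similarity between two genes
#'
#' Combines [term_pair_score()] over the genes' annotation term sets `S`
#' and `T`. `mode = "max"` takes the maximum over `S x T`; `mode = "bma"`
#' takes the best-match average: every term of each gene is matched to
#' its best-scoring partner on the other gene and the matches are
#' averaged, `(sum_i best(s_i, T) + sum_j best(t_j, S)) / (|S| + |T|)`.
#' Genes without a non-root annotation are unscorable and returned with
#' `score = NA` rather than silently dropped.
#'
#' @param index A `tcss_index`.
#' @param a,b Gene ids.
#' @param mode `"max"` or `"bma"`.
#' @return List with `gene_a`, `gene_b`, `score` (`NA` if unscorable),
#'   `mode`, `level` and the contributing `term_a`/`term_b` (MAX mode).
#' @export
gene_pair_similarity <- function(index, a, b, mode = c("max", "bma")) {
  mode <- match.arg(mode)
  S <- usable_terms(index, a)
  T_ <- usable_terms(index, b)
  res <- list(gene_a = a, gene_b = b, score = NA_real_, mode = mode,
              level = NA_character_, term_a = NA_character_,
              term_b = NA_character_)
  if (is.null(S) || is.null(T_)) return(res)
  mat <- matrix(NA_real_, length(S), length(T_), dimnames = list(S, T_))
  lev <- matrix(NA_character_, length(S), length(T_))
  for (i in seq_along(S)) {
    for (j in seq_along(T_)) {
      ts <- term_pair_score(index, S[[i]], T_[[j]])
      mat[i, j] <- ts$score
      lev[i, j] <- ts$level
    }
  }
  if (mode == "max") {
    k <- which(mat == max(mat), arr.ind = TRUE)[1L, ]
    res$score <- max(mat)
    res$level <- lev[k[[1L]], k[[2L]]]
    res$term_a <- S[[k[[1L]]]]
    res$term_b <- T_[[k[[2L]]]]
  } else {
    best_s <- apply(mat, 1L, max)
    best_t <- apply(mat, 2L, max)
    res$score <- (sum(best_s) + sum(best_t)) / (length(S) + length(T_))
    k <- which(mat == max(mat), arr.ind = TRUE)[1L, ]
    res$level <- lev[k[[1L]], k[[2L]]]
  }
  res
}

#' Score a table of gene pairs with any implemented measure
#'
#' Front end used by the command line and the evaluation harness. For
#' `method = "tcss"` a `tcss_index` is built at the topology `cutoff`
#' (namespace default when `NULL`); the baseline measures run on the same
#' most-specific-filtered corpus through [ic_context()].
#'
#' @param dag An `ontology_dag`.
#' @param ann An `annotation_set`.
#' @param pairs Data frame whose first two columns are gene ids (an
#'   optional third column `label` is carried through).
#' @param method One of `"tcss"`, `"resnik"`, `"lin"`, `"jiang"`,
#'   `"schlicker"`, `"simgic"`.
#' @param combine `"max"`, `"bma"` or `"avg"` (`avg` for baselines only;
#'   simGIC takes no combination rule).
#' @param cutoff Topology cutoff for TCSS.
#' @param most_specific Apply most-specific annotation filtering.
#' @param warn Passed through to [build_subgraphs()].
#' @return `pairs` with columns `score` (NA when unscorable) and, for
#'   TCSS, `level`.
#' @export
score_gene_pairs <- function(dag, ann, pairs,
                             method = c("tcss", "resnik", "lin", "jiang",
                                        "schlicker", "simgic"),
                             combine = c("max", "bma", "avg"),
                             cutoff = NULL, most_specific = TRUE,
                             warn = FALSE) {
  method <- match.arg(method)
  combine <- match.arg(combine)
  if (method == "simgic" && !missing(combine)) {
    stop("combination modes are not applicable to simGIC")
  }
  if (method == "tcss" && combine == "avg") {
    stop("TCSS supports combine = 'max' or 'bma'")
  }
  out <- as.data.frame(pairs)
  ga <- as.character(out[[1L]]); gb <- as.character(out[[2L]])

  if (method == "tcss") {
    if (is.null(cutoff)) cutoff <- default_topology_cutoff(dag$namespace)
    index <- tcss_index(dag, ann, cutoff, warn = warn)
    res <- mapply(function(a, b) {
      r <- gene_pair_similarity(index, a, b, mode = combine)
      c(score = r$score, level = r$level)
    }, ga, gb)
    out$score <- as.numeric(res["score", ])
    out$level <- as.character(res["level", ])
  } else {
    ctx <- ic_context(dag, ann, most_specific = most_specific)
    out$score <- mapply(function(a, b) {
      if (method == "simgic") simgic_gene(ctx, a, b)
      else baseline_gene(ctx, a, b, measure = method, mode = combine)
    }, ga, gb)
  }
  out
}
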