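# Generators for small, structurally controlled OBO/GAF/pair/expression
# fixtures: imbalanced branch depths, tunable multi-parent rate,
# annotation specificity bias, and planted co-sub-graph signal for
# labeled PPI benchmarks. Everything is deterministic under a seed.

#' Specification for a synthetic ontology/annotation fixture
#'
#' @param branches List of `list(depth =, width =)`: each branch hangs
#'   off the namespace root, reaches exactly `depth` levels below the
#'   root, and carries `width` terms per level below the branch root.
#'   Unequal depths emulate the uneven development of real GO branches
#'   (e.g. deep intracellular vs shallow extracellular sub-hierarchies).
#' @param multi_parent_p Probability that a term receives a second
#'   parent (drawn from any strictly shallower term, so the graph stays
#'   acyclic); second parents use the `part_of` relationship type.
#' @param n_genes Number of annotated genes.
#' @param specificity_bias Probability that an annotation lands on a
#'   leaf rather than an internal term.
#' @param iea_fraction Fraction of GAF rows tagged with the IEA evidence
#'   code (the rest use IDA).
#' @param terms_per_gene Integer vector to sample each gene's annotation
#'   count from, default 1:3.
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(branches = list(list(depth = 4, width = 4),
                                         list(depth = 4, width = 4),
                                         list(depth = 2, width = 3)),
                         multi_parent_p = 0.1, n_genes = 100,
                         specificity_bias = 0.7, iea_fraction = 0,
                         terms_per_gene = 1:3, seed = 1) {
  for (b in branches) {
    if (b$depth < 1L || b$width < 1L) {
      stop("each branch needs depth >= 1 and width >= 1")
    }
  }
  structure(list(branches = branches, multi_parent_p = multi_parent_p,
                 n_genes = n_genes, specificity_bias = specificity_bias,
                 iea_fraction = iea_fraction,
                 terms_per_gene = terms_per_gene, seed = seed),
            class = "fixture_spec")
}

go_id <- function(k) sprintf("GO:%07d", k)

#' Generate a synthetic OBO ontology
#'
#' Emits parseable OBO 1.2 text for a single-rooted DAG in the
#' `cellular_component` namespace. Each branch root is a child of the
#' namespace root; every deeper level attaches each term to a random
#' parent one level up (so branch depths are met exactly), and extra
#' `part_of` parents are added with probability `multi_parent_p` from
#' strictly shallower terms anywhere in the graph.
#'
#' @param spec A [fixture_spec()].
#' @return Character vector of OBO lines, with a `terms` attribute (data
#'   frame id/branch/level/leaf).
#' @export
generate_ontology <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr_seed(spec$seed, {
    id_counter <- 1L
    root <- go_id(id_counter)
    terms <- data.frame(id = root, branch = 0L, level = 0L,
                        stringsAsFactors = FALSE)
    parents <- stats::setNames(list(character(0)), root)
    reltype <- stats::setNames(list(character(0)), root)
    for (bi in seq_along(spec$branches)) {
      br <- spec$branches[[bi]]
      prev_level <- character(0)
      for (lvl in seq_len(br$depth)) {
        width <- if (lvl == 1L) 1L else br$width
        this_level <- character(0)
        for (w in seq_len(width)) {
          id_counter <- id_counter + 1L
          id <- go_id(id_counter)
          p <- if (lvl == 1L) root
               else if (w == 1L) prev_level[[1L]]  # guarantee full depth
               else prev_level[[sample.int(length(prev_level), 1L)]]
          parents[[id]] <- p
          reltype[[id]] <- "is_a"
          terms <- rbind(terms, data.frame(id = id, branch = bi,
                                           level = lvl,
                                           stringsAsFactors = FALSE))
          this_level <- c(this_level, id)
        }
        prev_level <- this_level
      }
    }
    # extra parents from strictly shallower terms keep the graph acyclic
    if (spec$multi_parent_p > 0) {
      for (k in seq_len(nrow(terms))) {
        id <- terms$id[[k]]; lvl <- terms$level[[k]]
        if (lvl < 2L || stats::runif(1) > spec$multi_parent_p) next
        shallower <- terms$id[terms$level < lvl & terms$id != root]
        shallower <- setdiff(shallower, parents[[id]])
        if (!length(shallower)) next
        p2 <- shallower[[sample.int(length(shallower), 1L)]]
        parents[[id]] <- c(parents[[id]], p2)
        reltype[[id]] <- c(reltype[[id]], "part_of")
      }
    }
    lines <- c("format-version: 1.2", "")
    for (k in seq_len(nrow(terms))) {
      id <- terms$id[[k]]
      lines <- c(lines, "[Term]",
                 paste0("id: ", id),
                 paste0("name: synthetic term ", sub("GO:", "", id)),
                 "namespace: cellular_component")
      ps <- parents[[id]]; rs <- reltype[[id]]
      for (e in seq_along(ps)) {
        lines <- c(lines,
                   if (rs[[e]] == "is_a") paste0("is_a: ", ps[[e]])
                   else paste0("relationship: ", rs[[e]], " ", ps[[e]]))
      }
      lines <- c(lines, "")
    }
    has_child <- unique(unlist(parents, use.names = FALSE))
    terms$leaf <- !(terms$id %in% has_child)
    attr(lines, "terms") <- terms
    lines
  })
}

#' Generate a synthetic GAF annotation file
#'
#' Every gene receives 1-3 terms (configurable) drawn with the
#' specificity bias (leaf vs internal term, the namespace root is never
#' drawn); a configurable fraction of rows carries the IEA evidence code
#' so that evidence filtering can be exercised.
#'
#' @param dag An `ontology_dag` parsed from [generate_ontology()] output.
#' @param spec The same [fixture_spec()].
#' @return Character vector of GAF 2.1 lines, with a `gene_terms`
#'   attribute (named list of the non-IEA-filtered gene -> term map).
#' @export
generate_annotations <- function(dag, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr_seed(spec$seed + 1L, {
    leaves <- dag$ids[vapply(dag$children[dag$ids], length, 1L) == 0L]
    internal <- setdiff(dag$ids, c(leaves, dag$root))
    if (!length(internal)) internal <- leaves
    lines <- c("!gaf-version: 2.1")
    gene_terms <- list()
    for (g in seq_len(spec$n_genes)) {
      gene <- sprintf("G%04d", g)
      k <- if (length(spec$terms_per_gene) == 1L) spec$terms_per_gene
           else sample(spec$terms_per_gene, 1L)
      terms <- character(0)
      for (j in seq_len(k)) {
        pool <- if (stats::runif(1) <= spec$specificity_bias) leaves
                else internal
        terms <- c(terms, pool[[sample.int(length(pool), 1L)]])
      }
      terms <- unique(terms)
      gene_terms[[gene]] <- sort(terms)
      for (t in terms) {
        ev <- if (stats::runif(1) < spec$iea_fraction) "IEA" else "IDA"
        lines <- c(lines, paste(
          "SYN", gene, gene, "", t, "SYN:0000001", ev, "",
          "C", paste0("synthetic gene ", g), "", "protein",
          "taxon:4932", "20100101", "SYN", sep = "\t"))
      }
    }
    attr(lines, "gene_terms") <- gene_terms
    lines
  })
}

#' Generate synthetic expression matrices
#'
#' Independent standard-normal profiles per experiment; a convenience
#' companion for exercising [expression_correlation()].
#'
#' @param genes Character vector of gene ids.
#' @param n_experiments Number of experiments (matrices).
#' @param n_conditions Profile length per experiment.
#' @param seed Integer seed.
#' @return Named list of matrices (genes x conditions).
#' @export
generate_expression <- function(genes, n_experiments = 5,
                                n_conditions = 20, seed = 1) {
  withr_seed(seed, {
    out <- lapply(seq_len(n_experiments), function(i) {
      m <- matrix(stats::rnorm(length(genes) * n_conditions),
                  nrow = length(genes),
                  dimnames = list(genes, NULL))
      m
    })
    names(out) <- paste0("exp", seq_len(n_experiments))
    out
  })
}

#' Generate a labeled PPI benchmark with planted co-clustering signal
#'
#' Builds a TCSS clustering at the reference `cutoff` and samples gene
#' pairs so that positives share at least one sub-graph with probability
#' `co_rate_pos` and negatives with probability `co_rate_neg`. Pairs are
#' unique, non-self, and positives and negatives are disjoint. Realized
#' co-clustering rates are reported in the attributes; the construction
#' cutoff is what a topology-cutoff grid search should recover.
#'
#' @param dag,ann Ontology and annotations (fixture scale).
#' @param n_pos,n_neg Pair counts (equal by default in published
#'   benchmark designs).
#' @param co_rate_pos,co_rate_neg Target co-sub-graph probabilities;
#'   `co_rate_pos > co_rate_neg` plants the signal.
#' @param cutoff Reference topology cutoff defining "share a sub-graph".
#' @param seed Integer seed.
#' @return Data frame `gene_a`, `gene_b`, `label` (logical), with
#'   attributes `co_rate_pos_realized`, `co_rate_neg_realized`,
#'   `cutoff`, `seed`.
#' @export
generate_ppi_benchmark <- function(dag, ann, n_pos, n_neg,
                                   co_rate_pos = 0.9, co_rate_neg = 0.2,
                                   cutoff, seed = 1) {
  if (co_rate_pos <= co_rate_neg) {
    stop("co_rate_pos must exceed co_rate_neg to plant a signal")
  }
  index <- tcss_index(dag, ann, cutoff, warn = FALSE)
  genes <- scorable_genes(index$dag, index$ann)
  memb <- lapply(genes, function(g) {
    terms <- usable_terms(index, g)
    sort(unique(unlist(index$subgraphs$membership[terms],
                       use.names = FALSE)))
  })
  names(memb) <- genes
  by_root <- split(
    rep(genes, lengths(memb)), unlist(memb, use.names = FALSE))
  by_root <- by_root[lengths(by_root) >= 2L]
  if (!length(by_root)) {
    stop("no sub-graph holds two scorable genes; cannot plant ",
         "co-clustered pairs (", length(genes), " genes, ",
         length(index$roots), " sub-graph roots)")
  }
  co_clustered <- function(a, b) length(intersect(memb[[a]], memb[[b]])) > 0L

  withr_seed(seed, {
    seen <- character(0)
    draw_pair <- function(want_shared) {
      for (try in seq_len(2000L)) {
        if (want_shared) {
          grp <- by_root[[sample.int(length(by_root), 1L)]]
          gs <- sample(grp, 2L)
        } else {
          gs <- sample(genes, 2L)
          if (co_clustered(gs[[1L]], gs[[2L]])) next
        }
        key <- pair_key(gs[[1L]], gs[[2L]])
        if (key %in% seen) next
        seen <<- c(seen, key)
        return(sort(gs))
      }
      stop("could not sample a ", if (want_shared) "co-clustered"
           else "non-co-clustered",
           " pair; annotation structure too restrictive")
    }
    sample_set <- function(n, co_rate) {
      a <- character(n); b <- character(n); shared <- logical(n)
      for (k in seq_len(n)) {
        want <- stats::runif(1) <= co_rate
        gs <- draw_pair(want)
        a[[k]] <- gs[[1L]]; b[[k]] <- gs[[2L]]
        shared[[k]] <- co_clustered(gs[[1L]], gs[[2L]])
      }
      list(a = a, b = b, shared = shared)
    }
    pos <- sample_set(n_pos, co_rate_pos)
    neg <- sample_set(n_neg, co_rate_neg)
    out <- data.frame(
      gene_a = c(pos$a, neg$a),
      gene_b = c(pos$b, neg$b),
      label = rep(c(TRUE, FALSE), c(n_pos, n_neg)),
      stringsAsFactors = FALSE)
    attr(out, "co_rate_pos_realized") <- mean(pos$shared)
    attr(out, "co_rate_neg_realized") <- mean(neg$shared)
    attr(out, "cutoff") <- cutoff
    attr(out, "seed") <- seed
    out
  })
}
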