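# Annotation corpus: gene -> set of GO terms of one namespace, after
# evidence filtering, plus the derived annotation counts and annotation
# information content (ICA).

new_annotation_set <- function(namespace, gene_terms, symbols,
                               excluded_evidence, report) {
  structure(list(
    namespace = namespace,
    gene_terms = gene_terms,
    symbols = symbols,
    excluded_evidence = excluded_evidence,
    report = report
  ), class = "annotation_set")
}

#' Parse a GAF 2.x annotation file
#'
#' Reads tab-separated GO annotation (GAF) rows and builds the gene ->
#' term-set corpus for the namespace of `dag`. Rows are kept when their
#' aspect column matches the namespace, their evidence code (column 7) is
#' not excluded, and their qualifier (column 4) does not contain `NOT`.
#' GO ids are resolved through `alt_id` aliases; rows with ids absent from
#' the ontology, or with fewer than 15 columns, are skipped and counted in
#' the load report.
#'
#' @param file Path to a GAF file, or a character scalar of GAF text.
#' @param dag The companion `ontology_dag`; supplies the namespace and the
#'   alt_id resolution table.
#' @param excluded_evidence Character vector of evidence codes to drop,
#'   e.g. `"IEA"` for manually-reviewed-only corpora.
#' @return An `annotation_set` with fields `gene_terms` (named list, gene
#'   id -> character vector of term ids), `symbols` (gene id -> symbol),
#'   and `report` (row accounting from the load).
#' @export
parse_gaf <- function(file, dag, excluded_evidence = character()) {
  aspect_code <- c(cellular_component = "C", biological_process = "P",
                   molecular_function = "F")[[dag$namespace]]
  lines <- read_input_lines(file)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]

  report <- c(n_rows = length(lines), n_kept = 0L, n_bad_columns = 0L,
              n_unknown_term = 0L, n_excluded_evidence = 0L,
              n_not_qualifier = 0L, n_other_namespace = 0L)
  gene_terms <- list()
  symbols <- character(0)

  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    for (f in fields) {
      if (length(f) < 15L) {
        report[["n_bad_columns"]] <- report[["n_bad_columns"]] + 1L
        next
      }
      if (f[[9L]] != aspect_code) {
        report[["n_other_namespace"]] <- report[["n_other_namespace"]] + 1L
        next
      }
      if (grepl("(^|\\|)NOT($|\\|)", f[[4L]])) {
        report[["n_not_qualifier"]] <- report[["n_not_qualifier"]] + 1L
        next
      }
      if (f[[7L]] %in% excluded_evidence) {
        report[["n_excluded_evidence"]] <- report[["n_excluded_evidence"]] + 1L
        next
      }
      term <- resolve_term(dag, f[[5L]], error = FALSE)
      if (is.na(term)) {
        report[["n_unknown_term"]] <- report[["n_unknown_term"]] + 1L
        next
      }
      gene <- f[[2L]]
      gene_terms[[gene]] <- c(gene_terms[[gene]], term)
      symbols[[gene]] <- f[[3L]]
      report[["n_kept"]] <- report[["n_kept"]] + 1L
    }
  }
  skipped <- report[["n_bad_columns"]] + report[["n_unknown_term"]]
  if (skipped > 0L) {
    warning("skipped ", skipped, " GAF row(s): ",
            report[["n_bad_columns"]], " with wrong column count, ",
            report[["n_unknown_term"]], " with unknown GO ids")
  }
  gene_terms <- lapply(gene_terms, function(x) sort(unique(x)))
  new_annotation_set(dag$namespace, gene_terms, symbols,
                     excluded_evidence, report)
}

#' Keep only each gene's most specific annotations
#'
#' For every gene, drops any annotated term that is an ancestor of another
#' term annotated to the same gene, leaving a per-gene antichain. A term
#' aggregates its descendants, so annotating both a term and its ancestor
#' is redundant for scoring.
#'
#' @param ann An `annotation_set`.
#' @param dag The companion `ontology_dag`.
#' @return An `annotation_set` with reduced term sets.
#' @export
reduce_to_most_specific <- function(ann, dag) {
  anc <- ancestor_sets(dag)
  ann$gene_terms <- lapply(ann$gene_terms, function(terms) {
    if (length(terms) < 2L) return(terms)
    covered <- unique(unlist(anc[terms], use.names = FALSE))
    terms[!(terms %in% covered)]
  })
  ann
}

# Distinct genes annotated to each term or any of its descendants.
# Bottom-up union over the child lists (reverse topological order), so a
# gene annotated to two descendants of t is counted once for t.
annotation_gene_sets <- function(dag, ann) {
  direct <- rep(list(character(0)), length(dag$ids))
  names(direct) <- dag$ids
  for (g in names(ann$gene_terms)) {
    for (t in ann$gene_terms[[g]]) direct[[t]] <- c(direct[[t]], g)
  }
  sets <- direct
  for (id in rev(dag$topo)) {
    ch <- dag$children[[id]]
    if (length(ch)) {
      sets[[id]] <- unique(c(direct[[id]], unlist(sets[ch], use.names = FALSE)))
    }
  }
  sets
}

#' Annotation counts and annotation information content (ICA)
#'
#' `annotation_counts()` returns, for every term, the number of distinct
#' genes annotated to the term or to any of its descendants.
#' `ica_table()` converts the counts to information content,
#' `ICA(t) = -ln(annot(t) / annot(root))`, where `annot(root)` is the
#' number of distinct annotated genes in the corpus; terms with no
#' annotated gene get `NA` (they cannot participate in scoring).
#'
#' @param dag An `ontology_dag`.
#' @param ann An `annotation_set`.
#' @return `annotation_counts()`: named integer vector over all terms.
#'   `ica_table()`: list with `counts`, `ica` (named numeric), and
#'   `corpus_size`.
#' @export
annotation_counts <- function(dag, ann) {
  sets <- annotation_gene_sets(dag, ann)
  counts <- vapply(sets, length, 1L)
  names(counts) <- dag$ids
  counts
}

#' @rdname annotation_counts
#' @export
ica_table <- function(dag, ann) {
  counts <- annotation_counts(dag, ann)
  corpus <- counts[[dag$root]]
  if (corpus == 0L) stop("annotation corpus is empty")
  ica <- ifelse(counts > 0L, -log(counts / corpus), NA_real_)
  names(ica) <- dag$ids
  list(counts = counts, ica = ica, corpus_size = corpus, root = dag$root)
}

#' @rdname annotation_counts
#' @param t A single term id.
#' @export
annotation_count <- function(dag, ann, t) {
  t <- resolve_term(dag, t)
  annotation_counts(dag, ann)[[t]]
}

#' @rdname annotation_counts
#' @export
ica <- function(dag, ann, t) {
  t <- resolve_term(dag, t)
  tab <- ica_table(dag, ann)
  if (tab$counts[[t]] == 0L) {
    stop("term ", t, " has no annotated genes; ICA undefined")
  }
  tab$ica[[t]]
}

# Genes usable for pair scoring: at least one non-root term.
scorable_genes <- function(dag, ann) {
  usable <- vapply(ann$gene_terms, function(terms) {
    any(terms != dag$root)
  }, TRUE)
  names(ann$gene_terms)[usable]
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", x$namespace, "\n ",
      length(x$gene_terms), "genes,",
      sum(vapply(x$gene_terms, length, 1L)), "annotations",
      if (length(x$excluded_evidence))
        paste0(" (excluding ", paste(x$excluded_evidence, collapse = ","), ")"),
      "\n")
  invisible(x)
}
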