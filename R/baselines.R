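# Classical information-content similarity measures on the same ICA
# corpus: Resnik (MAX/AVG/BMA), Lin, Jiang & Conrath, Schlicker simRel,
# and simGIC. These are the comparison baselines for TCSS.

#' Information-content context for the baseline measures
#'
#' Bundles the ontology, the ICA table, the ontology-wide maximum ICA
#' (used to normalize Resnik scores to \[0, 1\]) and the annotation
#' probability `p(t) = annot(t) / annot(root)`.
#'
#' @param dag An `ontology_dag`.
#' @param ann An `annotation_set`.
#' @param most_specific Apply most-specific annotation filtering first
#'   (the package default corpus treatment).
#' @return An `ic_context` list.
#' @export
ic_context <- function(dag, ann, most_specific = TRUE) {
  if (most_specific) ann <- reduce_to_most_specific(ann, dag)
  tab <- ica_table(dag, ann)
  max_ica <- suppressWarnings(max(tab$ica, na.rm = TRUE))
  if (!is.finite(max_ica) || max_ica <= 0) {
    stop("corpus has no informative term (max ICA <= 0)")
  }
  structure(list(dag = dag, ann = ann, ica_tab = tab,
                 max_ica = max_ica,
                 p = tab$counts / tab$corpus_size),
            class = "ic_context")
}

# maximum-ICA common ancestor (ancestor-or-self), NA if none annotated
mica <- function(ctx, s, t) lca(ctx$dag, s, t, ctx$ica_tab$ica)

#' Term-level baseline similarities
#'
#' All four measures pick the common ancestor with maximal ICA (the
#' "lowest" common ancestor in information terms) and are bounded in
#' \[0, 1\]:
#' \itemize{
#'   \item Resnik: `ICA(lca) / max ICA` (normalized by the ontology-wide
#'     maximum so scores are comparable across corpora);
#'   \item Lin: `2 ICA(lca) / (ICA(s) + ICA(t))` (0 when both terms are
#'     the root);
#'   \item Jiang & Conrath: similarity `1 / (1 + d)` of the distance
#'     `d = ICA(s) + ICA(t) - 2 ICA(lca)`;
#'   \item Schlicker simRel: Lin weighted by `1 - p(lca)`.
#' }
#'
#' @param ctx An `ic_context`.
#' @param s,t Term ids (annotated; a term with zero annotation count is
#'   unscorable and yields `NA`).
#' @return A similarity in \[0, 1\], or `NA`.
#' @export
resnik_term <- function(ctx, s, t) {
  a <- mica(ctx, s, t)
  if (is.na(a)) return(NA_real_)
  unname(ctx$ica_tab$ica[[a]] / ctx$max_ica)
}

#' @rdname resnik_term
#' @export
lin_term <- function(ctx, s, t) {
  a <- mica(ctx, s, t)
  ics <- ctx$ica_tab$ica[[s]]; ict_ <- ctx$ica_tab$ica[[t]]
  if (is.na(a) || is.na(ics) || is.na(ict_)) return(NA_real_)
  denom <- ics + ict_
  if (denom == 0) return(0)
  unname(2 * ctx$ica_tab$ica[[a]] / denom)
}

#' @rdname resnik_term
#' @export
jiang_term <- function(ctx, s, t) {
  a <- mica(ctx, s, t)
  ics <- ctx$ica_tab$ica[[s]]; ict_ <- ctx$ica_tab$ica[[t]]
  if (is.na(a) || is.na(ics) || is.na(ict_)) return(NA_real_)
  d <- ics + ict_ - 2 * ctx$ica_tab$ica[[a]]
  unname(1 / (1 + d))
}

#' @rdname resnik_term
#' @export
schlicker_term <- function(ctx, s, t) {
  a <- mica(ctx, s, t)
  l <- lin_term(ctx, s, t)
  if (is.na(a) || is.na(l)) return(NA_real_)
  unname(l * (1 - ctx$p[[a]]))
}

baseline_term_fn <- function(measure) {
  switch(measure,
         resnik = resnik_term, lin = lin_term,
         jiang = jiang_term, schlicker = schlicker_term,
         stop("unknown measure '", measure, "'"))
}

#' Gene-level baseline similarity with MAX / AVG / BMA combination
#'
#' Applies a term-level measure over the cross product of the two genes'
#' (non-root) annotation term sets and combines by the maximum, the
#' all-pairs mean, or the best-match average. Genes without a non-root
#' annotation are unscorable (`NA`).
#'
#' @param ctx An `ic_context`.
#' @param a,b Gene ids.
#' @param measure `"resnik"`, `"lin"`, `"jiang"` or `"schlicker"`.
#' @param mode `"max"`, `"avg"` or `"bma"`.
#' @return A similarity in \[0, 1\], or `NA` when unscorable.
#' @export
baseline_gene <- function(ctx, a, b,
                          measure = c("resnik", "lin", "jiang", "schlicker"),
                          mode = c("max", "avg", "bma")) {
  measure <- match.arg(measure)
  mode <- match.arg(mode)
  fn <- baseline_term_fn(measure)
  S <- baseline_terms(ctx, a)
  T_ <- baseline_terms(ctx, b)
  if (is.null(S) || is.null(T_)) return(NA_real_)
  mat <- outer(S, T_, Vectorize(function(x, y) fn(ctx, x, y)))
  if (anyNA(mat)) return(NA_real_)
  switch(mode,
         max = max(mat),
         avg = mean(mat),
         bma = (sum(apply(mat, 1L, max)) + sum(apply(mat, 2L, max))) /
               (length(S) + length(T_)))
}

#' @rdname baseline_gene
#' @export
resnik_gene <- function(ctx, a, b, mode = c("max", "avg", "bma")) {
  baseline_gene(ctx, a, b, measure = "resnik", mode = match.arg(mode))
}

baseline_terms <- function(ctx, gene) {
  terms <- ctx$ann$gene_terms[[gene]]
  if (is.null(terms)) return(NULL)
  terms <- setdiff(terms, ctx$dag$root)
  if (!length(terms)) return(NULL)
  terms
}

#' simGIC: graph information content similarity
#'
#' Jaccard similarity over the IC-weighted, ancestor-closed annotation
#' sets of the two genes:
#' `sum ICA over the closures' intersection / sum ICA over their union`.
#' No MAX/AVG/BMA variant applies; the measure already aggregates over
#' the whole annotation sets.
#'
#' @param ctx An `ic_context`.
#' @param a,b Gene ids.
#' @return A similarity in \[0, 1\], `NA` when either gene is
#'   unscorable, and 0 when the union carries no information content.
#' @export
simgic_gene <- function(ctx, a, b) {
  S <- baseline_terms(ctx, a)
  T_ <- baseline_terms(ctx, b)
  if (is.null(S) || is.null(T_)) return(NA_real_)
  close_up <- function(terms) {
    unique(c(terms, unlist(ancestor_sets(ctx$dag)[terms], use.names = FALSE)))
  }
  A <- close_up(S); B <- close_up(T_)
  w <- function(terms) {
    v <- ctx$ica_tab$ica[terms]
    sum(v[!is.na(v)])
  }
  denom <- w(union(A, B))
  if (denom == 0) return(0)
  w(intersect(A, B)) / denom
}
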