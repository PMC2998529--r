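# The shipped 14-node worked fixture: two informative sub-graphs of five
# terms each plus four meta-level terms, annotated with eight genes. Its
# ICT/ICA/ICS/ICM values and the full pair-score table were computed once
# with an independent calculation and frozen under inst/extdata, so the
# scoring path can be checked end to end against hand-verifiable numbers.

#' Load the shipped worked fixture
#'
#' @param cutoff Topology cutoff to build the index at; 1.2 (the
#'   fixture's reference value) puts `GO:0000005` and `GO:0000006` at the
#'   sub-graph roots with four meta-level terms above them.
#' @return List with `dag`, `ann`, `index` (a `tcss_index`) and the
#'   paths of the fixture files.
#' @export
worked_fixture <- function(cutoff = 1.2) {
  obo <- system.file("extdata", "worked_fixture.obo", package = "tcss",
                     mustWork = TRUE)
  gaf <- system.file("extdata", "worked_fixture.gaf", package = "tcss",
                     mustWork = TRUE)
  dag <- parse_obo(obo, "cellular_component")
  ann <- parse_gaf(gaf, dag)
  index <- tcss_index(dag, ann, cutoff)
  list(dag = dag, ann = ann, index = index, obo = obo, gaf = gaf)
}

#' Golden score table of the worked fixture
#'
#' Frozen TCSS MAX/BMA scores for all 28 gene pairs of the worked
#' fixture, computed independently of the package's scoring path.
#'
#' @return Data frame `gene_a`, `gene_b`, `max`, `bma`.
#' @export
worked_fixture_scores <- function() {
  path <- system.file("extdata", "worked_fixture_scores.tsv",
                      package = "tcss", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
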