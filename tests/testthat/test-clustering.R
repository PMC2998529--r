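# 100-term ontology with two 9-descendant branches used for the ICT
# closed forms: root, c1 and c2 each with 9 descendants, 79 spare leaves.
hundred_term_dag <- function() {
  child <- c("GO:0000002", sprintf("GO:%07d", 3:11),
             "GO:0000012", sprintf("GO:%07d", 13:21),
             sprintf("GO:%07d", 22:100))
  parent <- c("GO:0000001", rep("GO:0000002", 9),
              "GO:0000001", rep("GO:0000012", 9),
              rep("GO:0000001", 79))
  parse_obo(obo_text(edge_df(child, parent)), "CC")
}

test_that("ICT closed forms: root 0, leaf ln|O|, 9-descendant term", {
  dag <- hundred_term_dag()
  expect_length(dag$ids, 100L)
  expect_equal(ict(dag, "GO:0000001"), 0)
  expect_equal(ict(dag, "GO:0000100"), log(100))
  expect_equal(ict(dag, "GO:0000002"), -log(10 / 100), tolerance = 1e-12)
})

test_that("ICT is monotone along every edge", {
  dag <- worked_fixture()$dag
  v <- ict_values(dag)
  for (id in dag$ids) {
    for (p in dag$parents[[id]]) expect_gte(v[[id]], v[[p]])
  }
})

test_that("root selection honors the cutoff and flags degenerate cases", {
  dag <- hundred_term_dag()
  expect_setequal(select_roots(dag, 2.4),
                  c("GO:0000001", "GO:0000002", "GO:0000012"))
  expect_equal(select_roots(dag, 1.0), "GO:0000001")
  expect_warning(r <- select_roots(dag, log(100)), "degenerate")
  expect_length(r, 100L)
  expect_error(select_roots(dag, -1), "positive")
})

test_that("nested roots within 20% ICT merge, in ascending-ICT order", {
  chain <- parse_obo(obo_text(edge_df(c("GO:0000002", "GO:0000003"),
                                      c("GO:0000001", "GO:0000002"))),
                     "CC")
  ivals <- c("GO:0000001" = 2.0, "GO:0000002" = 2.3, "GO:0000003" = 2.6)
  roots <- c("GO:0000001", "GO:0000002", "GO:0000003")
  # descendant at 2.3 within 1.2 x 2.0 merges; 2.6 survives vs the top
  expect_equal(merge_similar_roots(chain, roots, ivals),
               c("GO:0000001", "GO:0000003"))
  # outside the window nothing merges
  ivals2 <- c("GO:0000001" = 1.0, "GO:0000002" = 2.0, "GO:0000003" = 5.0)
  expect_equal(merge_similar_roots(chain, roots, ivals2), roots)
})

test_that("terms join the sub-graph of their most specific root ancestor", {
  wf <- worked_fixture()
  sg <- wf$index$subgraphs
  expect_setequal(wf$index$roots,
                  c("GO:0000001", "GO:0000002", "GO:0000003",
                    "GO:0000004", "GO:0000005", "GO:0000006"))
  expect_equal(sg$members[["GO:0000005"]],
               c("GO:0000005", sprintf("GO:%07d", 7:10)))
  expect_equal(sg$members[["GO:0000006"]],
               c("GO:0000006", sprintf("GO:%07d", 11:14)))
  # each root belongs to its own sub-graph
  for (r in wf$index$roots) expect_true(r %in% sg$members[[r]])
  # t24 has two parents inside one sub-graph: present exactly once
  expect_equal(sg$membership[["GO:0000014"]], "GO:0000006")
  # membership plus meta nodes covers every term
  covered <- union(names(sg$membership)[lengths(sg$membership) > 0],
                   wf$index$meta$nodes)
  expect_setequal(covered, wf$dag$ids)
})

test_that("a term with disjunctive paths into tied roots is duplicated", {
  # root R; A and B have equal descendant counts (tied ICT); X descends
  # from both, so X and its children belong to both sub-graphs
  edges <- edge_df(
    c("GO:0000002", "GO:0000003", "GO:0000004", "GO:0000004",
      "GO:0000005", "GO:0000006", "GO:0000007", "GO:0000008",
      "GO:0000009", "GO:0000010", "GO:0000011", "GO:0000012"),
    c("GO:0000001", "GO:0000001", "GO:0000002", "GO:0000003",
      "GO:0000004", "GO:0000004", "GO:0000002", "GO:0000002",
      "GO:0000003", "GO:0000003", "GO:0000001", "GO:0000001"))
  dag <- parse_obo(obo_text(edges), "CC")
  expect_length(dag$ids, 12L)
  ann <- parse_gaf(gaf_text(list(g1 = "GO:0000005", g2 = "GO:0000006",
                                 g3 = "GO:0000007", g4 = "GO:0000009")),
                   dag)
  idx <- tcss_index(dag, ann, cutoff = 1.0, warn = FALSE)
  expect_setequal(idx$roots,
                  c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_setequal(idx$subgraphs$membership[["GO:0000004"]],
                  c("GO:0000002", "GO:0000003"))
  expect_setequal(idx$subgraphs$membership[["GO:0000005"]],
                  c("GO:0000002", "GO:0000003"))
  # terms on a single path stay in one sub-graph
  expect_equal(idx$subgraphs$membership[["GO:0000007"]], "GO:0000002")
})

test_that("meta-graph nodes, edges and ICM behave", {
  wf <- worked_fixture()
  meta <- wf$index$meta
  expect_setequal(meta$nodes, wf$index$roots)
  expect_equal(unname(meta$icm[["GO:0000001"]]), 0)
  expect_true(all(meta$icm >= 0 & meta$icm <= 1, na.rm = TRUE))
  # meta edges follow original reachability, transitively reduced
  expect_equal(meta$parents[["GO:0000006"]], "GO:0000004")
  expect_equal(meta$parents[["GO:0000004"]], "GO:0000003")
  expect_length(meta$parents[["GO:0000001"]], 0L)

  # single root (tiny cutoff): one meta node with ICM 0
  idx0 <- tcss_index(wf$dag, wf$ann, cutoff = 1e-6, warn = FALSE)
  expect_equal(idx0$meta$nodes, "GO:0000001")
  expect_equal(unname(idx0$meta$icm), 0)

  # two sibling roots under the namespace root: 3 nodes, 2 edges
  edges <- edge_df(c("GO:0000002", "GO:0000003", "GO:0000004",
                     "GO:0000005", "GO:0000006", "GO:0000007"),
                   c("GO:0000001", "GO:0000001", "GO:0000002",
                     "GO:0000002", "GO:0000003", "GO:0000003"))
  dag <- parse_obo(obo_text(edges), "CC")
  ann <- parse_gaf(gaf_text(list(g1 = "GO:0000004", g2 = "GO:0000006")),
                   dag)
  tab <- ica_table(dag, reduce_to_most_specific(ann, dag))
  meta2 <- build_metagraph(dag, c("GO:0000002", "GO:0000003"), tab)
  expect_length(meta2$nodes, 3L)
  expect_equal(meta2$parents[["GO:0000002"]], "GO:0000001")
  expect_equal(meta2$parents[["GO:0000003"]], "GO:0000001")
})

test_that("ICS tables are normalized within each sub-graph", {
  wf <- worked_fixture()
  sg <- wf$index$subgraphs
  for (r in setdiff(names(sg$ics), sg$unannotated_subgraphs)) {
    vals <- sg$ics[[r]]
    expect_true(all(vals >= 0 & vals <= 1, na.rm = TRUE))
    expect_equal(max(vals, na.rm = TRUE), 1)
  }
})

test_that("sub-graph roots are stable across the immediate cutoff range", {
  wf <- worked_fixture()
  base <- tcss_index(wf$dag, wf$ann, cutoff = 1.2, warn = FALSE)$roots
  for (ct in c(1.1, 1.15, 1.25, 1.3)) {
    expect_equal(tcss_index(wf$dag, wf$ann, cutoff = ct,
                            warn = FALSE)$roots, base)
  }
})
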