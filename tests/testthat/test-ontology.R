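test_that("parse_obo builds the requested namespace graph", {
  txt <- obo_text(edge_df(c("GO:0000002", "GO:0000003"),
                          c("GO:0000001", "GO:0000001"),
                          rel = c("is_a", "part_of")))
  dag <- parse_obo(txt, "cellular_component")
  expect_s3_class(dag, "ontology_dag")
  expect_length(dag$ids, 3L)
  expect_equal(dag$root, "GO:0000001")
  expect_equal(sort(dag$children[["GO:0000001"]]),
               c("GO:0000002", "GO:0000003"))
  expect_equal(dag$reltypes[["GO:0000003"]], "part_of")
})

test_that("obsolete terms are excluded and alt_ids resolve", {
  txt <- obo_text(edge_df(c("GO:0000002", "GO:0000003"),
                          c("GO:0000001", "GO:0000001")),
                  obsolete = "GO:0000009",
                  alt = list("GO:0000002" = "GO:0000099"))
  dag <- parse_obo(txt, "CC")
  expect_length(dag$ids, 3L)
  expect_false("GO:0000009" %in% dag$ids)
  expect_equal(resolve_term(dag, "GO:0000099"), "GO:0000002")
  expect_error(resolve_term(dag, "GO:1111111"), "unknown term")
})

test_that("a term can carry both is_a and part_of parents", {
  txt <- obo_text(edge_df(c("GO:0000002", "GO:0000003", "GO:0000004",
                            "GO:0000004"),
                          c("GO:0000001", "GO:0000001", "GO:0000002",
                            "GO:0000003"),
                          rel = c("is_a", "is_a", "is_a", "part_of")))
  dag <- parse_obo(txt, "CC")
  expect_length(dag$parents[["GO:0000004"]], 2L)
  expect_setequal(dag$reltypes[["GO:0000004"]], c("is_a", "part_of"))
})

test_that("relationship restriction and cross-namespace dropping work", {
  lines <- c("format-version: 1.2",
             "[Term]", "id: GO:0000001", "name: r",
             "namespace: cellular_component",
             "[Term]", "id: GO:0000002", "name: a",
             "namespace: cellular_component", "is_a: GO:0000001",
             "relationship: part_of GO:0000001",
             "[Term]", "id: GO:0000003", "name: bp term",
             "namespace: biological_process")
  dag <- parse_obo(paste(lines, collapse = "\n"), "CC",
                   relations = "is_a")
  expect_equal(dag$reltypes[["GO:0000002"]], "is_a")
  expect_false("GO:0000003" %in% dag$ids)
})

test_that("malformed stanzas and dangling parents are load errors", {
  bad <- c("format-version: 1.2", "[Term]", "id: GO:0000001",
           "name: r", "namespace: cellular_component",
           "[Term]", "id: GO:0000002", "name: x",
           "namespace: cellular_component", "this line has no tag")
  expect_error(parse_obo(paste(bad, collapse = "\n"), "CC"),
               "line 10")
  dangling <- obo_text(edge_df("GO:0000002", "GO:0000001"))
  dangling <- sub("is_a: GO:0000001", "is_a: GO:0009999", dangling)
  expect_error(parse_obo(dangling, "CC"), "GO:0009999")
})

test_that("cycles are rejected at load", {
  lines <- c("format-version: 1.2",
             "[Term]", "id: GO:0000001", "name: r",
             "namespace: cellular_component",
             "[Term]", "id: GO:0000002", "name: a",
             "namespace: cellular_component",
             "is_a: GO:0000001", "is_a: GO:0000003",
             "[Term]", "id: GO:0000003", "name: b",
             "namespace: cellular_component", "is_a: GO:0000002")
  expect_error(parse_obo(paste(lines, collapse = "\n"), "CC"), "cycle")
})

test_that("ancestors and descendants match a brute-force closure oracle", {
  expect_length(ancestors(worked_fixture()$dag, "GO:0000001"), 0L)
  chain <- parse_obo(obo_text(edge_df(c("GO:0000002", "GO:0000003"),
                                      c("GO:0000001", "GO:0000002"))),
                     "CC")
  expect_setequal(ancestors(chain, "GO:0000003"),
                  c("GO:0000001", "GO:0000002"))

  for (seed in 1:5) {
    n <- 10L + 2L * seed
    edges <- random_dag_edges(n, seed = seed)
    dag <- parse_obo(obo_text(edges), "CC")
    cl <- closure_matrix(dag$ids, edges)
    for (t in dag$ids) {
      expect_setequal(ancestors(dag, t), dag$ids[cl[t, ]])
      expect_setequal(descendants(dag, t), dag$ids[cl[, t]])
    }
  }
})

test_that("transitive reduction removes shortcut edges and is idempotent", {
  # a -> b -> c plus the shortcut a -> c (child->parent orientation:
  # c is_a b is_a a, and c is_a a directly)
  edges <- edge_df(c("GO:0000002", "GO:0000003", "GO:0000003"),
                   c("GO:0000001", "GO:0000002", "GO:0000001"))
  dag <- parse_obo(obo_text(edges), "CC")
  red <- transitive_reduction(dag)
  expect_equal(red$parents[["GO:0000003"]], "GO:0000002")
  expect_equal(n_edges(red), 2L)

  red2 <- transitive_reduction(red)
  expect_equal(dag_edge_keys(red2), dag_edge_keys(red))

  chain <- parse_obo(obo_text(edge_df(c("GO:0000002", "GO:0000003"),
                                      c("GO:0000001", "GO:0000002"))),
                     "CC")
  expect_equal(dag_edge_keys(transitive_reduction(chain)),
               dag_edge_keys(chain))
})

test_that("reduction preserves closure and is edge-minimal on random DAGs", {
  for (seed in 1:10) {
    n <- sample(10:30, 1L)
    edges <- random_dag_edges(n, seed = 100 + seed, max_parents = 3L)
    dag <- parse_obo(obo_text(edges), "CC")
    red <- transitive_reduction(dag)
    red_edges <- do.call(rbind, lapply(red$ids, function(id) {
      ps <- red$parents[[id]]
      if (!length(ps)) return(NULL)
      edge_df(rep(id, length(ps)), ps)
    }))
    expect_identical(closure_matrix(dag$ids, red_edges),
                     closure_matrix(dag$ids, edges))
    expect_equal(dag_edge_keys(red),
                 reduction_edges_oracle(dag$ids, edges))
  }
})

test_that("serializing and re-parsing yields an isomorphic DAG", {
  wf <- worked_fixture()
  txt <- paste(write_obo(wf$dag), collapse = "\n")
  dag2 <- parse_obo(txt, "CC")
  expect_setequal(dag2$ids, wf$dag$ids)
  expect_equal(dag_edge_keys(dag2), dag_edge_keys(wf$dag))
  expect_equal(dag2$alt_ids, wf$dag$alt_ids)
})
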