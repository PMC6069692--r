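test_that("inversion swaps endpoints, maps types, and is an involution", {
  g <- relation_graph(c("a", "a", "a"), c("b", "b", "b"),
                      c("BEFORE", "AFTER", "OVERLAP"))
  inv <- invert_relations(g)
  expect_equal(graph_key(inv),
               sort(c("b|a|AFTER", "b|a|BEFORE", "b|a|OVERLAP")))
  expect_equal(graph_key(invert_relations(inv)), graph_key(g))
})

test_that("only the four licensed compositions infer a relation", {
  expect_equal(compose_types("BEFORE", "BEFORE"), "BEFORE")
  expect_equal(compose_types("BEFORE", "OVERLAP"), "BEFORE")
  expect_equal(compose_types("OVERLAP", "BEFORE"), "BEFORE")
  expect_equal(compose_types("OVERLAP", "OVERLAP"), "OVERLAP")
  for (r1 in c("BEFORE", "AFTER", "OVERLAP")) {
    for (r2 in c("BEFORE", "AFTER", "OVERLAP")) {
      licensed <- paste(r1, r2) %in% c("BEFORE BEFORE", "BEFORE OVERLAP",
                                       "OVERLAP BEFORE", "OVERLAP OVERLAP")
      expect_equal(compose_types(r1, r2) != "NONE", licensed)
    }
  }
})

test_that("closure derives the entailed relations of a before/overlap chain", {
  g <- relation_graph(c("a", "b"), c("b", "c"), c("BEFORE", "OVERLAP"))
  cl <- transitive_closure(g)
  for (k in c("a|b|BEFORE", "b|a|AFTER", "b|c|OVERLAP", "c|b|OVERLAP",
              "a|c|BEFORE", "c|a|AFTER")) {
    expect_true(k %in% graph_key(cl), label = k)
  }
  expect_equal(nrow(cl), 6)
  expect_equal(nrow(transitive_closure(relation_graph())), 0)
})

test_that("inverse-closure makes AFTER chains compose without AFTER rules", {
  g <- relation_graph(c("a", "b"), c("b", "c"), c("AFTER", "AFTER"))
  expect_true("a|c|AFTER" %in% graph_key(transitive_closure(g)))
})

test_that("closure is idempotent, inverse-closed, monotone, and contains its input", {
  set.seed(101)
  for (trial in 1:40) {
    rg <- random_graph(sample(3:7, 1), sample(2:8, 1))
    cl <- transitive_closure(rg$graph)
    expect_true(all(graph_key(rg$graph) %in% graph_key(cl)))
    expect_equal(graph_key(transitive_closure(cl)), graph_key(cl))
    expect_equal(graph_key(invert_relations(cl)), graph_key(cl))
    # monotonicity: closing a superset yields a superset
    extra <- random_graph(7, 2)
    sup <- relation_graph(c(rg$graph$source, extra$graph$source),
                          c(rg$graph$target, extra$graph$target),
                          c(rg$graph$type, extra$graph$type))
    expect_true(all(graph_key(cl) %in% graph_key(transitive_closure(sup))))
  }
})

test_that("closure matches the naive oracle on random graphs", {
  set.seed(202)
  for (trial in 1:60) {
    rg <- random_graph(sample(2:8, 1), sample(1:12, 1))
    expect_identical(graph_to_array(transitive_closure(rg$graph), rg$ids),
                     oracle_closure(rg$src, rg$tgt, rg$typ, rg$ids))
  }
})

test_that("contradictions are reported once per mention pair", {
  g <- relation_graph(c("a", "a"), c("b", "b"), c("BEFORE", "OVERLAP"))
  con <- find_contradictions(g)
  expect_equal(nrow(con), 1)
  expect_equal(con$a, "a")
  expect_equal(con$b, "b")
  expect_equal(con$types, "BEFORE,OVERLAP")

  chain <- relation_graph(c("a", "b"), c("b", "c"), c("BEFORE", "BEFORE"))
  expect_equal(nrow(find_contradictions(chain)), 0)

  cyc <- relation_graph(c("a", "b", "c"), c("b", "c", "a"),
                        c("BEFORE", "BEFORE", "BEFORE"))
  con2 <- find_contradictions(cyc)
  expect_equal(nrow(con2), 3)
  expect_true(all(con2$types == "AFTER,BEFORE"))
})

test_that("the corpus filter keeps canonical intra-sentential time-event links", {
  doc <- flat_doc(
    "f1",
    list(c("fever", "and", "chills", "on", "monday"),
         c("biopsy", "done")),
    list(list(id = "E0", sent = 1, from = 1, to = 1, category = "EVENT",
              type = "PROBLEM"),
         list(id = "E1", sent = 1, from = 3, to = 3, category = "EVENT",
              type = "PROBLEM"),
         list(id = "T0", sent = 1, from = 5, to = 5, category = "TIME",
              type = "DATE"),
         list(id = "E2", sent = 2, from = 1, to = 1, category = "EVENT",
              type = "TEST")))
  g <- relation_graph(c("E0", "E0", "T0", "T0"),
                      c("E1", "T0", "E2", "E1"),
                      c("OVERLAP", "AFTER", "OVERLAP", "OVERLAP"))
  f <- filter_intra_sentential_time_event(g, doc)
  # event-event dropped, cross-sentence dropped, orientation canonicalized
  expect_equal(graph_key(f), sort(c("T0|E0|BEFORE", "T0|E1|OVERLAP")))
  expect_error(
    filter_intra_sentential_time_event(
      relation_graph("T0", "E9", "OVERLAP"), doc),
    "E9")
})
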