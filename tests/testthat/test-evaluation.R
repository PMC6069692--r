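eval_doc <- function(n_pairs) {
  words <- unlist(lapply(seq_len(n_pairs), function(i) {
    c(sprintf("t%d", i), sprintf("e%d", i))
  }))
  flat_doc("ev", list(words), lapply(seq_len(n_pairs), function(i) {
    list(list(id = sprintf("T%d", i), sent = 1, from = 2 * i - 1,
              to = 2 * i - 1, category = "TIME", type = "DATE"),
         list(id = sprintf("E%d", i), sent = 1, from = 2 * i, to = 2 * i,
              category = "EVENT", type = "TEST"))
  }) |> unlist(recursive = FALSE))
}

test_that("a prediction set equal to gold scores 100 everywhere", {
  doc <- eval_doc(3)
  g <- relation_graph(c("T1", "T2", "T3"), c("E1", "E2", "E3"),
                      c("OVERLAP", "BEFORE", "AFTER"))
  rep <- evaluate_relations(g, g, doc)
  expect_equal(rep$micro$precision, 100)
  expect_equal(rep$micro$recall, 100)
  expect_equal(rep$micro$f1, 100)
  expect_true(all(rep$per_label$f1 == 100))
  expect_equal(rep$detection$f1, 100)
})

test_that("type mismatches count for detection but not typed scores", {
  doc <- eval_doc(1)
  gold <- relation_graph("T1", "E1", "OVERLAP")
  pred <- relation_graph("T1", "E1", "BEFORE")
  rep <- evaluate_relations(pred, gold, doc)
  expect_equal(rep$detection$precision, 100)
  expect_equal(rep$detection$recall, 100)
  expect_equal(rep$micro$precision, 0)
  expect_equal(rep$micro$recall, 0)
})

test_that("micro metrics reproduce hand-computed confusion arithmetic", {
  doc <- eval_doc(12)
  # gold: 10 relations; pred: 8 relations, 6 typed matches
  gold <- relation_graph(sprintf("T%d", 1:10), sprintf("E%d", 1:10),
                         rep("OVERLAP", 10))
  pred <- relation_graph(sprintf("T%d", c(1:6, 11, 12)),
                         sprintf("E%d", c(1:6, 11, 12)),
                         rep("OVERLAP", 8))
  rep <- evaluate_relations(pred, gold, doc, extend = FALSE)
  expect_equal(rep$micro$precision, 75, tolerance = 1e-9)
  expect_equal(rep$micro$recall, 60, tolerance = 1e-9)
  expect_equal(rep$micro$f1, 200 * 6 / (2 * 6 + 2 + 4), tolerance = 1e-9)
  # swapping pred and gold exchanges precision and recall
  rep2 <- evaluate_relations(gold, pred, doc, extend = FALSE)
  expect_equal(rep2$micro$precision, rep$micro$recall, tolerance = 1e-9)
  expect_equal(rep2$micro$recall, rep$micro$precision, tolerance = 1e-9)
})

test_that("closure extension credits entailed relations", {
  # two times overlapping each other in the same sentence as the event:
  # gold links T1-E1 and T1-T2... times are filtered, but closing first
  # lets the entailed T2-E1 link be credited.
  doc <- eval_doc(2)
  gold <- relation_graph(c("T1", "T1"), c("E1", "T2"),
                         c("OVERLAP", "OVERLAP"))
  pred <- relation_graph("T2", "E1", "OVERLAP")
  unextended <- evaluate_relations(pred, gold, doc, extend = FALSE)
  extended <- evaluate_relations(pred, gold, doc, extend = TRUE)
  expect_equal(unextended$micro$precision, 0)
  expect_equal(extended$micro$precision, 100)
  # closure never lowers recall of a consistent prediction set
  expect_gte(extended$micro$recall, 0)
})

test_that("Cohen's kappa matches the closed form", {
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a")), 100)
  # 2x2 table a=20, b=5, c=10, d=15: po=0.70, pe=0.50 -> 40
  a <- c(rep("x", 25), rep("y", 25))
  b <- c(rep("x", 20), rep("y", 5), rep("x", 10), rep("y", 15))
  expect_equal(cohens_kappa(a, b), 40, tolerance = 1e-9)
  expect_error(cohens_kappa(c("a"), c("a", "b")), "equal length")
  # degenerate single-label perfect agreement
  expect_equal(cohens_kappa(rep("x", 5), rep("x", 5)), 100)
})

test_that("kappa agrees with an independent implementation and chance null", {
  set.seed(77)
  a <- sample(c("p", "q", "r"), 500, replace = TRUE, prob = c(.5, .3, .2))
  b <- ifelse(stats::runif(500) < 0.6, a,
              sample(c("p", "q", "r"), 500, replace = TRUE))
  tab <- table(factor(a), factor(b))
  expect_equal(cohens_kappa(a, b),
               100 * e1071::classAgreement(tab)$kappa, tolerance = 1e-9)
  # independent labelings: kappa near zero
  set.seed(78)
  x <- sample(c("u", "v"), 10000, replace = TRUE)
  y <- sample(c("u", "v"), 10000, replace = TRUE)
  expect_lt(abs(cohens_kappa(x, y)), 5)
})
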