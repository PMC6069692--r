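test_that("head finding follows the per-label scan rules", {
  np <- parse_bracketed_tree(
    "(NP (NP (NN resection)) (PP (IN of) (NP (DT the) (NN cancer))))")
  expect_equal(lexical_head_index(np), 1L)  # "resection"
  pp <- parse_bracketed_tree("(PP (IN of) (NP (NN diarrhea)))")
  expect_equal(find_head(pp), 1L)           # preposition heads the PP
  single <- parse_bracketed_tree("(FOO (NN x))")
  expect_equal(find_head(single), 1L)
  # coordinated phrase is headed by its leftmost conjunct
  coord <- parse_bracketed_tree(
    "(NP (NP (NN fever)) (CC and) (NP (NN pain)))")
  expect_equal(lexical_head_index(coord), 1L)
})

test_that("projections widen through the three exception cases", {
  wx <- worked_examples()
  proj_of <- function(f, which_id) {
    doc <- f$doc
    m <- doc$mentions[doc$mentions$id == which_id, ]
    maximal_head_projection(m, doc$sentences[[1]])
  }
  ep <- proj_of(wx$direct_pp_exception, "E0")
  expect_equal(ep$exceptions, "PP_CASE")
  expect_equal(ep$node$label, "PP")

  ec <- proj_of(wx$direct_coordination, "E0")
  expect_true("COORD_CASE" %in% ec$exceptions)
  expect_equal(c(ec$node$from, ec$node$to), c(4L, 7L))  # full coordination

  et <- proj_of(wx$direct_type_preserving, "E0")
  expect_true("TYPE_PRESERVING_CASE" %in% et$exceptions)
  expect_equal(c(et$node$from, et$node$to), c(3L, 7L))  # "an episode of ..."
  expect_true(et$aligned)
})

test_that("a mention crossing brackets is flagged as not aligned", {
  doc <- toy_doc("cross", "(S (NP (DT a) (NN b)) (VP (VBD c) (NP (NN d))))",
                 list(list(id = "T0", from = 2, to = 3, type = "DATE")))
  pr <- maximal_head_projection(doc$mentions[1, ], doc$sentences[[1]])
  expect_false(pr$aligned)
})

test_that("the rule engine reproduces all worked-example verdicts", {
  for (f in c(worked_examples(), snapshot_sentences())) {
    doc <- f$doc
    dec <- classify_pair(doc$mentions[doc$mentions$id == "T0", ],
                         doc$mentions[doc$mentions$id == "E0", ],
                         doc$sentences[[1]])
    expect_equal(dec$is_direct, f$direct, label = f$name)
    expect_equal(dec$rationale, f$rationale, label = f$name)
    expect_setequal(dec$exceptions, f$exceptions)
    expect_equal(dec$rationale %in% c("MODIFICATION", "SAME_PREDICATE"),
                 dec$is_direct)
  }
})

test_that("decisions are deterministic", {
  f <- worked_examples()$direct_type_preserving
  doc <- f$doc
  d1 <- classify_pair(doc$mentions[1, ], doc$mentions[2, ],
                      doc$sentences[[1]])
  d2 <- classify_pair(doc$mentions[1, ], doc$mentions[2, ],
                      doc$sentences[[1]])
  expect_identical(d1, d2)
})

test_that("enabling exceptions never flips a pair from direct to non-direct", {
  all_opts <- expand.grid(pp = c(FALSE, TRUE), co = c(FALSE, TRUE),
                          tp = c(FALSE, TRUE))
  fixtures <- c(worked_examples(), snapshot_sentences())
  for (f in fixtures) {
    doc <- f$doc
    verdict <- function(o) {
      classify_pair(doc$mentions[doc$mentions$id == "T0", ],
                    doc$mentions[doc$mentions$id == "E0", ],
                    doc$sentences[[1]],
                    options = rule_options(o$pp, o$co, o$tp))$is_direct
    }
    v <- vapply(seq_len(nrow(all_opts)), function(i) verdict(all_opts[i, ]),
                logical(1))
    # monotone: adding exceptions keeps or gains directness
    for (i in seq_len(nrow(all_opts))) {
      for (j in seq_len(nrow(all_opts))) {
        dominates <- all(unlist(all_opts[j, ]) >= unlist(all_opts[i, ]))
        if (dominates && v[i]) expect_true(v[j], label = f$name)
      }
    }
  }
})

test_that("emptying the type-preserving lexicon flips exactly its fixtures", {
  empty_lex <- parse_tp_templates(character(0))
  for (f in worked_examples()) {
    doc <- f$doc
    dec <- classify_pair(doc$mentions[doc$mentions$id == "T0", ],
                         doc$mentions[doc$mentions$id == "E0", ],
                         doc$sentences[[1]], lexicon = empty_lex)
    expected <- f$direct && !"TYPE_PRESERVING_CASE" %in% f$exceptions
    expect_equal(dec$is_direct, expected, label = f$name)
  }
})

test_that("the dependency fallback stands in when frames are absent", {
  f <- worked_examples()$direct_same_predicate
  doc <- f$doc
  doc$sentences[[1]]$frames <- list()
  dec <- classify_pair(doc$mentions[doc$mentions$id == "T0", ],
                       doc$mentions[doc$mentions$id == "E0", ],
                       doc$sentences[[1]])
  expect_true(dec$is_direct)
  expect_equal(dec$rationale, "SAME_PREDICATE")
  expect_true(dec$dependency_fallback)
  # and it can be disabled
  dec2 <- classify_pair(doc$mentions[doc$mentions$id == "T0", ],
                        doc$mentions[doc$mentions$id == "E0", ],
                        doc$sentences[[1]],
                        options = rule_options(dependency_fallback = FALSE))
  expect_false(dec2$is_direct)
})

test_that("classify_candidates reports one decision per candidate pair", {
  corpus <- generate_corpus(generator_config(n_documents = 4, seed = 13))
  doc <- corpus$documents[[1]]
  dec <- classify_candidates(doc)
  expect_equal(nrow(dec), nrow(enumerate_candidates(doc)))
  expect_true(all(dec$rationale %in% c("MODIFICATION", "SAME_PREDICATE",
                                       "NOT_HEAD", "NO_SYNTACTIC_LINK")))
  expect_identical(dec, classify_candidates(doc))
})
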