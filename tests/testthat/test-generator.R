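test_that("generation is deterministic given the seed", {
  c1 <- generate_corpus(generator_config(n_documents = 5, seed = 42))
  c2 <- generate_corpus(generator_config(n_documents = 5, seed = 42))
  expect_identical(c1$gold, c2$gold)
  expect_identical(lapply(c1$documents, `[[`, "text"),
                   lapply(c2$documents, `[[`, "text"))
  d1 <- withr::local_tempfile()
  d2 <- withr::local_tempfile()
  write_corpus(c1, d1)
  write_corpus(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  c3 <- generate_corpus(generator_config(n_documents = 5, seed = 43))
  expect_false(identical(c1$gold, c3$gold))
})

test_that("a single-template mix yields only that construction", {
  w <- c(modification = 1)
  cfg <- generator_config(n_documents = 10, sentences_per_doc = c(1, 1),
                          template_weights = w, seed = 3)
  corpus <- generate_corpus(cfg)
  expect_equal(nrow(corpus$gold), 10)
  expect_true(all(corpus$gold$construction == "modification"))
  expect_true(all(corpus$gold$is_direct))
  for (doc in corpus$documents) {
    dec <- classify_candidates(doc)
    expect_true(all(dec$is_direct))
    expect_true(all(dec$rationale == "MODIFICATION"))
  }
  expect_error(generator_config(template_weights = c(modification = 0)),
               "positive sum")
})

test_that("relation-type proportions track the configured imbalance", {
  cfg <- generator_config(n_documents = 170, seed = 7)
  corpus <- generate_corpus(cfg)
  direct <- corpus$gold[corpus$gold$is_direct, ]
  expect_gte(nrow(direct), 600)
  prop <- prop.table(table(direct$rel_type))
  expect_lt(abs(prop[["OVERLAP"]] - 0.66), 0.03)
  expect_lt(abs(prop[["BEFORE"]] - 0.18), 0.03)
  expect_lt(abs(prop[["AFTER"]] - 0.16), 0.03)
})

test_that("every rationale and exception value is exercised by the default mix", {
  corpus <- generate_corpus(generator_config(n_documents = 40, seed = 19))
  dec <- do.call(rbind, lapply(corpus$documents, classify_candidates))
  expect_setequal(unique(dec$rationale),
                  c("MODIFICATION", "SAME_PREDICATE", "NOT_HEAD",
                    "NO_SYNTACTIC_LINK"))
  exc <- unique(unlist(strsplit(dec$exceptions[nzchar(dec$exceptions)],
                                ",")))
  expect_setequal(exc, c("PP_CASE", "COORD_CASE", "TYPE_PRESERVING_CASE"))
  expect_setequal(unique(dec$exception_used),
                  c("NONE", "PP_CASE", "COORD_CASE",
                    "TYPE_PRESERVING_CASE"))
})

test_that("rule-engine recovery on clean trees is exact by construction", {
  corpus <- generate_corpus(generator_config(n_documents = 30, seed = 23))
  for (doc in corpus$documents) {
    dec <- classify_candidates(doc)
    g <- corpus$gold[corpus$gold$doc_id == doc$doc_id, ]
    m <- merge(dec, g, by = c("doc_id", "sentence_index", "time_id",
                              "event_id"))
    expect_equal(nrow(m), nrow(g))
    expect_true(all(m$is_direct.x == m$is_direct.y),
                label = doc$doc_id)
  }
})

test_that("tree noise degrades rule-engine accuracy monotonically", {
  acc <- vapply(c(0, 0.45, 0.9), function(p) {
    corpus <- generate_corpus(generator_config(n_documents = 40, seed = 29,
                                               noise_p = p))
    dec <- do.call(rbind, lapply(corpus$documents, classify_candidates))
    m <- merge(dec, corpus$gold,
               by = c("doc_id", "sentence_index", "time_id", "event_id"))
    mean(m$is_direct.x == m$is_direct.y)
  }, numeric(1))
  expect_equal(acc[1], 1)
  expect_lte(acc[2], acc[1])
  expect_lte(acc[3], acc[2])
  expect_lt(acc[3], 1)
})
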