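test_that("candidate enumeration is the intra-sentential time-event product", {
  doc <- flat_doc(
    "d1",
    list(c("a", "b", "c", "d", "e", "f")),
    list(list(id = "T0", sent = 1, from = 1, to = 1, category = "TIME",
              type = "DATE"),
         list(id = "T1", sent = 1, from = 2, to = 2, category = "TIME",
              type = "TIME"),
         list(id = "E0", sent = 1, from = 3, to = 3, category = "EVENT",
              type = "PROBLEM"),
         list(id = "E1", sent = 1, from = 4, to = 4, category = "EVENT",
              type = "TEST"),
         list(id = "E2", sent = 1, from = 5, to = 5, category = "EVENT",
              type = "TREATMENT")))
  cand <- enumerate_candidates(doc)
  expect_equal(nrow(cand), 6)  # 2 TIME x 3 EVENT
  expect_setequal(paste(cand$time_id, cand$event_id),
                  as.vector(outer(c("T0", "T1"), c("E0", "E1", "E2"),
                                  paste)))
  # deterministically ordered by (sentence, time start, event start)
  expect_equal(cand$time_id, rep(c("T0", "T1"), each = 3))
  expect_equal(cand$event_id[1:3], c("E0", "E1", "E2"))
  # pure function: repeat call identical
  expect_identical(cand, enumerate_candidates(doc))
})

test_that("cross-sentence and like-category pairs are never candidates", {
  doc <- flat_doc(
    "d2",
    list(c("on", "monday"), c("the", "biopsy")),
    list(list(id = "T0", sent = 1, from = 2, to = 2, category = "TIME",
              type = "DATE"),
         list(id = "E0", sent = 2, from = 2, to = 2, category = "EVENT",
              type = "TEST")))
  expect_equal(nrow(enumerate_candidates(doc)), 0)

  doc2 <- flat_doc(
    "d3",
    list(c("a", "b", "c", "d", "e")),
    lapply(1:5, function(i) {
      list(id = paste0("E", i), sent = 1, from = i, to = i,
           category = "EVENT", type = "PROBLEM")
    }))
  expect_equal(nrow(enumerate_candidates(doc2)), 0)
})

test_that("pair count equals the per-sentence product and respects the bound", {
  set.seed(11)
  for (trial in 1:20) {
    n_sent <- sample(1:4, 1)
    sents <- lapply(seq_len(n_sent), function(i) {
      rep(letters[i], sample(3:6, 1))
    })
    ms <- list()
    expected <- 0
    for (s in seq_len(n_sent)) {
      nt <- sample(0:2, 1)
      ne <- sample(0:2, 1)
      expected <- expected + nt * ne
      for (k in seq_len(nt)) {
        ms[[length(ms) + 1]] <- list(id = sprintf("T%d_%d", s, k), sent = s,
                                     from = k, to = k, category = "TIME",
                                     type = "DATE")
      }
      for (k in seq_len(ne)) {
        ms[[length(ms) + 1]] <- list(id = sprintf("E%d_%d", s, k), sent = s,
                                     from = k, to = k, category = "EVENT",
                                     type = "TEST")
      }
    }
    if (!length(ms)) next
    doc <- flat_doc(sprintf("r%d", trial), sents, ms)
    n <- nrow(doc$mentions)
    got <- nrow(enumerate_candidates(doc))
    expect_equal(got, expected)
    expect_lte(got, n * (n - 1) / 2)
  }
})

test_that("documents validate mention spans and sentence assignment", {
  expect_error(
    flat_doc("bad", list(c("a", "b")),
             list(list(id = "T0", sent = 1, from = 1, to = 1,
                       category = "TIME", type = "DATE"),
                  list(id = "T0", sent = 1, from = 2, to = 2,
                       category = "TIME", type = "DATE"))),
    "duplicate mention ids")
  # a mention crossing a sentence boundary is kept, assigned by span start
  sent_words <- list(c("pain", "on"), c("monday", "x"))
  lines <- vapply(sent_words, paste, character(1), collapse = " ")
  text <- paste(lines, collapse = "\n")
  sents <- lapply(1:2, function(i) {
    start <- if (i == 1) 0L else nchar(lines[1]) + 1L
    words <- sent_words[[i]]
    ws <- start + c(0L, cumsum(nchar(words) + 1L))[seq_along(words)]
    annotated_sentence(start, start + nchar(lines[i]),
                       data.frame(text = words, start = ws,
                                  end = ws + nchar(words),
                                  pos = NA_character_))
  })
  cross <- time_mention("T0", 5, 14, "on\nmonday", "DATE")
  expect_warning(
    doc <- new_document("d", text, sents, cross),
    "crosses a sentence boundary")
  expect_equal(doc$mentions$sentence_index, 1L)
})

test_that("relation graphs deduplicate and reject malformed input", {
  g <- relation_graph(c("a", "a"), c("b", "b"), c("BEFORE", "BEFORE"))
  expect_equal(nrow(g), 1)
  expect_error(relation_graph("a", "a", "BEFORE"), "self-relations")
  expect_error(relation_graph("a", "b", "SOMETIME"), "unknown relation type")
})
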