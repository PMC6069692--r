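test_that("feature extraction emits the documented families", {
  f2 <- worked_examples()$direct_same_predicate
  doc <- f2$doc
  tm <- doc$mentions[doc$mentions$id == "T0", ]
  em <- doc$mentions[doc$mentions$id == "E0", ]
  v <- extract_features(tm, em, doc$sentences[[1]])
  expect_equal(unname(v["time_type=time"]), 1)
  expect_equal(unname(v["event_type=test"]), 1)
  expect_equal(unname(v["same_pred"]), 1)
  expect_equal(unname(v["t_pred=check"]), 1)
  expect_equal(unname(v["e_pred=check"]), 1)
  # mentions adjacent: empty in-between bag
  expect_equal(unname(v["btw_count"]), 0)
  expect_false(any(startsWith(names(v), "btw_tok=")))
  expect_equal(unname(v["e_tok=creatinine"]), 1)
  expect_equal(unname(v["t_tok=afternoon"]), 1)
  expect_true(any(startsWith(names(v), "verb_")))
  expect_equal(unname(v["section=hospital_course"]), 1)
  # exactly one time_type indicator
  expect_equal(sum(startsWith(names(v), "time_type=")), 1)
  # pure: identical on repeat call
  expect_identical(v, extract_features(tm, em, doc$sentences[[1]]))
})

test_that("duration time expressions set only their type indicator", {
  f <- worked_examples()$direct_pp_exception
  doc <- f$doc
  v <- extract_features(doc$mentions[doc$mentions$id == "T0", ],
                        doc$mentions[doc$mentions$id == "E0", ],
                        doc$sentences[[1]])
  expect_equal(unname(v["time_type=duration"]), 1)
  expect_false("time_type=date" %in% names(v))
  expect_equal(unname(v["btw_count"]), 1)  # "of"
  expect_equal(unname(v["btw_tok=of"]), 1)
})

test_that("class weights are inverse-frequency with unit balanced case", {
  expect_equal(unname(compute_class_weights(c(a = 5, b = 5, c = 5))),
               rep(1, 3))
  w <- compute_class_weights(c(before = 387, after = 345, overlap = 1518))
  expect_true(w["after"] > w["before"])
  expect_true(w["before"] > w["overlap"])
  w2 <- compute_class_weights(c(a = 100, b = 300))
  expect_equal(unname(w2), c(2, 2 / 3))
  # sum(count * weight) = N invariant on random counts
  set.seed(9)
  for (i in 1:10) {
    counts <- sample(1:500, sample(2:5, 1))
    names(counts) <- paste0("l", seq_along(counts))
    w <- compute_class_weights(counts)
    expect_equal(sum(counts * w), sum(counts))
  }
  expect_error(compute_class_weights(c(a = 3, b = 0)), "positive")
})

test_that("the classifier separates a separable corpus and is deterministic", {
  set.seed(31)
  labels <- rep(c("OVERLAP", "BEFORE", "AFTER", "NO_RELATION"), each = 20)
  feats <- lapply(labels, function(l) {
    v <- c(1, stats::setNames(1, paste0("cue=", l)))
    names(v)[1] <- "bias"
    v[sample(length(v))]
  })
  expect_error(train_classifier(feats[1:20], labels[1:20]), "two distinct")
  model <- train_classifier(feats, labels, train_config(seed = 4))
  expect_equal(predict_labels(model, feats), labels)
  # unknown features are ignored
  novel <- lapply(feats, function(v) c(v, novel_feature = 1))
  expect_equal(predict_labels(model, novel), labels)
  model2 <- train_classifier(feats, labels, train_config(seed = 4))
  expect_identical(predict_labels(model2, feats),
                   predict_labels(model, feats))
})

test_that("models serialize losslessly", {
  labels <- rep(c("OVERLAP", "BEFORE"), each = 10)
  feats <- lapply(labels, function(l) stats::setNames(1, paste0("cue=", l)))
  model <- train_classifier(feats, labels)
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(model, path)
  expect_equal(predict_labels(read_model(path), feats),
               predict_labels(model, feats))
  saveRDS(list(format = "other"), path)
  expect_error(read_model(path), "not a dirtlink model")
})

test_that("post-processing removes exactly the two specified patterns", {
  doc <- flat_doc(
    "pp1",
    list(c("tylenol", "bid", "for", "pain"),
         c("pain", "worse", "where", "bid", "given"),
         c("dialysis", "bid", "continued")),
    list(list(id = "T0", sent = 1, from = 2, to = 2, category = "TIME",
              type = "FREQUENCY"),
         list(id = "E0", sent = 1, from = 4, to = 4, category = "EVENT",
              type = "PROBLEM"),
         list(id = "E1", sent = 2, from = 1, to = 1, category = "EVENT",
              type = "PROBLEM"),
         list(id = "T1", sent = 2, from = 4, to = 4, category = "TIME",
              type = "DATE"),
         list(id = "T2", sent = 3, from = 2, to = 2, category = "TIME",
              type = "FREQUENCY"),
         list(id = "E2", sent = 3, from = 1, to = 1, category = "EVENT",
              type = "TREATMENT")))
  preds <- data.frame(time_id = c("T0", "T1", "T2"),
                      event_id = c("E0", "E1", "E2"),
                      label = c("OVERLAP", "OVERLAP", "OVERLAP"),
                      stringsAsFactors = FALSE)
  out <- postprocess_predictions(preds, doc)
  # frequency medication + problem event -> removed
  expect_equal(out$label[1], "NO_RELATION")
  expect_true(out$removed_by_postprocess[1])
  # "where" strictly between the mentions -> removed
  expect_equal(out$label[2], "NO_RELATION")
  # treatment event with "bid" -> retained
  expect_equal(out$label[3], "OVERLAP")
  expect_false(out$removed_by_postprocess[3])
  # idempotent and removal-only
  again <- postprocess_predictions(out[, 1:3], doc)
  expect_equal(again$label, out$label)
  expect_true(all(out$label == preds$label | out$label == "NO_RELATION"))
})
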