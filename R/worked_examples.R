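# Hand-encoded worked examples with gold linguistic analyses: five direct
# constructions (plain modification, shared predicate, and the three
# exception cases) and four non-direct ones (head violations and
# cross-clause configurations), plus six snapshot sentences with gold
# relation labels used to track classifier behaviour on realistic clinical
# prose. Trees and frames are hand-built to the intended readings, so these
# fixtures test the rules, not a parser.

we_frame <- function(pred, ...) {
  rows <- list(...)
  list(pred = as.integer(pred),
       args = data.frame(
         role = vapply(rows, `[[`, character(1), 1),
         from = vapply(rows, function(r) as.integer(r[[2]]), integer(1)),
         to = vapply(rows, function(r) as.integer(r[[3]]), integer(1)),
         kind = vapply(rows, `[[`, character(1), 4),
         stringsAsFactors = FALSE))
}

we_arg <- function(role, from, to, kind = "ARGUMENT") list(role, from, to, kind)

make_fixture_doc <- function(doc_id, tree_str, frames, time, event,
                             enum = FALSE) {
  tree <- parse_bracketed_tree(tree_str)
  words <- tree_leaves(tree, "token")
  pos <- tree_leaves(tree, "label")
  starts <- c(0L, cumsum(nchar(words) + 1L))[seq_along(words)]
  tokens <- data.frame(text = words, start = starts,
                       end = starts + nchar(words), pos = pos,
                       stringsAsFactors = FALSE)
  text <- paste(words, collapse = " ")
  sent <- annotated_sentence(0L, nchar(text), tokens, tree,
                             derive_dependencies(tree), frames,
                             section_label = "HOSPITAL COURSE",
                             starts_with_enumeration = enum)
  mentions <- rbind(
    time_mention("T0", tokens$start[time$from], tokens$end[time$to],
                 paste(words[time$from:time$to], collapse = " "),
                 time$type),
    event_mention("E0", tokens$start[event$from], tokens$end[event$to],
                  paste(words[event$from:event$to], collapse = " "),
                  event$type))
  new_document(doc_id, text, list(sent), mentions)
}

fixture <- function(name, doc, direct, rationale, exceptions = character(0),
                    gold_rel = NA_character_) {
  list(name = name, doc = doc, time_id = "T0", event_id = "E0",
       direct = direct, rationale = rationale, exceptions = exceptions,
       gold_rel = gold_rel)
}

#' Curated worked examples for the rule engine
#'
#' Nine single-sentence documents with gold analyses: five direct pairs (one
#' per construction: plain modification, shared predicate, PP exception,
#' type-preserving exception, coordination exception) and four non-direct
#' pairs (two head violations, a cross-clause conjunction, an embedded
#' clause). Each carries the expected decision, rationale and exception set.
#'
#' @return Named list of fixtures (`name`, `doc`, `time_id`, `event_id`,
#'   `direct`, `rationale`, `exceptions`, `gold_rel`).
#' @export
worked_examples <- function() {
  out <- list(
    fixture(
      "direct_modification_advp",
      make_fixture_doc(
        "we_mod",
        paste0("(S (NP (PRP She)) (VP (VBD underwent)",
               " (NP (NP (JJ laparoscopic) (NN cholecystectomy))",
               " (ADVP (NP (CD 7) (NNS weeks)) (RB prior)",
               " (PP (TO to) (NP (NN admission)))))) (. .))"),
        list(we_frame(2, we_arg("A0", 1, 1), we_arg("A1", 3, 9))),
        time = list(from = 5, to = 9, type = "DATE"),
        event = list(from = 3, to = 4, type = "TREATMENT")),
      direct = TRUE, rationale = "MODIFICATION", gold_rel = "OVERLAP"),
    fixture(
      "direct_same_predicate",
      make_fixture_doc(
        "we_pred",
        paste0("(S (NP (PRP We)) (VP (MD will) (VP (VB check)",
               " (NP (NN creatinine)) (NP (DT this) (NN afternoon))))",
               " (. .))"),
        list(we_frame(3, we_arg("A0", 1, 1), we_arg("A1", 4, 4),
                      we_arg("AM-TMP", 5, 6, "ADJUNCT"))),
        time = list(from = 5, to = 6, type = "TIME"),
        event = list(from = 4, to = 4, type = "TEST")),
      direct = TRUE, rationale = "SAME_PREDICATE", gold_rel = "OVERLAP"),
    fixture(
      "direct_pp_exception",
      make_fixture_doc(
        "we_pp",
        paste0("(S (NP (DT The) (NN patient)) (VP (VBD had)",
               " (NP (NP (CD two) (NNS months))",
               " (PP (IN of) (NP (NN diarrhea))))) (. .))"),
        list(we_frame(3, we_arg("A0", 1, 2), we_arg("A1", 4, 7))),
        time = list(from = 4, to = 5, type = "DURATION"),
        event = list(from = 7, to = 7, type = "PROBLEM")),
      direct = TRUE, rationale = "MODIFICATION", exceptions = "PP_CASE",
      gold_rel = "OVERLAP"),
    fixture(
      "direct_type_preserving",
      make_fixture_doc(
        "we_tp",
        paste0("(S (NP (PRP He)) (VP (VBD had)",
               " (NP (NP (DT an) (NN episode))",
               " (PP (IN of) (NP (JJ epigastric) (NN pain))))",
               " (NP (NN yesterday))) (. .))"),
        list(we_frame(2, we_arg("A0", 1, 1), we_arg("A1", 3, 7),
                      we_arg("AM-TMP", 8, 8, "ADJUNCT"))),
        time = list(from = 8, to = 8, type = "DATE"),
        event = list(from = 6, to = 7, type = "PROBLEM")),
      direct = TRUE, rationale = "SAME_PREDICATE",
      exceptions = c("PP_CASE", "TYPE_PRESERVING_CASE"),
      gold_rel = "OVERLAP"),
    fixture(
      "direct_coordination",
      make_fixture_doc(
        "we_coord",
        paste0("(S (NP (DT The) (NN patient)) (VP (VBD had)",
               " (NP (NP (NN fever)) (CC and)",
               " (NP (JJ epigastric) (NN pain)))",
               " (PP (IN at) (NP (CD 4) (NN AM)))) (. .))"),
        list(we_frame(3, we_arg("A0", 1, 2), we_arg("A1", 4, 7),
                      we_arg("AM-TMP", 8, 10, "ADJUNCT"))),
        time = list(from = 9, to = 10, type = "TIME"),
        event = list(from = 6, to = 7, type = "PROBLEM")),
      direct = TRUE, rationale = "SAME_PREDICATE",
      exceptions = c("PP_CASE", "COORD_CASE"), gold_rel = "OVERLAP"),
    fixture(
      "nondirect_pp_attachment",
      make_fixture_doc(
        "we_nothead1",
        paste0("(S (NP (DT The) (NN patient)) (VP (VBD underwent)",
               " (NP (NP (NP (NN resection)) (PP (IN of)",
               " (NP (DT the) (JJ left) (NN face) (JJ squamous)",
               " (NN cell) (NN cancer))))",
               " (PP (IN on) (NP (CD 2016-03-13))))) (. .))"),
        list(we_frame(3, we_arg("A0", 1, 2), we_arg("A1", 4, 13))),
        time = list(from = 13, to = 13, type = "DATE"),
        event = list(from = 6, to = 11, type = "PROBLEM")),
      direct = FALSE, rationale = "NOT_HEAD", exceptions = "PP_CASE"),
    fixture(
      "nondirect_argument_head",
      make_fixture_doc(
        "we_nothead2",
        paste0("(S (NP (NP (NN Repeat) (NN CBC)) (PP (IN on)",
               " (NP (NP (NN day)) (PP (IN of) (NP (NN life) (CD two))))))",
               " (VP (VBD showed) (NP (CD 41) (NN %) (NNS neutrophils)))",
               " (. .))"),
        list(we_frame(8, we_arg("A0", 1, 7), we_arg("A1", 9, 11))),
        time = list(from = 4, to = 7, type = "DATE"),
        event = list(from = 11, to = 11, type = "TEST")),
      direct = FALSE, rationale = "NOT_HEAD", exceptions = "PP_CASE"),
    fixture(
      "nondirect_cross_clause",
      make_fixture_doc(
        "we_cross",
        paste0("(S (S (NP (PRP He)) (VP (VBD was) (VP (VBN admitted)",
               " (PP (IN on) (NP (CD 10-24)))))) (, ,) (CC and)",
               " (S (NP (NN chest) (NN x-ray)) (VP (VBD was)",
               " (VP (VBN obtained)))) (. .))"),
        list(we_frame(3, we_arg("A1", 1, 1),
                      we_arg("AM-TMP", 4, 5, "ADJUNCT")),
             we_frame(11, we_arg("A1", 8, 9))),
        time = list(from = 5, to = 5, type = "DATE"),
        event = list(from = 8, to = 9, type = "TEST")),
      direct = FALSE, rationale = "NO_SYNTACTIC_LINK",
      exceptions = "PP_CASE"),
    fixture(
      "nondirect_embedded_clause",
      make_fixture_doc(
        "we_embed",
        paste0("(S (PP (IN On) (NP (CD 11-05))) (, ,)",
               " (NP (DT the) (NN team)) (VP (VBD discussed)",
               " (NP (NP (DT the) (NN plan)) (SBAR (WHNP (WDT that))",
               " (S (VP (VBD included) (NP (NN dialysis))))))) (. .))"),
        list(we_frame(6, we_arg("A0", 4, 5), we_arg("A1", 7, 11),
                      we_arg("AM-TMP", 1, 2, "ADJUNCT")),
             we_frame(10, we_arg("A1", 11, 11))),
        time = list(from = 2, to = 2, type = "DATE"),
        event = list(from = 11, to = 11, type = "TREATMENT")),
      direct = FALSE, rationale = "NOT_HEAD", exceptions = "PP_CASE")
  )
  stats::setNames(out, vapply(out, `[[`, character(1), "name"))
}

#' Snapshot sentences with gold relation labels
#'
#' Six single-sentence documents of realistic clinical prose, each with a
#' marked time-event pair and a gold label: `OVERLAP`, `OVERLAP`, `NA`
#' (non-direct), `OVERLAP`, `AFTER`, `AFTER`. Sentence 3 is non-direct under
#' its gold reading (the "with ..." phrase attaches to the noun, not the
#' verb); classifier predictions on these sentences are tracked as
#' regression snapshots, while the rule engine's direct/non-direct verdicts
#' are asserted.
#'
#' @return Named list of fixtures in the same layout as
#'   [worked_examples()].
#' @export
snapshot_sentences <- function() {
  out <- list(
    fixture(
      "snap_creatinine_rose",
      make_fixture_doc(
        "snap1",
        paste0("(S (ADVP (RB Subsequently))",
               " (NP (PRP$ his) (NN creatinine))",
               " (VP (VP (VBD rose) (PP (IN for)",
               " (NP (CD three) (NNS days)))) (CC and)",
               " (VP (ADVP (RB then)) (VBD stabilized)",
               " (PP (IN at) (NP (CD 10))))) (. .))"),
        list(we_frame(4, we_arg("A1", 2, 3),
                      we_arg("AM-TMP", 5, 7, "ADJUNCT"))),
        time = list(from = 6, to = 7, type = "DURATION"),
        event = list(from = 2, to = 3, type = "TEST")),
      direct = TRUE, rationale = "SAME_PREDICATE", exceptions = "PP_CASE",
      gold_rel = "OVERLAP"),
    fixture(
      "snap_catheterization",
      make_fixture_doc(
        "snap2",
        paste0("(S (NP (JJ Cardiac) (NN catheterization))",
               " (VP (VBD was) (VP (VBN performed)",
               " (PP (IN without) (NP (NN complication)))",
               " (PP (IN from) (NP (DT the) (JJ right) (NN neck)))",
               " (PP (IN on) (NP (NP (DT the) (NN day))",
               " (PP (IN of) (NP (NN admission))))))) (. .))"),
        list(we_frame(4, we_arg("A1", 1, 2),
                      we_arg("AM-MNR", 5, 6, "ADJUNCT"),
                      we_arg("AM-TMP", 11, 15, "ADJUNCT"))),
        time = list(from = 12, to = 13, type = "DATE"),
        event = list(from = 1, to = 2, type = "TEST")),
      direct = TRUE, rationale = "SAME_PREDICATE", exceptions = "PP_CASE",
      gold_rel = "OVERLAP"),
    fixture(
      "snap_sbp_morning",
      make_fixture_doc(
        "snap3",
        paste0("(S (LST (LS 3.)) (PP (IN On) (NP (NP (DT the)",
               " (NN morning)) (PP (IN of) (NP (CD 12-01))))) (, ,)",
               " (NP (DT the) (NN patient)) (VP (VBD had)",
               " (NP (NP (DT some) (JJ transient) (NNS episodes))",
               " (PP (IN of) (NP (NP (NN hypotension)) (PP (IN with)",
               " (NP (NP (NN SBP) (NNS s)) (PP (IN in)",
               " (NP (DT the) (CD 70) (NNS s))))))))) (. .))"),
        list(we_frame(10, we_arg("A0", 8, 9), we_arg("A1", 11, 22),
                      we_arg("AM-TMP", 2, 6, "ADJUNCT"))),
        time = list(from = 3, to = 6, type = "DATE"),
        event = list(from = 17, to = 18, type = "TEST"),
        enum = TRUE),
      direct = FALSE, rationale = "NOT_HEAD", exceptions = "PP_CASE"),
    fixture(
      "snap_vanc_friday",
      make_fixture_doc(
        "snap4",
        paste0("(S (ADVP (RB Initially)) (PP (IN on)",
               " (NP (NP (NP (NNP Vanc)) (CC and) (NP (NNP Cipro)))",
               " (PP (IN on) (NP (NNP Friday))))) (CC but)",
               " (ADVP (RB then)) (VP (VBN seen)",
               " (PP (IN by) (NP (NNP ID)))) (. .))"),
        list(we_frame(10, we_arg("A1", 12, 12))),
        time = list(from = 7, to = 7, type = "DATE"),
        event = list(from = 3, to = 3, type = "TREATMENT")),
      direct = TRUE, rationale = "MODIFICATION",
      exceptions = "PP_CASE", gold_rel = "OVERLAP"),
    fixture(
      "snap_cardioversion",
      make_fixture_doc(
        "snap5",
        paste0("(S (NP (NN Anti-coagulation)) (VP (VBD was)",
               " (VP (VBN started) (PP (IN with) (NP (NP (DT a)",
               " (NN plan)) (PP (IN for) (NP (NP (NN cardioversion))",
               " (PP (IN in) (NP (CD 6) (NNS weeks))))))))) (. .))"),
        list(we_frame(3, we_arg("A1", 1, 1))),
        time = list(from = 10, to = 11, type = "DURATION"),
        event = list(from = 8, to = 8, type = "TREATMENT")),
      direct = TRUE, rationale = "MODIFICATION", exceptions = "PP_CASE",
      gold_rel = "AFTER"),
    fixture(
      "snap_tf_resumed",
      make_fixture_doc(
        "snap6",
        paste0("(S (S (NP (NN POD#) (CD 15/6)) (, ,) (NP (PRP she))",
               " (VP (VBD resumed) (NP (NNP TF) (POS 's)))) (CC and)",
               " (S (NP (NNP TPN)) (VP (VBD was) (VP (VBN tapered))))",
               " (. .))"),
        list(we_frame(5, we_arg("A0", 4, 4), we_arg("A1", 6, 7),
                      we_arg("AM-TMP", 1, 2, "ADJUNCT")),
             we_frame(11, we_arg("A1", 9, 9))),
        time = list(from = 1, to = 2, type = "DATE"),
        event = list(from = 6, to = 6, type = "TREATMENT")),
      direct = TRUE, rationale = "SAME_PREDICATE", gold_rel = "AFTER")
  )
  stats::setNames(out, vapply(out, `[[`, character(1), "name"))
}
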