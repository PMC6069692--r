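# Seeded synthetic-corpus generator. Sentences are instantiated from
# construction templates with slot lexicons; gold trees, dependencies and
# predicate frames are emitted consistently with the surface string, so the
# rule engine can be tested in isolation from parser error. Direct/non-direct
# status and the relation type are properties of the template, which makes
# rule-engine recovery exact by construction on clean trees.
#
# Relation types in generated text follow a fixed cue convention (e.g. the
# prepositions on/during mark OVERLAP, after/since mark BEFORE, before/until
# mark AFTER), so the type is a deterministic function of surface evidence -
# the situation the classifier is meant to learn.

GEN_TEMPLATES <- c("modification", "same_predicate", "pp_exception",
                   "coordination", "type_preserving", "not_head",
                   "cross_clause", "distractor")

#' Generator configuration
#'
#' The defaults emulate the construction inventory of direct and non-direct
#' intra-sentential time-event pairs and the ~66/18/16
#' overlap/before/after type imbalance observed in direct-relation corpora.
#'
#' @param n_documents Number of documents.
#' @param sentences_per_doc Inclusive range (length-2 vector) of sentences
#'   per document.
#' @param template_weights Named nonnegative weights over the eight
#'   construction templates (five direct, two non-direct, one no-relation
#'   distractor); must not sum to zero.
#' @param relation_mix Named probabilities over OVERLAP/BEFORE/AFTER for
#'   direct pairs.
#' @param seed Seed fixing all randomness.
#' @param noise_p Probability of deleting each internal tree node (a parse
#'   corruption knob; 0 keeps gold trees).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_documents = 100,
                             sentences_per_doc = c(4, 8),
                             template_weights = c(modification = 0.17,
                                                  same_predicate = 0.17,
                                                  pp_exception = 0.16,
                                                  coordination = 0.12,
                                                  type_preserving = 0.12,
                                                  not_head = 0.10,
                                                  cross_clause = 0.08,
                                                  distractor = 0.08),
                             relation_mix = c(OVERLAP = 0.66, BEFORE = 0.18,
                                              AFTER = 0.16),
                             seed = 7L, noise_p = 0) {
  w <- template_weights[GEN_TEMPLATES]
  w[is.na(w)] <- 0
  names(w) <- GEN_TEMPLATES
  if (any(w < 0) || sum(w) <= 0) {
    stop("template weights must be nonnegative with positive sum",
         call. = FALSE)
  }
  structure(list(n_documents = n_documents,
                 sentences_per_doc = sentences_per_doc,
                 template_weights = w / sum(w),
                 relation_mix = relation_mix / sum(relation_mix),
                 seed = as.integer(seed), noise_p = noise_p),
            class = "generator_config")
}

# --- slot lexicons (fixed, versioned in source) ----------------------------

GEN_SLOTS <- list(
  subjects = list(c("The", "patient"), c("She"), c("He"), c("The", "team")),
  treatments = list(c("laparoscopic", "cholecystectomy"), c("chemotherapy"),
                    c("dialysis"), c("warfarin"), c("radiation", "therapy"),
                    c("intubation")),
  problems = list(c("diarrhea"), c("fever"), c("epigastric", "pain"),
                  c("hypotension"), c("orthostasis"), c("nausea"),
                  c("dyspnea"), c("anemia")),
  tests = list(c("creatinine"), c("chest", "x-ray"), c("cbc"),
               c("blood", "cultures"), c("echocardiogram"), c("colonoscopy")),
  dates = list(c("2016-03-13"), c("monday"), c("friday"), c("12-01"),
               c("10-24"), c("september", "2")),
  durations = list(c("two", "months"), c("three", "days"), c("6", "weeks"),
                   c("seven", "weeks"), c("ten", "days")),
  times_of_day = list(c("this", "afternoon"), c("this", "morning"),
                      c("4", "am"), c("midnight"))
)

CUE_PREP <- list(OVERLAP = c("on", "during"), BEFORE = c("after", "since"),
                 AFTER = c("before", "until"))
CUE_ADV <- list(OVERLAP = "ago", BEFORE = "afterward", AFTER = "beforehand")
CUE_PREVERB <- list(OVERLAP = "promptly", BEFORE = "subsequently",
                    AFTER = "previously")

gen_pos <- function(tok) {
  adjectives <- c("laparoscopic", "epigastric", "physical", "left")
  determiners <- c("the", "this", "an", "a")
  if (grepl("^[0-9]", tok)) "CD"
  else if (tolower(tok) %in% adjectives) "JJ"
  else if (tolower(tok) %in% determiners) "DT"
  else if (tolower(tok) %in% c("monday", "friday", "september")) "NNP"
  else if (tolower(tok) %in% c("she", "he")) "PRP"
  else "NN"
}

np_of <- function(tokens) {
  const_node("NP", lapply(tokens, function(t) const_leaf(gen_pos(t), t)))
}

subj_node <- function(tokens) np_of(tokens)

pick <- function(lst) lst[[sample.int(length(lst), 1)]]

sample_type <- function(mix) {
  sample(names(mix), 1, prob = as.numeric(mix))
}

# A template instance: token/POS sequences plus token-index positions for the
# two mentions and the frames. `time`/`event` are lists with from/to (token
# indices), attr type.
gen_sentence <- function(template, rel_mix) {
  switch(template,
    modification = {
      rel <- sample_type(rel_mix)
      subj <- pick(GEN_SLOTS$subjects)
      treat <- pick(GEN_SLOTS$treatments)
      dur <- pick(GEN_SLOTS$durations)
      cue <- CUE_ADV[[rel]]
      ns <- length(subj)
      nt <- length(treat)
      nd <- length(dur)
      tree <- const_node("S", list(
        subj_node(subj),
        const_node("VP", list(
          const_leaf("VBD", "underwent"),
          const_node("NP", list(
            np_of(treat),
            const_node("ADVP", list(np_of(dur), const_leaf("RB", cue))))))),
        const_leaf(".", ".")))
      ev_from <- ns + 2L
      list(tree = tree, rel_type = rel, is_direct = TRUE,
           construction = "modification",
           event = list(from = ev_from, to = ev_from + nt - 1L,
                        type = "TREATMENT"),
           time = list(from = ev_from + nt, to = ev_from + nt + nd,
                       type = "DURATION"),
           frames = list(list(pred = ns + 1L, args = data.frame(
             role = c("A0", "A1"),
             from = c(1L, ev_from),
             to = c(ns, ev_from + nt + nd),
             kind = c("ARGUMENT", "ARGUMENT"), stringsAsFactors = FALSE))))
    },
    same_predicate = {
      rel <- sample_type(rel_mix)
      subj <- pick(GEN_SLOTS$subjects)
      test <- pick(GEN_SLOTS$tests)
      tod <- pick(GEN_SLOTS$times_of_day)
      cue <- CUE_PREVERB[[rel]]
      verb <- sample(c("checked", "repeated", "obtained"), 1)
      ns <- length(subj)
      nt <- length(test)
      nd <- length(tod)
      tree <- const_node("S", list(
        subj_node(subj),
        const_node("VP", list(
          const_node("ADVP", list(const_leaf("RB", cue))),
          const_leaf("VBD", verb),
          np_of(test),
          np_of(tod))),
        const_leaf(".", ".")))
      ev_from <- ns + 3L
      list(tree = tree, rel_type = rel, is_direct = TRUE,
           construction = "same_predicate",
           event = list(from = ev_from, to = ev_from + nt - 1L,
                        type = "TEST"),
           time = list(from = ev_from + nt, to = ev_from + nt + nd - 1L,
                       type = "TIME"),
           frames = list(list(pred = ns + 2L, args = data.frame(
             role = c("A0", "A1", "AM-TMP"),
             from = c(1L, ev_from, ev_from + nt),
             to = c(ns, ev_from + nt - 1L, ev_from + nt + nd - 1L),
             kind = c("ARGUMENT", "ARGUMENT", "ADJUNCT"),
             stringsAsFactors = FALSE))))
    },
    pp_exception = {
      rel <- sample_type(rel_mix)
      subj <- pick(GEN_SLOTS$subjects)
      treat <- pick(GEN_SLOTS$treatments)
      date <- pick(GEN_SLOTS$dates)
      cue <- sample(CUE_PREP[[rel]], 1)
      ns <- length(subj)
      nt <- length(treat)
      nd <- length(date)
      tree <- const_node("S", list(
        subj_node(subj),
        const_node("VP", list(
          const_leaf("VBD", "underwent"),
          np_of(treat),
          const_node("PP", list(const_leaf("IN", cue), np_of(date))))),
        const_leaf(".", ".")))
      ev_from <- ns + 2L
      list(tree = tree, rel_type = rel, is_direct = TRUE,
           construction = "pp_exception",
           event = list(from = ev_from, to = ev_from + nt - 1L,
                        type = "TREATMENT"),
           time = list(from = ev_from + nt + 1L,
                       to = ev_from + nt + nd, type = "DATE"),
           frames = list(list(pred = ns + 1L, args = data.frame(
             role = c("A0", "A1", "AM-TMP"),
             from = c(1L, ev_from, ev_from + nt),
             to = c(ns, ev_from + nt - 1L, ev_from + nt + nd),
             kind = c("ARGUMENT", "ARGUMENT", "ADJUNCT"),
             stringsAsFactors = FALSE))))
    },
    coordination = {
      rel <- sample_type(rel_mix)
      subj <- pick(GEN_SLOTS$subjects)
      probs <- sample(GEN_SLOTS$problems, 2)
      p1 <- probs[[1]]
      p2 <- probs[[2]]
      tod <- pick(GEN_SLOTS$times_of_day)
      cue <- sample(CUE_PREP[[rel]], 1)
      ns <- length(subj)
      n1 <- length(p1)
      n2 <- length(p2)
      nd <- length(tod)
      tree <- const_node("S", list(
        subj_node(subj),
        const_node("VP", list(
          const_leaf("VBD", "had"),
          const_node("NP", list(np_of(p1), const_leaf("CC", "and"),
                                np_of(p2))),
          const_node("PP", list(const_leaf("IN", cue), np_of(tod))))),
        const_leaf(".", ".")))
      e_from <- ns + 2L + n1 + 1L
      list(tree = tree, rel_type = rel, is_direct = TRUE,
           construction = "coordination",
           event = list(from = e_from, to = e_from + n2 - 1L,
                        type = "PROBLEM"),
           time = list(from = e_from + n2 + 1L, to = e_from + n2 + nd,
                       type = "TIME"),
           frames = list(list(pred = ns + 1L, args = data.frame(
             role = c("A0", "A1", "AM-TMP"),
             from = c(1L, ns + 2L, e_from + n2),
             to = c(ns, e_from + n2 - 1L, e_from + n2 + nd),
             kind = c("ARGUMENT", "ARGUMENT", "ADJUNCT"),
             stringsAsFactors = FALSE))))
    },
    type_preserving = {
      rel <- sample_type(rel_mix)
      subj <- pick(GEN_SLOTS$subjects)
      prob <- pick(GEN_SLOTS$problems)
      tod <- pick(GEN_SLOTS$times_of_day)
      cue <- sample(CUE_PREP[[rel]], 1)
      ns <- length(subj)
      np <- length(prob)
      nd <- length(tod)
      tree <- const_node("S", list(
        subj_node(subj),
        const_node("VP", list(
          const_leaf("VBD", "had"),
          const_node("NP", list(
            const_node("NP", list(const_leaf("DT", "an"),
                                  const_leaf("NN", "episode"))),
            const_node("PP", list(const_leaf("IN", "of"), np_of(prob))))),
          const_node("PP", list(const_leaf("IN", cue), np_of(tod))))),
        const_leaf(".", ".")))
      e_from <- ns + 5L
      list(tree = tree, rel_type = rel, is_direct = TRUE,
           construction = "type_preserving",
           event = list(from = e_from, to = e_from + np - 1L,
                        type = "PROBLEM"),
           time = list(from = e_from + np + 1L, to = e_from + np + nd,
                       type = "TIME"),
           frames = list(list(pred = ns + 1L, args = data.frame(
             role = c("A0", "A1", "AM-TMP"),
             from = c(1L, ns + 2L, e_from + np),
             to = c(ns, e_from + np - 1L, e_from + np + nd),
             kind = c("ARGUMENT", "ARGUMENT", "ADJUNCT"),
             stringsAsFactors = FALSE))))
    },
    not_head = {
      subj <- pick(GEN_SLOTS$subjects)
      prob <- pick(GEN_SLOTS$problems)
      date <- pick(GEN_SLOTS$dates)
      cue <- sample(unlist(CUE_PREP), 1)
      ns <- length(subj)
      np <- length(prob)
      nd <- length(date)
      tree <- const_node("S", list(
        subj_node(subj),
        const_node("VP", list(
          const_leaf("VBD", "underwent"),
          const_node("NP", list(
            const_node("NP", list(
              const_node("NP", list(const_leaf("NN", "resection"))),
              const_node("PP", list(const_leaf("IN", "of"), np_of(prob))))),
            const_node("PP", list(const_leaf("IN", cue), np_of(date))))))),
        const_leaf(".", ".")))
      e_from <- ns + 4L
      list(tree = tree, rel_type = NA_character_, is_direct = FALSE,
           construction = "not_head",
           event = list(from = e_from, to = e_from + np - 1L,
                        type = "PROBLEM"),
           time = list(from = e_from + np + 1L, to = e_from + np + nd,
                       type = "DATE"),
           frames = list(list(pred = ns + 1L, args = data.frame(
             role = c("A0", "A1"),
             from = c(1L, ns + 2L),
             to = c(ns, e_from + np + nd),
             kind = c("ARGUMENT", "ARGUMENT"), stringsAsFactors = FALSE))))
    },
    cross_clause = {
      subj <- pick(GEN_SLOTS$subjects)
      test <- pick(GEN_SLOTS$tests)
      date <- pick(GEN_SLOTS$dates)
      cue <- sample(unlist(CUE_PREP), 1)
      ns <- length(subj)
      nt <- length(test)
      nd <- length(date)
      tree <- const_node("S", list(
        const_node("S", list(
          subj_node(subj),
          const_node("VP", list(
            const_leaf("VBD", "was"),
            const_node("VP", list(
              const_leaf("VBN", "admitted"),
              const_node("PP", list(const_leaf("IN", cue),
                                    np_of(date))))))))),
        const_leaf(",", ","),
        const_leaf("CC", "and"),
        const_node("S", list(
          np_of(test),
          const_node("VP", list(
            const_leaf("VBD", "was"),
            const_node("VP", list(const_leaf("VBN", "obtained"))))))),
        const_leaf(".", ".")))
      t_from <- ns + 4L
      e_from <- ns + nd + 6L
      list(tree = tree, rel_type = NA_character_, is_direct = FALSE,
           construction = "cross_clause",
           time = list(from = t_from, to = t_from + nd - 1L, type = "DATE"),
           event = list(from = e_from, to = e_from + nt - 1L,
                        type = "TEST"),
           frames = list(
             list(pred = ns + 2L, args = data.frame(
               role = c("A1", "AM-TMP"),
               from = c(1L, ns + 3L),
               to = c(ns, ns + 3L + nd),
               kind = c("ARGUMENT", "ADJUNCT"), stringsAsFactors = FALSE)),
             list(pred = e_from + nt + 1L, args = data.frame(
               role = "A1", from = e_from, to = e_from + nt - 1L,
               kind = "ARGUMENT", stringsAsFactors = FALSE))))
    },
    distractor = {
      subj <- pick(GEN_SLOTS$subjects)
      test <- pick(GEN_SLOTS$tests)
      date <- pick(GEN_SLOTS$dates)
      ns <- length(subj)
      nt <- length(test)
      nd <- length(date)
      tree <- const_node("S", list(
        const_node("PP", list(const_leaf("IN", "On"), np_of(date))),
        const_leaf(",", ","),
        subj_node(subj),
        const_node("VP", list(
          const_leaf("VBD", "returned"),
          const_node("PP", list(
            const_leaf("TO", "to"),
            const_node("NP", list(
              const_node("NP", list(const_leaf("DT", "the"),
                                    const_leaf("NN", "unit"))),
              const_node("SBAR", list(
                const_node("WHADVP", list(const_leaf("WRB", "where"))),
                const_node("S", list(
                  np_of(test),
                  const_node("VP", list(
                    const_leaf("VBD", "was"),
                    const_node("VP",
                               list(const_leaf("VBN", "performed"))))))))))))))),
        const_leaf(".", ".")))
      e_from <- ns + nd + 8L
      list(tree = tree, rel_type = NA_character_, is_direct = FALSE,
           construction = "distractor",
           time = list(from = 2L, to = 1L + nd, type = "DATE"),
           event = list(from = e_from, to = e_from + nt - 1L,
                        type = "TEST"),
           frames = list(
             list(pred = 1L + nd + 1L + ns + 1L, args = data.frame(
               role = c("A0", "AM-TMP"),
               from = c(1L + nd + 2L, 1L),
               to = c(1L + nd + 1L + ns, 1L + nd),
               kind = c("ARGUMENT", "ADJUNCT"), stringsAsFactors = FALSE)),
             list(pred = e_from + nt + 1L, args = data.frame(
               role = "A1", from = e_from, to = e_from + nt - 1L,
               kind = "ARGUMENT", stringsAsFactors = FALSE))))
    },
    stop("unknown template: ", template, call. = FALSE)
  )
}

#' Derive dependency edges from a constituency tree
#'
#' Percolates lexical heads with the head table; every non-head child's head
#' token attaches to its parent's head token, labelled with the child's
#' constituent label (lowercased). The sentence head attaches to the
#' artificial root 0.
#'
#' @param tree An indexed `const_node`.
#' @param head_table A [default_head_table()].
#' @return Dependency data frame (`head`, `dep`, `label`).
#' @export
derive_dependencies <- function(tree, head_table = default_head_table()) {
  edges <- list()
  walk <- function(node) {
    if (node$terminal) return(node$from)
    hi <- find_head(node, head_table)
    heads <- lapply(node$children, walk)
    for (i in seq_along(node$children)) {
      if (i == hi) next
      edges[[length(edges) + 1L]] <<-
        list(heads[[hi]], heads[[i]], tolower(node$children[[i]]$label))
    }
    heads[[hi]]
  }
  root <- walk(tree)
  edges[[length(edges) + 1L]] <- list(0L, root, "root")
  data.frame(head = vapply(edges, function(e) as.integer(e[[1]]), integer(1)),
             dep = vapply(edges, function(e) as.integer(e[[2]]), integer(1)),
             label = vapply(edges, function(e) e[[3]], character(1)),
             stringsAsFactors = FALSE)
}

# Delete each eligible internal node (non-root, non-terminal) with
# probability p, splicing its children into its parent; leaves are preserved,
# so tokens still align.
perturb_tree <- function(tree, p) {
  splice <- function(node) {
    if (node$terminal) return(node)
    kids <- list()
    for (ch in node$children) {
      ch <- splice(ch)
      if (!ch$terminal && stats::runif(1) < p) {
        kids <- c(kids, ch$children)
      } else {
        kids <- c(kids, list(ch))
      }
    }
    node$children <- kids
    node
  }
  index_tree(splice(tree))
}

GEN_SECTIONS <- c("HOSPITAL COURSE", "HISTORY OF PRESENT ILLNESS",
                  "LABORATORY DATA", "ASSESSMENT AND PLAN")

#' Generate a synthetic annotated corpus
#'
#' Emits documents whose sentences instantiate the construction templates,
#' with gold mentions, relations (canonically time-to-event oriented),
#' parse trees, dependencies and predicate frames, plus a gold table of
#' per-pair direct/non-direct status. Deterministic given the seed.
#'
#' @param config A [generator_config()].
#' @return List with `documents` (list of [new_document()]) and `gold` (data
#'   frame: `doc_id`, `sentence_index`, `time_id`, `event_id`,
#'   `construction`, `is_direct`, `rel_type`).
#' @export
generate_corpus <- function(config = generator_config()) {
  set.seed(config$seed)
  docs <- list()
  gold <- data.frame(doc_id = character(), sentence_index = integer(),
                     time_id = character(), event_id = character(),
                     construction = character(), is_direct = logical(),
                     rel_type = character(), stringsAsFactors = FALSE)
  for (d in seq_len(config$n_documents)) {
    doc_id <- sprintf("synth%04d", d)
    n_s <- sample(seq(config$sentences_per_doc[1],
                      config$sentences_per_doc[2]), 1)
    templates <- sample(GEN_TEMPLATES, n_s, replace = TRUE,
                        prob = config$template_weights)
    section <- GEN_SECTIONS[(d - 1L) %% length(GEN_SECTIONS) + 1L]
    header <- paste0(section, ":")
    text_lines <- header
    offset <- nchar(header) + 1L
    sentences <- list()
    mentions <- empty_mentions()
    rel_src <- character(0)
    rel_tgt <- character(0)
    rel_typ <- character(0)
    for (si in seq_len(n_s)) {
      inst <- gen_sentence(templates[si], config$relation_mix)
      tree <- index_tree(inst$tree)
      if (config$noise_p > 0) tree <- perturb_tree(tree, config$noise_p)
      words <- tree_leaves(tree, "token")
      pos <- tree_leaves(tree, "label")
      line <- paste(words, collapse = " ")
      starts <- offset + c(0L, cumsum(nchar(words) + 1L))[seq_along(words)]
      tokens <- data.frame(text = words, start = starts,
                           end = starts + nchar(words), pos = pos,
                           stringsAsFactors = FALSE)
      sentences[[si]] <- annotated_sentence(
        start = offset, end = offset + nchar(line), tokens = tokens,
        tree = tree, deps = derive_dependencies(tree), frames = inst$frames,
        section_label = section)
      tid <- sprintf("T%d", nrow(mentions))
      mentions <- rbind(mentions, time_mention(
        tid, tokens$start[inst$time$from], tokens$end[inst$time$to],
        paste(words[inst$time$from:inst$time$to], collapse = " "),
        inst$time$type, sentence_index = si))
      eid <- sprintf("E%d", nrow(mentions))
      mentions <- rbind(mentions, event_mention(
        eid, tokens$start[inst$event$from], tokens$end[inst$event$to],
        paste(words[inst$event$from:inst$event$to], collapse = " "),
        inst$event$type, sentence_index = si))
      gold <- rbind(gold, data.frame(
        doc_id = doc_id, sentence_index = si, time_id = tid, event_id = eid,
        construction = inst$construction, is_direct = inst$is_direct,
        rel_type = if (inst$is_direct) inst$rel_type else NA_character_,
        stringsAsFactors = FALSE))
      if (inst$is_direct) {
        rel_src <- c(rel_src, tid)
        rel_tgt <- c(rel_tgt, eid)
        rel_typ <- c(rel_typ, inst$rel_type)
      }
      text_lines <- c(text_lines, line)
      offset <- offset + nchar(line) + 1L
    }
    text <- paste(text_lines, collapse = "\n")
    docs[[d]] <- new_document(doc_id, text, sentences, mentions,
                              relation_graph(rel_src, rel_tgt, rel_typ))
  }
  list(documents = docs, gold = gold)
}

#' Write a generated corpus to disk
#'
#' Emits one annotation XML and one sidecar analysis file per document, plus
#' a tab-separated gold table of per-pair direct/non-direct status.
#'
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (doc in corpus$documents) {
    write_annotations(doc, file.path(dir, paste0(doc$doc_id, ".xml")))
    write_sidecar(doc, file.path(dir, paste0(doc$doc_id, ".analysis.jsonl")))
  }
  utils::write.table(corpus$gold, file.path(dir, "gold_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
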