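---
title: "Direct temporal relations: model, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct temporal relations: model, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirtlink)
```

## The problem and the model

Temporal-relation annotation over clinical narratives conventionally
targets every relation inferable from a document. That set mixes two very
different populations: relations stated by the syntax of a single sentence,
and relations that only follow by chaining several pieces of temporal
information. `dirtlink` operationalizes the first population — *direct*
temporal relations between a time expression and a clinical event mention —
on the view that these are the basic building blocks from which the rest of
the network can be reconstructed by closure.

A candidate is any intra-sentential (time, event) pair. The pair is
**direct** when either

1. *modification*: the phrase headed by one mention modifies the phrase
   headed by the other, forming a larger grammatical element; or
2. *shared predicate*: both mentions head phrases that serve as arguments
   or adjuncts of one predicate, at least one of them an argument.

The head requirement is load-bearing: in *"resection of the left face
squamous cell cancer on 2016-03-13"* the date modifies the NP headed by
*resection*, not by the cancer mention, so the pair is non-direct. Three
exception cases relax the requirement where the relation is still read
directly off the surface:

* **PP case** — the mention heads the NP inside a PP (the preposition is
  the PP's formal head): *"two months of **diarrhea**"*.
* **Coordination case** — the mention heads one coordinate of a
  coordinated phrase: *"fever and **epigastric pain**"*.
* **Type-preserving case** — the mention heads a phrase embedded in a
  phrase whose semantic type it determines, e.g. *"an episode of
  [problem]"*. The shipped lexicon
  (`inst/extdata/type_preserving_phrases.txt`) contains five templates and
  is user-extensible; emptying it disables the case.

Direct relations carry a type in {`BEFORE`, `AFTER`, `OVERLAP`}, stored
canonically with the time expression as source.

## The closure algebra

The algebra is deliberately minimal: the three inversion rules plus four
compositions (`BEFORE∘BEFORE`, `BEFORE∘OVERLAP`, `OVERLAP∘BEFORE` give
`BEFORE`; `OVERLAP∘OVERLAP` gives `OVERLAP`). Nothing else composes — in
particular no Allen-style disjunctive labels are imported, and
`BEFORE∘AFTER` infers nothing. `AFTER` needs no composition entries of its
own: the closure is kept inverse-closed each pass, so `AFTER` chains follow
from the `BEFORE` entries. This is provably equivalent to hand-expanding a
nine-entry table and keeps the trusted core small; the test-suite checks
the implementation against an independent naive fixed-point oracle,
exhaustively over every graph on five mentions with up to three seed
relations and on random graphs.

Overlap is not transitive in the world (A may overlap B and B overlap C
with A and C disjoint), so closure can create pairs carrying two types.
These contradictions are retained in the closed graph and surfaced by
`find_contradictions()` — one row per unordered mention pair — rather than
resolved automatically: resolving them is an annotation decision, not an
algebraic one. During evaluation the gold side keeps all types of a
contradictory pair and a prediction matching any of them counts, and the
report flags that this happened.

## The rule engine

The engine is a pure function of the sentence analyses. It never parses:
tokens, POS tags, a Penn-style constituency tree, dependency edges and
predicate–argument frames arrive in a sidecar file (one JSON record per
sentence), so rule behaviour can be tested on gold analyses and parser
error studied separately (the `noise_p` knob of the generator corrupts
trees with controlled probability; accuracy degrades monotonically).

**Head finding** uses per-label scan rules in the classic head-percolation
style: NPs take the rightmost noun-like child, PPs the leftmost
preposition, VPs the leftmost verb, with a leftmost-child fallback for
unknown labels. Coordinated phrases are headed by their leftmost conjunct,
the usual convention, which also gives the coordination exception real
work to do for every non-initial coordinate. A constituent counts as
coordinated when two same-label children are separated by an explicit
conjunction, or three or more by commas; a comma with only two same-label
children is read as apposition or adjunction, not coordination.

**Projection.** For each mention the engine finds the largest constituent
whose lexical head falls inside the mention, then widens it through the
enabled exception cases, iterated to a fixed point — so a type-preserving
phrase can wrap a PP-widened projection. Whether annotators would chain
exceptions is not specified anywhere; chaining is this package's choice,
consistent with the goal of minimal-inference relations, and is covered by
a dedicated fixture in which disabling either case alone still leaves the
other operative.

**Modification** is detected between the two projection *chains* (every
constituent from the smallest covering node up to the final projection):
some member of one chain must be a direct child of, or a sibling of, a
member of the other. Sibling configurations under a clause or VP node are
excluded — co-children of a VP are related through the verb, which is the
shared-predicate rule's territory; without this exclusion every
verb-argument pair would masquerade as modification.

**Shared predicate** requires, within one frame, an argument/adjunct span
per mention that contains the mention and is covered by the mention's
projection — i.e. the mention (possibly via an exception) heads the whole
phrase filling the role — with at least one span an argument. When a
sentence carries no frames at all, an optional dependency fallback accepts
a verb to which both mention head tokens attach by a single edge; decisions
made this way are flagged `dependency_fallback` so provenance stays honest.

Non-direct pairs are explained: `NOT_HEAD` when a frame covers both
mentions or their lowest common ancestor is a phrase-level node (a
syntactic link exists but a head requirement failed), otherwise
`NO_SYNTACTIC_LINK`. Mentions whose tokens cross brackets get the smallest
covering node and an `aligned = FALSE` flag instead of an error.

## The classifier

Typing a direct relation often needs information the rules cannot see
("chest tubes were removed on post-op day 2" is *before*; "underwent
sigmoidoscopy Friday" is *overlap*), so a learner handles the four-way
decision {`OVERLAP`, `BEFORE`, `AFTER`, `NO_RELATION`}. Every enumerated
candidate pair absent from the gold direct set is a `NO_RELATION` training
instance; no negative subsampling happens by default (a ratio is available
in `train_config()`).

Features are sparse indicators and small counts: time type; event
type/polarity/modality; bags of mention tokens; three context tokens on
each side of each mention; the bag and count of in-between tokens;
in-between punctuation count; mention POS tags; tense × position of every
sentence verb (POS-derived: VBD/VBN past, VBZ/VBP present, MD future);
section label; enumeration-start and colon-end flags; the POS and surface
form of the lowest common dependency ancestor and a noun-on-path
indicator; each mention's predicate and a same-predicate indicator; and,
by default, the rule engine's verdict (`rule_direct`, rationale,
exception) as decision aids — switchable off in `train_config()` for
ablation.

The model is an SVM through `e1071` (LibSVM). Choices worth recording:

* **Multiclass reduction**: LibSVM's native one-vs-one voting. An
  alternative one-vs-rest design with explicit tie-breaking was
  considered; the native reduction was preferred because it is the
  established behaviour of the named implementation and is deterministic
  given fixed inputs.
* **Cost sensitivity**: per-class weights `w(t) = N/(K·count(t))`.
  "Inversely proportional" fixes only the ratios; this normalization makes
  the balanced case give unit weights so the regularization constant keeps
  its meaning, and satisfies `sum(count·w) = N`.
* **Kernel and C**: linear kernel, `C = 1` by default; binary indicator
  features of comparable scale make the linear kernel the natural default
  and leave little for an RBF kernel to add. A seeded cross-validation
  tuner over a small grid is available (`train_config(tune = TRUE)`) but
  is off by default so that default runs stay fast and exactly
  reproducible.
* **Post-processing** removes (never adds or retypes) predictions matching
  two patterns: a PROBLEM event paired with a FREQUENCY time whose surface
  form is in the medication-frequency lexicon ("bid", "prn", "q2h", ...,
  editable), and any pair with the token "where" strictly between the
  mentions. Both filters are idempotent.

## The synthetic generator and what passing tests mean

`generate_corpus()` emits documents whose sentences instantiate eight
templates — the five direct constructions, two non-direct ones (a
head-violating PP attachment and a cross-clause conjunction) and a
no-relation distractor containing a "where" clause — with gold trees,
dependencies (derived by head percolation) and frames consistent with the
surface string. Defaults: 100 documents of 4–8 sentences, template weights
0.17/0.17/0.16/0.12/0.12/0.10/0.08/0.08 in the order above, and a
66/18/16 overlap/before/after mix for direct pairs, the distribution
reported for direct-relation corpora; seed 7. Relation types in generated
text follow a fixed cue convention (on/during ↔ overlap, after/since ↔
before, before/until ↔ after, and the adverbs ago/afterward/beforehand in
the modification template), so the type is a deterministic function of
surface evidence — precisely the situation the classifier is supposed to
exploit.

Because gold analyses accompany every sentence, rule-engine accuracy on
generated corpora is 100% *by construction*: any failure is a rule bug,
not noise. The flip side is what passing does **not** show: generated
sentences are short, unambiguous, and have perfect trees and frames. Real
clinical text brings parser error (the dominant error source for this
task), PP-attachment ambiguity that the engine deliberately does not
re-resolve (it trusts the provided tree), misspellings, and type
assignments needing domain knowledge. Held-out macro-F1 near 1.0 on the
synthetic corpus validates the pipeline's mechanics, not clinical-grade
accuracy; the curated worked examples and snapshot sentences (realistic
prose with hand-built gold readings, including one whose gold attachment
makes the pair non-direct) are the harder, fixed probes.

## Numerical and format conventions

* Character offsets are 0-based half-open over the raw text everywhere;
  token indices are 1-based inclusive (the R convention) in trees,
  dependencies and frames.
* Closure iterates boolean matrix products to a fixed point; iteration
  order cannot affect the result, and all relation sets are kept in a
  canonical sort so outputs are byte-stable.
* TLINK labels outside {BEFORE, AFTER, OVERLAP} pass through an explicit
  map (`default_tlink_label_map()`): SIMULTANEOUS/DURING → OVERLAP,
  BEFORE_OVERLAP/ENDED_BY → BEFORE, BEGUN_BY → AFTER, chosen by endpoint
  semantics. The map is an argument, and an unmapped label is a hard
  error, never a silent skip.
* Evaluation metrics are reported on the 0–100 scale; micro-F1 is computed
  from summed counts. Cohen's kappa is also on 0–100, with the degenerate
  single-label perfect-agreement case defined as 100.
* Problem sizes used by the test-suite and acceptance script: the
  exhaustive closure sweep covers all 36,050 seed sets on five mentions
  plus 200 random graphs; the end-to-end experiment uses 334 documents
  (≈2,000 candidate pairs) with an 80/20 document split; the
  cost-sensitivity comparison uses 120 documents. These sizes give stable
  statistics while keeping a full run in the low minutes on one CPU.

## Known limitations

* The engine inherits its input analyses: a wrong attachment or a missing
  frame propagates to the decision. The dependency fallback recovers some
  shared-predicate cases but approximates roles by edge labels.
* The type-preserving lexicon ships with example templates only; coverage
  of real clinical phraseology requires extending it.
* Typing (as opposed to detecting) direct relations fundamentally needs
  common-sense/domain inference in many sentences; the feature set carries
  surface correlates of it, no more.
* Event–event and time–time relations, cross-sentence inference, and
  probabilistic merging of contradictory annotations are out of scope.
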