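---
title: "Mining connectivity statements: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining connectivity statements: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`conntext` extracts statements of neuroanatomical connectivity from abstract
text in four stages: recognize brain-region mentions, standardize them to
lexicon concepts, classify within-sentence mention pairs as connected or
not, and aggregate the predictions into species-specific connectivity
matrices. This vignette explains each model, the parameters that matter,
and the design decisions taken where more than one reasonable choice
existed. Every number quoted here is computed by the test-suite or by
`scripts/acceptance.R`; the vignette states no empirical result beyond
those.

## The recognition model

Mention recognition is a sequence-labelling problem: each token of a
sentence receives one of the three BIO states (Begin, Inside, Outside), and
maximal `B I*` runs decode to mention spans. We use the smallest label set
consistent with the task — BIO rather than BILOU — because the corpus
annotations are plain spans with no need for single-token or last-token
distinctions.

The labeller is a linear-chain conditional random field: state-feature
weights, a 3×3 transition matrix and an initial-state vector, trained by
L-BFGS on the penalized negative log-likelihood with gradients from
forward–backward. The objective adds an L2 penalty `c2 * ||theta||^2` with
`c2 = 1.0` and runs at most 200 iterations; both are exposed in
`train_ner()`. These are the standard defaults for this model family;
training is deterministic given the corpus order, so repeated fits give
identical predictions.

Feature families, per token (see `ner_config()`):

* **surrounding words** — lowercase surfaces of the token and its
  neighbours within a window of 2 on each side, position-tagged, with
  beginning/end-of-sentence markers;
* **word base forms** — Porter stems of the same window;
* **abbreviation expansion** — when a token is a document-defined short
  form, the words of its long form are added as features, so "SNC" can
  behave like "substantia nigra compact part" even in sentences far from
  the definition;
* **orthographic shape** — a compressed case/digit/punctuation shape
  ("SNc" → `Aa`), initial-capital, all-caps, has-digit and punctuation
  flags;
* **lexicon membership** (optional, off by default) — flags for tokens
  inside a longest dictionary match of any lexicon name.

The window default of 2 balances context against sparsity on
abstract-length sentences; it is a configuration parameter, not a tuned
constant. Decoding is Viterbi; an `I` that follows an `O` is repaired by
promotion to `B` so every decoded sequence is well-formed. Mentions whose
gold boundaries fall inside a token are snapped outward to token
boundaries at encoding time, which preserves recallable spans at the cost
of occasionally widening one.

Evaluation is span-based. In *exact* mode a true positive requires
identical spans. In *partial* mode any character overlap counts, with a
one-to-one greedy matching by overlap size and ties broken leftmost; the
matching rule is stated because partial-match scores are only reproducible
once it is fixed. Partial scores can never fall below exact scores under
this rule, which the property suite asserts. Cross-validation folds
partition *documents*, never sentences, so no abstract contributes to both
training and test; eight folds is the default.

## The standardization cascade

A mention string is mapped to lexicon concepts by a four-rung ladder, each
rung requiring **all** words or stems of the mention to match the lexicon
name:

1. case-insensitive exact match;
2. bag-of-words match (word multisets, so "reticular thalamic nucleus"
   matches "thalamic reticular nucleus");
3. exact match of Porter-stemmed strings;
4. bag-of-stems match.

Diacritics are folded to ASCII before stemming only — storage keeps
unicode as-is — so "nucleus raphé dorsalis" stems to
"nucleu raph dorsali". Note that the Latin genitive and the English form
keep distinct stems ("dorsali" vs "dorsal"); the two name variants are
separate lexicon entries of one concept, not stem-collapsed.

When the ladder fails, *modifiers* edit the mention, each sacrificing some
information: strip bracketed text, strip hemisphere qualifiers
(left/right/ipsi-/contra-/bilateral), strip one phrase-initial directional
prefix (anterior, posterior, dorsal, ventral, medial, lateral, rostral,
caudal), strip a trailing bare abbreviation, collapse
whitespace/punctuation, singularize a terminal plural. Two semantics were
open: whether edits accumulate, and whether the full ladder re-runs after
each edit. We apply modifiers **cumulatively in registry order** and
**re-run the full ladder after every edit that changed the string**,
stopping at the first rung with at least one concept. Cumulative
application matches the intuition that each edit progressively discards
detail; the full-ladder re-run means a word-order change introduced by an
edit is still caught by the bag rungs. The registry ships six concrete
modifiers and is extensible; a production deployment against real
lexicons would add more (the direction is the same: each added edit can
only increase coverage, which the monotonicity property asserts).

Ambiguity — several concepts surviving at the winning rung — is returned,
not resolved. Resolving it properly needs species and atlas context that
a lexical matcher does not have, and downstream aggregation prefers to
drop an ambiguous mention (precision first) rather than guess.

## The relation classifier

Candidate pairs are all unordered pairs of distinct mentions within one
sentence; cross-sentence connectivity is out of scope. Both mentions of a
pair are *blinded* — collapsed to placeholder tokens assigned by textual
order, with any other region mention in the sentence collapsed to a third,
role-free placeholder — so the classifier learns from context, not from
which regions are named.

Features follow the shallow linguistic kernel, "shallow" because no parse
trees are involved. The *global context* is three bags of stem n-grams
(n = 1..3) over the fore-between, between and between-after token windows.
The *local context* is position-tagged surface/stem/shape attributes of the
tokens within ±2 of each entity; the two entities' blocks are included
under both role tags, making the representation order-symmetric. The
relation is undirected (connection direction is not predicted), and
neighbouring entity placeholders are renamed to a role-free symbol in
feature strings, so swapping the two entities provably leaves the feature
map — hence the kernel and every prediction — unchanged; a test asserts
this invariance. The n-gram order and window width are configuration
parameters (`ngram_max`, `local_window`) with the defaults above.

The kernel is the sum of the cosine-normalized global and local dot
products, so `K(x, x) = 2` for any instance with non-empty blocks.
Equivalently, the explicit representation concatenates the two
L2-normalized blocks, and a linear kernel on that matrix *is* the summed
normalized kernel; the acceptance suite verifies the two routes agree to
1e-9 and that Gram matrices are positive semidefinite to 1e-8. The SVM is
fitted through the precomputed kernel matrix with cost `C = 1` and a
decision threshold of 0, both exposed; decision values are kept for
confidence ranking, and `score_decile_lengths()` reports mean sentence
length per score decile because sentence length correlates with
classification difficulty. Negative training examples are all co-mention
pairs not labelled connected — most of them sentences that merely mention
two regions.

## Triage

The abstract ranker is a Bernoulli naive Bayes: binary
presence/absence features over title+abstract words, journal name and MeSH
terms (kept as opaque strings, qualifiers included), with add-one
smoothing. A record's score is the sum of per-feature log-likelihood
ratios of its present known features plus the class-prior log odds. The
Bernoulli variant was chosen over multinomial because repetition of a word
within one abstract carries little signal for relevance ranking, and it
makes the exposed per-feature ratios directly interpretable (the most
positive ratios are the vocabulary that distinguishes connectivity
abstracts).

## Connectome assembly

Predicted, normalized pairs aggregate into symmetric count matrices — one
per species plus a pooled matrix. A document tagged with several species
contributes its pairs to every species matrix (duplication prevents
losing a connection when filtering by species) but once to the pooled
matrix. Unnormalized, ambiguous and self-pairs are excluded and tallied in
a skip report. `filter_by_support()` implements the precision/recall
trade: requiring a connection to be supported by at least *t* statements
zeroes weakly supported entries, with nested thresholds. Exports are a
square TSV (re-importable) and line-oriented RDF N-Triples — one
connects-with triple per supported pair plus one evidence triple per
supporting statement — so the extracted graph can be loaded into any
SPARQL store.

## The synthetic generator: what it emulates, and what not

`generate_corpus()` builds fully annotated abstracts: a title mentioning a
region, a species sentence (occasionally two species, exercising the
duplication rule), optionally an abbreviation definition "long form (SF)"
whose short form later mentions may use, and content sentences that either
assert a connection through one of twenty connective phrases or co-mention
two regions with no connectivity. Region names come from a bundled
50-concept lexicon and are corrupted with word-order shuffles, hemisphere
or directional qualifiers, and bracketed abbreviations — exactly the
variation the standardization cascade is designed to undo.

Defaults (in `synth_config()`): 5 content sentences per abstract;
connectivity probability 0.2 per content sentence, giving roughly the
positive-pair proportion curated relation corpora in this domain show
(about one pair in five); abbreviation probability 0.3; corruption
probabilities 0.1 (reorder), 0.1 (qualifier), 0.05 (bracket). Generation
is fully deterministic given the seed.

What the generator does **not** emulate: real syntactic variety
(conjunctions, enumerations, anaphora), hedged or negated statements,
regions absent from the lexicon, and non-mammalian vocabulary. Passing
recovery tests on this corpus therefore demonstrates that the machinery is
implemented correctly — BIO encoding, feature extraction, kernel algebra,
fold hygiene, the cascade — not that real-text accuracy is high. On real
curated corpora these methods are known to perform far below their
synthetic ceiling, and nothing here claims otherwise; reproducing
published real-text figures requires the external corpus and lexicons,
which are deliberately not bundled.

Problem sizes used by the standard runs were chosen to keep a full check
comfortably on one CPU while leaving no statistical doubt at the asserted
bounds: 200 documents for the cross-validation recovery runs (about 2,200
mentions and 1,000 labelled pairs), 300 corrupted names for the
standardization closed loop, 100 random instance pairs for the kernel
oracle.

## Numerical and degenerate-input choices

* Character offsets are 0-based half-open over "title + single space +
  abstract"; one coordinate system everywhere, converted only at the
  AirolaXML boundary (whose offsets are sentence-relative inclusive).
* Undefined precision/recall (zero denominator) is `NA`, serialized as
  JSON null, never silently 0; F1 of two zero rates is 0.
* Empty feature blocks contribute 0 to the kernel (an instance with no
  between-window tokens is valid); `K(x,x) = 2` holds only for
  non-degenerate instances.
* Ladder lookups are hash-exact on canonicalized keys; lexicon indexes are
  pure functions of the entry list, so rebuilding them cannot change
  match results.
* Fold assignment uses `sample(rep_len(1:k, n))` under a caller seed:
  balanced fold sizes, every document in exactly one test fold.
* Titles are included in mention extraction — titles of anatomical papers
  frequently name the studied regions, and excluding them would discard
  gold annotations; flagged as a choice since either convention is
  defensible.

## Known limitations

Connection direction is not extracted (matrices are symmetric), negated
("no projection was found") statements are not a separate class,
cross-sentence statements are invisible to a within-sentence classifier,
and the bundled lexicons are miniatures meant for testing and
demonstration. The CRF feature set captures the named feature families but
does not reproduce any particular historical toolkit's feature templates
bit-for-bit, so exact parity with previously published classifiers is not
claimed.
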