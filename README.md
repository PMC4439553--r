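# conntext

Neuroscience knows a great deal about which brain regions are anatomically
connected, but most of that knowledge is buried in decades of prose —
"the dorsal raphe nucleus projects to the caudate nucleus" — rather than in
databases. `conntext` is an R implementation of a literature-mining
pipeline that turns abstracts into connectivity data. It is written for
neuroinformaticians building literature-derived connectomes and for
text-mining researchers who want a fully testable, self-contained
implementation of the classic extraction stack.

The pipeline has four stages:

1. **Recognition** — a linear-chain conditional random field labels each
   token with a BIO state (Begin/Inside/Outside of a brain-region
   mention). For a token sequence $x$ and label sequence $y$,

   $$p(y \mid x) \propto \exp\Big(\sum_t \big(w^\top f(x, t, y_t) + T_{y_{t-1}, y_t}\big)\Big),$$

   trained by L-BFGS on the L2-penalized log-likelihood
   ($c_2\lVert\theta\rVert^2$, $c_2 = 1$). Features are surrounding
   words, Porter stems, orthographic shape, Schwartz–Hearst abbreviation
   expansions and optional lexicon flags.

2. **Standardization** — each mention is mapped to lexicon concepts
   through a matching ladder (case-insensitive exact → bag-of-words →
   stemmed → bag-of-stems), then through cumulative mention-editing
   modifiers (strip bracketed text, hemisphere qualifiers, directional
   prefixes, …) with the ladder re-run after each edit.

3. **Relation extraction** — every within-sentence mention pair is
   classified as connected / not connected by an SVM with the shallow
   linguistic kernel

   $$K(x, y) = \frac{K_g(x,y)}{\sqrt{K_g(x,x)K_g(y,y)}} + \frac{K_l(x,y)}{\sqrt{K_l(x,x)K_l(y,y)}},$$

   where $K_g$ counts shared stem n-grams ($n \le 3$) in the
   fore-between/between/between-after windows around the blinded entities
   and $K_l$ compares position-tagged token attributes within ±2 of each
   entity. The relation is undirected.

4. **Assembly** — predictions with standardized concepts and species tags
   aggregate into symmetric, species-specific connectivity matrices with
   per-statement provenance, a repetition-support filter, and TSV /
   RDF N-Triples exports.

A Bernoulli naive Bayes triage module ranks unlabeled abstracts by
similarity to a connectivity-positive training set, and a synthetic-corpus
generator produces fully annotated abstracts (planted mentions,
abbreviations, species, gold pairs) so that the entire pipeline is
testable without downloading anything.

## Worked example

```r
library(conntext)

# a fully annotated synthetic corpus of 40 abstracts
corp <- generate_corpus(synth_config(n_documents = 40, seed = 7))

# abstract-level cross-validation of the mention recognizer
cv <- cross_validate_ner(corp, k = 4, seed = 7)
cv$pooled$exact
#> tp=436 fp=8 fn=6  P=0.982 R=0.986 F1=0.984
cv$pooled$partial
#> tp=442 fp=2 fn=0  P=0.995 R=1.000 F1=0.998

# connectivity classification, with a confidence-ranked prediction table
rel <- cross_validate_relations(corp, k = 5, seed = 7)
rel$pooled
#> tp=30 fp=0 fn=0  P=1.000 R=1.000 F1=1.000
head(rel$ranked[, c("region_a", "region_b", "score", "predicted", "gold")], 3)
#>                      region_a               region_b    score predicted gold
#> 1      ventral tegmental area   basolateral amygdala 1.173402      TRUE TRUE
#> 2             caudate nucleus      entorhinal cortex 1.106582      TRUE TRUE
#> 3 ipsilateral dentate nucleus ventral tegmental area 1.034612      TRUE TRUE

# standardization: the cascade undoes qualifiers, brackets, word order
normalize_mention("left nucleus raphe dorsalis (DRN)", toy_region_lexicon())
#> $concept_ids  "cx:0003"
#> $match_stage  "modified:strip_hemisphere_qualifiers"
#> $edited_text  "nucleus raphe dorsalis"

# assemble species-specific connectivity matrices from gold pairs
nc  <- normalize_corpus(corp, toy_region_lexicon())
cc  <- collect_connections(nc, use = "gold")
agg <- aggregate_connections(cc$predictions, cc$doc_species)
agg$matrices$all
#> <cx_connmatrix> species=all: 31 regions, 30 connected pairs, 30 statements
agg$matrices[["10118"]]   # the rat-tagged subset
#> <cx_connmatrix> species=10118: 31 regions, 5 connected pairs, 5 statements
```

The exact-match scores count a prediction correct only when its span is
character-identical to a gold mention; partial scores credit any overlap,
so they bound the exact scores from above. Relation scores are SVM
decision values — higher means more confidently connected — and the
synthetic templates are separable by design, so near-perfect recovery is
the expected outcome on this corpus (real abstracts are far harder; see
the vignette).

A thin command-line front-end is installed at
`system.file("cli", "conntext.R", package = "conntext")` with
`simulate`, `preprocess`, `ner-cv`, `relations-cv`, `normalize` and
`aggregate` subcommands.

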