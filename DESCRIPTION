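Package: conntext
Title: Mining Brain-Region Connectivity Statements from the Neuroscience
    Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A text-mining pipeline that extracts statements of
    neuroanatomical connectivity from abstracts: conditional random field
    recognition of brain-region mentions over BIO-encoded token sequences,
    standardization of mentions to neuroanatomical lexicon concepts
    through an iterative matching cascade (exact, bag-of-words, stemmed,
    bag-of-stems, plus mention-editing modifiers), shallow linguistic
    kernel classification of within-sentence region pairs as connected or
    not, naive Bayes triage of abstracts, and aggregation of predictions
    into species-specific connectivity matrices.  Includes
    Schwartz-Hearst abbreviation expansion, dictionary species tagging,
    readers and writers for a JSONL corpus format and AirolaXML relation
    corpora, and a synthetic-corpus generator so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    kernlab,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
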