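# Fixtures built in code: a miniature lexicon with known structure, and a
# convenience wrapper around the synthetic generator.

mini_lexicon <- function() {
  new_lexicon(data.frame(
    concept_id = c("r1", "r2", "r3", "r4"),
    name = c("thalamic reticular nucleus", "dorsal raphe nucleus",
             "cochlear nucleus", "Substantia nigra pars compacta"),
    source = "fixture",
    is_preferred = TRUE,
    stringsAsFactors = FALSE
  ))
}

# a hand-built sentence: "the SNc projects to the striatum"
# offsets:                 0123456789...
hand_sentence <- function(text = "The SNc projects to the striatum.",
                          base = 0L) {
  cx_sentence(start = base, end = base + nchar(text),
              tokens = tokenize(text, base_offset = base))
}

small_corpus <- function(n = 12L, seed = 404L, ...) {
  generate_corpus(synth_config(n_documents = n, seed = seed, ...))
}

expect_metrics <- function(m, p, r, tol = 1e-12) {
  expect_s3_class(m, "cx_metrics")
  expect_equal(m$precision, p, tolerance = tol)
  expect_equal(m$recall, r, tolerance = tol)
}
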