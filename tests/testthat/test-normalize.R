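test_that("the matching ladder resolves worked examples at the right rung", {
  lex <- mini_lexicon()

  r <- normalize_mention("reticular thalamic nucleus", lex)
  expect_equal(r$concept_ids, "r1")
  expect_equal(r$match_stage, "bag_of_words")

  # case differences resolve at the exact rung
  r2 <- normalize_mention("substantia nigra pars compacta", lex)
  expect_equal(r2$concept_ids, "r4")
  expect_equal(r2$match_stage, "exact")

  # hemisphere qualifier resolved by the modifier cascade
  r3 <- normalize_mention("left dorsal raphe nucleus", lex)
  expect_equal(r3$concept_ids, "r2")
  expect_equal(r3$match_stage, "modified:strip_hemisphere_qualifiers")
  expect_equal(r3$edited_text, "dorsal raphe nucleus")

  r4 <- normalize_mention("contralateral cochlear nucleus", lex)
  expect_equal(r4$concept_ids, "r3")
  expect_equal(r4$match_stage, "modified:strip_hemisphere_qualifiers")

  miss <- normalize_mention("flux capacitor", lex)
  expect_length(miss$concept_ids, 0L)
  expect_true(is.na(miss$match_stage))
})

test_that("individual rungs behave per their definitions", {
  lex <- mini_lexicon()
  expect_equal(match_exact("Thalamic Reticular Nucleus", lex), "r1")
  expect_equal(match_bag_of_words("nucleus reticular thalamic", lex), "r1")
  expect_length(match_exact("nucleus reticular thalamic", lex), 0L)

  # stemming equates inflectional variants the exact rung cannot
  lex2 <- new_lexicon(data.frame(concept_id = "p1", name = "pontine nuclei",
                                 source = "f", is_preferred = TRUE))
  expect_length(match_exact("pontine nucleus", lex2), 0L)
  # whether the stems collide is decided by the shipped stemmer itself
  same_stem <- identical(stem_phrase("pontine nuclei"), stem_phrase("pontine nucleus"))
  expect_equal(length(match_stem("pontine nucleus", lex2)) == 1L, same_stem)

  # the latin-genitive synonym does NOT stem-match the english form:
  # "dorsali(s)" and "dorsal" keep distinct stems
  expect_false(stem_phrase("nucleus raphé dorsalis") ==
               stem_phrase("dorsal raphe nucleus"))
  expect_length(match_bag_of_stems("nucleus raphe dorsalis", lex), 0L)

  expect_length(match_bag_of_stems("flux capacitor", lex), 0L)
})

test_that("modifiers apply cumulatively in registry order", {
  seq <- apply_modifiers("dorsal raphe (DR) nucleus")
  expect_equal(seq$text[seq$modifier == "strip_bracketed_text"],
               "dorsal raphe nucleus")

  seq2 <- apply_modifiers("contralateral cochlear nucleus")
  expect_equal(seq2$text[seq2$modifier == "strip_hemisphere_qualifiers"],
               "cochlear nucleus")

  # untouched text: every step records the same string, nothing changed
  seq3 <- apply_modifiers("putamen")
  expect_true(all(seq3$text == "putamen"))
  expect_false(any(seq3$changed))

  mods <- default_modifiers()
  expect_equal(mods$singularize_terminal_plural("pontine nuclei"),
               "pontine nucleus")
  expect_equal(mods$collapse_whitespace_punct("cortico-thalamic  tract"),
               "cortico thalamic tract")
  expect_equal(mods$strip_parenthetical_abbrev("dorsal raphe DR"),
               "dorsal raphe")
})

test_that("ambiguity is returned unresolved and results are deterministic", {
  lex <- new_lexicon(data.frame(
    concept_id = c("a1", "a2"), name = c("medial nucleus", "medial nucleus"),
    source = "f", is_preferred = TRUE))
  r <- normalize_mention("medial nucleus", lex)
  expect_equal(r$concept_ids, c("a1", "a2"))
  r2 <- normalize_mention("medial nucleus", lex)
  expect_identical(r, r2)
})

test_that("lexicon names self-match exactly; permutations match by bag", {
  lex <- toy_region_lexicon()
  for (nm in sample(lex$entries$name, 12L)) {
    self <- normalize_mention(nm, lex)
    expect_equal(self$match_stage, "exact")
    words <- strsplit(nm, " ")[[1L]]
    if (length(words) > 1L) {
      perm <- paste(rev(words), collapse = " ")
      r <- normalize_mention(perm, lex)
      expect_true(r$match_stage %in% c("exact", "bag_of_words"))
      expect_true(lex$entries$concept_id[lex$entries$name == nm] %in%
                  r$concept_ids)
    }
  }
})

test_that("enabling modifiers never decreases coverage", {
  lex <- toy_region_lexicon()
  cfg <- synth_config(n_documents = 1L, seed = 1L, p_reorder = 0.5,
                      p_qualifier = 0.5, p_bracket = 0.4)
  set.seed(303)
  queries <- replicate(60, {
    row <- lex$entries[sample(nrow(lex$entries), 1L), ]
    corrupt_region_name(row$name, cfg)$text
  })
  bare <- vapply(queries, function(q)
    length(normalize_mention(q, lex, modifiers = list())$concept_ids) > 0,
    logical(1))
  full <- vapply(queries, function(q)
    length(normalize_mention(q, lex)$concept_ids) > 0, logical(1))
  expect_true(all(full >= bare))
  expect_gte(mean(full), mean(bare))
})

test_that("normalization evaluation reports coverage, metrics and stages", {
  gold <- setNames(paste0("c", 1:10), paste0("m", 1:10))
  results <- lapply(1:10, function(i) {
    if (i <= 5) list(concept_ids = paste0("c", i), match_stage = "exact")
    else if (i == 6) list(concept_ids = "wrong", match_stage = "bag_of_words")
    else list(concept_ids = character(), match_stage = NA_character_)
  })
  names(results) <- names(gold)
  ev <- evaluate_normalization(gold, results)
  expect_equal(ev$coverage, 0.6)
  expect_equal(ev$metrics$precision, 5 / 6)
  expect_equal(ev$metrics$recall, 0.5)
  expect_equal(unname(ev$stage_counts["exact"]), 5L)

  # all correct
  all_ok <- lapply(seq_along(gold), function(i)
    list(concept_ids = gold[[i]], match_stage = "exact"))
  names(all_ok) <- names(gold)
  ev2 <- evaluate_normalization(gold, all_ok)
  expect_equal(ev2$coverage, 1)
  expect_equal(ev2$metrics$f1, 1)

  # none matched: coverage 0 and precision undefined (null)
  none <- lapply(seq_along(gold), function(i)
    list(concept_ids = character(), match_stage = NA_character_))
  names(none) <- names(gold)
  ev3 <- evaluate_normalization(gold, none)
  expect_equal(ev3$coverage, 0)
  expect_true(is.na(ev3$metrics$precision))
})
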