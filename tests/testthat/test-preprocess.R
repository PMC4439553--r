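test_that("sentence splitting respects abbreviations and covers the text", {
  s <- split_sentences("A projects to B. C receives input from D.")
  expect_equal(nrow(s), 2L)

  s2 <- split_sentences("The nucleus (e.g., VPM) is large. It projects.")
  expect_equal(nrow(s2), 2L)
  expect_equal(span_text("The nucleus (e.g., VPM) is large. It projects.",
                         s2$start[2], s2$end[2]), "It projects.")

  expect_equal(nrow(split_sentences("")), 0L)

  # spans cover all non-whitespace characters, ordered and disjoint
  text <- "First finding. Second finding follows.  Third, shorter."
  sp <- split_sentences(text)
  expect_true(all(diff(sp$start) > 0))
  covered <- unlist(Map(seq, sp$start + 1L, sp$end))
  chars <- strsplit(text, "")[[1L]]
  expect_true(all(grepl("\\s", chars[-covered])))
})

test_that("tokenization splits punctuation and hyphens, stems attached", {
  tk <- tokenize("projects to the SNc.")
  expect_equal(tk$surface, c("projects", "to", "the", "SNc", "."))
  expect_equal(tokenize("cortico-thalamic")$surface,
               c("cortico", "-", "thalamic"))
  expect_equal(tokenize("nucleus raphé dorsalis")$stem,
               c("nucleu", "raph", "dorsali"))

  # surfaces equal the text slices; concatenation reconstructs the sentence
  text <- "The cortico-thalamic (CT) loop, broadly."
  tk2 <- tokenize(text)
  expect_equal(tk2$surface, span_text(text, tk2$start, tk2$end))
  gaps <- strrep(" ", c(tk2$start[-1L], nchar(text)) - tk2$end)
  expect_equal(paste0(tk2$surface, gaps, collapse = ""),
               paste0(text, strrep(" ", nchar(text) - tk2$end[nrow(tk2)])))
})

test_that("abbreviation definitions are found per Schwartz-Hearst", {
  ab <- extract_abbreviations("substantia nigra compact part (SNC) neurons")
  expect_equal(ab$short_form, "SNC")
  expect_equal(ab$long_form, "substantia nigra compact part")

  # all-numeric candidate rejected
  expect_equal(nrow(extract_abbreviations("the area (17) of cortex")), 0L)

  # definition site span lies on the parenthetical
  txt <- "ventral tegmental area (VTA) and VTA efferents"
  ab2 <- extract_abbreviations(txt)
  expect_equal(nrow(ab2), 1L)
  expect_equal(span_text(txt, ab2$start, ab2$end), "(VTA)")

  # short-form characters must trace through the long form in order
  expect_equal(nrow(extract_abbreviations("the big toe (XYZ) here")), 0L)
})

test_that("short-form validity rules hold on random planted definitions", {
  lex <- toy_region_lexicon()
  multi <- lex$entries$name[lengths(strsplit(lex$entries$name, " ")) >= 2L]
  set.seed(2024)
  n_found <- 0L; n_valid <- 0L
  for (i in seq_len(120L)) {
    nm <- sample(multi, 1L)
    sf <- toupper(paste(substring(strsplit(nm, " ")[[1L]], 1L, 1L),
                        collapse = ""))
    txt <- sprintf("Neurons of the %s (%s) were labeled.", nm, sf)
    valid <- nchar(sf) >= 2L && nchar(sf) <= 10L
    ab <- extract_abbreviations(txt)
    if (valid) {
      n_valid <- n_valid + 1L
      if (nrow(ab) == 1L && ab$short_form == sf && ab$long_form == nm) {
        n_found <- n_found + 1L
      }
    }
  }
  expect_gt(n_valid, 100L)
  expect_equal(n_found, n_valid)  # every valid planted definition recovered
})

test_that("expansion annotates standalone short forms only", {
  text <- "The substantia nigra compact part (SNC) was injected. The SNC and SNCA differ."
  doc <- preprocess_document("d", text)
  ab <- extract_abbreviations(text)
  sent2 <- doc$sentences[[2]]
  # plant mentions over "SNC" and "SNCA"
  g <- gregexpr("SNCA?", text)[[1]]
  starts <- as.integer(g); lens <- attr(g, "match.length")
  sel <- starts > sent2$start
  sent2$mentions <- mention_frame(
    start = starts[sel] - 1L, end = starts[sel] - 1L + lens[sel],
    surface = substring(text, starts[sel], starts[sel] + lens[sel] - 1L))
  out <- expand_abbreviations(sent2, ab)
  expect_equal(out$mentions$expanded[out$mentions$surface == "SNC"],
               "substantia nigra compact part")
  expect_equal(out$mentions$expanded[out$mentions$surface == "SNCA"], "SNCA")

  # no short forms: unchanged; conflicting definitions: first one kept
  expect_identical(expand_abbreviations(sent2, ab[0, ]), sent2)
  dup <- rbind(ab, data.frame(short_form = "SNC", long_form = "something else",
                              start = 0L, end = 1L))
  expect_warning(out2 <- expand_abbreviations(sent2, dup), "conflicting")
  expect_equal(out2$mentions$expanded[out2$mentions$surface == "SNC"],
               "substantia nigra compact part")
})

test_that("species tagging is case-insensitive, longest-match, sorted", {
  doc <- preprocess_document("s1", "Tracers were injected in the rat and cat brain.")
  tags <- doc$species
  expect_equal(tags$name, c("rat", "cat"))
  expect_equal(tags$taxon_id, c("10118", "9685"))

  doc2 <- preprocess_document("s2", "No animals are named here.")
  expect_equal(nrow(doc2$species), 0L)

  # longest match wins over an embedded shorter name
  doc3 <- preprocess_document("s3", "Studies in the rhesus monkey cortex.")
  expect_equal(doc3$species$name, "rhesus monkey")
  expect_equal(doc3$species$taxon_id, "9544")

  # property: sorted, non-overlapping spans over random species sequences
  lex <- load_species_lexicon()
  set.seed(5)
  for (i in 1:20) {
    nm <- sample(names(lex), 3L)
    doc <- preprocess_document("p", paste("Seen in", nm[1], "and", nm[2],
                                          "but not", nm[3], "."))
    tg <- doc$species
    if (nrow(tg) > 1L) {
      expect_true(all(diff(tg$start) > 0))
      expect_true(all(tg$start[-1L] >= tg$end[-nrow(tg)]))
    }
    expect_true(all(nzchar(tg$taxon_id)))
  }
})
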