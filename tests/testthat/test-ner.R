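test_that("BIO encoding marks mention tokens and round-trips", {
  text <- "the substantia nigra is large"
  sent <- cx_sentence(0L, nchar(text), tokens = tokenize(text))
  sent$mentions <- mention_frame(start = 4L, end = 20L,
                                 surface = "substantia nigra")
  expect_equal(encode_bio(sent), c("O", "B", "I", "O", "O"))

  # no mentions -> all O; adjacent mentions -> B B
  empty <- cx_sentence(0L, nchar(text), tokens = tokenize(text))
  expect_equal(encode_bio(empty), rep("O", 5))

  t2 <- "caudate putamen"
  s2 <- cx_sentence(0L, nchar(t2), tokens = tokenize(t2))
  s2$mentions <- mention_frame(start = c(0L, 8L), end = c(7L, 15L),
                               surface = c("caudate", "putamen"))
  expect_equal(encode_bio(s2), c("B", "B"))

  # overlapping gold mentions are a corpus error
  s3 <- cx_sentence(0L, nchar(text), tokens = tokenize(text))
  s3$mentions <- mention_frame(start = c(4L, 15L), end = c(20L, 29L),
                               surface = span_text(text, c(4L, 15L), c(20L, 29L)))
  expect_error(encode_bio(s3), "overlapping")
})

test_that("decode(encode(x)) recovers mentions on generated sentences", {
  corp <- small_corpus(n = 6L, seed = 31L)
  for (doc in corp$documents) {
    for (sent in doc$sentences) {
      labels <- encode_bio(sent)
      back <- decode_bio(sent, labels, text = doc$text)
      expect_equal(back[c("start", "end", "surface")],
                   sent$mentions[order(sent$mentions$start),
                                 c("start", "end", "surface")],
                   ignore_attr = TRUE)
    }
  }
})

test_that("illegal I-after-O decoding is repaired into one mention", {
  text <- "alpha beta gamma"
  sent <- cx_sentence(0L, nchar(text), tokens = tokenize(text))
  m <- decode_bio(sent, c("O", "I", "I"))
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 6L)
  expect_equal(m$end, 16L)
  expect_equal(m$surface, "beta gamma")
  expect_equal(nrow(decode_bio(sent, c("O", "O", "O"))), 0L)
})

test_that("token features include windowed context and expansions", {
  sent <- hand_sentence("the SNc projects")
  f <- featurize_token(sent, 2L, ner_config(window = 1L))
  expect_true("w=snc" %in% f)
  expect_true("w@-1=the" %in% f)
  expect_true("w@+1=projects" %in% f)
  expect_true("sh=Aa" %in% f)  # orthographic shape family ("SNc" -> Aa)
  expect_true("cap" %in% f)

  ab <- data.frame(short_form = "SNc",
                   long_form = "substantia nigra pars compacta",
                   start = 0L, end = 1L)
  f2 <- featurize_token(sent, 2L, ner_config(window = 1L), abbrevs = ab)
  expect_true(all(c("xw=substantia", "xw=compacta") %in% f2))

  # window 0, no lexicon: only token-local features
  f3 <- featurize_token(sent, 2L, ner_config(window = 0L))
  expect_false(any(grepl("@", f3)))

  # lexicon membership flags
  cfg <- ner_config(window = 0L, lexicon = mini_lexicon())
  s4 <- hand_sentence("the dorsal raphe nucleus projects")
  f4 <- lapply(seq_len(5), function(i) featurize_token(s4, i, cfg))
  expect_false("inlex" %in% f4[[1]])
  expect_true(all(vapply(f4[2:4], function(f) "inlex" %in% f, logical(1))))
  expect_true("inlex_b" %in% f4[[2]])
})

test_that("mention evaluation counts exact and partial matches correctly", {
  g <- mention_frame(start = 5L, end = 20L, surface = "x")
  p_same <- mention_frame(start = 5L, end = 20L, surface = "x")
  expect_metrics(evaluate_ner(g, p_same, "exact"), 1, 1)

  p_part <- mention_frame(start = 5L, end = 15L, surface = "x")
  expect_metrics(evaluate_ner(g, p_part, "exact"), 0, 0)
  expect_metrics(evaluate_ner(g, p_part, "partial"), 1, 1)

  # hand-counted: 3 gold, 2 predictions, 1 exact match
  g3 <- mention_frame(start = c(0L, 10L, 30L), end = c(5L, 20L, 40L),
                      surface = c("a", "b", "c"))
  p2 <- mention_frame(start = c(10L, 50L), end = c(20L, 60L),
                      surface = c("b", "z"))
  expect_metrics(evaluate_ner(g3, p2, "exact"), 0.5, 1 / 3)
})

test_that("partial-match metrics are never below exact-match metrics", {
  set.seed(88)
  for (i in 1:40) {
    ng <- sample(0:5, 1); np <- sample(0:5, 1)
    gs <- sort(sample(0:60, ng)) * 2L
    ps <- sort(sample(0:60, np)) * 2L
    g <- mention_frame(start = gs, end = gs + sample(2:8, ng, TRUE),
                       surface = rep("g", ng))
    p <- mention_frame(start = ps, end = ps + sample(2:8, np, TRUE),
                       surface = rep("p", np))
    ex <- evaluate_ner(g, p, "exact")
    pa <- evaluate_ner(g, p, "partial")
    if (!is.na(ex$precision)) expect_gte(pa$precision, ex$precision)
    if (!is.na(ex$recall)) expect_gte(pa$recall, ex$recall)
  }
})

test_that("training learns separable templated data and is deterministic", {
  corp <- small_corpus(n = 20L, seed = 77L)
  model <- train_ner(corp, ner_config(), maxit = 150L)
  counts <- c(tp = 0, fp = 0, fn = 0)
  for (doc in corp$documents) {
    ab <- extract_abbreviations(doc$text)
    for (sent in doc$sentences) {
      m <- evaluate_ner(sent$mentions,
                        predict_mentions(model, sent, ab, text = doc$text),
                        "exact")
      counts <- counts + c(m$tp, m$fp, m$fn)
    }
  }
  train_fit <- compute_metrics(counts[1], counts[2], counts[3])
  expect_gte(train_fit$f1, 0.95)

  # same data twice -> identical predictions on a held-out fixture
  model2 <- train_ner(corp, ner_config(), maxit = 150L)
  held <- generate_corpus(synth_config(n_documents = 2L, seed = 909L))
  for (doc in held$documents) {
    for (sent in doc$sentences) {
      expect_identical(predict_mentions(model, sent, text = doc$text),
                       predict_mentions(model2, sent, text = doc$text))
    }
  }

  expect_error(train_ner(cx_corpus(list())), "empty")
  no_mentions <- cx_corpus(list(preprocess_document("n", "Nothing here.")))
  expect_error(train_ner(no_mentions), "no gold mentions")
})

test_that("fold assignment partitions documents and is seed-stable", {
  f <- make_folds(8L, 8L, seed = 4L)
  expect_setequal(f, 1:8)  # each document held out exactly once
  f2 <- make_folds(40L, 8L, seed = 9L)
  expect_identical(f2, make_folds(40L, 8L, seed = 9L))
  expect_equal(sort(unique(f2)), 1:8)
  expect_error(make_folds(5L, 8L, seed = 1L), "more folds")
})

test_that("cross-validation pools held-out metrics over document folds", {
  corp <- small_corpus(n = 16L, seed = 13L)
  cv <- cross_validate_ner(corp, k = 4L, seed = 2L, maxit = 120L)
  expect_length(cv$folds, 16L)
  expect_equal(sort(unique(cv$folds)), 1:4)
  # micro identity: pooled counts are the fold sums
  expect_equal(cv$pooled$exact$tp,
               sum(vapply(cv$per_fold, function(x) x$exact$tp, integer(1))))
  expect_gte(cv$pooled$partial$recall, cv$pooled$exact$recall)
})
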