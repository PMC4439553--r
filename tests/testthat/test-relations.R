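make_pair_sentence <- function(text, spans) {
  sent <- cx_sentence(0L, nchar(text), tokens = tokenize(text))
  sent$mentions <- mention_frame(start = spans[, 1], end = spans[, 2],
                                 surface = span_text(text, spans[, 1], spans[, 2]))
  sent$pairs <- generate_pairs(sent)
  sent
}

test_that("candidate pair generation follows m(m-1)/2 combinatorics", {
  text <- "alpha nucleus and beta field and gamma area interact"
  spans <- rbind(c(0L, 13L), c(18L, 28L), c(33L, 43L))
  sent <- make_pair_sentence(text, spans)
  expect_equal(nrow(sent$pairs), 3L)
  expect_true(all(sent$pairs$a_start <= sent$pairs$b_start))

  one <- make_pair_sentence(text, spans[1, , drop = FALSE])
  expect_equal(nrow(one$pairs), 0L)

  # identical surfaces at different spans still form one pair
  t2 <- "the SNc and the SNc again"
  s2 <- make_pair_sentence(t2, rbind(c(4L, 7L), c(16L, 19L)))
  expect_equal(nrow(s2$pairs), 1L)
})

test_that("entity blinding collapses mentions into placeholders", {
  text <- "the SNc projects to the striatum"
  sent <- make_pair_sentence(text, rbind(c(4L, 7L), c(24L, 32L)))
  inst <- blind_entities(sent, sent$pairs[1, ])
  expect_equal(inst$tokens$surface,
               c("the", "ENTITY_A", "projects", "to", "the", "ENTITY_B"))
  expect_equal(inst$a_index, 2L)
  expect_equal(inst$b_index, 6L)

  # a third mention becomes ENTITY_O; multi-token mentions collapse to one
  t3 <- "the dorsal raphe nucleus and the SNc innervate the striatum"
  s3 <- make_pair_sentence(t3, rbind(c(4L, 24L), c(33L, 36L), c(51L, 59L)))
  inst3 <- blind_entities(s3, s3$pairs[s3$pairs$a_start == 4L &
                                       s3$pairs$b_start == 33L, ])
  expect_equal(inst3$tokens$surface,
               c("the", "ENTITY_A", "and", "the", "ENTITY_B", "innervate",
                 "the", "ENTITY_O"))

  bad <- pair_frame(a_start = 4L, a_end = 24L, b_start = 10L, b_end = 30L)
  expect_error(blind_entities(s3, bad), "overlapping")
})

test_that("global context n-grams enumerate the between window", {
  text <- "the SNc projects to the striatum"
  sent <- make_pair_sentence(text, rbind(c(4L, 7L), c(24L, 32L)))
  f <- slk_features(blind_entities(sent, sent$pairs[1, ]))
  expect_true(all(c("G|B|1|project", "G|B|1|to", "G|B|1|the") %in%
                  names(f$global)))
  expect_true("G|B|2|project_to" %in% names(f$global))
  expect_true("G|B|3|project_to_the" %in% names(f$global))
  # fore-between includes the leading token, between alone does not
  expect_true("G|FB|1|the" %in% names(f$global))
  expect_equal(unname(f$global["G|FB|1|the"]), 2)

  # adjacent entities: empty between window, vector still valid
  t2 <- "SNc striatum linked"
  s2 <- make_pair_sentence(t2, rbind(c(0L, 3L), c(4L, 12L)))
  f2 <- slk_features(blind_entities(s2, s2$pairs[1, ]))
  expect_false(any(grepl("^G\\|B\\|", names(f2$global))))
  expect_gt(length(f2$local), 0L)
})

test_that("kernel is self-normalized, symmetric, bounded and PSD", {
  corp <- small_corpus(n = 12L, seed = 51L)
  coll <- conntext:::.collect_relation_instances(corp)
  inst <- coll$instances
  expect_gte(length(inst), 10L)
  f <- lapply(inst, slk_features)

  expect_equal(slk_kernel(f[[1]], f[[1]]), 2, tolerance = 1e-12)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(slk_kernel(f[[i]], f[[j]]), slk_kernel(f[[j]], f[[i]]),
                 tolerance = 1e-12)
    expect_gte(slk_kernel(f[[i]], f[[j]]), 0)
    expect_lte(slk_kernel(f[[i]], f[[j]]), 2 + 1e-12)
  }

  n <- min(length(f), 25L)
  K <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) slk_kernel(f[[i]], f[[j]])))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  # disjoint instances score zero
  ta <- "alpha beta linked here"
  sa <- make_pair_sentence(ta, rbind(c(0L, 5L), c(6L, 10L)))
  tb <- "gamma delta joined there"
  sb <- make_pair_sentence(tb, rbind(c(0L, 5L), c(6L, 11L)))
  ia <- blind_entities(sa, sa$pairs[1, ])
  ib <- blind_entities(sb, sb$pairs[1, ])
  fa <- slk_features(ia); fb <- slk_features(ib)
  expect_true(length(intersect(names(fa$global), names(fb$global))) == 0L)
  fa$local <- fa$local[0]; fb$local <- fb$local[0]
  expect_equal(slk_kernel(fa, fb), 0)
})

test_that("kernel values equal explicit normalized feature dot products", {
  corp <- small_corpus(n = 15L, seed = 61L)
  f <- lapply(conntext:::.collect_relation_instances(corp)$instances,
              slk_features)
  em <- conntext:::.slk_matrix(f)
  G <- as.matrix(Matrix::tcrossprod(em$X))
  set.seed(1)
  for (rep in 1:50) {
    ij <- sample(length(f), 2L, replace = TRUE)
    expect_equal(slk_kernel(f[[ij[1]]], f[[ij[2]]]), G[ij[1], ij[2]],
                 tolerance = 1e-9)
  }
})

test_that("swapping the two entities leaves features and scores unchanged", {
  corp <- small_corpus(n = 10L, seed = 71L)
  coll <- conntext:::.collect_relation_instances(corp)
  swap <- function(inst) {
    s <- inst
    a <- s$a_index; b <- s$b_index
    s$tokens$surface[c(a, b)] <- s$tokens$surface[c(b, a)]
    s$tokens$stem[c(a, b)] <- s$tokens$stem[c(b, a)]
    s$a_index <- a; s$b_index <- b  # roles relabelled, text order fixed
    s
  }
  model <- train_relation_classifier(coll$instances, coll$info$gold)
  swapped <- lapply(coll$instances, swap)
  expect_equal(predict_relations(model, swapped)$score,
               predict_relations(model, coll$instances)$score,
               tolerance = 1e-9)
})

test_that("SVM separates templated data and matches a linear-kernel oracle", {
  skip_if_not_installed("e1071")
  corp <- small_corpus(n = 14L, seed = 81L)
  coll <- conntext:::.collect_relation_instances(corp)
  keep <- seq_len(min(50L, length(coll$instances)))
  f <- lapply(coll$instances[keep], slk_features)
  y <- coll$info$gold[keep]
  model <- train_relation_classifier(f, y, C = 1)
  pred <- predict_relations(model, f)
  expect_equal(mean(pred$predicted == y), 1)  # separable by construction

  # decision values agree with an independent linear SVM on the explicit
  # normalized feature matrix (same kernel, different solver)
  X <- as.matrix(conntext:::.slk_matrix(f)$X)
  or <- e1071::svm(X, factor(y, levels = c(FALSE, TRUE)), kernel = "linear",
                   cost = 1, scale = FALSE)
  dec <- attr(predict(or, X, decision.values = TRUE),
              "decision.values")[, 1]
  if (cor(dec, pred$score) < 0) dec <- -dec
  expect_gt(cor(dec, pred$score), 0.999)
  expect_equal(mean((dec > 0) == pred$predicted), 1)

  expect_error(train_relation_classifier(f, y, C = 0), "positive")
  expect_error(train_relation_classifier(f, rep(TRUE, length(f))), "both classes")

  # same data and settings reproduce the same support-vector count
  model2 <- train_relation_classifier(f, y, C = 1)
  expect_equal(model$n_sv, model2$n_sv)
})

test_that("relation cross-validation predicts every pair exactly once", {
  corp <- small_corpus(n = 14L, seed = 91L)
  cv <- cross_validate_relations(corp, k = 7L, seed = 5L)
  expect_false(any(is.na(cv$ranked$score)))
  n_pairs <- sum(vapply(corp$documents, function(d)
    sum(vapply(d$sentences, function(s) sum(!is.na(s$pairs$gold_label)),
               integer(1))), integer(1)))
  expect_equal(nrow(cv$ranked), n_pairs)
  expect_identical(cv$pooled$tp + cv$pooled$fn, sum(cv$ranked$gold))

  cv2 <- cross_validate_relations(corp, k = 7L, seed = 5L)
  expect_equal(cv$pooled$f1, cv2$pooled$f1)

  dl <- score_decile_lengths(cv$ranked)
  expect_equal(sum(dl$n), n_pairs)
  expect_error(cross_validate_relations(corp, k = 50L, seed = 1L), "folds")
})
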