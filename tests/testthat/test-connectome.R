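pred_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(doc_id = r[[1]], sentence_index = as.integer(r[[2]]),
               concept_a = r[[3]], concept_b = r[[4]],
               score = if (length(r) > 4) as.numeric(r[[5]]) else 1,
               stringsAsFactors = FALSE)
  }))
}

test_that("aggregation counts statements with full provenance", {
  preds <- pred_df(list("d1", 3, "A", "B"), list("d2", 1, "B", "A"))
  sp <- data.frame(doc_id = c("d1", "d2"), taxon_id = c("10116", "10116"))
  agg <- aggregate_connections(preds, sp)
  m <- agg$matrices[["10116"]]
  expect_equal(m$counts["A", "B"], 2L)
  expect_equal(m$counts["B", "A"], 2L)  # symmetric, unordered pair
  expect_equal(nrow(m$provenance), 2L)
  expect_equal(agg$matrices$all$counts["A", "B"], 2L)
})

test_that("multi-species documents duplicate into each species matrix", {
  preds <- pred_df(list("d1", 2, "A", "B"))
  sp <- data.frame(doc_id = c("d1", "d1"), taxon_id = c("10116", "9685"))
  agg <- aggregate_connections(preds, sp)
  expect_equal(agg$matrices[["10116"]]$counts["A", "B"], 1L)
  expect_equal(agg$matrices[["9685"]]$counts["A", "B"], 1L)
  # the pooled matrix counts the document once
  expect_equal(agg$matrices$all$counts["A", "B"], 1L)
})

test_that("unnormalized and ambiguous pairs are excluded and reported", {
  preds <- pred_df(list("d1", 1, "A", "B"),
                   list("d1", 2, NA, "B"),
                   list("d1", 3, "A|C", "B"),
                   list("d1", 4, "A", "A"))
  sp <- data.frame(doc_id = "d1", taxon_id = "10116")
  agg <- aggregate_connections(preds, sp)
  expect_equal(unname(agg$skipped),
               c(1L, 1L, 1L))  # unnormalized, ambiguous, self
  expect_equal(sum(agg$matrices$all$counts), 2L)  # one pair, two cells
})

test_that("statement contributions are conserved under species duplication", {
  corp <- generate_corpus(synth_config(n_documents = 25L, seed = 77L))
  corp <- normalize_corpus(corp, toy_region_lexicon())
  cc <- collect_connections(corp, use = "gold")
  agg <- aggregate_connections(cc$predictions, cc$doc_species)
  kept <- nrow(cc$predictions) - sum(agg$skipped)
  per_species <- vapply(agg$matrices[names(agg$matrices) != "all"],
                        function(m) nrow(m$provenance), integer(1))
  # each kept prediction appears once per species tag of its document
  tags_per_doc <- table(cc$doc_species$doc_id)
  kept_rows <- cc$predictions[!is.na(cc$predictions$concept_a) &
                              !is.na(cc$predictions$concept_b) &
                              !grepl("|", cc$predictions$concept_a, fixed = TRUE) &
                              !grepl("|", cc$predictions$concept_b, fixed = TRUE) &
                              cc$predictions$concept_a != cc$predictions$concept_b, ]
  expected <- sum(tags_per_doc[kept_rows$doc_id])
  expect_equal(sum(per_species), expected)
  expect_equal(nrow(agg$matrices$all$provenance), kept)
})

test_that("support filtering is the identity at 1 and nested beyond", {
  preds <- pred_df(list("d1", 1, "A", "B"), list("d2", 1, "A", "B"),
                   list("d3", 1, "A", "C"), list("d4", 1, "B", "C"),
                   list("d5", 1, "B", "C"), list("d6", 1, "B", "C"))
  sp <- data.frame(doc_id = paste0("d", 1:6), taxon_id = "10116")
  m <- aggregate_connections(preds, sp)$matrices$all
  expect_identical(filter_by_support(m, 1L), m)
  f2 <- filter_by_support(m, 2L)
  expect_equal(f2$counts["A", "C"], 0L)
  expect_equal(f2$counts["A", "B"], 2L)
  expect_equal(f2$counts["B", "C"], 3L)
  expect_equal(nrow(f2$provenance), 5L)

  # nesting over random matrices: support at t+1 is a subset of support at t
  set.seed(12)
  for (rep in 1:10) {
    rows <- lapply(1:20, function(i) {
      ab <- sort(sample(LETTERS[1:5], 2L))
      list(paste0("d", i), 1L, ab[1], ab[2])
    })
    mm <- aggregate_connections(do.call(pred_df, rows),
                                data.frame(doc_id = paste0("d", 1:20),
                                           taxon_id = "x"))$matrices$all
    for (t in 1:3) {
      a <- filter_by_support(mm, t)
      b <- filter_by_support(mm, t + 1L)
      expect_true(all(which(b$counts > 0) %in% which(a$counts > 0)))
    }
  }
})

test_that("TSV round-trips and N-Triples counts follow the matrix", {
  preds <- pred_df(list("d1", 1, "A", "B"), list("d2", 2, "A", "B"),
                   list("d3", 1, "A", "B"))
  sp <- data.frame(doc_id = paste0("d", 1:3), taxon_id = "10116")
  m <- aggregate_connections(preds, sp)$matrices$all

  tf <- withr::local_tempfile(fileext = ".tsv")
  export_matrix(m, tf, "tsv")
  back <- read_matrix_tsv(tf)
  expect_identical(back$counts, m$counts)

  # one pair with count 3: 1 connectivity triple + 3 evidence triples
  tr <- withr::local_tempfile(fileext = ".nt")
  export_matrix(m, tr, "rdf_ntriples")
  lines <- readLines(tr)
  expect_length(lines, 4L)
  expect_length(grep("connects-with", lines), 1L)
  expect_length(grep("evidence", lines), 3L)
  expect_true(all(grepl(" \\.$", lines)))

  # empty matrix: header-only TSV
  e <- connectivity_matrix("all", character())
  te <- withr::local_tempfile(fileext = ".tsv")
  export_matrix(e, te, "tsv")
  expect_length(readLines(te), 1L)
})
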