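# Summary connectivity statistics of the curated and predicted corpora
# that seed the pipeline: abstract counts, within-sentence region-pair
# counts and curated connection counts, with the cross-validated
# recall/precision where available.  The bundled table ships as plain TSV
# and is the input for corpus-level arithmetic (merged connection counts,
# positive-pair proportions).

#' Summary statistics of the curated and predicted corpora
#'
#' @param path optional TSV path; defaults to the bundled table with the
#'   four corpora (the manually curated original corpus, the evaluated
#'   extension corpus, and the two automatically predicted corpora).
#' @return data.frame with columns `corpus`, `abstracts`, `region_pairs`,
#'   `connections`, `recall_pct`, `precision_pct`.
#' @export
corpus_summary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "corpus_summary.tsv",
                        package = "conntext", mustWork = TRUE)
  }
  df <- read.delim(path, sep = "\t", header = TRUE, fileEncoding = "UTF-8")
  need <- c("corpus", "abstracts", "region_pairs", "connections")
  if (!all(need %in% names(df))) stop("summary table missing columns")
  df
}

#' Merge curated corpora statistics
#'
#' Sums abstracts, region pairs and connection counts over the named
#' corpora; merging the two curated corpora gives the total number of
#' curated connectivity statements available for training.
#'
#' @param corpora character vector of corpus names to merge.
#' @param summary a [corpus_summary()] table.
#' @return list with `abstracts`, `region_pairs`, `connections`.
#' @export
merge_corpus_stats <- function(corpora = c("original", "evaluated_extension"),
                               summary = corpus_summary()) {
  rows <- summary[summary$corpus %in% corpora, , drop = FALSE]
  if (nrow(rows) != length(corpora)) {
    stop("unknown corpus name(s): ",
         paste(setdiff(corpora, summary$corpus), collapse = ", "))
  }
  list(abstracts = sum(rows$abstracts),
       region_pairs = sum(rows$region_pairs),
       connections = sum(rows$connections))
}

#' Positive-pair percentage of a corpus
#'
#' The proportion of annotated region pairs that are connectivity
#' statements, as a percentage.
#'
#' @param corpus corpus name in the summary table.
#' @param summary a [corpus_summary()] table.
#' @param digits rounding (default 0, the precision the proportions are
#'   usually quoted at).
#' @return numeric percentage.
#' @export
positive_pair_percent <- function(corpus = "evaluated_extension",
                                  summary = corpus_summary(), digits = 0) {
  row <- summary[summary$corpus == corpus, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown corpus name: ", corpus)
  round(100 * row$connections / row$region_pairs, digits)
}
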