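# Domain containers for annotated documents.  All character offsets are
# 0-based half-open intervals into the document text, which is the title and
# abstract concatenated with a single space.  Tokens, mentions, candidate
# pairs and species tags are stored as data frames so they serialize cleanly;
# sentences and documents are plain S3 lists.

#' Slice a document text by a half-open span
#'
#' @param text a single string.
#' @param start,end 0-based half-open character offsets.
#' @return the substring `text[start, end)`.
#' @export
span_text <- function(text, start, end) {
  if (length(start) == 0L) return(character())
  substring(text, start + 1L, end)
}

#' Empty or populated token table
#'
#' @param start,end integer 0-based half-open spans (document coordinates).
#' @param surface token surface strings.
#' @param stem Porter stems of the lowercase surfaces.
#' @param bio optional BIO labels ("B", "I", "O" or `NA`).
#' @return data.frame with columns start, end, surface, stem, bio.
#' @export
token_frame <- function(start = integer(), end = integer(),
                        surface = character(), stem = character(),
                        bio = rep(NA_character_, length(start))) {
  data.frame(start = as.integer(start), end = as.integer(end),
             surface = as.character(surface), stem = as.character(stem),
             bio = as.character(bio), stringsAsFactors = FALSE)
}

#' Mention table
#'
#' @param start,end integer 0-based half-open spans (document coordinates).
#' @param surface mention surface strings.
#' @param expanded abbreviation-expanded form (equals surface when the
#'   mention is not an abbreviation).
#' @param concept_id optional standardized concept id (`NA` when unmapped;
#'   ambiguous mappings are stored "id1|id2").
#' @param match_stage optional cascade stage that produced the mapping.
#' @return data.frame with the six mention columns.
#' @export
mention_frame <- function(start = integer(), end = integer(),
                          surface = character(),
                          expanded = surface,
                          concept_id = rep(NA_character_, length(start)),
                          match_stage = rep(NA_character_, length(start))) {
  data.frame(start = as.integer(start), end = as.integer(end),
             surface = as.character(surface), expanded = as.character(expanded),
             concept_id = as.character(concept_id),
             match_stage = as.character(match_stage), stringsAsFactors = FALSE)
}

#' Candidate pair table
#'
#' A candidate pair is two distinct mentions within one sentence, the unit
#' classified as connected / not connected.  Mention A precedes mention B by
#' span start.
#'
#' @param a_start,a_end,b_start,b_end spans of the two mentions.
#' @param gold_label optional logical curation label.
#' @param score optional real classifier score.
#' @param predicted optional logical prediction.
#' @return data.frame with the pair columns.
#' @export
pair_frame <- function(a_start = integer(), a_end = integer(),
                       b_start = integer(), b_end = integer(),
                       gold_label = rep(NA, length(a_start)),
                       score = rep(NA_real_, length(a_start)),
                       predicted = rep(NA, length(a_start))) {
  data.frame(a_start = as.integer(a_start), a_end = as.integer(a_end),
             b_start = as.integer(b_start), b_end = as.integer(b_end),
             gold_label = as.logical(gold_label), score = as.numeric(score),
             predicted = as.logical(predicted), stringsAsFactors = FALSE)
}

#' Species tag table
#'
#' @param start,end spans of the species name in the document text.
#' @param name matched surface form.
#' @param taxon_id NCBI-style numeric taxon identifier (as string).
#' @return data.frame with the species columns.
#' @export
species_frame <- function(start = integer(), end = integer(),
                          name = character(), taxon_id = character()) {
  data.frame(start = as.integer(start), end = as.integer(end),
             name = as.character(name), taxon_id = as.character(taxon_id),
             stringsAsFactors = FALSE)
}

#' Construct a sentence
#'
#' @param start,end 0-based half-open span of the sentence in the document.
#' @param tokens token table (document coordinates).
#' @param mentions mention table.
#' @param pairs candidate-pair table.
#' @return an object of class `cx_sentence`.
#' @export
cx_sentence <- function(start, end, tokens = token_frame(),
                        mentions = mention_frame(), pairs = pair_frame()) {
  structure(list(start = as.integer(start), end = as.integer(end),
                 tokens = tokens, mentions = mentions, pairs = pairs),
            class = "cx_sentence")
}

#' Construct a document
#'
#' @param doc_id unique identifier.
#' @param text title and abstract concatenated with a single space.
#' @param sentences list of [cx_sentence()] in reading order.
#' @param species species tag table.
#' @return an object of class `cx_document`.
#' @export
cx_document <- function(doc_id, text, sentences = list(),
                        species = species_frame()) {
  structure(list(doc_id = as.character(doc_id), text = as.character(text),
                 sentences = sentences, species = species),
            class = "cx_document")
}

#' Construct a corpus
#'
#' @param documents list of [cx_document()].
#' @return an object of class `cx_corpus`.
#' @export
cx_corpus <- function(documents = list()) {
  structure(list(documents = documents), class = "cx_corpus")
}

#' @exportS3Method base::print
print.cx_corpus <- function(x, ...) {
  n_sent <- sum(vapply(x$documents, function(d) length(d$sentences), integer(1)))
  n_men <- sum(vapply(x$documents, function(d)
    sum(vapply(d$sentences, function(s) nrow(s$mentions), integer(1))), integer(1)))
  n_pair <- sum(vapply(x$documents, function(d)
    sum(vapply(d$sentences, function(s) nrow(s$pairs), integer(1))), integer(1)))
  cat(sprintf("<cx_corpus> %d documents, %d sentences, %d mentions, %d pairs\n",
              length(x$documents), n_sent, n_men, n_pair))
  invisible(x)
}

.check_spans_sorted <- function(start, end, lo, hi, what, doc_id) {
  if (length(start) == 0L) return(invisible(TRUE))
  if (any(end <= start)) {
    stop(sprintf("document %s: empty or inverted %s span", doc_id, what))
  }
  if (any(start < lo) || any(end > hi)) {
    stop(sprintf("document %s: %s span outside [%d, %d)", doc_id, what, lo, hi))
  }
  if (length(start) > 1L) {
    o <- order(start)
    if (any(diff(start) < 0)) {
      stop(sprintf("document %s: %s spans not sorted", doc_id, what))
    }
    if (any(start[o][-1L] < end[o][-length(o)])) {
      stop(sprintf("document %s: overlapping %s spans", doc_id, what))
    }
  }
  invisible(TRUE)
}

#' Validate a document against the data-model invariants
#'
#' Checks that sentence spans are sorted, non-overlapping and inside the
#' text; token and mention spans lie inside their sentence; and every token
#' and mention surface equals the corresponding text slice.
#'
#' @param doc a `cx_document`.
#' @return the document, invisibly; errors describe the offending field.
#' @export
validate_document <- function(doc) {
  stopifnot(inherits(doc, "cx_document"))
  n <- nchar(doc$text)
  s_start <- vapply(doc$sentences, `[[`, integer(1), "start")
  s_end <- vapply(doc$sentences, `[[`, integer(1), "end")
  .check_spans_sorted(s_start, s_end, 0L, n, "sentence", doc$doc_id)
  for (sent in doc$sentences) {
    tk <- sent$tokens
    .check_spans_sorted(tk$start, tk$end, sent$start, sent$end, "token", doc$doc_id)
    if (nrow(tk) && !all(tk$surface == span_text(doc$text, tk$start, tk$end))) {
      stop(sprintf("document %s: token surface/span mismatch", doc$doc_id))
    }
    mn <- sent$mentions
    if (nrow(mn)) {
      if (any(mn$end <= mn$start)) {
        stop(sprintf("document %s: empty mention span", doc$doc_id))
      }
      if (any(mn$start < sent$start) || any(mn$end > sent$end)) {
        stop(sprintf("document %s: mention outside its sentence", doc$doc_id))
      }
      if (!all(mn$surface == span_text(doc$text, mn$start, mn$end))) {
        stop(sprintf("document %s: mention surface/span mismatch", doc$doc_id))
      }
      if (any(!nzchar(mn$expanded))) {
        stop(sprintf("document %s: empty mention expansion", doc$doc_id))
      }
    }
    pr <- sent$pairs
    if (nrow(pr)) {
      key <- function(st, en) paste(st, en)
      mk <- key(mn$start, mn$end)
      if (!all(key(pr$a_start, pr$a_end) %in% mk) ||
          !all(key(pr$b_start, pr$b_end) %in% mk)) {
        stop(sprintf("document %s: pair references unknown mention", doc$doc_id))
      }
      if (any(pr$a_start >= pr$b_start & pr$a_end >= pr$b_end &
              pr$a_start == pr$b_start & pr$a_end == pr$b_end)) {
        stop(sprintf("document %s: pair of identical mentions", doc$doc_id))
      }
      if (any(pr$a_start > pr$b_start)) {
        stop(sprintf("document %s: pair not ordered by mention start", doc$doc_id))
      }
    }
  }
  if (nrow(doc$species) && any(!nzchar(doc$species$taxon_id) | is.na(doc$species$taxon_id))) {
    stop(sprintf("document %s: species tag without taxon id", doc$doc_id))
  }
  invisible(doc)
}

#' Validate every document of a corpus
#'
#' @param corpus a `cx_corpus`.
#' @return the corpus, invisibly.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "cx_corpus"))
  ids <- vapply(corpus$documents, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids)) stop("duplicate doc_id in corpus")
  for (doc in corpus$documents) validate_document(doc)
  invisible(corpus)
}
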