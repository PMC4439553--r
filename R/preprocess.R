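# Text preprocessing: sentence splitting, tokenization with Porter stems,
# Schwartz-Hearst abbreviation detection, and dictionary species tagging.
# All offsets are 0-based half-open document coordinates.

.abbrev_no_split <- c("e.g", "i.e", "cf", "vs", "al", "fig", "figs", "ref",
                      "refs", "no", "approx", "ca", "etc")

#' Split text into sentence spans
#'
#' Splits on sentence-final punctuation (`.?!`) followed by whitespace and an
#' upper-case letter, digit or opening quote/bracket, with exceptions for
#' common abbreviations ("e.g.", "et al.", "Fig.") and single-letter
#' initials.  Spans exclude leading/trailing whitespace and cover all
#' non-whitespace text.
#'
#' @param text a single string ("" gives an empty result).
#' @return data.frame with 0-based half-open columns `start`, `end`.
#' @export
split_sentences <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) {
    return(data.frame(start = integer(), end = integer()))
  }
  n <- nchar(text)
  # candidate boundaries: terminal punctuation run followed by whitespace
  m <- gregexpr("[.?!]+(?=\\s)", text, perl = TRUE)[[1L]]
  breaks <- integer()
  if (m[1L] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L  # 1-based last punct
    for (e in ends) {
      before <- substring(text, 1L, e - 1L)
      # word immediately before the punctuation (may itself contain periods)
      word <- regmatches(before, regexpr("[A-Za-z][A-Za-z.]*$", before))
      if (length(word) == 1L) {
        w <- tolower(sub("\\.$", "", word))
        if (w %in% .abbrev_no_split) next
      }
      rest <- substring(text, e + 1L)
      nxt <- regmatches(rest, regexpr("^\\s+(.)", rest, perl = TRUE))
      if (length(nxt) == 0L) next
      first <- substring(nxt, nchar(nxt), nchar(nxt))
      if (!grepl('[A-Z0-9"“(\\[]', first)) next
      breaks <- c(breaks, e)  # sentence ends after char e (1-based)
    }
  }
  starts1 <- c(1L, breaks + 1L)
  ends1 <- c(breaks, n)
  spans <- do.call(rbind, lapply(seq_along(starts1), function(i) {
    seg <- substring(text, starts1[i], ends1[i])
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    s <- starts1[i] + lead
    e <- ends1[i] - trail
    if (e < s) return(NULL)
    c(s - 1L, e)  # to 0-based half-open
  }))
  if (is.null(spans)) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(spans[, 1]), end = as.integer(spans[, 2]))
}

#' Tokenize a sentence
#'
#' Tokens are maximal alphanumeric runs or single punctuation characters;
#' whitespace separates.  Hyphenated forms split at the hyphen with the
#' hyphen kept as its own token ("cortico-thalamic" gives three tokens), so
#' compound region names share stems with their unhyphenated variants.
#' Each token carries the Porter stem of its folded lowercase surface.
#'
#' @param sentence_text text of one sentence.
#' @param base_offset 0-based offset of the sentence in the document; token
#'   spans are emitted in document coordinates.
#' @return a [token_frame()].
#' @export
tokenize <- function(sentence_text, base_offset = 0L) {
  stopifnot(length(sentence_text) == 1L)
  if (is.na(sentence_text) || !nzchar(sentence_text)) return(token_frame())
  m <- gregexpr("[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]", sentence_text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(token_frame())
  start1 <- as.integer(m)
  len <- attr(m, "match.length")
  surface <- substring(sentence_text, start1, start1 + len - 1L)
  token_frame(
    start = base_offset + start1 - 1L,
    end = base_offset + start1 + len - 1L,
    surface = surface,
    stem = porter_stem(surface)
  )
}

# ---- Schwartz-Hearst abbreviation detection ----

.sh_valid_short_form <- function(sf) {
  nc <- nchar(sf)
  if (nc < 2L || nc > 10L) return(FALSE)
  if (!grepl("^[A-Za-z0-9]", sf)) return(FALSE)
  if (!grepl("[A-Za-z]", sf)) return(FALSE)       # all-numeric rejected
  if (lengths(strsplit(sf, "\\s+")) > 2L) return(FALSE)
  TRUE
}

# core Schwartz-Hearst matcher: scan the short form right-to-left through
# the candidate long form; the first character of the short form must align
# with the first character of a long-form word.  Returns the matched suffix
# of `lf` or NA.
.sh_best_long_form <- function(sf, lf) {
  sfc <- strsplit(tolower(sf), "", fixed = TRUE)[[1L]]
  lfc <- strsplit(tolower(lf), "", fixed = TRUE)[[1L]]
  si <- length(sfc)
  li <- length(lfc)
  while (si >= 1L) {
    c <- sfc[si]
    if (!grepl("[a-z0-9]", c)) { si <- si - 1L; next }
    repeat {
      if (li < 1L) return(NA_character_)
      ok <- lfc[li] == c
      if (ok && si == 1L && li > 1L && grepl("[a-z0-9]", lfc[li - 1L])) ok <- FALSE
      if (ok) break
      li <- li - 1L
    }
    si <- si - 1L
    li <- li - 1L
  }
  sub("^\\s+", "", substring(lf, li + 1L))
}

#' Detect abbreviation definitions (Schwartz-Hearst)
#'
#' Finds "long form (SF)" definition sites: for each parenthesized candidate
#' short form, the shortest preceding long-form suffix is sought such that
#' every short-form character appears in order, with the short form's first
#' character at the start of a long-form word.  Valid short forms are 2-10
#' characters, start alphanumeric, and contain at least one letter; the long
#' form may have at most `min(|SF| + 5, 2 |SF|)` words.
#'
#' @param document_text full document text.
#' @return data.frame with columns `short_form`, `long_form`, `start`, `end`
#'   (span of the parenthetical, 0-based half-open).
#' @export
extract_abbreviations <- function(document_text) {
  stopifnot(length(document_text) == 1L)
  out <- data.frame(short_form = character(), long_form = character(),
                    start = integer(), end = integer())
  if (is.na(document_text) || !nzchar(document_text)) return(out)
  m <- gregexpr("\\(([^()]+)\\)", document_text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(out)
  starts1 <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts1)) {
    sf <- substring(document_text, starts1[i] + 1L, starts1[i] + lens[i] - 2L)
    sf <- trimws(sf)
    if (!.sh_valid_short_form(sf)) next
    before <- trimws(substring(document_text, 1L, starts1[i] - 1L))
    # candidate long form: up to min(|SF|+5, 2|SF|) trailing words, within
    # the current sentence (cut at sentence punctuation)
    before <- sub(".*[.;?!]", "", before)
    words <- strsplit(before, "\\s+")[[1L]]
    if (length(words) == 0L) next
    max_words <- min(nchar(sf) + 5L, 2L * nchar(sf))
    take <- min(length(words), max_words)
    cand <- paste(words[(length(words) - take + 1L):length(words)], collapse = " ")
    lf <- .sh_best_long_form(sf, cand)
    if (is.na(lf) || !nzchar(lf)) next
    if (lengths(strsplit(lf, "\\s+")) > max_words) next
    if (nchar(lf) <= nchar(sf)) next
    if (grepl(paste0("\\b", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", sf), "\\b"), lf)) next
    out <- rbind(out, data.frame(
      short_form = sf, long_form = lf,
      start = starts1[i] - 1L, end = starts1[i] + lens[i] - 1L
    ))
  }
  rownames(out) <- NULL
  out
}

#' Annotate mentions with abbreviation expansions
#'
#' For every mention whose surface is exactly a known short form (token
#' bounded - "SNC" inside "SNCA" is not expanded), sets `expanded` to the
#' long form.  Spans are untouched: expansion is an annotation, not a text
#' rewrite.  Abbreviation scope is the whole document, so sentences that
#' follow the definition inherit it.
#'
#' @param sentence a `cx_sentence`.
#' @param abbrevs result of [extract_abbreviations()] on the enclosing
#'   document.  Conflicting definitions of one short form keep the first
#'   (with a warning at extraction aggregation time).
#' @return the sentence with mention `expanded` fields filled.
#' @export
expand_abbreviations <- function(sentence, abbrevs) {
  stopifnot(inherits(sentence, "cx_sentence"))
  if (nrow(abbrevs) == 0L || nrow(sentence$mentions) == 0L) return(sentence)
  if (anyDuplicated(abbrevs$short_form)) {
    warning("conflicting abbreviation definitions; keeping the first of each")
    abbrevs <- abbrevs[!duplicated(abbrevs$short_form), ]
  }
  idx <- match(sentence$mentions$surface, abbrevs$short_form)
  hit <- !is.na(idx)
  sentence$mentions$expanded[hit] <- abbrevs$long_form[idx[hit]]
  sentence
}

# ---- dictionary matching (species tagging, lexicon NER features) ----

# All non-overlapping, case-insensitive, longest matches of `names` in
# `text` at word boundaries.  Longer names win over shorter ones starting at
# the same position; matches are returned sorted and non-overlapping.
.dict_match <- function(text, names) {
  if (length(names) == 0L || !nzchar(text)) {
    return(data.frame(start = integer(), end = integer(), name = character()))
  }
  names <- names[order(nchar(names), decreasing = TRUE)]
  esc <- gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", names)
  esc <- gsub("\\s+", "\\\\s+", esc)
  pat <- paste0("(?<![\\p{L}\\p{N}])(?:", paste(esc, collapse = "|"),
                ")(?![\\p{L}\\p{N}])")
  m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(), end = integer(), name = character()))
  }
  start1 <- as.integer(m)
  len <- attr(m, "match.length")
  data.frame(start = start1 - 1L, end = start1 + len - 1L,
             name = substring(text, start1, start1 + len - 1L))
}

#' Tag species mentions in a document
#'
#' Case-insensitive longest-match dictionary tagging over the document text.
#' A document may carry several species; tags are sorted and
#' non-overlapping.  Names that are missing from the lexicon cannot produce
#' tags, so every tag carries a taxon id.
#'
#' @param document a `cx_document`.
#' @param species_lexicon named character vector name -> taxon id, e.g. from
#'   [load_species_lexicon()].
#' @return a [species_frame()].
#' @export
tag_species <- function(document, species_lexicon = load_species_lexicon()) {
  stopifnot(inherits(document, "cx_document"))
  hits <- .dict_match(document$text, names(species_lexicon))
  if (nrow(hits) == 0L) return(species_frame())
  key <- match(tolower(hits$name), tolower(names(species_lexicon)))
  species_frame(start = hits$start, end = hits$end, name = hits$name,
                taxon_id = unname(species_lexicon[key]))
}

#' Run the full preprocessing pass over a raw document
#'
#' Splits sentences, tokenizes, extracts and applies abbreviation
#' definitions, and tags species.
#'
#' @param doc_id document identifier.
#' @param text document text (title + single space + abstract).
#' @param species_lexicon named vector name -> taxon id.
#' @return a `cx_document` with sentences, tokens and species populated
#'   (mentions empty - they come from the recognizer).
#' @export
preprocess_document <- function(doc_id, text,
                                species_lexicon = load_species_lexicon()) {
  spans <- split_sentences(text)
  sentences <- lapply(seq_len(nrow(spans)), function(i) {
    s <- spans$start[i]; e <- spans$end[i]
    cx_sentence(start = s, end = e,
                tokens = tokenize(span_text(text, s, e), base_offset = s))
  })
  doc <- cx_document(doc_id = doc_id, text = text, sentences = sentences)
  doc$species <- tag_species(doc, species_lexicon)
  doc
}
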