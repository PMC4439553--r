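# Standardization of mention strings to lexicon concepts.  The matching
# ladder has four rungs - case-insensitive exact, bag-of-words, stemmed
# exact, bag-of-stems - each requiring ALL words or stems of the mention to
# match the lexicon name.  When the ladder fails, mention-editing modifiers
# are applied cumulatively, re-running the full ladder after each edit.
# Each edit sacrifices some information (hemisphere qualifiers, bracketed
# text, directional prefixes, ...), trading precision for coverage.

.norm_words <- function(text) {
  w <- strsplit(tolower(trimws(text)), "[^\\p{L}\\p{N}]+", perl = TRUE)[[1L]]
  w[nzchar(w)]
}

.bag_key <- function(words) paste(sort(words), collapse = " ")

.lex_index <- function(lexicon) {
  stopifnot(inherits(lexicon, "cx_lexicon"))
  env <- lexicon$.index
  if (!is.null(env$built)) return(env)
  nm <- lexicon$entries$name
  cid <- lexicon$entries$concept_id
  words <- lapply(nm, .norm_words)
  stems <- lapply(words, porter_stem)
  key_add <- function(map, keys) {
    for (i in seq_along(keys)) {
      k <- keys[i]
      if (!nzchar(k)) next
      map[[k]] <- unique(c(map[[k]], cid[i]))
    }
    map
  }
  env$exact <- key_add(new.env(parent = emptyenv()),
                       vapply(words, paste, character(1), collapse = " "))
  env$bow <- key_add(new.env(parent = emptyenv()),
                     vapply(words, .bag_key, character(1)))
  env$stem <- key_add(new.env(parent = emptyenv()),
                      vapply(stems, paste, character(1), collapse = " "))
  env$bos <- key_add(new.env(parent = emptyenv()),
                     vapply(stems, .bag_key, character(1)))
  env$built <- TRUE
  env
}

.lex_lookup <- function(map, key) {
  hit <- map[[key]]
  if (is.null(hit)) character() else hit
}

#' Single-rung lexicon matchers
#'
#' `match_exact()` is case-insensitive full-string equality (after
#' whitespace/punctuation canonicalization), `match_bag_of_words()` equality
#' of lowercase word multisets, `match_stem()` equality of the
#' stemmed-and-joined strings, and `match_bag_of_stems()` equality of stem
#' multisets.  Diacritics are folded before stemming only.
#'
#' @param text mention string.
#' @param lexicon a `cx_lexicon`.
#' @return character vector of matching concept ids (possibly empty or
#'   ambiguous); deterministic given the lexicon entry order.
#' @export
match_exact <- function(text, lexicon) {
  .lex_lookup(.lex_index(lexicon)$exact, paste(.norm_words(text), collapse = " "))
}

#' @rdname match_exact
#' @export
match_bag_of_words <- function(text, lexicon) {
  .lex_lookup(.lex_index(lexicon)$bow, .bag_key(.norm_words(text)))
}

#' @rdname match_exact
#' @export
match_stem <- function(text, lexicon) {
  .lex_lookup(.lex_index(lexicon)$stem,
              paste(porter_stem(.norm_words(text)), collapse = " "))
}

#' @rdname match_exact
#' @export
match_bag_of_stems <- function(text, lexicon) {
  .lex_lookup(.lex_index(lexicon)$bos, .bag_key(porter_stem(.norm_words(text))))
}

.run_ladder <- function(text, lexicon) {
  for (rung in c("exact", "bag_of_words", "stem_exact", "bag_of_stems")) {
    ids <- switch(rung,
      exact = match_exact(text, lexicon),
      bag_of_words = match_bag_of_words(text, lexicon),
      stem_exact = match_stem(text, lexicon),
      bag_of_stems = match_bag_of_stems(text, lexicon)
    )
    if (length(ids)) return(list(concept_ids = ids, rung = rung))
  }
  NULL
}

# ---- modifiers ----

.hemisphere_words <- c("left", "right", "ipsilateral", "contralateral", "bilateral")
.directional_words <- c("anterior", "posterior", "dorsal", "ventral", "medial",
                        "lateral", "rostral", "caudal")

#' Default mention-editing modifiers
#'
#' Ordered registry of string edits applied when the plain matching ladder
#' fails.  The shipped defaults: strip bracketed/parenthesized text, strip
#' hemisphere qualifiers (left/right/ipsi-/contra-/bilateral), strip one
#' phrase-initial directional prefix (anterior, posterior, dorsal, ...),
#' strip a trailing upper-case abbreviation, collapse whitespace and
#' punctuation, singularize a terminal plural.  The registry is extensible:
#' pass additional `list(name =, transform =)` entries to
#' [normalize_mention()].
#'
#' @return named list of modifier functions, in application order.
#' @export
default_modifiers <- function() {
  list(
    strip_bracketed_text = function(x) {
      trimws(gsub("\\s*\\([^()]*\\)|\\s*\\[[^][]*\\]", "", x))
    },
    strip_hemisphere_qualifiers = function(x) {
      pat <- paste0("(?i)\\b(", paste(.hemisphere_words, collapse = "|"), ")\\b")
      trimws(gsub("\\s+", " ", gsub(pat, "", x, perl = TRUE)))
    },
    strip_directional_prefixes = function(x) {
      pat <- paste0("(?i)^(", paste(.directional_words, collapse = "|"), ")\\s+")
      sub(pat, "", x, perl = TRUE)
    },
    strip_parenthetical_abbrev = function(x) {
      # trailing bare abbreviation: "dorsal raphe DR" -> "dorsal raphe"
      sub("\\s+[A-Z][A-Z0-9]{1,5}$", "", x)
    },
    collapse_whitespace_punct = function(x) {
      trimws(gsub("\\s+", " ", gsub("[-_,;:/]+", " ", x)))
    },
    singularize_terminal_plural = function(x) {
      words <- strsplit(trimws(x), "\\s+")[[1L]]
      if (length(words) == 0L) return(x)
      last <- words[length(words)]
      irregular <- c(nuclei = "nucleus", gyri = "gyrus", cortices = "cortex",
                     bodies = "body", ganglia = "ganglion")
      low <- tolower(last)
      if (low %in% names(irregular)) {
        last <- irregular[[low]]
      } else if (grepl("[a-z]s$", last) && !grepl("(ss|us|is)$", low)) {
        last <- substring(last, 1L, nchar(last) - 1L)
      }
      paste(c(words[-length(words)], last), collapse = " ")
    }
  )
}

#' Cumulative application of modifiers
#'
#' @param text mention string.
#' @param modifiers named list of string transforms (see
#'   [default_modifiers()]).
#' @return data.frame with columns `modifier`, `text`: the successive
#'   cumulative edits (an edit that leaves the string unchanged is recorded
#'   but flagged, so the ladder is not re-run for it).
#' @export
apply_modifiers <- function(text, modifiers = default_modifiers()) {
  cur <- text
  out <- data.frame(modifier = character(), text = character(),
                    changed = logical())
  for (nm in names(modifiers)) {
    nxt <- modifiers[[nm]](cur)
    changed <- !identical(nxt, cur) && nzchar(trimws(nxt))
    if (changed) cur <- nxt
    out <- rbind(out, data.frame(modifier = nm, text = cur, changed = changed))
  }
  out
}

#' Standardize a mention string to lexicon concepts
#'
#' Runs the four-rung matching ladder on the raw text; on failure applies
#' the modifiers cumulatively in registry order, re-running the full ladder
#' after each edit that changed the string.  Stops at the first rung that
#' yields at least one concept.  Ambiguity (several concepts at the winning
#' rung) is returned, not resolved.
#'
#' @param text mention string (typically the abbreviation-expanded form).
#' @param lexicon a `cx_lexicon`.
#' @param modifiers ordered named list of transforms.
#' @return list with `concept_ids` (character, possibly empty or length
#'   > 1), `match_stage` (`"exact"`, `"bag_of_words"`, `"stem_exact"`,
#'   `"bag_of_stems"` or `"modified:<name>"`, `NA` when unmatched) and
#'   `edited_text` (the string that finally matched).
#' @examples
#' lex <- new_lexicon(data.frame(
#'   concept_id = "r1", name = "thalamic reticular nucleus",
#'   source = "toy", is_preferred = TRUE))
#' normalize_mention("reticular thalamic nucleus", lex)$match_stage
#' @export
normalize_mention <- function(text, lexicon, modifiers = default_modifiers()) {
  stopifnot(length(text) == 1L, nzchar(text))
  hit <- .run_ladder(text, lexicon)
  if (!is.null(hit)) {
    return(list(concept_ids = hit$concept_ids, match_stage = hit$rung,
                edited_text = text))
  }
  cur <- text
  for (nm in names(modifiers)) {
    nxt <- modifiers[[nm]](cur)
    if (identical(nxt, cur) || !nzchar(trimws(nxt))) next
    cur <- nxt
    hit <- .run_ladder(cur, lexicon)
    if (!is.null(hit)) {
      return(list(concept_ids = hit$concept_ids,
                  match_stage = paste0("modified:", nm), edited_text = cur))
    }
  }
  list(concept_ids = character(), match_stage = NA_character_,
       edited_text = cur)
}

#' Normalize every mention of a corpus
#'
#' Fills mention `concept_id` (ambiguous matches joined with "|") and
#' `match_stage` using the expanded mention form.
#'
#' @param corpus a `cx_corpus` with mentions.
#' @param lexicon a `cx_lexicon`.
#' @param modifiers modifier registry.
#' @return the corpus with normalized mentions.
#' @export
normalize_corpus <- function(corpus, lexicon, modifiers = default_modifiers()) {
  for (di in seq_along(corpus$documents)) {
    for (si in seq_along(corpus$documents[[di]]$sentences)) {
      mn <- corpus$documents[[di]]$sentences[[si]]$mentions
      for (mi in seq_len(nrow(mn))) {
        res <- normalize_mention(mn$expanded[mi], lexicon, modifiers)
        mn$concept_id[mi] <- if (length(res$concept_ids)) {
          paste(res$concept_ids, collapse = "|")
        } else NA_character_
        mn$match_stage[mi] <- res$match_stage
      }
      corpus$documents[[di]]$sentences[[si]]$mentions <- mn
    }
  }
  corpus
}

#' Evaluate normalization against a gold mapping
#'
#' @param gold named character vector mention text -> gold concept id.
#' @param results named list of [normalize_mention()] results keyed
#'   identically.
#' @return list with `coverage` (fraction of mentions with a non-empty
#'   result), a `cx_metrics` (`metrics`; a prediction is correct when the
#'   unique returned concept equals gold - ambiguous results count as
#'   incorrect matches), and `stage_counts`, the per-stage tally that makes
#'   the modifier contribution to coverage visible.  Precision is `NA`
#'   (null) when nothing matched.
#' @export
evaluate_normalization <- function(gold, results) {
  stopifnot(length(gold) == length(results),
            all(names(gold) %in% names(results)))
  results <- results[names(gold)]
  matched <- vapply(results, function(r) length(r$concept_ids) > 0L, logical(1))
  correct <- vapply(seq_along(results), function(i) {
    r <- results[[i]]
    length(r$concept_ids) == 1L && r$concept_ids == gold[[i]]
  }, logical(1))
  stages <- vapply(results, function(r)
    if (is.na(r$match_stage)) "unmatched" else r$match_stage, character(1))
  list(
    coverage = mean(matched),
    metrics = compute_metrics(tp = sum(correct),
                              fp = sum(matched & !correct),
                              fn = sum(!correct)),
    stage_counts = table(stages)
  )
}
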