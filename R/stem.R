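# Porter (1980) suffix-stripping stemmer, used as the "base form" reducer
# throughout the pipeline (token stems, stemmed lexicon indexes).  Diacritics
# are folded to ASCII before stemming, so "raphé" stems like "raphe" -> "raph".

.stem_cache <- new.env(parent = emptyenv())

#' Fold diacritics to ASCII
#'
#' Transliterates accented characters to their unaccented ASCII counterparts
#' ("raphé" becomes "raphe").  Characters with no transliteration are kept.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
fold_diacritics <- function(x) {
  out <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  bad <- is.na(out)
  out[bad] <- x[bad]
  # iconv may emit "'" markers for accents on some platforms; drop them
  gsub("[\"'^`~]", "", out)
}

.pt_is_cons <- function(ch, i) {
  c <- ch[i]
  if (c %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (c == "y") {
    if (i == 1L) return(TRUE)
    return(!.pt_is_cons(ch, i - 1L))
  }
  TRUE
}

# measure m of a stem: [C](VC)^m[V]
.pt_measure <- function(stem) {
  n <- nchar(stem)
  if (n == 0L) return(0L)
  ch <- strsplit(stem, "", fixed = TRUE)[[1L]]
  types <- vapply(seq_len(n), function(i) .pt_is_cons(ch, i), logical(1))
  # collapse runs, count vowel-run -> consonant-run transitions
  runs <- rle(types)$values
  sum(vapply(seq_along(runs)[-1L], function(i) !runs[i - 1L] && runs[i], logical(1)))
}

.pt_has_vowel <- function(stem) {
  n <- nchar(stem)
  if (n == 0L) return(FALSE)
  ch <- strsplit(stem, "", fixed = TRUE)[[1L]]
  any(!vapply(seq_len(n), function(i) .pt_is_cons(ch, i), logical(1)))
}

.pt_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  ch <- strsplit(word, "", fixed = TRUE)[[1L]]
  ch[n] == ch[n - 1L] && .pt_is_cons(ch, n)
}

# consonant-vowel-consonant ending where the final consonant is not w, x or y
.pt_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  ch <- strsplit(word, "", fixed = TRUE)[[1L]]
  .pt_is_cons(ch, n - 2L) && !.pt_is_cons(ch, n - 1L) && .pt_is_cons(ch, n) &&
    !(ch[n] %in% c("w", "x", "y"))
}

.pt_ends <- function(word, suffix) {
  n <- nchar(word); k <- nchar(suffix)
  n > k && substring(word, n - k + 1L, n) == suffix
}

.pt_chop <- function(word, k) substring(word, 1L, nchar(word) - k)

# rule tables: suffix -> replacement, applied to the longest matching suffix
# only, guarded by a measure condition on the remaining stem
.pt_rule_set <- function(word, rules, cond) {
  sufs <- names(rules)
  sufs <- sufs[order(nchar(sufs), decreasing = TRUE)]
  for (s in sufs) {
    if (.pt_ends(word, s)) {
      stem <- .pt_chop(word, nchar(s))
      if (cond(stem)) return(paste0(stem, rules[[s]]))
      return(word)
    }
  }
  word
}

.porter_stem_one <- function(word) {
  if (nchar(word) <= 2L) return(word)
  w <- word

  # step 1a
  if (.pt_ends(w, "sses")) w <- .pt_chop(w, 2L)
  else if (.pt_ends(w, "ies")) w <- .pt_chop(w, 2L)
  else if (.pt_ends(w, "ss")) w <- w
  else if (.pt_ends(w, "s")) w <- .pt_chop(w, 1L)

  # step 1b
  if (.pt_ends(w, "eed")) {
    if (.pt_measure(.pt_chop(w, 3L)) > 0L) w <- .pt_chop(w, 1L)
  } else {
    removed <- FALSE
    if (.pt_ends(w, "ed") && .pt_has_vowel(.pt_chop(w, 2L))) {
      w <- .pt_chop(w, 2L); removed <- TRUE
    } else if (.pt_ends(w, "ing") && .pt_has_vowel(.pt_chop(w, 3L))) {
      w <- .pt_chop(w, 3L); removed <- TRUE
    }
    if (removed) {
      if (.pt_ends(w, "at") || .pt_ends(w, "bl") || .pt_ends(w, "iz")) {
        w <- paste0(w, "e")
      } else if (.pt_double_cons(w) &&
                 !(substring(w, nchar(w)) %in% c("l", "s", "z"))) {
        w <- .pt_chop(w, 1L)
      } else if (.pt_measure(w) == 1L && .pt_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # step 1c
  if (.pt_ends(w, "y") && .pt_has_vowel(.pt_chop(w, 1L))) {
    w <- paste0(.pt_chop(w, 1L), "i")
  }

  # step 2
  w <- .pt_rule_set(w, list(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"
  ), function(stem) .pt_measure(stem) > 0L)

  # step 3
  w <- .pt_rule_set(w, list(
    icate = "ic", ative = "", alize = "al", iciti = "ic",
    ical = "ic", ful = "", ness = ""
  ), function(stem) .pt_measure(stem) > 0L)

  # step 4
  sufs <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
            "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
            "ous", "ive", "ize")
  sufs <- sufs[order(nchar(sufs), decreasing = TRUE)]
  for (s in sufs) {
    if (.pt_ends(w, s)) {
      stem <- .pt_chop(w, nchar(s))
      ok <- .pt_measure(stem) > 1L
      if (ok && s == "ion") {
        ok <- substring(stem, nchar(stem)) %in% c("s", "t")
      }
      if (ok) w <- stem
      break
    }
  }

  # step 5a
  if (.pt_ends(w, "e")) {
    stem <- .pt_chop(w, 1L)
    m <- .pt_measure(stem)
    if (m > 1L || (m == 1L && !.pt_cvc(stem))) w <- stem
  }
  # step 5b
  if (.pt_measure(w) > 1L && .pt_double_cons(w) &&
      substring(w, nchar(w)) == "l") {
    w <- .pt_chop(w, 1L)
  }
  w
}

#' Porter stem of a word
#'
#' Reduces each word to its Porter (1980) stem after lowercasing and folding
#' diacritics to ASCII.  The published worked example of the standardization
#' cascade holds: `porter_stem(c("nucleus", "raphé", "dorsalis"))` yields
#' `c("nucleu", "raph", "dorsali")`.
#'
#' @param words character vector of single words.
#' @return character vector of stems, lowercase.
#' @examples
#' porter_stem(c("nucleus", "raphé", "dorsalis"))
#' @export
porter_stem <- function(words) {
  vapply(words, function(word) {
    word <- fold_diacritics(tolower(word))
    if (!grepl("^[a-z]+$", word)) return(word)
    hit <- .stem_cache[[word]]
    if (!is.null(hit)) return(hit)
    out <- .porter_stem_one(word)
    assign(word, out, envir = .stem_cache)
    out
  }, character(1), USE.NAMES = FALSE)
}

#' Stem every word of a phrase
#'
#' @param phrase character vector of phrases (words separated by whitespace).
#' @return character vector with each word replaced by its stem.
#' @export
stem_phrase <- function(phrase) {
  vapply(phrase, function(p) {
    words <- strsplit(trimws(p), "\\s+")[[1L]]
    if (length(words) == 0L) return("")
    paste(porter_stem(words), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}
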