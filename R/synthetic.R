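# Synthetic corpus generation.  Documents are built from templated
# sentences - a species sentence, optionally an abbreviation-defining
# sentence, then connectivity statements ("X projects to Y") and
# co-mention sentences without connectivity - with every span, BIO label,
# gold pair, species tag and gold concept id recorded.  The templates are
# deliberately easier than real abstracts: recovery on this corpus
# exercises the machinery, it does not emulate real-text difficulty.

#' Default connective phrases
#'
#' Twenty phrases that assert a connection between two regions, in the
#' spirit of "projects to" and "terminating in".  A larger phrase list can
#' be dropped in through [synth_config()].
#'
#' @return character vector.
#' @export
default_connective_phrases <- function() {
  c("projects to", "terminating in", "receives input from",
    "sends fibers to", "is connected with", "innervates",
    "sends axons to", "receives projections from", "is reciprocally connected with",
    "sends efferents to", "receives afferents from", "gives rise to projections to",
    "terminates in", "provides input to", "sends a strong projection to",
    "is a major source of afferents to", "relays signals to",
    "receives a dense projection from", "sends descending fibers to",
    "makes synaptic contacts in")
}

.negative_templates <- c(
  "Both the %s and the %s contained labeled neurons.",
  "Cell counts were obtained for the %s and the %s.",
  "The %s and the %s showed distinct cytoarchitecture.",
  "Staining intensity differed between the %s and the %s.",
  "Immunoreactivity was present in the %s and the %s."
)

.positive_templates <- c(
  "The %s %s the %s.",
  "Tracing experiments showed that the %s %s the %s.",
  "We found that the %s %s the %s.",
  "Injections revealed that the %s %s the %s."
)

#' Configuration of the synthetic-corpus generator
#'
#' The defaults define the standard study conditions used across the test
#' suite: five content sentences per abstract, a connectivity-statement
#' probability of 0.2 per content sentence (so roughly a fifth of candidate
#' pairs are positive, the proportion curated relation corpora in this
#' domain show), mild lexical corruption of region names, and abbreviation
#' definitions in about a third of the abstracts.
#'
#' @param n_documents number of abstracts to generate.
#' @param region_lexicon a `cx_lexicon` of region names (defaults to the
#'   bundled toy lexicon).
#' @param connective_phrases phrases asserting a connection.
#' @param p_connective_sentence probability that a content sentence is a
#'   connectivity statement.
#' @param p_abbreviation probability that a document defines an
#'   abbreviation "long form (SF)".
#' @param p_reorder,p_qualifier,p_bracket mention-corruption probabilities
#'   (word-order shuffle; hemisphere/directional qualifier prefix;
#'   appended bracketed abbreviation).
#' @param n_sentences content sentences per document.
#' @param species_pool species names (must be present in the bundled
#'   species lexicon).
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return a `cx_synth_config`.
#' @export
synth_config <- function(n_documents = 100L,
                         region_lexicon = toy_region_lexicon(),
                         connective_phrases = default_connective_phrases(),
                         p_connective_sentence = 0.2,
                         p_abbreviation = 0.3,
                         p_reorder = 0.1, p_qualifier = 0.1, p_bracket = 0.05,
                         n_sentences = 5L,
                         species_pool = c("rat", "cat", "mouse", "human",
                                          "rabbit", "rhesus monkey",
                                          "guinea pig", "chicken"),
                         seed = 1L) {
  probs <- c(p_connective_sentence, p_abbreviation, p_reorder, p_qualifier,
             p_bracket)
  stopifnot(n_documents >= 1L, all(probs >= 0), all(probs <= 1),
            length(connective_phrases) > 0L)
  if (nrow(region_lexicon$entries) == 0L) stop("empty region lexicon")
  structure(list(
    n_documents = as.integer(n_documents), region_lexicon = region_lexicon,
    connective_phrases = connective_phrases,
    p_connective_sentence = p_connective_sentence,
    p_abbreviation = p_abbreviation, p_reorder = p_reorder,
    p_qualifier = p_qualifier, p_bracket = p_bracket,
    n_sentences = as.integer(n_sentences), species_pool = species_pool,
    seed = as.integer(seed)
  ), class = "cx_synth_config")
}

#' Corrupt a region name
#'
#' Applies, with the configured probabilities: a word-order shuffle (a
#' non-identity permutation of the name's words), a prepended hemisphere or
#' directional qualifier, and an appended bracketed abbreviation - the
#' lexical variation the standardization cascade is designed to undo.
#'
#' @param name region name (>= 1 word).
#' @param config a `cx_synth_config` (probabilities are read from it).
#' @return list with `text` (the variant) and `ops` (character vector of
#'   applied operations).  With all probabilities zero this is the
#'   identity.
#' @export
corrupt_region_name <- function(name, config) {
  words <- strsplit(trimws(name), "\\s+")[[1L]]
  stopifnot(length(words) >= 1L)
  ops <- character()
  if (length(words) >= 2L && runif(1) < config$p_reorder) {
    repeat {
      perm <- sample(length(words))
      if (!all(perm == seq_along(words))) break
    }
    words <- words[perm]
    ops <- c(ops, "reorder")
  }
  text <- paste(words, collapse = " ")
  if (runif(1) < config$p_qualifier) {
    pool <- c(.hemisphere_words,
              if (!(tolower(words[1L]) %in% .directional_words)) .directional_words)
    q <- sample(pool, 1L)
    text <- paste(q, text)
    ops <- c(ops, paste0("qualifier:", q))
  }
  if (runif(1) < config$p_bracket) {
    sf <- toupper(paste(substring(strsplit(name, "\\s+")[[1L]], 1L, 1L),
                        collapse = ""))
    if (nchar(sf) >= 2L) {
      text <- paste0(text, " (", sf, ")")
      ops <- c(ops, "bracket")
    }
  }
  list(text = text, ops = ops)
}

# sentence assembly from segments; a segment is plain text, a mention, or a
# species phrase
.seg <- function(text, kind = "text", concept = NA_character_,
                 expanded = text, taxon = NA_character_) {
  list(text = text, kind = kind, concept = concept, expanded = expanded,
       taxon = taxon)
}

.build_sentence <- function(segs, pair_label = NA) {
  text <- ""
  mentions <- list(); species <- list()
  for (s in segs) {
    start <- nchar(text)
    text <- paste0(text, s$text)
    if (s$kind == "mention") {
      mentions[[length(mentions) + 1L]] <-
        data.frame(rel_start = start, rel_end = nchar(text), surface = s$text,
                   expanded = s$expanded, concept = s$concept,
                   stringsAsFactors = FALSE)
    } else if (s$kind == "species") {
      species[[length(species) + 1L]] <-
        data.frame(rel_start = start, rel_end = nchar(text), name = s$text,
                   taxon = s$taxon, stringsAsFactors = FALSE)
    }
  }
  list(text = text, mentions = do.call(rbind, mentions),
       species = do.call(rbind, species), pair_label = pair_label)
}

# fill a template "... %s ... %s ..." with mention segments
.template_segs <- function(template, mention_segs, phrase = NULL) {
  parts <- strsplit(if (is.null(phrase)) template else template, "%s",
                    fixed = TRUE)[[1L]]
  # templates with a connective use three slots: A, phrase, B
  segs <- list()
  slot <- 1L
  fillers <- if (is.null(phrase)) {
    mention_segs
  } else {
    list(mention_segs[[1L]], .seg(phrase), mention_segs[[2L]])
  }
  for (i in seq_along(parts)) {
    if (nzchar(parts[i])) segs[[length(segs) + 1L]] <- .seg(parts[i])
    if (slot <= length(fillers)) {
      segs[[length(segs) + 1L]] <- fillers[[slot]]
      slot <- slot + 1L
    }
  }
  segs
}

.sample1 <- function(x) x[sample.int(length(x), 1L)]

#' Generate a fully annotated synthetic corpus
#'
#' Each document carries a title mentioning a region, a species sentence,
#' optionally an abbreviation-defining sentence "long form (SF)" whose
#' short form later sentences may use as a mention, and content sentences
#' that either assert a connection between two regions (gold-positive
#' pair) or co-mention two regions without connectivity (gold-negative
#' pair).  All spans, tokens, BIO-consistent mentions, gold pairs, gold
#' concept ids and species tags are recorded; output is deterministic
#' given the seed.
#'
#' @param config a [synth_config()].
#' @return a validated `cx_corpus`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "cx_synth_config"))
  species_lex <- load_species_lexicon()
  species_key <- setNames(unname(species_lex), tolower(names(species_lex)))
  missing <- setdiff(tolower(config$species_pool), names(species_key))
  if (length(missing)) stop("species not in lexicon: ", paste(missing, collapse = ", "))
  entries <- config$region_lexicon$entries
  concepts <- unique(entries$concept_id)
  .with_seed(config$seed, {
    docs <- lapply(seq_len(config$n_documents), function(d) {
      doc_id <- sprintf("synth-%04d", d)
      pick_name <- function(cid) .sample1(entries$name[entries$concept_id == cid])

      # abbreviation setup: a multi-word region defined once, reusable later
      abbrev <- NULL
      if (runif(1) < config$p_abbreviation) {
        multi <- concepts[vapply(concepts, function(cid) {
          any(lengths(strsplit(entries$name[entries$concept_id == cid], "\\s+")) >= 2L)
        }, logical(1))]
        cid <- .sample1(multi)
        nms <- entries$name[entries$concept_id == cid]
        nm <- .sample1(nms[lengths(strsplit(nms, "\\s+")) >= 2L])
        sf <- toupper(paste(substring(strsplit(nm, "\\s+")[[1L]], 1L, 1L),
                            collapse = ""))
        if (nchar(sf) >= 2L) abbrev <- list(concept = cid, long = nm, sf = sf)
      }

      # species for the document (occasionally two)
      sp1 <- .sample1(config$species_pool)
      sp2 <- if (runif(1) < 0.1) .sample1(setdiff(config$species_pool, sp1)) else NULL

      mention_seg <- function(cid) {
        nm <- pick_name(cid)
        if (!is.null(abbrev) && cid == abbrev$concept && runif(1) < 0.5) {
          return(.seg(abbrev$sf, "mention", concept = cid,
                      expanded = abbrev$long))
        }
        var <- corrupt_region_name(nm, config)
        .seg(var$text, "mention", concept = cid, expanded = var$text)
      }

      sentences <- list()
      title_cid <- .sample1(concepts)
      sentences[[1L]] <- .build_sentence(list(
        .seg("Connectivity of the "), mention_seg(title_cid), .seg(".")
      ))
      sentences[[2L]] <- .build_sentence(list(
        .seg("Experiments were performed in the adult "),
        .seg(sp1, "species", taxon = species_key[[tolower(sp1)]]),
        .seg(" brain.")
      ))
      if (!is.null(sp2)) {
        sentences[[length(sentences) + 1L]] <- .build_sentence(list(
          .seg("Additional observations were made in the "),
          .seg(sp2, "species", taxon = species_key[[tolower(sp2)]]),
          .seg(".")
        ))
      }
      if (!is.null(abbrev)) {
        sentences[[length(sentences) + 1L]] <- .build_sentence(list(
          .seg("The "),
          .seg(abbrev$long, "mention", concept = abbrev$concept),
          .seg(paste0(" (", abbrev$sf, ") was examined in detail."))
        ))
      }
      for (i in seq_len(config$n_sentences)) {
        cids <- sample(concepts, 2L)
        positive <- runif(1) < config$p_connective_sentence
        segs <- if (positive) {
          .template_segs(.sample1(.positive_templates),
                         list(mention_seg(cids[1L]), mention_seg(cids[2L])),
                         phrase = .sample1(config$connective_phrases))
        } else {
          .template_segs(.sample1(.negative_templates),
                         list(mention_seg(cids[1L]), mention_seg(cids[2L])))
        }
        sentences[[length(sentences) + 1L]] <- .build_sentence(segs, positive)
      }

      # assemble the document text (sentences joined by single spaces) and
      # lift sentence-relative spans to document coordinates
      texts <- vapply(sentences, `[[`, character(1), "text")
      starts <- cumsum(c(0L, head(nchar(texts), -1L) + 1L))
      text <- paste(texts, collapse = " ")
      species_rows <- list()
      sent_objs <- lapply(seq_along(sentences), function(si) {
        sn <- sentences[[si]]
        off <- starts[si]
        mn <- sn$mentions
        mentions <- if (is.null(mn)) mention_frame() else {
          mention_frame(start = off + mn$rel_start, end = off + mn$rel_end,
                        surface = mn$surface, expanded = mn$expanded,
                        concept_id = mn$concept)
        }
        if (!is.null(sn$species)) {
          species_rows[[length(species_rows) + 1L]] <<- data.frame(
            start = off + sn$species$rel_start, end = off + sn$species$rel_end,
            name = sn$species$name, taxon_id = sn$species$taxon,
            stringsAsFactors = FALSE
          )
        }
        pairs <- if (!is.na(sn$pair_label) && nrow(mentions) == 2L) {
          o <- order(mentions$start)
          pair_frame(a_start = mentions$start[o[1L]], a_end = mentions$end[o[1L]],
                     b_start = mentions$start[o[2L]], b_end = mentions$end[o[2L]],
                     gold_label = sn$pair_label)
        } else pair_frame()
        sent <- cx_sentence(start = off, end = off + nchar(sn$text),
                            tokens = tokenize(sn$text, base_offset = off),
                            mentions = mentions, pairs = pairs)
        sent$tokens$bio <- encode_bio(sent)
        sent
      })
      sp <- do.call(rbind, species_rows)
      cx_document(doc_id = doc_id, text = text, sentences = sent_objs,
                  species = if (is.null(sp)) species_frame() else
                    species_frame(sp$start, sp$end, sp$name, sp$taxon_id))
    })
    corpus <- cx_corpus(docs)
    validate_corpus(corpus)
    corpus
  })
}
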