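# Readers and writers.  JSONL is the canonical on-disk corpus format (one
# document per line, full annotations).  AirolaXML, the interchange format
# used by the protein-protein interaction benchmarks, carries sentences,
# entities and labelled pairs only; tokens are regenerated on read.

.span_out <- function(start, end) list(as.integer(start), as.integer(end))

.doc_to_list <- function(doc) {
  list(
    id = doc$doc_id,
    text = doc$text,
    sentences = lapply(doc$sentences, function(s) {
      list(
        span = .span_out(s$start, s$end),
        tokens = lapply(seq_len(nrow(s$tokens)), function(i) {
          tk <- s$tokens[i, ]
          list(span = .span_out(tk$start, tk$end), surface = tk$surface,
               stem = tk$stem, bio = if (is.na(tk$bio)) NULL else tk$bio)
        }),
        mentions = lapply(seq_len(nrow(s$mentions)), function(i) {
          m <- s$mentions[i, ]
          list(span = .span_out(m$start, m$end), surface = m$surface,
               expanded = m$expanded,
               concept_id = if (is.na(m$concept_id)) NULL else m$concept_id,
               match_stage = if (is.na(m$match_stage)) NULL else m$match_stage)
        }),
        pairs = lapply(seq_len(nrow(s$pairs)), function(i) {
          p <- s$pairs[i, ]
          list(a = .span_out(p$a_start, p$a_end), b = .span_out(p$b_start, p$b_end),
               gold_label = if (is.na(p$gold_label)) NULL else p$gold_label,
               score = if (is.na(p$score)) NULL else p$score,
               predicted = if (is.na(p$predicted)) NULL else p$predicted)
        })
      )
    }),
    species = lapply(seq_len(nrow(doc$species)), function(i) {
      sp <- doc$species[i, ]
      list(span = .span_out(sp$start, sp$end), name = sp$name,
           taxon_id = sp$taxon_id)
    })
  )
}

.null_na <- function(x, cast = as.character) if (is.null(x)) cast(NA) else cast(x)

.doc_from_list <- function(rec) {
  if (is.null(rec$id) || is.null(rec$text)) {
    stop("malformed corpus record: missing id or text")
  }
  sentences <- lapply(rec$sentences, function(s) {
    tk <- s$tokens
    mn <- s$mentions
    pr <- s$pairs
    cx_sentence(
      start = s$span[[1]], end = s$span[[2]],
      tokens = token_frame(
        start = vapply(tk, function(t) as.integer(t$span[[1]]), integer(1)),
        end = vapply(tk, function(t) as.integer(t$span[[2]]), integer(1)),
        surface = vapply(tk, function(t) as.character(t$surface), character(1)),
        stem = vapply(tk, function(t) as.character(t$stem), character(1)),
        bio = vapply(tk, function(t) .null_na(t$bio), character(1))
      ),
      mentions = mention_frame(
        start = vapply(mn, function(m) as.integer(m$span[[1]]), integer(1)),
        end = vapply(mn, function(m) as.integer(m$span[[2]]), integer(1)),
        surface = vapply(mn, function(m) as.character(m$surface), character(1)),
        expanded = vapply(mn, function(m) as.character(m$expanded), character(1)),
        concept_id = vapply(mn, function(m) .null_na(m$concept_id), character(1)),
        match_stage = vapply(mn, function(m) .null_na(m$match_stage), character(1))
      ),
      pairs = pair_frame(
        a_start = vapply(pr, function(p) as.integer(p$a[[1]]), integer(1)),
        a_end = vapply(pr, function(p) as.integer(p$a[[2]]), integer(1)),
        b_start = vapply(pr, function(p) as.integer(p$b[[1]]), integer(1)),
        b_end = vapply(pr, function(p) as.integer(p$b[[2]]), integer(1)),
        gold_label = vapply(pr, function(p) .null_na(p$gold_label, as.logical), logical(1)),
        score = vapply(pr, function(p) .null_na(p$score, as.numeric), numeric(1)),
        predicted = vapply(pr, function(p) .null_na(p$predicted, as.logical), logical(1))
      )
    )
  })
  sp <- rec$species
  cx_document(
    doc_id = rec$id, text = rec$text, sentences = sentences,
    species = species_frame(
      start = vapply(sp, function(x) as.integer(x$span[[1]]), integer(1)),
      end = vapply(sp, function(x) as.integer(x$span[[2]]), integer(1)),
      name = vapply(sp, function(x) as.character(x$name), character(1)),
      taxon_id = vapply(sp, function(x) as.character(x$taxon_id), character(1))
    )
  )
}

#' Read a corpus from disk
#'
#' @param path path to a JSONL corpus (one document per line) or an
#'   AirolaXML relation corpus.
#' @param format `"jsonl"` or `"airola_xml"`.
#' @return a validated [cx_corpus()].  In AirolaXML, character offsets are
#'   sentence-relative inclusive (`charOffset="s-e"`); they are converted to
#'   the package's 0-based half-open document coordinates on read, and the
#'   document text is reconstructed by joining sentence texts with single
#'   spaces.  Tokens are regenerated with [tokenize()].
#' @export
read_corpus <- function(path, format = c("jsonl", "airola_xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  corpus <- if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    cx_corpus(lapply(lines, function(ln) {
      rec <- tryCatch(jsonlite::fromJSON(ln, simplifyVector = FALSE),
                      error = function(e) stop("malformed JSONL record: ",
                                               conditionMessage(e)))
      .doc_from_list(rec)
    }))
  } else {
    .read_airola(path)
  }
  validate_corpus(corpus)
  corpus
}

#' Write a corpus to disk
#'
#' Inverse of [read_corpus()]: reading back a written corpus reproduces the
#' ids, text, spans and labels it carried (for AirolaXML, within what that
#' format stores: sentences, mentions and pairs).
#'
#' @param corpus a `cx_corpus`.
#' @param path output file path.
#' @param format `"jsonl"` or `"airola_xml"`.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "airola_xml")) {
  format <- match.arg(format)
  validate_corpus(corpus)
  if (format == "jsonl") {
    lines <- vapply(corpus$documents, function(doc) {
      as.character(jsonlite::toJSON(.doc_to_list(doc), auto_unbox = TRUE,
                                    null = "null", digits = NA))
    }, character(1))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, useBytes = TRUE)
  } else {
    .write_airola(corpus, path)
  }
  invisible(path)
}

# ---- AirolaXML ----

.write_airola <- function(corpus, path) {
  root <- xml2::xml_new_root("corpus", source = "conntext")
  for (di in seq_along(corpus$documents)) {
    doc <- corpus$documents[[di]]
    dnode <- xml2::xml_add_child(root, "document",
                                 id = sprintf("conntext.d%d", di - 1L),
                                 origId = doc$doc_id)
    for (si in seq_along(doc$sentences)) {
      sent <- doc$sentences[[si]]
      sid <- sprintf("conntext.d%d.s%d", di - 1L, si - 1L)
      stext <- span_text(doc$text, sent$start, sent$end)
      snode <- xml2::xml_add_child(dnode, "sentence", id = sid, text = stext)
      mn <- sent$mentions
      eids <- character(nrow(mn))
      for (mi in seq_len(nrow(mn))) {
        eids[mi] <- sprintf("%s.e%d", sid, mi - 1L)
        # inclusive offsets relative to the sentence text
        xml2::xml_add_child(
          snode, "entity", id = eids[mi],
          charOffset = sprintf("%d-%d", mn$start[mi] - sent$start,
                               mn$end[mi] - sent$start - 1L),
          text = mn$surface[mi], type = "brainregion"
        )
      }
      mkey <- paste(mn$start, mn$end)
      pr <- sent$pairs
      for (pi in seq_len(nrow(pr))) {
        e1 <- eids[match(paste(pr$a_start[pi], pr$a_end[pi]), mkey)]
        e2 <- eids[match(paste(pr$b_start[pi], pr$b_end[pi]), mkey)]
        pnode <- xml2::xml_add_child(
          snode, "pair", id = sprintf("%s.p%d", sid, pi - 1L),
          e1 = e1, e2 = e2,
          interaction = if (is.na(pr$gold_label[pi])) "Unknown"
                        else if (pr$gold_label[pi]) "True" else "False"
        )
        if (!is.na(pr$score[pi])) {
          xml2::xml_set_attr(pnode, "score", format(pr$score[pi], digits = 17))
        }
        if (!is.na(pr$predicted[pi])) {
          xml2::xml_set_attr(pnode, "predicted",
                             if (pr$predicted[pi]) "True" else "False")
        }
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

.read_airola <- function(path) {
  root <- xml2::read_xml(path)
  docs <- lapply(xml2::xml_find_all(root, "./document"), function(dnode) {
    orig <- xml2::xml_attr(dnode, "origId")
    if (is.na(orig)) orig <- xml2::xml_attr(dnode, "id")
    snodes <- xml2::xml_find_all(dnode, "./sentence")
    stexts <- xml2::xml_attr(snodes, "text")
    text <- paste(stexts, collapse = " ")
    offset <- 0L
    sentences <- vector("list", length(snodes))
    for (si in seq_along(snodes)) {
      snode <- snodes[[si]]
      stext <- stexts[si]
      s_start <- offset
      s_end <- offset + nchar(stext)
      offset <- s_end + 1L
      enodes <- xml2::xml_find_all(snode, "./entity")
      eid <- xml2::xml_attr(enodes, "id")
      co <- xml2::xml_attr(enodes, "charOffset")
      if (length(co) && any(!grepl("^\\d+-\\d+$", co))) {
        stop(sprintf("document %s: unparseable charOffset", orig))
      }
      rel <- do.call(rbind, lapply(strsplit(co, "-"), as.integer))
      m_start <- if (length(enodes)) s_start + rel[, 1] else integer()
      m_end <- if (length(enodes)) s_start + rel[, 2] + 1L else integer()
      msurf <- span_text(text, m_start, m_end)
      decl <- xml2::xml_attr(enodes, "text")
      if (length(enodes) && any(!is.na(decl) & decl != msurf)) {
        stop(sprintf("document %s: entity text does not match its span", orig))
      }
      pnodes <- xml2::xml_find_all(snode, "./pair")
      p_e1 <- match(xml2::xml_attr(pnodes, "e1"), eid)
      p_e2 <- match(xml2::xml_attr(pnodes, "e2"), eid)
      if (length(pnodes) && anyNA(c(p_e1, p_e2))) {
        stop(sprintf("document %s: pair references unknown entity", orig))
      }
      inter <- xml2::xml_attr(pnodes, "interaction")
      score <- suppressWarnings(as.numeric(xml2::xml_attr(pnodes, "score")))
      pred <- xml2::xml_attr(pnodes, "predicted")
      # order each pair by span start
      a_first <- m_start[p_e1] < m_start[p_e2] |
        (m_start[p_e1] == m_start[p_e2] & m_end[p_e1] <= m_end[p_e2])
      ai <- ifelse(a_first, p_e1, p_e2)
      bi <- ifelse(a_first, p_e2, p_e1)
      toks <- tokenize(stext, base_offset = s_start)
      sentences[[si]] <- cx_sentence(
        start = s_start, end = s_end, tokens = toks,
        mentions = mention_frame(start = m_start, end = m_end, surface = msurf),
        pairs = pair_frame(
          a_start = m_start[ai], a_end = m_end[ai],
          b_start = m_start[bi], b_end = m_end[bi],
          gold_label = ifelse(inter == "Unknown", NA, inter == "True"),
          score = score,
          predicted = ifelse(is.na(pred), NA, pred == "True")
        )
      )
    }
    cx_document(doc_id = orig, text = text, sentences = sentences)
  })
  cx_corpus(docs)
}

# ---- Lexicons ----

#' Load a neuroanatomical lexicon from TSV files
#'
#' Each file must be UTF-8 tab-separated with a header row and columns
#' `concept_id`, `name`, `source`, `is_preferred`.  Entries are merged
#' across files preserving file order; duplicated (concept_id, name) rows
#' collapse to the first occurrence.  The same name listed under different
#' concept ids is kept for both - the ambiguity surfaces at match time.
#'
#' @param paths character vector of TSV paths.
#' @return an object of class `cx_lexicon` with an `entries` data frame and
#'   lazily built matching indexes.
#' @export
load_lexicon <- function(paths) {
  frames <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("lexicon file not found: ", p)
    df <- read.delim(p, sep = "\t", header = TRUE, quote = "",
                     colClasses = "character", fileEncoding = "UTF-8")
    need <- c("concept_id", "name", "source", "is_preferred")
    if (!all(need %in% names(df))) {
      stop("lexicon file ", p, " missing column(s): ",
           paste(setdiff(need, names(df)), collapse = ", "))
    }
    df[need]
  })
  entries <- do.call(rbind, frames)
  entries$is_preferred <- tolower(entries$is_preferred) %in% c("true", "t", "1", "yes")
  entries <- entries[!duplicated(paste(entries$concept_id, entries$name)), ]
  rownames(entries) <- NULL
  if (nrow(entries) && any(!nzchar(entries$name))) stop("lexicon contains empty names")
  new_lexicon(entries)
}

#' Build a lexicon from an entries data frame
#'
#' @param entries data frame with columns concept_id, name, source,
#'   is_preferred.
#' @return a `cx_lexicon`.
#' @export
new_lexicon <- function(entries) {
  structure(list(entries = entries, .index = new.env(parent = emptyenv())),
            class = "cx_lexicon")
}

#' @exportS3Method base::print
print.cx_lexicon <- function(x, ...) {
  cat(sprintf("<cx_lexicon> %d entries, %d concepts, sources: %s\n",
              nrow(x$entries), length(unique(x$entries$concept_id)),
              paste(unique(x$entries$source), collapse = ", ")))
  invisible(x)
}

#' Bundled toy region lexicon
#'
#' A small lexicon of mammalian brain-region names with synonyms, used by
#' the synthetic-corpus generator and the test-suite.  Real lexicons
#' (NeuroNames, NIFSTD, BAMS and kin) are drop-in replacements via
#' [load_lexicon()].
#'
#' @return a `cx_lexicon`.
#' @export
toy_region_lexicon <- function() {
  load_lexicon(system.file("extdata", "region_lexicon.tsv",
                           package = "conntext", mustWork = TRUE))
}

#' Bundled species lexicon
#'
#' Species names with NCBI-style taxon identifiers for the species most
#' frequently associated with connectivity reports.  Larger dictionaries
#' (e.g. full taxonomies) can be supplied in the same two-column TSV format
#' (`name`, `taxon_id`).
#'
#' @param path optional TSV path; defaults to the bundled table.
#' @return named character vector mapping name to taxon id.
#' @export
load_species_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "species_lexicon.tsv",
                        package = "conntext", mustWork = TRUE)
  }
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("name", "taxon_id") %in% names(df))) {
    stop("species lexicon needs columns name, taxon_id")
  }
  setNames(df$taxon_id, df$name)
}
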