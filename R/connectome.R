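# Assembly of predicted, normalized, species-tagged connections into
# species-specific connectivity matrices.  Matrices are undirected and
# symmetric (connection direction is not predicted); counts tally the
# supporting extracted statements, with full provenance.

#' Construct a connectivity matrix
#'
#' @param species taxon id (or `"all"` for the pooled matrix).
#' @param index sorted character vector of concept ids.
#' @param counts symmetric non-negative integer matrix (defaults to zero).
#' @param provenance data.frame with columns concept_a, concept_b, doc_id,
#'   sentence_index, score (one row per supporting statement; counts equal
#'   provenance tallies).
#' @return a `cx_connmatrix`.
#' @export
connectivity_matrix <- function(species, index,
                                counts = NULL, provenance = NULL) {
  index <- sort(unique(as.character(index)))
  if (is.null(counts)) {
    counts <- matrix(0L, length(index), length(index),
                     dimnames = list(index, index))
  }
  if (is.null(provenance)) {
    provenance <- data.frame(concept_a = character(), concept_b = character(),
                             doc_id = character(), sentence_index = integer(),
                             score = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(species = species, index = index, counts = counts,
                 provenance = provenance),
            class = "cx_connmatrix")
}

#' @exportS3Method base::print
print.cx_connmatrix <- function(x, ...) {
  nz <- sum(x$counts[upper.tri(x$counts)] > 0)
  cat(sprintf("<cx_connmatrix> species=%s: %d regions, %d connected pairs, %d statements\n",
              x$species, length(x$index), nz, nrow(x$provenance)))
  invisible(x)
}

.conn_validate <- function(m) {
  stopifnot(inherits(m, "cx_connmatrix"))
  if (!isTRUE(all.equal(m$counts, t(m$counts)))) stop("counts not symmetric")
  if (any(m$counts < 0)) stop("negative counts")
  if (sum(m$counts[upper.tri(m$counts, diag = TRUE)]) != nrow(m$provenance)) {
    stop("counts do not equal provenance tallies")
  }
  invisible(m)
}

#' Aggregate predicted connections into per-species matrices
#'
#' Each prediction contributes to the matrix of every species tagged on its
#' document (a document mentioning several species is duplicated into each
#' species matrix) and once to the pooled `"all"` matrix.  Pairs whose
#' mentions did not normalize (`NA` concept) or normalized ambiguously
#' (several concepts) are excluded and tallied in the skip report -
#' precision-first, matching the high-precision standardization stance.
#'
#' @param predictions data.frame with columns `doc_id`, `sentence_index`,
#'   `concept_a`, `concept_b` (standardized concept ids, `NA` when
#'   unmapped, `"id1|id2"` when ambiguous), `score`.
#' @param doc_species data.frame mapping `doc_id` to `taxon_id` (one row
#'   per document-species tag).
#' @return list with `matrices` (named list of `cx_connmatrix`, one per
#'   taxon plus `"all"`) and `skipped` (counts of excluded pairs by
#'   reason).
#' @export
aggregate_connections <- function(predictions, doc_species) {
  need <- c("doc_id", "sentence_index", "concept_a", "concept_b", "score")
  stopifnot(all(need %in% names(predictions)),
            all(c("doc_id", "taxon_id") %in% names(doc_species)))
  ambiguous <- grepl("|", predictions$concept_a, fixed = TRUE) |
               grepl("|", predictions$concept_b, fixed = TRUE)
  unmapped <- is.na(predictions$concept_a) | is.na(predictions$concept_b)
  self <- !unmapped & !ambiguous &
          predictions$concept_a == predictions$concept_b
  keep <- predictions[!unmapped & !ambiguous & !self, , drop = FALSE]
  skipped <- c(unnormalized = sum(unmapped), ambiguous = sum(ambiguous & !unmapped),
               self_connection = sum(self))
  index <- sort(unique(c(keep$concept_a, keep$concept_b)))
  build <- function(rows, species) {
    m <- connectivity_matrix(species, index)
    for (i in rows) {
      a <- keep$concept_a[i]; b <- keep$concept_b[i]
      m$counts[a, b] <- m$counts[a, b] + 1L
      if (a != b) m$counts[b, a] <- m$counts[b, a] + 1L
      lo <- min(a, b); hi <- max(a, b)
      m$provenance <- rbind(m$provenance, data.frame(
        concept_a = lo, concept_b = hi, doc_id = keep$doc_id[i],
        sentence_index = keep$sentence_index[i], score = keep$score[i],
        stringsAsFactors = FALSE
      ))
    }
    m
  }
  matrices <- list(all = build(seq_len(nrow(keep)), "all"))
  for (taxon in unique(doc_species$taxon_id)) {
    docs <- doc_species$doc_id[doc_species$taxon_id == taxon]
    rows <- which(keep$doc_id %in% docs)
    if (length(rows) == 0L) next
    matrices[[taxon]] <- build(rows, taxon)
  }
  list(matrices = matrices, skipped = skipped)
}

#' Collect predicted connections and species tags from a corpus
#'
#' Walks an annotated corpus and emits one row per pair flagged as
#' connected (predicted, or gold when `use = "gold"`), carrying the
#' normalized concept ids of the two mentions, plus the document-species
#' table - the two inputs of [aggregate_connections()].
#'
#' @param corpus a `cx_corpus` with normalized mentions and labelled or
#'   predicted pairs.
#' @param use `"predicted"` or `"gold"`: which pair flag selects
#'   connections.
#' @return list with `predictions` and `doc_species` data frames.
#' @export
collect_connections <- function(corpus, use = c("predicted", "gold")) {
  use <- match.arg(use)
  rows <- list(); sp <- list()
  for (doc in corpus$documents) {
    if (nrow(doc$species)) {
      sp[[length(sp) + 1L]] <- data.frame(
        doc_id = doc$doc_id, taxon_id = unique(doc$species$taxon_id),
        stringsAsFactors = FALSE)
    }
    for (si in seq_along(doc$sentences)) {
      sent <- doc$sentences[[si]]
      pr <- sent$pairs
      if (nrow(pr) == 0L) next
      flag <- if (use == "predicted") pr$predicted else pr$gold_label
      mn <- sent$mentions
      mkey <- paste(mn$start, mn$end)
      for (pi in which(!is.na(flag) & flag)) {
        ca <- mn$concept_id[match(paste(pr$a_start[pi], pr$a_end[pi]), mkey)]
        cb <- mn$concept_id[match(paste(pr$b_start[pi], pr$b_end[pi]), mkey)]
        rows[[length(rows) + 1L]] <- data.frame(
          doc_id = doc$doc_id, sentence_index = si,
          concept_a = ca, concept_b = cb, score = pr$score[pi],
          stringsAsFactors = FALSE)
      }
    }
  }
  list(
    predictions = if (length(rows)) do.call(rbind, rows) else
      data.frame(doc_id = character(), sentence_index = integer(),
                 concept_a = character(), concept_b = character(),
                 score = numeric(), stringsAsFactors = FALSE),
    doc_species = if (length(sp)) do.call(rbind, sp) else
      data.frame(doc_id = character(), taxon_id = character(),
                 stringsAsFactors = FALSE)
  )
}

#' Threshold a connectivity matrix by repetition support
#'
#' Requiring connections to occur more than once across the corpus trades
#' recall for precision: entries supported by fewer than `min_count`
#' statements are zeroed and their provenance pruned.  `min_count = 1` is
#' the identity, and thresholds are nested (the surviving pairs at t+1 are
#' a subset of those at t).
#'
#' @param matrix a `cx_connmatrix`.
#' @param min_count minimum number of supporting statements (>= 1).
#' @return the filtered `cx_connmatrix`.
#' @export
filter_by_support <- function(matrix, min_count) {
  stopifnot(inherits(matrix, "cx_connmatrix"), min_count >= 1L)
  m <- matrix
  drop <- m$counts < min_count
  m$counts[drop] <- 0L
  if (nrow(m$provenance)) {
    keep <- vapply(seq_len(nrow(m$provenance)), function(i) {
      m$counts[m$provenance$concept_a[i], m$provenance$concept_b[i]] > 0
    }, logical(1))
    m$provenance <- m$provenance[keep, , drop = FALSE]
    rownames(m$provenance) <- NULL
  }
  m
}

.nt_escape <- function(x) gsub("([<>\"{}|^`\\\\])", "", x)

#' Export a connectivity matrix
#'
#' `tsv` writes the square labelled count matrix (re-importable with
#' [read_matrix_tsv()]).  `rdf_ntriples` writes one connects-with triple
#' per supported unordered pair plus one evidence triple per supporting
#' statement, so extracted connectivity can be queried with SPARQL tooling.
#'
#' @param matrix a `cx_connmatrix`.
#' @param path output path.
#' @param format `"tsv"` or `"rdf_ntriples"`.
#' @export
export_matrix <- function(matrix, path, format = c("tsv", "rdf_ntriples")) {
  format <- match.arg(format)
  .conn_validate(matrix)
  if (format == "tsv") {
    df <- as.data.frame(matrix$counts)
    df <- cbind(concept = rownames(matrix$counts), df)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
  } else {
    base <- "urn:conntext"
    lines <- character()
    idx <- which(matrix$counts > 0 & upper.tri(matrix$counts, diag = TRUE),
                 arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      a <- matrix$index[idx[r, 1L]]; b <- matrix$index[idx[r, 2L]]
      lines <- c(lines, sprintf(
        "<%s:concept:%s> <%s:connects-with> <%s:concept:%s> .",
        base, .nt_escape(a), base, base, .nt_escape(b)))
    }
    pv <- matrix$provenance
    for (i in seq_len(nrow(pv))) {
      lines <- c(lines, sprintf(
        "<%s:connection:%s--%s> <%s:evidence> <%s:doc:%s#s%d> .",
        base, .nt_escape(pv$concept_a[i]), .nt_escape(pv$concept_b[i]),
        base, base, .nt_escape(pv$doc_id[i]), pv$sentence_index[i]))
    }
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Read back a TSV connectivity matrix
#'
#' @param path a file written by [export_matrix()] in `tsv` format.
#' @param species species label to attach.
#' @return a `cx_connmatrix` (provenance empty - the TSV carries counts
#'   only, so validation of provenance tallies is skipped on import).
#' @export
read_matrix_tsv <- function(path, species = "all") {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   fileEncoding = "UTF-8")
  index <- as.character(df$concept)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- index
  storage.mode(counts) <- "integer"
  m <- connectivity_matrix(species, index)
  m$counts <- counts[m$index, m$index, drop = FALSE]
  m
}

#' Write the provenance table of a matrix
#'
#' @param matrix a `cx_connmatrix`.
#' @param path output TSV path.
#' @export
export_provenance <- function(matrix, path) {
  pv <- matrix$provenance
  pv$species <- matrix$species
  write.table(pv, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
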