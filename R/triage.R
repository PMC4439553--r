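# Abstract triage: a Bernoulli naive Bayes ranker that orders unlabeled
# abstracts by similarity to a connectivity-positive training set, in the
# style of supervised PubMed filtering front-ends.  Features are binary
# (presence/absence) over three families: title+abstract words, journal
# name and MeSH terms (kept as opaque strings, qualifiers included).

.triage_features <- function(record, flags) {
  f <- character()
  if (isTRUE(flags["words"])) {
    text <- paste(record$title %||% "", record$abstract %||% "")
    w <- unique(.norm_words(text))
    f <- c(f, paste0("W:", w))
  }
  if (isTRUE(flags["journal"]) && !is.null(record$journal) &&
      nzchar(record$journal)) {
    f <- c(f, paste0("J:", tolower(record$journal)))
  }
  if (isTRUE(flags["mesh"]) && length(record$mesh) > 0L) {
    f <- c(f, paste0("M:", tolower(unlist(record$mesh))))
  }
  unique(f)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the abstract triage classifier
#'
#' Bernoulli naive Bayes with add-one smoothing over the enabled binary
#' feature families.  For feature `f`, the per-feature log-likelihood ratio
#' is `log((df_pos + 1) / (n_pos + 2)) - log((df_bg + 1) / (n_bg + 2))`
#' where `df` are document frequencies; the ratios are exposed so that the
#' most relevant features can be inspected directly.
#'
#' @param positives list of records (each a list with fields `doc_id`,
#'   `title`, `abstract`, `journal`, `mesh`) known to contain connectivity
#'   statements.
#' @param background list of records representing the background
#'   literature.
#' @param feature_flags named logical vector enabling families `words`,
#'   `journal`, `mesh`.
#' @return a `cx_triage_model` with the `llr` vector, the class-prior log
#'   odds, and the counts.
#' @export
train_triage <- function(positives, background,
                         feature_flags = c(words = TRUE, journal = TRUE,
                                           mesh = TRUE)) {
  stopifnot(length(positives) > 0L, length(background) > 0L)
  fpos <- lapply(positives, .triage_features, flags = feature_flags)
  fbg <- lapply(background, .triage_features, flags = feature_flags)
  vocab <- unique(c(unlist(fpos), unlist(fbg)))
  if (length(vocab) == 0L) stop("no features enabled or present")
  df_pos <- table(factor(unlist(lapply(fpos, unique)), levels = vocab))
  df_bg <- table(factor(unlist(lapply(fbg, unique)), levels = vocab))
  n_pos <- length(positives); n_bg <- length(background)
  llr <- log((as.numeric(df_pos) + 1) / (n_pos + 2)) -
         log((as.numeric(df_bg) + 1) / (n_bg + 2))
  structure(list(llr = setNames(llr, vocab), prior = log(n_pos / n_bg),
                 n_pos = n_pos, n_bg = n_bg, feature_flags = feature_flags),
            class = "cx_triage_model")
}

#' @exportS3Method base::print
print.cx_triage_model <- function(x, ...) {
  cat(sprintf("<cx_triage_model> %d features, %d positive / %d background\n",
              length(x$llr), x$n_pos, x$n_bg))
  top <- head(sort(x$llr, decreasing = TRUE), 5L)
  cat("top features:", paste(names(top), collapse = ", "), "\n")
  invisible(x)
}

#' Score an abstract for connectivity relevance
#'
#' Sum of the log-likelihood ratios of the known features present in the
#' record (each counted once - Bernoulli) plus the class-prior log odds.
#' Higher is more connectivity-like; deterministic.
#'
#' @param model a `cx_triage_model`.
#' @param record an abstract record (see [train_triage()]).
#' @return a single numeric score.
#' @export
score_abstract <- function(model, record) {
  stopifnot(inherits(model, "cx_triage_model"))
  f <- .triage_features(record, model$feature_flags)
  known <- f[f %in% names(model$llr)]
  sum(model$llr[known]) + model$prior
}

#' Rank a set of abstracts by triage score
#'
#' @param model a `cx_triage_model`.
#' @param records list of abstract records.
#' @return data.frame with `doc_id` and `score`, sorted by decreasing
#'   score.
#' @export
rank_abstracts <- function(model, records) {
  scores <- vapply(records, function(r) score_abstract(model, r), numeric(1))
  ids <- vapply(records, function(r) as.character(r$doc_id %||% NA_character_),
                character(1))
  out <- data.frame(doc_id = ids, score = scores, stringsAsFactors = FALSE)
  out <- out[order(-out$score), ]
  rownames(out) <- NULL
  out
}
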