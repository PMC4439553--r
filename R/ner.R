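# Brain-region named entity recognition: a linear-chain conditional random
# field over BIO-encoded token sequences, trained by L-BFGS with L2
# regularization.  The most informative feature families are the surrounding
# words, the word base forms (stems) and abbreviation expansions;
# orthographic shape and lexicon membership flags are optional extras.

.BIO <- c("O", "B", "I")  # state 1 = O, 2 = B, 3 = I

#' NER feature configuration
#'
#' @param window tokens of context on each side contributing word/stem
#'   features (default 2).
#' @param use_stems include Porter-stem features.
#' @param use_abbrev_expansion include the long-form words of tokens that
#'   are defined abbreviations.
#' @param lexicon optional `cx_lexicon`; when given, tokens inside a
#'   longest dictionary match of any lexicon name get membership flags.
#' @param orthographic include capitalization/digit/punctuation shape
#'   features.
#' @return a `cx_ner_config`.
#' @export
ner_config <- function(window = 2L, use_stems = TRUE,
                       use_abbrev_expansion = TRUE, lexicon = NULL,
                       orthographic = TRUE) {
  stopifnot(window >= 0L)
  structure(list(window = as.integer(window), use_stems = use_stems,
                 use_abbrev_expansion = use_abbrev_expansion,
                 lexicon = lexicon, orthographic = orthographic),
            class = "cx_ner_config")
}

.token_shape <- function(surface) {
  sh <- gsub("[A-Z]", "A", surface)
  sh <- gsub("[a-z]", "a", sh)
  sh <- gsub("[0-9]", "0", sh)
  gsub("(.)\\1+", "\\1", sh)
}

# features for every token of a sentence; abbrevs/lex_cover are
# document-level context
.featurize_sentence <- function(sentence, config, abbrevs = NULL) {
  tk <- sentence$tokens
  n <- nrow(tk)
  if (n == 0L) return(list())
  lows <- tolower(tk$surface)
  lex_cover <- lex_first <- rep(FALSE, n)
  if (!is.null(config$lexicon)) {
    # longest dictionary matches of lexicon names over the sentence text
    stext <- paste(tk$surface, collapse = " ")
    # map via token offsets instead: match against the document-coordinate
    # joined surface is fragile; use the span-based matcher on the original
    # coordinates by reconstructing gaps
    recon <- .reconstruct_sentence_text(sentence)
    hits <- .dict_match(recon$text, unique(config$lexicon$entries$name))
    for (i in seq_len(nrow(hits))) {
      inside <- recon$tok_start >= hits$start[i] & recon$tok_end <= hits$end[i]
      lex_cover <- lex_cover | inside
      first <- which(inside)[1L]
      if (!is.na(first)) lex_first[first] <- TRUE
    }
  }
  exp_words <- vector("list", n)
  if (config$use_abbrev_expansion && !is.null(abbrevs) && nrow(abbrevs)) {
    idx <- match(tk$surface, abbrevs$short_form)
    for (i in which(!is.na(idx))) {
      exp_words[[i]] <- tolower(strsplit(abbrevs$long_form[idx[i]], "\\s+")[[1L]])
    }
  }
  lapply(seq_len(n), function(i) {
    f <- c("b", paste0("w=", lows[i]))
    if (config$use_stems) f <- c(f, paste0("s=", tk$stem[i]))
    if (config$orthographic) {
      f <- c(f, paste0("sh=", .token_shape(tk$surface[i])))
      if (grepl("^[A-Z]", tk$surface[i])) f <- c(f, "cap")
      if (grepl("^[A-Z0-9]+$", tk$surface[i]) && grepl("[A-Z]", tk$surface[i])) {
        f <- c(f, "allcap")
      }
      if (grepl("[0-9]", tk$surface[i])) f <- c(f, "hasdigit")
      if (!grepl("[[:alnum:]]", tk$surface[i])) f <- c(f, "punct")
    }
    if (config$window > 0L) {
      for (d in seq_len(config$window)) {
        for (sgn in c(-1L, 1L)) {
          j <- i + sgn * d
          tag <- sprintf("%+d", sgn * d)
          if (j < 1L) {
            f <- c(f, paste0("w@", tag, "=<BOS>"))
          } else if (j > n) {
            f <- c(f, paste0("w@", tag, "=<EOS>"))
          } else {
            f <- c(f, paste0("w@", tag, "=", lows[j]))
            if (config$use_stems) f <- c(f, paste0("s@", tag, "=", tk$stem[j]))
          }
        }
      }
    }
    if (!is.null(exp_words[[i]])) f <- c(f, paste0("xw=", exp_words[[i]]))
    if (lex_cover[i]) f <- c(f, "inlex")
    if (lex_first[i]) f <- c(f, "inlex_b")
    f
  })
}

# sentence text rebuilt from token surfaces with single-space gaps, plus the
# token offsets inside that rebuilt string
.reconstruct_sentence_text <- function(sentence) {
  tk <- sentence$tokens
  n <- nrow(tk)
  if (n == 0L) return(list(text = "", tok_start = integer(), tok_end = integer()))
  gaps <- c(0L, pmax(tk$start[-1L] - tk$end[-n], 0L))
  starts <- cumsum(gaps + c(0L, nchar(tk$surface[-n])))
  list(text = paste0(paste0(strrep(" ", gaps), tk$surface), collapse = ""),
       tok_start = starts, tok_end = starts + nchar(tk$surface))
}

#' Features of a single token
#'
#' @param sentence a `cx_sentence` with tokens.
#' @param index token position (1-based).
#' @param config a [ner_config()].
#' @param abbrevs optional abbreviation table for the enclosing document.
#' @return character vector of feature strings.
#' @export
featurize_token <- function(sentence, index, config = ner_config(),
                            abbrevs = NULL) {
  stopifnot(index >= 1L, index <= nrow(sentence$tokens))
  .featurize_sentence(sentence, config, abbrevs)[[index]]
}

#' Encode gold mentions as BIO labels
#'
#' The first token of each mention is labelled `B`, the remaining mention
#' tokens `I`, all others `O`.  Mentions whose boundaries fall inside a
#' token are snapped outward to token boundaries (with a warning).
#'
#' @param sentence a `cx_sentence`.
#' @param gold_mentions mention table (defaults to the sentence's own).
#' @return character vector of labels, one per token.
#' @export
encode_bio <- function(sentence, gold_mentions = sentence$mentions) {
  tk <- sentence$tokens
  mn <- gold_mentions
  labels <- rep("O", nrow(tk))
  if (nrow(mn) == 0L) return(labels)
  o <- order(mn$start)
  if (any(mn$start[o][-1L] < mn$end[o][-length(o)])) {
    stop("overlapping gold mentions; corpus invalid")
  }
  snapped <- FALSE
  for (i in seq_len(nrow(mn))) {
    inside <- tk$start < mn$end[i] & tk$end > mn$start[i]
    idx <- which(inside)
    if (length(idx) == 0L) next
    if (tk$start[idx[1L]] != mn$start[i] ||
        tk$end[idx[length(idx)]] != mn$end[i]) snapped <- TRUE
    labels[idx[1L]] <- "B"
    if (length(idx) > 1L) labels[idx[-1L]] <- "I"
  }
  if (snapped) warning("mention boundary inside a token; snapped outward")
  labels
}

#' Decode BIO labels to mention spans
#'
#' `I` following `O` (or opening a sentence) is repaired by promotion to
#' `B`, so every decoded mention is a maximal `B I*` run.
#'
#' @param sentence a `cx_sentence`.
#' @param labels character vector of BIO labels, one per token.
#' @param text optional document text used to fill mention surfaces; when
#'   absent, surfaces are rebuilt from token surfaces with single-space
#'   gaps.
#' @return a [mention_frame()].
#' @export
decode_bio <- function(sentence, labels, text = NULL) {
  tk <- sentence$tokens
  stopifnot(length(labels) == nrow(tk))
  starts <- integer(); ends <- integer()
  open <- FALSE
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (lab == "B" || (lab == "I" && !open)) {
      starts <- c(starts, tk$start[i]); ends <- c(ends, tk$end[i])
      open <- TRUE
    } else if (lab == "I") {
      ends[length(ends)] <- tk$end[i]
    } else {
      open <- FALSE
    }
  }
  if (length(starts) == 0L) return(mention_frame())
  surface <- if (!is.null(text)) {
    span_text(text, starts, ends)
  } else {
    vapply(seq_along(starts), function(i) {
      idx <- which(tk$start >= starts[i] & tk$end <= ends[i])
      recon <- character()
      for (j in seq_along(idx)) {
        if (j > 1L) {
          recon <- c(recon, strrep(" ", tk$start[idx[j]] - tk$end[idx[j - 1L]]))
        }
        recon <- c(recon, tk$surface[idx[j]])
      }
      paste(recon, collapse = "")
    }, character(1))
  }
  mention_frame(start = starts, end = ends, surface = surface)
}

# ---- training ----

.crf_pack_corpus <- function(corpus, config) {
  seqs <- list()
  meta <- list()
  for (di in seq_along(corpus$documents)) {
    doc <- corpus$documents[[di]]
    abbrevs <- if (config$use_abbrev_expansion) {
      extract_abbreviations(doc$text)
    } else NULL
    for (si in seq_along(doc$sentences)) {
      sent <- doc$sentences[[si]]
      if (nrow(sent$tokens) == 0L) next
      seqs[[length(seqs) + 1L]] <- list(
        feats = .featurize_sentence(sent, config, abbrevs),
        labels = match(encode_bio(sent), .BIO)
      )
      meta[[length(meta) + 1L]] <- list(doc = di, sent = si)
    }
  }
  list(seqs = seqs, meta = meta)
}

.crf_fit <- function(seqs, c2, maxit) {
  vocab <- unique(unlist(lapply(seqs, function(s) unlist(s$feats))))
  nfeat <- length(vocab)
  seqs_idx <- lapply(seqs, function(s) {
    list(feats = lapply(s$feats, function(f) match(f, vocab)),
         labels = as.integer(s$labels))
  })
  npar <- nfeat * 3L + 9L + 3L
  cache <- new.env(parent = emptyenv())
  evalf <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    res <- crf_nll_grad(par, seqs_idx, nfeat, c2)
    cache$par <- par
    cache$res <- res
    res
  }
  fit <- optim(rep(0, npar), fn = function(p) evalf(p)$nll,
               gr = function(p) evalf(p)$grad, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e7))
  list(theta = fit$par, vocab = vocab)
}

#' Train the mention recognizer
#'
#' @param corpus a `cx_corpus` with gold mentions.
#' @param config a [ner_config()].
#' @param c2 L2 regularization strength (default 1.0).
#' @param maxit maximum L-BFGS iterations (default 200).
#' @return a `cx_ner_model`.  Training is deterministic given the corpus
#'   order.
#' @export
train_ner <- function(corpus, config = ner_config(), c2 = 1.0, maxit = 200L) {
  stopifnot(inherits(corpus, "cx_corpus"))
  if (length(corpus$documents) == 0L) stop("cannot train on an empty corpus")
  packed <- .crf_pack_corpus(corpus, config)
  if (length(packed$seqs) == 0L) stop("corpus has no tokenized sentences")
  n_mentions <- sum(vapply(packed$seqs, function(s) sum(s$labels == 2L), integer(1)))
  if (n_mentions == 0L) stop("corpus has no gold mentions; nothing to learn")
  fit <- .crf_fit(packed$seqs, c2, maxit)
  structure(list(theta = fit$theta, vocab = fit$vocab, config = config,
                 labels = .BIO, c2 = c2, maxit = maxit),
            class = "cx_ner_model")
}

#' @exportS3Method base::print
print.cx_ner_model <- function(x, ...) {
  cat(sprintf("<cx_ner_model> %d features, window %d\n",
              length(x$vocab), x$config$window))
  invisible(x)
}

#' Save / load a recognizer model
#'
#' The on-disk form is a versioned RDS container holding the CRF parameters
#' and the feature configuration.
#'
#' @param model a `cx_ner_model`.
#' @param path file path.
#' @return `load_ner_model` returns the model.
#' @export
save_ner_model <- function(model, path) {
  stopifnot(inherits(model, "cx_ner_model"))
  saveRDS(list(format = "conntext-ner", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_ner_model
#' @export
load_ner_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "conntext-ner")) stop("not a recognizer model file")
  obj$model
}

#' Predict brain-region mentions in a sentence
#'
#' @param model a trained `cx_ner_model`.
#' @param sentence a tokenized `cx_sentence`.
#' @param abbrevs optional abbreviation table for the document.
#' @param text optional document text for exact mention surfaces.
#' @return a [mention_frame()] (empty for an all-`O` decoding).
#' @export
predict_mentions <- function(model, sentence, abbrevs = NULL, text = NULL) {
  stopifnot(inherits(model, "cx_ner_model"))
  if (nrow(sentence$tokens) == 0L) return(mention_frame())
  feats <- .featurize_sentence(sentence, model$config, abbrevs)
  idx <- lapply(feats, function(f) {
    i <- match(f, model$vocab)
    as.integer(i[!is.na(i)])
  })
  labels <- .BIO[crf_viterbi(idx, model$theta, length(model$vocab))]
  decode_bio(sentence, labels, text = text)
}

#' Tag every sentence of a corpus with predicted mentions
#'
#' @param model a `cx_ner_model`.
#' @param corpus a `cx_corpus` (gold mentions, if any, are replaced).
#' @return the corpus with predicted mentions.
#' @export
tag_corpus <- function(model, corpus) {
  for (di in seq_along(corpus$documents)) {
    doc <- corpus$documents[[di]]
    abbrevs <- if (model$config$use_abbrev_expansion) {
      extract_abbreviations(doc$text)
    } else NULL
    for (si in seq_along(doc$sentences)) {
      sent <- doc$sentences[[si]]
      mn <- predict_mentions(model, sent, abbrevs, text = doc$text)
      sent$mentions <- mn
      sent$pairs <- pair_frame()
      corpus$documents[[di]]$sentences[[si]] <-
        expand_abbreviations(sent, if (is.null(abbrevs)) {
          data.frame(short_form = character(), long_form = character())
        } else abbrevs)
    }
  }
  corpus
}

# ---- evaluation ----

#' Evaluate predicted mentions against gold
#'
#' In `exact` mode a true positive requires identical spans; in `partial`
#' mode any character overlap counts.  Matching is one-to-one and greedy by
#' overlap size with ties broken leftmost, so partial-match precision and
#' recall are never below their exact-match counterparts.
#'
#' @param gold,predicted mention tables from the same sentences.
#' @param mode `"exact"` or `"partial"`.
#' @return a `cx_metrics`.
#' @export
evaluate_ner <- function(gold, predicted, mode = c("exact", "partial")) {
  mode <- match.arg(mode)
  ng <- nrow(gold); np <- nrow(predicted)
  if (ng == 0L || np == 0L) return(compute_metrics(0L, np, ng))
  cand <- expand.grid(g = seq_len(ng), p = seq_len(np))
  ov <- pmin(gold$end[cand$g], predicted$end[cand$p]) -
        pmax(gold$start[cand$g], predicted$start[cand$p])
  if (mode == "exact") {
    keep <- gold$start[cand$g] == predicted$start[cand$p] &
            gold$end[cand$g] == predicted$end[cand$p]
  } else {
    keep <- ov >= 1L
  }
  cand <- cand[keep, , drop = FALSE]
  ov <- ov[keep]
  o <- order(-ov, gold$start[cand$g], predicted$start[cand$p])
  used_g <- logical(ng); used_p <- logical(np)
  tp <- 0L
  for (i in o) {
    g <- cand$g[i]; p <- cand$p[i]
    if (used_g[g] || used_p[p]) next
    used_g[g] <- TRUE; used_p[p] <- TRUE
    tp <- tp + 1L
  }
  compute_metrics(tp, np - tp, ng - tp)
}

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Fold assignment over documents
#'
#' Documents - never sentences - are partitioned uniformly at random into
#' `k` folds, so no abstract is split between training and testing.
#'
#' @param n_docs number of documents.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold ids (1..k), one per document; every fold
#'   is non-empty.
#' @export
make_folds <- function(n_docs, k, seed) {
  if (k > n_docs) stop("more folds than documents")
  .with_seed(seed, sample(rep_len(seq_len(k), n_docs)))
}

#' Cross-validate the mention recognizer
#'
#' Abstract-level k-fold cross-validation: folds partition documents, each
#' document is held out exactly once, and pooled metrics are computed over
#' the concatenated held-out predictions (micro-averaged).
#'
#' @param corpus a `cx_corpus` with gold mentions.
#' @param k number of folds (default 8).
#' @param config a [ner_config()].
#' @param seed RNG seed for the fold assignment.
#' @param c2,maxit CRF training hyperparameters.
#' @return list with `folds` (assignment), `per_fold` (list of
#'   exact/partial `cx_metrics`), and `pooled` (exact and partial
#'   `cx_metrics` over all held-out predictions).
#' @export
cross_validate_ner <- function(corpus, k = 8L, config = ner_config(),
                               seed = 1L, c2 = 1.0, maxit = 200L) {
  ndoc <- length(corpus$documents)
  folds <- make_folds(ndoc, k, seed)
  per_fold <- vector("list", k)
  pooled <- list(exact = integer(3), partial = integer(3))  # tp, fp, fn
  acc <- function(tot, m) tot + c(m$tp, m$fp, m$fn)
  for (f in seq_len(k)) {
    train <- cx_corpus(corpus$documents[folds != f])
    test_docs <- corpus$documents[folds == f]
    model <- train_ner(train, config, c2 = c2, maxit = maxit)
    fold_counts <- list(exact = integer(3), partial = integer(3))
    for (doc in test_docs) {
      abbrevs <- if (config$use_abbrev_expansion) {
        extract_abbreviations(doc$text)
      } else NULL
      for (sent in doc$sentences) {
        pred <- predict_mentions(model, sent, abbrevs, text = doc$text)
        for (mode in c("exact", "partial")) {
          m <- evaluate_ner(sent$mentions, pred, mode)
          fold_counts[[mode]] <- acc(fold_counts[[mode]], m)
          pooled[[mode]] <- acc(pooled[[mode]], m)
        }
      }
    }
    per_fold[[f]] <- lapply(fold_counts, function(x)
      compute_metrics(x[1], x[2], x[3]))
  }
  list(
    folds = folds,
    per_fold = per_fold,
    pooled = lapply(pooled, function(x) compute_metrics(x[1], x[2], x[3]))
  )
}
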