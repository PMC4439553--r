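# Connectivity statement extraction: classify within-sentence brain-region
# mention pairs as connected / not connected with the shallow linguistic
# kernel - a global context kernel (bag-of-n-grams over the fore-between,
# between and between-after token windows) plus a local context kernel
# (position-tagged attributes around each entity), each cosine-normalized
# and summed.  "Shallow" means no syntactic parsing is involved.  The
# relation is undirected: entity placeholders are assigned by textual order
# and the local blocks include both orderings, so swapping the two entities
# leaves features, kernel values and predictions unchanged.

#' All candidate pairs of a sentence
#'
#' Every unordered pair of distinct mentions co-occurring in the sentence,
#' ordered by the first mention's start.  A sentence with m mentions yields
#' m(m-1)/2 pairs.
#'
#' @param sentence a `cx_sentence` with (gold or predicted) mentions.
#' @return a [pair_frame()].
#' @export
generate_pairs <- function(sentence) {
  mn <- sentence$mentions
  mn <- mn[order(mn$start, mn$end), , drop = FALSE]
  m <- nrow(mn)
  if (m < 2L) return(pair_frame())
  idx <- utils::combn(m, 2L)
  pair_frame(
    a_start = mn$start[idx[1L, ]], a_end = mn$end[idx[1L, ]],
    b_start = mn$start[idx[2L, ]], b_end = mn$end[idx[2L, ]]
  )
}

#' Blind the entities of a candidate pair
#'
#' Collapses each mention of the pair to a single placeholder token
#' (`ENTITY_A` / `ENTITY_B`, assigned by textual order) and every other
#' region mention in the sentence to `ENTITY_O`, so the classifier learns
#' from context rather than from region names.
#'
#' @param sentence a `cx_sentence`.
#' @param pair one row of a [pair_frame()].
#' @return a `cx_blinded` instance: list with `tokens` (surface, stem,
#'   shape), `a_index`, `b_index`.
#' @export
blind_entities <- function(sentence, pair) {
  stopifnot(nrow(pair) == 1L)
  if (pair$a_start < pair$b_end && pair$b_start < pair$a_end) {
    stop("overlapping mentions in candidate pair")
  }
  tk <- sentence$tokens
  mn <- sentence$mentions
  # role of each token: 0 plain, 1 = A, 2 = B, 3 = other mention
  role <- integer(nrow(tk))
  tok_in <- function(s, e) which(tk$start < e & tk$end > s)
  role[tok_in(pair$a_start, pair$a_end)] <- 1L
  role[tok_in(pair$b_start, pair$b_end)] <- 2L
  for (i in seq_len(nrow(mn))) {
    hit <- tok_in(mn$start[i], mn$end[i])
    role[hit[role[hit] == 0L]] <- 3L
  }
  surface <- character(); stem <- character(); out_role <- integer()
  i <- 1L
  n <- nrow(tk)
  while (i <= n) {
    if (role[i] == 0L) {
      surface <- c(surface, tolower(tk$surface[i]))
      stem <- c(stem, tk$stem[i])
      out_role <- c(out_role, 0L)
      i <- i + 1L
    } else {
      r <- role[i]
      j <- i
      while (j < n && role[j + 1L] == r) j <- j + 1L
      ph <- c("ENTITY_A", "ENTITY_B", "ENTITY_O")[r]
      surface <- c(surface, ph)
      stem <- c(stem, ph)
      out_role <- c(out_role, r)
      i <- j + 1L
    }
  }
  a_index <- which(out_role == 1L)
  b_index <- which(out_role == 2L)
  if (length(a_index) != 1L || length(b_index) != 1L) {
    stop("pair mentions do not map to sentence tokens")
  }
  structure(list(
    tokens = data.frame(surface = surface, stem = stem,
                        shape = .token_shape(surface),
                        stringsAsFactors = FALSE),
    a_index = a_index, b_index = b_index
  ), class = "cx_blinded")
}

.ngram_counts <- function(stems, tag, ngram_max) {
  out <- character()
  len <- length(stems)
  for (n in seq_len(min(ngram_max, len))) {
    if (len - n + 1L < 1L) next
    grams <- vapply(seq_len(len - n + 1L), function(i) {
      paste(stems[i:(i + n - 1L)], collapse = "_")
    }, character(1))
    out <- c(out, paste0("G|", tag, "|", n, "|", grams))
  }
  out
}

# neighbours of the other entity keep a role-free placeholder name so that
# features are invariant under swapping the two entities
.sym_surface <- function(x) ifelse(x %in% c("ENTITY_A", "ENTITY_B"), "ENTITY_X", x)

.local_block <- function(tokens, center, tag, window) {
  out <- character()
  n <- nrow(tokens)
  for (d in seq_len(window)) {
    for (sgn in c(-1L, 1L)) {
      j <- center + sgn * d
      pos <- sprintf("%+d", sgn * d)
      if (j < 1L || j > n) {
        out <- c(out, paste0("L|", tag, "|", pos, "|<PAD>"))
      } else {
        out <- c(out,
                 paste0("L|", tag, "|", pos, "|w=", .sym_surface(tokens$surface[j])),
                 paste0("L|", tag, "|", pos, "|s=", .sym_surface(tokens$stem[j])),
                 paste0("L|", tag, "|", pos, "|sh=", tokens$shape[j]))
      }
    }
  }
  out
}

#' Shallow-linguistic-kernel feature maps of a blinded instance
#'
#' Global context: counts of stem n-grams (n = 1..`ngram_max`) in the
#' fore-between, between and between-after windows (entities excluded from
#' all windows).  Local context: position-tagged surface/stem/shape
#' attributes of the tokens within `local_window` of each entity; the two
#' entities' blocks are emitted under both role tags, making the map
#' order-symmetric.
#'
#' @param instance a `cx_blinded`.
#' @param ngram_max maximum n-gram order (default 3).
#' @param local_window tokens of context around each entity (default 2).
#' @return a `cx_slk_vector`: list of two named count vectors, `global` and
#'   `local`.
#' @export
slk_features <- function(instance, ngram_max = 3L, local_window = 2L) {
  stopifnot(inherits(instance, "cx_blinded"))
  tk <- instance$tokens
  a <- instance$a_index; b <- instance$b_index
  stems <- .sym_surface(tk$stem)
  fore <- if (a > 1L) stems[1:(a - 1L)] else character()
  between <- if (b - a > 1L) stems[(a + 1L):(b - 1L)] else character()
  after <- if (b < nrow(tk)) stems[(b + 1L):nrow(tk)] else character()
  global <- c(
    .ngram_counts(c(fore, between), "FB", ngram_max),
    .ngram_counts(between, "B", ngram_max),
    .ngram_counts(c(between, after), "BA", ngram_max)
  )
  local <- c(
    .local_block(tk, a, "A", local_window),
    .local_block(tk, b, "B", local_window),
    .local_block(tk, b, "A", local_window),
    .local_block(tk, a, "B", local_window)
  )
  as_counts <- function(x) {
    if (length(x) == 0L) return(setNames(numeric(), character()))
    tab <- table(x)
    setNames(as.numeric(tab), names(tab))
  }
  structure(list(global = as_counts(global), local = as_counts(local)),
            class = "cx_slk_vector")
}

.dot_named <- function(x, y) {
  common <- intersect(names(x), names(y))
  if (length(common) == 0L) return(0)
  sum(x[common] * y[common])
}

.norm_dot <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  .dot_named(x, y) / (nx * ny)
}

#' Shallow linguistic kernel between two instances
#'
#' `K(x, y) = K_g(x, y) / sqrt(K_g(x, x) K_g(y, y)) +
#'  K_l(x, y) / sqrt(K_l(x, x) K_l(y, y))`, each sub-kernel the sparse dot
#' product of the corresponding feature maps.  For any instance with
#' non-empty global and local features, `K(x, x) = 2`.
#'
#' @param x,y `cx_blinded` instances or precomputed `cx_slk_vector`s.
#' @param ngram_max,local_window feature parameters (ignored for
#'   precomputed vectors).
#' @return a real in `[0, 2]`.
#' @export
slk_kernel <- function(x, y, ngram_max = 3L, local_window = 2L) {
  fx <- if (inherits(x, "cx_slk_vector")) x else slk_features(x, ngram_max, local_window)
  fy <- if (inherits(y, "cx_slk_vector")) y else slk_features(y, ngram_max, local_window)
  .norm_dot(fx$global, fy$global) + .norm_dot(fx$local, fy$local)
}

# explicit representation: rows are instances, the global and local blocks
# are L2-normalized separately, so the plain dot product of two rows equals
# the summed normalized kernel
.slk_matrix <- function(fvecs, vocab = NULL) {
  gnames <- lapply(fvecs, function(f) names(f$global))
  lnames <- lapply(fvecs, function(f) names(f$local))
  if (is.null(vocab)) {
    vocab <- list(global = unique(unlist(gnames)), local = unique(unlist(lnames)))
  }
  n <- length(fvecs)
  build <- function(block, vnames) {
    i <- integer(); j <- integer(); x <- numeric()
    for (r in seq_len(n)) {
      v <- fvecs[[r]][[block]]
      nrm <- sqrt(sum(v^2))
      if (nrm == 0) next
      idx <- match(names(v), vnames)
      keep <- !is.na(idx)
      i <- c(i, rep.int(r, sum(keep)))
      j <- c(j, idx[keep])
      x <- c(x, v[keep] / nrm)
    }
    Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, length(vnames)))
  }
  list(X = cbind(build("global", vocab$global), build("local", vocab$local)),
       vocab = vocab)
}

#' Train the connectivity classifier
#'
#' A support vector machine on the explicit normalized shallow-linguistic
#' feature representation; the linear kernel on the concatenated normalized
#' global/local blocks is exactly the summed normalized kernel, and the SVM
#' is fitted through the precomputed kernel matrix.  Decision scores are
#' exposed for ranking.
#'
#' @param instances list of `cx_blinded` (or precomputed `cx_slk_vector`).
#' @param labels logical vector (TRUE = connected); both classes required.
#' @param C SVM cost parameter (> 0; default 1).
#' @param ngram_max,local_window feature parameters.
#' @return a `cx_relation_model`.
#' @export
train_relation_classifier <- function(instances, labels, C = 1,
                                      ngram_max = 3L, local_window = 2L) {
  if (!is.numeric(C) || length(C) != 1L || C <= 0) {
    stop("C must be a positive number")
  }
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  fvecs <- lapply(instances, function(x) {
    if (inherits(x, "cx_slk_vector")) x else slk_features(x, ngram_max, local_window)
  })
  em <- .slk_matrix(fvecs)
  K <- as.matrix(Matrix::tcrossprod(em$X))
  y <- factor(labels, levels = c(FALSE, TRUE))
  svm <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc",
                       C = C, scaled = FALSE)
  sv <- kernlab::SVindex(svm)
  dec <- kernlab::predict(svm, kernlab::as.kernelMatrix(K[, sv, drop = FALSE]),
                          type = "decision")[, 1L]
  resp <- kernlab::predict(svm, kernlab::as.kernelMatrix(K[, sv, drop = FALSE]))
  flip <- mean(dec[resp == "TRUE"]) < mean(dec[resp == "FALSE"])
  structure(list(svm = svm, X = em$X[sv, , drop = FALSE], sv = sv,
                 vocab = em$vocab, flip = flip, C = C,
                 ngram_max = ngram_max, local_window = local_window,
                 n_sv = length(sv)),
            class = "cx_relation_model")
}

#' Score candidate pairs with a trained relation model
#'
#' @param model a `cx_relation_model`.
#' @param instances list of `cx_blinded` or `cx_slk_vector`.
#' @param threshold decision threshold for the predicted label (default 0).
#' @return data.frame with columns `score` (decision value, higher =
#'   more connected) and `predicted`.
#' @export
predict_relations <- function(model, instances, threshold = 0) {
  fvecs <- lapply(instances, function(x) {
    if (inherits(x, "cx_slk_vector")) x
    else slk_features(x, model$ngram_max, model$local_window)
  })
  Xt <- .slk_matrix(fvecs, vocab = model$vocab)$X
  Kt <- as.matrix(Xt %*% Matrix::t(model$X))
  dec <- kernlab::predict(model$svm, kernlab::as.kernelMatrix(Kt),
                          type = "decision")[, 1L]
  if (model$flip) dec <- -dec
  data.frame(score = dec, predicted = dec > threshold)
}

# gold-labelled blinded instances of a corpus, with bookkeeping columns
.collect_relation_instances <- function(corpus) {
  inst <- list()
  info <- list()
  for (di in seq_along(corpus$documents)) {
    doc <- corpus$documents[[di]]
    for (si in seq_along(doc$sentences)) {
      sent <- doc$sentences[[si]]
      pr <- sent$pairs
      for (pi in seq_len(nrow(pr))) {
        if (is.na(pr$gold_label[pi])) next
        inst[[length(inst) + 1L]] <- blind_entities(sent, pr[pi, , drop = FALSE])
        info[[length(info) + 1L]] <- data.frame(
          doc = di, doc_id = doc$doc_id, sentence_index = si, pair_index = pi,
          region_a = sent$mentions$surface[match(paste(pr$a_start[pi], pr$a_end[pi]),
                                                 paste(sent$mentions$start, sent$mentions$end))],
          region_b = sent$mentions$surface[match(paste(pr$b_start[pi], pr$b_end[pi]),
                                                 paste(sent$mentions$start, sent$mentions$end))],
          gold = pr$gold_label[pi],
          sentence_len = nrow(sent$tokens),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  list(instances = inst, info = do.call(rbind, info))
}

#' Cross-validate the connectivity classifier
#'
#' Folds partition documents; pooled precision/recall are micro-averaged
#' over the held-out pairs, and a ranked prediction table with decision
#' scores is returned for confidence-ordered inspection.
#'
#' @param corpus a `cx_corpus` with gold-labelled pairs.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param C SVM cost.
#' @param ngram_max,local_window feature parameters.
#' @return list with `folds`, `pooled` (`cx_metrics`), and `ranked` (one
#'   row per pair: doc_id, sentence_index, region_a, region_b, score,
#'   predicted, gold, sentence_len; sorted by decreasing score).
#' @export
cross_validate_relations <- function(corpus, k = 10L, seed = 1L, C = 1,
                                     ngram_max = 3L, local_window = 2L) {
  coll <- .collect_relation_instances(corpus)
  if (is.null(coll$info) || nrow(coll$info) == 0L) {
    stop("corpus has no gold-labelled pairs")
  }
  folds <- make_folds(length(corpus$documents), k, seed)
  fvecs <- lapply(coll$instances, slk_features,
                  ngram_max = ngram_max, local_window = local_window)
  info <- coll$info
  info$score <- NA_real_
  info$predicted <- NA
  for (f in seq_len(k)) {
    test_rows <- which(folds[info$doc] == f)
    train_rows <- setdiff(seq_len(nrow(info)), test_rows)
    if (length(test_rows) == 0L) next
    model <- train_relation_classifier(fvecs[train_rows], info$gold[train_rows],
                                       C = C, ngram_max = ngram_max,
                                       local_window = local_window)
    pred <- predict_relations(model, fvecs[test_rows])
    info$score[test_rows] <- pred$score
    info$predicted[test_rows] <- pred$predicted
  }
  pooled <- compute_metrics(
    tp = sum(info$predicted & info$gold, na.rm = TRUE),
    fp = sum(info$predicted & !info$gold, na.rm = TRUE),
    fn = sum(!info$predicted & info$gold, na.rm = TRUE)
  )
  ranked <- info[order(-info$score),
                 c("doc_id", "sentence_index", "region_a", "region_b",
                   "score", "predicted", "gold", "sentence_len")]
  rownames(ranked) <- NULL
  list(folds = folds, pooled = pooled, ranked = ranked)
}

#' Mean sentence length by score decile
#'
#' Summarizes a ranked prediction table: predictions are split into ten
#' equal groups from the highest to the lowest decision score and the mean
#' sentence length (in tokens) is reported per group, making the
#' length/confidence relationship visible.
#'
#' @param ranked the `ranked` table of [cross_validate_relations()].
#' @return data.frame with columns `decile`, `n`, `mean_sentence_len`.
#' @export
score_decile_lengths <- function(ranked) {
  ranked <- ranked[order(-ranked$score), ]
  n <- nrow(ranked)
  dec <- ceiling(seq_len(n) / n * 10)
  agg <- aggregate(ranked$sentence_len, by = list(decile = dec), FUN = mean)
  cnt <- as.vector(table(dec))
  data.frame(decile = agg$decile, n = cnt, mean_sentence_len = agg$x)
}
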