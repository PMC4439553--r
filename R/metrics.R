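# Shared precision/recall/F1 containers.  Precision is the proportion of
# true positives among positive predictions, recall the proportion of true
# positives among actual positives; both are NA (reported as null in JSON)
# when their denominator is zero.

#' Precision, recall and F1 from confusion counts
#'
#' @param tp,fp,fn non-negative integer counts of true positives, false
#'   positives and false negatives.
#' @return an object of class `cx_metrics`: a list with fields `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f1`.  Undefined ratios are `NA`.
#' @examples
#' compute_metrics(70, 70, 30)  # precision 0.5, recall 0.7
#' @export
compute_metrics <- function(tp, fp, fn) {
  stopifnot(length(tp) == 1L, length(fp) == 1L, length(fn) == 1L)
  if (any(c(tp, fp, fn) < 0)) stop("confusion counts must be non-negative")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(precision) || is.na(recall)) {
    NA_real_
  } else if (precision + recall == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         precision = precision, recall = recall, f1 = f1),
    class = "cx_metrics"
  )
}

#' Micro-averaged pooling of per-fold metrics
#'
#' Sums confusion counts across folds and recomputes the ratios, so pooled
#' rates are corpus-level rates (micro-averaging).
#'
#' @param metrics_list list of `cx_metrics`.
#' @param macro if `TRUE`, average precision/recall/F1 over folds instead
#'   (folds with undefined values are dropped from the mean).
#' @return a `cx_metrics` object (micro) or a list of means (macro).
#' @export
pool_metrics <- function(metrics_list, macro = FALSE) {
  stopifnot(length(metrics_list) > 0L)
  if (!macro) {
    return(compute_metrics(
      sum(vapply(metrics_list, `[[`, integer(1), "tp")),
      sum(vapply(metrics_list, `[[`, integer(1), "fp")),
      sum(vapply(metrics_list, `[[`, integer(1), "fn"))
    ))
  }
  avg <- function(field) {
    v <- vapply(metrics_list, `[[`, numeric(1), field)
    mean(v[!is.na(v)])
  }
  list(precision = avg("precision"), recall = avg("recall"), f1 = avg("f1"))
}

#' @exportS3Method base::print
print.cx_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat(sprintf("tp=%d fp=%d fn=%d  P=%s R=%s F1=%s\n",
              x$tp, x$fp, x$fn,
              fmt(x$precision), fmt(x$recall), fmt(x$f1)))
  invisible(x)
}
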