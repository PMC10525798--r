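# Overlap metrics from one-vs-rest pixel confusion counts. All five
# metrics are pure functions of (TP, FP, FN, TN); Dice and F1 are
# algebraically identical, and Dice = 2*IoU / (1 + IoU).

#' Per-label confusion counts
#'
#' One-vs-rest pixel counts for a single label.
#'
#' @param pred,truth `H x W` integer masks of equal shape.
#' @param label The label treated as positive.
#' @return Object of class `confusion_counts`: list with `tp`, `fp`, `fn`,
#'   `tn` (their sum is the pixel count).
#' @export
confusion_counts <- function(pred, truth, label) {
  if (!is.matrix(pred) || !is.matrix(truth) ||
      !all(dim(pred) == dim(truth)))
    validation_error("'pred' and 'truth' must be matrices of equal shape")
  p <- pred == label
  t <- truth == label
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t)),
            class = "confusion_counts")
}

as_counts <- function(c) {
  if (inherits(c, "confusion_counts")) return(c)
  if (is.list(c) && all(c("tp", "fp", "fn") %in% names(c))) {
    if (is.null(c$tn)) c$tn <- 0
    return(structure(c, class = "confusion_counts"))
  }
  validation_error("expected confusion counts with tp/fp/fn")
}

# degenerate-denominator convention: an entirely absent label that is also
# never predicted is perfect agreement (1); any other empty denominator is 0
degenerate <- function(c) {
  if (c$tp == 0 && c$fp == 0 && c$fn == 0) 1 else 0
}

#' Overlap metrics from confusion counts
#'
#' `dice(c)` is `2*TP / (FP + FN + 2*TP)`; `iou(c)` is
#' `TP / (TP + FP + FN)`; `recall(c)` is `TP / (TP + FN)`; `precision(c)`
#' is `TP / (TP + FP)`; `f1(c)` is `2*TP / ((TP + FN) + (TP + FP))`.
#' When both masks are empty for the label (tp = fp = fn = 0) all return
#' 1; any other zero denominator returns 0.
#'
#' @param c A [confusion_counts()] or list with `tp`, `fp`, `fn`.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(c) {
  c <- as_counts(c)
  den <- c$fp + c$fn + 2 * c$tp
  if (den == 0) return(degenerate(c))
  2 * c$tp / den
}

#' @rdname dice
#' @export
iou <- function(c) {
  c <- as_counts(c)
  den <- c$tp + c$fp + c$fn
  if (den == 0) return(degenerate(c))
  c$tp / den
}

#' @rdname dice
#' @export
recall <- function(c) {
  c <- as_counts(c)
  den <- c$tp + c$fn
  if (den == 0) return(degenerate(c))
  c$tp / den
}

#' @rdname dice
#' @export
precision <- function(c) {
  c <- as_counts(c)
  den <- c$tp + c$fp
  if (den == 0) return(degenerate(c))
  c$tp / den
}

#' @rdname dice
#' @export
f1 <- function(c) {
  c <- as_counts(c)
  den <- (c$tp + c$fn) + (c$tp + c$fp)
  if (den == 0) return(degenerate(c))
  2 * c$tp / den
}

#' Evaluate predicted masks against ground truth
#'
#' Confusion counts are pooled over all samples per label
#' (micro-averaging, the default) and the five metrics computed from the
#' pooled counts; `macro = TRUE` instead averages per-sample metrics. The
#' reported `mean` row averages the non-background labels (organ metrics
#' only, background excluded).
#'
#' @param preds,truths Equal-length lists of `H x W` integer masks.
#' @param scheme A [label_scheme()] or scheme name.
#' @param macro Average per-sample metrics instead of pooling counts.
#' @return Object of class `metrics_report`: data frame with columns
#'   `label, dice, iou, recall, precision, f1`; one row per label plus a
#'   `mean` row over non-background labels. Attribute `n` holds the sample
#'   count.
#' @export
evaluate <- function(preds, truths, scheme = "multi", macro = FALSE) {
  scheme <- label_scheme(scheme)
  if (!is.list(preds)) preds <- list(preds)
  if (!is.list(truths)) truths <- list(truths)
  if (length(preds) == 0L) validation_error("no masks to evaluate")
  if (length(preds) != length(truths))
    validation_error("'preds' and 'truths' must have the same length")
  k <- n_labels(scheme)
  metric_fns <- list(dice = dice, iou = iou, recall = recall,
                     precision = precision, f1 = f1)
  rows <- lapply(seq_len(k) - 1L, function(lab) {
    if (!macro) {
      tot <- list(tp = 0, fp = 0, fn = 0, tn = 0)
      for (i in seq_along(preds)) {
        cc <- confusion_counts(preds[[i]], truths[[i]], lab)
        tot <- Map(`+`, tot, cc[c("tp", "fp", "fn", "tn")])
      }
      vals <- vapply(metric_fns, function(f) f(as_counts(tot)), numeric(1))
    } else {
      per <- vapply(seq_along(preds), function(i) {
        cc <- confusion_counts(preds[[i]], truths[[i]], lab)
        vapply(metric_fns, function(f) f(cc), numeric(1))
      }, numeric(5))
      vals <- rowMeans(per)
    }
    data.frame(label = scheme$labels[lab + 1L], t(vals))
  })
  rep <- do.call(rbind, rows)
  organ <- rep[rep$label != "background", ]
  rep <- rbind(rep, data.frame(label = "mean",
                               t(colMeans(organ[, -1, drop = FALSE]))))
  attr(rep, "n") <- length(preds)
  class(rep) <- c("metrics_report", "data.frame")
  rep
}

#' Write a metrics report as comma-separated text
#'
#' Columns mirror the conventional comparison-table order:
#' `label,dice,iou,recall,precision,f1`.
#'
#' @param report A [evaluate()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
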