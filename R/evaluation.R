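#' Confusion matrix of predicted versus true labels
#'
#' @param truth character/factor vector of true labels.
#' @param predicted vector of predicted labels, same length.
#' @param labels label order; defaults to the sorted union.
#' @return Square integer matrix indexed `(true, predicted)` with dimnames,
#'   of class `confusion_matrix`. Row sums are the per-label sample counts.
#' @export
confusion_matrix <- function(truth, predicted, labels = NULL) {
  if (is.null(labels)) labels <- sort(unique(c(as.character(truth),
                                               as.character(predicted))))
  t_f <- factor(as.character(truth), levels = labels)
  p_f <- factor(as.character(predicted), levels = labels)
  stopifnot(!anyNA(t_f), !anyNA(p_f))
  cm <- table(truth = t_f, predicted = p_f)
  cm <- matrix(as.integer(cm), nrow = length(labels),
               dimnames = list(truth = labels, predicted = labels))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Row-normalize a confusion matrix
#'
#' Divides each row by its sum, i.e. normalizes to the number of instances
#' of each label; all-zero rows stay zero.
#'
#' @param cm a [confusion_matrix()].
#' @return Numeric matrix of per-true-label prediction proportions.
#' @export
normalize_confusion <- function(cm) {
  rs <- rowSums(cm)
  out <- sweep(unclass(cm), 1, pmax(rs, 1), "/")
  out[rs == 0, ] <- 0
  out
}

#' Per-label classification tally
#'
#' Computes TP, FP, FN and TN for one label of a multi-class confusion
#' matrix. Two TN conventions are available: `"tp_rest"` (the default)
#' defines TN as the sum of the true positives of the other labels — the
#' convention this pipeline reports — while `"standard"` is the usual
#' one-vs-rest count of all correct rejections (everything that is neither
#' in the label's row nor its column).
#'
#' @param cm a [confusion_matrix()].
#' @param label label name (must be present in `cm`).
#' @param tn_convention `"tp_rest"` or `"standard"`.
#' @return A list of class `label_tally` with fields `TP`, `FP`, `FN`, `TN`,
#'   `label`, `tn_convention`.
#' @export
tally_label <- function(cm, label, tn_convention = c("tp_rest", "standard")) {
  tn_convention <- match.arg(tn_convention)
  labels <- rownames(cm)
  if (!label %in% labels) {
    stop(sprintf("label '%s' not present in the confusion matrix", label),
         call. = FALSE)
  }
  i <- match(label, labels)
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  tn <- if (tn_convention == "tp_rest") {
    sum(diag(unclass(cm))) - tp
  } else {
    sum(cm) - tp - fp - fn
  }
  structure(list(TP = as.numeric(tp), FP = as.numeric(fp), FN = as.numeric(fn),
                 TN = as.numeric(tn), label = label,
                 tn_convention = tn_convention),
            class = "label_tally")
}

zero_with_warning <- function(what, label) {
  warning(sprintf("%s undefined for label '%s' (zero denominator); returning 0",
                  what, label), call. = FALSE)
  0
}

#' F1 score of a label tally
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`; returns 0 with a warning when the
#' denominator is zero.
#'
#' @param t a [tally_label()] result.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(t) {
  den <- 2 * t$TP + t$FP + t$FN
  if (den == 0) return(zero_with_warning("F1", t$label))
  2 * t$TP / den
}

#' Sensitivity, specificity and accuracy of a label tally
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `accuracy = (TP+TN)/(TP+FP+TN+FN)`. Zero denominators yield 0 with a
#' warning so fold aggregation never fails.
#'
#' @param t a [tally_label()] result.
#' @return Named numeric vector `c(sensitivity, specificity, accuracy)`.
#' @export
sensitivity_specificity_accuracy <- function(t) {
  sens <- if (t$TP + t$FN == 0) {
    zero_with_warning("sensitivity", t$label)
  } else t$TP / (t$TP + t$FN)
  spec <- if (t$TN + t$FP == 0) {
    zero_with_warning("specificity", t$label)
  } else t$TN / (t$TN + t$FP)
  tot <- t$TP + t$FP + t$TN + t$FN
  acc <- if (tot == 0) {
    zero_with_warning("accuracy", t$label)
  } else (t$TP + t$TN) / tot
  c(sensitivity = sens, specificity = spec, accuracy = acc)
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps a decision threshold over the target-class score, grouping tied
#' scores, and traces `(1 - specificity, sensitivity)`. The AUC is the
#' trapezoidal area, which under the tie-grouping (midpoint) convention
#' equals the Mann-Whitney U statistic divided by `n_pos * n_neg`.
#'
#' @param scores numeric vector of target-class scores (higher = more
#'   confident in `target_label`), or a matrix/data.frame of per-class
#'   scores with column names containing `target_label`.
#' @param labels true labels.
#' @param target_label the positive class.
#' @return A list of class `roc_curve`: `points` (tibble `fpr`, `tpr`,
#'   `threshold`), `auc`, `target_label`, `n_pos`, `n_neg`.
#' @export
roc_one_vs_rest <- function(scores, labels, target_label) {
  if (is.matrix(scores) || is.data.frame(scores)) {
    cn <- colnames(scores)
    col <- if (target_label %in% cn) target_label else paste0("p_", target_label)
    stopifnot(col %in% cn)
    scores <- if (is.data.frame(scores)) as.numeric(scores[[col]]) else
      as.numeric(scores[, col])
  }
  pos <- labels == target_label
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC undefined: need at least one positive and one negative sample",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group ties: cumulative counts at each distinct score
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last_of_group]
  fp <- cumsum(!p)[last_of_group]
  pts <- tibble::tibble(
    fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos),
    threshold = c(Inf, s[last_of_group]))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, target_label = target_label,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve '%s': AUC %.4f (%d pos / %d neg)>\n",
              x$target_label, x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Chance level of an n-way classification
#'
#' @param n_classes number of classes (>= 2).
#' @return Chance accuracy in percent, rounded to two decimals (e.g. 14.29
#'   for seven classes, 50 for two, 25 for four).
#' @export
chance_level <- function(n_classes) {
  stopifnot(n_classes >= 2)
  round(100 / n_classes, 2)
}

#' Full metrics report for a set of predictions
#'
#' Per-label F1, sensitivity, specificity and accuracy (under the reported
#' TN convention), plus one-vs-rest AUC when per-class scores are supplied.
#'
#' @param truth true labels.
#' @param predicted predicted labels.
#' @param scores optional per-class score matrix/tibble (columns `p_<label>`).
#' @param tn_convention TN convention passed to [tally_label()].
#' @return A list of class `metrics_report`: `overall_accuracy`,
#'   `chance_level`, `confusion` and `by_label` (tibble).
#' @export
metrics_report <- function(truth, predicted, scores = NULL,
                           tn_convention = "tp_rest") {
  cm <- confusion_matrix(truth, predicted)
  labels <- rownames(cm)
  by_label <- purrr::map_dfr(labels, function(l) {
    t <- tally_label(cm, l, tn_convention)
    ssa <- suppressWarnings(sensitivity_specificity_accuracy(t))
    row <- tibble::tibble(
      label = l, TP = t$TP, FP = t$FP, FN = t$FN, TN = t$TN,
      f1 = suppressWarnings(f1_score(t)),
      sensitivity = ssa["sensitivity"], specificity = ssa["specificity"],
      accuracy = ssa["accuracy"])
    if (!is.null(scores)) {
      row$auc <- roc_one_vs_rest(scores, truth, l)$auc
    }
    row
  })
  structure(
    list(overall_accuracy = mean(as.character(truth) == as.character(predicted)),
         chance_level = chance_level(length(labels)),
         confusion = cm, by_label = by_label),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report: accuracy %.1f%% (chance %.2f%%)>\n",
              100 * x$overall_accuracy, x$chance_level))
  print(x$by_label)
  invisible(x)
}

#' @rdname metrics_report
#' @param x a `metrics_report`.
#' @param ... unused.
#' @export
tidy.metrics_report <- function(x, ...) x$by_label

#' @rdname metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(accuracy = x$overall_accuracy,
                 chance_level_pct = x$chance_level,
                 macro_f1 = mean(x$by_label$f1),
                 n_labels = nrow(x$by_label))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
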