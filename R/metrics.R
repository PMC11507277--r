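#' Multiclass confusion matrix
#'
#' Counts with rows = true label and columns = predicted label, both in the
#' fixed vocabulary code order, so the layout is identical across runs.
#'
#' @param true,predicted label vectors (character or factor) of equal length.
#' @return 4x4 integer matrix of class `posture_confusion`.
#' @export
confusion_matrix <- function(true, predicted) {
  if (length(true) != length(predicted)) {
    stop("contract error: true and predicted labels differ in length",
         call. = FALSE)
  }
  t_f <- parse_posture_labels(true)
  p_f <- parse_posture_labels(predicted)
  cm <- table(true = t_f, predicted = p_f)
  m <- matrix(as.integer(cm), nrow = length(posture_levels()),
              dimnames = list(true = posture_levels(),
                              predicted = posture_levels()))
  structure(m, class = c("posture_confusion", class(m)))
}

#' Row-normalized confusion matrix
#'
#' @param cm a confusion matrix of counts.
#' @return Matrix of per-true-class proportions; empty rows stay 0.
#' @export
confusion_proportions <- function(cm) {
  rs <- rowSums(cm)
  sweep(unclass(cm), 1, pmax(rs, 1), "/")
}

#' Five-metric evaluation of a confusion matrix
#'
#' Accuracy is trace/total. Precision, recall and F1 are computed one-vs-rest
#' per class from the binary TP/FP/FN forms and then averaged: macro (the
#' default) weights every posture equally; micro pools counts, in which case
#' precision and recall both equal accuracy (a useful self-check). Cohen's
#' kappa is `(Po - Pe) / (1 - Pe)` with `Po` the accuracy and
#' `Pe = sum(row_k * col_k) / total^2` the chance agreement from the margins.
#' A class absent from both margins gets precision and recall 0 with a
#' warning before averaging.
#'
#' @param cm matrix of counts from [confusion_matrix()].
#' @param average `"macro"` (default) or `"micro"`.
#' @return Named numeric vector `accuracy, precision, recall, f1, kappa`.
#' @export
score_confusion <- function(cm, average = c("macro", "micro")) {
  average <- match.arg(average)
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  k <- nrow(cm)
  tp <- diag(cm)
  row_s <- rowSums(cm) # true counts
  col_s <- colSums(cm) # predicted counts
  accuracy <- sum(tp) / total

  if (average == "macro") {
    empty <- (row_s + col_s) == 0
    if (any(empty)) {
      warning("class(es) with no observations or predictions scored as 0: ",
              paste(rownames(cm)[empty], collapse = ", "), call. = FALSE)
    }
    prec_c <- ifelse(col_s > 0, tp / col_s, 0)
    rec_c <- ifelse(row_s > 0, tp / row_s, 0)
    f1_c <- ifelse(prec_c + rec_c > 0, 2 * prec_c * rec_c / (prec_c + rec_c), 0)
    precision <- mean(prec_c)
    recall <- mean(rec_c)
    f1 <- mean(f1_c)
  } else {
    precision <- accuracy
    recall <- accuracy
    f1 <- accuracy
  }

  pe <- sum(row_s * col_s) / total^2
  kappa <- if (pe >= 1) {
    if (accuracy >= 1) 1 else 0
  } else {
    (accuracy - pe) / (1 - pe)
  }
  c(accuracy = accuracy, precision = precision, recall = recall,
    f1 = f1, kappa = kappa)
}

#' Score predicted against true labels
#'
#' Convenience wrapper: [confusion_matrix()] then [score_confusion()].
#'
#' @inheritParams confusion_matrix
#' @inheritParams score_confusion
#' @return Named numeric vector of the five metrics.
#' @export
score_predictions <- function(true, predicted, average = "macro") {
  score_confusion(confusion_matrix(true, predicted), average = average)
}

metric_cols <- function() c("accuracy", "precision", "recall", "f1", "kappa")
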