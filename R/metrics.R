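#' Confusion counts at a probability threshold
#'
#' An enhancer is predicted positive when its probability is at or above the
#' threshold.
#'
#' @param labels 0/1 vector (1 = eRNA-positive).
#' @param probabilities numeric vector in [0,1], same length.
#' @param threshold decision threshold (default 0.5).
#' @return A list of class \code{confusion_counts} with integer \code{TP},
#'   \code{TN}, \code{FP}, \code{FN}.
#' @export
confusion_at_threshold <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities))
  if (length(labels) == 0L) stop("empty input", call. = FALSE)
  y <- as.integer(labels)
  stopifnot(all(y %in% c(0L, 1L)), all(probabilities >= 0 & probabilities <= 1))
  pred <- probabilities >= threshold
  structure(list(TP = sum(pred & y == 1L), TN = sum(!pred & y == 0L),
                 FP = sum(pred & y == 0L), FN = sum(!pred & y == 1L)),
            class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' with the convention that any zero factor in the denominator gives 0.
#'
#' @param counts a \code{confusion_counts} object, or a list/vector with
#'   elements TP, TN, FP, FN.
#' @return A value in [-1, 1].
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' MCC of probabilistic predictions at a threshold, or maximized over thresholds
#' @param labels 0/1 vector.
#' @param probabilities predicted probabilities.
#' @param threshold decision threshold (default 0.5).
#' @param maximize if \code{TRUE}, return the maximum MCC over all
#'   distinct-probability thresholds.
#' @return A value in [-1, 1].
#' @export
mcc_at <- function(labels, probabilities, threshold = 0.5, maximize = FALSE) {
  if (!maximize) return(mcc(confusion_at_threshold(labels, probabilities, threshold)))
  thr <- sort(unique(probabilities))
  max(vapply(thr, function(t) mcc(confusion_at_threshold(labels, probabilities, t)),
             numeric(1)))
}

#' ROC curve and AUC
#'
#' AUC is computed as the normalized Mann-Whitney statistic -- the fraction
#' of (positive, negative) pairs where the positive outscores the negative,
#' ties counted half -- which equals the trapezoidal area under the
#' sensitivity versus 1 - specificity curve. A perfect separation scores 1;
#' scores carrying no label information score 0.5 in expectation.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores numeric scores (higher = more positive).
#' @return A list of class \code{erna_roc} with \code{auc} and a
#'   data.frame \code{points} of (threshold, sensitivity, specificity).
#' @export
roc_auc <- function(labels, scores) {
  y <- as.integer(labels)
  stopifnot(length(y) == length(scores), all(y %in% c(0L, 1L)))
  P <- sum(y == 1L); N <- sum(y == 0L)
  if (P == 0L || N == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks: ties get half credit
  auc <- (sum(r[y == 1L]) - P * (P + 1) / 2) / (P * N)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(y[ord] == 1L)
  fp <- cumsum(y[ord] == 0L)
  s <- scores[ord]
  last <- rev(!duplicated(rev(s)))  # keep last point of each tied run
  points <- data.frame(threshold = c(Inf, s[last]),
                       sensitivity = c(0, tp[last] / P),
                       specificity = c(1, 1 - fp[last] / N))
  structure(list(auc = auc, points = points), class = "erna_roc")
}

#' @export
print.erna_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d operating points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.erna_roc <- function(x, ...) {
  plot(1 - x$points$specificity, x$points$sensitivity, type = "l",
       xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Evaluate probabilistic predictions: AUC, MCC at 0.5 and maximized MCC
#' @param labels 0/1 vector.
#' @param probabilities predicted probabilities.
#' @return A one-row data.frame with \code{auc}, \code{mcc}, \code{mcc_max}.
#' @export
evaluate_predictions <- function(labels, probabilities) {
  data.frame(auc = roc_auc(labels, probabilities)$auc,
             mcc = mcc_at(labels, probabilities, 0.5),
             mcc_max = mcc_at(labels, probabilities, maximize = TRUE))
}
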