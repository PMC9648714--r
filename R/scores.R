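#' Prediction score under the "filter" strategy: decoded mass
#'
#' A filter-trained autoencoder lets only positive-class information through
#' the bottleneck, so the total amount of decoded information — the sum of
#' all cells of the decoded output — scores how positive an element looks.
#' Ranges over `[0, p]`.
#'
#' @param x_prime decoded matrix (or vector) with entries in [0, 1].
#' @return Scalar score.
#' @export
score_filter <- function(x_prime) {
  if (any(x_prime < 0 | x_prime > 1)) stop("decoded entries must lie in [0, 1]")
  sum(x_prime)
}

#' Prediction score under the "inverse" strategy: inverse reconstruction error
#'
#' An inverse-trained autoencoder reconstructs positives and the complement
#' of negatives, so a low reconstruction error flags a positive. The score
#' is `1 - (1/p) * sum((x - x')^2)`, in [0, 1].
#'
#' @param x input matrix with entries in [0, 1].
#' @param x_prime decoded matrix of the same shape.
#' @return Scalar score in [0, 1].
#' @export
score_inverse <- function(x, x_prime) {
  if (length(x) != length(x_prime)) stop("x and x_prime have different shapes")
  1 - mean((x - x_prime)^2)
}

#' Gini-impurity-minimising threshold for 1-D scores
#'
#' Scans the midpoints of consecutive sorted unique scores and returns the
#' cut minimising the size-weighted Gini impurity of the induced two-group
#' split (the CART split criterion). Ties are broken towards the smallest
#' threshold. The split convention downstream is `predicted = score >=
#' threshold`.
#'
#' @param scores numeric vector.
#' @param classes 0/1 vector of the same length (both classes present).
#' @return The threshold, with the achieved impurity in
#'   `attr(, "impurity")`.
#' @export
gini_threshold <- function(scores, classes) {
  if (length(scores) != length(classes)) stop("scores/classes length mismatch")
  if (length(unique(classes)) < 2L) stop("both classes must be present")
  u <- sort(unique(scores))
  if (length(u) < 2L) stop("degenerate split: all scores identical")
  cand <- (u[-length(u)] + u[-1L]) / 2
  n <- length(scores)
  best <- Inf; best_t <- NA_real_
  for (t in cand) {
    left <- scores < t
    nl <- sum(left); nr <- n - nl
    p1l <- if (nl > 0L) mean(classes[left]) else 0
    p1r <- if (nr > 0L) mean(classes[!left]) else 0
    imp <- (nl / n) * 2 * p1l * (1 - p1l) + (nr / n) * 2 * p1r * (1 - p1r)
    if (imp < best - 1e-12) { best <- imp; best_t <- t }
  }
  structure(best_t, impurity = best)
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney form with average ranks for ties: the probability that a
#' random positive outscores a random negative, ties counting half.
#'
#' @param scores numeric vector.
#' @param classes 0/1 vector.
#' @return AUC-ROC in [0, 1].
#' @export
auc_roc <- function(scores, classes) {
  n1 <- sum(classes == 1L); n0 <- sum(classes == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[classes == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step integration)
#'
#' Thresholds descend through the unique scores; at each, precision and
#' recall are computed from cumulative counts (tied scores enter together)
#' and the curve is integrated as `sum((R_k - R_{k-1}) * P_k)`.
#'
#' @inheritParams auc_roc
#' @return AUC-PR in [0, 1].
#' @export
auc_pr <- function(scores, classes) {
  P <- sum(classes == 1L)
  if (P == 0L || sum(classes == 0L) == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- classes[o]
  tp <- cumsum(y == 1L); fp <- cumsum(y == 0L)
  last <- !duplicated(s, fromLast = TRUE)     # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  rec <- tp / P; prec <- tp / (tp + fp)
  sum(diff(c(0, rec)) * prec)
}

#' Matthews correlation coefficient at a threshold
#'
#' Computed from the confusion matrix of `predicted = score >= threshold`.
#' A zero margin (denominator) yields MCC 0 with a warning.
#'
#' @inheritParams auc_roc
#' @param threshold decision threshold.
#' @return MCC in [-1, 1].
#' @export
mcc <- function(scores, classes, threshold) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & classes == 1L); tn <- sum(pred == 0L & classes == 0L)
  fp <- sum(pred == 1L & classes == 0L); fn <- sum(pred == 0L & classes == 1L)
  den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) {
    warning("MCC denominator is zero (a confusion margin is empty); reporting 0")
    return(0)
  }
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
}

#' Evaluate scores against outcomes
#'
#' Bundles AUC-ROC, AUC-PR and the MCC at a threshold (computed by
#' [gini_threshold()] when not supplied) with the confusion counts.
#'
#' @inheritParams auc_roc
#' @param threshold optional decision threshold; default: Gini-minimising.
#' @return Object of class `evaluation_report`: list with `auc_roc`,
#'   `auc_pr`, `mcc`, `threshold` and `confusion` (tp, fp, fn, tn).
#' @export
evaluate_scores <- function(scores, classes, threshold = NULL) {
  if (is.null(threshold)) threshold <- as.numeric(gini_threshold(scores, classes))
  pred <- as.integer(scores >= threshold)
  conf <- c(tp = sum(pred == 1L & classes == 1L),
            fp = sum(pred == 1L & classes == 0L),
            fn = sum(pred == 0L & classes == 1L),
            tn = sum(pred == 0L & classes == 0L))
  structure(list(auc_roc = auc_roc(scores, classes),
                 auc_pr = auc_pr(scores, classes),
                 mcc = mcc(scores, classes, threshold),
                 threshold = as.numeric(threshold),
                 confusion = conf),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report\n")
  cat(sprintf("  AUC-ROC: %.4f   AUC-PR: %.4f   MCC: %.4f\n",
              x$auc_roc, x$auc_pr, x$mcc))
  cat(sprintf("  threshold: %.6g   confusion (tp fp fn tn): %s\n",
              x$threshold, paste(x$confusion, collapse = " ")))
  invisible(x)
}

#' Write per-patient scores to CSV
#'
#' Columns `patient_id,score,class,predicted`.
#'
#' @param patient_ids,scores,classes aligned vectors.
#' @param threshold decision threshold for the `predicted` column.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_scores <- function(patient_ids, scores, classes, threshold, path) {
  utils::write.csv(data.frame(patient_id = patient_ids, score = scores,
                              class = classes,
                              predicted = as.integer(scores >= threshold)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
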