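# Classification, ranking, agreement and similarity metrics.

#' Rank-based AUROC
#'
#' Area under the ROC curve via the Mann-Whitney U normalization with
#' average ranks for ties.
#'
#' @param yTrue binary 0/1 vector with both classes present.
#' @param yProb scores.
#' @return AUROC in \[0, 1\].
#' @export
aurocScore <- function(yTrue, yProb) {
  pos <- yTrue == 1
  nP <- sum(pos); nN <- sum(!pos)
  stopifnot(nP > 0, nN > 0)
  r <- rank(yProb)
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise summation over the descending-score ranking, ties broken by
#' stable input order.
#'
#' @inheritParams aurocScore
#' @export
averagePrecision <- function(yTrue, yProb) {
  ord <- order(-yProb)
  y <- yTrue[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / sum(y)
  dRec <- diff(c(0, rec))
  sum(prec * dRec)
}

#' Confusion-derived and ranking metrics for one model/test pairing
#'
#' Computes sensitivity, specificity, balanced accuracy, MCC, F1, PPV and
#' the positive likelihood ratio LR+ = sensitivity / (1 - specificity)
#' from the confusion matrix of the thresholded calls, plus average
#' precision and AUROC from the probability ranking when provided. When
#' specificity is 1 the LR+ is reported as the `Inf` sentinel and flagged.
#'
#' @param yTrue binary truth (both classes required).
#' @param yCall binary calls.
#' @param yProb optional probabilities for the ranking metrics.
#' @return a `MetricReport`: named list with the metric fields and the
#'   confusion counts.
#' @examples
#' binaryMetrics(c(1, 1, 1, 0, 0, 0), c(1, 1, 0, 0, 0, 1))
#' @export
binaryMetrics <- function(yTrue, yCall, yProb = NULL) {
  stopifnot(length(yTrue) == length(yCall), all(yTrue %in% 0:1),
            all(yCall %in% 0:1))
  if (length(unique(yTrue)) < 2L) stop("both classes must be present in yTrue")
  tp <- sum(yTrue == 1 & yCall == 1)
  fp <- sum(yTrue == 0 & yCall == 1)
  tn <- sum(yTrue == 0 & yCall == 0)
  fn <- sum(yTrue == 1 & yCall == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  mccDen <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mccDen > 0) (tp * tn - fp * fn) / mccDen else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  lr <- if (spec < 1) sens / (1 - spec) else Inf
  rep <- list(
    sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2,
    mcc = mcc, f1 = f1, ppv = ppv, lr_plus = lr,
    lr_plus_sentinel = !is.finite(lr),
    average_precision = if (!is.null(yProb)) averagePrecision(yTrue, yProb)
                        else NA_real_,
    auroc = if (!is.null(yProb)) aurocScore(yTrue, yProb) else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
  class(rep) <- c("MetricReport", class(rep))
  rep
}

#' @export
print.MetricReport <- function(x, ...) {
  cat(sprintf(
    "MetricReport: BA=%.3f MCC=%.3f F1=%.3f LR+=%.2f AUROC=%s [TP=%d FP=%d TN=%d FN=%d]\n",
    x$balanced_accuracy, x$mcc, x$f1, x$lr_plus,
    ifelse(is.na(x$auroc), "NA", sprintf("%.3f", x$auroc)),
    x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' @export
as.data.frame.MetricReport <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Top-k detection analysis along the ROC curve
#'
#' Counts true and false positives among the k top-ranked compounds
#' (descending probability, ties broken by stable input order) and reports
#' the precision PPV = tp/k and the positive likelihood ratio
#' LR+ = (tp/P)/(fp/N) at that operating point; when no false positive is
#' present among the top k the LR+ is the `Inf` sentinel.
#'
#' @param yTrue binary truth.
#' @param yProb probabilities.
#' @param k number of top-ranked compounds, 1 <= k <= length(yTrue).
#' @return list with `k`, `tp`, `fp`, `ppv`, `lr_plus`, `P`, `N`.
#' @examples
#' topkDetection(c(1, 0, 1, 1), c(0.9, 0.8, 0.7, 0.2), k = 2)
#' @export
topkDetection <- function(yTrue, yProb, k) {
  if (k <= 0 || k > length(yTrue)) stop("k must be in 1..length(yTrue)")
  P <- sum(yTrue == 1); N <- sum(yTrue == 0)
  ord <- order(-yProb)
  top <- yTrue[ord][seq_len(k)]
  tp <- sum(top == 1); fp <- k - tp
  list(k = k, tp = tp, fp = fp, ppv = tp / k,
       lr_plus = if (fp > 0) (tp / P) / (fp / N) else Inf,
       P = P, N = N)
}

#' Positive-match (Jaccard) similarity of two prediction vectors
#'
#' Intersection over union of the positive calls; mutual absences do not
#' count as matches. An empty union returns 0 with the `"emptyUnion"`
#' attribute set.
#'
#' @param callsA,callsB equal-length binary vectors.
#' @export
predictionJaccard <- function(callsA, callsB) {
  if (length(callsA) != length(callsB)) stop("call vectors differ in length")
  inter <- sum(callsA == 1 & callsB == 1)
  uni <- sum(callsA == 1 | callsB == 1)
  out <- if (uni == 0) 0 else inter / uni
  attr(out, "emptyUnion") <- uni == 0
  out
}

# Tanimoto similarity between two 0/1 fingerprint matrices (rows = mols).
tanimotoMatrix <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  inter <- tcrossprod(a, b)
  ca <- rowSums(a); cb <- rowSums(b)
  den <- outer(ca, cb, "+") - inter
  out <- ifelse(den == 0, 0, inter / den)
  out
}

#' Nearest-neighbour similarity profile of a test set to a training set
#'
#' For each test compound, the mean of the `nNeighbors` highest Tanimoto
#' similarities (2048-bit circular fingerprints) to the training compounds;
#' used as a structural applicability note. With fewer training compounds
#' than neighbours the mean is over the available ones (flagged).
#'
#' @param testFps,trainFps 0/1 fingerprint matrices.
#' @param nNeighbors number of nearest neighbours (default 3).
#' @return numeric vector in \[0, 1\], one value per test compound.
#' @export
nnSimilarityProfile <- function(testFps, trainFps, nNeighbors = 3L) {
  if (is.null(dim(trainFps)) || nrow(trainFps) == 0L)
    stop("empty training set")
  sims <- tanimotoMatrix(testFps, trainFps)
  k <- min(nNeighbors, ncol(sims))
  out <- apply(sims, 1L, function(s) mean(sort(s, decreasing = TRUE)[seq_len(k)]))
  attr(out, "truncated") <- k < nNeighbors
  out
}

#' Paired comparison of fold-level metric distributions
#'
#' Paired t-test on a chosen metric across fold-level reports from two
#' models evaluated on identical fold/repeat pairings. A zero-variance
#' difference vector is degenerate and flagged instead of tested.
#'
#' @param reportsA,reportsB data.frames of fold-level metrics with matching
#'   `repeat_id`/`fold` columns.
#' @param metric column to compare (default `"balanced_accuracy"`).
#' @return list with `t`, `p_value`, `mean_difference`, `degenerate`.
#' @export
compareFoldDistributions <- function(reportsA, reportsB,
                                     metric = "balanced_accuracy") {
  key <- function(df) paste(df$repeat_id, df$fold)
  if (!identical(sort(key(reportsA)), sort(key(reportsB))))
    stop("reports are not paired by fold/repeat identity")
  a <- reportsA[order(key(reportsA)), metric]
  b <- reportsB[order(key(reportsB)), metric]
  d <- a - b
  if (stats::sd(d) < 1e-10 * max(1, abs(mean(d)))) {
    if (all(abs(d) < 1e-12)) {
      # identical distributions: no difference to test
      return(list(t = 0, p_value = 1, mean_difference = 0, degenerate = FALSE))
    }
    # constant nonzero shift: zero-variance denominator, flagged
    return(list(t = NA_real_, p_value = NA_real_, mean_difference = mean(d),
                degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_difference = mean(d), degenerate = FALSE)
}
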