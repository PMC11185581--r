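# Classification, ranking, agreement and similarity metrics.

bruteMetrics <- function(y, call) {
  tp <- sum(y & call); fp <- sum(!y & call)
  tn <- sum(!y & !call); fn <- sum(y & !call)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  list(tp = tp, fp = fp, tn = tn, fn = fn, sens = sens, spec = spec)
}

test_that("binary metrics match their confusion-count definitions", {
  # perfect classifier
  m <- binaryMetrics(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(m$balanced_accuracy, 1)
  expect_equal(m$mcc, 1)
  expect_true(is.infinite(m$lr_plus))
  expect_true(m$lr_plus_sentinel)
  expect_equal(m$auroc, 1)

  # hand-evaluated example: TP=2 TN=2 FP=1 FN=1
  m2 <- binaryMetrics(c(1, 1, 1, 0, 0, 0), c(1, 1, 0, 1, 0, 0))
  expect_equal(m2$mcc, 1 / 3)
  expect_equal(m2$f1, 2 / 3)

  # sensitivity 0.34 / specificity 0.74 -> LR+ = 1.31 (2 d.p.)
  y <- c(rep(1, 100), rep(0, 100))
  call <- c(rep(1, 34), rep(0, 66), rep(1, 26), rep(0, 74))
  m3 <- binaryMetrics(y, call)
  expect_equal(m3$sensitivity, 0.34)
  expect_equal(m3$specificity, 0.74)
  expect_equal(round(m3$lr_plus, 2), 1.31)

  expect_error(binaryMetrics(c(1, 1), c(1, 0)), "both classes")
})

test_that("every metric equals brute-force recomputation on random instances", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(6:200, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    p <- runif(n)
    call <- as.integer(p >= runif(1))
    m <- binaryMetrics(y, call, p)
    b <- bruteMetrics(y, call)
    expect_identical(c(m$tp, m$fp, m$tn, m$fn), c(b$tp, b$fp, b$tn, b$fn))
    expect_equal(m$sensitivity, b$sens)
    expect_equal(m$specificity, b$spec)
    expect_equal(m$balanced_accuracy, (b$sens + b$spec) / 2)
    expect_equal(m$ppv, if (b$tp + b$fp > 0) b$tp / (b$tp + b$fp) else NA_real_)
    expect_equal(m$f1, 2 * b$tp / (2 * b$tp + b$fp + b$fn))
    den <- sqrt(prod(c(b$tp + b$fp, b$tp + b$fn, b$tn + b$fp, b$tn + b$fn)))
    expect_equal(m$mcc,
                 if (den > 0) (b$tp * b$tn - b$fp * b$fn) / den else 0)
    if (b$spec < 1) expect_equal(m$lr_plus, b$sens / (1 - b$spec))
    expect_true(m$mcc >= -1 - 1e-12 && m$mcc <= 1 + 1e-12)
  }
})

test_that("AUROC equals the Mann-Whitney U normalization", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(8:60, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- runif(n)
    u <- suppressWarnings(
      stats::wilcox.test(p[y == 1], p[y == 0])$statistic)
    expect_equal(aurocScore(y, p),
                 unname(u) / (sum(y == 1) * sum(y == 0)),
                 tolerance = 1e-12)
  }
})

test_that("top-k detection reproduces the published arithmetic", {
  # 25 true positives among the top 29 of 156 positives / 67 negatives
  y <- c(rep(1, 25), rep(0, 4), rep(1, 131), rep(0, 63))
  p <- seq(1, 0, length.out = length(y))
  tk <- topkDetection(y, p, 29)
  expect_equal(tk$tp, 25L)
  expect_equal(tk$fp, 4L)
  expect_equal(round(tk$lr_plus, 2), 2.68)
  expect_equal(round(tk$ppv, 2), 0.86)
  # the structure-only operating point: 23 of 29
  y2 <- c(rep(1, 23), rep(0, 6), rep(1, 133), rep(0, 61))
  tk2 <- topkDetection(y2, p, 29)
  expect_equal(round(tk2$lr_plus, 2), 1.65)
  # k = n reproduces the whole-set sensitivity/FPR ratio
  tkAll <- topkDetection(y, p, length(y))
  expect_equal(tkAll$lr_plus, (tkAll$tp / 156) / (tkAll$fp / 67))
  # all-positive top-k: sentinel
  tk1 <- topkDetection(y, p, 10)
  expect_equal(tk1$ppv, 1)
  expect_true(is.infinite(tk1$lr_plus))
  expect_error(topkDetection(y, p, 0), "k must be")
  # monotonicity: tp never decreases with k
  tps <- vapply(1:50, function(k) topkDetection(y, p, k)$tp, 1L)
  expect_true(all(diff(tps) >= 0))
})

test_that("positive-match Jaccard ignores mutual absences", {
  expect_equal(as.numeric(predictionJaccard(c(1, 1, 0), c(1, 1, 0))), 1)
  expect_equal(as.numeric(predictionJaccard(c(1, 0, 0), c(0, 1, 0))), 0)
  expect_equal(as.numeric(predictionJaccard(c(1, 1, 0), c(1, 0, 1))), 1 / 3)
  empty <- predictionJaccard(c(0, 0), c(0, 0))
  expect_equal(as.numeric(empty), 0)
  expect_true(attr(empty, "emptyUnion"))
  expect_error(predictionJaccard(c(1, 0), c(1, 0, 1)), "length")
})

test_that("nearest-neighbour profiles match exhaustive computation", {
  # a test compound with three identical training duplicates scores 1
  fp <- matrix(c(1, 0, 1, 1), 1)
  train <- rbind(fp, fp, fp, matrix(c(0, 1, 0, 0), 1))
  expect_equal(as.numeric(nnSimilarityProfile(fp, train)), 1)

  set.seed(23)
  for (i in 1:10) {
    test <- matrix(rbinom(20 * 50, 1, 0.3), 20)
    train <- matrix(rbinom(50 * 50, 1, 0.3), 50)
    got <- as.numeric(nnSimilarityProfile(test, train))
    naive <- apply(test, 1, function(a) {
      sims <- apply(train, 1, function(b) {
        inter <- sum(a & b); uni <- sum(a | b)
        if (uni == 0) 0 else inter / uni
      })
      mean(sort(sims, decreasing = TRUE)[1:3])
    })
    expect_equal(got, naive, tolerance = 1e-12)
    # mean of top-3 never exceeds the single nearest neighbour
    nn1 <- as.numeric(nnSimilarityProfile(test, train, nNeighbors = 1L))
    expect_true(all(got <= nn1 + 1e-12))
  }
  expect_error(nnSimilarityProfile(matrix(1, 1, 4), matrix(numeric(0), 0, 4)),
               "empty")
})

test_that("paired fold comparison matches the textbook t statistic", {
  mk <- function(v) data.frame(repeat_id = 1, fold = seq_along(v),
                               balanced_accuracy = v)
  # identical distributions
  same <- compareFoldDistributions(mk(c(0.6, 0.7, 0.8)), mk(c(0.6, 0.7, 0.8)))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # constant nonzero shift: degenerate zero-variance case
  shift <- compareFoldDistributions(mk(c(0.6, 0.7, 0.8)), mk(c(0.5, 0.6, 0.7)))
  expect_true(shift$degenerate)
  # 5-pair hand example against the formula
  a <- c(0.61, 0.72, 0.68, 0.55, 0.63)
  b <- c(0.58, 0.69, 0.70, 0.50, 0.60)
  d <- a - b
  tHand <- mean(d) / (sd(d) / sqrt(5))
  got <- compareFoldDistributions(mk(a), mk(b))
  expect_equal(got$t, tHand, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * pt(-abs(tHand), df = 4), tolerance = 1e-12)
  # unpaired inputs are an error
  expect_error(compareFoldDistributions(mk(a), mk(b)[1:3, ]), "paired")
})
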