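# Proxy endpoint models: thresholds, halving search, regressors, the
# 11-column block, and the cross-prediction grid.

bruteForceThreshold <- function(y, p) {
  cand <- sort(unique(c(p / 2, p, p + 1e-9, (sort(p)[-1] + sort(p)[-length(p)]) / 2,
                        min(p) / 2, max(p) + 0.5)))
  js <- vapply(cand, function(t) {
    call <- as.integer(p >= t)
    sens <- sum(call & y) / sum(y)
    spec <- sum(!call & !y) / sum(!y)
    sens + spec - 1
  }, numeric(1))
  max(js)
}

test_that("Youden threshold maximizes J with the smallest-tie rule", {
  # perfect separation: midpoint returned
  thr <- selectThreshold(c(0, 1), c(0.2, 0.9))
  expect_equal(thr$value, 0.55)
  expect_equal(thr$j, 1)
  # worked example: max J = 0.5, two optimal regions, smallest candidate
  thr2 <- selectThreshold(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
  expect_equal(thr2$value, 0.225)
  expect_equal(thr2$j, 0.5)
  # constant probabilities: degenerate, 0.5
  thr3 <- selectThreshold(c(0, 1), c(0.4, 0.4))
  expect_true(thr3$degenerate)
  expect_equal(thr3$value, 0.5)
  expect_error(selectThreshold(c(1, 1), c(0.2, 0.3)), "both classes")

  # exhaustive oracle: the attained J equals the brute-force maximum over
  # all thresholds, on random instances up to n = 50
  set.seed(14)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)
    got <- selectThreshold(y, p)
    expect_equal(got$j, bruteForceThreshold(y, p), tolerance = 1e-12)
    # smallest qualifying threshold: the returned value is the first
    # candidate attaining the maximum J
    u <- sort(unique(p))
    cand <- c(u[1] / 2, (u[-length(u)] + u[-1]) / 2, (u[length(u)] + 1) / 2)
    js <- vapply(cand, function(t) {
      call <- as.integer(p >= t)
      sum(call & y) / sum(y) + sum(!call & !y) / sum(!y) - 1
    }, numeric(1))
    expect_equal(got$value, cand[which(js >= max(js) - 1e-9)[1]],
                 tolerance = 1e-12)
  }
})

test_that("stratified folds balance classes and cover every record once", {
  set.seed(2)
  y <- rbinom(100, 1, 0.3)
  f <- stratifiedFolds(y, 5, seed = 9)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(length(f), 100L)
  perFold <- table(f, y)
  expect_true(max(perFold[, "1"]) - min(perFold[, "1"]) <= 1)
  # deterministic given the seed
  expect_identical(f, stratifiedFolds(y, 5, seed = 9))
})

test_that("endpoint classifiers learn planted signal and not noise", {
  # linearly separable planted bit, n = 60
  ft <- toyFeatureTable(60, seed = 21)
  y <- featureMatrix(ft)[, "morgan_0003"]
  ds <- toyEndpoint(ft, y)
  clf <- trainEndpointClassifier(ds, ft, tinySearch())
  expect_gte(clf$cvScore, 0.95)
  expect_true(clf$threshold$value >= 0 && clf$threshold$value <= 1)

  # labels independent of features: held-out performance near chance
  ft2 <- toyFeatureTable(200, seed = 22)
  set.seed(7)
  yNull <- rbinom(200, 1, 0.5)
  clf2 <- trainEndpointClassifier(toyEndpoint(ft2, yNull), ft2, tinySearch(7))
  expect_true(clf2$cvScore >= 0.35 && clf2$cvScore <= 0.65)

  # a single-class dataset is an undefined task
  expect_error(
    trainEndpointClassifier(toyEndpoint(ft, rep(1, 60)), ft, tinySearch()),
    "single class")
})

test_that("halving search is deterministic and refits the winner", {
  ft <- toyFeatureTable(80, seed = 30)
  y <- featureMatrix(ft)[, "morgan_0001"]
  x <- featureMatrix(ft)
  s1 <- halvingSearch(x, y, "binary", tinySearch(3))
  s2 <- halvingSearch(x, y, "binary", tinySearch(3))
  expect_identical(s1$best, s2$best)
  expect_identical(s1$score, s2$score)
  expect_true(nrow(s1$trace) >= tinySearch()@nCandidates)
})

test_that("Cmax regressors recover linear structure and refuse tiny data", {
  ft <- toyFeatureTable(400, seed = 31)
  x <- featureMatrix(ft)
  y <- 3 * x[, "desc1"]
  search <- modelSearchSpec(cvFolds = 5L, nCandidates = 8L,
                            minResource = 50L, seed = 9L)
  reg <- trainCmaxRegressor(toyEndpoint(ft, y, task = "regression"), ft,
                            search)
  expect_gte(reg$cvScore, 0.8)
  pred <- diliNet:::.predictForest(reg$model, x)
  expect_true(all(is.finite(pred)))

  # permuted targets carry no signal
  set.seed(8)
  search@seed <- 8L
  regNull <- trainCmaxRegressor(toyEndpoint(ft, sample(y), task = "regression"),
                                ft, search)
  expect_lte(regNull$cvScore, 0.1)

  ftSmall <- toyFeatureTable(10, seed = 32)
  expect_error(
    trainCmaxRegressor(toyEndpoint(ftSmall, rnorm(10), task = "regression"),
                       ftSmall, tinySearch()),
    "insufficient")
})

test_that("the proxy block has 11 registry-ordered probability/Cmax columns", {
  bundle <- smallBundle()
  f <- smallFeatures()
  # the small registry: 3 classifiers + 1 regressor
  expect_equal(length(bundle@registryOrder),
               length(bundle@classifiers) + length(bundle@regressors))
  block <- buildProxyBlock(f$gold, bundle)
  expect_equal(ncol(block), length(bundle@registryOrder))
  expect_equal(colnames(block), paste0("proxy_", bundle@registryOrder))
  probCols <- paste0("proxy_", names(bundle@classifiers))
  expect_true(all(block[, probCols] >= 0 & block[, probCols] <= 1))
  expect_true(all(is.finite(block)))

  # full registry arithmetic: 9 classifiers + 2 regressors = 11 columns
  expect_equal(length(fixtureSpec()@nPerEndpoint) +
                 length(fixtureSpec()@nCmax), 11L)

  # leak-freedom: block values depend only on the model and features, not
  # on any training label
  block2 <- buildProxyBlock(f$gold, bundle)
  expect_identical(block, block2)
})

test_that("cross-prediction flags the diagonal as resubstitution", {
  bundle <- smallBundle()
  f <- smallFeatures()
  proxies <- smallProxies()
  binEps <- Filter(function(e) taskType(e) == "binary", proxies)
  grid <- crossPredictMatrix(bundle, binEps, f$proxy)
  nb <- length(binEps)
  expect_equal(nrow(grid), nb * nb)
  expect_equal(sum(grid$resubstitution), nb)
  # resubstitution cells score at least as well as transfer cells on
  # average (optimism of in-sample evaluation)
  ok <- !grid$empty
  expect_gte(mean(grid$balanced_accuracy[grid$resubstitution & ok]),
             mean(grid$balanced_accuracy[!grid$resubstitution & ok]))
  # off-diagonal cells exclude the model's own training compounds
  diag_n <- grid$n[grid$resubstitution]
  expect_true(all(diag_n > 0))
})
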