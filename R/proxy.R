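# Tree-ensemble training for proxy endpoints: successive-halving random
# search under stratified CV, Youden-J decision thresholds, the 11-column
# proxy feature block, and the 9x9 cross-prediction grid.

#' Stratified cross-validation fold assignment
#'
#' Classification labels stratify by class; regression targets by
#' quartile bin. Folds are balanced within every stratum and fully
#' determined by the seed.
#'
#' @param y labels or continuous targets.
#' @param k number of folds.
#' @param seed integer seed.
#' @param task `"binary"` or `"regression"`.
#' @return integer fold id per record.
#' @export
stratifiedFolds <- function(y, k, seed, task = "binary") {
  stopifnot(k >= 2L)
  set.seed(seed)
  strata <- if (task == "binary") factor(y) else {
    cut(rank(y, ties.method = "first"), breaks = min(4L, length(y)),
        labels = FALSE)
  }
  folds <- integer(length(y))
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

.xgbObjective <- function(task) {
  if (task == "binary") "binary:logistic" else "reg:squarederror"
}

.rfParams <- function(cfg, task, p, seed, nthread = 1L) {
  colsample <- switch(as.character(cfg$max_features),
    sqrt = max(1, floor(sqrt(p))) / p,
    log2 = max(1, floor(log2(p))) / p,
    as.numeric(cfg$max_features)
  )
  depth <- as.integer(cfg$max_depth)
  if (depth == 0L) depth <- 15L   # "unlimited" depth, bounded for hist trees
  # min_child_weight is a hessian sum: ~0.25 per sample for logistic loss
  # at the initial score, ~1 per sample for squared error
  leafScale <- if (task == "binary") 0.25 else 1
  list(
    objective = .xgbObjective(task),
    eta = 1, max_depth = depth,
    subsample = 0.8, colsample_bynode = colsample,
    min_child_weight = leafScale * as.numeric(cfg$min_samples_leaf),
    tree_method = "hist",
    nthread = nthread, seed = as.integer(seed) %% .Machine$integer.max
  )
}

# Fit a random-forest-mode ensemble (bagged trees in one boosting round).
.fitForest <- function(x, y, cfg, task, seed, ntrees = NULL) {
  params <- .rfParams(cfg, task, ncol(x), seed)
  params$num_parallel_tree <- as.integer(ntrees %||% cfg$trees)
  dm <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(params = params, data = dm, nrounds = 1L, verbose = 0)
}

.predictForest <- function(model, x) {
  if (is.raw(model)) model <- xgboost::xgb.load.raw(model)
  predict(model, xgboost::xgb.DMatrix(x))
}

.scoreCV <- function(x, y, cfg, task, folds, seed, ntrees) {
  scores <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    if (task == "binary" && length(unique(y[tr])) < 2L) return(NA_real_)
    m <- .fitForest(x[tr, , drop = FALSE], y[tr], cfg, task, seed, ntrees)
    p <- .predictForest(m, x[!tr, , drop = FALSE])
    if (task == "binary") {
      if (length(unique(y[!tr])) < 2L) return(NA_real_)
      aurocScore(y[!tr], p)
    } else {
      1 - sum((y[!tr] - p)^2) / sum((y[!tr] - mean(y[!tr]))^2)
    }
  }, numeric(1L))
  mean(scores, na.rm = TRUE)
}

.sampleConfigs <- function(space, n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    lapply(space, function(vals) vals[[sample.int(length(vals), 1L)]])
  })
}

#' Successive-halving random hyperparameter search
#'
#' Samples `nCandidates` configurations from the declared space and
#' evaluates them under stratified cross-validation at an increasing tree
#' budget (the halving resource), discarding all but the top `1/factor`
#' at each rung. The surviving configuration is scored at its full sampled
#' tree count. Fully reproducible from the spec seed.
#'
#' @param x feature matrix.
#' @param y labels (0/1) or continuous targets.
#' @param task `"binary"` or `"regression"`.
#' @param spec a [modelSearchSpec()].
#' @return list: `best` (configuration), `score` (CV score of the winner),
#'   `trace` (data.frame of rung evaluations), `folds` (fold assignment).
#' @export
halvingSearch <- function(x, y, task, spec) {
  k <- spec@cvFolds
  if (length(y) < 2L * k) {
    k <- max(2L, length(y) %/% 2L)
    warning("fewer records than folds; reducing to ", k, " folds")
  }
  folds <- stratifiedFolds(y, k, spec@seed, task)
  cands <- .sampleConfigs(spec@space, spec@nCandidates, spec@seed)
  resource <- spec@minResource
  trace <- NULL
  rung <- 0L
  while (TRUE) {
    rung <- rung + 1L
    scores <- vapply(seq_along(cands), function(i) {
      .scoreCV(x, y, cands[[i]], task, folds, spec@seed + i, resource)
    }, numeric(1L))
    trace <- rbind(trace, data.frame(rung = rung, resource = resource,
                                     candidate = seq_along(cands),
                                     score = scores))
    if (length(cands) == 1L) break
    keep <- order(-scores)[seq_len(max(1L, ceiling(length(cands) / spec@factor)))]
    cands <- cands[keep]
    if (length(cands) == 1L) {
      resource <- NULL  # final evaluation at the winner's own tree count
      rung <- rung + 1L
      score <- .scoreCV(x, y, cands[[1L]], task, folds, spec@seed, cands[[1L]]$trees)
      trace <- rbind(trace, data.frame(rung = rung, resource = cands[[1L]]$trees,
                                       candidate = 1L, score = score))
      return(list(best = cands[[1L]], score = score, trace = trace, folds = folds))
    }
    resource <- resource * spec@factor
  }
  list(best = cands[[1L]], score = trace$score[nrow(trace)], trace = trace,
       folds = folds)
}

#' Youden-J optimal decision threshold
#'
#' Maximizes J = sensitivity + specificity - 1 over the midpoints between
#' adjacent sorted distinct probabilities plus below-minimum and
#' above-maximum sentinels; calls are `prob >= threshold`. Ties resolve to
#' the smallest qualifying threshold. Constant probability vectors return
#' threshold 0.5 flagged as degenerate.
#'
#' @param yTrue binary truth (both classes required).
#' @param yProb probabilities from the derivation set.
#' @param derivation recorded provenance of `yProb`
#'   (`"out-of-fold"` or `"fit-set"`).
#' @return list: `value`, `j`, `derivation`, `degenerate`.
#' @examples
#' selectThreshold(c(0, 1), c(0.2, 0.9))$value   # 0.55
#' @export
selectThreshold <- function(yTrue, yProb, derivation = "fit-set") {
  stopifnot(length(yTrue) == length(yProb))
  if (length(unique(yTrue)) < 2L) stop("both classes must be present")
  u <- sort(unique(yProb))
  if (length(u) == 1L) {
    return(list(value = 0.5, j = 0, derivation = derivation, degenerate = TRUE))
  }
  cand <- c(u[1L] / 2, (u[-length(u)] + u[-1L]) / 2, (u[length(u)] + 1) / 2)
  js <- vapply(cand, function(t) {
    call <- as.integer(yProb >= t)
    sens <- sum(call == 1 & yTrue == 1) / sum(yTrue == 1)
    spec <- sum(call == 0 & yTrue == 0) / sum(yTrue == 0)
    sens + spec - 1
  }, numeric(1L))
  # candidates ascend, so the first near-maximal J wins ties; the tolerance
  # absorbs last-ulp differences between algebraically equal J values
  best <- which(js >= max(js) - 1e-9)[1L]
  list(value = cand[best], j = js[best], derivation = derivation,
       degenerate = FALSE)
}

# Out-of-fold probabilities of a configuration on (x, y).
.oofProbs <- function(x, y, cfg, task, k, seed) {
  folds <- stratifiedFolds(y, k, seed, task)
  p <- numeric(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    m <- .fitForest(x[tr, , drop = FALSE], y[tr], cfg, task, seed)
    p[!tr] <- .predictForest(m, x[!tr, , drop = FALSE])
  }
  p
}

.featureRows <- function(features, keys) {
  idx <- match(keys, rowKeys(features))
  if (anyNA(idx)) stop("feature table does not cover all endpoint compounds")
  idx
}

#' Train a threshold-equipped classifier for one binary proxy endpoint
#'
#' Hyperparameters are chosen by successive-halving random search under
#' stratified cross-validation, the winning configuration is refit on the
#' full endpoint dataset, and a Youden-J decision threshold is derived
#' (by default from the resubstitution probabilities of the refit model;
#' `thresholdDerivation = "out-of-fold"` uses cross-validated estimates).
#'
#' @param dataset binary [EndpointDataset-class] with both classes present.
#' @param features [FeatureTable-class] covering all endpoint compounds.
#' @param spec a [modelSearchSpec()].
#' @param blocks feature blocks used for proxy models.
#' @param thresholdDerivation `"fit-set"` or `"out-of-fold"`.
#' @return list: serialized `model`, `threshold`, `best` configuration,
#'   `cvScore`, `trainKeys`.
#' @export
trainEndpointClassifier <- function(dataset, features, spec = modelSearchSpec(),
                                    blocks = c("morgan", "maccs",
                                               "descriptors", "physchem"),
                                    thresholdDerivation = c("fit-set",
                                                            "out-of-fold")) {
  thresholdDerivation <- match.arg(thresholdDerivation)
  r <- records(dataset)
  y <- r$label
  if (length(unique(y)) < 2L) {
    stop("endpoint '", endpointName(dataset), "' has a single class")
  }
  cfgBlocks <- new("FeatureSpaceConfig", id = "proxy-features", blocks = blocks)
  x <- featureSubset(features, cfgBlocks)[.featureRows(features, r$inchikey_hash), ,
                                          drop = FALSE]
  search <- halvingSearch(x, y, "binary", spec)
  model <- .fitForest(x, y, search$best, "binary", spec@seed)
  probs <- if (thresholdDerivation == "fit-set") {
    .predictForest(model, x)
  } else {
    .oofProbs(x, y, search$best, "binary", min(spec@cvFolds, 5L), spec@seed)
  }
  thr <- selectThreshold(y, probs, derivation = thresholdDerivation)
  list(model = xgboost::xgb.save.raw(model), threshold = thr,
       best = search$best, cvScore = search$score,
       trainKeys = r$inchikey_hash, blocks = blocks, seed = spec@seed)
}

#' Train a Cmax regressor
#'
#' Same search-and-refit protocol as the endpoint classifiers, applied to a
#' continuous pMolar endpoint (median plasma concentration on the negative
#' log-molar scale).
#'
#' @inheritParams trainEndpointClassifier
#' @return list: serialized `model`, `best`, `cvScore` (out-of-fold R^2),
#'   `trainKeys`.
#' @export
trainCmaxRegressor <- function(dataset, features, spec = modelSearchSpec(),
                               blocks = c("morgan", "maccs",
                                          "descriptors", "physchem")) {
  r <- records(dataset)
  if (nrow(r) < 20L) {
    stop("insufficient data for Cmax regression (", nrow(r), " < 20 records)")
  }
  cfgBlocks <- new("FeatureSpaceConfig", id = "proxy-features", blocks = blocks)
  x <- featureSubset(features, cfgBlocks)[.featureRows(features, r$inchikey_hash), ,
                                          drop = FALSE]
  y <- r$label
  search <- halvingSearch(x, y, "regression", spec)
  model <- .fitForest(x, y, search$best, "regression", spec@seed)
  list(model = xgboost::xgb.save.raw(model), best = search$best,
       cvScore = search$score, trainKeys = r$inchikey_hash,
       blocks = blocks, seed = spec@seed)
}

#' Build the full proxy model bundle
#'
#' Trains one threshold-equipped classifier per binary endpoint and one
#' regressor per continuous (Cmax) endpoint; the registry order of the
#' endpoints fixes the proxy block column order.
#'
#' @param endpoints named list of [EndpointDataset-class] (binary and
#'   regression tasks mixed).
#' @param features [FeatureTable-class] covering all endpoint compounds.
#' @param spec a [modelSearchSpec()].
#' @return a [ProxyModelBundle-class].
#' @export
buildProxyBundle <- function(endpoints, features, spec = modelSearchSpec()) {
  classifiers <- list()
  regressors <- list()
  for (ep in endpoints) {
    if (taskType(ep) == "binary") {
      classifiers[[endpointName(ep)]] <-
        trainEndpointClassifier(ep, features, spec)
    } else {
      regressors[[endpointName(ep)]] <-
        trainCmaxRegressor(ep, features, spec)
    }
  }
  new("ProxyModelBundle", classifiers = classifiers, regressors = regressors,
      registryOrder = c(names(classifiers), names(regressors)),
      provenance = list(seed = spec@seed,
                        backend = paste0("openbabel-", .obVersion())))
}

#' Compute the 11-column proxy feature block
#'
#' Class-1 probabilities from every proxy classifier followed by the
#' predicted Cmax values, in registry order. Compounds are always scored by
#' model output, never by training-label lookup.
#'
#' @param features [FeatureTable-class] rows to score.
#' @param bundle a [ProxyModelBundle-class].
#' @return numeric matrix, one column per bundle member.
#' @export
buildProxyBlock <- function(features, bundle) {
  members <- c(bundle@classifiers, bundle@regressors)
  out <- matrix(NA_real_, nrow = nrow(featureMatrix(features)),
                ncol = length(bundle@registryOrder),
                dimnames = list(NULL, paste0("proxy_", bundle@registryOrder)))
  for (nm in bundle@registryOrder) {
    mem <- members[[nm]]
    cfgBlocks <- new("FeatureSpaceConfig", id = "proxy-features",
                     blocks = mem$blocks)
    x <- featureSubset(features, cfgBlocks)
    out[, paste0("proxy_", nm)] <- .predictForest(mem$model, x)
  }
  out
}

#' Cross-prediction grid over the binary proxy endpoints
#'
#' Cell (i, j) evaluates model i's thresholded predictions on endpoint j's
#' compounds. Off-diagonal cells exclude compounds present in model i's
#' training set; the diagonal is resubstitution and flagged as such. Cells
#' with no scoreable compounds (or a single truth class) are flagged empty.
#'
#' @param bundle trained [ProxyModelBundle-class].
#' @param endpoints named list of binary [EndpointDataset-class].
#' @param features [FeatureTable-class] covering all compounds.
#' @return data.frame with one row per (model, endpoint) pair.
#' @export
crossPredictMatrix <- function(bundle, endpoints, features) {
  binNames <- names(bundle@classifiers)
  out <- NULL
  for (i in binNames) {
    clf <- bundle@classifiers[[i]]
    for (j in binNames) {
      ep <- endpoints[[j]]
      r <- records(ep)
      resub <- i == j
      if (!resub) r <- r[!r$inchikey_hash %in% clf$trainKeys, , drop = FALSE]
      row <- data.frame(model = i, endpoint = j, n = nrow(r),
                        resubstitution = resub, empty = FALSE)
      if (nrow(r) < 2L || length(unique(r$label)) < 2L) {
        row$empty <- TRUE
        out <- rbind(out, cbind(row, as.data.frame(.emptyMetricRow())))
        next
      }
      cfgBlocks <- new("FeatureSpaceConfig", id = "proxy-features",
                       blocks = clf$blocks)
      x <- featureSubset(features, cfgBlocks)[
        .featureRows(features, r$inchikey_hash), , drop = FALSE]
      p <- .predictForest(clf$model, x)
      m <- binaryMetrics(r$label, as.integer(p >= clf$threshold$value), p)
      out <- rbind(out, cbind(row, as.data.frame(m)))
    }
  }
  out
}

.emptyMetricRow <- function() {
  m <- list(sensitivity = NA_real_, specificity = NA_real_,
            balanced_accuracy = NA_real_, mcc = NA_real_, f1 = NA_real_,
            ppv = NA_real_, lr_plus = NA_real_, lr_plus_sentinel = NA,
            average_precision = NA_real_, auroc = NA_real_,
            tp = NA_integer_, fp = NA_integer_, tn = NA_integer_,
            fn = NA_integer_)
  m
}
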