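# Gold-standard modelling: Butina scaffold split, repeated nested CV over
# feature-space configurations, final refit with out-of-fold Youden
# threshold, and end-to-end prediction for new compounds.

#' Butina clustering scaffold split
#'
#' Leader-style sphere-exclusion clustering of the 2048-bit circular
#' fingerprints at the Tanimoto similarity cutoff, followed by whole-cluster
#' assignment: clusters (largest first) fill the training partition until
#' its target size is reached, the remainder forms the test partition, so
#' no cluster is ever divided. Compounds are canonicalized by structure-key
#' order before clustering, making the split platform-stable.
#'
#' @param gold a [GoldStandardDILI-class].
#' @param fingerprints 0/1 matrix of 2048-bit circular fingerprints aligned
#'   to `records(gold)` rows.
#' @param spec a [splitSpec()].
#' @return list: `train`, `test` (inchikey hashes), `clusters` (integer
#'   cluster id per record, in `records(gold)` order).
#' @export
butinaSplit <- function(gold, fingerprints, spec = splitSpec()) {
  r <- records(gold)
  n <- nrow(r)
  stopifnot(n >= 2L, nrow(fingerprints) == n)
  ord <- order(r$inchikey_hash)
  fps <- fingerprints[ord, , drop = FALSE]
  sims <- tanimotoMatrix(fps, fps)
  neigh <- sims >= spec@tanimotoCutoff
  diag(neigh) <- FALSE
  assigned <- rep(NA_integer_, n)
  cid <- 0L
  while (anyNA(assigned)) {
    free <- which(is.na(assigned))
    counts <- if (length(free) == 1L) 0L else rowSums(neigh[free, free, drop = FALSE])
    centroid <- free[which.max(counts)]
    cid <- cid + 1L
    members <- c(centroid, free[neigh[centroid, free]])
    assigned[unique(members)] <- cid
  }
  sizes <- table(assigned)
  clusterOrder <- order(-as.integer(sizes), as.integer(names(sizes)))
  trainTarget <- n - ceiling(spec@testFraction * n)
  train <- integer(0)
  test <- integer(0)
  for (cl in as.integer(names(sizes))[clusterOrder]) {
    members <- which(assigned == cl)
    if (length(train) < trainTarget) train <- c(train, members)
    else test <- c(test, members)
  }
  keys <- r$inchikey_hash[ord]
  list(train = keys[sort(train)], test = keys[sort(test)],
       clusters = assigned[match(seq_len(n), ord)])
}

.cfgId <- function(cfg) {
  paste(vapply(cfg, as.character, ""), collapse = "|")
}

#' Repeated nested cross-validation
#'
#' For each repeat (seeded `seedBase + r`), the training data are split
#' into stratified outer folds; per outer fold a successive-halving search
#' is run under inner-fold CV on the outer-training portion, the winner is
#' refit on it, a Youden-J threshold is derived from its inner out-of-fold
#' probabilities, and the held-out validation fold is scored with that
#' threshold. Produces `repeats x outerFolds` fold-level reports.
#'
#' @param x feature matrix of the training compounds.
#' @param y binary labels.
#' @param spec a [nestedCVSpec()].
#' @return data.frame of fold-level metric reports, with the winning
#'   configuration id and decision threshold per fold.
#' @export
repeatedNestedCV <- function(x, y, spec = nestedCVSpec()) {
  out <- NULL
  for (r in seq_len(spec@repeats)) {
    repSeed <- spec@seedBase + r
    folds <- stratifiedFolds(y, spec@outerFolds, repSeed)
    for (f in sort(unique(folds))) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) {
        stop("stratification failed for repeat ", r, " fold ", f)
      }
      innerSpec <- spec@search
      innerSpec@cvFolds <- spec@innerFolds
      innerSpec@seed <- repSeed * 100L + f
      search <- halvingSearch(x[tr, , drop = FALSE], y[tr], "binary", innerSpec)
      oof <- .oofProbs(x[tr, , drop = FALSE], y[tr], search$best, "binary",
                       spec@innerFolds, innerSpec@seed)
      thr <- selectThreshold(y[tr], oof, derivation = "out-of-fold")
      model <- .fitForest(x[tr, , drop = FALSE], y[tr], search$best, "binary",
                          innerSpec@seed)
      p <- .predictForest(model, x[!tr, , drop = FALSE])
      m <- binaryMetrics(y[!tr], as.integer(p >= thr$value), p)
      out <- rbind(out, cbind(
        data.frame(repeat_id = r, fold = f, config = .cfgId(search$best),
                   threshold = thr$value, stringsAsFactors = FALSE),
        as.data.frame(m)))
    }
  }
  out
}

# Best configuration rule: the configuration whose mean outer-validation
# AUROC within a repeat is highest across all repeats.
.bestConfigFromCV <- function(cv) {
  agg <- stats::aggregate(auroc ~ config + repeat_id, data = cv, FUN = mean)
  agg$config[which.max(agg$auroc)]
}

.parseCfgId <- function(id, space) {
  vals <- strsplit(id, "|", fixed = TRUE)[[1L]]
  cfg <- list()
  for (i in seq_along(space)) {
    v <- vals[i]
    cfg[[names(space)[i]]] <- if (grepl("^-?[0-9.]+$", v)) as.numeric(v) else v
  }
  cfg
}

#' Train the final DILI classifier
#'
#' Runs repeated nested cross-validation for the chosen feature-space
#' configuration on the scaffold-split training compounds, refits the best
#' hyperparameter configuration on all of them, and derives the decision
#' threshold from inner-fold out-of-fold probability estimates on the full
#' training data.
#'
#' @param gold a [GoldStandardDILI-class].
#' @param features [FeatureTable-class] covering the gold compounds
#'   (including the proxy block when `config` requires it).
#' @param trainKeys structure keys of the training partition
#'   (from [butinaSplit()]).
#' @param config a [featureSpaceConfig()].
#' @param selector the fitted [FeatureSelector-class] (carried for scoring
#'   new compounds).
#' @param bundle [ProxyModelBundle-class]; required when `config` includes
#'   the proxy block.
#' @param ncv a [nestedCVSpec()].
#' @return list: `model` ([DiliModel-class]) and `cv` (fold-level reports).
#' @export
trainDiliModel <- function(gold, features, trainKeys, config, selector,
                           bundle = NULL, ncv = nestedCVSpec()) {
  if ("proxy" %in% config@blocks && is.null(bundle)) {
    stop("configuration '", config@id, "' requires a proxy model bundle")
  }
  r <- records(gold)
  idx <- match(trainKeys, r$inchikey_hash)
  stopifnot(!anyNA(idx))
  fidx <- .featureRows(features, trainKeys)
  x <- featureSubset(features, config)[fidx, , drop = FALSE]
  y <- r$label[idx]
  cv <- repeatedNestedCV(x, y, ncv)
  bestId <- .bestConfigFromCV(cv)
  best <- .parseCfgId(bestId, ncv@search@space)
  finalSeed <- ncv@seedBase
  model <- .fitForest(x, y, best, "binary", finalSeed)
  oof <- .oofProbs(x, y, best, "binary", ncv@innerFolds, finalSeed)
  thr <- selectThreshold(y, oof, derivation = "out-of-fold")
  morgan <- featureMatrix(features)[fidx, featureBlocks(features)$morgan,
                                    drop = FALSE]
  dili <- new("DiliModel",
    booster = xgboost::xgb.save.raw(model),
    threshold = thr,
    config = config,
    selector = selector,
    bundle = bundle %||% new("ProxyModelBundle", classifiers = list(),
                             regressors = list(), registryOrder = character(0),
                             provenance = list()),
    trainFingerprints = morgan,
    manifest = list(
      trainKeys = trainKeys,
      seedBase = ncv@seedBase,
      bestConfig = best,
      cvSummary = list(meanAUROC = mean(cv$auroc),
                       meanBA = mean(cv$balanced_accuracy),
                       nReports = nrow(cv)),
      backend = paste0("openbabel-", .obVersion())
    ))
  list(model = dili, cv = cv)
}

#' Predict DILI for new compounds
#'
#' Standardizes, featurizes and scores a batch of SMILES with a trained
#' model. Each compound receives a probability, a binary call
#' (`probability >= threshold`) and a structural applicability note (mean
#' Tanimoto similarity of the three nearest training neighbours).
#' Compounds failing standardization yield per-compound failure records;
#' the batch continues.
#'
#' @param model a [DiliModel-class].
#' @param smiles character vector of raw SMILES.
#' @return data.frame: `smiles`, `std_smiles`, `probability`, `call`,
#'   `nn_similarity`, `status`.
#' @export
predictDili <- function(model, smiles) {
  prep <- prepareCompounds(smiles)
  out <- data.frame(
    smiles = smiles, std_smiles = prep$std_smiles,
    probability = NA_real_, call = NA_integer_, nn_similarity = NA_real_,
    status = prep$status, stringsAsFactors = FALSE
  )
  ok <- which(prep$status == "ok")
  if (!length(ok)) return(out)
  ft <- featurizeCompounds(prep[ok, , drop = FALSE], selector = model@selector,
                           fit = FALSE)
  tab <- ft$table
  if ("proxy" %in% model@config@blocks) {
    proxy <- buildProxyBlock(tab, model@bundle)
    tab <- assembleProxy(tab, proxy)
  }
  x <- featureSubset(tab, model@config)
  p <- .predictForest(model@booster, x)
  out$probability[ok] <- p
  out$call[ok] <- as.integer(p >= model@threshold$value)
  morgan <- featureMatrix(tab)[, featureBlocks(tab)$morgan, drop = FALSE]
  out$nn_similarity[ok] <- as.numeric(
    nnSimilarityProfile(morgan, model@trainFingerprints))
  out
}

#' Append a proxy prediction block to a feature table
#' @param table a [FeatureTable-class].
#' @param proxy matrix from [buildProxyBlock()], rows aligned to `table`.
#' @return a [FeatureTable-class] with a `proxy` block.
#' @export
assembleProxy <- function(table, proxy) {
  stopifnot(is(table, "FeatureTable"), nrow(proxy) == nrow(table@x))
  x <- cbind(table@x, proxy)
  blocks <- table@blocks
  blocks$proxy <- ncol(table@x) + seq_len(ncol(proxy))
  new("FeatureTable", x = x, blocks = blocks, rowKeys = table@rowKeys,
      provenance = table@provenance)
}

#' Persist / restore a trained DILI model
#'
#' The artifact is a directory holding the serialized model object plus a
#' human-readable JSON manifest (configuration id, threshold, seeds,
#' training keys, backend versions).
#'
#' @param model a [DiliModel-class].
#' @param dir artifact directory (created if needed).
#' @return `saveDiliModel` the directory, `loadDiliModel` the model.
#' @export
saveDiliModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  jsonlite::write_json(
    list(config = model@config@id,
         threshold = model@threshold[c("value", "j", "derivation")],
         manifest = model@manifest[c("seedBase", "bestConfig", "cvSummary",
                                     "backend")]),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @param dir artifact directory.
#' @rdname saveDiliModel
#' @export
loadDiliModel <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
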