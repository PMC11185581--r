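# End-to-end pipeline: curate -> featurize -> train proxies -> train DILI
# -> evaluate (-> explain), with a run manifest for reproducibility.

.fileHash <- function(path) {
  if (!file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}

.configDigest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(config, NULL, version = 2L), tmp)
  .fileHash(tmp)
}

#' Run the full pipeline from a configuration
#'
#' Stages, in dependency order: corpus (synthetic generation via
#' [generateCorpus()], or loading a manifest of CSVs via
#' [readEndpointManifest()]); leak removal and concordance; featurization
#' with selector fitting on the proxy corpus; proxy bundle training; Butina
#' scaffold split; DILI model training for the requested feature-space
#' configurations; held-out evaluation (metrics, top-k detection). A JSON
#' run manifest (config digest, seeds, stage status, versions) is written
#' alongside the artifacts; reruns with unchanged config digest and intact
#' stage outputs reuse the cached stage results.
#'
#' @param config list (or path to a YAML file) with optional elements
#'   `seed`, `outDir`, `configs` (feature-space ids), `fixture` (arguments
#'   to [fixtureSpec()]), `search`/`ncv` (arguments to [modelSearchSpec()]
#'   and [nestedCVSpec()]), `topkFraction`.
#' @return list with the trained models, evaluation reports, and the run
#'   manifest (invisibly written to `outDir`).
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  outDir <- config$outDir %||% tempfile("diliNet-run-")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  configIds <- config$configs %||% c("structural", "all")
  topkFraction <- config$topkFraction %||% 0.13
  digest <- .configDigest(config[setdiff(names(config), "outDir")])
  cachePath <- file.path(outDir, "stage-cache.rds")
  manifest <- list(configDigest = digest, seed = seed,
                   backend = paste0("openbabel-", .obVersion()),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  cache <- if (file.exists(cachePath)) readRDS(cachePath) else NULL
  if (!is.null(cache) && identical(cache$digest, digest)) {
    message("reusing cached corpus/features for unchanged configuration")
    state <- cache$state
  } else {
    state <- list()
  }

  stamp <- function(name) {
    manifest$stages[[name]] <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  }

  # corpus
  if (is.null(state$corpus)) {
    fixtureArgs <- config$fixture %||% list()
    fixtureArgs$seed <- fixtureArgs$seed %||% seed
    if (!is.null(config$manifestFile)) {
      endpoints <- readEndpointManifest(config$manifestFile)
      isBin <- vapply(endpoints, function(e) taskType(e) == "binary", TRUE)
      goldName <- config$goldEndpoint %||% names(endpoints)[isBin][1L]
      gold <- new("GoldStandardDILI",
                  records = records(endpoints[[goldName]]),
                  sourceRule = paste("endpoint", goldName))
      endpoints[[goldName]] <- NULL
      state$corpus <- list(endpoints = endpoints, gold = gold,
                           manifest = list())
    } else {
      state$corpus <- do.call(
        function(...) generateCorpus(do.call(fixtureSpec, list(...))),
        fixtureArgs)
    }
  }
  stamp("corpus")
  corpus <- state$corpus
  proxies <- removeOverlap(corpus$endpoints, corpus$gold)
  binary <- Filter(function(e) taskType(e) == "binary", proxies)
  concordance <- concordanceMatrix(binary, corpus$gold)
  stamp("curate")

  # featurization (selector fitted on the leak-free proxy corpus)
  if (is.null(state$features)) {
    proxyRecs <- unique(do.call(rbind, lapply(proxies, function(e) {
      r <- records(e)
      r[, c("raw_smiles", "std_smiles", "prot_smiles", "inchikey_hash",
            "status")]
    })))
    proxyRecs <- proxyRecs[!duplicated(proxyRecs$inchikey_hash), ]
    ftProxy <- featurizeCompounds(cbind(proxyRecs, label = NA, sources = ""),
                                  fit = TRUE, corpusId = "proxy-corpus")
    goldRecs <- records(corpus$gold)
    ftGold <- featurizeCompounds(goldRecs, selector = ftProxy$selector,
                                 fit = FALSE)
    state$features <- list(proxy = ftProxy$table, gold = ftGold$table,
                           selector = ftProxy$selector)
  }
  stamp("featurize")
  features <- state$features

  # proxy bundle
  if (is.null(state$bundle)) {
    search <- do.call(modelSearchSpec, c(config$search %||% list()))
    search@seed <- seed
    state$bundle <- buildProxyBundle(proxies, features$proxy, search)
  }
  stamp("train-proxy")
  bundle <- state$bundle

  saveRDS(list(digest = digest, state = state), cachePath)

  # scaffold split + DILI models
  goldMorgan <- featureMatrix(features$gold)[, featureBlocks(features$gold)$morgan,
                                             drop = FALSE]
  split <- butinaSplit(corpus$gold, goldMorgan, splitSpec())
  goldProxy <- buildProxyBlock(features$gold, bundle)
  goldAll <- assembleProxy(features$gold, goldProxy)
  ncvArgs <- config$ncv %||% list(repeats = 2L)
  ncv <- do.call(nestedCVSpec, ncvArgs)
  ncv@seedBase <- seed * 1000L
  models <- list()
  reports <- list()
  goldRecs <- records(corpus$gold)
  testIdx <- match(split$test, goldRecs$inchikey_hash)
  yTest <- goldRecs$label[testIdx]
  for (cid in configIds) {
    cfg <- featureSpaceConfig(cid)
    fit <- trainDiliModel(corpus$gold, goldAll, split$train, cfg,
                          features$selector, bundle = bundle, ncv = ncv)
    models[[cid]] <- fit$model
    x <- featureSubset(goldAll, cfg)[.featureRows(goldAll, split$test), ,
                                     drop = FALSE]
    p <- .predictForest(fit$model@booster, x)
    calls <- as.integer(p >= fit$model@threshold$value)
    k <- max(1L, round(topkFraction * length(yTest)))
    reports[[cid]] <- list(
      cv = fit$cv,
      heldout = binaryMetrics(yTest, calls, p),
      topk = topkDetection(yTest, p, k)
    )
    saveDiliModel(fit$model, file.path(outDir, paste0("model-", cid)))
  }
  stamp("train-dili")
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(outDir, "run-manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(concordance, file.path(outDir, "concordance.csv"),
                   row.names = FALSE)
  list(corpus = corpus, proxies = proxies, concordance = concordance,
       features = features, bundle = bundle, split = split,
       models = models, reports = reports, manifest = manifest,
       outDir = outDir)
}
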