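# Shared fixtures, generated in code and memoised for the test session.

.testEnv <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.testEnv[[name]])) .testEnv[[name]] <- force(expr)
  .testEnv[[name]]
}

# A compact three-endpoint corpus exercising all three latent families.
smallSpec <- function(seed = 11L) {
  fixtureSpec(
    nGold = 120L,
    nPerEndpoint = c(human_hepatotoxicity = 150L,
                     preclinical_hepatotoxicity = 180L,
                     mitotox = 150L),
    nCmax = c(cmax_total = 60L),
    seed = seed
  )
}

smallCorpus <- function() memo("smallCorpus", generateCorpus(smallSpec()))

smallProxies <- function() memo("smallProxies", {
  corpus <- smallCorpus()
  removeOverlap(corpus$endpoints, corpus$gold)
})

smallFeatures <- function() memo("smallFeatures", {
  corpus <- smallCorpus()
  proxies <- smallProxies()
  recs <- do.call(rbind, lapply(proxies, function(e) {
    r <- records(e)
    r[, c("raw_smiles", "std_smiles", "prot_smiles", "inchikey_hash", "status")]
  }))
  recs <- recs[!duplicated(recs$inchikey_hash), ]
  ftP <- featurizeCompounds(cbind(recs, label = NA, sources = ""),
                            fit = TRUE, corpusId = "test-proxy")
  ftG <- featurizeCompounds(records(corpus$gold), selector = ftP$selector,
                            fit = FALSE)
  list(proxy = ftP$table, gold = ftG$table, selector = ftP$selector)
})

tinySearch <- function(seed = 5L) {
  modelSearchSpec(cvFolds = 3L, nCandidates = 4L, minResource = 30L,
                  seed = seed)
}

smallBundle <- function() memo("smallBundle", {
  suppressWarnings(
    buildProxyBundle(smallProxies(), smallFeatures()$proxy, tinySearch()))
})

smallDiliFit <- function() memo("smallDiliFit", {
  corpus <- smallCorpus()
  f <- smallFeatures()
  bundle <- smallBundle()
  goldMorgan <- featureMatrix(f$gold)[, featureBlocks(f$gold)$morgan,
                                      drop = FALSE]
  split <- butinaSplit(corpus$gold, goldMorgan, splitSpec())
  goldAll <- diliNet:::assembleProxy(f$gold, buildProxyBlock(f$gold, bundle))
  ncv <- nestedCVSpec(outerFolds = 3L, innerFolds = 3L, repeats = 1L,
                      seedBase = 77L, search = tinySearch())
  fit <- trainDiliModel(corpus$gold, goldAll, split$train,
                        featureSpaceConfig("all"), f$selector,
                        bundle = bundle, ncv = ncv)
  list(fit = fit, split = split, goldAll = goldAll)
})

# Toy feature table with the standard block layout, for model-level tests
# that do not need real chemistry.
toyFeatureTable <- function(n, seed = 1L) {
  set.seed(seed)
  morgan <- matrix(rbinom(n * 30L, 1L, 0.3), n)
  colnames(morgan) <- sprintf("morgan_%04d", 1:30)
  maccs <- matrix(rbinom(n * 10L, 1L, 0.4), n)
  colnames(maccs) <- sprintf("maccs_%03d", 1:10)
  desc <- matrix(stats::rnorm(n * 8L), n)
  colnames(desc) <- paste0("desc", 1:8)
  phys <- matrix(stats::rnorm(n * 4L), n)
  colnames(phys) <- paste0("phys", 1:4)
  x <- cbind(morgan, maccs, desc, phys)
  new("FeatureTable", x = x,
      blocks = list(morgan = 1:30, maccs = 31:40, descriptors = 41:48,
                    physchem = 49:52),
      rowKeys = sprintf("KEY%011d", seq_len(n)),
      provenance = list())
}

toyEndpoint <- function(features, label, name = "toy", task = "binary") {
  recs <- data.frame(
    raw_smiles = rowKeys(features), std_smiles = rowKeys(features),
    inchikey_hash = rowKeys(features), label = label,
    sources = name, status = "ok", stringsAsFactors = FALSE
  )
  new("EndpointDataset", name = name, assayType = "mechanism", task = task,
      records = recs, activeDefinition = "toy")
}
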