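#' @import methods
NULL

#' Drug-likeness filter specification
#'
#' Rules applied to raw (pre-standardization) molecules, in order: presence
#' of carbon, multi-fragment inputs with no resolvable organic principal
#' fragment, metal-only composition, and a molecular weight ceiling.
#'
#' @slot requireCarbon reject molecules without a carbon atom.
#' @slot rejectMultifragment reject disconnected inputs that cannot be
#'   resolved to a single organic principal fragment.
#' @slot rejectMetalsOnly reject molecules composed entirely of metals.
#' @slot maxMolecularWeight weight ceiling in Daltons (default 1500).
#' @export
setClass("FilterSpec", representation(
  requireCarbon = "logical",
  rejectMultifragment = "logical",
  rejectMetalsOnly = "logical",
  maxMolecularWeight = "numeric"
), validity = function(object) {
  if (length(object@maxMolecularWeight) != 1L || object@maxMolecularWeight <= 0)
    return("maxMolecularWeight must be a single positive number")
  TRUE
})

#' @param requireCarbon,rejectMultifragment,rejectMetalsOnly,maxMolecularWeight
#'   see slot documentation.
#' @rdname FilterSpec-class
#' @export
filterSpec <- function(requireCarbon = TRUE, rejectMultifragment = TRUE,
                       rejectMetalsOnly = TRUE, maxMolecularWeight = 1500) {
  new("FilterSpec", requireCarbon = requireCarbon,
      rejectMultifragment = rejectMultifragment,
      rejectMetalsOnly = rejectMetalsOnly,
      maxMolecularWeight = maxMolecularWeight)
}

#' Standardization configuration
#'
#' Ordered list of structure-normalization steps applied iteratively (up to
#' `maxIterations` times) until the canonical SMILES reaches a fixed point;
#' if no fixed point is reached the modal SMILES over the iteration trace is
#' selected (ties broken lexicographically).
#'
#' @slot maxIterations maximum number of passes over the step list.
#' @slot protonationPH pH at which ionizable groups are assigned downstream.
#' @slot steps ordered character vector of step identifiers.
#' @export
setClass("StandardizationConfig", representation(
  maxIterations = "integer",
  protonationPH = "numeric",
  steps = "character"
), validity = function(object) {
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  if (!length(object@steps)) return("steps must be non-empty")
  TRUE
})

#' @param maxIterations,protonationPH,steps see slot documentation.
#' @rdname StandardizationConfig-class
#' @export
standardizationConfig <- function(maxIterations = 5L, protonationPH = 7.0,
                                  steps = c("disconnect_metals",
                                            "principal_fragment",
                                            "normalize",
                                            "neutralize",
                                            "remove_isotopes",
                                            "remove_stereo",
                                            "canonical_tautomer")) {
  new("StandardizationConfig", maxIterations = as.integer(maxIterations),
      protonationPH = protonationPH, steps = steps)
}

#' A named, labelled endpoint dataset
#'
#' One proxy-hepatotoxicity or pharmacokinetic endpoint: a set of keyed
#' compound records with either binary activity labels or continuous
#' pMolar Cmax values.
#'
#' @slot name endpoint identifier.
#' @slot assayType one of `"human hepatotoxicity"`, `"animal hepatotoxicity"`,
#'   `"heterogeneous"`, `"mechanism"`, `"PK"`.
#' @slot task `"binary"` or `"regression"`.
#' @slot records data.frame with columns `raw_smiles`, `std_smiles`,
#'   `inchikey_hash`, `label`, `sources`, `status`.
#' @slot activeDefinition free-text description of the active class.
#' @export
setClass("EndpointDataset", representation(
  name = "character",
  assayType = "character",
  task = "character",
  records = "data.frame",
  activeDefinition = "character"
), validity = function(object) {
  r <- object@records
  need <- c("std_smiles", "inchikey_hash", "label")
  if (!all(need %in% names(r)))
    return(paste("records must contain columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(r$inchikey_hash))
    return("record keys (inchikey_hash) must be unique")
  if (object@task == "binary" && nrow(r) && !all(r$label %in% c(0, 1)))
    return("binary endpoint labels must be 0/1")
  if (object@task == "regression" && nrow(r) && !all(is.finite(r$label)))
    return("regression endpoint values must be finite")
  TRUE
})

#' The merged gold-standard DILI dataset
#'
#' Standardized, hash-deduplicated union of the DILI source lists, with
#' cross-source label conflicts resolved toward the toxic annotation.
#'
#' @slot records keyed compound records with a binary `label` column.
#' @slot sourceRule description of the label-mapping rule used at merge time.
#' @export
setClass("GoldStandardDILI", representation(
  records = "data.frame",
  sourceRule = "character"
), validity = function(object) {
  if (anyDuplicated(object@records$inchikey_hash))
    return("gold-standard keys must be unique")
  if (nrow(object@records) && !all(object@records$label %in% c(0, 1)))
    return("gold-standard labels must be 0/1")
  TRUE
})

#' Variance-threshold feature selector
#'
#' Per-block variance filters fitted once on the proxy-endpoint corpus and
#' reused unchanged for every later feature table (including the
#' gold-standard DILI corpus). Binary blocks use the Bernoulli variance
#' p(1-p); the physicochemical block is never filtered.
#'
#' @slot morganThreshold,maccsThreshold,descriptorThreshold strict (`>`)
#'   variance cutoffs per block.
#' @slot masks named list of integer index vectors of retained columns.
#' @slot descriptorNames column names of the descriptor block at fit time.
#' @slot fitCorpusId identifier of the corpus the masks were fitted on.
#' @export
setClass("FeatureSelector", representation(
  morganThreshold = "numeric",
  maccsThreshold = "numeric",
  descriptorThreshold = "numeric",
  masks = "list",
  descriptorNames = "character",
  descriptorMedians = "numeric",
  fitCorpusId = "character"
))

#' Assembled model-ready feature table
#'
#' Row-keyed numeric matrix with a recorded block layout
#' (`morgan`, `maccs`, `descriptors`, `physchem`, and optionally `proxy`).
#'
#' @slot x numeric matrix, rows = compounds.
#' @slot blocks named list of integer column indices per block.
#' @slot rowKeys inchikey hash per row.
#' @slot provenance list of selector/backend version metadata.
#' @export
setClass("FeatureTable", representation(
  x = "matrix",
  blocks = "list",
  rowKeys = "character",
  provenance = "list"
), validity = function(object) {
  if (nrow(object@x) != length(object@rowKeys))
    return("rowKeys length must match matrix rows")
  if (anyNA(object@x)) return("feature table must not contain missing values")
  idx <- unlist(object@blocks, use.names = FALSE)
  if (length(idx) && (max(idx) > ncol(object@x) || anyDuplicated(idx)))
    return("block indices must partition the matrix columns")
  TRUE
})

#' Hyperparameter search specification
#'
#' Successive-halving random search over a tree-ensemble parameter space,
#' scored by stratified cross-validation; the best configuration is refit on
#' the full dataset.
#'
#' @slot cvFolds number of (stratified) CV folds.
#' @slot nCandidates number of sampled configurations entering the search.
#' @slot minResource number of trees at the first halving rung.
#' @slot factor halving factor between rungs.
#' @slot space named list of candidate values per hyperparameter.
#' @slot seed integer seed controlling sampling, folds, and fits.
#' @export
setClass("ModelSearchSpec", representation(
  cvFolds = "integer",
  nCandidates = "integer",
  minResource = "integer",
  factor = "integer",
  space = "list",
  seed = "integer"
))

#' Default tree-ensemble hyperparameter space
#'
#' Number of trees, maximum depth, minimum samples per split and leaf, and
#' per-node feature subsampling, mirroring the conventional random-forest
#' search grid. Any element can be overridden.
#' @return named list of candidate values.
#' @export
defaultParamSpace <- function() {
  list(
    trees = c(100L, 200L, 300L, 500L, 750L, 1000L),
    max_depth = c(0L, 5L, 10L, 15L, 20L, 30L),
    min_samples_split = 2:10,
    min_samples_leaf = 1:5,
    max_features = c("sqrt", "log2", "0.3")
  )
}

#' @param cvFolds,nCandidates,minResource,factor,space,seed see slots.
#' @rdname ModelSearchSpec-class
#' @export
modelSearchSpec <- function(cvFolds = 5L, nCandidates = 12L, minResource = 50L,
                            factor = 3L, space = defaultParamSpace(),
                            seed = 1L) {
  new("ModelSearchSpec", cvFolds = as.integer(cvFolds),
      nCandidates = as.integer(nCandidates),
      minResource = as.integer(minResource), factor = as.integer(factor),
      space = space, seed = as.integer(seed))
}

#' Trained proxy-endpoint model bundle
#'
#' Nine threshold-equipped binary classifiers plus two Cmax regressors; its
#' predictions form the 11-column proxy feature block, in registry order.
#'
#' @slot classifiers named list: serialized model, Youden-J decision
#'   threshold, and search metadata per binary endpoint.
#' @slot regressors named list of serialized Cmax regressors.
#' @slot registryOrder endpoint names fixing the proxy block column order.
#' @slot provenance list (seeds, feature layout, versions).
#' @export
setClass("ProxyModelBundle", representation(
  classifiers = "list",
  regressors = "list",
  registryOrder = "character",
  provenance = "list"
))

#' Scaffold-split specification (Butina clustering)
#'
#' @slot tanimotoCutoff similarity threshold defining cluster neighbourhoods.
#' @slot testFraction fraction of compounds targeted for the test partition.
#' @export
setClass("SplitSpec", representation(
  tanimotoCutoff = "numeric",
  testFraction = "numeric"
), validity = function(object) {
  if (object@tanimotoCutoff <= 0 || object@tanimotoCutoff > 1)
    return("tanimotoCutoff must be in (0, 1]")
  if (object@testFraction <= 0 || object@testFraction >= 1)
    return("testFraction must be in (0, 1)")
  TRUE
})

#' @param tanimotoCutoff,testFraction see slot documentation.
#' @rdname SplitSpec-class
#' @export
splitSpec <- function(tanimotoCutoff = 0.70, testFraction = 0.20) {
  new("SplitSpec", tanimotoCutoff = tanimotoCutoff, testFraction = testFraction)
}

#' Repeated nested cross-validation specification
#'
#' @slot outerFolds stratified outer folds (default 5).
#' @slot innerFolds folds for the inner hyperparameter search and for the
#'   out-of-fold threshold estimates (default 4).
#' @slot repeats number of independent repetitions with fresh splits.
#' @slot seedBase repeat r uses seed `seedBase + r`.
#' @slot search `ModelSearchSpec` for the inner search.
#' @export
setClass("NestedCVSpec", representation(
  outerFolds = "integer",
  innerFolds = "integer",
  repeats = "integer",
  seedBase = "integer",
  search = "ModelSearchSpec"
))

#' @param outerFolds,innerFolds,repeats,seedBase,search see slots.
#' @rdname NestedCVSpec-class
#' @export
nestedCVSpec <- function(outerFolds = 5L, innerFolds = 4L, repeats = 10L,
                         seedBase = 1000L, search = modelSearchSpec()) {
  new("NestedCVSpec", outerFolds = as.integer(outerFolds),
      innerFolds = as.integer(innerFolds), repeats = as.integer(repeats),
      seedBase = as.integer(seedBase), search = search)
}

#' Feature-space configuration for the DILI model
#'
#' @slot id one of `"structural"`, `"descriptors"`,
#'   `"structural+descriptors"`, `"proxy"`, `"all"`.
#' @slot blocks feature-table blocks included under this configuration.
#' @export
setClass("FeatureSpaceConfig", representation(
  id = "character",
  blocks = "character"
))

#' @param id configuration identifier.
#' @rdname FeatureSpaceConfig-class
#' @export
featureSpaceConfig <- function(id = c("all", "structural", "descriptors",
                                      "structural+descriptors", "proxy")) {
  id <- match.arg(id)
  blocks <- switch(id,
    structural = c("morgan", "maccs"),
    descriptors = c("descriptors", "physchem"),
    "structural+descriptors" = c("morgan", "maccs", "descriptors", "physchem"),
    proxy = "proxy",
    all = c("morgan", "maccs", "descriptors", "physchem", "proxy")
  )
  new("FeatureSpaceConfig", id = id, blocks = blocks)
}

#' Final DILI classifier
#'
#' Refit tree ensemble with its out-of-fold Youden-J decision threshold and
#' everything needed to score new compounds end-to-end (selector, proxy
#' bundle, training fingerprints for the applicability note).
#'
#' @slot booster serialized tree-ensemble model.
#' @slot threshold list: `value`, `j`, `derivation`.
#' @slot config the `FeatureSpaceConfig` the model was trained under.
#' @slot selector fitted `FeatureSelector`.
#' @slot bundle `ProxyModelBundle` (empty when the configuration does not
#'   use the proxy block).
#' @slot trainFingerprints 2048-bit fingerprints of the training compounds.
#' @slot manifest list: seeds, training keys, versions, CV summary.
#' @export
setClass("DiliModel", representation(
  booster = "raw",
  threshold = "list",
  config = "FeatureSpaceConfig",
  selector = "FeatureSelector",
  bundle = "ProxyModelBundle",
  trainFingerprints = "matrix",
  manifest = "list"
))

#' Synthetic corpus specification
#'
#' Controls the generator that emulates the study conditions: several binary
#' proxy endpoints of differing size with partially overlapping chemistry, a
#' planted toxicophore signal, a count-based secondary signal carried by one
#' informative endpoint, tunable inter-endpoint concordance, and two
#' continuous log-scale Cmax endpoints linear in physicochemical properties.
#'
#' @slot nGold gold-standard corpus size.
#' @slot nPerEndpoint named sizes for the binary proxy endpoints.
#' @slot nCmax sizes for the two Cmax endpoints.
#' @slot toxicophore SMARTS-like fragment planted in toxic compounds.
#' @slot q probability a latent-toxic compound actually carries the
#'   toxicophore (must exceed 0.5).
#' @slot labelNoise per-endpoint label flip probability implied by
#'   `proxyConcordance`.
#' @slot proxyConcordance target Cohen's kappa between endpoints sharing a
#'   latent signal.
#' @slot cmaxNoiseSd Gaussian noise of the Cmax linear model (pMolar units).
#' @slot seed generator seed.
#' @export
setClass("FixtureSpec", representation(
  nGold = "integer",
  nPerEndpoint = "integer",
  nCmax = "integer",
  toxicophore = "character",
  q = "numeric",
  proxyConcordance = "numeric",
  cmaxNoiseSd = "numeric",
  seed = "integer"
), validity = function(object) {
  if (object@q <= 0.5 || object@q > 1) return("q must be in (0.5, 1]")
  if (object@proxyConcordance <= 0 || object@proxyConcordance > 1)
    return("proxyConcordance must be in (0, 1]")
  TRUE
})
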