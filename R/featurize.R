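# Structural fingerprints, variance-threshold selection, and assembly of
# model-ready feature tables.

#' Compute the 2,214-bit structural fingerprint block
#'
#' Concatenation of a radius-2 circular (Morgan/ECFP4) fingerprint folded to
#' `morganNbits` positions and the 166 MACCS substructure keys, giving the
#' standard 2048 + 166 = 2214-bit layout.
#'
#' @param smiles standardized canonical SMILES (pre-validated).
#' @param morganNbits fold width of the circular fingerprint (default 2048).
#' @return integer 0/1 matrix with columns `morgan_*` then `maccs_*`;
#'   unparseable rows are all-`NA`.
#' @examples
#' \donttest{ncol(computeStructural("CCO")) == 2214}
#' @export
computeStructural <- function(smiles, morganNbits = 2048L) {
  morgan <- obFingerprint(smiles, "ECFP4", nbits = as.integer(morganNbits))
  maccs <- obFingerprint(smiles, "MACCS")[, 1:166, drop = FALSE]
  colnames(morgan) <- sprintf("morgan_%04d", seq_len(ncol(morgan)))
  colnames(maccs) <- sprintf("maccs_%03d", 1:166)
  cbind(morgan, maccs)
}

.bernoulliVariance <- function(col) {
  p <- mean(col)
  p * (1 - p)
}

#' Fit the variance-threshold feature selector
#'
#' Retains a column when its variance strictly exceeds the per-block
#' threshold. Binary fingerprint blocks use the Bernoulli variance p(1-p);
#' the descriptor block uses the sample variance. Masks are fitted once on
#' the proxy-endpoint corpus and must be reused unchanged for every other
#' corpus (recorded via `fitCorpusId`); the physicochemical block is never
#' filtered. Descriptor column medians are stored so that degenerate values
#' arising in later corpora can be imputed consistently.
#'
#' @param structural 0/1 matrix from [computeStructural()].
#' @param descriptors descriptor matrix from [computeDescriptors()].
#' @param corpusId identifier of the fitting corpus.
#' @param morganThreshold,maccsThreshold,descriptorThreshold strict variance
#'   cutoffs (defaults 0.05, 0.10, 0.10).
#' @return a fitted [FeatureSelector-class].
#' @export
fitVarianceSelector <- function(structural, descriptors, corpusId = "proxy",
                                morganThreshold = 0.05,
                                maccsThreshold = 0.10,
                                descriptorThreshold = 0.10) {
  stopifnot(nrow(structural) > 0, nrow(structural) == nrow(descriptors))
  nM <- ncol(structural) - 166L
  morgan <- structural[, seq_len(nM), drop = FALSE]
  maccs <- structural[, nM + 1:166, drop = FALSE]
  vMorgan <- apply(morgan, 2L, .bernoulliVariance)
  vMaccs <- apply(maccs, 2L, .bernoulliVariance)
  vDesc <- apply(descriptors, 2L, stats::var)
  masks <- list(
    morgan = which(vMorgan > morganThreshold),
    maccs = which(vMaccs > maccsThreshold),
    descriptors = which(vDesc > descriptorThreshold)
  )
  new("FeatureSelector",
      morganThreshold = morganThreshold, maccsThreshold = maccsThreshold,
      descriptorThreshold = descriptorThreshold,
      masks = masks,
      descriptorNames = colnames(descriptors),
      descriptorMedians = apply(descriptors, 2L, stats::median),
      fitCorpusId = corpusId)
}

#' Assemble a model-ready feature table
#'
#' Applies the fitted selector masks to the structural and descriptor
#' blocks, appends the unfiltered 15-column physicochemical block and, when
#' supplied, the 11-column proxy prediction block. Column layout (recorded
#' in the block map) is fixed: selected Morgan bits, selected MACCS keys,
#' selected descriptors, physchem, proxy.
#'
#' @param structural matrix from [computeStructural()].
#' @param descriptors matrix from [computeDescriptors()] (columns may be a
#'   superset or subset of the fit corpus; missing fitted columns are
#'   median-imputed from the fit corpus).
#' @param physchem matrix from [computePhyschem()].
#' @param selector fitted [FeatureSelector-class].
#' @param rowKeys inchikey hashes, one per row.
#' @param proxy optional 11-column proxy prediction block.
#' @return a [FeatureTable-class].
#' @export
assembleFeatures <- function(structural, descriptors, physchem, selector,
                             rowKeys, proxy = NULL) {
  stopifnot(is(selector, "FeatureSelector"))
  nM <- ncol(structural) - 166L
  morgan <- structural[, selector@masks$morgan, drop = FALSE]
  maccs <- structural[, nM + selector@masks$maccs, drop = FALSE]
  colnames(maccs) <- sprintf("maccs_%03d", selector@masks$maccs)
  descFit <- selector@descriptorNames[selector@masks$descriptors]
  desc <- matrix(NA_real_, nrow = nrow(structural), ncol = length(descFit),
                 dimnames = list(NULL, descFit))
  have <- intersect(descFit, colnames(descriptors))
  desc[, have] <- descriptors[, have, drop = FALSE]
  for (cn in descFit) {
    bad <- !is.finite(desc[, cn])
    if (any(bad)) desc[bad, cn] <- selector@descriptorMedians[[cn]]
  }
  blocks <- list(
    morgan = seq_len(ncol(morgan)),
    maccs = ncol(morgan) + seq_len(ncol(maccs)),
    descriptors = ncol(morgan) + ncol(maccs) + seq_len(ncol(desc)),
    physchem = ncol(morgan) + ncol(maccs) + ncol(desc) + seq_len(ncol(physchem))
  )
  x <- cbind(morgan, maccs, desc, physchem)
  if (!is.null(proxy)) {
    stopifnot(nrow(proxy) == nrow(x))
    blocks$proxy <- ncol(x) + seq_len(ncol(proxy))
    x <- cbind(x, proxy)
  }
  rownames(x) <- NULL
  new("FeatureTable", x = x, blocks = blocks, rowKeys = rowKeys,
      provenance = list(
        selector = selector@fitCorpusId,
        backend = paste0("openbabel-", .obVersion()),
        assembledRingsNote = "fused ring-system count"
      ))
}

#' Featurize prepared compound records end-to-end
#'
#' Convenience wrapper: computes structural fingerprints, descriptors and
#' physicochemical parameters for the protonated structures of the `"ok"`
#' records, optionally fits the variance selector on them, and assembles
#' the feature table.
#'
#' @param recs data.frame from [prepareCompounds()] (only `status == "ok"`
#'   rows are used).
#' @param selector fitted selector, or `NULL` with `fit = TRUE` to fit one.
#' @param fit fit the selector on this corpus.
#' @param corpusId corpus identifier recorded when fitting.
#' @param proxy optional proxy block.
#' @return list with elements `table` ([FeatureTable-class]) and `selector`.
#' @export
featurizeCompounds <- function(recs, selector = NULL, fit = is.null(selector),
                               corpusId = "corpus", proxy = NULL) {
  recs <- recs[recs$status == "ok", , drop = FALSE]
  if (!nrow(recs)) stop("no accepted compound records to featurize")
  smi <- recs$prot_smiles
  graphs <- .molGraphs(smi)
  structural <- computeStructural(smi)
  desc <- computeDescriptors(smi, graphs = graphs)
  phys <- computePhyschem(smi, graphs = graphs)
  if (fit) {
    selector <- fitVarianceSelector(structural, desc, corpusId = corpusId)
  }
  bad <- which(!is.finite(phys), arr.ind = TRUE)
  if (nrow(bad)) phys[bad] <- 0
  tab <- assembleFeatures(structural, desc, phys, selector,
                          rowKeys = recs$inchikey_hash, proxy = proxy)
  list(table = tab, selector = selector)
}

#' Subset a feature table to a feature-space configuration
#'
#' Returns the columns of the blocks named by the configuration, in the
#' order they are laid out in the table.
#'
#' @param table a [FeatureTable-class].
#' @param config a [featureSpaceConfig()].
#' @return numeric matrix.
#' @export
featureSubset <- function(table, config) {
  stopifnot(is(table, "FeatureTable"), is(config, "FeatureSpaceConfig"))
  want <- config@blocks
  missing <- setdiff(want, names(table@blocks))
  if (length(missing)) {
    stop("feature table lacks required block(s): ",
         paste(missing, collapse = ", "))
  }
  idx <- unlist(table@blocks[want], use.names = FALSE)
  table@x[, idx, drop = FALSE]
}

#' Persist / restore a fitted selector as JSON
#'
#' Thresholds, retained-column index lists, descriptor names and medians,
#' and the fitting-corpus identifier, in a human-readable sidecar format.
#'
#' @param selector a fitted [FeatureSelector-class].
#' @param path JSON file path.
#' @return `saveSelector` the path; `loadSelector` the selector.
#' @export
saveSelector <- function(selector, path) {
  jsonlite::write_json(list(
    thresholds = list(morgan = selector@morganThreshold,
                      maccs = selector@maccsThreshold,
                      descriptors = selector@descriptorThreshold),
    masks = lapply(selector@masks, unname),
    descriptorNames = selector@descriptorNames,
    descriptorMedians = unname(selector@descriptorMedians),
    fitCorpusId = selector@fitCorpusId
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveSelector
#' @param path JSON file path.
#' @export
loadSelector <- function(path) {
  j <- jsonlite::fromJSON(path)
  new("FeatureSelector",
      morganThreshold = j$thresholds$morgan,
      maccsThreshold = j$thresholds$maccs,
      descriptorThreshold = j$thresholds$descriptors,
      masks = lapply(j$masks, as.integer),
      descriptorNames = j$descriptorNames,
      descriptorMedians = stats::setNames(j$descriptorMedians,
                                          j$descriptorNames),
      fitCorpusId = j$fitCorpusId)
}

#' Write a feature table to CSV (row key + named feature columns)
#' @param table a [FeatureTable-class].
#' @param path CSV file path.
#' @export
writeFeatureCsv <- function(table, path) {
  df <- data.frame(inchikey_hash = rowKeys(table),
                   featureMatrix(table), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
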