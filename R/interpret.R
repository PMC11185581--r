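# Per-compound interpretation: exact additive tree attributions, MACCS
# substructure highlighting on the molecule, and proxy-endpoint ranking.

#' The 166-key MACCS SMARTS table
#'
#' Parsed from the OpenBabel key-definition table (the standard
#' RDKit-derived MACCS SMARTS set). Keys defined outside SMARTS (isotope
#' and fragment-count keys) carry `NA` patterns and are excluded from
#' substructure highlighting.
#'
#' @return data.frame: `id`, `smarts` (`NA` when not SMARTS-expressible),
#'   `mincount` (key fires when unique matches exceed this count).
#' @export
maccsKeyTable <- function() {
  if (!is.null(.diliNetEnv$maccsKeys)) return(.diliNetEnv$maccsKeys)
  lines <- readLines(file.path(.obDataDir(), "MACCS.txt"))
  lines <- grep("^\\s*[0-9]+:\\(", lines, value = TRUE)
  m <- regmatches(lines, regexec("^\\s*([0-9]+):\\('(.*)',([0-9]+)\\)", lines))
  tab <- data.frame(
    id = as.integer(vapply(m, `[`, "", 2L)),
    smarts = vapply(m, `[`, "", 3L),
    mincount = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  tab$smarts[tab$smarts == "?"] <- NA_character_
  tab <- tab[order(tab$id), ]
  .diliNetEnv$maccsKeys <- tab
  tab
}

#' Exact additive feature attribution for one compound
#'
#' Tree-path-exact additive contributions (SHAP values) from the ensemble:
#' the base value plus the per-feature contributions reproduces the model's
#' margin (log-odds) output to numerical precision. Deterministic for a
#' given model and compound.
#'
#' @param model a [DiliModel-class].
#' @param featureRow single-row feature matrix laid out as the model's
#'   feature table (see [predictDili()] for end-to-end scoring).
#' @return list: `contributions` (named numeric), `base_value`,
#'   `margin` (base + sum), `probability`.
#' @export
explainFeatures <- function(model, featureRow) {
  stopifnot(is.matrix(featureRow), nrow(featureRow) == 1L)
  booster <- xgboost::xgb.load.raw(model@booster)
  dm <- xgboost::xgb.DMatrix(featureRow)
  contrib <- predict(booster, dm, predcontrib = TRUE)
  contrib <- contrib[1L, ]
  if (is.null(names(contrib))) {
    names(contrib) <- c(colnames(featureRow), "(Intercept)")
  }
  # the expected-value (bias) term is the last column
  base <- contrib[[length(contrib)]]
  contrib <- contrib[-length(contrib)]
  margin <- base + sum(contrib)
  list(contributions = contrib, base_value = base, margin = margin,
       probability = stats::plogis(margin))
}

#' Explain a DILI prediction from a SMILES string
#'
#' Standardizes and featurizes the compound under the model's selector and
#' configuration, computes the additive attribution, the dominant MACCS
#' substructure highlight, and (for proxy-aware configurations) the ranked
#' proxy-endpoint contributions.
#'
#' @param model a [DiliModel-class].
#' @param smiles a single SMILES string.
#' @return list: `attribution`, `highlight`, `proxyRanking`, `std_smiles`,
#'   `probability`, `call`.
#' @export
explainDili <- function(model, smiles) {
  stopifnot(length(smiles) == 1L)
  prep <- prepareCompounds(smiles)
  if (prep$status[1L] != "ok") {
    stop("compound failed preparation: ", prep$status[1L])
  }
  ft <- featurizeCompounds(prep, selector = model@selector, fit = FALSE)
  tab <- ft$table
  if ("proxy" %in% model@config@blocks) {
    tab <- assembleProxy(tab, buildProxyBlock(tab, model@bundle))
  }
  x <- featureSubset(tab, model@config)
  att <- explainFeatures(model, x[1L, , drop = FALSE])
  hl <- highlightTopSubstructure(att, prep$std_smiles[1L],
                                 featureRow = x[1L, ])
  pr <- if ("proxy" %in% model@config@blocks) rankProxyContributions(att)
        else NULL
  list(attribution = att, highlight = hl, proxyRanking = pr,
       std_smiles = prep$std_smiles[1L],
       probability = att$probability,
       call = as.integer(att$probability >= model@threshold$value))
}

#' Highlight the dominant MACCS substructure on a molecule
#'
#' Among the MACCS keys present in the compound (bit = 1) with positive
#' attribution, selects the largest contributor and maps its SMARTS onto
#' the molecule's atoms; when no positive MACCS contribution exists, the
#' most negative (safety-associated) key is highlighted with its sign
#' noted. Keys without a SMARTS definition are excluded. A SMARTS that no
#' longer matches an on-bit molecule indicates a fingerprint/key-table
#' mismatch and raises a consistency error.
#'
#' @param attribution result of [explainFeatures()].
#' @param smiles standardized SMILES of the compound.
#' @param featureRow the feature row the attribution was computed on
#'   (named; used to restrict to on-bits).
#' @return list: `key`, `smarts`, `atoms` (list of matched atom index
#'   sets), `contribution`, `sign`, `empty`.
#' @export
highlightTopSubstructure <- function(attribution, smiles, featureRow) {
  contrib <- attribution$contributions
  keyTab <- maccsKeyTable()
  maccsIdx <- grep("^maccs_", names(contrib))
  if (!length(maccsIdx)) {
    return(list(key = NA_integer_, smarts = NA_character_, atoms = list(),
                contribution = NA_real_, sign = NA_character_, empty = TRUE))
  }
  ids <- as.integer(sub("^maccs_", "", names(contrib)[maccsIdx]))
  on <- featureRow[names(contrib)[maccsIdx]] == 1
  defined <- !is.na(keyTab$smarts[match(ids, keyTab$id)])
  usable <- which(on & defined)
  if (!length(usable)) {
    return(list(key = NA_integer_, smarts = NA_character_, atoms = list(),
                contribution = NA_real_, sign = NA_character_, empty = TRUE))
  }
  vals <- contrib[maccsIdx][usable]
  pick <- if (any(vals > 0)) usable[which.max(vals)] else
    usable[which.min(vals)]
  keyId <- ids[pick]
  sm <- keyTab$smarts[match(keyId, keyTab$id)]
  atoms <- obSmartsAtoms(smiles, sm)
  if (!length(atoms)) {
    stop("consistency error: on-bit MACCS key ", keyId,
         " does not re-match the molecule")
  }
  list(key = keyId, smarts = sm, atoms = atoms,
       contribution = unname(contrib[maccsIdx][pick]),
       sign = if (contrib[maccsIdx][pick] >= 0) "toxicity" else "safety",
       empty = FALSE)
}

#' Rank proxy-endpoint contributions for one prediction
#'
#' Orders the 11 proxy features by absolute attribution (ties broken by
#' registry order) and surfaces the top 3 with their signed values.
#'
#' @param attribution result of [explainFeatures()] for a proxy-aware model.
#' @param topN number of endpoints surfaced (default 3).
#' @return data.frame: `endpoint`, `contribution`, `rank`.
#' @export
rankProxyContributions <- function(attribution, topN = 3L) {
  contrib <- attribution$contributions
  idx <- grep("^proxy_", names(contrib))
  if (!length(idx)) {
    stop("attribution does not contain the proxy block ",
         "(unsupported feature-space configuration)")
  }
  vals <- contrib[idx]
  ord <- order(-abs(vals), seq_along(vals))
  out <- data.frame(
    endpoint = sub("^proxy_", "", names(vals)[ord]),
    contribution = unname(vals[ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  out$top3 <- out$rank <= topN
  out
}
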