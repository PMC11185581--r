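# Synthetic multi-endpoint corpus generator. Emits pipeline-valid chemistry
# built from a drug-like scaffold/decoration grammar with planted
# structure-label relationships, so every stage of the pipeline is testable
# without external data.

# Scaffold templates: {R1}/{R2} mark substitution points; empty substituents
# are cleaned away. All templates are validated at generation time (the
# generator refuses to emit chemistry the preparation pipeline would not
# accept).
.FIXTURE_SCAFFOLDS <- c(
  "c1cc({R2})ccc1{R1}", "c1cc({R2})cnc1{R1}", "Cc1cc({R2})ccc1{R1}",
  "COc1cc({R2})ccc1{R1}", "Nc1cc({R2})ccc1{R1}", "Oc1cc({R2})ccc1{R1}",
  "Fc1cc({R2})ccc1{R1}", "Clc1cc({R2})ccc1{R1}",
  "c1ccc2cc({R1})c({R2})cc2c1", "c1ccc2nc({R1})cc({R2})c2c1",
  "c1cc({R2})oc1{R1}", "c1cc({R2})sc1{R1}", "c1cc({R2})[nH]c1{R1}",
  "C1CC({R1})CCC1{R2}", "C1CC({R1})CC1{R2}", "C1CN({R1})CCC1{R2}",
  "C1CN({R1})CCN1{R2}", "C1CC({R1})OC1{R2}", "O=C1CCC({R1})CC1",
  "NC(=O)c1ccc({R1})cc1{R2}", "CC(=O)c1ccc({R1})cc1{R2}",
  "COC(=O)c1ccc({R1})cc1{R2}", "C=Cc1ccc({R1})cc1{R2}",
  "NCc1ccc({R1})cc1{R2}", "OC(=O)COc1ccc({R1})cc1{R2}",
  "NS(=O)(=O)c1ccc({R1})cc1{R2}", "c1ccc(-c2ccc({R1})cc2)cc1{R2}",
  "CC(C)c1cc({R2})ccc1{R1}",
  "c1cc({R2})ncc1{R1}", "c1nc({R2})ccc1{R1}", "c1cnc({R1})cn1",
  "c1ccc2c(c1)oc({R1})c2{R2}", "c1ccc2c(c1)sc({R1})c2{R2}",
  "c1ccc2c(c1)[nH]c({R1})c2{R2}", "c1ccc2c(c1)nc({R1})o2",
  "c1ccc2c(c1)nc({R1})s2", "c1ccc2c(c1)nc({R1})[nH]2",
  "Cn1cc({R1})cn1", "Cc1cc({R1})on1", "Cc1cc({R1})no1",
  "Cc1nc({R1})cs1", "Cc1nc({R1})co1",
  "c1cc({R1})nnc1{R2}", "c1cnc({R1})nc1{R2}",
  "O=c1cc({R1})oc2ccccc12", "O=c1ccc2cc({R1})ccc2o1",
  "C1CC({R1})c2ccccc2C1", "C1CCc2cc({R1})ccc2C1",
  "C1COCC({R1})O1", "C1OC({R1})OCC1", "C1CCN({R1})CC1",
  "C1CCN({R1})CCC1", "O=C1CC({R1})CN1", "O=C1CCC({R1})N1",
  "C1=CC({R1})CCC1", "C1COC({R1})C1", "S1C({R1})CCC1",
  "O=S1(=O)CCC({R1})C1", "N1({R1})CCOCC1", "C1CSC({R1})C1",
  "c1cc2ccccc2n1{R1}", "c1coc2cc({R1})ccc12"
)

# Decorations with their heavy-atom sizes (sizes steer substituent bulk,
# which feeds the lipophilicity latent and the toxicophore linker length).
.FIXTURE_DECOR <- data.frame(
  smiles = c("", "C", "CC", "F", "Cl", "Br", "O", "OC", "N", "NC",
             "C#N", "C(=O)O", "C(=O)N", "CO", "CN", "CCl", "SC",
             "C(=O)C", "CCC", "CCCC", "CCCCC", "CCOC", "CCN(C)C", "CCCO",
             "C(F)(F)F", "S(=O)(=O)N", "CCCCCC", "CCOCC", "N(CC)CC",
             "C(C)(C)C", "CC(C)C", "OC(C)C", "OCC", "OCCC", "SCC",
             "NC(=O)C", "OC(=O)C", "CC(=O)O", "OC(F)(F)F", "CCCl"),
  size = c(0, 1, 2, 1, 1, 1, 1, 2, 1, 2,
           2, 3, 3, 2, 2, 2, 2,
           3, 3, 4, 5, 4, 5, 4,
           4, 4, 6, 5, 5,
           4, 4, 4, 3, 4, 3,
           4, 4, 4, 5, 3),
  stringsAsFactors = FALSE
)

#' @param nGold,nPerEndpoint,nCmax corpus sizes; `nPerEndpoint` must be a
#'   named integer vector (one entry per binary endpoint).
#' @param toxicophore substituent fragment planted in latent-toxic
#'   compounds (default: aromatic nitro group).
#' @param q probability that a latent-toxic compound carries the planted
#'   toxicophore.
#' @param proxyConcordance target Cohen's kappa between endpoints sharing
#'   a latent signal; converted to a per-endpoint label flip rate.
#' @param cmaxNoiseSd Gaussian noise (pMolar) of the Cmax linear model.
#' @param seed generator seed.
#' @rdname FixtureSpec-class
#' @export
fixtureSpec <- function(nGold = 600L,
                        nPerEndpoint = c(
                          human_hepatotoxicity = 900L,
                          animal_hepatotoxicity_a = 500L,
                          animal_hepatotoxicity_b = 600L,
                          preclinical_hepatotoxicity = 1200L,
                          diverse_dili_a = 800L,
                          diverse_dili_c = 450L,
                          bsep_inhibition = 450L,
                          mitotox = 1500L,
                          reactive_metabolite = 300L),
                        nCmax = c(cmax_total = 250L, cmax_unbound = 180L),
                        toxicophore = "[N+](=O)[O-]",
                        q = 0.9, proxyConcordance = 0.6,
                        cmaxNoiseSd = 0.3, seed = 1L) {
  new("FixtureSpec", nGold = as.integer(nGold),
      nPerEndpoint = vapply(nPerEndpoint, as.integer, 1L),
      nCmax = vapply(nCmax, as.integer, 1L),
      toxicophore = toxicophore, q = q,
      proxyConcordance = proxyConcordance,
      cmaxNoiseSd = cmaxNoiseSd, seed = as.integer(seed))
}

.fillTemplate <- function(template, r1, r2) {
  s <- sub("{R1}", r1, template, fixed = TRUE)
  s <- sub("{R2}", r2, s, fixed = TRUE)
  gsub("()", "", s, fixed = TRUE)
}

# Endpoint latent assignment: the human/heterogeneous family tracks the
# composite DILI latent, the preclinical/animal family tracks the
# secondary (lipophilicity) signal, the mechanism family tracks the
# toxicophore itself.
.endpointLatent <- function(name) {
  if (grepl("preclinical|animal|diverse_dili_c", name)) return("chain")
  if (grepl("human|diverse_dili_a", name)) return("dili")
  "tox"
}

# Symmetric label-flip rate that yields the target Cohen's kappa between
# two noisy copies of a shared latent with prevalence pi.
.flipForKappa <- function(kappa, pi) {
  kap <- function(e) {
    m <- pi * (1 - e) + (1 - pi) * e
    po <- (1 - e)^2 + e^2
    pe <- m^2 + (1 - m)^2
    (po - pe) / (1 - pe)
  }
  if (kappa >= 1) return(0)
  stats::uniroot(function(e) kap(e) - kappa, c(1e-6, 0.499))$root
}

# The secondary (lipophilicity) latent: molecules whose computed logP
# reaches this threshold. A whole-molecule aggregate is directly visible
# to descriptor-based models but hard to reconstruct from local
# substructure bits, emulating the complementary value of biological
# endpoint data over raw structure.
.CHAIN_LOGP <- 2.9

# Draw one unique molecule table of size n with an independent toxicophore
# latent. Toxicophore-bearing substituents keep an alkyl linker of the
# drawn decoration size so the toxic subspace stays combinatorially rich
# and bulk distributions match; the lipophilicity latent is computed after
# generation from the prepared structures.
.sampleMolecules <- function(n, spec, pTox = 0.45) {
  decor <- .FIXTURE_DECOR
  env <- new.env(hash = TRUE, parent = emptyenv())
  rows <- vector("list", n)
  made <- 0L
  guard <- 0L
  while (made < n) {
    guard <- guard + 1L
    if (guard > 200L * n) stop("fixture grammar exhausted before reaching n")
    tox <- stats::runif(1) < pTox
    hasTox <- tox && stats::runif(1) < spec@q
    scaf <- sample(length(.FIXTURE_SCAFFOLDS), 1L)
    d1 <- sample(nrow(decor), 1L)
    d2 <- sample(nrow(decor), 1L)
    r1 <- if (hasTox) {
      paste0(strrep("C", decor$size[d1]), spec@toxicophore)
    } else {
      decor$smiles[d1]
    }
    smi <- .fillTemplate(.FIXTURE_SCAFFOLDS[scaf], r1, decor$smiles[d2])
    if (!is.null(env[[smi]])) next
    env[[smi]] <- TRUE
    made <- made + 1L
    rows[[made]] <- data.frame(
      smiles = smi, scaffold = scaf, tox = tox,
      has_toxicophore = hasTox,
      decorSize = decor$size[d1] + decor$size[d2],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.flipLabels <- function(latent, e) {
  flip <- stats::runif(length(latent)) < e
  as.integer(ifelse(flip, 1L - latent, latent))
}

#' Generate a synthetic multi-endpoint corpus
#'
#' Builds a gold-standard DILI set and a registry of binary proxy
#' endpoints plus two continuous Cmax endpoints from a drug-like
#' scaffold/decoration grammar. The composite DILI latent is (toxicophore
#' OR lipophilicity signal, the latter a computed-logP threshold); endpoint
#' labels are noisy copies of their family latent, with flip rates solved
#' exactly from the target concordance at each latent's prevalence. Cmax targets are linear in
#' molecular weight and logP plus Gaussian noise. Every emitted SMILES is
#' guaranteed to survive the preparation pipeline; the ground-truth
#' manifest records every planted fact.
#'
#' @param spec a [fixtureSpec()].
#' @return list: `endpoints` (named list of [EndpointDataset-class]),
#'   `gold` ([GoldStandardDILI-class]), `manifest` (ground truth).
#' @export
generateCorpus <- function(spec = fixtureSpec()) {
  set.seed(spec@seed)
  pTox <- 0.45
  sizes <- spec@nPerEndpoint
  poolSize <- max(max(sizes), ceiling(0.45 * sum(sizes)))
  # pool and gold drawn in one pass so their chemistry is disjoint at the
  # SMILES level; gold is oversampled because distinct SMILES can still
  # collapse to one structure key after standardization
  goldDraw <- ceiling(spec@nGold * 1.15)
  allTab <- .sampleMolecules(poolSize + goldDraw, spec)
  # prepare (validates the grammar end-to-end) and key everything at once
  prep <- prepareCompounds(allTab$smiles)
  if (any(prep$status != "ok")) {
    stop("fixture generator emitted pipeline-invalid chemistry: ",
         paste(unique(prep$status[prep$status != "ok"]), collapse = ", "))
  }
  allTab$key <- prep$inchikey_hash
  allProps <- obProperties(prep$prot_smiles)
  allTab$chain <- !is.na(allProps$logP) & allProps$logP >= .CHAIN_LOGP
  allTab$dili_latent <- as.integer(allTab$tox | allTab$chain)
  poolRows <- seq_len(poolSize)
  poolRows <- poolRows[!duplicated(allTab$key[poolRows])]
  goldRows <- poolSize + seq_len(goldDraw)
  goldRows <- goldRows[!duplicated(allTab$key[goldRows]) &
                         !(allTab$key[goldRows] %in% allTab$key[poolRows])]
  if (length(goldRows) < spec@nGold) {
    stop("fixture grammar could not supply ", spec@nGold,
         " key-distinct gold compounds")
  }
  goldRows <- goldRows[seq_len(spec@nGold)]
  pool <- allTab[poolRows, ]
  goldTab <- allTab[goldRows, ]
  rownames(pool) <- rownames(goldTab) <- NULL
  poolSize <- nrow(pool)
  poolPrep <- prep[poolRows, ]
  goldPrep <- prep[goldRows, ]
  rownames(poolPrep) <- rownames(goldPrep) <- NULL
  # flip rates calibrated to the target kappa at each latent's empirical
  # prevalence in the pool
  prev <- c(tox = mean(pool$tox), chain = mean(pool$chain),
            dili = mean(pool$dili_latent))
  eFam <- tryCatch(
    vapply(prev, function(p) .flipForKappa(spec@proxyConcordance, p),
           numeric(1L)),
    error = function(err) stop("unachievable concordance target: ",
                               spec@proxyConcordance))

  endpoints <- list()
  membership <- list()
  for (nm in names(sizes)) {
    idx <- sample(poolSize, min(sizes[[nm]], poolSize))
    fam <- .endpointLatent(nm)
    latent <- switch(fam,
                     dili = pool$dili_latent[idx],
                     chain = as.integer(pool$chain[idx]),
                     tox = as.integer(pool$tox[idx]))
    labels <- .flipLabels(latent, eFam[[fam]])
    recs <- poolPrep[idx, ]
    recs$label <- labels
    recs$sources <- nm
    endpoints[[nm]] <- endpointDataset(
      name = nm, recs = recs,
      assayType = switch(.endpointLatent(nm), dili = "human hepatotoxicity",
                         chain = "animal hepatotoxicity", "mechanism"),
      task = "binary",
      activeDefinition = "synthetic latent signal with calibrated noise")
    membership[[nm]] <- idx
  }
  props <- allProps[poolRows, ]
  cmaxCoef <- list(intercept = 8, mw = -0.01, logp = -0.5)
  for (nm in names(spec@nCmax)) {
    idx <- sample(poolSize, spec@nCmax[[nm]])
    value <- cmaxCoef$intercept + cmaxCoef$mw * props$MW[idx] +
      cmaxCoef$logp * props$logP[idx] +
      stats::rnorm(length(idx), 0, spec@cmaxNoiseSd)
    recs <- poolPrep[idx, ]
    recs$label <- value
    recs$sources <- nm
    endpoints[[nm]] <- endpointDataset(
      name = nm, recs = recs, assayType = "PK", task = "regression",
      activeDefinition = "median pMolar plasma concentration (synthetic)")
    membership[[nm]] <- idx
  }
  # the gold standard emulates a curated, adjudicated label source: a small
  # residual error rate, far below the assay-level noise of the proxies
  goldLabels <- .flipLabels(goldTab$dili_latent, 0.02)
  goldRecs <- goldPrep
  goldRecs$label <- goldLabels
  goldRecs$sources <- "synthetic_gold"
  goldRecs <- dedupResolve(goldRecs, task = "binary")
  gold <- new("GoldStandardDILI", records = goldRecs,
              sourceRule = "synthetic composite latent, 2% label noise")
  list(
    endpoints = endpoints,
    gold = gold,
    manifest = list(
      pool = pool, goldTruth = goldTab, membership = membership,
      flipRate = eFam, cmaxCoef = cmaxCoef,
      toxicophore = spec@toxicophore,
      params = list(q = spec@q, kappaTarget = spec@proxyConcordance,
                    cmaxNoiseSd = spec@cmaxNoiseSd, seed = spec@seed)
    )
  )
}

#' Inject controlled key overlap between gold standard and proxy endpoints
#'
#' Copies the first `floor(fraction * |gold|)` gold compounds (with their
#' gold labels) into each named proxy endpoint, for exercising
#' [removeOverlap()] round trips.
#'
#' @param proxies named list of [EndpointDataset-class].
#' @param gold a [GoldStandardDILI-class].
#' @param fraction overlap fraction in \[0, 1\].
#' @param into endpoint names receiving the overlap (default: all).
#' @return the modified endpoint list.
#' @export
injectOverlap <- function(proxies, gold, fraction, into = names(proxies)) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  g <- records(gold)
  k <- floor(fraction * nrow(g))
  if (!k) return(proxies)
  add <- g[seq_len(k), , drop = FALSE]
  for (nm in into) {
    r <- records(proxies[[nm]])
    new <- add[!add$inchikey_hash %in% r$inchikey_hash, , drop = FALSE]
    keep <- intersect(names(r), names(new))
    proxies[[nm]]@records <- rbind(r[, keep, drop = FALSE],
                                   new[, keep, drop = FALSE])
    rownames(proxies[[nm]]@records) <- NULL
  }
  proxies
}
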