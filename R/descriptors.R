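# 2D descriptor collection and the 15 physicochemical parameters, computed
# from the molecular graph (explicit-hydrogen SDF via OpenBabel) plus
# OpenBabel group-contribution properties (logP, TPSA, MR, HBA, HBD).

.ATOM_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                F = 18.998, P = 30.974, S = 32.065, Cl = 35.453, Br = 79.904,
                I = 126.904, Si = 28.086, Se = 78.971)
.ATOM_EN <- c(H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44, F = 3.98,
              P = 2.19, S = 2.58, Cl = 3.16, Br = 2.96, I = 2.66, Si = 1.90,
              Se = 2.55)
.ATOM_RCOV <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39,
                Si = 1.11, Se = 1.20)

.lookupAtomProp <- function(tab, els, default) {
  v <- tab[els]
  v[is.na(v)] <- default
  unname(v)
}

# Per-molecule graph info from an explicit-hydrogen SDF.
# Returns: elements (heavy), degree, bonds (heavy-heavy, with order),
# nH per heavy atom, heavy igraph, total H count.
.molGraphOne <- function(sdfMol) {
  ab <- ChemmineR::atomblock(sdfMol)
  bb <- ChemmineR::bondblock(sdfMol)
  els <- sub("_[0-9]+$", "", rownames(ab))
  heavy <- which(els != "H")
  hmap <- match(seq_along(els), heavy)
  nH <- integer(length(heavy))
  bonds <- NULL
  if (length(bb) && nrow(bb)) {
    a1 <- as.integer(bb[, 1L]); a2 <- as.integer(bb[, 2L])
    ord <- as.integer(bb[, 3L])
    hh <- els[a1] != "H" & els[a2] != "H"
    if (any(hh)) {
      bonds <- data.frame(a = hmap[a1[hh]], b = hmap[a2[hh]], order = ord[hh])
    }
    for (k in which(!hh)) {
      ha <- if (els[a1[k]] != "H") a1[k] else if (els[a2[k]] != "H") a2[k] else NA
      if (!is.na(ha)) nH[hmap[ha]] <- nH[hmap[ha]] + 1L
    }
  }
  g <- igraph::make_empty_graph(n = length(heavy), directed = FALSE)
  if (!is.null(bonds)) {
    g <- igraph::add_edges(g, rbind(bonds$a, bonds$b))
  }
  list(els = els[heavy], nH = nH, bonds = bonds, g = g,
       nHTotal = sum(els == "H"))
}

.molGraphs <- function(smiles) {
  sdf <- obSdf(smiles, addH = TRUE)
  ids <- as.integer(sub("^m", "", ChemmineR::sdfid(sdf)))
  out <- vector("list", length(smiles))
  for (i in seq_along(sdf)) out[[ids[i]]] <- .molGraphOne(sdf[[i]])
  out
}

.PHYSCHEM_SMARTS <- c(
  csp3 = "[CX4]",
  rotatable = "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]",
  arom_ring5 = "[a]1[a][a][a][a]1",
  arom_ring6 = "[a]1[a][a][a][a][a]1"
)

.DESC_SMARTS <- c(
  nCX4 = "[CX4]",
  nCarbonyl = "[CX3]=[OX1]",
  nCarboxyl = "[CX3](=O)[OX2H1,OX1-]",
  nEster = "[CX3](=O)[OX2][#6]",
  nAmide = "[CX3](=O)[NX3]",
  nNitro = "[NX3+](=O)[O-]",
  nSulfonyl = "[SX4](=O)(=O)",
  nEther = "[#6][OX2;!$([OX2]C=O)][#6]",
  nPrimAmine = "[NX3;H2;!$(NC=O)]",
  nHydroxyl = "[OX2H]",
  nNitrile = "[CX2]#[NX1]",
  nAromN = "[n]"
)

.safeDiv <- function(a, b) ifelse(b == 0, NA_real_, a / b)

# One row of the descriptor block for one molecule.
.descRow <- function(mg) {
  els <- mg$els
  g <- mg$g
  A <- length(els)
  deg <- igraph::degree(g)
  ec <- igraph::ecount(g)
  comp <- igraph::components(g)$no
  mu <- ec - A + comp                     # cyclomatic number (SSSR count)
  bridges <- if (ec) igraph::bridges(g) else integer(0)
  ringEdges <- setdiff(seq_len(ec), as.integer(bridges))
  ringAtoms <- unique(as.vector(igraph::ends(g, ringEdges)))
  fused <- if (length(ringEdges)) {
    sg <- igraph::subgraph_from_edges(g, ringEdges, delete.vertices = TRUE)
    igraph::components(sg)$no
  } else 0L
  D <- if (A > 1) igraph::distances(g) else matrix(0, 1, 1)
  finD <- D[upper.tri(D)]
  finD <- finD[is.finite(finD)]
  eccs <- if (A > 1) apply(D, 1L, function(r) max(r[is.finite(r)])) else 0
  diam <- max(eccs); rad <- min(eccs)
  mass <- .lookupAtomProp(.ATOM_MASS, els, 10)
  en <- .lookupAtomProp(.ATOM_EN, els, 2.0)
  rcov <- .lookupAtomProp(.ATOM_RCOV, els, 1.0)
  ats <- function(w, d) {
    if (d == 0) return(sum(w * w))
    if (A < 2) return(0)
    sum(outer(w, w)[which(D == d)]) / 2
  }
  ords <- if (is.null(mg$bonds)) integer(0) else mg$bonds$order
  bondEls <- if (is.null(mg$bonds)) NULL else
    cbind(els[mg$bonds$a], els[mg$bonds$b])
  polarBonds <- if (is.null(bondEls)) 0L else sum(bondEls[, 1] != bondEls[, 2])
  p2 <- sum(choose(deg, 2))
  tri <- sum(igraph::count_triangles(g)) / 3
  p3 <- if (is.null(mg$bonds)) 0 else {
    sum((deg[mg$bonds$a] - 1) * (deg[mg$bonds$b] - 1)) - 3 * tri
  }
  kappa1 <- .safeDiv(A * (A - 1)^2, ec^2)
  kappa2 <- .safeDiv((A - 1) * (A - 2)^2, p2^2)
  kappa3 <- if (A %% 2 == 1) .safeDiv((A - 1) * (A - 3)^2, p3^2) else
    .safeDiv((A - 3) * (A - 2)^2, p3^2)
  balaban <- if (ec && A > 2 && is.finite(sum(D))) {
    s <- rowSums(D)
    e <- igraph::ends(g, seq_len(ec))
    .safeDiv(ec, mu + 1) * sum(1 / sqrt(s[e[, 1]] * s[e[, 2]]))
  } else NA_real_
  halos <- c(F = sum(els == "F"), Cl = sum(els == "Cl"),
             Br = sum(els == "Br"), I = sum(els == "I"))
  c(
    nHeavy = A, nC = sum(els == "C"), nN = sum(els == "N"),
    nO = sum(els == "O"), nS = sum(els == "S"), nP = sum(els == "P"),
    nF = halos[["F"]], nCl = halos[["Cl"]], nBr = halos[["Br"]],
    nI = halos[["I"]], nHalogen = sum(halos),
    nHetero = sum(!els %in% c("C", "H")), nHExplicit = mg$nHTotal,
    molWeight = sum(mass) + 1.008 * mg$nHTotal,
    avgAtomicMass = (sum(mass) + 1.008 * mg$nHTotal) / (A + mg$nHTotal),
    nBonds = ec, nDouble = sum(ords == 2), nTriple = sum(ords == 3),
    nRings = mu, nRingAtoms = length(ringAtoms),
    nRingBonds = length(ringEdges), nFusedSystems = fused,
    graphDiameter = diam, graphRadius = rad,
    petitjeanShape = .safeDiv(diam - rad, rad), meanEccentricity = mean(eccs),
    zagreb1 = sum(deg^2), zagreb2 = if (is.null(mg$bonds)) 0 else
      sum(deg[mg$bonds$a] * deg[mg$bonds$b]),
    chi0 = sum(.safeDiv(1, sqrt(deg))[deg > 0], na.rm = TRUE),
    chi1 = if (is.null(mg$bonds)) 0 else
      sum(1 / sqrt(deg[mg$bonds$a] * deg[mg$bonds$b])),
    nTerminal = sum(deg == 1), nBranch3 = sum(deg == 3),
    nBranch4 = sum(deg >= 4), meanDegree = mean(deg),
    plattIndex = if (is.null(mg$bonds)) 0 else
      sum(deg[mg$bonds$a] + deg[mg$bonds$b] - 2),
    graphDensity = .safeDiv(2 * ec, A * (A - 1)),
    wienerIndex = sum(finD), meanDistance = .safeDiv(sum(finD), length(finD)),
    hararyIndex = sum(1 / finD[finD > 0]),
    eccentricConnectivity = sum(eccs * deg),
    balabanJ = balaban,
    kappa1 = kappa1, kappa2 = kappa2, kappa3 = kappa3,
    pathCount2 = p2, pathCount3 = p3,
    atsMass0 = ats(mass, 0), atsMass1 = ats(mass, 1),
    atsMass2 = ats(mass, 2), atsMass3 = ats(mass, 3),
    atsEN0 = ats(en, 0), atsEN1 = ats(en, 1),
    atsEN2 = ats(en, 2), atsEN3 = ats(en, 3),
    atsRcov0 = ats(rcov, 0), atsRcov1 = ats(rcov, 1),
    atsRcov2 = ats(rcov, 2), atsRcov3 = ats(rcov, 3),
    sumEN = sum(en), meanEN = mean(en),
    polarBondCount = polarBonds,
    fracPolarBonds = .safeDiv(polarBonds, ec),
    nHDonorAtoms = sum(mg$nH > 0 & els %in% c("N", "O")),
    sumHOnNO = sum(mg$nH[els %in% c("N", "O")])
  )
}

#' Compute the 2D molecular descriptor collection
#'
#' A graph-topological 2D descriptor set (constitutional counts, ring and
#' shape statistics, connectivity and distance indices, kappa shape indices,
#' Moreau-Broto autocorrelations over mass/electronegativity/covalent
#' radius, electronic bond polarity summaries) supplemented by OpenBabel
#' group-contribution properties (logP, TPSA, molar refractivity, H-bond
#' counts) and substructure counts. Columns containing any missing or
#' non-finite value across the corpus are dropped and reported, so the
#' retained set is a property of the corpus (degenerate molecules such as
#' single atoms produce undefined distance/shape indices).
#'
#' @param smiles standardized (and typically protonated) canonical SMILES.
#' @param graphs optional precomputed result of the internal graph pass,
#'   for callers that also compute the physicochemical block.
#' @return numeric matrix (rows = compounds) with the retained descriptor
#'   columns; dropped column names are in `attr(, "dropped")`.
#' @export
computeDescriptors <- function(smiles, graphs = NULL) {
  stopifnot(length(smiles) > 0)
  if (is.null(graphs)) graphs <- .molGraphs(smiles)
  rows <- lapply(graphs, function(mg) {
    if (is.null(mg)) return(NULL)
    .descRow(mg)
  })
  proto <- rows[[which(!vapply(rows, is.null, TRUE))[1L]]]
  mat <- t(vapply(rows, function(r) r %||% rep(NA_real_, length(proto)),
                  numeric(length(proto))))
  colnames(mat) <- names(proto)
  props <- obProperties(smiles)
  mat <- cbind(mat, logP = props$logP, TPSA = props$TPSA, molarRefract = props$MR,
               HBA = props$HBA1, HBALipinski = props$HBA2, HBD = props$HBD)
  sc <- obSmartsCount(smiles, .DESC_SMARTS)
  mat <- cbind(mat, sc)
  bad <- apply(mat, 2L, function(col) any(!is.finite(col)))
  out <- mat[, !bad, drop = FALSE]
  if (!ncol(out)) stop("all descriptor columns dropped for this corpus")
  attr(out, "dropped") <- colnames(mat)[bad]
  out
}

.PHYSCHEM_NAMES <- c(
  "TPSA", "HBondAcceptors", "HBondDonors", "FractionCSP3", "logP",
  "RotatableBonds", "Rings", "AssembledRings", "AromaticRings",
  "Heteroatoms", "Stereocenters", "PositiveAtoms", "NegativeAtoms",
  "NHOHCount", "NOCount"
)

.countChargedAtoms <- function(smi, sign = "+") {
  brackets <- regmatches(smi, gregexpr("\\[[^]]*\\]", smi))[[1L]]
  sum(vapply(brackets, function(b) {
    grepl(sign, b, fixed = TRUE)
  }, logical(1L)))
}

# Potential tetrahedral stereocenter heuristic: saturated carbons bearing
# at most one hydrogen whose heavy-neighbour depth-1 signatures are all
# distinct. An approximation of the perception in full cheminformatics
# toolkits, adequate for descriptor purposes on stereo-free structures.
.countStereocenters <- function(mg) {
  if (is.null(mg$bonds)) return(0L)
  deg <- igraph::degree(mg$g)
  nbr <- igraph::adjacent_vertices(mg$g, seq_along(mg$els))
  cand <- which(mg$els == "C" & (deg + mg$nH) == 4L & mg$nH <= 1L & deg >= 3L)
  unsat <- unique(c(mg$bonds$a[mg$bonds$order > 1], mg$bonds$b[mg$bonds$order > 1]))
  cand <- setdiff(cand, unsat)
  count <- 0L
  for (v in cand) {
    sigs <- vapply(as.integer(nbr[[v]]), function(u) {
      nn <- sort(mg$els[setdiff(as.integer(nbr[[u]]), v)])
      paste(mg$els[u], deg[u], mg$nH[u], paste(nn, collapse = ""))
    }, "")
    if (!anyDuplicated(sigs)) count <- count + 1L
  }
  count
}

#' Compute the 15 physicochemical parameters
#'
#' Topological polar surface area, H-bond acceptor and donor counts,
#' fraction of sp3 carbons, logP, rotatable bonds, ring counts (total,
#' assembled/fused systems, aromatic), heteroatoms, potential
#' stereocenters, positively and negatively charged atoms, and the NHOH and
#' NO counts, in that fixed order.
#'
#' @inheritParams computeDescriptors
#' @return numeric matrix with the 15 named columns in declared order.
#' @examples
#' \donttest{computePhyschem("CCO")[, c("HBondDonors", "TPSA")]}
#' @export
computePhyschem <- function(smiles, graphs = NULL) {
  stopifnot(length(smiles) > 0)
  if (is.null(graphs)) graphs <- .molGraphs(smiles)
  props <- obProperties(smiles)
  sc <- obSmartsCount(smiles, .PHYSCHEM_SMARTS)
  out <- matrix(NA_real_, nrow = length(smiles), ncol = 15L,
                dimnames = list(NULL, .PHYSCHEM_NAMES))
  for (i in seq_along(smiles)) {
    mg <- graphs[[i]]
    if (is.null(mg)) next
    A <- length(mg$els)
    ec <- igraph::ecount(mg$g)
    mu <- ec - A + igraph::components(mg$g)$no
    bridges <- if (ec) as.integer(igraph::bridges(mg$g)) else integer(0)
    ringEdges <- setdiff(seq_len(ec), bridges)
    fused <- if (length(ringEdges)) {
      sg <- igraph::subgraph_from_edges(mg$g, ringEdges, delete.vertices = TRUE)
      igraph::components(sg)$no
    } else 0L
    nC <- sum(mg$els == "C")
    out[i, ] <- c(
      props$TPSA[i], props$HBA1[i], props$HBD[i],
      if (nC) sc[i, "csp3"] / nC else 0,
      props$logP[i], sc[i, "rotatable"], mu, fused,
      sc[i, "arom_ring5"] + sc[i, "arom_ring6"],
      sum(!mg$els %in% c("C", "H")),
      .countStereocenters(mg),
      .countChargedAtoms(smiles[i], "+"),
      .countChargedAtoms(smiles[i], "-"),
      sum(mg$nH[mg$els %in% c("N", "O")]),
      sum(mg$els %in% c("N", "O"))
    )
  }
  out
}
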