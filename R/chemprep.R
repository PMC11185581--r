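# Compound ingestion: parse, filter, standardize, protonate, hash, dedup.

.METALS <- c(
  "Li", "Na", "K", "Rb", "Cs", "Fr", "Be", "Mg", "Ca", "Sr", "Ba", "Ra",
  "Al", "Ga", "In", "Tl", "Sn", "Pb", "Bi", "Sc", "Ti", "V", "Cr", "Mn",
  "Fe", "Co", "Ni", "Cu", "Zn", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh",
  "Pd", "Ag", "Cd", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "La", "Ce", "Pr", "Nd", "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er",
  "Tm", "Yb", "Lu", "Ac", "Th", "Pa", "U", "Np", "Pu"
)

# Tokenize a SMILES string into heavy-atom element symbols. This is an
# element counter for filtering (not a structure parser); bonds, ring
# closures and branches are skipped, bracket atoms are reduced to their
# element symbol, and aromatic organic-subset atoms are upcased.
.smilesElements <- function(smi) {
  out <- character(0)
  i <- 1L
  n <- nchar(smi)
  while (i <= n) {
    ch <- substr(smi, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(smi, i, n), fixed = TRUE)
      body <- substr(smi, i + 1L, i + j - 2L)
      body <- sub("^[0-9]+", "", body)       # isotope
      el <- regmatches(body, regexpr("^[A-Za-z][a-z]?", body))
      if (length(el)) {
        el <- sub("^([a-z])", "\\U\\1", el, perl = TRUE)
        out <- c(out, el)
      }
      i <- i + j
      next
    }
    two <- substr(smi, i, i + 1L)
    if (two %in% c("Cl", "Br")) {
      out <- c(out, two); i <- i + 2L; next
    }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      out <- c(out, ch); i <- i + 1L; next
    }
    if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      out <- c(out, toupper(ch)); i <- i + 1L; next
    }
    i <- i + 1L
  }
  out[out != "H"]
}

.fragmentInfo <- function(canonical) {
  frags <- strsplit(canonical, ".", fixed = TRUE)[[1L]]
  els <- lapply(frags, .smilesElements)
  data.frame(
    fragment = frags,
    heavy = vapply(els, length, integer(1L)),
    organic = vapply(els, function(e) "C" %in% e, logical(1L)),
    stringsAsFactors = FALSE
  )
}

# Pick the single organic principal fragment, or NA when unresolvable
# (no organic fragment, or a tie for the largest organic fragment).
.principalFragment <- function(canonical) {
  fi <- .fragmentInfo(canonical)
  if (nrow(fi) == 1L) return(fi$fragment)
  org <- fi[fi$organic, , drop = FALSE]
  if (!nrow(org)) return(NA_character_)
  if (nrow(org) == 1L) return(org$fragment)
  mx <- max(org$heavy)
  top <- org$fragment[org$heavy == mx]
  if (length(top) > 1L) return(NA_character_)
  top
}

#' Drug-likeness filter
#'
#' Applies the raw-molecule acceptance rules in specification order and
#' reports the first failing rule: no carbon atom; a disconnected input with
#' no single resolvable organic principal fragment; metal-only composition;
#' molecular weight above the cutoff (computed on the raw, pre-fragment
#' molecule).
#'
#' @param smiles character vector of SMILES.
#' @param spec a [filterSpec()].
#' @return data.frame with columns `smiles`, `accept`, `reason`
#'   (`NA` when accepted, `"parse_error"` for unparseable input).
#' @examples
#' passesDruglikeFilter(c("CCO", "[Na+].[Cl-]"))
#' @export
passesDruglikeFilter <- function(smiles, spec = filterSpec()) {
  canonical <- obCanonical(smiles)
  mw <- obProperties(canonical)$MW
  reason <- rep(NA_character_, length(smiles))
  for (i in seq_along(smiles)) {
    if (is.na(canonical[i])) { reason[i] <- "parse_error"; next }
    els <- .smilesElements(canonical[i])
    if (spec@requireCarbon && !("C" %in% els)) {
      reason[i] <- "no_carbon"
    } else if (spec@rejectMultifragment &&
               grepl(".", canonical[i], fixed = TRUE) &&
               is.na(.principalFragment(canonical[i]))) {
      reason[i] <- "disconnected"
    } else if (spec@rejectMetalsOnly && length(els) &&
               all(els %in% .METALS)) {
      reason[i] <- "metals_only"
    } else if (!is.na(mw[i]) && mw[i] > spec@maxMolecularWeight) {
      reason[i] <- "molecular_weight"
    }
  }
  data.frame(smiles = smiles, accept = is.na(reason), reason = reason,
             stringsAsFactors = FALSE)
}

.stdSteps <- list(
  # ionic alkali-oxygen bonds written covalently are split into charged
  # fragments; broader organometallic chemistry is out of scope
  disconnect_metals = function(smi) {
    smi <- gsub("O\\[(Na|K|Li)\\]", "[O-].[\\1+]", smi)
    gsub("\\[(Na|K|Li)\\]O", "[\\1+].[O-]", smi)
  },
  principal_fragment = function(smi) {
    if (!grepl(".", smi, fixed = TRUE)) return(smi)
    pf <- .principalFragment(smi)
    if (is.na(pf)) smi else pf
  },
  normalize = function(smi) obCanonical(smi),
  neutralize = function(smi) obNeutralize(smi),
  remove_isotopes = function(smi) {
    smi <- gsub("\\[[0-9]+H\\]", "[H]", smi)
    gsub("\\[[0-9]+", "[", smi)
  },
  remove_stereo = function(smi) {
    smi <- gsub("@", "", smi, fixed = TRUE)
    smi <- gsub("/", "", smi, fixed = TRUE)
    gsub("\\", "", smi, fixed = TRUE)
  },
  # no tautomer standardizer is available in this toolchain; kept as an
  # explicit identity hook so the declared step order is complete
  canonical_tautomer = function(smi) smi
)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Apply one standardization step to a vector of SMILES (batched through
# OpenBabel where the step needs the toolkit).
.applyStep <- function(st, smi) {
  switch(st,
    normalize = obCanonical(smi),
    neutralize = obNeutralize(smi),
    principal_fragment = vapply(smi, .stdSteps$principal_fragment, "",
                                USE.NAMES = FALSE),
    {
      f <- .stdSteps[[st]]
      if (is.null(f)) stop("unknown standardization step: ", st)
      f(smi)
    }
  )
}

#' Standardize SMILES to a canonical, stereo-free, single-fragment form
#'
#' Applies the configured transform sequence (metal disconnection, principal
#' organic fragment, normalization, charge neutralization, isotope and
#' stereo removal) iteratively up to `maxIterations` times, stopping at a
#' fixed point; when the trace does not converge the modal SMILES across the
#' iterations is selected, with ties broken lexicographically. The output is
#' idempotent: re-standardizing a standardized string returns it unchanged.
#'
#' @param smiles character vector of filtered SMILES.
#' @param config a [standardizationConfig()].
#' @return character vector of standardized canonical SMILES; failures are
#'   `NA` with the failing step recorded in the `"failedStep"` attribute.
#' @examples
#' standardizeSmiles("C(C)O")                    # "CCO"
#' @export
standardizeSmiles <- function(smiles, config = standardizationConfig()) {
  n <- length(smiles)
  cur <- obCanonical(smiles)
  failed <- ifelse(is.na(cur), "parse", NA_character_)
  active <- which(is.na(failed))
  done <- rep(FALSE, n)
  trace <- matrix(NA_character_, nrow = n, ncol = config@maxIterations)
  for (iter in seq_len(config@maxIterations)) {
    if (!length(active)) break
    prev <- cur[active]
    work <- cur[active]
    for (st in config@steps) {
      res <- .applyStep(st, work)
      bad <- is.na(res) | !nzchar(res)
      if (any(bad)) {
        failed[active[bad]] <- st
        active <- active[!bad]
        res <- res[!bad]
        prev <- prev[!bad]
      }
      work <- res
      if (!length(active)) break
    }
    if (!length(active)) break
    work <- obCanonical(work)
    bad <- is.na(work)
    if (any(bad)) {
      failed[active[bad]] <- "canonicalize"
      active <- active[!bad]
      work <- work[!bad]
      prev <- prev[!bad]
    }
    cur[active] <- work
    trace[active, iter] <- work
    conv <- work == prev
    done[active[conv]] <- TRUE
    active <- active[!conv]
  }
  # molecules with no fixed point: modal SMILES over the trace, ties
  # broken lexicographically
  for (i in active) {
    tr <- trace[i, !is.na(trace[i, ])]
    tab <- table(tr)
    cur[i] <- sort(names(tab)[tab == max(tab)])[[1L]]
  }
  cur[!is.na(failed)] <- NA_character_
  attr(cur, "failedStep") <- failed
  cur
}

#' Assign protonation states at a given pH
#'
#' Ionizable groups are (de)protonated according to OpenBabel's
#' substructure-to-pKa transform table evaluated at the given pH. Molecules
#' without ionizable groups are returned unchanged. The rule-table identity
#' and backend version are recorded in the `"ruleTable"` attribute so runs
#' are reproducible.
#'
#' @param smiles standardized canonical SMILES.
#' @param pH pH units in \[0, 14\] (default 7.0, hepatic physiological pH).
#' @return character vector of protonated canonical SMILES.
#' @examples
#' protonateAtPH("CC(=O)O")   # carboxylate at pH 7
#' @export
protonateAtPH <- function(smiles, pH = 7.0) {
  stopifnot(pH >= 0, pH <= 14)
  out <- obProtonate(smiles, pH = pH)
  attr(out, "ruleTable") <- paste0("openbabel-", .obVersion(), "/phmodel.txt")
  out
}

#' Connectivity-level structure key (InChIKey hash layer)
#'
#' First 14 characters of the standard InChIKey: a connectivity hash that is
#' identical for stereoisomers and isotopologues of one skeleton. Failures
#' return `NA` (callers quarantine such records rather than dropping them).
#'
#' @param smiles canonical SMILES.
#' @return character vector of 14-character keys.
#' @examples
#' hashKey("CCO")   # "LFQSCWFLJHTTHZ"
#' @export
hashKey <- function(smiles) {
  substr(obInchikey(smiles), 1L, 14L)
}

#' Resolve duplicate records sharing a structure key
#'
#' Collapses records to one per `inchikey_hash`, preserving first-occurrence
#' order. Conflicting binary labels resolve to the active class (1) when
#' `preferPositive`; conflicting continuous values resolve to their median
#' (flagged in the returned `conflict` column and in a message).
#'
#' @param records data.frame with `inchikey_hash`, `label` and optionally
#'   `sources` columns.
#' @param task `"binary"` or `"regression"`.
#' @param preferPositive resolve binary conflicts toward 1.
#' @return deduplicated data.frame with a logical `conflict` column.
#' @export
dedupResolve <- function(records, task = "binary", preferPositive = TRUE) {
  stopifnot(all(c("inchikey_hash", "label") %in% names(records)))
  if (!nrow(records)) return(cbind(records, conflict = logical(0)))
  keys <- records$inchikey_hash
  first <- !duplicated(keys)
  out <- records[first, , drop = FALSE]
  rownames(out) <- NULL
  out$conflict <- FALSE
  if (all(first)) return(out)
  grp <- split(seq_along(keys), keys)
  for (k in names(grp)) {
    idx <- grp[[k]]
    if (length(idx) == 1L) next
    labs <- records$label[idx]
    row <- match(k, out$inchikey_hash)
    if (length(unique(labs)) > 1L) {
      out$conflict[row] <- TRUE
      if (task == "binary") {
        out$label[row] <- if (preferPositive) max(labs) else min(labs)
      } else {
        out$label[row] <- stats::median(labs)
        message("continuous label conflict for ", k, ": median taken")
      }
    }
    if ("sources" %in% names(records)) {
      src <- unique(unlist(strsplit(records$sources[idx], ";", fixed = TRUE)))
      out$sources[row] <- paste(src[nzchar(src)], collapse = ";")
    }
  }
  out
}

#' Run the full compound-preparation pipeline
#'
#' Filter, standardize, protonate and key a vector of raw SMILES. Every
#' input yields exactly one output row: accepted records have status
#' `"ok"`, filtered ones `"rejected:<rule>"`, standardization or keying
#' failures `"quarantined:<step>"` (conservation:
#' accepted + rejected + quarantined = inputs).
#'
#' Structure keys are computed on the pre-protonation standardized form, so
#' deduplication operates at the connectivity level regardless of
#' protonation state.
#'
#' @param smiles raw SMILES.
#' @param label optional per-compound labels (binary or continuous).
#' @param source optional per-compound source names.
#' @param filter a [filterSpec()].
#' @param config a [standardizationConfig()].
#' @return data.frame with columns `raw_smiles`, `std_smiles`,
#'   `prot_smiles`, `inchikey_hash`, `label`, `sources`, `status`.
#' @export
prepareCompounds <- function(smiles, label = NULL, source = NULL,
                             filter = filterSpec(),
                             config = standardizationConfig()) {
  n <- length(smiles)
  label <- label %||% rep(NA_real_, n)
  source <- if (is.null(source)) rep("", n) else as.character(source)
  out <- data.frame(
    raw_smiles = smiles,
    std_smiles = NA_character_,
    prot_smiles = NA_character_,
    inchikey_hash = NA_character_,
    label = label,
    sources = source,
    status = NA_character_,
    stringsAsFactors = FALSE
  )
  filt <- passesDruglikeFilter(smiles, filter)
  out$status[!filt$accept] <- ifelse(
    filt$reason[!filt$accept] == "parse_error", "quarantined:parse",
    paste0("rejected:", filt$reason[!filt$accept])
  )
  idx <- which(filt$accept)
  if (length(idx)) {
    std <- standardizeSmiles(smiles[idx], config)
    failed <- attr(std, "failedStep")
    bad <- is.na(std)
    out$status[idx[bad]] <- paste0("quarantined:standardize:", failed[bad])
    out$std_smiles[idx] <- as.character(std)
    good <- idx[!bad]
    if (length(good)) {
      out$prot_smiles[good] <- as.character(
        protonateAtPH(out$std_smiles[good], config@protonationPH))
      keys <- hashKey(out$std_smiles[good])
      kbad <- is.na(keys)
      out$inchikey_hash[good] <- keys
      out$status[good[kbad]] <- "quarantined:inchikey"
      out$status[good[!kbad]] <- "ok"
    }
  }
  out
}

#' Read a compound CSV (`smiles`, optional `label`, `source`)
#' @param path file path.
#' @return data.frame.
#' @export
readCompoundCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!"smiles" %in% names(df)) {
    # accept prepared-record exports keyed by raw_smiles
    if ("raw_smiles" %in% names(df)) df$smiles <- df$raw_smiles
    else stop("CSV must contain a 'smiles' column")
  }
  df
}

#' Write prepared compounds to CSV
#' @param records data.frame from [prepareCompounds()].
#' @param path output file path.
#' @export
writeCompoundCsv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
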