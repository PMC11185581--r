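# Internal OpenBabel backend: SMILES parsing/canonicalization, InChIKey,
# pH-model protonation, fingerprints and SMARTS matching. Everything here is
# order-preserving and returns NA (never drops rows) on per-molecule failure.

.diliNetEnv <- new.env(parent = emptyenv())

.obabelBin <- function() {
  bin <- Sys.which("obabel")
  if (!nzchar(bin)) stop("obabel executable not found on PATH")
  bin
}

# Directory with OpenBabel data tables (MACCS.txt, phmodel.txt, ...).
.obDataDir <- function() {
  if (!is.null(.diliNetEnv$obDataDir)) return(.diliNetEnv$obDataDir)
  root <- dirname(dirname(.obabelBin()))
  cand <- Sys.glob(file.path(root, "share", "openbabel", "*"))
  cand <- cand[file.exists(file.path(cand, "MACCS.txt"))]
  if (!length(cand)) stop("OpenBabel data directory (MACCS.txt) not found")
  .diliNetEnv$obDataDir <- cand[[1L]]
  cand[[1L]]
}

.obVersion <- function() {
  if (is.null(.diliNetEnv$obVersion)) {
    out <- suppressWarnings(system2(.obabelBin(), "-V", stdout = TRUE, stderr = FALSE))
    .diliNetEnv$obVersion <- sub("^Open Babel\\s+([^ ]+).*$", "\\1", out[[1L]])
  }
  .diliNetEnv$obVersion
}

# Batch conversion through ChemmineOB with resume-on-failure. OpenBabel's
# in-memory converter aborts the whole batch at the first unparseable
# molecule, so on a short read we mark the offending input NA and resume
# with the remainder. One output line per successful input is assumed
# (true for the SMILES/CAN/INCHI/INCHIKEY writers used here).
.obConvert <- function(smiles, to = "CAN", options = NULL) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  if (!n) return(out)
  todo <- which(!is.na(smiles) & nzchar(smiles))
  while (length(todo)) {
    src <- paste0(paste0(smiles[todo], "\tx"), "\n", collapse = "")
    res <- tryCatch(
      if (is.null(options)) {
        ChemmineOB::convertFormat("SMI", to, source = src)
      } else {
        ChemmineOB::convertFormat("SMI", to, source = src, options = options)
      },
      error = function(e) ""
    )
    lines <- strsplit(res, "\n", fixed = TRUE)[[1L]]
    lines <- lines[nzchar(trimws(lines))]
    k <- length(lines)
    if (k) {
      vals <- vapply(lines, function(x) strsplit(x, "[ \t]")[[1L]][[1L]], "",
                     USE.NAMES = FALSE)
      out[todo[seq_len(k)]] <- vals
    }
    if (k >= length(todo)) break
    # input k+1 failed: leave NA, resume with the rest
    todo <- todo[-seq_len(k + 1L)]
  }
  out
}

#' Canonical SMILES via the OpenBabel backend
#'
#' @param smiles character vector of SMILES.
#' @return canonical SMILES, `NA` for unparseable input.
#' @export
obCanonical <- function(smiles) .obConvert(smiles, "CAN")

#' Standard InChIKey via the OpenBabel backend
#' @inheritParams obCanonical
#' @return full 27-character InChIKeys (`NA` on failure).
#' @export
obInchikey <- function(smiles) {
  out <- .obConvert(smiles, "INCHIKEY")
  bad <- !is.na(out) & !grepl("^[A-Z]{14}-", out)
  out[bad] <- NA_character_
  out
}

#' Apply the OpenBabel pH transform model and canonicalize
#' @inheritParams obCanonical
#' @param pH pH at which protonation states are assigned.
#' @return canonical SMILES in the pH-adjusted protonation state.
#' @export
obProtonate <- function(smiles, pH = 7.0) {
  opts <- data.frame(names = "p", args = as.character(pH))
  .obConvert(smiles, "CAN", options = opts)
}

#' Neutralize +1/-1 charge centres and canonicalize
#' @inheritParams obCanonical
#' @export
obNeutralize <- function(smiles) {
  opts <- data.frame(names = "neutralize", args = "")
  .obConvert(smiles, "CAN", options = opts)
}

.parseHexFpt <- function(lines, nbits) {
  idx <- which(startsWith(lines, ">"))
  if (!length(idx)) return(NULL)
  nm <- sub("^>([^ \t]+).*$", "\\1", lines[idx])
  bound <- c(idx, length(lines) + 1L)
  nwords <- nbits %/% 32L
  mat <- matrix(0L, nrow = length(idx), ncol = nbits)
  for (i in seq_along(idx)) {
    body <- lines[seq.int(idx[i] + 1L, bound[i + 1L] - 1L)]
    words <- unlist(strsplit(trimws(body), "\\s+"))
    words <- words[grepl("^[0-9a-fA-F]{8}$", words)]
    if (length(words) != nwords) {
      stop("unexpected fingerprint width: got ", length(words), " words")
    }
    # printed most-significant word first; bit index = 32*word + LSB position
    for (j in seq_along(words)) {
      w <- nwords - j  # 0-based word index
      hi <- strtoi(substr(words[j], 1L, 4L), 16L)
      lo <- strtoi(substr(words[j], 5L, 8L), 16L)
      val <- hi * 65536 + lo
      if (val == 0) next
      bits <- which(as.logical(intToBits(lo))[1:16]) - 1L
      bits <- c(bits, which(as.logical(intToBits(hi))[1:16]) + 15L)
      mat[i, 32L * w + bits + 1L] <- 1L
    }
  }
  rownames(mat) <- nm
  mat
}

#' Structural fingerprints via the OpenBabel CLI (batch)
#'
#' `"ECFP4"` is the radius-2 circular fingerprint (foldable via `nbits`);
#' `"MACCS"` is the 166-key set (returned in a 256-bit frame whose 1-based
#' bit positions equal the key identifiers).
#'
#' @inheritParams obCanonical
#' @param type fingerprint family.
#' @param nbits fold width (circular fingerprints only).
#' @return integer 0/1 matrix, one row per molecule; unparseable rows `NA`.
#' @export
obFingerprint <- function(smiles, type = c("ECFP4", "MACCS"), nbits = NULL) {
  type <- match.arg(type)
  if (is.null(nbits)) nbits <- if (type == "MACCS") 256L else 4096L
  n <- length(smiles)
  out <- matrix(NA_integer_, nrow = n, ncol = nbits)
  ok <- which(!is.na(smiles) & nzchar(smiles))
  if (!length(ok)) return(out)
  tmp <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(paste0(smiles[ok], "\ti", ok), tmp)
  args <- c(tmp, "-ofpt", paste0("-xf", type), "-xh")
  if (type != "MACCS") args <- c(args, paste0("-xN", nbits))
  lines <- suppressWarnings(
    system2(.obabelBin(), args, stdout = TRUE, stderr = FALSE)
  )
  mat <- .parseHexFpt(lines, nbits)
  if (is.null(mat)) return(out)
  got <- as.integer(sub("^i", "", rownames(mat)))
  out[got, ] <- mat
  out
}

#' SMARTS match counts over a batch of molecules
#'
#' Patterns are compiled once and applied to every molecule.
#'
#' @inheritParams obCanonical
#' @param smarts character vector of SMARTS patterns.
#' @param unique count unique (set-distinct) matches.
#' @return integer matrix, molecules x patterns.
#' @export
obSmartsCount <- function(smiles, smarts, unique = TRUE) {
  pats <- lapply(smarts, function(s) {
    sp <- ChemmineOB:::OBSmartsPattern()
    if (!ChemmineOB:::OBSmartsPattern_Init(sp, s)) return(NULL)
    sp
  })
  n <- length(smiles)
  out <- matrix(NA_integer_, nrow = n, ncol = length(smarts),
                dimnames = list(NULL, names(smarts)))
  ok <- which(!is.na(smiles) & nzchar(smiles))
  if (!length(ok)) return(out)
  src <- paste0(paste0(smiles[ok], "\tx"), "\n", collapse = "")
  counts <- ChemmineOB:::forEachMol("SMILES", src, function(mol) {
    vapply(pats, function(sp) {
      if (is.null(sp)) return(NA_integer_)
      ChemmineOB:::OBSmartsPattern_Match(sp, mol)
      if (unique) {
        length(ChemmineOB:::OBSmartsPattern_GetUMapList(sp))
      } else {
        as.integer(ChemmineOB:::OBSmartsPattern_NumMatches(sp))
      }
    }, integer(1L))
  })
  if (length(counts) != length(ok)) {
    stop("SMARTS matching lost molecules; inputs must be pre-validated")
  }
  out[ok, ] <- t(vapply(counts, identity, integer(length(smarts))))
  out
}

#' Atom indices of SMARTS matches on one molecule
#' @param smiles a single SMILES string.
#' @param smarts one SMARTS pattern.
#' @return list of 1-based atom index vectors, one per unique match.
#' @export
obSmartsAtoms <- function(smiles, smarts) {
  sp <- ChemmineOB:::OBSmartsPattern()
  if (!ChemmineOB:::OBSmartsPattern_Init(sp, smarts)) {
    stop("failed to parse SMARTS: ", smarts)
  }
  res <- ChemmineOB:::forEachMol("SMILES", paste0(smiles, "\tx\n"), function(mol) {
    ChemmineOB:::OBSmartsPattern_Match(sp, mol)
    ChemmineOB:::OBSmartsPattern_GetUMapList(sp)
  })
  if (!length(res)) stop("unparseable SMILES in obSmartsAtoms")
  lapply(res[[1L]], as.integer)
}

# SDFset for a batch of (valid) SMILES; optionally with explicit hydrogens.
obSdf <- function(smiles, addH = FALSE) {
  ids <- sprintf("m%06d", seq_along(smiles))
  if (!addH) {
    return(suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, ids))))
  }
  src <- paste0(paste0(smiles, "\t", ids), "\n", collapse = "")
  sdfTxt <- ChemmineOB::convertFormat(
    "SMI", "SDF", source = src,
    options = data.frame(names = "h", args = "")
  )
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(sdfTxt, tmp)
  suppressWarnings(ChemmineR::read.SDFset(tmp))
}

#' Bulk OpenBabel group-contribution properties
#'
#' Molecular weight, logP, TPSA, molar refractivity and H-bond counts in
#' one batch call; unparseable rows stay `NA`.
#'
#' @inheritParams obCanonical
#' @return data.frame with columns MW, logP, TPSA, MR, HBA1, HBA2, HBD.
#' @export
obProperties <- function(smiles) {
  ok <- which(!is.na(smiles) & nzchar(smiles))
  cols <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD")
  out <- as.data.frame(matrix(NA_real_, nrow = length(smiles),
                              ncol = length(cols)))
  names(out) <- cols
  if (!length(ok)) return(out)
  tmp <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(paste0(smiles[ok], "\ti", ok), tmp)
  lines <- suppressWarnings(system2(
    .obabelBin(), c(tmp, "-osmi", "--append", shQuote(paste(cols, collapse = " "))),
    stdout = TRUE, stderr = FALSE))
  parts <- strsplit(lines, "[ \t]+")
  for (p in parts) {
    if (length(p) != length(cols) + 2L) next
    i <- suppressWarnings(as.integer(sub("^i", "", p[[2L]])))
    if (is.na(i)) next
    out[i, ] <- as.numeric(p[-(1:2)])
  }
  out
}
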