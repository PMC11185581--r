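# Endpoint registry, gold-standard merge, leak removal and concordance.

#' Construct an endpoint dataset from prepared records
#'
#' Accepted (`status == "ok"`) records are deduplicated by structure key
#' (conflicts toward the active class for binary tasks, median for
#' regression) before validation.
#'
#' @param name endpoint identifier.
#' @param recs data.frame from [prepareCompounds()].
#' @param assayType assay family, see [EndpointDataset-class].
#' @param task `"binary"` or `"regression"`.
#' @param activeDefinition free-text rule defining the active class.
#' @return an [EndpointDataset-class].
#' @export
endpointDataset <- function(name, recs, assayType = "heterogeneous",
                            task = "binary", activeDefinition = "") {
  ok <- recs[recs$status == "ok" & !is.na(recs$label), , drop = FALSE]
  ok <- dedupResolve(ok, task = task, preferPositive = TRUE)
  rownames(ok) <- NULL
  new("EndpointDataset", name = name, assayType = assayType, task = task,
      records = ok, activeDefinition = activeDefinition)
}

#' Load an endpoint registry from a manifest
#'
#' The manifest (YAML or JSON) lists one entry per endpoint with fields
#' `name`, `file` (CSV with `smiles`, `label`, optional `source`),
#' `assay_type`, `task` and optional `active_definition`; file paths are
#' resolved relative to the manifest. All corpora load through the same
#' preparation pipeline.
#'
#' @param path manifest file path.
#' @param filter,config preparation settings, see [prepareCompounds()].
#' @return named list of [EndpointDataset-class] objects.
#' @export
readEndpointManifest <- function(path, filter = filterSpec(),
                                 config = standardizationConfig()) {
  man <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = FALSE)
  base <- dirname(path)
  out <- list()
  for (entry in man$endpoints) {
    df <- readCompoundCsv(file.path(base, entry$file))
    recs <- prepareCompounds(df$smiles, label = df$label,
                             source = df$source %||% entry$name,
                             filter = filter, config = config)
    out[[entry$name]] <- endpointDataset(
      name = entry$name, recs = recs,
      assayType = entry$assay_type %||% "heterogeneous",
      task = entry$task %||% "binary",
      activeDefinition = entry$active_definition %||% ""
    )
  }
  out
}

#' Merge DILI source lists into the gold-standard dataset
#'
#' Hash-deduplicated union of the two source datasets (both already mapped
#' to binary labels; ambiguous-concern compounds are excluded before this
#' call). Cross-source label conflicts resolve to the toxic annotation and
#' source names are unioned. Positive/negative counts are reported.
#'
#' @param dilist,dilirank binary [EndpointDataset-class] objects.
#' @return a [GoldStandardDILI-class].
#' @export
mergeDiliSources <- function(dilist, dilirank) {
  stopifnot(taskType(dilist) == "binary", taskType(dilirank) == "binary")
  both <- rbind(records(dilist), records(dilirank))
  merged <- dedupResolve(both, task = "binary", preferPositive = TRUE)
  rownames(merged) <- NULL
  message(sprintf("gold standard: %d compounds (%d positive, %d negative)",
                  nrow(merged), sum(merged$label == 1), sum(merged$label == 0)))
  new("GoldStandardDILI", records = merged,
      sourceRule = "conflicts resolved toward toxic annotation")
}

#' Remove gold-standard compounds from the proxy endpoints
#'
#' Deletes from every proxy endpoint (including the PK endpoints) any record
#' whose structure key occurs in the gold standard, preventing information
#' leaks into the stacked model. Removal counts are reported per endpoint.
#'
#' @param proxies list of [EndpointDataset-class].
#' @param gold a [GoldStandardDILI-class].
#' @return the filtered endpoint list.
#' @export
removeOverlap <- function(proxies, gold) {
  goldKeys <- records(gold)$inchikey_hash
  lapply(proxies, function(ep) {
    r <- records(ep)
    drop <- r$inchikey_hash %in% goldKeys
    if (any(drop)) {
      message(sprintf("removed %d/%d overlapping compounds from '%s'",
                      sum(drop), nrow(r), endpointName(ep)))
    }
    ep@records <- r[!drop, , drop = FALSE]
    rownames(ep@records) <- NULL
    if (!nrow(ep@records)) warning("endpoint '", endpointName(ep),
                                   "' is empty after overlap removal")
    ep
  })
}

.cohenKappa <- function(a, b) {
  tab <- table(factor(a, levels = c(0, 1)), factor(b, levels = c(0, 1)))
  e1071::classAgreement(tab)$kappa
}

#' Pairwise label concordance (Cohen's kappa) between endpoints
#'
#' For every unordered pair of binary endpoints (optionally including the
#' gold standard as an additional endpoint), computes Cohen's kappa over
#' the compounds shared by both, keyed by structure hash. Pairs where
#' either label is constant on the overlap are flagged as degenerate with
#' `NA` kappa.
#'
#' @param endpoints list of binary [EndpointDataset-class].
#' @param gold optional [GoldStandardDILI-class] appended as endpoint "DILI".
#' @return data.frame: `endpoint_a`, `endpoint_b`, `n_overlap`, `kappa`,
#'   `degenerate`.
#' @export
concordanceMatrix <- function(endpoints, gold = NULL) {
  labelled <- lapply(endpoints, function(ep) {
    stopifnot(taskType(ep) == "binary")
    r <- records(ep)
    stats::setNames(r$label, r$inchikey_hash)
  })
  names(labelled) <- vapply(endpoints, endpointName, "")
  if (!is.null(gold)) {
    r <- records(gold)
    labelled$DILI <- stats::setNames(r$label, r$inchikey_hash)
  }
  nms <- names(labelled)
  out <- NULL
  for (i in seq_along(nms)) {
    for (j in seq_len(i - 1L)) {
      a <- labelled[[nms[i]]]
      b <- labelled[[nms[j]]]
      keys <- intersect(names(a), names(b))
      if (!length(keys)) next
      la <- a[keys]; lb <- b[keys]
      degenerate <- length(unique(la)) < 2L || length(unique(lb)) < 2L
      kap <- if (degenerate) NA_real_ else .cohenKappa(la, lb)
      out <- rbind(out, data.frame(
        endpoint_a = nms[j], endpoint_b = nms[i],
        n_overlap = length(keys), kappa = kap, degenerate = degenerate,
        stringsAsFactors = FALSE
      ))
    }
  }
  out
}
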