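#' Access the compound records of a dataset object
#' @param x an `EndpointDataset` or `GoldStandardDILI`.
#' @return data.frame of keyed compound records.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "EndpointDataset", function(x) x@records)

#' @rdname records
#' @export
setMethod("records", "GoldStandardDILI", function(x) x@records)

#' Endpoint name accessor
#' @param x an `EndpointDataset`.
#' @export
setGeneric("endpointName", function(x) standardGeneric("endpointName"))

#' @rdname endpointName
#' @export
setMethod("endpointName", "EndpointDataset", function(x) x@name)

#' Task type accessor ("binary" or "regression")
#' @param x an `EndpointDataset`.
#' @export
setGeneric("taskType", function(x) standardGeneric("taskType"))

#' @rdname taskType
#' @export
setMethod("taskType", "EndpointDataset", function(x) x@task)

#' Feature matrix accessor
#' @param x a `FeatureTable`.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "FeatureTable", function(x) x@x)

#' Feature block layout accessor
#' @param x a `FeatureTable`.
#' @return named list of integer column indices.
#' @export
setGeneric("featureBlocks", function(x) standardGeneric("featureBlocks"))

#' @rdname featureBlocks
#' @export
setMethod("featureBlocks", "FeatureTable", function(x) x@blocks)

#' Row keys (inchikey hashes) accessor
#' @param x a `FeatureTable`.
#' @export
setGeneric("rowKeys", function(x) standardGeneric("rowKeys"))

#' @rdname rowKeys
#' @export
setMethod("rowKeys", "FeatureTable", function(x) x@rowKeys)

setMethod("show", "EndpointDataset", function(object) {
  r <- object@records
  cat("EndpointDataset:", object@name, "(", object@assayType, ")\n")
  cat("  task:", object@task, "| compounds:", nrow(r))
  if (object@task == "binary" && nrow(r)) {
    cat(" | actives:", sum(r$label == 1))
  }
  cat("\n")
})

setMethod("show", "GoldStandardDILI", function(object) {
  r <- object@records
  cat("GoldStandardDILI:", nrow(r), "compounds (",
      sum(r$label == 1), "positive /", sum(r$label == 0), "negative )\n")
})

setMethod("show", "FeatureTable", function(object) {
  widths <- vapply(object@blocks, length, integer(1L))
  cat("FeatureTable:", nrow(object@x), "compounds x", ncol(object@x),
      "features\n  blocks:",
      paste(sprintf("%s(%d)", names(widths), widths), collapse = " "), "\n")
})

setMethod("show", "FeatureSelector", function(object) {
  widths <- vapply(object@masks, length, integer(1L))
  cat("FeatureSelector fitted on:", object@fitCorpusId, "\n  retained:",
      paste(sprintf("%s=%d", names(widths), widths), collapse = " "), "\n")
})

setMethod("show", "ProxyModelBundle", function(object) {
  cat("ProxyModelBundle:", length(object@classifiers), "classifiers +",
      length(object@regressors), "regressors\n  order:",
      paste(object@registryOrder, collapse = ", "), "\n")
})

setMethod("show", "DiliModel", function(object) {
  cat("DiliModel [", object@config@id, "] threshold =",
      round(object@threshold$value, 4),
      "(Youden J =", round(object@threshold$j, 4), ",",
      object@threshold$derivation, ")\n")
})
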