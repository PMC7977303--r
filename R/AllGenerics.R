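#' @include AllClasses.R
NULL

#' Accessors for BhotExperiment
#'
#' \code{exprs} returns the log2 assay (genes x samples);
#' \code{linearIntensity} the derived linear-scale view (\code{2^log2});
#' \code{diagnosis}, \code{batch} and \code{housekeeping} the per-sample
#' diagnosis factor, batch code and per-gene housekeeping flag.
#'
#' @param object,x a \linkS4class{BhotExperiment}.
#' @param value replacement value.
#' @return matrix, factor or logical vector as described.
#' @name bhot-accessors
#' @aliases exprs linearIntensity diagnosis batch batch<- housekeeping
NULL

#' @rdname bhot-accessors
#' @export
setGeneric("exprs", function(object) standardGeneric("exprs"))
#' @rdname bhot-accessors
#' @export
setMethod("exprs", "BhotExperiment", function(object) assay(object, "log2"))

#' @rdname bhot-accessors
#' @export
setGeneric("linearIntensity",
           function(object) standardGeneric("linearIntensity"))
#' @rdname bhot-accessors
#' @export
setMethod("linearIntensity", "BhotExperiment",
          function(object) 2^assay(object, "log2"))

#' @rdname bhot-accessors
#' @export
setGeneric("diagnosis", function(object) standardGeneric("diagnosis"))
#' @rdname bhot-accessors
#' @export
setMethod("diagnosis", "BhotExperiment", function(object) {
  if (!"diagnosis" %in% names(colData(object))) return(NULL)
  factor(as.character(colData(object)$diagnosis), levels = diagnosisLevels())
})

#' @rdname bhot-accessors
#' @export
setGeneric("batch", function(object) standardGeneric("batch"))
#' @rdname bhot-accessors
#' @export
setMethod("batch", "BhotExperiment", function(object) {
  if (!"batch" %in% names(colData(object))) return(NULL)
  colData(object)$batch
})

#' @rdname bhot-accessors
#' @export
setGeneric("batch<-", function(object, value) standardGeneric("batch<-"))
#' @rdname bhot-accessors
#' @export
setMethod("batch<-", "BhotExperiment", function(object, value) {
  colData(object)$batch <- value
  validObject(object)
  object
})

#' @rdname bhot-accessors
#' @export
setGeneric("housekeeping", function(object) standardGeneric("housekeeping"))
#' @rdname bhot-accessors
#' @export
setMethod("housekeeping", "BhotExperiment", function(object) {
  hk <- rowData(object)$housekeeping
  stats::setNames(as.logical(hk), rownames(object))
})

setMethod("show", "BhotExperiment", function(object) {
  cat(sprintf("BhotExperiment: %d genes x %d samples\n",
              nrow(object), ncol(object)))
  dx <- diagnosis(object)
  if (!is.null(dx)) {
    tb <- table(dx)
    cat("diagnoses:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  if (!is.null(batch(object)))
    cat("batches:", paste(names(table(batch(object))), collapse = ", "), "\n")
  cat(sprintf("housekeeping genes: %d\n", sum(housekeeping(object))))
  invisible(NULL)
})

#' Accessors for GeneSetCatalog
#'
#' @param object a \linkS4class{GeneSetCatalog}.
#' @param name set name.
#' @return \code{geneSets}: named list of symbol vectors;
#'   \code{setSources}: named character vector of source tags.
#' @name catalog-accessors
NULL

#' @rdname catalog-accessors
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))
#' @rdname catalog-accessors
#' @export
setMethod("geneSets", "GeneSetCatalog", function(object) object@sets)

#' @rdname catalog-accessors
#' @export
setGeneric("setSources", function(object) standardGeneric("setSources"))
#' @rdname catalog-accessors
#' @export
setMethod("setSources", "GeneSetCatalog",
          function(object) stats::setNames(object@source, names(object@sets)))

setMethod("show", "GeneSetCatalog", function(object) {
  cat(sprintf("GeneSetCatalog: %d sets\n", length(object@sets)))
  n <- head(names(object@sets), 6)
  for (s in n)
    cat(sprintf("  %s [%s]: %d genes\n", s,
                setSources(object)[[s]], length(object@sets[[s]])))
  if (length(object@sets) > 6) cat("  ...\n")
  invisible(NULL)
})

#' Accessors for PCSet
#'
#' @param object a \linkS4class{PCSet}.
#' @return \code{pcScores}: samples x components matrix;
#'   \code{pcLoadings}: genes x components matrix; \code{eigenvalues}:
#'   numeric; \code{pcKind}: character; \code{pcProvenance}: data.frame.
#' @name pcset-accessors
NULL

#' @rdname pcset-accessors
#' @export
setGeneric("pcScores", function(object) standardGeneric("pcScores"))
#' @rdname pcset-accessors
#' @export
setMethod("pcScores", "PCSet", function(object) object@scores)

#' @rdname pcset-accessors
#' @export
setGeneric("pcLoadings", function(object) standardGeneric("pcLoadings"))
#' @rdname pcset-accessors
#' @export
setMethod("pcLoadings", "PCSet", function(object) object@loadings)

#' @rdname pcset-accessors
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))
#' @rdname pcset-accessors
#' @export
setMethod("eigenvalues", "PCSet", function(object) object@eigenvalues)

#' @rdname pcset-accessors
#' @export
setGeneric("pcKind", function(object) standardGeneric("pcKind"))
#' @rdname pcset-accessors
#' @export
setMethod("pcKind", "PCSet", function(object) object@kind)

#' @rdname pcset-accessors
#' @export
setGeneric("pcProvenance", function(object) standardGeneric("pcProvenance"))
#' @rdname pcset-accessors
#' @export
setMethod("pcProvenance", "PCSet", function(object) object@provenance)

setMethod("show", "PCSet", function(object) {
  cat(sprintf("PCSet [%s]: %d components over %d samples\n", object@kind,
              ncol(object@scores), nrow(object@scores)))
  if (ncol(object@scores))
    cat("eigenvalues:",
        paste(sprintf("%.2f", head(object@eigenvalues, 8)), collapse = ", "),
        if (length(object@eigenvalues) > 8) "..." else "", "\n")
  invisible(NULL)
})

#' Accessors for FeatureBundle
#'
#' @param object a \linkS4class{FeatureBundle}.
#' @return \code{bundleName}: character; \code{featureMatrix}:
#'   samples x features matrix.
#' @name bundle-accessors
NULL

#' @rdname bundle-accessors
#' @export
setGeneric("bundleName", function(object) standardGeneric("bundleName"))
#' @rdname bundle-accessors
#' @export
setMethod("bundleName", "FeatureBundle", function(object) object@name)

#' @rdname bundle-accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname bundle-accessors
#' @export
setMethod("featureMatrix", "FeatureBundle", function(object) object@features)

setMethod("show", "FeatureBundle", function(object) {
  cat(sprintf("FeatureBundle [%s]: %d samples x %d features\n",
              object@name, nrow(object@features), ncol(object@features)))
  invisible(NULL)
})

#' Accessors for PredictionTable
#'
#' @param object a \linkS4class{PredictionTable}.
#' @return \code{assignedClass}/\code{trueClass}: factors;
#'   \code{classProbabilities}: samples x levels matrix.
#' @name prediction-accessors
NULL

#' @rdname prediction-accessors
#' @export
setGeneric("assignedClass", function(object) standardGeneric("assignedClass"))
#' @rdname prediction-accessors
#' @export
setMethod("assignedClass", "PredictionTable", function(object) object@assigned)

#' @rdname prediction-accessors
#' @export
setGeneric("trueClass", function(object) standardGeneric("trueClass"))
#' @rdname prediction-accessors
#' @export
setMethod("trueClass", "PredictionTable", function(object) object@truth)

#' @rdname prediction-accessors
#' @export
setGeneric("classProbabilities",
           function(object) standardGeneric("classProbabilities"))
#' @rdname prediction-accessors
#' @export
setMethod("classProbabilities", "PredictionTable",
          function(object) object@prob)

setMethod("show", "PredictionTable", function(object) {
  acc <- mean(as.character(object@truth) == as.character(object@assigned))
  cat(sprintf("PredictionTable: %d samples, %d levels [model=%s, bundle=%s]\n",
              length(object@truth), ncol(object@prob),
              object@meta$model %||% "?", object@meta$bundle %||% "?"))
  cat(sprintf("out-of-fold accuracy: %.3f\n", acc))
  invisible(NULL)
})

setMethod("show", "TANModel", function(object) {
  nk <- sum(!is.na(object@parent))
  cat(sprintf(
    "TANModel: %d binary features, %d class levels, %d feature edge%s\n",
    length(object@features), length(object@classLevels), nk,
    if (nk == 1) "" else "s"))
  cat(sprintf("MDL score: %.1f (alpha = %.2f)\n", object@mdl, object@alpha))
  invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
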