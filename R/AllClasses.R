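#' BhotExperiment: expression container for panel analyses
#'
#' Extends \link[SummarizedExperiment]{SummarizedExperiment} with the
#' conventions this package relies on: a single \code{"log2"} assay of
#' log2 intensities with genes in rows and samples in columns, unique
#' gene symbols as rownames, a \code{diagnosis} column in \code{colData}
#' restricted to the six summary classes (plus optional \code{series}
#' and \code{batch} columns), and logical \code{housekeeping} /
#' character \code{module} columns in \code{rowData}.
#'
#' The linear-intensity view used for coefficient-of-variation work is
#' derived on demand as \code{2^log2} via \code{\link{linearIntensity}}.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @export
setClass("BhotExperiment", contains = "SummarizedExperiment")

.validBhotExperiment <- function(object) {
  msg <- character()
  if (!"log2" %in% names(assays(object)))
    msg <- c(msg, "assay 'log2' is required")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene symbols (rownames) must be present and unique")
  if ("log2" %in% names(assays(object)) && anyNA(assay(object, "log2")))
    msg <- c(msg, "log2 assay must not contain missing values")
  if ("diagnosis" %in% names(colData(object))) {
    dx <- as.character(colData(object)$diagnosis)
    bad <- setdiff(unique(dx[!is.na(dx)]), diagnosisLevels())
    if (length(bad))
      msg <- c(msg, paste0("diagnosis labels outside the six-class set: ",
                           paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}
setValidity("BhotExperiment", .validBhotExperiment)

#' Construct a BhotExperiment
#'
#' @param log2 numeric matrix of log2 intensities, genes in rows, samples
#'   in columns, with unique rownames (gene symbols) and colnames
#'   (sample ids).
#' @param colData data.frame/DataFrame of per-sample annotations; a
#'   \code{diagnosis} column, when present, must use the six summary
#'   labels (see \code{\link{diagnosisLevels}}).
#' @param rowData data.frame/DataFrame of per-gene annotations;
#'   a logical \code{housekeeping} column is added (all \code{FALSE})
#'   when absent.
#' @param metadata list of free-form metadata.
#' @return A \linkS4class{BhotExperiment}.
#' @export
#' @examples
#' m <- matrix(rnorm(20, 7), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' be <- BhotExperiment(m, colData = data.frame(
#'   diagnosis = c("ABMR", "TCMR", "NORMAL", "AKI", "NOREJECTION")))
#' be
BhotExperiment <- function(log2, colData = NULL, rowData = NULL,
                           metadata = list()) {
  log2 <- as.matrix(log2)
  if (is.null(rownames(log2)))
    stop("log2 matrix must carry gene symbols as rownames")
  if (is.null(colnames(log2)))
    colnames(log2) <- paste0("sample", seq_len(ncol(log2)))
  if (is.null(colData))
    colData <- DataFrame(row.names = colnames(log2))
  colData <- DataFrame(colData, row.names = colnames(log2))
  if ("diagnosis" %in% names(colData))
    colData$diagnosis <- factor(as.character(colData$diagnosis),
                                levels = diagnosisLevels())
  if (is.null(rowData))
    rowData <- DataFrame(row.names = rownames(log2))
  rowData <- DataFrame(rowData, row.names = rownames(log2))
  if (!"housekeeping" %in% names(rowData))
    rowData$housekeeping <- FALSE
  se <- SummarizedExperiment(assays = list(log2 = log2),
                             colData = colData, rowData = rowData,
                             metadata = metadata)
  new("BhotExperiment", se)
}

#' GeneSetCatalog: named gene sets with source tags
#'
#' Holds named, non-empty gene sets (symbol vectors) each tagged with a
#' source (CIBERSORT, KEGG, BloodAtlas, BHOT, panel, housekeeping or
#' custom), as used for gene-set principal components and loading
#' annotation.
#'
#' @slot sets named list of character vectors of gene symbols.
#' @slot source character vector parallel to \code{sets}.
#' @export
setClass("GeneSetCatalog",
         representation(sets = "list", source = "character"))

.validGeneSetCatalog <- function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "set names must be present and unique")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "sets must be nonempty")
  if (length(object@source) != length(object@sets))
    msg <- c(msg, "one source tag per set is required")
  ok <- c("CIBERSORT", "KEGG", "BloodAtlas", "BHOT", "panel",
          "housekeeping", "custom")
  if (length(setdiff(unique(object@source), ok)))
    msg <- c(msg, paste0("source tags must be among: ",
                         paste(ok, collapse = ", ")))
  if (length(msg)) msg else TRUE
}
setValidity("GeneSetCatalog", .validGeneSetCatalog)

#' Construct a GeneSetCatalog
#'
#' @param sets named list of character vectors (gene symbols).
#' @param source character scalar or vector of source tags (recycled).
#' @return A \linkS4class{GeneSetCatalog}.
#' @export
#' @examples
#' GeneSetCatalog(list(TUB = c("UMOD", "AQP2"), ENDO = c("PECAM1", "VWF")),
#'                source = "custom")
GeneSetCatalog <- function(sets, source = "custom") {
  source <- rep_len(source, length(sets))
  new("GeneSetCatalog", sets = lapply(sets, as.character), source = source)
}

#' PCSet: principal-component feature set
#'
#' Scores, loadings, eigenvalues and provenance for one gene-parsing
#' strategy. \code{kind} is one of \code{"PBPC"} (supervised contrasts
#' against the reference class), \code{"CPPC"} (one component per gene
#' set) or \code{"UPC"} (unsupervised, all genes). For pooled kinds the
#' \code{decomposition} field of the provenance groups components that
#' came from one decomposition; eigenvalues are nonincreasing within
#' each group and every retained eigenvalue meets the kind's threshold.
#'
#' @slot kind character, one of PBPC/CPPC/UPC.
#' @slot scores samples x components matrix of standardized scores.
#' @slot loadings genes x components matrix; unit column norms (genes
#'   absent from a component's decomposition carry zero loading).
#' @slot eigenvalues numeric per component.
#' @slot provenance data.frame per component: component, decomposition,
#'   n_genes, threshold.
#' @slot geneLists list per component of the gene symbols decomposed.
#' @export
setClass("PCSet",
         representation(kind = "character", scores = "matrix",
                        loadings = "matrix", eigenvalues = "numeric",
                        provenance = "data.frame", geneLists = "list"))

.validPCSet <- function(object) {
  msg <- character()
  if (!object@kind %in% c("PBPC", "CPPC", "UPC"))
    msg <- c(msg, "kind must be PBPC, CPPC or UPC")
  k <- ncol(object@scores)
  if (ncol(object@loadings) != k || length(object@eigenvalues) != k ||
      nrow(object@provenance) != k || length(object@geneLists) != k)
    msg <- c(msg, "components inconsistent across slots")
  if (k > 0) {
    nrm <- sqrt(colSums(object@loadings^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "loading columns must have unit norm")
    ev <- split(object@eigenvalues, object@provenance$decomposition)
    if (any(vapply(ev, function(e) any(diff(e) > 1e-8), logical(1))))
      msg <- c(msg, "eigenvalues must be nonincreasing within a decomposition")
    if (any(object@eigenvalues + 1e-8 < object@provenance$threshold))
      msg <- c(msg, "retained eigenvalues must meet the retention threshold")
  }
  if (length(msg)) msg else TRUE
}
setValidity("PCSet", .validPCSet)

#' FeatureBundle: classifier feature matrix assembled from PC sets
#'
#' @slot name one of ALL, CPPC, PBPC, UPC (or custom).
#' @slot features samples x features numeric matrix, no missing values.
#' @slot provenance data.frame: feature, kind, decomposition.
#' @export
setClass("FeatureBundle",
         representation(name = "character", features = "matrix",
                        provenance = "data.frame"))

.validFeatureBundle <- function(object) {
  msg <- character()
  if (anyNA(object@features))
    msg <- c(msg, "feature matrix must not contain missing values")
  if (nrow(object@provenance) != ncol(object@features))
    msg <- c(msg, "provenance must describe every feature column")
  if (length(msg)) msg else TRUE
}
setValidity("FeatureBundle", .validFeatureBundle)

#' PredictionTable: per-sample class probabilities and assignments
#'
#' @slot truth factor of true target labels.
#' @slot prob samples x levels probability matrix (rows sum to 1).
#' @slot assigned factor of argmax labels (ties broken by level order).
#' @slot meta list: model, bundle, target, folds, seed.
#' @export
setClass("PredictionTable",
         representation(truth = "factor", prob = "matrix",
                        assigned = "factor", meta = "list"))

.validPredictionTable <- function(object) {
  msg <- character()
  n <- length(object@truth)
  if (nrow(object@prob) != n || length(object@assigned) != n)
    msg <- c(msg, "truth, prob and assigned must align")
  if (n > 0) {
    if (any(object@prob < -1e-9))
      msg <- c(msg, "probabilities must be nonnegative")
    if (any(abs(rowSums(object@prob) - 1) > 1e-6))
      msg <- c(msg, "probabilities must sum to 1 per sample (tol 1e-6)")
    if (!identical(levels(object@assigned), colnames(object@prob)))
      msg <- c(msg, "assigned levels must match probability columns")
  }
  if (length(msg)) msg else TRUE
}
setValidity("PredictionTable", .validPredictionTable)

#' TANModel: tree-augmented naive Bayes over binary features
#'
#' Feature nodes are binary (\code{"low"}/\code{"high"}); every feature
#' has the class node as a parent and at most one feature parent. The
#' feature-parent graph is a forest (a tree when no edge was pruned by
#' the MDL criterion). Conditional probability tables use add-alpha
#' smoothing and are row-normalized.
#'
#' @slot classLevels character vector of target levels.
#' @slot features character vector of feature names.
#' @slot parent named character vector: feature -> feature parent
#'   (\code{NA} for roots).
#' @slot classPrior named numeric, smoothed class prior.
#' @slot cpts list per feature: array of P(feature state | class
#'   [, parent state]).
#' @slot edgeTable data.frame of candidate edges with conditional mutual
#'   information, likelihood gain, MDL penalty and kept flag.
#' @slot alpha smoothing pseudocount.
#' @slot mdl numeric MDL score of the final model.
#' @export
setClass("TANModel",
         representation(classLevels = "character", features = "character",
                        parent = "character", classPrior = "numeric",
                        cpts = "list", edgeTable = "data.frame",
                        alpha = "numeric", mdl = "numeric"))

.validTANModel <- function(object) {
  msg <- character()
  p <- object@parent
  if (!identical(sort(names(p)), sort(object@features)))
    msg <- c(msg, "every feature needs a parent entry (NA for roots)")
  kept <- p[!is.na(p)]
  if (length(kept) > max(0L, length(object@features) - 1L))
    msg <- c(msg, "feature-parent graph must be a forest")
  # cycle check by following parents
  for (f in object@features) {
    seen <- character(); cur <- f
    while (!is.na(p[[cur]])) {
      if (cur %in% seen) { msg <- c(msg, "parent graph contains a cycle"); break }
      seen <- c(seen, cur); cur <- p[[cur]]
    }
  }
  for (f in object@features) {
    cpt <- object@cpts[[f]]
    sums <- apply(cpt, seq_along(dim(cpt))[-1], sum)
    if (any(abs(sums - 1) > 1e-9))
      msg <- c(msg, sprintf("CPT of %s is not row-normalized", f))
  }
  if (abs(sum(object@classPrior) - 1) > 1e-9)
    msg <- c(msg, "class prior must sum to 1")
  if (length(msg)) msg else TRUE
}
setValidity("TANModel", .validTANModel)
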