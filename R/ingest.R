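#' Ingest an expression matrix against the BHOT panel
#'
#' Reads an expression source (plain TSV written by
#' \code{\link{writeExperimentTSV}}, a GEO series-matrix file, or an
#' in-memory genes x samples matrix), restricts genes to the panel
#' minus a configured exclusion list (e.g. non-renal parenchymal and
#' viral genes), collapses multiple probes per symbol by maximum mean
#' intensity, maps source diagnosis labels to the six summary classes
#' through an explicit mapping, and returns a
#' \linkS4class{BhotExperiment} of log2 intensities.
#'
#' @param expr_source matrix (genes x samples), or path to a TSV /
#'   series-matrix file (series-matrix files are recognized by content).
#' @param annotations data.frame with rownames (or column
#'   \code{sample}) matching sample ids and a \code{diagnosis} column of
#'   source labels; or path to such a TSV. \code{NULL} allowed when the
#'   source carries no annotations yet.
#' @param panel character vector of panel gene symbols, or a
#'   \linkS4class{GeneSetCatalog} (sets tagged \code{BHOT}/\code{panel}
#'   are used; all sets when none is tagged).
#' @param exclude symbols to drop from the panel before intersection.
#' @param mapping named character vector (source label -> summary
#'   class), e.g. from \code{\link{readDiagnosisMapping}}. Labels
#'   already in the six-class set pass through when \code{mapping} is
#'   \code{NULL}.
#' @param housekeeping symbols flagged as housekeeping in the result.
#' @param probe_map optional named character vector probe id -> symbol,
#'   applied before collapsing (series-matrix sources are probe-level).
#' @param log2_transform logical; set \code{FALSE} when the source is
#'   already log2 (synthetic TSVs are). Series-matrix intensities are
#'   log2-transformed by default.
#' @return A \linkS4class{BhotExperiment}.
#' @export
ingestExpression <- function(expr_source, annotations = NULL, panel,
                             exclude = character(), mapping = NULL,
                             housekeeping = character(),
                             probe_map = NULL, log2_transform = FALSE) {
  sample_info <- NULL
  if (is.character(expr_source) && length(expr_source) == 1L) {
    head_lines <- readLines(expr_source, n = 200L, warn = FALSE)
    if (any(grepl("^!series_matrix_table_begin", head_lines)) ||
        any(grepl("^!Series_", head_lines))) {
      sm <- readSeriesMatrix(expr_source)
      m <- sm$expr
      sample_info <- sm$sampleInfo
    } else {
      m <- readExpressionTSV(expr_source)
    }
  } else {
    m <- as.matrix(expr_source)
  }
  if (anyNA(m)) stop("expression source contains missing values")
  if (!is.null(probe_map)) {
    keep <- rownames(m) %in% names(probe_map)
    m <- m[keep, , drop = FALSE]
    rownames(m) <- unname(probe_map[rownames(m)])
  }

  if (is(panel, "GeneSetCatalog")) {
    tagged <- setSources(panel) %in% c("BHOT", "panel")
    sets <- geneSets(panel)
    panel <- unique(unlist(if (any(tagged)) sets[tagged] else sets))
  }
  panel <- setdiff(panel, exclude)
  keep <- rownames(m) %in% panel
  if (!any(keep))
    stop("panel error: no genes in common between the source and the panel")
  m <- m[keep, , drop = FALSE]

  # collapse multiple probes per symbol by maximum mean intensity
  if (anyDuplicated(rownames(m))) {
    means <- rowMeans(m)
    ord <- order(rownames(m), -means)
    m <- m[ord, , drop = FALSE][!duplicated(rownames(m)[ord]), , drop = FALSE]
  }
  if (log2_transform) m <- log2(pmax(m, 1e-12))

  cd <- NULL
  if (!is.null(annotations)) {
    if (is.character(annotations) && length(annotations) == 1L)
      annotations <- utils::read.delim(annotations,
                                       stringsAsFactors = FALSE)
    annotations <- as.data.frame(annotations)
    if ("sample" %in% names(annotations))
      rownames(annotations) <- annotations$sample
    missing_s <- setdiff(colnames(m), rownames(annotations))
    if (length(missing_s))
      stop("annotations missing for samples: ",
           paste(head(missing_s, 5), collapse = ", "))
    annotations <- annotations[colnames(m), , drop = FALSE]
    if ("diagnosis" %in% names(annotations)) {
      lab <- as.character(annotations$diagnosis)
      if (!is.null(mapping)) {
        unmapped <- setdiff(unique(lab), names(mapping))
        if (length(unmapped))
          stop("mapping error: unmapped annotation labels: ",
               paste(unmapped, collapse = ", "))
        lab <- unname(mapping[lab])
      }
      bad <- setdiff(unique(lab), diagnosisLevels())
      if (length(bad))
        stop("mapping error: labels outside the six-class set: ",
             paste(bad, collapse = ", "))
      annotations$diagnosis <- lab
    }
    cd <- annotations
  } else if (!is.null(sample_info)) {
    cd <- sample_info
  }
  rd <- data.frame(symbol = rownames(m),
                   housekeeping = rownames(m) %in% housekeeping,
                   bhot = TRUE, row.names = rownames(m))
  BhotExperiment(m, colData = cd, rowData = rd)
}

#' Renormalize samples by their housekeeping genes
#'
#' Shifts each sample (in log2, i.e. multiplicatively on the linear
#' scale) so its housekeeping geometric mean equals the cohort-wide
#' housekeeping geometric mean; the shift applies to all genes of the
#' sample. A sample already at the cohort mean is unchanged.
#'
#' @param ds a \linkS4class{BhotExperiment}.
#' @param hk housekeeping gene symbols; defaults to the genes flagged in
#'   \code{rowData(ds)$housekeeping}. At least 3 are required.
#' @return The renormalized \linkS4class{BhotExperiment}; per-sample
#'   shifts are stored in \code{colData(ds)$hk_shift}.
#' @export
renormalizeHousekeeping <- function(ds, hk = NULL) {
  stopifnot(is(ds, "BhotExperiment"))
  if (is.null(hk)) hk <- names(which(housekeeping(ds)))
  absent <- setdiff(hk, rownames(ds))
  if (length(absent))
    stop("housekeeping gene(s) absent from the dataset: ",
         paste(absent, collapse = ", "))
  if (length(hk) < 3L)
    stop("at least 3 housekeeping genes are required")
  x <- exprs(ds)
  gm <- colMeans(x[hk, , drop = FALSE])  # per-sample log2 geometric mean
  shift <- mean(gm) - gm
  assay(ds, "log2") <- sweep(x, 2L, shift, "+")
  colData(ds)$hk_shift <- shift
  ds
}

#' Per-gene coefficient of variation on the linear scale
#'
#' CV(g) = sd(2^log2) / mean(2^log2) with the sample (n-1) standard
#' deviation, reported in percent. Scale-invariant: multiplying a gene's
#' linear intensities by a constant leaves its CV unchanged.
#'
#' @param ds a \linkS4class{BhotExperiment}, or a genes x samples matrix
#'   of linear-scale intensities.
#' @return data.frame with columns \code{gene}, \code{mean}, \code{sd}
#'   and \code{cv} (percent).
#' @export
computeCV <- function(ds) {
  lin <- if (is(ds, "BhotExperiment")) linearIntensity(ds) else as.matrix(ds)
  mu <- rowMeans(lin)
  if (any(mu <= 0))
    stop("nonpositive gene mean; CV is undefined for: ",
         paste(head(rownames(lin)[mu <= 0], 5), collapse = ", "))
  s <- matrixStats::rowSds(lin)
  data.frame(gene = rownames(lin), mean = mu, sd = s, cv = 100 * s / mu,
             row.names = rownames(lin))
}

#' Drop the lowest-CV genes and the housekeeping block
#'
#' Removes the genes in the lowest \code{quantile} fraction of CV, and
#' all housekeeping genes regardless of their CV (they carry no
#' partitioning value).
#'
#' @param ds a \linkS4class{BhotExperiment}.
#' @param cv CV table from \code{\link{computeCV}} (computed on the
#'   spot when \code{NULL}).
#' @param quantile fraction of genes to remove from the low-CV end; the
#'   \code{floor(quantile * n_genes)} smallest-CV genes are dropped
#'   (so \code{quantile = 0} is the identity).
#' @return The filtered \linkS4class{BhotExperiment}.
#' @export
dropLowCV <- function(ds, cv = NULL, quantile = 0.05) {
  stopifnot(is(ds, "BhotExperiment"), quantile >= 0, quantile < 1)
  if (is.null(cv)) cv <- computeCV(ds)
  cv <- cv[rownames(ds), ]
  k <- floor(quantile * nrow(ds))
  low <- rownames(ds)[order(cv$cv)][seq_len(k)]
  drop <- union(low, names(which(housekeeping(ds))))
  keep <- setdiff(rownames(ds), drop)
  if (!length(keep))
    stop("low-CV filtering would remove every gene")
  ds[keep, ]
}
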