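#' Detect batch structure from low-CV genes
#'
#' Embeds samples in 2-D with UMAP using only low-CV reference genes
#' (which include the housekeeping genes by construction: genes with a
#' linear-scale CV at or below the threshold carry essentially no
#' diagnostic partitioning value, so residual structure among them is
#' batch, not biology), then clusters the embedding with K-means,
#' selecting the cluster count by average silhouette width over
#' k in 2..\code{k_max}. A single batch (k = 1) is declared when no k
#' reaches \code{sil_threshold}; among near-ties (silhouette within
#' 0.05 of the best) the smallest k wins.
#'
#' @param ds a \linkS4class{BhotExperiment}.
#' @param cv CV table from \code{\link{computeCV}} (computed on the
#'   spot when \code{NULL}).
#' @param cv_threshold reference-gene cut; percent CV in
#'   \code{"absolute"} mode (genes with CV <= threshold), a gene
#'   fraction in \code{"quantile"} mode (lowest \code{cv_threshold/100}
#'   of genes).
#' @param mode \code{"absolute"} (default) or \code{"quantile"}.
#' @param labels optional manual batch labels overriding the clustering
#'   (no embedding is computed then; offsets still are).
#' @param reference_genes optional explicit reference gene list,
#'   bypassing the CV filter (e.g. a known housekeeping set).
#' @param k_max largest cluster count scanned.
#' @param sil_threshold minimum average silhouette accepting k >= 2.
#' @param n_neighbors,min_dist UMAP parameters.
#' @param seed integer seed (UMAP and K-means).
#' @return A \code{BatchModel} list: \code{embedding} (samples x 2),
#'   \code{labels}, \code{k}, \code{offsets} (per-batch log2 offsets of
#'   the reference genes, relative to the first batch),
#'   \code{correction} (per-batch offsets centered to the grand mean,
#'   subtracted by \code{\link{batchNormalize}}), \code{reference_genes},
#'   \code{silhouette} table.
#' @export
detectBatches <- function(ds, cv = NULL, cv_threshold = 5,
                          mode = c("absolute", "quantile"), labels = NULL,
                          reference_genes = NULL, k_max = 6,
                          sil_threshold = 0.55, n_neighbors = 15,
                          min_dist = 0.1, seed = 1L) {
  stopifnot(is(ds, "BhotExperiment"))
  mode <- match.arg(mode)
  if (is.null(reference_genes)) {
    if (is.null(cv)) cv <- computeCV(ds)
    cv <- cv[rownames(ds), ]
    ref <- if (mode == "absolute") {
      rownames(ds)[cv$cv <= cv_threshold]
    } else {
      k <- max(2L, floor(cv_threshold / 100 * nrow(ds)))
      rownames(ds)[order(cv$cv)][seq_len(k)]
    }
  } else {
    ref <- intersect(reference_genes, rownames(ds))
  }
  if (length(ref) < 2L)
    stop("fewer than 2 genes pass the CV filter (", cv_threshold,
         if (mode == "absolute") "%" else " quantile",
         "); consider a higher threshold")
  emb <- NULL
  sil <- data.frame(k = integer(), silhouette = numeric())
  if (is.null(labels)) {
    x <- t(exprs(ds)[ref, , drop = FALSE])  # samples x reference genes
    nn <- min(n_neighbors, nrow(x) - 1L)
    emb <- .withSeed(seed,
      uwot::umap(x, n_neighbors = nn, min_dist = min_dist,
                 n_threads = 1, n_sgd_threads = 0))
    rownames(emb) <- colnames(ds)
    d <- stats::dist(emb)
    fits <- list()
    for (k in 2:min(k_max, nrow(emb) - 1L)) {
      km <- .withSeed(seed + k, stats::kmeans(emb, centers = k,
                                              nstart = 10, iter.max = 50))
      sw <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
      sil <- rbind(sil, data.frame(k = k, silhouette = sw))
      fits[[as.character(k)]] <- km
    }
    if (max(sil$silhouette) < sil_threshold) {
      kk <- 1L
      labels <- rep(1L, nrow(emb))
    } else {
      ok <- sil$k[sil$silhouette >= max(sil$silhouette) - 0.05]
      kk <- min(ok)
      labels <- fits[[as.character(kk)]]$cluster
    }
  } else {
    if (length(labels) != ncol(ds))
      stop("override labels must cover every sample")
    kk <- length(unique(labels))
  }
  labels <- stats::setNames(as.integer(factor(labels)), colnames(ds))

  structure(list(embedding = emb, labels = labels, k = kk,
                 reference_genes = ref, silhouette = sil,
                 offsets = .batchOffsets(ds, labels, ref)$relative,
                 correction = .batchOffsets(ds, labels, ref)$centered,
                 seed = seed),
            class = "BatchModel")
}

# per-batch scalar log2 offsets estimated from reference genes only
.batchOffsets <- function(ds, labels, ref) {
  x <- exprs(ds)[ref, , drop = FALSE]
  dev <- colMeans(x - rowMeans(x))   # per-sample mean deviation
  off <- tapply(dev, labels, mean)
  off <- stats::setNames(as.numeric(off), names(off))
  small <- table(labels) < 2L
  if (any(small))
    warning("batch(es) with < 2 samples: ",
            paste(names(small)[small], collapse = ", "),
            "; offset still estimated")
  list(relative = off - off[[1L]], centered = off)
}

#' @export
print.BatchModel <- function(x, ...) {
  cat(sprintf("BatchModel: %d batch(es) over %d samples, %d reference genes\n",
              x$k, length(x$labels), length(x$reference_genes)))
  if (x$k > 1L)
    cat("relative offsets (log2):",
        paste(sprintf("%s=%.3f", names(x$offsets), x$offsets),
              collapse = ", "), "\n")
  invisible(x)
}

#' Remove scalar batch offsets
#'
#' Subtracts from every gene of a batch's samples the batch's scalar
#' log2 offset, estimated as the mean deviation of the reference low-CV
#' genes from their grand means. With a single batch the data are
#' unchanged; the operation is idempotent (a second pass estimates
#' offsets ~0).
#'
#' @param ds a \linkS4class{BhotExperiment}.
#' @param bm a \code{BatchModel} from \code{\link{detectBatches}}.
#' @return The corrected \linkS4class{BhotExperiment}; batch labels are
#'   recorded in \code{colData(ds)$batch_detected}.
#' @export
batchNormalize <- function(ds, bm) {
  stopifnot(is(ds, "BhotExperiment"), inherits(bm, "BatchModel"))
  corr <- bm$correction[as.character(bm$labels[colnames(ds)])]
  assay(ds, "log2") <- sweep(exprs(ds), 2L, unname(corr), "-")
  colData(ds)$batch_detected <- unname(bm$labels[colnames(ds)])
  ds
}
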