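#' Robust per-gene standardization
#'
#' Centers each gene at its median and scales by 1.4826 x MAD (falling
#' back to the classical SD when the MAD is zero), then winsorizes at
#' +/-4 robust z units to suppress outliers before any principal
#' component is computed. Genes with zero variance are standardized to
#' all-zeros with a warning.
#'
#' @param ds a \linkS4class{BhotExperiment} (its log2 assay is used) or
#'   a genes x samples numeric matrix.
#' @param winsor cap on |robust z|.
#' @return samples x genes matrix of robust z-scores (the observation
#'   x variable orientation expected by the PC derivations).
#' @export
robustStandardize <- function(ds, winsor = 4) {
  x <- if (is(ds, "BhotExperiment")) exprs(ds) else as.matrix(ds)
  ctr <- matrixStats::rowMedians(x)
  sc <- matrixStats::rowMads(x)           # 1.4826 * MAD by default
  fallback <- sc == 0
  if (any(fallback)) sc[fallback] <- matrixStats::rowSds(x)[fallback]
  dead <- sc == 0
  if (any(dead)) {
    warning(sum(dead), " zero-variance gene(s) standardized to zeros")
    sc[dead] <- 1
  }
  z <- (x - ctr) / sc
  z[z > winsor] <- winsor
  z[z < -winsor] <- -winsor
  t(z)
}

# PCA with eigenvalue retention and a positive-loading-sum sign anchor;
# z is samples x genes (robust-standardized; mean-centered here so
# scores are exactly uncorrelated and eigenvalues sum to the variance)
.pcaRetain <- function(z, min_eigen, strict = FALSE) {
  pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- if (strict) which(ev > min_eigen) else which(ev >= min_eigen)
  rot <- pc$rotation[, keep, drop = FALSE]
  sco <- pc$x[, keep, drop = FALSE]
  flip <- colSums(rot) < 0
  rot[, flip] <- -rot[, flip]
  sco[, flip] <- -sco[, flip]
  list(scores = sco, loadings = rot, eigenvalues = ev[keep],
       total_variance = sum(ev))
}

.assemblePCSet <- function(kind, parts, ds_genes, threshold) {
  if (!length(parts))
    return(new("PCSet", kind = kind,
               scores = matrix(0, 0, 0), loadings = matrix(0, 0, 0),
               eigenvalues = numeric(), provenance = data.frame(
                 component = character(), decomposition = character(),
                 n_genes = integer(), threshold = numeric()),
               geneLists = list()))
  scores <- do.call(cbind, lapply(parts, `[[`, "scores"))
  comp <- unname(unlist(lapply(parts, `[[`, "names")))
  colnames(scores) <- comp
  loadings <- matrix(0, length(ds_genes), length(comp),
                     dimnames = list(ds_genes, comp))
  geneLists <- vector("list", length(comp)); names(geneLists) <- comp
  prov <- data.frame(component = comp,
                     decomposition = unlist(lapply(parts, function(p)
                       rep(p$decomposition, length(p$names)))),
                     n_genes = unlist(lapply(parts, function(p)
                       rep(length(p$genes), length(p$names)))),
                     threshold = unlist(lapply(parts, function(p)
                       rep(p$threshold, length(p$names)))),
                     row.names = NULL)
  i <- 0L
  for (p in parts) for (j in seq_along(p$names)) {
    i <- i + 1L
    loadings[p$genes, i] <- p$loadings[, j]
    geneLists[[i]] <- p$genes
  }
  new("PCSet", kind = kind, scores = scores, loadings = loadings,
      eigenvalues = unname(unlist(lapply(parts, `[[`, "eigenvalues"))),
      provenance = prov, geneLists = geneLists)
}

#' Pathology-based principal components (supervised contrasts)
#'
#' For each diagnosis other than the reference, fits per-gene two-group
#' ordinary linear models (equal-variance t via \pkg{limma}'s
#' \code{lmFit}, without moderation) of that class against the
#' reference, selects genes at a Benjamini-Hochberg adjusted p below
#' \code{alpha_fdr}, and decomposes the robust-standardized selected
#' genes across \emph{all} samples (so scores exist for every sample).
#' Components with eigenvalue at or above \code{min_eigen} are retained
#' and pooled across contrasts with provenance labels.
#'
#' @param ds a \linkS4class{BhotExperiment} with a complete diagnosis.
#' @param reference reference class (default NOREJECTION).
#' @param alpha_fdr BH-adjusted significance cut (default 0.005,
#'   i.e. -log10 = 2.3).
#' @param min_eigen eigenvalue retention threshold (standardized
#'   variance units).
#' @param max_genes optional cap per contrast: keep the top
#'   \code{max_genes} by |t| among the significant genes.
#' @return A \linkS4class{PCSet} of kind \code{"PBPC"}.
#' @export
derivePBPC <- function(ds, reference = "NOREJECTION", alpha_fdr = 0.005,
                       min_eigen = 3, max_genes = NULL) {
  stopifnot(is(ds, "BhotExperiment"))
  dx <- diagnosis(ds)
  if (is.null(dx) || anyNA(dx)) stop("a complete diagnosis is required")
  if (!reference %in% dx) stop("reference class '", reference, "' absent")
  z <- robustStandardize(ds)
  parts <- list()
  for (cls in setdiff(diagnosisLevels(), reference)) {
    if (!cls %in% dx) next
    ct <- contrastGenes(ds, cls, reference, alpha_fdr = alpha_fdr)
    genes <- ct$gene[ct$selected]
    if (!is.null(max_genes) && length(genes) > max_genes) {
      tt <- ct$t[match(genes, ct$gene)]
      genes <- genes[order(-abs(tt))][seq_len(max_genes)]
    }
    if (length(genes) < 2L) {
      warning("contrast ", cls, " vs ", reference,
              ": no significant genes; contrast skipped")
      next
    }
    dec <- .pcaRetain(z[, genes, drop = FALSE], min_eigen)
    if (!ncol(dec$scores)) next
    nm <- paste0(cls, "_PC", seq_len(ncol(dec$scores)))
    parts[[cls]] <- list(names = nm, decomposition = cls, genes = genes,
                         scores = dec$scores, loadings = dec$loadings,
                         eigenvalues = dec$eigenvalues,
                         threshold = min_eigen)
  }
  .assemblePCSet("PBPC", parts, rownames(ds), min_eigen)
}

#' Per-gene two-group contrast against a reference class
#'
#' Ordinary (non-moderated) equal-variance linear-model t-tests of one
#' diagnosis against the reference, gene by gene, with
#' Benjamini-Hochberg adjustment; the gene-selection step of
#' \code{\link{derivePBPC}}, exposed for calibration checks and custom
#' contrast work.
#'
#' @param ds a \linkS4class{BhotExperiment}.
#' @param cls comparison class.
#' @param reference reference class.
#' @param alpha_fdr BH-adjusted selection threshold.
#' @return data.frame: gene, t, p, p_adj, selected.
#' @export
contrastGenes <- function(ds, cls, reference = "NOREJECTION",
                          alpha_fdr = 0.005) {
  dx <- diagnosis(ds)
  sel <- dx %in% c(cls, reference)
  grp <- factor(dx[sel] == cls, levels = c(FALSE, TRUE))
  design <- cbind(1, as.integer(grp) - 1L)
  fit <- limma::lmFit(exprs(ds)[, sel, drop = FALSE], design)
  tstat <- fit$coefficients[, 2] / (fit$stdev.unscaled[, 2] * fit$sigma)
  pval <- 2 * stats::pt(-abs(tstat), df = fit$df.residual)
  padj <- stats::p.adjust(pval, method = "BH")
  data.frame(gene = rownames(ds), t = unname(tstat), p = unname(pval),
             p_adj = unname(padj), selected = unname(padj < alpha_fdr),
             row.names = NULL)
}

#' Cell-pathway principal components (gene-set scores)
#'
#' For every catalog set intersecting the dataset, computes the first
#' principal component (first right-singular direction) of the
#' robust-standardized gene-set submatrix. A component is retained when
#' its eigenvalue exceeds \code{min_eigen}; the score sign is anchored
#' so the mean loading is positive (the score increases with the set's
#' mean expression). Sets with a single overlapping gene are kept with
#' the threshold waived (the score is the standardized gene itself);
#' sets with no overlap are skipped with a warning.
#'
#' @param ds a \linkS4class{BhotExperiment}.
#' @param catalog a \linkS4class{GeneSetCatalog}.
#' @param min_eigen retention threshold on the first eigenvalue.
#' @return A \linkS4class{PCSet} of kind \code{"CPPC"}, one component
#'   per retained set.
#' @export
deriveCPPC <- function(ds, catalog, min_eigen = 5) {
  stopifnot(is(ds, "BhotExperiment"), is(catalog, "GeneSetCatalog"))
  z <- robustStandardize(ds)
  parts <- list()
  for (nm in names(geneSets(catalog))) {
    genes <- intersect(geneSets(catalog)[[nm]], rownames(ds))
    if (length(genes) == 0L) {
      warning("set '", nm, "' has no overlapping genes; skipped")
      next
    }
    zs <- scale(z[, genes, drop = FALSE], center = TRUE, scale = FALSE)
    if (length(genes) == 1L) {
      sc <- zs[, 1, drop = FALSE]
      part <- list(scores = sc, loadings = matrix(1, 1, 1),
                   eigenvalues = stats::var(sc[, 1]))
    } else {
      sv <- svd(zs, nu = 1, nv = 1)
      ev1 <- sv$d[1]^2 / (nrow(zs) - 1)
      if (ev1 <= min_eigen) next
      part <- list(scores = sv$u[, 1, drop = FALSE] * sv$d[1],
                   loadings = sv$v[, 1, drop = FALSE], eigenvalues = ev1)
    }
    if (sum(part$loadings) < 0) {
      part$loadings <- -part$loadings
      part$scores <- -part$scores
    }
    rownames(part$scores) <- colnames(ds)
    parts[[nm]] <- list(names = nm, decomposition = nm, genes = genes,
                        scores = part$scores, loadings = part$loadings,
                        eigenvalues = part$eigenvalues,
                        threshold = if (length(genes) == 1L) 0 else min_eigen)
  }
  .assemblePCSet("CPPC", parts, rownames(ds), min_eigen)
}

#' Unsupervised principal components (all genes)
#'
#' PCA of the full robust-standardized matrix without regard to class;
#' components with eigenvalue at or above \code{min_eigen} are
#' retained, ordered by eigenvalue.
#'
#' @param ds a \linkS4class{BhotExperiment}.
#' @param min_eigen retention threshold.
#' @return A \linkS4class{PCSet} of kind \code{"UPC"} with components
#'   UPC1, UPC2, ...
#' @export
deriveUPC <- function(ds, min_eigen = 3) {
  stopifnot(is(ds, "BhotExperiment"))
  if (nrow(ds) < 2L) stop("at least 2 genes are required")
  z <- robustStandardize(ds)
  dec <- .pcaRetain(z, min_eigen)
  if (!ncol(dec$scores))
    return(.assemblePCSet("UPC", list(), rownames(ds), min_eigen))
  nm <- paste0("UPC", seq_len(ncol(dec$scores)))
  parts <- list(list(names = nm, decomposition = "all", genes = rownames(ds),
                     scores = dec$scores, loadings = dec$loadings,
                     eigenvalues = dec$eigenvalues, threshold = min_eigen))
  .assemblePCSet("UPC", parts, rownames(ds), min_eigen)
}

#' Top-loading report with catalog membership
#'
#' For every component, lists the \code{top_n} genes by absolute
#' loading together with their catalog memberships, and the enrichment
#' fraction of each catalog set among those top genes.
#'
#' @param pcs a \linkS4class{PCSet}.
#' @param catalog a \linkS4class{GeneSetCatalog} (may be empty-ish: an
#'   empty membership column is returned).
#' @param top_n genes per component.
#' @return list with \code{top} (data.frame: component, rank, gene,
#'   loading, sets) and \code{enrichment} (components x sets matrix of
#'   fractions).
#' @export
loadingReport <- function(pcs, catalog = NULL, top_n = 25) {
  stopifnot(is(pcs, "PCSet"))
  sets <- if (is.null(catalog)) list() else geneSets(catalog)
  comps <- colnames(pcs@scores)
  rows <- list()
  enr <- matrix(NA_real_, length(comps), length(sets),
                dimnames = list(comps, names(sets)))
  for (cc in comps) {
    genes <- pcs@geneLists[[cc]]
    ld <- pcs@loadings[genes, cc]
    ord <- order(-abs(ld))[seq_len(min(top_n, length(genes)))]
    top <- genes[ord]
    memb <- vapply(top, function(g)
      paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
            collapse = ","), character(1))
    rows[[cc]] <- data.frame(component = cc, rank = seq_along(top),
                             gene = top, loading = unname(ld[ord]),
                             sets = unname(memb), row.names = NULL)
    for (s in names(sets)) enr[cc, s] <- mean(top %in% sets[[s]])
  }
  list(top = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       enrichment = enr)
}

#' Assemble classifier feature bundles from PC sets
#'
#' Builds the four feature bundles used for classification: the three
#' single-kind bundles and ALL (the column-concatenation of CPPC, PBPC
#' and UPC scores). Feature names are prefixed with their kind.
#'
#' @param pbpc,cppc,upc \linkS4class{PCSet}s (any may be NULL).
#' @return named list of \linkS4class{FeatureBundle}s (\code{ALL} plus
#'   one per non-NULL kind).
#' @export
makeBundles <- function(pbpc = NULL, cppc = NULL, upc = NULL) {
  one <- function(pcs) {
    if (is.null(pcs) || !ncol(pcs@scores)) return(NULL)
    f <- pcs@scores
    colnames(f) <- paste0(pcs@kind, ":", colnames(f))
    list(features = f,
         provenance = data.frame(feature = colnames(f), kind = pcs@kind,
                                 decomposition = pcs@provenance$decomposition))
  }
  ps <- Filter(Negate(is.null), list(CPPC = one(cppc), PBPC = one(pbpc),
                                     UPC = one(upc)))
  if (!length(ps)) stop("at least one PCSet is required")
  out <- lapply(names(ps), function(k)
    new("FeatureBundle", name = k, features = ps[[k]]$features,
        provenance = ps[[k]]$provenance))
  names(out) <- names(ps)
  out$ALL <- new("FeatureBundle", name = "ALL",
                 features = do.call(cbind, lapply(ps, `[[`, "features")),
                 provenance = do.call(rbind, c(lapply(ps, `[[`, "provenance"),
                                               list(make.row.names = FALSE))))
  out[c("ALL", intersect(c("CPPC", "PBPC", "UPC"), names(out)))]
}
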