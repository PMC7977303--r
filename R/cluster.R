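#' Sarle's cubic clustering criterion
#'
#' Compares the R-squared of a K-means partition to its expectation
#' under a uniform null on the data's principal hyperbox (the SAS
#' Technical Report A-108 formulation, with the data implicitly
#' projected onto principal axes through the covariance eigenvalues).
#' Values above ~2-3 indicate genuine cluster structure; a uniform
#' sample stays at or below ~2 across K.
#'
#' @param x samples x features numeric matrix.
#' @param k number of clusters (>= 2, < n).
#' @param seed integer seed for the K-means restarts.
#' @param restarts K-means restarts.
#' @param km optional precomputed \code{stats::kmeans} fit at \code{k}
#'   (then no K-means is run here).
#' @return list: \code{ccc}, \code{r2}, \code{k}, \code{km}.
#' @export
cubicClusteringCriterion <- function(x, k, seed = 1L, restarts = 25,
                                     km = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(k >= 2, n > k)
  if (all(matrixStats::colSds(x) == 0))
    stop("degenerate (zero-variance) data")
  if (is.null(km))
    km <- .withSeed(seed, stats::kmeans(x, centers = k, nstart = restarts,
                                        iter.max = 100))
  r2 <- 1 - km$tot.withinss / km$totss
  list(ccc = .sarleCCC(x, r2, k), r2 = r2, k = k, km = km)
}

# CCC from R^2 and the covariance eigenvalues (SAS A-108)
.sarleCCC <- function(x, r2, q) {
  n <- nrow(x)
  xc <- sweep(x, 2L, colMeans(x))
  s2 <- eigen(crossprod(xc) / (n - 1), symmetric = TRUE,
              only.values = TRUE)$values
  s <- sqrt(pmax(s2, 0))
  s <- s[s > 1e-12 * max(s)]
  p <- length(s)
  # p* = largest integer < q with u_{p*} >= 1, where u = s/c and
  # c = (prod(s[1:p*])/q)^(1/p*)
  pstar <- 1L
  for (cand in seq_len(min(p, q - 1L))) {
    cc <- (prod(s[seq_len(cand)]) / q)^(1 / cand)
    if (s[cand] / cc >= 1) pstar <- cand
  }
  cc <- (prod(s[seq_len(pstar)]) / q)^(1 / pstar)
  u <- s / cc
  num <- sum(1 / (n + u[seq_len(pstar)]))
  if (pstar < p)
    num <- num + sum(u[(pstar + 1):p]^2 / (n + u[(pstar + 1):p]))
  er2 <- 1 - (num / sum(u^2)) * ((n - q)^2 / n) * (1 + 4 / n)
  log((1 - er2) / (1 - r2)) * sqrt(n * pstar / 2) / (0.001 + er2)^1.2
}

#' K-means with cluster count chosen by the cubic clustering criterion
#'
#' Runs K-means (k-means++-style multiple restarts via
#' \code{stats::kmeans} \code{nstart}) for every K in
#' \code{kmin..kmax}, computes the CCC at each K, and returns the
#' assignment from the best-inertia run at the CCC-maximizing K. When
#' the best CCC stays below the signal threshold (2), the result is
#' flagged \code{no_structure} and \code{kmin} is kept.
#'
#' @param bundle a \linkS4class{FeatureBundle} or samples x features
#'   matrix (PC scores are already variance-scaled; Euclidean distance
#'   is used directly).
#' @param kmin,kmax scanned range of K.
#' @param restarts K-means restarts per K.
#' @param seed integer seed; the scan is reproducible end-to-end.
#' @return A \code{ClusterAssignment} list: \code{cluster} (named
#'   integer per sample), \code{k}, \code{ccc} (data.frame K, ccc, r2),
#'   \code{no_structure}, \code{seed}.
#' @export
kmeansSelect <- function(bundle, kmin = 2, kmax = 20, restarts = 25,
                         seed = 1L) {
  x <- if (is(bundle, "FeatureBundle")) featureMatrix(bundle) else
    as.matrix(bundle)
  stopifnot(nrow(x) > kmax, kmin >= 2, kmax >= kmin)
  seeds <- .childSeeds(seed, kmax - kmin + 1L)
  fits <- list(); tab <- NULL
  for (i in seq_along(kmin:kmax)) {
    k <- (kmin:kmax)[i]
    res <- cubicClusteringCriterion(x, k, seed = seeds[i],
                                    restarts = restarts)
    fits[[as.character(k)]] <- res
    tab <- rbind(tab, data.frame(K = k, ccc = res$ccc, r2 = res$r2))
  }
  best <- as.integer(tab$K[which.max(tab$ccc)])
  no_structure <- max(tab$ccc) < 2
  if (no_structure) best <- as.integer(kmin)
  cl <- fits[[as.character(best)]]$km$cluster
  names(cl) <- rownames(x)
  structure(list(cluster = cl, k = best, ccc = tab,
                 no_structure = no_structure, seed = as.integer(seed)),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: K = %d over %d samples (max CCC = %.2f%s)\n",
              x$k, length(x$cluster), max(x$ccc$ccc),
              if (x$no_structure) ", no structure" else ""))
  invisible(x)
}

#' Diagnosis x cluster contingency table
#'
#' Counts of each diagnosis across clusters with row totals, and a
#' chi-square association statistic reported descriptively (no
#' modelling decision hangs on it).
#'
#' @param dx factor of diagnoses (aligned with the clustering).
#' @param clusters a \code{ClusterAssignment} or integer vector.
#' @return list: \code{table} (diagnoses x clusters with a Total
#'   column), \code{chisq} (statistic), \code{p_value}.
#' @export
contingencyDx <- function(dx, clusters) {
  cl <- if (inherits(clusters, "ClusterAssignment")) clusters$cluster
        else clusters
  if (length(dx) != length(cl))
    stop("diagnoses and clusters must be aligned")
  tab <- table(DX = factor(dx), cluster = cl)
  cs <- suppressWarnings(stats::chisq.test(tab))
  out <- cbind(tab, Total = rowSums(tab))
  mode(out) <- "integer"
  list(table = out, chisq = unname(cs$statistic), p_value = cs$p.value)
}
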