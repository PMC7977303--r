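#' Supervised two-bin discretization of features
#'
#' For every feature, a depth-1 decision split supervised on the target
#' picks the cut point: candidate cuts are the midpoints between
#' consecutive sorted unique values, scored by information gain about
#' the target; a small seeded perturbation of the scores breaks exact
#' ties deterministically. Values above the cut map to \code{"high"},
#' the rest to \code{"low"}.
#'
#' @param bundle a \linkS4class{FeatureBundle} or samples x features
#'   matrix with nonconstant columns.
#' @param target factor of target labels.
#' @param seed integer seed for the tie-breaking perturbation.
#' @return A \code{DiscretizationMap}: named numeric vector of cut
#'   points with class \code{"DiscretizationMap"}.
#' @export
discretizeFeatures <- function(bundle, target, seed = 1L) {
  x <- if (is(bundle, "FeatureBundle")) featureMatrix(bundle) else
    as.matrix(bundle)
  y <- droplevels(as.factor(target))
  n <- length(y)
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log(p))
  }
  h_y <- ent(table(y))
  cuts <- numeric(ncol(x))
  seeds <- .childSeeds(seed, ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    u <- sort(unique(v))
    if (length(u) < 2L)
      stop("constant feature cannot be discretized: ",
           colnames(x)[j] %||% paste0("feature ", j))
    cand <- (u[-1] + u[-length(u)]) / 2
    gain <- vapply(cand, function(cut) {
      hi <- v > cut
      h_y - (sum(hi) / n) * ent(table(y[hi])) -
        (sum(!hi) / n) * ent(table(y[!hi]))
    }, numeric(1))
    gain <- gain + .withSeed(seeds[j],
                             stats::runif(length(gain), 0, 1e-12))
    cuts[j] <- cand[which.max(gain)]
  }
  names(cuts) <- colnames(x) %||% paste0("feature", seq_len(ncol(x)))
  structure(cuts, class = "DiscretizationMap")
}

#' Apply a discretization map
#'
#' @param map a \code{DiscretizationMap}.
#' @param bundle a \linkS4class{FeatureBundle} or matrix covering the
#'   map's features.
#' @return character matrix of \code{"low"}/\code{"high"} bins, one
#'   column per mapped feature.
#' @export
applyDiscretization <- function(map, bundle) {
  x <- if (is(bundle, "FeatureBundle")) featureMatrix(bundle) else
    as.matrix(bundle)
  feats <- names(map)
  miss <- setdiff(feats, colnames(x))
  if (length(miss)) stop("features absent from the data: ",
                         paste(miss, collapse = ", "))
  out <- matrix("low", nrow(x), length(feats),
                dimnames = list(rownames(x), feats))
  for (f in feats) out[x[, f] > map[[f]], f] <- "high"
  out
}

.binStates <- c("low", "high")

# smoothed count array helpers -------------------------------------------

.countsXC <- function(xf, y, alpha) {
  tab <- table(factor(xf, levels = .binStates), y) + alpha
  sweep(tab, 2L, colSums(tab), "/")            # P(x | c), 2 x |C|
}

.countsXCP <- function(xf, y, pf, alpha) {
  tab <- table(factor(xf, levels = .binStates), y,
               factor(pf, levels = .binStates)) + alpha
  sweep(tab, c(2L, 3L), apply(tab, c(2L, 3L), sum), "/")  # 2 x |C| x 2
}

# empirical conditional mutual information I(Xi; Xj | C) in nats (MLE)
.cmi <- function(xi, xj, y) {
  n <- length(y)
  tot <- 0
  for (c in levels(y)) {
    sel <- y == c
    nc <- sum(sel)
    if (!nc) next
    t2 <- table(factor(xi[sel], levels = .binStates),
                factor(xj[sel], levels = .binStates)) / nc
    pi_ <- rowSums(t2); pj <- colSums(t2)
    for (a in 1:2) for (b in 1:2)
      if (t2[a, b] > 0)
        tot <- tot + (nc / n) * t2[a, b] * log(t2[a, b] / (pi_[a] * pj[b]))
  }
  tot
}

#' Learn a tree-augmented naive Bayes model with MDL pruning
#'
#' Builds the maximum-weight spanning tree over the features' class-
#' conditional mutual information I(Xi; Xj | C), then walks the tree
#' edges in decreasing weight and keeps an edge only when its
#' likelihood gain n I(Xi; Xj | C) exceeds the MDL penalty
#' (added parameters / 2) log n; pruning can leave a forest, down to
#' plain naive Bayes. Conditional probability tables are estimated with
#' add-\code{alpha} smoothing (Jeffreys 0.5 by default, so small
#' class-by-bin cells never go to zero).
#'
#' @param binary character/factor matrix of \code{"low"}/\code{"high"}
#'   bins (from \code{\link{applyDiscretization}}), >= 2 columns.
#' @param target factor of target labels.
#' @param alpha_smooth CPT pseudocount.
#' @return A \linkS4class{TANModel}.
#' @export
learnTAN <- function(binary, target, alpha_smooth = 0.5) {
  x <- as.matrix(binary)
  y <- droplevels(as.factor(target))
  n <- length(y)
  feats <- colnames(x)
  if (is.null(feats) || length(feats) < 2L)
    stop("at least 2 named binary features are required")
  bad <- !apply(x, 2L, function(v) all(v %in% .binStates))
  if (any(bad)) stop("features must be binary low/high: ",
                     paste(feats[bad], collapse = ", "))
  ncls <- nlevels(y)
  penalty <- (ncls / 2) * log(n)   # one extra binary parent doubles the CPT

  pairs <- utils::combn(length(feats), 2L)
  ew <- apply(pairs, 2L, function(ij)
    .cmi(x[, ij[1]], x[, ij[2]], y))
  ord <- order(-ew)

  # Kruskal maximum spanning tree
  comp <- seq_along(feats)
  in_tree <- logical(ncol(pairs))
  for (e in ord) {
    a <- comp[pairs[1, e]]; b <- comp[pairs[2, e]]
    if (a != b) {
      in_tree[e] <- TRUE
      comp[comp == b] <- a
      if (sum(in_tree) == length(feats) - 1L) break
    }
  }

  # greedy MDL walk over tree edges in decreasing CMI
  loglik0 <- .tanLoglik0(x, y)
  params <- (ncls - 1) + length(feats) * ncls
  mdl <- -loglik0 + (params / 2) * log(n)
  mdl_trace <- mdl
  kept <- logical(ncol(pairs))
  for (e in ord[in_tree[ord]]) {
    gain <- n * ew[e]
    if (gain > penalty) {
      kept[e] <- TRUE
      mdl <- mdl - (gain - penalty)
      mdl_trace <- c(mdl_trace, mdl)
    }
  }

  # orient kept edges away from per-component roots (first feature)
  adj <- lapply(seq_along(feats), function(i) integer())
  for (e in which(kept)) {
    i <- pairs[1, e]; j <- pairs[2, e]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  parent <- stats::setNames(rep(NA_character_, length(feats)), feats)
  visited <- logical(length(feats))
  for (root in seq_along(feats)) {
    if (visited[root]) next
    queue <- root; visited[root] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) if (!visited[nb]) {
        visited[nb] <- TRUE
        parent[feats[nb]] <- feats[cur]
        queue <- c(queue, nb)
      }
    }
  }

  prior <- (table(y) + alpha_smooth) / (n + alpha_smooth * ncls)
  cpts <- list()
  for (i in seq_along(feats)) {
    f <- feats[i]
    cpts[[f]] <- if (is.na(parent[[f]]))
      .countsXC(x[, f], y, alpha_smooth)
    else
      .countsXCP(x[, f], y, x[, parent[[f]]], alpha_smooth)
  }
  edgeTable <- data.frame(
    from = feats[pairs[1, ]], to = feats[pairs[2, ]], cmi = ew,
    gain = n * ew, penalty = penalty, in_tree = in_tree, kept = kept)
  model <- new("TANModel", classLevels = levels(y), features = feats,
               parent = parent,
               classPrior = stats::setNames(as.numeric(prior), levels(y)),
               cpts = cpts, edgeTable = edgeTable,
               alpha = alpha_smooth, mdl = mdl)
  attr(model, "mdl_trace") <- mdl_trace
  model
}

# naive Bayes log-likelihood with MLE parameters (structure scoring base)
.tanLoglik0 <- function(x, y) {
  n <- length(y)
  ll <- sum(table(y) * log(pmax(table(y) / n, 1e-300)))
  for (j in seq_len(ncol(x))) {
    tab <- table(factor(x[, j], levels = .binStates), y)
    cs <- colSums(tab)
    p <- sweep(tab, 2L, pmax(cs, 1L), "/")
    ll <- ll + sum(tab[tab > 0] * log(p[tab > 0]))
  }
  ll
}

#' Posterior class probabilities from a TAN model
#'
#' Exact inference with full evidence: the posterior factorizes as
#' prior times the product of each feature's CPT entry, normalized per
#' sample (equivalent to brute-force enumeration of the joint).
#'
#' @param model a \linkS4class{TANModel}.
#' @param binary bin matrix covering the model's features.
#' @return samples x classes probability matrix.
#' @export
predictTAN <- function(model, binary) {
  x <- as.matrix(binary)
  lev <- model@classLevels
  n <- nrow(x)
  logp <- matrix(rep(log(model@classPrior), each = n), n, length(lev),
                 dimnames = list(rownames(x), lev))
  for (f in model@features) {
    cpt <- model@cpts[[f]]
    xi <- match(x[, f], .binStates)
    if (is.na(model@parent[[f]])) {
      for (c in seq_along(lev))
        logp[, c] <- logp[, c] + log(cpt[cbind(xi, c)])
    } else {
      xp <- match(x[, model@parent[[f]]], .binStates)
      for (c in seq_along(lev))
        logp[, c] <- logp[, c] + log(cpt[cbind(xi, c, xp)])
    }
  }
  p <- exp(logp - apply(logp, 1L, max))
  p / rowSums(p)
}

#' Bayes factors of feature states per class
#'
#' BF(class c, feature f, bin b) = P(f = b | C = c) / P(f = b | C != c),
#' estimated from add-alpha smoothed empirical marginals; the log2 BF
#' and the Kullback-Leibler divergence of P(f | C = c) from
#' P(f | C != c) (bits) are reported alongside, so either evidence
#' reading is inspectable. A bin independent of the class gives BF = 1.
#'
#' @param model a \linkS4class{TANModel} (provides class levels,
#'   features and the smoothing alpha).
#' @param binary bin matrix.
#' @param target factor of class labels aligned with \code{binary}.
#' @return data.frame: class, feature, bin, p_in, p_out, bf, log2_bf,
#'   kl_bits.
#' @export
bayesFactors <- function(model, binary, target) {
  x <- as.matrix(binary)
  y <- factor(as.character(target), levels = model@classLevels)
  a <- model@alpha
  rows <- list()
  for (cl in model@classLevels) {
    inc <- y == cl
    for (f in model@features) {
      n_in <- table(factor(x[inc, f], levels = .binStates)) + a
      n_out <- table(factor(x[!inc, f], levels = .binStates)) + a
      p_in <- n_in / sum(n_in); p_out <- n_out / sum(n_out)
      kl <- sum(p_in * log2(p_in / p_out))
      for (b in .binStates)
        rows[[length(rows) + 1L]] <- data.frame(
          class = cl, feature = f, bin = b,
          p_in = as.numeric(p_in[b]), p_out = as.numeric(p_out[b]),
          bf = as.numeric(p_in[b] / p_out[b]),
          log2_bf = log2(as.numeric(p_in[b] / p_out[b])),
          kl_bits = kl)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Evaluate a TAN model (resubstitution or cross-validated)
#'
#' Resubstitution mode scores a fitted model on supplied data; the
#' K-fold mode refits the discretization and the network inside every
#' training fold and scores out-of-fold, mirroring
#' \code{\link{fitPredict}}.
#'
#' @param model a fitted \linkS4class{TANModel} (ignored in K-fold
#'   mode, may be NULL there).
#' @param binary bin matrix (resubstitution mode) or, in K-fold mode,
#'   the continuous \linkS4class{FeatureBundle}/matrix to discretize
#'   per fold.
#' @param target factor of target labels.
#' @param folds NULL for resubstitution, otherwise the fold count.
#' @param alpha_smooth,seed K-fold refit parameters.
#' @return list: \code{prediction} (\linkS4class{PredictionTable}) and
#'   \code{report} (\code{ModelReport}).
#' @export
evaluateTAN <- function(model, binary, target, folds = NULL,
                        alpha_smooth = 0.5, seed = 1L) {
  y <- droplevels(as.factor(target))
  if (is.null(folds)) {
    prob <- predictTAN(model, binary)[, levels(y), drop = FALSE]
    meta <- list(model = "tan", bundle = "binary", folds = 0,
                 seed = as.integer(seed))
  } else {
    x <- if (is(binary, "FeatureBundle")) featureMatrix(binary) else
      as.matrix(binary)
    smallest <- min(table(y))
    if (smallest < folds) {
      folds <- max(2L, smallest)
      warning("folds reduced to ", folds)
    }
    foldid <- .stratifiedFolds(y, folds, seed)
    prob <- matrix(NA_real_, nrow(x), nlevels(y),
                   dimnames = list(rownames(x), levels(y)))
    for (f in seq_len(folds)) {
      tr <- foldid != f
      map <- discretizeFeatures(x[tr, , drop = FALSE], y[tr],
                                seed = seed + f)
      m <- learnTAN(applyDiscretization(map, x[tr, , drop = FALSE]),
                    y[tr], alpha_smooth = alpha_smooth)
      p <- predictTAN(m, applyDiscretization(map, x[!tr, , drop = FALSE]))
      prob[!tr, ] <- p[, levels(y), drop = FALSE]
    }
    meta <- list(model = "tan-cv", bundle = "binary", folds = folds,
                 seed = as.integer(seed))
  }
  pt <- new("PredictionTable", truth = y, prob = prob,
            assigned = .argmaxAssign(prob), meta = meta)
  list(prediction = pt, report = evaluatePredictions(pt))
}

#' Serialize a TAN model
#'
#' \code{writeTANJson} writes nodes, edges, priors and CPTs as JSON;
#' \code{tanToDot} renders the graph in DOT for graph tools.
#'
#' @param model a \linkS4class{TANModel}.
#' @param path output path (JSON).
#' @return \code{writeTANJson}: the path, invisibly; \code{tanToDot}:
#'   a character scalar of DOT source.
#' @name tan-io
NULL

#' @rdname tan-io
#' @export
writeTANJson <- function(model, path) {
  obj <- list(classLevels = model@classLevels, features = model@features,
              parent = as.list(model@parent),
              classPrior = as.list(model@classPrior),
              cpts = lapply(model@cpts, function(a) {
                d <- dim(a)
                list(dim = d, values = as.numeric(a))
              }),
              alpha = model@alpha, mdl = model@mdl)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname tan-io
#' @export
tanToDot <- function(model) {
  lines <- c("digraph TAN {", "  C [shape=doublecircle];")
  for (f in model@features) {
    lines <- c(lines, sprintf("  \"%s\";", f),
               sprintf("  C -> \"%s\";", f))
    if (!is.na(model@parent[[f]]))
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\";",
                                model@parent[[f]], f))
  }
  paste(c(lines, "}"), collapse = "\n")
}
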