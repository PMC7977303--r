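#' Classifier registry
#'
#' Model names accepted by \code{\link{fitPredict}} and
#' \code{\link{compareModels}}.
#'
#' @return character vector of registered model names.
#' @export
modelRegistry <- function() {
  c("multinomial-logistic-elasticnet", "random-forest", "pls-da", "lda",
    "gradient-boosting", "extra-trees")
}

.clipProb <- function(p, lev) {
  p <- pmax(p, 0)
  p <- p / rowSums(p)
  colnames(p) <- lev
  p
}

# adaptive elastic net: ridge-derived weights, then a weighted elastic
# net with alpha chosen on a grid by inner CV deviance
.trainElasticNet <- function(x, y, seed, alpha_grid = c(0.1, 0.5, 0.9),
                             inner_nfolds = 3) {
  foldid <- .stratifiedFolds(y, inner_nfolds, seed, ids = rownames(x))
  ridge <- glmnet::cv.glmnet(x, y, family = "multinomial", alpha = 0,
                             foldid = foldid, nlambda = 40,
                             standardize = TRUE)
  b <- do.call(cbind, lapply(
    glmnet::coef.glmnet(ridge, s = "lambda.min"),
    function(co) abs(as.numeric(co)[-1])))
  w <- 1 / (rowMeans(b) + 1e-3)
  best <- NULL
  for (a in alpha_grid) {
    cv <- glmnet::cv.glmnet(x, y, family = "multinomial", alpha = a,
                            penalty.factor = w, foldid = foldid,
                            nlambda = 40, standardize = TRUE)
    sc <- min(cv$cvm)
    if (is.null(best) || sc < best$score)
      best <- list(score = sc, alpha = a, lambda = cv$lambda.min, cv = cv)
  }
  fit <- best$cv$glmnet.fit
  list(predict = function(newx) {
    p <- predict(fit, newx = newx, s = best$lambda, type = "response")
    p[, , 1]
  }, alpha = best$alpha, lambda = best$lambda, weights = w, fit = fit)
}

.trainModel <- function(model, x, y, seed) {
  lev <- levels(y)
  switch(model,
    "multinomial-logistic-elasticnet" = {
      if (ncol(x) < 2L)
        stop("the elastic-net model needs at least 2 features")
      en <- .trainElasticNet(x, y, seed)
      function(newx) .clipProb(en$predict(newx)[, lev, drop = FALSE], lev)
    },
    "random-forest" = {
      fit <- ranger::ranger(x = x, y = y, probability = TRUE,
                            num.trees = 500, seed = seed, num.threads = 1)
      function(newx)
        .clipProb(predict(fit, data = newx,
                          num.threads = 1)$predictions[, lev, drop = FALSE],
                  lev)
    },
    "extra-trees" = {
      fit <- ranger::ranger(x = x, y = y, probability = TRUE,
                            num.trees = 500, splitrule = "extratrees",
                            replace = FALSE, sample.fraction = 1,
                            seed = seed, num.threads = 1)
      function(newx)
        .clipProb(predict(fit, data = newx,
                          num.threads = 1)$predictions[, lev, drop = FALSE],
                  lev)
    },
    "lda" = {
      fit <- MASS::lda(x, grouping = y)
      function(newx) {
        p <- predict(fit, newdata = newx)$posterior
        miss <- setdiff(lev, colnames(p))
        if (length(miss)) {
          p <- cbind(p, matrix(0, nrow(p), length(miss),
                               dimnames = list(NULL, miss)))
        }
        .clipProb(p[, lev, drop = FALSE], lev)
      }
    },
    "gradient-boosting" = {
      dtr <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      fit <- .withSeed(seed, xgboost::xgb.train(
        params = list(objective = "multi:softprob", num_class = length(lev),
                      max_depth = 3, eta = 0.1, nthread = 1,
                      seed = seed),
        data = dtr, nrounds = 150, verbose = 0))
      function(newx) {
        p <- predict(fit, newdata = xgboost::xgb.DMatrix(newx))
        p <- matrix(p, ncol = length(lev), byrow = TRUE,
                    dimnames = list(NULL, lev))
        .clipProb(p, lev)
      }
    },
    "pls-da" = {
      grid <- 2:10
      grid <- grid[grid <= min(ncol(x), nrow(x) - 1L)]
      if (!length(grid)) grid <- min(2L, ncol(x))
      best <- grid[1]
      if (length(grid) > 1L) {
        foldid <- .stratifiedFolds(y, 5, seed)
        acc <- vapply(grid, function(nc) {
          hit <- 0L
          for (f in unique(foldid)) {
            tr <- foldid != f
            fit <- mixOmics::plsda(x[tr, , drop = FALSE], y[tr], ncomp = nc)
            cl <- predict(fit, x[!tr, , drop = FALSE])$class$max.dist[, nc]
            hit <- hit + sum(cl == as.character(y[!tr]))
          }
          hit / length(y)
        }, numeric(1))
        best <- grid[which.max(acc)]
      }
      fit <- mixOmics::plsda(x, y, ncomp = best)
      function(newx) {
        raw <- predict(fit, newx)$predict[, , best, drop = FALSE][, , 1]
        if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1,
                                             dimnames = list(NULL, names(raw)))
        # soft-max the predicted class indicators into probabilities
        e <- exp(raw - apply(raw, 1, max))
        .clipProb((e / rowSums(e))[, lev, drop = FALSE], lev)
      }
    },
    stop("registry error: unknown model '", model, "'; see modelRegistry()")
  )
}

#' Cross-validated per-sample class probabilities
#'
#' Fits one registered model under stratified K-fold cross-validation
#' and returns the out-of-fold probabilities: every sample's
#' probabilities come from the fold in which it was held out, so the
#' resulting confusion matrices describe validated, not resubstitution,
#' performance. The assigned class is the argmax probability with ties
#' broken by the fixed level order. Deterministic given \code{seed}.
#'
#' @param bundle a \linkS4class{FeatureBundle} (or samples x features
#'   matrix).
#' @param target factor (or vector) of target labels, length = samples;
#'   must have at least 2 levels.
#' @param model a name from \code{\link{modelRegistry}}.
#' @param folds number of CV folds; reduced with a warning when the
#'   smallest class has fewer samples.
#' @param seed integer seed (folds and any stochastic fit).
#' @return A \linkS4class{PredictionTable}.
#' @export
fitPredict <- function(bundle, target,
                       model = "multinomial-logistic-elasticnet",
                       folds = 10, seed = 1L) {
  x <- if (is(bundle, "FeatureBundle")) featureMatrix(bundle) else
    as.matrix(bundle)
  bname <- if (is(bundle, "FeatureBundle")) bundleName(bundle) else "custom"
  y <- droplevels(as.factor(target))
  if (nlevels(y) < 2L) stop("target must have at least 2 levels")
  if (length(y) != nrow(x)) stop("target length must match samples")
  model <- match.arg(model, modelRegistry())
  smallest <- min(table(y))
  if (smallest < folds) {
    folds <- max(2L, smallest)
    warning("folds reduced to ", folds,
            " (smallest class has that many samples)")
  }
  foldid <- .stratifiedFolds(y, folds, seed, ids = rownames(x))
  prob <- matrix(NA_real_, nrow(x), nlevels(y),
                 dimnames = list(rownames(x), levels(y)))
  for (f in seq_len(folds)) {
    tr <- foldid != f
    predictor <- .trainModel(model, x[tr, , drop = FALSE],
                             droplevels(y[tr]), seed + f)
    p <- predictor(x[!tr, , drop = FALSE])
    miss <- setdiff(levels(y), colnames(p))
    if (length(miss))
      p <- cbind(p, matrix(0, nrow(p), length(miss),
                           dimnames = list(NULL, miss)))
    prob[!tr, ] <- p[, levels(y), drop = FALSE]
  }
  new("PredictionTable", truth = y, prob = prob,
      assigned = .argmaxAssign(prob),
      meta = list(model = model, bundle = bname,
                  target = deparse(substitute(target))[1],
                  folds = folds, seed = as.integer(seed)))
}

#' Feature selection by linear models and elastic-net active effects
#'
#' Returns the union of (a) features whose one-way linear model against
#' the target has a Benjamini-Hochberg adjusted p below
#' \code{alpha_fdr}, and (b) features with a nonzero coefficient (any
#' class) in the cross-validated adaptive elastic-net multinomial fit,
#' each tagged with its selection route.
#'
#' @param bundle a \linkS4class{FeatureBundle} or matrix.
#' @param target factor of target labels.
#' @param alpha_fdr BH threshold for route (a).
#' @param seed seed for the elastic-net inner CV.
#' @return data.frame: feature, f_statistic, p_adj, coef_norm, route
#'   (\code{"anova"}, \code{"elasticnet"} or \code{"both"}), restricted
#'   to selected features.
#' @export
activeEffects <- function(bundle, target, alpha_fdr = 0.005, seed = 1L) {
  x <- if (is(bundle, "FeatureBundle")) featureMatrix(bundle) else
    as.matrix(bundle)
  if (ncol(x) < 2L) stop("at least 2 features are required")
  y <- droplevels(as.factor(target))
  fstat <- pval <- rep(NA_real_, ncol(x))
  for (j in seq_len(ncol(x))) {
    if (stats::var(x[, j]) == 0) { fstat[j] <- 0; pval[j] <- 1; next }
    a <- stats::anova(stats::lm(x[, j] ~ y))
    fstat[j] <- a$`F value`[1]; pval[j] <- a$`Pr(>F)`[1]
  }
  padj <- stats::p.adjust(pval, method = "BH")
  route_a <- padj < alpha_fdr
  constant <- matrixStats::colSds(x) == 0
  en <- .trainElasticNet(x[, !constant, drop = FALSE], y, seed)
  cf <- do.call(cbind, lapply(
    glmnet::coef.glmnet(en$fit, s = en$lambda),
    function(co) as.numeric(co)[-1]))
  coef_norm <- rep(0, ncol(x))
  coef_norm[!constant] <- sqrt(rowSums(cf^2))
  route_b <- coef_norm > 0
  sel <- route_a | route_b
  route <- ifelse(route_a & route_b, "both",
                  ifelse(route_a, "anova", "elasticnet"))
  data.frame(feature = colnames(x), f_statistic = fstat, p_adj = padj,
             coef_norm = coef_norm, route = route,
             row.names = NULL)[sel, , drop = FALSE]
}

#' Fit and rank several models under identical folds
#'
#' All models are fit by \code{\link{fitPredict}} under the same folds
#' and seed, evaluated, and ranked by mean out-of-fold accuracy with
#' ties broken alphabetically by model name. A failing model is
#' reported in the ranking with \code{NA} metrics, not fatal.
#'
#' @param bundle a \linkS4class{FeatureBundle} or matrix.
#' @param target factor of target labels.
#' @param models subset of \code{\link{modelRegistry}} (>= 1).
#' @param folds,seed as in \code{\link{fitPredict}}.
#' @return list with \code{ranking} (data.frame: model, accuracy,
#'   percent_error, mean_auroc, error message if any) and
#'   \code{reports} / \code{predictions} (named lists).
#' @export
compareModels <- function(bundle, target, models = modelRegistry(),
                          folds = 10, seed = 1L) {
  models <- match.arg(models, modelRegistry(), several.ok = TRUE)
  preds <- list(); reports <- list()
  rows <- lapply(models, function(m) {
    res <- tryCatch({
      pt <- fitPredict(bundle, target, model = m, folds = folds,
                       seed = seed)
      rp <- evaluatePredictions(pt)
      preds[[m]] <<- pt; reports[[m]] <<- rp
      data.frame(model = m, accuracy = rp$accuracy,
                 percent_error = rp$percent_error,
                 mean_auroc = rp$mean_auroc, error = NA_character_)
    }, error = function(e)
      data.frame(model = m, accuracy = NA_real_, percent_error = NA_real_,
                 mean_auroc = NA_real_, error = conditionMessage(e)))
    res
  })
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(-ranking$accuracy, ranking$model,
                           na.last = TRUE), ]
  rownames(ranking) <- NULL
  list(ranking = ranking, reports = reports, predictions = preds)
}
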