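#' Evaluate a prediction table
#'
#' Builds the confusion matrix of true against assigned labels and the
#' standard summary metrics: percent error (100 x (1 - trace/total)),
#' accuracy, one-vs-rest AUROC per class (rank-based) and their mean,
#' per-class precision and recall, and multiclass log-loss with
#' probabilities clipped at 1e-15.
#'
#' @param pred a \linkS4class{PredictionTable}.
#' @return A \code{ModelReport} list: \code{confusion} (true x
#'   assigned), \code{percent_error}, \code{accuracy},
#'   \code{auroc} (per class), \code{mean_auroc}, \code{precision},
#'   \code{recall}, \code{log_loss}, \code{n}, \code{meta}.
#' @export
evaluatePredictions <- function(pred) {
  stopifnot(is(pred, "PredictionTable"))
  truth <- pred@truth; assigned <- pred@assigned; prob <- pred@prob
  n <- length(truth)
  if (!n) stop("empty prediction table")
  lev <- levels(truth)
  confusion <- table(true = truth, assigned = assigned)
  correct <- sum(diag(confusion))
  auroc <- vapply(lev, function(l)
    .aucRank(prob[, l], truth == l), numeric(1))
  precision <- diag(confusion) / pmax(colSums(confusion), 1L)
  recall <- diag(confusion) / pmax(rowSums(confusion), 1L)
  p_true <- pmin(pmax(prob[cbind(seq_len(n), as.integer(truth))], 1e-15),
                 1 - 1e-15)
  structure(list(
    confusion = confusion,
    percent_error = 100 * (1 - correct / n),
    accuracy = correct / n,
    auroc = auroc,
    mean_auroc = mean(auroc, na.rm = TRUE),
    precision = precision, recall = recall,
    log_loss = -mean(log(p_true)),
    n = n, meta = pred@meta), class = "ModelReport")
}

#' @export
print.ModelReport <- function(x, ...) {
  cat(sprintf("ModelReport [%s on %s]: n = %d\n",
              x$meta$model %||% "?", x$meta$bundle %||% "?", x$n))
  cat(sprintf(
    "percent error %.1f | accuracy %.3f | mean AUROC %.3f | log-loss %.3f\n",
    x$percent_error, x$accuracy, x$mean_auroc, x$log_loss))
  print(x$confusion)
  invisible(x)
}
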