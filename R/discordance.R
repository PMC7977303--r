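#' Per-sample discordance across prediction tables
#'
#' Two per-sample statistics are reported. \code{percent_discordant}
#' counts samples whose assigned labels are not all equal across the
#' compared prediction tables (mutual disagreement; identical tables
#' give 0). \code{percent_any_error} counts samples that sit
#' off-diagonal in at least one table's confusion matrix (assigned
#' label differs from the annotation in one or more of the compared
#' groups) — the per-sample error statistic summarizing several data
#' groups of one target, which upper-bounds every member's own error
#' and contains the mutual-disagreement set. Pairwise disagreement
#' percentages are also emitted for model-vs-model comparisons.
#'
#' @param tables list of >= 2 \linkS4class{PredictionTable}s over
#'   identical samples and target levels.
#' @param names optional names for the tables (defaults to
#'   model:bundle from their metadata).
#' @return A \code{DiscordanceReport} list: \code{percent_discordant}
#'   and \code{flags} (mutual disagreement), \code{percent_any_error}
#'   and \code{any_error_flags} (off-diagonal in >= 1 table),
#'   \code{pairwise} (percent matrix), \code{member_errors} (percent
#'   error per table).
#' @export
perSampleDiscordance <- function(tables, names = NULL) {
  if (length(tables) < 2L) stop("at least 2 prediction tables required")
  ids <- lapply(tables, function(t) rownames(t@prob))
  base_id <- ids[[1L]]
  for (i in seq_along(tables)[-1L]) {
    if (!identical(sort(ids[[i]]), sort(base_id)) ||
        is.null(base_id) && length(tables[[i]]@truth) !=
        length(tables[[1L]]@truth))
      stop("alignment error: tables cover different samples")
    if (!identical(levels(tables[[i]]@assigned),
                   levels(tables[[1L]]@assigned)))
      stop("alignment error: tables use different target levels")
  }
  if (is.null(names))
    names <- vapply(tables, function(t)
      paste0(t@meta$model %||% "?", ":", t@meta$bundle %||% "?"),
      character(1))
  names <- make.unique(names)
  asn <- vapply(tables, function(t) {
    a <- as.character(t@assigned)
    if (!is.null(base_id)) names(a) <- rownames(t@prob)
    if (!is.null(base_id)) a[base_id] else a
  }, character(length(tables[[1L]]@truth)))
  colnames(asn) <- names
  flags <- apply(asn, 1L, function(r) length(unique(r)) > 1L)
  tru <- as.character(tables[[1L]]@truth)
  if (!is.null(base_id)) {
    names(tru) <- rownames(tables[[1L]]@prob)
    tru <- tru[base_id]
  }
  any_error_flags <- rowSums(asn != tru) > 0L
  m <- length(tables)
  pairwise <- matrix(0, m, m, dimnames = list(names, names))
  for (i in seq_len(m)) for (j in seq_len(m))
    pairwise[i, j] <- 100 * mean(asn[, i] != asn[, j])
  member_errors <- vapply(tables, function(t)
    100 * mean(as.character(t@truth) != as.character(t@assigned)),
    numeric(1))
  names(member_errors) <- names
  structure(list(percent_discordant = 100 * mean(flags), flags = flags,
                 percent_any_error = 100 * mean(any_error_flags),
                 any_error_flags = any_error_flags,
                 pairwise = pairwise, member_errors = member_errors,
                 n = nrow(asn)),
            class = "DiscordanceReport")
}

#' @export
print.DiscordanceReport <- function(x, ...) {
  cat(sprintf(
    "DiscordanceReport: %d tables, %d samples, %.1f%% discordant, %.1f%% off-diagonal in >= 1 table\n",
    nrow(x$pairwise), x$n, x$percent_discordant, x$percent_any_error))
  cat("member percent errors:",
      paste(sprintf("%s=%.1f", names(x$member_errors), x$member_errors),
            collapse = ", "), "\n")
  invisible(x)
}

#' Assigned-class probability by disparity status
#'
#' Splits samples into disparities (assigned class differs from the
#' annotated one) and concordant samples, and summarizes the assigned
#' class's probability in each group; misclassified samples are
#' expected to ride on lower probabilities. A rank-based two-group
#' (Wilcoxon) test is reported when both groups are nonempty.
#'
#' @param pred a \linkS4class{PredictionTable}.
#' @param alpha_fdr significance threshold reported alongside the
#'   p-value (the global 0.005 default).
#' @return list: \code{mean_disparity}, \code{mean_concordant},
#'   \code{n_disparity}, \code{n_concordant}, \code{p_value} (NA when a
#'   group is empty), \code{significant}, \code{probabilities}
#'   (data.frame per sample: assigned probability, disparity flag).
#' @export
disparityProbability <- function(pred, alpha_fdr = 0.005) {
  stopifnot(is(pred, "PredictionTable"))
  if (!length(pred@truth)) stop("empty prediction table")
  p_assigned <- pred@prob[cbind(seq_along(pred@assigned),
                                as.integer(pred@assigned))]
  disparity <- as.character(pred@assigned) != as.character(pred@truth)
  out <- list(
    mean_disparity = if (any(disparity)) mean(p_assigned[disparity])
                     else NA_real_,
    mean_concordant = if (any(!disparity)) mean(p_assigned[!disparity])
                      else NA_real_,
    n_disparity = sum(disparity), n_concordant = sum(!disparity),
    p_value = NA_real_, significant = NA,
    probabilities = data.frame(probability = p_assigned,
                               disparity = disparity))
  if (any(disparity) && any(!disparity)) {
    wt <- suppressWarnings(stats::wilcox.test(
      p_assigned[disparity], p_assigned[!disparity]))
    out$p_value <- wt$p.value
    out$significant <- wt$p.value < alpha_fdr
  }
  out
}
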