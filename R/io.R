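#' Read a plain-TSV expression matrix
#'
#' Expects samples in rows and genes in columns: a header row of gene
#' ids and a first column of sample ids (the orientation written by
#' \code{\link{writeExperimentTSV}}).
#'
#' @param path file path.
#' @return numeric matrix, genes x rows are returned transposed to the
#'   internal genes-in-rows convention (genes x samples).
#' @export
readExpressionTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  m <- t(as.matrix(df))
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression matrix contains missing values")
  m
}

#' Read a GEO series-matrix file
#'
#' Minimal parser for the \code{series_matrix.txt} format: tab-separated
#' \code{!Sample_*} annotation lines and the expression table delimited
#' by \code{!series_matrix_table_begin} / \code{!series_matrix_table_end}.
#'
#' @param path file path to an (uncompressed) series matrix file.
#' @return list with \code{expr} (numeric matrix, probes x samples) and
#'   \code{sampleInfo} (data.frame of the \code{!Sample_*} fields, one
#'   row per sample; repeated fields such as
#'   \code{characteristics_ch1} are suffixed \code{.1}, \code{.2}, ...).
#' @export
readSeriesMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  unq <- function(x) gsub('^"|"$', "", x)
  tb <- grep("^!series_matrix_table_begin", lines)
  te <- grep("^!series_matrix_table_end", lines)
  if (length(tb) != 1L || length(te) != 1L || te <= tb + 1L)
    stop("no series matrix table found in ", path)
  tab <- utils::read.delim(text = lines[(tb + 1L):(te - 1L)],
                           check.names = FALSE)
  rn <- unq(as.character(tab[[1L]]))
  expr <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(expr) <- "double"
  rownames(expr) <- rn
  colnames(expr) <- unq(colnames(expr))

  smp <- grep("^!Sample_", lines, value = TRUE)
  info <- list()
  for (ln in smp) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    key <- sub("^!Sample_", "", parts[1L])
    vals <- unq(parts[-1L])
    base <- key; i <- 0L
    while (key %in% names(info)) { i <- i + 1L; key <- paste0(base, ".", i) }
    info[[key]] <- vals
  }
  n <- ncol(expr)
  info <- info[lengths(info) == n]
  sampleInfo <- as.data.frame(info, check.names = FALSE,
                              stringsAsFactors = FALSE)
  if ("geo_accession" %in% names(sampleInfo))
    rownames(sampleInfo) <- sampleInfo$geo_accession
  list(expr = expr, sampleInfo = sampleInfo)
}

#' Read a GMT gene-set file into a GeneSetCatalog
#'
#' @param path GMT file path.
#' @param source source tag applied to all sets in the file.
#' @return A \linkS4class{GeneSetCatalog}.
#' @export
readGMT <- function(path, source = "custom") {
  sets <- fgsea::gmtPathways(path)
  GeneSetCatalog(sets, source = source)
}

#' Read a diagnosis mapping table
#'
#' Two-column TSV (\code{label}, \code{diagnosis}) mapping annotation
#' strings of a source series to the six summary classes. The package
#' ships an editable template for the archival kidney accessions under
#' \code{system.file("extdata", "diagnosis_mapping.tsv", package =
#' "bhotmodel")}; the mapping is always explicit, never inferred.
#'
#' @param path TSV path.
#' @return named character vector label -> diagnosis.
#' @export
readDiagnosisMapping <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("label", "diagnosis") %in% names(df)))
    stop("mapping table needs columns 'label' and 'diagnosis'")
  bad <- setdiff(unique(df$diagnosis), diagnosisLevels())
  if (length(bad))
    stop("mapping targets outside the six-class set: ",
         paste(bad, collapse = ", "))
  stats::setNames(df$diagnosis, df$label)
}

#' Write a cohort as TSV files
#'
#' Writes \code{expression.tsv} (samples in rows, header row of gene
#' ids), \code{sample_annotations.tsv} and \code{gene_annotations.tsv}
#' into \code{dir}.
#'
#' @param ds a \linkS4class{BhotExperiment}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeExperimentTSV <- function(ds, dir) {
  stopifnot(is(ds, "BhotExperiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "expression.tsv")
  p2 <- file.path(dir, "sample_annotations.tsv")
  p3 <- file.path(dir, "gene_annotations.tsv")
  m <- t(exprs(ds))
  utils::write.table(data.frame(sample = rownames(m), m,
                                check.names = FALSE),
                     p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(ds),
                                as.data.frame(colData(ds)),
                                check.names = FALSE),
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(ds),
                                as.data.frame(rowData(ds)),
                                check.names = FALSE),
                     p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Read / write a simulation configuration as YAML
#'
#' @param config a \code{SimConfig} (for writing).
#' @param path YAML file path.
#' @return \code{readSimConfig} returns a validated \code{SimConfig};
#'   \code{writeSimConfig} returns \code{path} invisibly.
#' @name simconfig-io
NULL

#' @rdname simconfig-io
#' @export
writeSimConfig <- function(config, path) {
  stopifnot(inherits(config, "SimConfig"))
  x <- unclass(config)
  x$hk_genes <- NULL   # derived from housekeeping_frac on read
  x$class_sizes <- as.list(x$class_sizes)
  x$n_subtypes <- as.list(x$n_subtypes)
  x$module_effect_sd <- as.list(x$module_effect_sd)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname simconfig-io
#' @export
readSimConfig <- function(path) {
  x <- yaml::read_yaml(path)
  modules <- lapply(x$modules, function(m)
    list(genes = as.integer(unlist(m$genes)), shifts = m$shifts))
  batches <- lapply(x$batch_offsets, function(b)
    list(offset = b$offset,
         genes = if (is.null(b$genes)) NULL else as.integer(unlist(b$genes))))
  simConfig(n_genes = x$n_genes,
            class_sizes = unlist(x$class_sizes),
            modules = modules,
            n_subtypes = unlist(x$n_subtypes),
            subtype_shift_sd = x$subtype_shift_sd,
            module_effect_sd = unlist(x$module_effect_sd),
            batch_offsets = batches,
            housekeeping_frac = x$housekeeping_frac,
            noise_sd = x$noise_sd, hk_noise_sd = x$hk_noise_sd,
            base_log2 = x$base_log2, seed = x$seed)
}
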