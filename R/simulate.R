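#' Simulation configuration for synthetic panel cohorts
#'
#' Describes a synthetic log2 expression cohort with the statistical
#' structure the downstream analyses assume: class-shifted gene modules,
#' within-class subtype heterogeneity, planted batches expressed partly
#' in low-variance genes, and a housekeeping block with near-zero
#' coefficient of variation.
#'
#' Gene indices are 1-based and must lie in \code{[1, n_genes]}. The
#' housekeeping block occupies the last \code{floor(housekeeping_frac *
#' n_genes)} genes and may not overlap any shifted module.
#'
#' @param n_genes number of genes.
#' @param class_sizes named integer vector over exactly the six
#'   diagnoses (see \code{\link{diagnosisLevels}}); all positive.
#' @param modules named list; each element is \code{list(genes =
#'   <integer indices>, shifts = <named numeric per-class log2 mean
#'   shift>)}. Classes absent from \code{shifts} shift by 0.
#' @param n_subtypes named integer vector per diagnosis: number of
#'   within-class mixture components (default 1 for all).
#' @param subtype_shift_sd SD (log2 units) of the per
#'   (class, subtype, module) mean shifts drawn for heterogeneity.
#' @param module_effect_sd SD (log2 units) of a continuous per
#'   (sample, module) random effect modelling the disease-severity /
#'   extent-of-involvement continuum within a class; either a scalar or
#'   a named per-class vector. 0 disables it (discrete mixtures only).
#' @param batch_offsets list; each element \code{list(offset = <log2>,
#'   genes = <indices or NULL for all genes>)}; one element per batch.
#' @param housekeeping_frac fraction of genes forming the housekeeping
#'   block.
#' @param noise_sd per-gene Gaussian noise SD in log2 units.
#' @param hk_noise_sd noise SD for housekeeping genes (near zero so
#'   their linear-scale CV stays small).
#' @param base_log2 baseline log2 intensity (linear intensities are
#'   \code{2^log2}, default base 2^7).
#' @param seed integer seed making generation deterministic.
#' @return A \code{SimConfig} list (validated).
#' @seealso \code{\link{simulateBhot}}, \code{\link{bhotFixtureConfig}}
#' @export
simConfig <- function(n_genes, class_sizes, modules = list(),
                      n_subtypes = NULL, subtype_shift_sd = 0.6,
                      module_effect_sd = 0,
                      batch_offsets = list(list(offset = 0, genes = NULL)),
                      housekeeping_frac = 0.06, noise_sd = 0.7,
                      hk_noise_sd = 0.02, base_log2 = 7, seed = 1L) {
  n_genes <- .assertScalarCount(n_genes, "n_genes")
  lv <- diagnosisLevels()
  if (!setequal(names(class_sizes), lv))
    stop("class_sizes must be named by exactly the six diagnoses: ",
         paste(lv, collapse = ", "), call. = FALSE)
  class_sizes <- vapply(lv, function(l)
    .assertScalarCount(class_sizes[[l]], paste0("class size ", l)),
    integer(1))
  if (is.null(n_subtypes)) n_subtypes <- stats::setNames(rep(1L, 6), lv)
  miss <- setdiff(lv, names(n_subtypes))
  n_subtypes <- c(n_subtypes, stats::setNames(rep(1L, length(miss)), miss))
  n_subtypes <- vapply(lv, function(l)
    .assertScalarCount(n_subtypes[[l]], paste0("n_subtypes ", l)), integer(1))
  n_hk <- as.integer(floor(housekeeping_frac * n_genes))
  hk_genes <- if (n_hk > 0) seq.int(n_genes - n_hk + 1L, n_genes) else integer()
  for (m in names(modules)) {
    g <- modules[[m]]$genes
    if (is.null(g) || any(g < 1 | g > n_genes | g != round(g)))
      stop("module '", m, "' has gene indices outside [1, n_genes]",
           call. = FALSE)
    if (length(intersect(g, hk_genes)))
      stop("module '", m, "' overlaps the housekeeping block; ",
           "housekeeping genes must belong to no shifted module",
           call. = FALSE)
    sh <- modules[[m]]$shifts
    if (length(setdiff(names(sh), lv)))
      stop("module '", m, "' shifts name unknown classes", call. = FALSE)
  }
  if (length(batch_offsets) < 1L)
    stop("at least one batch is required", call. = FALSE)
  for (b in batch_offsets) {
    if (!is.null(b$genes) &&
        any(b$genes < 1 | b$genes > n_genes | b$genes != round(b$genes)))
      stop("batch gene subset outside [1, n_genes]", call. = FALSE)
  }
  lv6 <- diagnosisLevels()
  if (length(module_effect_sd) == 1L && is.null(names(module_effect_sd)))
    module_effect_sd <- stats::setNames(rep(module_effect_sd, 6), lv6)
  miss_me <- setdiff(lv6, names(module_effect_sd))
  if (length(miss_me))
    stop("module_effect_sd must be a scalar or name every class",
         call. = FALSE)
  module_effect_sd <- module_effect_sd[lv6]
  if (any(module_effect_sd < 0))
    stop("module_effect_sd must be nonnegative", call. = FALSE)
  structure(list(
    n_genes = n_genes, class_sizes = class_sizes, modules = modules,
    n_subtypes = n_subtypes, subtype_shift_sd = subtype_shift_sd,
    module_effect_sd = module_effect_sd,
    batch_offsets = batch_offsets, housekeeping_frac = housekeeping_frac,
    hk_genes = hk_genes, noise_sd = noise_sd, hk_noise_sd = hk_noise_sd,
    base_log2 = base_log2, seed = as.integer(seed)
  ), class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf("SimConfig: %d genes, %d samples, %d modules, %d batches\n",
              x$n_genes, sum(x$class_sizes), length(x$modules),
              length(x$batch_offsets)))
  cat("class sizes:",
      paste(sprintf("%s=%d", names(x$class_sizes), x$class_sizes),
            collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic panel cohort with ground truth
#'
#' Draws a cohort from a \code{\link{simConfig}}: the log2 signal of
#' sample \eqn{s} in gene \eqn{g} is base + class-module shift +
#' subtype shift + batch offset + Gaussian noise, and the linear-scale
#' view is \code{2^log2}. Subtype mean shifts are drawn once per
#' (class, subtype, module) from \eqn{N(0, subtype\_shift\_sd^2)},
#' centered within each class (so the planted class-module means are
#' preserved exactly) and recorded in the ground truth, so mixture
#' means are known exactly.
#' Batch assignment is stratified within each diagnosis so batch is not
#' confounded with class. Identical seeds give identical output.
#'
#' @param config a \code{SimConfig}.
#' @return list with elements \code{dataset}
#'   (a \linkS4class{BhotExperiment} with diagnosis/subtype/batch in
#'   \code{colData} and module/housekeeping flags in \code{rowData}) and
#'   \code{truth} (samples table, genes table, planted per-class module
#'   means, subtype shifts, batch offsets).
#' @export
#' @examples
#' cfg <- bhotFixtureConfig(n_genes = 60, class_sizes = c(
#'   ABMR = 10, AKI = 6, MIXED = 6, TCMR = 8, NOREJECTION = 20, NORMAL = 5))
#' sim <- simulateBhot(cfg)
#' sim$dataset
simulateBhot <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  lv <- diagnosisLevels()
  n <- sum(config$class_sizes)
  p <- config$n_genes
  genes <- sprintf("g%04d", seq_len(p))
  samples <- sprintf("s%04d", seq_len(n))
  dx <- factor(rep(lv, config$class_sizes[lv]), levels = lv)
  mods <- config$modules
  gene_module <- rep(NA_character_, p)
  for (m in names(mods)) gene_module[mods[[m]]$genes] <- m
  hk <- seq_len(p) %in% config$hk_genes
  gene_module[hk] <- "housekeeping"

  nb <- length(config$batch_offsets)
  seeds <- .childSeeds(config$seed, 4L)

  # subtype and batch assignment, stratified within class
  subtype <- integer(n); bat <- integer(n)
  .withSeed(seeds[1], {
    for (l in lv) {
      idx <- which(dx == l)
      ns <- config$n_subtypes[[l]]
      subtype[idx] <- rep_len(seq_len(ns), length(idx))[sample.int(length(idx))]
      bat[idx] <- rep_len(seq_len(nb), length(idx))[sample.int(length(idx))]
    }
  })

  # planted subtype mean shifts: (class, subtype) x module
  subtype_shifts <- list()
  .withSeed(seeds[2], {
    for (l in lv) {
      ns <- config$n_subtypes[[l]]
      sh <- matrix(0, ns, length(mods),
                   dimnames = list(NULL, names(mods)))
      if (ns > 1L && length(mods)) {
        sh[] <- stats::rnorm(ns * length(mods), 0, config$subtype_shift_sd)
        # center within class so heterogeneity is purely within-class
        # and the planted class-module means stay exact
        sh <- sweep(sh, 2L, colMeans(sh))
      }
      subtype_shifts[[l]] <- sh
    }
  })

  # mean structure, genes x samples
  mu <- matrix(config$base_log2, p, n, dimnames = list(genes, samples))
  class_shift <- matrix(0, length(mods), 6,
                        dimnames = list(names(mods), lv))
  for (m in names(mods)) {
    sh <- mods[[m]]$shifts
    class_shift[m, names(sh)] <- unlist(sh)
  }
  # continuous per-(sample, module) severity effects
  effect_sd <- config$module_effect_sd[as.character(dx)]
  sample_effects <- .withSeed(seeds[4],
    matrix(stats::rnorm(n * length(mods), 0, rep(effect_sd,
                                                 length(mods))),
           n, length(mods), dimnames = list(samples, names(mods))))
  for (m in names(mods)) {
    gi <- mods[[m]]$genes
    shift_s <- class_shift[m, as.character(dx)] +
      vapply(seq_len(n), function(s)
        subtype_shifts[[as.character(dx[s])]][subtype[s], m], numeric(1)) +
      sample_effects[, m]
    mu[gi, ] <- mu[gi, ] + rep(shift_s, each = length(gi))
  }
  for (b in seq_len(nb)) {
    off <- config$batch_offsets[[b]]$offset
    gi <- config$batch_offsets[[b]]$genes
    if (is.null(gi)) gi <- seq_len(p)
    in_b <- bat == b
    if (off != 0 && any(in_b)) mu[gi, in_b] <- mu[gi, in_b] + off
  }

  sd_g <- ifelse(hk, config$hk_noise_sd, config$noise_sd)
  x <- .withSeed(seeds[3],
    mu + matrix(stats::rnorm(p * n, 0, rep(sd_g, n)), p, n))
  dimnames(x) <- list(genes, samples)

  ds <- BhotExperiment(
    x,
    colData = data.frame(diagnosis = dx, subtype = subtype, batch = bat,
                         series = "synthetic", row.names = samples),
    rowData = data.frame(module = gene_module, housekeeping = hk,
                         bhot = TRUE, row.names = genes),
    metadata = list(config = config))
  truth <- list(
    samples = data.frame(sample = samples, diagnosis = as.character(dx),
                         subtype = subtype, batch = bat),
    genes = data.frame(gene = genes, module = gene_module,
                       housekeeping = hk),
    class_module_means = class_shift,
    subtype_shifts = subtype_shifts,
    sample_module_effects = sample_effects,
    batch_offsets = vapply(config$batch_offsets, `[[`, numeric(1), "offset"),
    base_log2 = config$base_log2)
  list(dataset = ds, truth = truth)
}

#' Default synthetic cohort emulating the archival kidney cohorts
#'
#' Returns a \code{\link{simConfig}} whose defaults reproduce the study
#' conditions of the joined archival cohorts: 667 genes, 764 samples
#' with class sizes ABMR=105, AKI=28, MIXED=28, TCMR=67,
#' NOREJECTION=514, NORMAL=22; six shifted modules (inflammatory,
#' interferon, endothelial, injury, tubular, glomerular) whose per-class
#' mean shifts follow the expected immunopathology (inflammatory highest
#' in TCMR/MIXED, endothelial high in ABMR/MIXED, tubular high in
#' NORMAL, injury high in AKI); within-class mixtures (2 subtypes for
#' ABMR/AKI/MIXED/TCMR, 4 for the heterogeneous NOREJECTION class)
#' overlaid with a continuous per-sample module severity effect (1 log2
#' for allograft classes, 0.5 for the homogeneous native NORMAL class),
#' which makes diagnosis-level classification genuinely imperfect; a
#' housekeeping block (~6\% of genes) with near-zero CV; and 3 batches
#' whose scalar log2 offsets touch every gene but are small enough that
#' housekeeping genes keep a linear CV below 5\%.
#'
#' @param n_genes,class_sizes,noise_sd,subtype_shift_sd,module_effect_sd,seed
#'   overrides of the defaults above.
#' @param heterogeneity logical; \code{FALSE} collapses every class to a
#'   single subtype (no within-class mixture).
#' @param batch_offsets override of the per-batch log2 offsets
#'   (\code{NULL} genes = all genes).
#' @return A \code{SimConfig}.
#' @export
#' @examples
#' cfg <- bhotFixtureConfig()
#' cfg$class_sizes
bhotFixtureConfig <- function(n_genes = 667,
                              class_sizes = c(ABMR = 105, AKI = 28,
                                              MIXED = 28, TCMR = 67,
                                              NOREJECTION = 514,
                                              NORMAL = 22),
                              heterogeneity = TRUE, noise_sd = 0.7,
                              subtype_shift_sd = 1.6,
                              module_effect_sd = c(
                                ABMR = 1, AKI = 0.6, MIXED = 1.2,
                                NOREJECTION = 1, NORMAL = 0.4, TCMR = 1),
                              batch_offsets = list(
                                list(offset = 0, genes = NULL),
                                list(offset = 0.08, genes = NULL),
                                list(offset = -0.06, genes = NULL)),
                              seed = 20210319L) {
  # module spans scale with n_genes; proportions fixed
  sp <- function(a, b) {
    lo <- max(1L, ceiling(a * n_genes)); hi <- floor(b * n_genes)
    if (hi < lo) integer() else seq.int(lo, hi)
  }
  modules <- list(
    inflammatory = list(
      genes = sp(0.001, 0.12),
      shifts = list(ABMR = 0.6, AKI = 0.1, MIXED = 1.1, NOREJECTION = 0,
                    NORMAL = -0.8, TCMR = 1.5)),
    interferon = list(
      genes = sp(0.125, 0.18),
      shifts = list(ABMR = 0.8, AKI = 0.2, MIXED = 0.8, NOREJECTION = 0,
                    NORMAL = -0.6, TCMR = 0.8)),
    endothelial = list(
      genes = sp(0.185, 0.255),
      shifts = list(ABMR = 1.2, AKI = 0, MIXED = 0.95, NOREJECTION = 0,
                    NORMAL = -0.3, TCMR = 0.1)),
    injury = list(
      genes = sp(0.26, 0.33),
      shifts = list(ABMR = 0.3, AKI = 2.2, MIXED = 0.4, NOREJECTION = 0.1,
                    NORMAL = -0.8, TCMR = 0.4)),
    tubular = list(
      genes = sp(0.335, 0.42),
      shifts = list(ABMR = -0.2, AKI = -0.8, MIXED = -0.3, NOREJECTION = 0,
                    NORMAL = 1.6, TCMR = -0.3)),
    glomerular = list(
      genes = sp(0.425, 0.465),
      shifts = list(ABMR = -0.3, AKI = -0.2, MIXED = -0.2, NOREJECTION = 0,
                    NORMAL = 1.2, TCMR = -0.1)))
  n_subtypes <- if (heterogeneity)
    c(ABMR = 2L, AKI = 2L, MIXED = 2L, TCMR = 2L, NOREJECTION = 4L,
      NORMAL = 1L)
  else
    c(ABMR = 1L, AKI = 1L, MIXED = 1L, TCMR = 1L, NOREJECTION = 1L,
      NORMAL = 1L)
  simConfig(n_genes = n_genes, class_sizes = class_sizes,
            modules = modules, n_subtypes = n_subtypes,
            subtype_shift_sd = subtype_shift_sd,
            module_effect_sd = module_effect_sd,
            batch_offsets = batch_offsets, housekeeping_frac = 0.06,
            noise_sd = noise_sd, seed = seed)
}

#' Gene-set catalog of a simulated cohort's planted modules
#'
#' Builds a \linkS4class{GeneSetCatalog} whose sets are the shifted
#' modules of a \code{SimConfig} (plus the housekeeping block), for use
#' as the gene-set input of \code{\link{deriveCPPC}} and
#' \code{\link{loadingReport}} on synthetic cohorts.
#'
#' @param config a \code{SimConfig}.
#' @return A \linkS4class{GeneSetCatalog}.
#' @export
fixtureCatalog <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  sets <- lapply(config$modules, function(m) genes[m$genes])
  src <- rep("custom", length(sets))
  if (length(config$hk_genes)) {
    sets$housekeeping <- genes[config$hk_genes]
    src <- c(src, "housekeeping")
  }
  GeneSetCatalog(sets, source = src)
}
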