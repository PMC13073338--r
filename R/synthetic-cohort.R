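#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated multi-stratum case-control
#' plasma-omics cohort: genotype strata of configurable size, a case fraction,
#' age confounding (cases older on average), two collection batches with an
#' additive log10 shift, log-normal analyte abundances, and planted per-SD
#' log-odds effects that are shared across strata, stratum-specific, or
#' opposite-signed between the first two strata.
#'
#' @param strata Character vector of stratum labels. The first two strata are
#'   the designated pair for opposite-signed effects.
#' @param n_samples_per_stratum Integer, scalar or one per stratum.
#' @param case_fraction Proportion of cases per stratum, in (0, 1).
#' @param n_analytes Number of analytes.
#' @param frac_shared_effects,frac_stratum_specific,frac_opposite Proportions
#'   of analytes carrying each planted effect class; must sum to at most 1.
#' @param effect_size_logodds Planted effect, log-odds of case status per
#'   standard deviation of the analyte (realised as a case-minus-control mean
#'   shift of \code{effect_size_logodds * noise_sd} on the log10 scale).
#' @param age_mean_case,age_mean_control Mean age (years) by status.
#' @param age_sd Age standard deviation (years).
#' @param batch_shift Additive offset on the log10 scale applied to batch 2.
#' @param noise_sd Residual standard deviation of log10 abundance.
#' @param missing_rate Missing-completely-at-random rate, in [0, 1).
#' @param seed Integer seed; all generator output is deterministic given it.
#' @return A validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(strata = c("33", "34", "44", "2x"),
                             n_samples_per_stratum = c(400L, 160L, 50L, 80L),
                             case_fraction = 0.45,
                             n_analytes = 1000L,
                             frac_shared_effects = 0.10,
                             frac_stratum_specific = 0.01,
                             frac_opposite = 0.01,
                             effect_size_logodds = 0.8,
                             age_mean_case = 75,
                             age_mean_control = 70,
                             age_sd = 8,
                             batch_shift = 0.1,
                             noise_sd = 0.25,
                             missing_rate = 0,
                             seed = 1L) {
  if (length(strata) < 1L) stop("configuration error: need at least one stratum")
  if (length(n_samples_per_stratum) == 1L) {
    n_samples_per_stratum <- rep(n_samples_per_stratum, length(strata))
  }
  if (length(n_samples_per_stratum) != length(strata)) {
    stop("configuration error: n_samples_per_stratum must be scalar or one per stratum")
  }
  if (any(n_samples_per_stratum < 1L)) stop("configuration error: non-positive n_samples_per_stratum")
  if (n_analytes < 1L) stop("configuration error: non-positive n_analytes")
  if (case_fraction <= 0 || case_fraction >= 1) stop("configuration error: case_fraction outside (0,1)")
  fr <- c(frac_shared_effects, frac_stratum_specific, frac_opposite)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("configuration error: effect fractions must lie in [0,1] and sum to at most 1")
  }
  if (effect_size_logodds < 0) stop("configuration error: effect_size_logodds must be positive")
  if (missing_rate < 0 || missing_rate >= 1) stop("configuration error: missing_rate outside [0,1)")
  if (noise_sd <= 0) stop("configuration error: noise_sd must be positive")
  structure(list(
    strata = as.character(strata),
    n_samples_per_stratum = as.integer(n_samples_per_stratum),
    case_fraction = case_fraction,
    n_analytes = as.integer(n_analytes),
    frac_shared_effects = frac_shared_effects,
    frac_stratum_specific = frac_stratum_specific,
    frac_opposite = frac_opposite,
    effect_size_logodds = effect_size_logodds,
    age_mean_case = age_mean_case,
    age_mean_control = age_mean_control,
    age_sd = age_sd,
    batch_shift = batch_shift,
    noise_sd = noise_sd,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic stratified case-control cohort
#'
#' Abundances follow \code{log10(x) ~ Normal(baseline + batch_shift * [batch 2]
#' + delta * [case], noise_sd)} with \code{delta = effect * noise_sd}, so the
#' planted coefficient is the log-odds of case status per analyte SD
#' (the linear-discriminant identity: slope = shift / SD^2 on the raw log10
#' scale, i.e. \code{effect} per SD). Shared effects carry identical
#' coefficients in every stratum; stratum-specific effects are non-zero in one
#' stratum; opposite effects flip sign between the first two strata. Cases are
#' drawn older than controls so that age adjustment is non-trivial; sex is
#' balanced; batches split each stratum about 50/50.
#'
#' @param config A [synthetic_config()].
#' @return A list of class \code{synthetic_cohort} with elements
#'   \code{matrix} (raw positive abundances, analytes x samples),
#'   \code{meta} (sample metadata data frame), \code{truth} (per-analyte effect
#'   class and per-stratum planted coefficient), and \code{config}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  m <- config$n_analytes
  strata <- config$strata
  analyte_id <- sprintf("APT%05d", seq_len(m))

  n_sh <- round(config$frac_shared_effects * m)
  n_sp <- round(config$frac_stratum_specific * m)
  n_op <- if (length(strata) >= 2L) round(config$frac_opposite * m) else 0L
  class_vec <- rep("null", m)
  class_vec[seq_len(n_sh)] <- "shared"
  if (n_sp > 0L) class_vec[n_sh + seq_len(n_sp)] <- "specific"
  if (n_op > 0L) class_vec[n_sh + n_sp + seq_len(n_op)] <- "opposite"

  eff <- config$effect_size_logodds
  coef <- matrix(0, nrow = m, ncol = length(strata),
                 dimnames = list(analyte_id, strata))
  sgn <- sample(c(-1, 1), m, replace = TRUE)
  for (i in which(class_vec == "shared")) coef[i, ] <- sgn[i] * eff
  for (i in which(class_vec == "specific")) {
    coef[i, sample(length(strata), 1L)] <- sgn[i] * eff
  }
  for (i in which(class_vec == "opposite")) {
    coef[i, 1L] <- sgn[i] * eff
    coef[i, 2L] <- -sgn[i] * eff
  }

  meta_list <- vector("list", length(strata))
  for (s in seq_along(strata)) {
    ns <- config$n_samples_per_stratum[s]
    n_case <- round(config$case_fraction * ns)
    status <- sample(rep(c("AD", "CO"), c(n_case, ns - n_case)))
    age <- stats::rnorm(ns,
                        ifelse(status == "AD", config$age_mean_case, config$age_mean_control),
                        config$age_sd)
    sex <- sample(rep(c("M", "F"), length.out = ns))
    batch <- sample(rep(1:2, length.out = ns))
    meta_list[[s]] <- data.frame(
      sample_id = sprintf("S%s_%04d", strata[s], seq_len(ns)),
      status = status, age = round(age, 1L), sex = sex,
      stratum = strata[s], batch = batch, dataset = paste0("ds", batch),
      stringsAsFactors = FALSE
    )
  }
  meta <- do.call(rbind, meta_list)
  rownames(meta) <- NULL
  n <- nrow(meta)

  baseline <- stats::rnorm(m, 3, 0.5)
  delta <- coef * config$noise_sd               # mean shift on the log10 scale
  is_case <- as.numeric(meta$status == "AD")
  stratum_idx <- match(meta$stratum, strata)
  log10_mat <- matrix(baseline, nrow = m, ncol = n) +
    matrix(config$batch_shift * (meta$batch == 2L), nrow = m, ncol = n, byrow = TRUE) +
    delta[, stratum_idx, drop = FALSE] * matrix(is_case, nrow = m, ncol = n, byrow = TRUE) +
    matrix(stats::rnorm(m * n, 0, config$noise_sd), nrow = m, ncol = n)
  mat <- 10^log10_mat
  dimnames(mat) <- list(analyte_id, meta$sample_id)
  if (config$missing_rate > 0) {
    mat[stats::runif(m * n) < config$missing_rate] <- NA_real_
  }

  truth <- data.frame(analyte_id = analyte_id, class = class_vec,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, stats::setNames(as.data.frame(coef), paste0("coef_", strata)))
  rownames(truth) <- NULL

  structure(list(matrix = mat, meta = meta, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' Generate annotations, gene sets, cell-type reference and interactome
#'
#' Builds every annotation resource the downstream stages consume, closed over
#' the cohort's analyte universe: an aptamer-to-gene map (a small fraction of
#' genes carry two aptamers, as on real aptamer panels), metabolite-style
#' super-/sub-pathway labels, a GMT-style gene-set collection with set sizes
#' spanning [5, 600] (so the GO size window is exercised) plus one planted set
#' holding 80\% of the shared-effect genes, a cell-type reference of mean
#' expression over \code{n_cell_types} types, and a connected undirected
#' interactome (random spanning tree plus extra edges) over all analyte genes
#' and connector nodes.
#'
#' @param cohort A \code{synthetic_cohort} from [generate_cohort()].
#' @param n_cell_types Number of reference cell types (default 13).
#' @param n_gene_sets Number of random gene sets in the collection.
#' @param n_connectors Number of non-analyte connector nodes in the interactome.
#' @return A list with \code{annotation} (data frame: analyte_id, gene,
#'   super_pathway, sub_pathway), \code{gene_sets}, \code{celltype_ref}
#'   (genes x cell types matrix), and \code{ppi} (igraph).
#' @export
generate_annotations <- function(cohort, n_cell_types = 13L, n_gene_sets = 20L,
                                 n_connectors = 50L) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop("state error: generate_annotations requires a cohort from generate_cohort()")
  }
  config <- cohort$config
  set.seed(config$seed + 1L)
  analyte_id <- rownames(cohort$matrix)
  m <- length(analyte_id)

  # aptamer -> gene map; ~5% of genes get a second aptamer
  n_genes <- max(1L, ceiling(m * 0.95))
  gene_pool <- sprintf("G%05d", seq_len(n_genes))
  gene_idx <- c(seq_len(min(m, n_genes)),
                if (m > n_genes) sample.int(n_genes, m - n_genes, replace = FALSE))
  gene <- gene_pool[gene_idx]

  supers <- c("Lipid", "Amino Acid", "Peptide", "Xenobiotics",
              "Nucleotide", "Carbohydrate", "Cofactors and Vitamins", "Energy")
  super_pathway <- sample(supers, m, replace = TRUE)
  sub_pathway <- paste0(super_pathway, " sub-", sample.int(4L, m, replace = TRUE))
  annotation <- data.frame(analyte_id = analyte_id, gene = gene,
                           super_pathway = super_pathway, sub_pathway = sub_pathway,
                           stringsAsFactors = FALSE)

  connectors <- sprintf("CONN%03d", seq_len(n_connectors))
  universe <- c(unique(gene), connectors)

  # gene sets: log-spaced sizes in [5, 600], capped at the universe
  max_size <- min(600L, length(universe))
  sizes <- unique(round(exp(seq(log(5), log(max_size), length.out = n_gene_sets))))
  gene_sets <- lapply(sizes, function(sz) sample(universe, sz))
  names(gene_sets) <- sprintf("SET%03d", seq_along(gene_sets))
  shared_genes <- unique(annotation$gene[cohort$truth$class == "shared"])
  if (length(shared_genes) >= 2L) {
    take <- sample(shared_genes, max(1L, round(0.8 * length(shared_genes))))
    pad <- sample(setdiff(universe, take), min(5L, length(universe) - length(take)))
    gene_sets[["SET_PLANTED_SHARED"]] <- c(take, pad)
  }
  attr(gene_sets, "description") <- stats::setNames(
    rep("synthetic gene set", length(gene_sets)), names(gene_sets))
  class(gene_sets) <- "gene_set_collection"

  cell_types <- c("Stem Cell", "Mast Cell", "Hematopoietic Precursor Cell",
                  "Lymphocyte", "Mononuclear Cell", "T Cell", "Monocyte",
                  "Glial Cell", "B Cell", "Erythrocyte", "Hepatocyte",
                  "Myeloid Leukocyte", "Dendritic Cell")
  if (n_cell_types <= length(cell_types)) {
    cell_types <- cell_types[seq_len(n_cell_types)]
  } else {
    cell_types <- c(cell_types,
                    sprintf("Cell Type %02d", seq_len(n_cell_types - length(cell_types))))
  }
  genes_u <- unique(gene)
  ref <- matrix(stats::rgamma(length(genes_u) * n_cell_types, shape = 2, rate = 1),
                nrow = length(genes_u), dimnames = list(genes_u, cell_types))
  specific <- stats::runif(length(genes_u)) < 0.5
  dom <- sample.int(n_cell_types, length(genes_u), replace = TRUE)
  for (i in which(specific)) {
    ref[i, dom[i]] <- 2 * max(ref[i, ]) # dominant type at >= 2x the runner-up
  }

  # interactome: random spanning tree over genes + connectors, plus extra edges
  nv <- length(universe)
  parent <- vapply(2:nv, function(i) sample.int(i - 1L, 1L), integer(1L))
  edges <- cbind(universe[parent], universe[2:nv])
  extra <- cbind(sample(universe, nv, replace = TRUE), sample(universe, nv, replace = TRUE))
  extra <- extra[extra[, 1L] != extra[, 2L], , drop = FALSE]
  ppi <- igraph::simplify(igraph::graph_from_edgelist(rbind(edges, extra), directed = FALSE))

  list(annotation = annotation, gene_sets = gene_sets,
       celltype_ref = ref, ppi = ppi)
}

#' Generate a quality-control fixture with planted violations
#'
#' Builds an abundance matrix (60 aptamers x 100 samples) plus the auxiliary
#' buffer, calibration and CV tables, in which exactly three aptamers or
#' samples violate each QC criterion and nothing else does:
#' \itemize{
#'   \item criterion 1 - three aptamers with 20\% of samples below the buffer
#'     mean + 2 SD (but inside their own IQR fences);
#'   \item criterion 2 - three aptamers whose plate-1 calibration factor sits
#'     0.7 above the plate median;
#'   \item criterion 3 - three aptamers with replicate CVs of 0.30;
#'   \item criterion 4 - three aptamers with 20\% of log10 values far outside
#'     the 1.5 x IQR fences;
#'   \item criterion 5 - three samples in which >15\% of the remaining aptamers
#'     are displaced beyond their fences;
#'   \item criterion 6 - three aptamers whose fence violations occur in all
#'     three of those outlier samples (a 100\% >= 80\% share).
#' }
#'
#' @param config A [synthetic_config()]; only its seed is used (the fixture's
#'   dimensions are fixed so the planted arithmetic stays exact).
#' @return A list with \code{matrix} (raw abundances), \code{buffer_stats},
#'   \code{calib} (aptamers x plates), \code{cv} (aptamers x replicates), and
#'   \code{truth} (data frame: entity, type, criterion).
#' @export
generate_qc_fixture <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  n_apt <- 60L
  n_samp <- 100L
  apt <- sprintf("QAPT%03d", seq_len(n_apt))
  smp <- sprintf("QS%03d", seq_len(n_samp))

  lg <- matrix(3 + stats::rnorm(n_apt * n_samp, 0, 0.05),
               nrow = n_apt, dimnames = list(apt, smp))

  buffer_stats <- data.frame(analyte_id = apt, buffer_mean = 20, buffer_sd = 5,
                             stringsAsFactors = FALSE)
  calib <- matrix(1, nrow = n_apt, ncol = 4L,
                  dimnames = list(apt, paste0("plate", 1:4)))
  cv <- matrix(0.05, nrow = n_apt, ncol = 5L,
               dimnames = list(apt, paste0("rep", 1:5)))

  # evenly spaced normal quantiles: a deterministic "spread" with sd ~ s
  spread <- function(n, mu, s) mu + s * stats::qnorm(seq(0.5 / n, 1 - 0.5 / n, length.out = n))

  # criterion 1: wide aptamers with a 20% low-signal tail under buffer+2SD
  for (i in 1:3) {
    lg[i, ] <- c(rep(2.0, 20L), spread(80L, 3, 0.3))
    buffer_stats$buffer_mean[i] <- 80
    buffer_stats$buffer_sd[i] <- 20           # threshold 120 raw = 10^2.079
  }
  # criterion 2: calibration factor 0.7 off the plate median
  calib[4:6, 1L] <- 1.7
  # criterion 3: replicate CVs of 0.30
  cv[7:9, ] <- 0.30
  # criterion 4: 20% of values far above the fences
  for (i in 10:12) lg[i, ] <- c(spread(80L, 3, 0.05), rep(4.5, 20L))

  # criterion 5 samples + criterion 6 shared aptamers
  out_samples <- 1:3
  shared_apts <- 13:15
  unique_apts <- list(16:23, 24:31, 32:39)
  for (k in seq_along(out_samples)) {
    s <- out_samples[k]
    lg[shared_apts, s] <- lg[shared_apts, s] + 1.0
    lg[unique_apts[[k]], s] <- lg[unique_apts[[k]], s] + 1.0
  }

  truth <- rbind(
    data.frame(entity = apt[1:3], type = "aptamer", criterion = 1L),
    data.frame(entity = apt[4:6], type = "aptamer", criterion = 2L),
    data.frame(entity = apt[7:9], type = "aptamer", criterion = 3L),
    data.frame(entity = apt[10:12], type = "aptamer", criterion = 4L),
    data.frame(entity = smp[out_samples], type = "sample", criterion = 5L),
    data.frame(entity = apt[shared_apts], type = "aptamer", criterion = 6L)
  )
  rownames(truth) <- NULL

  list(matrix = 10^lg, buffer_stats = buffer_stats, calib = calib, cv = cv,
       truth = truth)
}
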