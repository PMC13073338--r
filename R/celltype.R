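#' Assign genes to cell types by the 1.5x dominance rule
#'
#' For each gene, the proportional contribution of each reference cell type is
#' its mean expression divided by the gene's total over all types. The gene is
#' assigned to its top cell type when that proportion is at least 1.5 times
#' the second-highest proportion (inclusive; equivalent to the same rule on
#' raw means, since the row total cancels); otherwise, and for all-zero rows
#' and tied maxima, it is unassigned.
#'
#' @param reference Nonnegative genes x cell-types matrix of mean expression
#'   (row and column names required).
#' @param dominance_ratio Dominance multiplier (default 1.5).
#' @return Named character vector: cell type per gene, \code{NA} = unassigned.
#' @export
assign_cell_specificity <- function(reference, dominance_ratio = 1.5) {
  stopifnot(is.matrix(reference), ncol(reference) >= 2L)
  if (any(reference < 0, na.rm = TRUE)) stop("negative entry in cell-type reference")
  out <- rep(NA_character_, nrow(reference))
  names(out) <- rownames(reference)
  tot <- rowSums(reference)
  for (i in which(tot > 0)) {
    prop <- reference[i, ] / tot[i]
    o <- order(prop, decreasing = TRUE)
    top <- prop[o[1L]]; second <- prop[o[2L]]
    if (top >= dominance_ratio * second && top > second) {
      out[i] <- colnames(reference)[o[1L]]
    }
  }
  out
}

#' Cell-type fold enrichment of a differentially-expressed gene set
#'
#' Per cell type t, the log2 ratio of the share of the DEP genes assigned to t
#' over the share of the background genes assigned to t. When either count is
#' zero, 0.5 is added to both counts (numerator and denominator) to keep the
#' estimate finite and sign-correct.
#'
#' @param dep_genes Character vector of hit genes; subset of
#'   \code{background}.
#' @param assignments Named vector from [assign_cell_specificity()], covering
#'   the background.
#' @param background Character vector, the gene universe.
#' @return Data frame: \code{cell_type, n_dep, n_background,
#'   log2_fold_enrichment}.
#' @export
celltype_fold_enrichment <- function(dep_genes, assignments, background) {
  if (length(dep_genes) == 0L) stop("empty DEP gene set")
  dep_genes <- unique(dep_genes)
  background <- unique(background)
  if (!all(dep_genes %in% background)) stop("dep_genes must be a subset of background")
  types <- sort(unique(stats::na.omit(assignments)))
  a_dep <- assignments[dep_genes]
  a_bg <- assignments[background]
  out <- lapply(types, function(t) {
    nd <- sum(a_dep == t, na.rm = TRUE)
    nb <- sum(a_bg == t, na.rm = TRUE)
    num <- nd; den <- nb
    if (nd == 0L || nb == 0L) { num <- nd + 0.5; den <- nb + 0.5 }
    fe <- log2((num / length(dep_genes)) / (den / length(background)))
    data.frame(cell_type = t, n_dep = nd, n_background = nb,
               log2_fold_enrichment = fe, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
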