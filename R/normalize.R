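#' log10-transform a raw abundance matrix
#'
#' @param mat Raw abundance matrix; all non-missing values must be strictly
#'   positive. Missing values are preserved.
#' @return Matrix of log10 abundances.
#' @export
log10_normalize <- function(mat) {
  bad <- which(!is.na(mat) & mat <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-positive abundance for analyte '%s', sample '%s'",
                 rownames(mat)[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]]))
  }
  log10(mat)
}

#' Remove additive batch effects from a log10 matrix
#'
#' Fits, per analyte, an additive linear model of the log10 value on the batch
#' factor (sum-to-zero coding) and subtracts the estimated batch terms, so the
#' grand mean is preserved and per-batch means agree after removal in the
#' balanced case. Delegates to \code{limma::removeBatchEffect}, the standard
#' tool for this adjustment on log-scale omics matrices. A single batch level
#' returns the input unchanged.
#'
#' @param mat Matrix of log10 abundances (analytes x samples).
#' @param batch Per-sample batch labels, length \code{ncol(mat)}.
#' @return Batch-adjusted matrix of the same shape.
#' @export
remove_batch_effect <- function(mat, batch) {
  if (length(batch) != ncol(mat)) stop("batch labels must match the sample columns")
  batch <- factor(batch)
  small <- table(batch) < 2L
  if (any(small)) {
    stop("batch level(s) with fewer than 2 samples: ",
         paste(names(which(small)), collapse = ", "))
  }
  if (nlevels(batch) == 1L) return(mat)
  out <- limma::removeBatchEffect(mat, batch = batch)
  dimnames(out) <- dimnames(mat)
  out
}

#' Merge normalized datasets and optionally standardize per dataset
#'
#' Column-concatenates a list of log10 matrices on their common analyte set
#' (the intersection, with a message when analytes are dropped). With
#' \code{zscore = TRUE} each analyte is centered and scaled within each source
#' dataset using the sample standard deviation (divisor n-1), the convention
#' used when effect sizes are to be read per analyte SD.
#'
#' @param matrices List of log10 matrices sharing (a subset of) analytes.
#' @param zscore Standardize per analyte within each source dataset?
#' @return Merged matrix on the analyte intersection.
#' @export
merge_and_standardize <- function(matrices, zscore = FALSE) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) == 0L) stop("empty analyte intersection across datasets")
  dropped <- sum(vapply(matrices, nrow, integer(1L))) - length(common) * length(matrices)
  if (dropped > 0L) message(dropped, " analyte row(s) outside the intersection dropped")
  pieces <- lapply(matrices, function(m) {
    m <- m[common, , drop = FALSE]
    if (zscore) {
      mu <- rowMeans(m, na.rm = TRUE)
      sd <- apply(m, 1L, stats::sd, na.rm = TRUE)
      degenerate <- !is.na(sd) & sd == 0
      if (any(degenerate)) {
        stop("zero-variance analyte(s) under z-scoring: ",
             paste(common[degenerate][seq_len(min(3L, sum(degenerate)))], collapse = ", "))
      }
      m <- (m - mu) / sd
    }
    m
  })
  do.call(cbind, pieces)
}
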