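#' Quality-control thresholds for the six-step aptamer/sample filter
#'
#' Defaults follow the standard aptamer-panel outlier criteria: an aptamer is
#' an outlier when (1) more than 15\% of samples fall below the dilution-buffer
#' mean + 2 SD, (2) its calibration factor deviates from the plate median by
#' more than 0.5 on any plate, (3) its median replicate CV exceeds 0.15, or
#' (4) more than 15\% of its log10 values fall outside 1.5 x IQR fences; a
#' sample is an outlier when (5) more than 15\% of its aptamer values fall
#' outside those fences; finally (6) any remaining aptamer whose fence
#' violations are shared by at least 80\% of the flagged outlier samples is
#' removed.
#'
#' @param low_signal_sample_frac Criterion-1 sample fraction (default 0.15).
#' @param buffer_sd_mult Buffer SD multiplier (default 2).
#' @param calib_max_diff Criterion-2 maximum calibration deviation (default 0.5).
#' @param cv_max Criterion-3 maximum median CV (default 0.15).
#' @param iqr_mult IQR fence multiplier (default 1.5).
#' @param iqr_sample_frac Criterion-4/5 fraction outside fences (default 0.15).
#' @param shared_outlier_frac Criterion-6 shared-violation share (default 0.80).
#' @return A list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(low_signal_sample_frac = 0.15, buffer_sd_mult = 2,
                          calib_max_diff = 0.5, cv_max = 0.15, iqr_mult = 1.5,
                          iqr_sample_frac = 0.15, shared_outlier_frac = 0.80) {
  th <- list(low_signal_sample_frac = low_signal_sample_frac,
             buffer_sd_mult = buffer_sd_mult, calib_max_diff = calib_max_diff,
             cv_max = cv_max, iqr_mult = iqr_mult,
             iqr_sample_frac = iqr_sample_frac,
             shared_outlier_frac = shared_outlier_frac)
  if (any(unlist(th) <= 0)) stop("all QC thresholds must be positive")
  structure(th, class = "qc_thresholds")
}

# per-aptamer 1.5xIQR fences on log10 values (type-7 quartiles, NAs dropped)
.iqr_fences <- function(mat, iqr_mult) {
  lg <- log10(mat)
  q <- t(apply(lg, 1L, stats::quantile, probs = c(0.25, 0.75), na.rm = TRUE,
               type = 7L, names = FALSE))
  iqr <- q[, 2L] - q[, 1L]
  list(log10 = lg, lo = q[, 1L] - iqr_mult * iqr, hi = q[, 2L] + iqr_mult * iqr)
}

# logical matrix: value outside its aptamer's fences (NA preserved)
.fence_violations <- function(mat, iqr_mult) {
  f <- .iqr_fences(mat, iqr_mult)
  f$log10 < f$lo | f$log10 > f$hi
}

#' Evaluate the aptamer-level QC criteria (1-4)
#'
#' All four criteria are evaluated on the full, unfiltered matrix; missing
#' values are excluded from every fraction's denominator. Criteria that need
#' vendor auxiliary tables (buffer, calibration, replicate CV) are skipped with
#' a warning when the table is absent, since public matrices rarely ship them.
#'
#' @param mat Raw abundance matrix (analytes x samples), strictly positive
#'   where non-missing.
#' @param buffer_stats Data frame \code{analyte_id, buffer_mean, buffer_sd}
#'   (raw scale), or \code{NULL} to skip criterion 1.
#' @param calib Aptamer x plate matrix of calibration factors, or \code{NULL}.
#' @param cv Aptamer x replicate matrix of CVs, or \code{NULL}.
#' @param thresholds A [qc_thresholds()].
#' @return Data frame with columns \code{analyte_id, crit1, crit2, crit3,
#'   crit4}; skipped criteria are \code{NA}.
#' @export
evaluate_aptamer_criteria <- function(mat, buffer_stats = NULL, calib = NULL,
                                      cv = NULL, thresholds = qc_thresholds()) {
  if (ncol(mat) < 4L) stop("IQR criteria undefined: matrix has fewer than 4 samples")
  th <- thresholds
  ids <- rownames(mat)
  out <- data.frame(analyte_id = ids, crit1 = NA, crit2 = NA, crit3 = NA,
                    crit4 = NA, stringsAsFactors = FALSE)

  if (is.null(buffer_stats)) {
    warning("buffer table absent; criterion 1 (low signal) skipped")
  } else {
    idx <- match(ids, buffer_stats$analyte_id)
    if (anyNA(idx)) warning("buffer table missing entries; criterion 1 NA for those aptamers")
    thr <- buffer_stats$buffer_mean[idx] + th$buffer_sd_mult * buffer_stats$buffer_sd[idx]
    frac <- rowMeans(mat < thr, na.rm = TRUE)
    out$crit1 <- frac > th$low_signal_sample_frac
    out$crit1[is.na(idx)] <- NA
  }

  if (is.null(calib)) {
    warning("calibration table absent; criterion 2 skipped")
  } else {
    plate_med <- apply(calib, 2L, stats::median, na.rm = TRUE)
    dev <- apply(abs(sweep(calib, 2L, plate_med)), 1L, max, na.rm = TRUE)
    idx <- match(ids, rownames(calib))
    if (anyNA(idx)) warning("calibration table missing entries; criterion 2 NA for those aptamers")
    out$crit2 <- (dev[idx] > th$calib_max_diff)
  }

  if (is.null(cv)) {
    warning("CV table absent; criterion 3 skipped")
  } else {
    med_cv <- apply(cv, 1L, stats::median, na.rm = TRUE)
    idx <- match(ids, rownames(cv))
    if (anyNA(idx)) warning("CV table missing entries; criterion 3 NA for those aptamers")
    out$crit3 <- (med_cv[idx] > th$cv_max)
  }

  viol <- .fence_violations(mat, th$iqr_mult)
  out$crit4 <- rowMeans(viol, na.rm = TRUE) > th$iqr_sample_frac
  out
}

#' Evaluate the sample-level QC criterion (5)
#'
#' A sample is flagged when more than \code{iqr_sample_frac} of its non-missing
#' aptamer values fall outside the per-aptamer 1.5 x IQR fences computed on
#' log10 values.
#'
#' @inheritParams evaluate_aptamer_criteria
#' @return Data frame with columns \code{sample_id, crit5}.
#' @export
evaluate_sample_criteria <- function(mat, thresholds = qc_thresholds()) {
  if (ncol(mat) < 4L) stop("IQR criteria undefined: matrix has fewer than 4 samples")
  empty <- colSums(!is.na(mat)) == 0L
  if (any(empty)) {
    stop("sample(s) with no non-missing values: ",
         paste(colnames(mat)[empty], collapse = ", "))
  }
  viol <- .fence_violations(mat, thresholds$iqr_mult)
  data.frame(sample_id = colnames(mat),
             crit5 = colMeans(viol, na.rm = TRUE) > thresholds$iqr_sample_frac,
             stringsAsFactors = FALSE)
}

#' Run the full six-step QC filter chain
#'
#' Criteria are applied in order: aptamer criteria 1-4 on the full matrix
#' (each flagged aptamer is bucketed under its first triggering criterion),
#' sample criterion 5 on the aptamer-filtered matrix, then criterion 6 removes
#' any remaining aptamer whose fence violations occur in at least
#' \code{shared_outlier_frac} of the flagged outlier samples.
#'
#' @inheritParams evaluate_aptamer_criteria
#' @return A list with \code{matrix} (filtered), and \code{report}: per-aptamer
#'   flags and removal reason, per-sample flags, surviving counts per step, and
#'   the thresholds used.
#' @export
run_qc <- function(mat, buffer_stats = NULL, calib = NULL, cv = NULL,
                   thresholds = qc_thresholds()) {
  apt_flags <- evaluate_aptamer_criteria(mat, buffer_stats, calib, cv, thresholds)
  flag14 <- as.matrix(apt_flags[, c("crit1", "crit2", "crit3", "crit4")])
  flag14[is.na(flag14)] <- FALSE
  reason <- apply(flag14, 1L, function(f) if (any(f)) which(f)[1L] else NA_integer_)
  apt_flags$reason <- reason

  keep_apt <- is.na(reason)
  counts <- c(input = nrow(mat))
  for (k in 1:4) counts[paste0("after_crit", k)] <-
    sum(is.na(reason) | reason > k)
  mat2 <- mat[keep_apt, , drop = FALSE]
  if (nrow(mat2) == 0L) stop("QC removed everything")

  samp_flags <- evaluate_sample_criteria(mat2, thresholds)
  out_samples <- samp_flags$sample_id[samp_flags$crit5]

  apt_flags$crit6 <- FALSE
  if (length(out_samples) > 0L) {
    viol <- .fence_violations(mat2, thresholds$iqr_mult)
    share <- rowMeans(viol[, out_samples, drop = FALSE], na.rm = TRUE)
    crit6 <- !is.na(share) & share >= thresholds$shared_outlier_frac
    apt_flags$crit6[match(rownames(mat2)[crit6], apt_flags$analyte_id)] <- TRUE
    apt_flags$reason[apt_flags$crit6 & is.na(apt_flags$reason)] <- 6L
  }

  keep_apt_final <- is.na(apt_flags$reason)
  keep_smp <- !(colnames(mat) %in% out_samples)
  counts["after_crit5_samples"] <- sum(keep_smp)
  counts["after_crit6"] <- sum(keep_apt_final)
  filtered <- mat[keep_apt_final, keep_smp, drop = FALSE]
  if (nrow(filtered) == 0L) stop("QC removed everything")

  list(matrix = filtered,
       report = list(aptamer = apt_flags, sample = samp_flags,
                     counts = counts, thresholds = thresholds))
}
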