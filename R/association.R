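#' Split a cohort into discovery and replication halves
#'
#' Random 50/50 split stratified by (stratum x status), so that within each
#' stratum the case and control counts differ by at most 1 between halves.
#' Odd groups put the extra sample in the discovery half. Strata with fewer
#' than 2 cases or 2 controls are excluded with a warning (split \code{NA}).
#'
#' @param meta Sample metadata data frame (columns \code{sample_id, status,
#'   stratum}; status coded AD/CO).
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return Data frame \code{sample_id, stratum, status, split} with
#'   \code{split} in \{"discovery", "replication", NA\}.
#' @export
split_cohort <- function(meta, seed) {
  stopifnot(all(c("sample_id", "status", "stratum") %in% names(meta)))
  set.seed(as.integer(seed))
  out <- data.frame(sample_id = meta$sample_id, stratum = meta$stratum,
                    status = meta$status, split = NA_character_,
                    stringsAsFactors = FALSE)
  for (s in sort(unique(meta$stratum))) {
    in_s <- meta$stratum == s
    if (sum(in_s & meta$status == "AD") < 2L || sum(in_s & meta$status == "CO") < 2L) {
      warning("stratum '", s, "' has <2 cases or <2 controls; excluded from split")
      next
    }
    for (st in c("AD", "CO")) {
      idx <- which(in_s & meta$status == st)
      idx <- sample(idx)
      n_disc <- ceiling(length(idx) / 2)
      out$split[idx[seq_len(n_disc)]] <- "discovery"
      out$split[idx[-seq_len(n_disc)]] <- "replication"
    }
  }
  out
}

# one age/sex-adjusted fit of a single analyte; returns beta/se/p for the
# analyte term.  logistic: status ~ age + sex + analyte (Wald, dispersion 1);
# linear: analyte ~ status + age + sex (t-based p).
.fit_one <- function(value, y, covars, model, maxit = 100L) {
  keep <- !is.na(value)
  value <- value[keep]; y <- y[keep]
  covars <- covars[keep, , drop = FALSE]
  n <- length(value)
  res <- c(beta = NA_real_, se = NA_real_, p = NA_real_,
           n_used = n, converged = 0)
  if (n < 10L) stop("fewer than 10 usable samples after casewise deletion")
  if (length(unique(y)) < 2L) stop("one outcome class absent")
  if (stats::var(value) == 0) return(res)   # zero-variance analyte: unconverged

  if (model == "logistic") {
    X <- cbind(`(Intercept)` = 1, covars, analyte = value)
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = stats::glm.control(maxit = maxit)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    j <- ncol(X)
    beta <- fit$coefficients[j]
    if (!fit$converged || sep || is.na(beta) || abs(beta) > 50) {
      res["beta"] <- beta
      return(res)
    }
    p1 <- seq_len(fit$rank)
    covmat <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
    se <- sqrt(diag(covmat))[which(colnames(X)[fit$qr$pivot[p1]] == "analyte")]
    res["beta"] <- beta
    res["se"] <- se
    res["p"] <- 2 * stats::pnorm(-abs(beta / se))
    res["converged"] <- 1
  } else {
    X <- cbind(`(Intercept)` = 1, status = y, covars)
    fit <- stats::lm.fit(X, value)
    if (fit$rank < ncol(X)) return(res)
    rdf <- n - fit$rank
    if (rdf < 1L) return(res)
    sigma2 <- sum(fit$residuals^2) / rdf
    R <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
    covmat <- chol2inv(R) * sigma2
    beta <- fit$coefficients["status"]
    se <- sqrt(diag(covmat))[which(colnames(X)[fit$qr$pivot] == "status")]
    res["beta"] <- beta
    res["se"] <- se
    res["p"] <- 2 * stats::pt(-abs(beta / se), rdf)
    res["converged"] <- 1
  }
  res
}

.covar_matrix <- function(meta, covariates) {
  cols <- list()
  if ("age" %in% covariates) cols$age <- meta$age
  if ("sex" %in% covariates) cols$sex <- as.numeric(meta$sex == "M")
  if (length(cols) == 0L) {
    return(matrix(numeric(0), nrow = nrow(meta), ncol = 0L))
  }
  do.call(cbind, cols)
}

#' Fit one analyte's case-control association
#'
#' The primary model is logistic regression of disease status on age, sex and
#' the analyte value (the reported coefficient is the log-odds per unit
#' analyte, with a two-sided Wald p-value); the linear sensitivity model
#' regresses the analyte on status, age and sex (coefficient = adjusted
#' case-minus-control mean difference). Samples with a missing analyte value
#' are dropped casewise. Non-convergence, separation, or an absurd coefficient
#' (|beta| > 50) yields \code{converged = FALSE} with a missing p-value.
#'
#' @param values Numeric vector of normalized analyte values, one per sample
#'   in \code{meta} (same order).
#' @param meta Sample metadata with columns \code{status, age, sex}.
#' @param model \code{"logistic"} (default) or \code{"linear"}.
#' @param covariates Covariates to adjust for (subset of \code{c("age","sex")}).
#' @param stage Stage label stored in the result.
#' @return One-row data frame: \code{stage, model, beta, se, p, n_used,
#'   converged}.
#' @export
fit_association <- function(values, meta, model = c("logistic", "linear"),
                            covariates = c("age", "sex"), stage = "discovery") {
  model <- match.arg(model)
  stopifnot(length(values) == nrow(meta))
  y <- as.numeric(meta$status == "AD")
  covars <- .covar_matrix(meta, covariates)
  r <- .fit_one(values, y, covars, model)
  data.frame(stage = stage, model = model, beta = unname(r["beta"]),
             se = unname(r["se"]), p = unname(r["p"]),
             n_used = as.integer(r["n_used"]), converged = r["converged"] == 1,
             stringsAsFactors = FALSE)
}

#' Fit every analyte of a matrix against case-control status
#'
#' Row-wise driver for [fit_association()]; analytes whose fit violates a
#' precondition (one outcome class, too few usable samples) are returned as
#' unconverged rows rather than aborting the scan.
#'
#' @param mat Normalized analyte x sample matrix.
#' @param meta Sample metadata, one row per column of \code{mat} (same order).
#' @inheritParams fit_association
#' @return Data frame with one row per analyte: \code{analyte_id, stage,
#'   model, beta, se, p, n_used, converged}.
#' @export
associate_all <- function(mat, meta, model = c("logistic", "linear"),
                          covariates = c("age", "sex"), stage = "discovery") {
  model <- match.arg(model)
  stopifnot(ncol(mat) == nrow(meta))
  y <- as.numeric(meta$status == "AD")
  covars <- .covar_matrix(meta, covariates)
  res <- matrix(NA_real_, nrow = nrow(mat), ncol = 5L,
                dimnames = list(NULL, c("beta", "se", "p", "n_used", "converged")))
  for (i in seq_len(nrow(mat))) {
    r <- tryCatch(.fit_one(mat[i, ], y, covars, model),
                  error = function(e) c(beta = NA_real_, se = NA_real_,
                                        p = NA_real_, n_used = NA_real_,
                                        converged = 0))
    res[i, ] <- r
  }
  data.frame(analyte_id = rownames(mat), stage = stage, model = model,
             beta = res[, "beta"], se = res[, "se"], p = res[, "p"],
             n_used = as.integer(res[, "n_used"]),
             converged = res[, "converged"] == 1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Joint analysis of the pooled stratum
#'
#' Same model as [fit_association()] fitted on all samples of the stratum
#' (discovery and replication pooled), used as a sensitivity comparator for
#' the split + meta-analysis route.
#'
#' @inheritParams associate_all
#' @return As [associate_all()], with \code{stage = "joint"}.
#' @export
joint_analysis <- function(mat, meta, model = c("logistic", "linear"),
                           covariates = c("age", "sex")) {
  associate_all(mat, meta, model = match.arg(model), covariates = covariates,
                stage = "joint")
}

#' Inverse-variance-weighted fixed-effect meta-analysis of two stages
#'
#' For each analyte with both stages converged, pools the discovery and
#' replication estimates with weights \code{w = 1/se^2}:
#' \code{beta_pooled = sum(w * beta) / sum(w)},
#' \code{se_pooled = sqrt(1 / sum(w))}, a chi-squared statistic
#' \code{(beta_pooled / se_pooled)^2} on 1 df, and its upper-tail p-value.
#'
#' @param disc,rep Stage results (data frames from [associate_all()], matched
#'   by \code{analyte_id}).
#' @return Data frame per analyte: stage betas/SEs/p-values, \code{beta_pooled,
#'   se_pooled, chi2, p_meta}; analytes unconverged in either stage get
#'   missing pooled fields.
#' @export
ivw_meta <- function(disc, rep) {
  ids <- disc$analyte_id
  j <- match(ids, rep$analyte_id)
  if (anyNA(j)) stop("replication results missing analytes present in discovery")
  rep <- rep[j, ]
  ok <- disc$converged & rep$converged & !is.na(disc$se) & !is.na(rep$se) &
    disc$se > 0 & rep$se > 0
  w1 <- 1 / disc$se^2
  w2 <- 1 / rep$se^2
  beta_pooled <- (w1 * disc$beta + w2 * rep$beta) / (w1 + w2)
  se_pooled <- sqrt(1 / (w1 + w2))
  chi2 <- (beta_pooled / se_pooled)^2
  p_meta <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  beta_pooled[!ok] <- se_pooled[!ok] <- chi2[!ok] <- p_meta[!ok] <- NA_real_
  data.frame(analyte_id = ids,
             beta_disc = disc$beta, se_disc = disc$se, p_disc = disc$p,
             beta_rep = rep$beta, se_rep = rep$se, p_rep = rep$p,
             beta_pooled = beta_pooled, se_pooled = se_pooled,
             chi2 = chi2, p_meta = p_meta,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment (via [stats::p.adjust()]); missing entries are
#' excluded from the family and returned missing.
#'
#' @param p Numeric vector of p-values in (0, 1]; \code{NA} allowed.
#' @return Vector of adjusted values, order preserved.
#' @export
bh_fdr <- function(p) {
  bad <- !is.na(p) & (p <= 0 | p > 1)
  if (any(bad)) stop("p-value(s) outside (0, 1]: ", p[which(bad)[1L]])
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Call differentially expressed analytes
#'
#' An analyte is called when the discovery and replication p-values are both
#' at most \code{alpha}, the BH FDR of the meta p-value (computed within the
#' supplied family) is at most \code{fdr}, and the two stage coefficients
#' agree in sign; direction is the sign of the pooled effect.
#'
#' @param meta_results Data frame from [ivw_meta()] for one
#'   stratum-by-model family.
#' @param alpha Stage-level significance threshold (default 0.05).
#' @param fdr Meta-analysis FDR threshold (default 0.05).
#' @return \code{meta_results} with added columns \code{fdr, called,
#'   direction}.
#' @export
call_analytes <- function(meta_results, alpha = 0.05, fdr = 0.05) {
  mr <- meta_results
  mr$fdr <- bh_fdr(mr$p_meta)
  called <- !is.na(mr$p_disc) & !is.na(mr$p_rep) & !is.na(mr$fdr) &
    mr$p_disc <= alpha & mr$p_rep <= alpha & mr$fdr <= fdr &
    sign(mr$beta_disc) == sign(mr$beta_rep)
  mr$called <- called
  mr$direction <- ifelse(is.na(mr$beta_pooled), NA_character_,
                         ifelse(mr$beta_pooled > 0, "up", "down"))
  mr
}

#' Concordance between two association result sets
#'
#' Summarizes agreement between two analysis routes (e.g. logistic vs linear,
#' or meta vs joint): direction agreement over the analytes called in the
#' first set (all common analytes if no \code{called} column is present),
#' Pearson correlation of effect sizes, and the R-squared of the
#' \code{-log10(p)} values, both over analytes finite in both sets.
#'
#' @param setA,setB Data frames with columns \code{analyte_id, beta, p}
#'   (pooled columns \code{beta_pooled}/\code{p_meta} are used when present);
#'   \code{setA} may carry a \code{called} column.
#' @return List: \code{direction_agreement}, \code{pearson_r},
#'   \code{r2_neglog10p}, \code{n_called}, \code{n_common}.
#' @export
sensitivity_concordance <- function(setA, setB) {
  get_beta <- function(d) if ("beta_pooled" %in% names(d)) d$beta_pooled else d$beta
  get_p <- function(d) if ("p_meta" %in% names(d)) d$p_meta else d$p
  common <- intersect(setA$analyte_id, setB$analyte_id)
  if (length(common) < 3L) stop("fewer than 3 common analytes")
  ia <- match(common, setA$analyte_id)
  ib <- match(common, setB$analyte_id)
  ba <- get_beta(setA)[ia]; bb <- get_beta(setB)[ib]
  pa <- get_p(setA)[ia]; pb <- get_p(setB)[ib]
  called <- if ("called" %in% names(setA)) setA$called[ia] else rep(TRUE, length(ia))
  called <- !is.na(called) & called & !is.na(ba) & !is.na(bb)
  agree <- if (any(called)) mean(sign(ba[called]) == sign(bb[called])) else NA_real_
  fin <- is.finite(ba) & is.finite(bb)
  r <- stats::cor(ba[fin], bb[fin])
  lp <- is.finite(-log10(pa)) & is.finite(-log10(pb))
  r2 <- stats::cor(-log10(pa[lp]), -log10(pb[lp]))^2
  list(direction_agreement = agree, pearson_r = r, r2_neglog10p = r2,
       n_called = sum(called), n_common = length(common))
}

#' Stratified discovery/replication meta-analysis of a cohort
#'
#' The package's central fit: for each genotype stratum, splits samples into
#' discovery and replication halves (stratified by status), fits the
#' age/sex-adjusted association for every analyte in each half, pools the two
#' estimates by inverse-variance-weighted fixed-effect meta-analysis, adjusts
#' the meta p-values by Benjamini-Hochberg within the stratum, and calls
#' analytes significant when both stage p-values, the FDR, and the
#' direction-agreement criterion all pass.
#'
#' @param mat Normalized analyte x sample matrix.
#' @param meta Sample metadata (one row per column of \code{mat}, same order;
#'   columns \code{sample_id, status, age, sex, stratum}).
#' @param model \code{"logistic"} (primary) or \code{"linear"} (sensitivity).
#' @param alpha Stage significance threshold.
#' @param fdr Meta FDR threshold.
#' @param seed Seed for the discovery/replication split.
#' @param strata Strata to analyse (default: all in \code{meta}).
#' @return An object of class \code{dep_meta}: per-stratum result tables
#'   (see [call_analytes()]), the split assignment, and the call parameters.
#'   Methods: \code{print}, \code{summary}, \code{coef}, \code{plot}.
#' @export
dep_meta <- function(mat, meta, model = c("logistic", "linear"),
                     alpha = 0.05, fdr = 0.05, seed = 1L, strata = NULL) {
  model <- match.arg(model)
  stopifnot(ncol(mat) == nrow(meta))
  if (is.null(strata)) strata <- sort(unique(meta$stratum))
  split <- split_cohort(meta[meta$stratum %in% strata, , drop = FALSE], seed)
  results <- list()
  for (s in strata) {
    in_s <- meta$stratum == s
    sp <- split$split[match(meta$sample_id[in_s], split$sample_id)]
    if (all(is.na(sp))) next
    m_s <- mat[, in_s, drop = FALSE]
    meta_s <- meta[in_s, , drop = FALSE]
    disc <- associate_all(m_s[, sp == "discovery", drop = FALSE],
                          meta_s[sp == "discovery", , drop = FALSE],
                          model = model, stage = "discovery")
    rep_ <- associate_all(m_s[, sp == "replication", drop = FALSE],
                          meta_s[sp == "replication", , drop = FALSE],
                          model = model, stage = "replication")
    pooled <- call_analytes(ivw_meta(disc, rep_), alpha = alpha, fdr = fdr)
    pooled <- cbind(stratum = s, pooled, stringsAsFactors = FALSE)
    results[[s]] <- pooled
  }
  structure(list(results = results, split = split, model = model,
                 alpha = alpha, fdr = fdr, seed = seed,
                 call = match.call()),
            class = "dep_meta")
}

#' @export
print.dep_meta <- function(x, ...) {
  cat("Stratified discovery/replication IVW meta-analysis (", x$model,
      " model)\n", sep = "")
  print(summary(x))
  invisible(x)
}

#' @export
summary.dep_meta <- function(object, ...) {
  rows <- lapply(object$results, function(r) {
    data.frame(stratum = r$stratum[1L], n_analytes = nrow(r),
               n_converged = sum(!is.na(r$p_meta)),
               n_called = sum(r$called, na.rm = TRUE),
               up = sum(r$called & r$direction == "up", na.rm = TRUE),
               down = sum(r$called & r$direction == "down", na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
coef.dep_meta <- function(object, ...) {
  strata <- names(object$results)
  ids <- object$results[[1L]]$analyte_id
  out <- sapply(object$results, function(r) r$beta_pooled[match(ids, r$analyte_id)])
  rownames(out) <- ids
  out
}

#' Volcano plot of the pooled meta-analysis results
#' @param x A \code{dep_meta} object.
#' @param stratum Stratum to plot (default: first).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dep_meta <- function(x, stratum = names(x$results)[1L], ...) {
  r <- x$results[[stratum]]
  cols <- ifelse(r$called, "firebrick", "grey50")
  graphics::plot(r$beta_pooled, -log10(r$p_meta), col = cols, pch = 16,
                 cex = 0.6, xlab = "pooled effect size",
                 ylab = expression(-log[10](p[meta])),
                 main = paste0("stratum ", stratum), ...)
  graphics::abline(h = -log10(x$alpha), lty = 2, col = "grey70")
  invisible(x)
}
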