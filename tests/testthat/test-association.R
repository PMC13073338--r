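test_that("split_cohort balances case/control counts within each half", {
  meta <- data.frame(sample_id = sprintf("s%02d", 1:20),
                     status = rep(c("AD", "CO"), each = 10),
                     stratum = "33")
  sp <- split_cohort(meta, seed = 5)
  tab <- table(sp$status, sp$split)
  expect_true(all(tab == 5))

  expect_identical(split_cohort(meta, seed = 5), sp)  # deterministic

  meta21 <- rbind(meta, data.frame(sample_id = "s21", status = "AD", stratum = "33"))
  sp21 <- split_cohort(meta21, seed = 5)
  counts <- table(sp21$status, sp21$split)["AD", ]
  expect_setequal(as.integer(counts), c(6L, 5L))      # odd group splits 6/5

  tiny <- data.frame(sample_id = c("a", "b", "c"),
                     status = c("AD", "CO", "CO"), stratum = "44")
  expect_warning(sp0 <- split_cohort(tiny, seed = 1), "excluded")
  expect_true(all(is.na(sp0$split)))
})

test_that("fit_association recovers symmetry, flags separation and degeneracy", {
  # symmetric design: analyte carries no status information -> beta = 0
  meta <- tiny_meta(rep(c("CO", "CO", "AD", "AD"), 5))
  vals <- rep(c(-1, 1, -1, 1), 5)
  fit <- fit_association(vals, meta, covariates = character(0))
  expect_equal(fit$beta, 0, tolerance = 1e-8)
  expect_true(fit$converged)

  # analyte identical to the status indicator -> perfect separation
  meta2 <- tiny_meta(rep(c("AD", "CO"), each = 10))
  sep <- fit_association(as.numeric(meta2$status == "AD"), meta2,
                         covariates = character(0))
  expect_false(sep$converged)
  expect_true(is.na(sep$p))

  # zero-variance analyte
  zv <- fit_association(rep(1, 20), meta2)
  expect_false(zv$converged)

  # one outcome class absent
  meta3 <- tiny_meta(rep("AD", 20))
  expect_error(fit_association(rnorm(20), meta3), "one outcome class")

  # casewise deletion leaves too few samples
  vals4 <- c(rnorm(5), rep(NA, 15))
  expect_error(fit_association(vals4, meta2), "fewer than 10")
})

test_that("logistic beta matches an independent optimizer of the likelihood", {
  set.seed(31)
  n <- 60
  meta <- tiny_meta(sample(rep(c("AD", "CO"), each = n / 2)),
                    age = rnorm(n, 72, 6), sex = sample(c("M", "F"), n, TRUE))
  vals <- rnorm(n) + 0.8 * (meta$status == "AD")
  fit <- fit_association(vals, meta)

  X <- cbind(1, meta$age, as.numeric(meta$sex == "M"), vals)
  y <- as.numeric(meta$status == "AD")
  opt <- optim(rep(0, 4), neg_loglik_logistic, X = X, y = y,
               method = "BFGS", control = list(reltol = 1e-14, maxit = 500))
  expect_equal(fit$beta, opt$par[4], tolerance = 1e-4)
})

test_that("linear sensitivity model returns the adjusted mean difference", {
  set.seed(32)
  n <- 80
  meta <- tiny_meta(sample(rep(c("AD", "CO"), each = n / 2)),
                    age = rnorm(n, 72, 6), sex = sample(c("M", "F"), n, TRUE))
  vals <- 0.5 * (meta$status == "AD") + 0.01 * meta$age + rnorm(n, 0, 0.3)
  fit <- fit_association(vals, meta, model = "linear")
  ref <- summary(lm(vals ~ I(meta$status == "AD") + meta$age +
                      I(meta$sex == "M")))$coefficients[2, ]
  expect_equal(fit$beta, unname(ref[1]))
  expect_equal(fit$se, unname(ref[2]))
  expect_equal(fit$p, unname(ref[4]))
})

test_that("IVW pooling reproduces its closed form and the symmetric limits", {
  mk <- function(beta, se) data.frame(analyte_id = "a", beta = beta, se = se,
                                      p = 0.05, converged = TRUE)
  # equal inputs: pooled = b, se/sqrt(2)
  m <- ivw_meta(mk(0.4, 0.1), mk(0.4, 0.1))
  expect_equal(m$beta_pooled, 0.4)
  expect_equal(m$se_pooled, 0.1 / sqrt(2))

  # worked example: w = (25, 100)
  m2 <- ivw_meta(mk(0.5, 0.2), mk(0.3, 0.1))
  expect_equal(m2$beta_pooled, 0.34)
  expect_equal(m2$se_pooled, sqrt(1 / 125))
  expect_equal(m2$chi2, 0.34^2 * 125)
  expect_equal(m2$p_meta, pchisq(0.34^2 * 125, 1, lower.tail = FALSE))

  # null point
  m3 <- ivw_meta(mk(0, 0.1), mk(0, 0.2))
  expect_equal(m3$chi2, 0)
  expect_equal(m3$p_meta, 1)

  # unconverged stage -> missing meta
  bad <- mk(0.5, 0.2); bad$converged <- FALSE
  expect_true(is.na(ivw_meta(bad, mk(0.3, 0.1))$p_meta))
})

test_that("IVW pooling agrees with metafor's fixed-effect model", {
  skip_if_not_installed("metafor")
  set.seed(33)
  for (i in 1:20) {
    b <- rnorm(2); s <- runif(2, 0.05, 0.5)
    m <- ivw_meta(data.frame(analyte_id = "a", beta = b[1], se = s[1],
                             p = 0.5, converged = TRUE),
                  data.frame(analyte_id = "a", beta = b[2], se = s[2],
                             p = 0.5, converged = TRUE))
    rma <- metafor::rma(yi = b, sei = s, method = "FE")
    expect_equal(m$beta_pooled, as.numeric(rma$beta), tolerance = 1e-10)
    expect_equal(m$se_pooled, rma$se, tolerance = 1e-10)
  }
})

test_that("shrinking one stage's SE pulls the pooled estimate toward it", {
  mk <- function(beta, se) data.frame(analyte_id = "a", beta = beta, se = se,
                                      p = 0.05, converged = TRUE)
  pooled <- function(s1) ivw_meta(mk(1, s1), mk(0, 0.2))$beta_pooled
  ses <- c(0.4, 0.2, 0.1, 0.05)
  vals <- vapply(ses, pooled, numeric(1))
  expect_true(all(diff(vals) > 0))       # monotone toward beta = 1
})

test_that("BH adjustment matches the hand step-up and handles edge cases", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(0.37), 0.37)                    # single p unchanged
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))      # all ties: p*m/m
  expect_equal(bh_fdr(c(0.01, NA, 0.04)), c(0.02, NA, 0.04))
  expect_error(bh_fdr(c(0.5, 0)), "outside")
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
})

test_that("DEP calling applies the three-criterion conjunction with sign check", {
  base <- data.frame(analyte_id = "a", beta_disc = 0.5, se_disc = 0.1,
                     p_disc = 0.04, beta_rep = 0.4, se_rep = 0.1, p_rep = 0.03,
                     beta_pooled = 0.45, se_pooled = 0.07, chi2 = 40,
                     p_meta = 0.04)
  expect_true(call_analytes(base)$called)
  expect_identical(call_analytes(base)$direction, "up")

  flip <- base; flip$beta_rep <- -0.4
  expect_false(call_analytes(flip)$called)             # sign disagreement

  border <- base; border$p_meta <- 0.051               # fdr = 0.051 > 0.05
  expect_false(call_analytes(border)$called)

  disc <- base; disc$p_disc <- 0.06
  expect_false(call_analytes(disc)$called)
})

test_that("joint analysis equals the stage fit when halves are identical", {
  set.seed(34)
  meta <- tiny_meta(rep(c("AD", "CO"), each = 15),
                    age = rnorm(30, 72, 5), sex = sample(c("M", "F"), 30, TRUE))
  mat <- matrix(rnorm(2 * 30), nrow = 2,
                dimnames = list(c("A1", "A2"), meta$sample_id))
  half <- associate_all(mat, meta, stage = "discovery")
  meta2 <- rbind(meta, meta)
  meta2$sample_id <- make.unique(meta2$sample_id)
  joint <- joint_analysis(cbind(mat, mat), meta2)
  expect_equal(joint$beta, half$beta, tolerance = 1e-6)
})

test_that("sensitivity concordance has the right fixed points", {
  set.seed(35)
  a <- data.frame(analyte_id = paste0("A", 1:10), beta = rnorm(10),
                  p = runif(10), called = rep(c(TRUE, FALSE), 5))
  cc <- sensitivity_concordance(a, a)
  expect_equal(cc$direction_agreement, 1)
  expect_equal(cc$pearson_r, 1)
  expect_equal(cc$r2_neglog10p, 1)
  expect_equal(cc$n_called, 5)

  b <- a; b$beta <- -a$beta
  cc2 <- sensitivity_concordance(a, b)
  expect_equal(cc2$direction_agreement, 0)
  expect_equal(cc2$pearson_r, -1)

  expect_error(sensitivity_concordance(a[1:2, ], a[1:2, ]), "fewer than 3")
})

test_that("dep_meta object exposes print, summary and coef methods", {
  cfg <- synthetic_config(strata = c("33", "34"),
                          n_samples_per_stratum = c(80L, 80L),
                          n_analytes = 30L, frac_shared_effects = 0.2,
                          frac_stratum_specific = 0, frac_opposite = 0,
                          seed = 9)
  co <- generate_cohort(cfg)
  fit <- dep_meta(normalize_cohort(co), co$meta, seed = 10)
  s <- summary(fit)
  expect_identical(s$stratum, c("33", "34"))
  expect_equal(s$n_called, s$up + s$down)
  cf <- coef(fit)
  expect_identical(dim(cf), c(30L, 2L))
  expect_output(print(fit), "IVW meta-analysis")
})
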