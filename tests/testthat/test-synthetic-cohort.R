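test_that("generator output has the promised cohort structure", {
  cfg <- synthetic_config(strata = c("33", "34", "44"),
                          n_samples_per_stratum = c(60L, 41L, 30L),
                          case_fraction = 0.4, n_analytes = 50L,
                          frac_shared_effects = 0.2, frac_stratum_specific = 0.1,
                          frac_opposite = 0.1, missing_rate = 0.05, seed = 71)
  co <- generate_cohort(cfg)
  expect_true(all(co$matrix > 0, na.rm = TRUE))          # raw scale positive
  expect_gt(mean(is.na(co$matrix)), 0.03)                # MCAR applied

  for (s in cfg$strata) {
    in_s <- co$meta$stratum == s
    n_s <- sum(in_s)
    expect_lte(abs(sum(co$meta$status[in_s] == "AD") - 0.4 * n_s), 1)
    expect_lte(abs(sum(co$meta$batch[in_s] == 1) - n_s / 2), 1)  # ~50/50 batches
  }
  # age confounding: cases about 5 years older
  gap <- mean(co$meta$age[co$meta$status == "AD"]) -
    mean(co$meta$age[co$meta$status == "CO"])
  expect_gt(gap, 2)

  tr <- co$truth
  shared <- tr[tr$class == "shared", grep("^coef_", names(tr))]
  expect_true(all(apply(shared, 1, function(r) length(unique(r)) == 1)))
  opp <- tr[tr$class == "opposite", ]
  expect_true(all(opp$coef_33 == -opp$coef_34))
  expect_true(all(abs(opp$coef_33) > 0))
  spec <- tr[tr$class == "specific", grep("^coef_", names(tr))]
  expect_true(all(rowSums(spec != 0) == 1))
  expect_true(all(tr[tr$class == "null", grep("^coef_", names(tr))] == 0))
})

test_that("all three generator operations are deterministic under a seed", {
  cfg <- synthetic_config(n_analytes = 40L, strata = c("33", "34"),
                          n_samples_per_stratum = c(30L, 30L), seed = 7)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1, co2)
  a1 <- generate_annotations(co1)
  a2 <- generate_annotations(co2)
  expect_identical(a1$annotation, a2$annotation)
  expect_identical(igraph::as_edgelist(a1$ppi), igraph::as_edgelist(a2$ppi))
  expect_identical(generate_qc_fixture(cfg), generate_qc_fixture(cfg))
})

test_that("configuration errors are rejected up front", {
  expect_error(synthetic_config(n_analytes = 0L), "configuration error")
  expect_error(synthetic_config(n_samples_per_stratum = -5L), "configuration error")
  expect_error(synthetic_config(frac_shared_effects = 0.8,
                                frac_stratum_specific = 0.3), "sum to at most 1")
  expect_error(synthetic_config(case_fraction = 1.2), "case_fraction")
  expect_error(generate_annotations(list()), "state error")
})

test_that("annotation resources have the advertised shapes", {
  cfg <- synthetic_config(n_analytes = 300L, strata = c("33", "34"),
                          n_samples_per_stratum = c(30L, 30L), seed = 72)
  co <- generate_cohort(cfg)
  ann <- generate_annotations(co)
  expect_identical(ann$annotation$analyte_id, rownames(co$matrix))
  expect_true(all(table(ann$annotation$super_pathway) > 0))
  expect_equal(ncol(ann$celltype_ref), 13)               # default cell-type count
  expect_true(all(ann$celltype_ref >= 0))
  expect_true(igraph::is_connected(ann$ppi))
  expect_false(igraph::any_loop(ann$ppi))
  expect_true(all(unique(ann$annotation$gene) %in% igraph::V(ann$ppi)$name))
  sizes <- lengths(ann$gene_sets)
  expect_lte(min(sizes), 10)                             # spans the GO window
  expect_gte(max(sizes), 300)
})

test_that("QC fixture truth matches its construction", {
  fx <- generate_qc_fixture(synthetic_config(seed = 73))
  # planted high-CV aptamers are listed under criterion 3
  cv_apts <- fx$truth$entity[fx$truth$criterion == 3]
  expect_equal(length(cv_apts), 3)
  expect_true(all(apply(fx$cv[cv_apts, ], 1, median) > 0.15))
  # a clean aptamer is absent from the truth table
  clean <- setdiff(rownames(fx$matrix), fx$truth$entity)[1]
  expect_false(clean %in% fx$truth$entity)
  expect_true(all(fx$matrix > 0))
})

test_that("planted shared effects are recovered by the pooled meta-analysis", {
  cfg <- synthetic_config(strata = c("33", "34"),
                          n_samples_per_stratum = c(600L, 600L),
                          case_fraction = 0.5, n_analytes = 60L,
                          frac_shared_effects = 50 / 60,
                          frac_stratum_specific = 0, frac_opposite = 0,
                          effect_size_logodds = 0.8, seed = 74)
  co <- generate_cohort(cfg)
  # fit on the log10/batch-adjusted scale; one analyte SD = noise_sd there,
  # so beta * noise_sd estimates the planted per-SD log-odds
  fit <- dep_meta(normalize_cohort(co, zscore = FALSE), co$meta, seed = 75)
  shared <- co$truth$analyte_id[co$truth$class == "shared"]
  est <- cov <- sgn <- NULL
  for (s in c("33", "34")) {
    r <- fit$results[[s]]
    i <- match(shared, r$analyte_id)
    planted <- co$truth[match(shared, co$truth$analyte_id), paste0("coef_", s)]
    b <- r$beta_pooled[i] * cfg$noise_sd
    se <- r$se_pooled[i] * cfg$noise_sd
    est <- c(est, b * sign(planted))
    cov <- c(cov, planted >= b - 1.96 * se & planted <= b + 1.96 * se)
    sgn <- c(sgn, sign(r$beta_pooled[i]) == sign(planted))
  }
  expect_lt(abs(mean(est) - 0.8), 0.1)    # mean pooled estimate near truth
  expect_gte(mean(cov), 0.90)             # 95% CIs cover the planted effect
  expect_gte(mean(sgn), 0.95)             # sign recovery
})
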