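test_that("aptamer criteria fire at their documented thresholds", {
  set.seed(11)
  n <- 100L
  lg <- matrix(3 + rnorm(4 * n, 0, 0.05), nrow = 4,
               dimnames = list(paste0("A", 1:4), paste0("s", 1:n)))
  # A1: 20% of samples below buffer mean + 2 SD; A2: only 10%
  lg[1, 1:20] <- 2.0
  lg[2, 1:10] <- 2.0
  buffer <- data.frame(analyte_id = paste0("A", 1:4),
                       buffer_mean = c(80, 80, 20, 20),
                       buffer_sd = c(20, 20, 5, 5))
  cv <- matrix(c(0.30, 0.10, 0.05, 0.05), nrow = 4, ncol = 3,
               dimnames = list(paste0("A", 1:4), NULL))
  calib <- matrix(1, nrow = 4, ncol = 2, dimnames = list(paste0("A", 1:4), NULL))
  calib[4, 1] <- 1.6
  flags <- evaluate_aptamer_criteria(10^lg, buffer, calib, cv)
  expect_true(flags$crit1[1])           # 0.20 > 0.15
  expect_false(flags$crit1[2])          # 0.10 <= 0.15
  expect_true(flags$crit3[1])           # median CV 0.30 > 0.15
  expect_false(flags$crit3[2])          # median CV 0.10
  expect_true(flags$crit2[4])           # calibration 0.6 off plate median
  expect_false(flags$crit2[1])
})

test_that("a 3% IQR-violation rate does not trip the aptamer fence criterion", {
  vals <- c(rep(1, 97), rep(1000, 3))
  mat <- matrix(rep(vals, 2), nrow = 2, byrow = TRUE,
                dimnames = list(c("A1", "A2"), paste0("s", 1:100)))
  flags <- suppressWarnings(evaluate_aptamer_criteria(mat))
  # fences collapse to [0,0] around log10(1); 3/100 outside is under 15%
  expect_false(any(flags$crit4))
})

test_that("sample criterion flags samples with >15% fence violations", {
  set.seed(12)
  n_apt <- 50L
  mat <- matrix(3 + rnorm(n_apt * 40, 0, 0.05), nrow = n_apt,
                dimnames = list(paste0("A", 1:n_apt), paste0("s", 1:40)))
  mat[1:8, 1] <- 5                       # 16% of aptamers displaced in s1
  flags <- evaluate_sample_criteria(10^mat)
  expect_true(flags$crit5[flags$sample_id == "s1"])
  expect_false(any(flags$crit5[flags$sample_id != "s1"]))

  mat[, 2] <- NA
  expect_error(evaluate_sample_criteria(10^mat), "s2")
})

test_that("run_qc is the identity on a clean matrix and errors on tiny input", {
  set.seed(13)
  mat <- 10^matrix(3 + rnorm(20 * 50, 0, 0.05), nrow = 20,
                   dimnames = list(paste0("A", 1:20), paste0("s", 1:50)))
  qc <- suppressWarnings(run_qc(mat))
  expect_identical(qc$matrix, mat)
  expect_true(all(is.na(qc$report$aptamer$reason)))

  expect_error(evaluate_aptamer_criteria(mat[, 1:3]), "fewer than 4 samples")
})

test_that("run_qc recovers every planted flag of the QC fixture exactly", {
  fx <- generate_qc_fixture(synthetic_config(seed = 3))
  qc <- suppressWarnings(run_qc(fx$matrix, fx$buffer_stats, fx$calib, fx$cv))
  rep_apt <- qc$report$aptamer
  recovered <- data.frame(entity = rep_apt$analyte_id[!is.na(rep_apt$reason)],
                          criterion = rep_apt$reason[!is.na(rep_apt$reason)])
  truth_apt <- fx$truth[fx$truth$type == "aptamer", c("entity", "criterion")]
  expect_identical(recovered[order(recovered$entity), ],
                   truth_apt[order(truth_apt$entity), ],
                   ignore_attr = TRUE)
  flagged_smp <- qc$report$sample$sample_id[qc$report$sample$crit5]
  expect_setequal(flagged_smp, fx$truth$entity[fx$truth$type == "sample"])
  # planted clean aptamers survive
  expect_true(all(setdiff(rownames(fx$matrix), fx$truth$entity) %in%
                    rownames(qc$matrix)))
})

test_that("relaxing thresholds never removes more entities", {
  fx <- generate_qc_fixture(synthetic_config(seed = 4))
  strict <- suppressWarnings(run_qc(fx$matrix, fx$buffer_stats, fx$calib, fx$cv))
  relaxed <- suppressWarnings(run_qc(
    fx$matrix, fx$buffer_stats, fx$calib, fx$cv,
    qc_thresholds(low_signal_sample_frac = 0.5, calib_max_diff = 10,
                  cv_max = Inf, iqr_sample_frac = 0.5)))
  expect_true(all(rownames(strict$matrix) %in% rownames(relaxed$matrix)))
  expect_true(all(colnames(strict$matrix) %in% colnames(relaxed$matrix)))
  # cv_max = Inf switches criterion 3 off entirely
  expect_false(any(relaxed$report$aptamer$crit3, na.rm = TRUE))
})

test_that("criteria needing absent auxiliary tables are skipped with a warning", {
  set.seed(14)
  mat <- 10^matrix(3 + rnorm(10 * 30, 0, 0.05), nrow = 10,
                   dimnames = list(paste0("A", 1:10), paste0("s", 1:30)))
  w <- capture_warnings(flags <- evaluate_aptamer_criteria(mat))
  expect_true(any(grepl("buffer", w)))
  expect_true(any(grepl("calibration", w)))
  expect_true(any(grepl("CV", w)))
  expect_true(all(is.na(flags$crit1)))
  expect_true(all(is.na(flags$crit2)))
  expect_true(all(is.na(flags$crit3)))
  expect_false(any(is.na(flags$crit4)))
})
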