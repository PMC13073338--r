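# shared builders for the test suite; everything is generated in code

# normalize a synthetic cohort the way the pipeline does (log10, batch
# removal, optional per-dataset z-scoring)
normalize_cohort <- function(cohort, zscore = TRUE) {
  lg <- log10_normalize(cohort$matrix)
  nb <- remove_batch_effect(lg, cohort$meta$batch)
  merge_and_standardize(list(nb), zscore = zscore)
}

# a tiny metadata frame for single-analyte association fits
tiny_meta <- function(status, age = NULL, sex = NULL) {
  n <- length(status)
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             status = status,
             age = if (is.null(age)) rep(70, n) else age,
             sex = if (is.null(sex)) rep(c("M", "F"), length.out = n) else sex,
             stratum = "33", batch = 1L, dataset = "ds1",
             stringsAsFactors = FALSE)
}

# hand-coded logistic negative log-likelihood, independent of glm
neg_loglik_logistic <- function(par, X, y) {
  eta <- drop(X %*% par)
  sum(log1p(exp(eta))) - sum(y * eta)
}

# brute-force BH step-up: sort ascending, q_i = p_i * m / i, enforce
# monotonicity from the top, cap at 1, restore order
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive hypergeometric upper tail P(X >= a) for a 2x2 enrichment table
hyper_enum <- function(a, set_size, universe_size, n_hits) {
  ks <- max(0L, n_hits - (universe_size - set_size)):min(set_size, n_hits)
  ks <- ks[ks >= a]
  if (length(ks) == 0L) return(0)
  sum(choose(set_size, ks) * choose(universe_size - set_size, n_hits - ks)) /
    choose(universe_size, n_hits)
}

# toy background interactome used in the network hand-trace
toy_background <- function() {
  igraph::graph_from_edgelist(
    cbind(c("A", "B", "C", "A"), c("B", "C", "D", "E")), directed = FALSE)
}
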