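---
title: "Methods: genotype-stratified differential abundance with IVW meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-stratified differential abundance with IVW meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratomics)
```

# The model and its assumptions

`stratomics` analyses case-control abundance data *within* genotype strata.
The primary per-analyte model is a logistic regression of disease status on
age, sex and the (normalized) analyte value, fitted separately in a discovery
and a replication half of each stratum; the two coefficients are then pooled
with inverse-variance weights:

$$w_n = \frac{1}{se_n^2}, \qquad
\hat\beta_{pooled} = \frac{\sum_n w_n \hat\beta_n}{\sum_n w_n}, \qquad
se_{pooled} = \sqrt{\frac{1}{\sum_n w_n}}, \qquad
\chi^2_{1} = \frac{\hat\beta_{pooled}^2}{se_{pooled}^2}.$$

The fixed-effect pooling assumes the two halves estimate the same underlying
effect — true by construction here, since both halves are random samples of
one stratum. An analyte is called differentially expressed when
$p_{disc} \le \alpha$, $p_{rep} \le \alpha$, the Benjamini–Hochberg FDR of
$p_{meta}$ is $\le$ the FDR threshold, and the two stage coefficients agree
in sign. The conjunction makes the caller deliberately conservative: under
the global null its false-positive rate is far below $\alpha$ (the test suite
checks $<1\%$ over 5000 null analytes).

Covariate adjustment is linear in age (years, untransformed) and a single
binary indicator for sex. The logistic coefficient is reported per unit of
the analyte on whatever scale was analysed; with per-dataset z-scoring
(`merge_and_standardize(..., zscore = TRUE)`) that unit is one analyte SD,
which makes effect sizes comparable across analytes and strata.

# Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `alpha` | 0.05 | per-stage significance threshold |
| `fdr` | 0.05 | BH threshold on the meta p-value, computed within one stratum × model family (matching per-genotype reporting) |
| `band_mult` | 1.5 | concordance band half-width in units of $\sigma$ (total band $3\sigma$) |
| QC thresholds | 0.15 / 2 / 0.5 / 0.15 / 1.5 / 0.15 / 0.80 | the six-step aptamer/sample criteria (see `qc_thresholds()`) |
| `go_min_size`, `go_max_size` | 10, 500 | in-universe gene-set size window, GO mode only |
| `dominance_ratio` | 1.5 | cell-type specificity rule: top proportional contribution at least 1.5× the runner-up (inclusive) |
| `roots_k` | 5 | number of highest-degree DEP genes used to seed network growth |

# What the synthetic generator emulates — and what it does not

`generate_cohort()` draws log10 abundances as
$\log_{10} x = b_m + \delta_{batch}\,[\text{batch 2}] +
\beta\,\sigma_\varepsilon\,[\text{case}] + \varepsilon$,
$\varepsilon \sim N(0, \sigma_\varepsilon^2)$. Under this two-Gaussian model
the true logistic slope per analyte SD equals the planted $\beta$ (the
linear-discriminant identity), so planted truth and fitted estimates live on
the same scale. Effects are shared across strata, specific to one stratum,
or sign-flipped between the two designated strata. Cases are drawn ~5 years
older than controls (75 vs 70, SD 8), sex is balanced, and two collection
batches differ by an additive log10 shift of 0.1 — so covariate adjustment
and batch removal are both non-trivial. Default effect fractions
(10% shared, 1% specific, 1% opposite) mirror the composition typically seen
in a called set: mostly concordant, with small specific and opposite tails.

The generator does **not** emulate aptamer cross-reactivity, dilution-bin
structure, heavy-tailed or skewed abundance distributions, missingness that
depends on abundance (metabolomics missingness is MCAR here), or correlation
between analytes. Passing tests therefore demonstrate correctness of the
*procedure* under its stated model, not robustness to every property of real
plasma data.

Missing values are handled by casewise deletion within each per-analyte fit
(with `n_used` recorded); no imputation is attempted, and zeros are treated
as valid abundances distinct from missing.

# Numerical and procedural choices

* **Quartiles** for all IQR fences use linear interpolation (type 7), the R
  default, fixed for reproducibility.
* **QC ordering**: aptamer criteria 1–4 are evaluated on the full matrix and
  each flagged aptamer is bucketed under its first triggering criterion;
  sample criterion 5 is evaluated after removing those aptamers; criterion 6
  then removes remaining aptamers whose fence violations are shared by
  ≥80% of the flagged samples. Criteria 1–4 are order-independent among
  themselves; only the removal-reason bookkeeping depends on the order.
  Criteria whose auxiliary vendor tables (buffer, calibration, replicate CV)
  are absent are skipped with a warning.
* **Wald p-values** are used for the logistic analyte term. Separation or
  non-convergence (100 IRLS iterations, or $|\hat\beta| > 50$) marks the fit
  unconverged with a missing p-value rather than reporting an unstable
  estimate; unconverged analytes propagate as missing through the
  meta-analysis.
* **Center line**: ordinary least squares of $\beta_B$ on $\beta_A$ (not
  total least squares), with *perpendicular* point-to-line distances and
  their sample SD as $\sigma$. The band half-width of $1.5\sigma$ implies
  an expected coverage of $\Phi(1.5)-\Phi(-1.5) = 86.6\%$ under Gaussian
  perpendicular scatter, which is what the acceptance simulation measures.
  With $\sigma = 0$ (perfectly collinear input) every off-line point is
  outside the band by definition. A coordinate exactly at zero is treated as
  positive for the quadrant decision; a both-zero point is consistent if
  within the band.
* **Enrichment** is one-sided (greater): the workflow asks whether called
  analytes are over-represented in a set, never depleted. The odds ratio is
  the plain count ratio $ad/bc$ (infinite when $bc = 0 < ad$), and pathway
  p-values are reported raw with a 0.05 cutoff; a BH column is included for
  information only. The gene universe is the unique gene set of all post-QC
  analytes, with multiple aptamers per gene collapsed (a gene is a hit if
  any of its aptamers is called). The [10, 500] size window applies in GO
  mode only; KEGG mode tests every set.
* **Cell-type rule**: the 1.5× dominance test on proportional contributions
  is identical to the same test on raw means (the row total cancels); it is
  applied inclusively, ties yield no assignment, and a 0.5 pseudocount on
  both counts keeps fold enrichments finite and sign-correct when a type is
  empty on either side.
* **Network growth** uses unweighted breadth-first shortest paths (the
  background interactome is an unweighted edge list). Root degree is
  measured in the full background. Ties — among candidates at the minimum
  distance, and among multiple shortest paths — are broken
  lexicographically (candidate symbol, then the path's node sequence), a
  reproducible stand-in for an otherwise arbitrary choice. Candidates in
  components that contain no network node are reported unreachable.
* **Z-scoring is off by default** in `merge_and_standardize()`: the primary
  path reports effects on the log10 scale, standardization being the
  documented convention for cross-cohort harmonization. The pipeline demo
  and the acceptance script opt in, so their effect sizes are per-SD.
* **BH within families**: FDR is computed within one stratum × omics-type ×
  model family; replication-stage p-values face only the per-stage 0.05
  threshold, with FDR control applied to the meta p-values.

# Problem sizes used by the test and acceptance suites

Simulated conditions were chosen so each property is measured with
comfortable margin at interactive runtimes: one 250-sample stratum with 1000
analytes (10% planted at $|\beta| = 0.6$) for the meta-vs-joint and
logistic-vs-linear concordance checks; two 600-sample strata with 500
analytes (10% shared, 1% specific, 1% opposite at $|\beta| = 0.8$) for
quadrant-label recovery; 5000 null analytes for caller calibration; and
50 replicates of 500 effect pairs for the band-coverage simulation.

# Known limitations

* The fixed-effect IVW pooling has exactly two stages (discovery,
  replication); random-effects pooling and external-cohort harmonization
  are out of scope.
* The quadrant geometry is descriptive: no formal heterogeneity test
  (e.g. Cochran's Q) accompanies the band classification.
* Enrichment is annotation-driven Fisher testing only — no rank-based or
  topology-aware methods.
* The shortest-path growth is greedy and unweighted; it does not optimize a
  global objective the way prize-collecting Steiner approaches do, and its
  tie-breaking, while deterministic, is one of several defensible choices.
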