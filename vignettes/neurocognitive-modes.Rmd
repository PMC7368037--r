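---
title: "Sparse canonical modes linking functional connectomes, cognition and ongoing thought"
author: "neurocca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse canonical modes linking functional connectomes, cognition and ongoing thought}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocca)
```

## The analysis problem

Individual differences in patterns of ongoing thought (mind-wandering,
mental time travel, task focus) are hypothesised to reflect stable
neurocognitive traits: joint variation in how the brain is organised at
rest and how people perform across a battery of cognitive tasks. The
analysis implemented here asks that question in three stages:

1. **Feature engineering.** Each participant's resting-state fMRI is
   summarised as a functional connectome: Pearson correlations between the
   average BOLD time series of 100 parcellation regions, Fisher
   r-to-z transformed, and vectorized as the 4,950 unique region-pair
   values of the upper triangle. A battery of nine tasks is reduced to 13
   summary scores (spans, fluency and semantic contrasts, accuracies,
   reversed switch costs, reversed efficiency scores). Both blocks are
   residualized on age, sex and head motion (mean frame-wise
   displacement), and the connectome block is restricted to its most
   variable 5% of edges (247 of 4,950) by median absolute deviation — a
   feature that does not vary between people cannot carry individual
   differences, and MAD is robust to outlying subjects.

2. **Sparse canonical correlation analysis (SCCA).** Canonical modes —
   pairs of weight vectors $(u_k, v_k)$ whose subject-level projections
   $X u_k$ and $Y v_k$ (the canonical variates) are maximally correlated —
   are estimated under L1 penalties that set most weights exactly to
   zero. Penalties are chosen by 5-fold cross-validation on the
   out-of-sample rank-1 canonical correlation; mode significance is
   assessed by permuting subject rows of the behavioural block 1,000 times
   and comparing every observed mode to the permutation distribution of
   the *first* canonical correlation (a family-wise-error-controlling max
   statistic).

3. **Validation against experience sampling.** Subjects are scored on each
   accepted mode (the mean of their two z-scored canonical variates), and
   a Type III multiple multivariate regression with Pillai's trace asks
   whether those neurocognitive scores explain the 13 experience-sampling
   item means, overall and separately per task condition (0-back/1-back)
   and day — the stability analyses.

The package implements each stage as an exported function, `scca()` being
the central model-fitting function (with `print`, `summary`, `coef`,
`predict` and `plot` methods), and `run_pipeline()` tying the stages
together with write-once tab-separated intermediates and a JSON manifest.

## The solver

`scca()` uses the penalized matrix decomposition: with both blocks
column-centered, each mode is a rank-1 decomposition of $M = X^\top Y$
under L2 and L1 constraints, computed by alternating

$$u \leftarrow \frac{S(Mv, \delta_u)}{\lVert S(Mv, \delta_u)\rVert_2},
\qquad
v \leftarrow \frac{S(M^\top u, \delta_v)}{\lVert S(M^\top u, \delta_v)\rVert_2},$$

where $S$ is the soft-thresholding operator and each $\delta$ is the
smallest threshold (bisection, tolerance $10^{-8}$) that brings the L1
norm of the unit vector under its bound. This treats the within-block
covariances as diagonal — the standard surrogate that makes sparse CCA
tractable when features outnumber subjects; covariance-aware sparse CCA is
out of scope. Design choices:

* **Penalty parameterisation.** User-facing penalties are fractions
  $c \in (0, 1]$ mapped to absolute bounds $\max(1, c\sqrt{p})$; $c = 1$
  disables the penalty (mode 1 then equals the leading singular pair of
  $M$, which the tests verify against `svd()`), and small $c$ forces a
  single nonzero weight.
* **Initialisation** from the leading right singular vector of the current
  $M$: deterministic, and exact when the penalty is inactive.
* **Convergence**: maximum elementwise weight change below `tol` (default
  `1e-6`), at most `max_iter = 200` alternations; non-convergence is
  reported on the fitted object, not raised. The objective
  $u^\top M v$ is non-decreasing across alternations up to the bisection
  tolerance, and the test suite asserts this on every fit it makes.
* **Deflation** $M \leftarrow M - (u^\top M v)\, u v^\top$ for successive
  modes; with no penalty and full rank this exhausts $M$ (tested to
  $10^{-8}$ Frobenius).
* **Orientation and order.** Signs are fixed by making the
  largest-magnitude task-side weight positive (the task block is small and
  interpretable). Modes are *reported in order of decreasing canonical
  correlation*. That is the defining order of canonical correlation
  analysis, and it matters for inference: the permutation scheme compares
  every mode to the permuted sample's first canonical correlation, which
  is an exact family-wise max-statistic comparison only when "first"
  means "largest". A deflated penalized solver does not guarantee that by
  itself — in null data the deflation-order second mode has the larger
  canonical correlation roughly a third of the time — so the package
  enforces the ordering, and `scca_permtest()` records the largest
  canonical correlation among the $K$ modes of each permuted refit. Our
  Monte-Carlo calibration (500 null cohorts, $n = 100$, 200 permutations,
  $K = 2$) puts the family-wise rejection rate at nominal level; without
  the ordering convention it was measurably liberal (about 0.084 at
  $\alpha = 0.05$).
* The inner rank-1 loop is compiled (RcppArmadillo) because the
  permutation test and the Monte-Carlo calibration studies perform on the
  order of $10^5$ rank-1 fits.

## Inference choices

* **Permutation p-values** use the $(1 + b)/(1 + B)$ estimator, so no
  p-value is exactly zero and the minimum attainable value is
  $1/(B + 1)$; fewer than 100 permutations triggers a resolution warning.
* **Permuting residualized data.** The pipeline residualizes both blocks
  on the same covariates before SCCA. Row permutation of residualized
  data is not exactly exchangeable: both blocks live in the same
  $(n - k - 1)$-dimensional residual subspace, and permutation destroys
  that shared alignment, which deflates the null and makes the test
  mildly liberal (in our Monte-Carlo at $n = 100$, $p = 105$, mean null
  p-value drops from 0.50 to about 0.38). This is a property of the
  residualize-then-permute scheme itself, shared with common practice in
  the field, and is documented here as a limitation; the package's
  calibration tests therefore use nuisance-free null cohorts, which are
  exactly exchangeable.
* **Cross-validated penalty selection** maximizes the mean out-of-sample
  signed rank-1 canonical correlation over a grid (default
  $0.1, \ldots, 1.0$ per side); exact ties resolve towards the less
  sparse model. A fold whose held-out variate is constant contributes a
  correlation of zero and increments a warning counter.
* **Pillai's trace** for a predictor is computed from Type III
  sums-of-squares-and-cross-products by model comparison (full model
  versus the model without the predictor) — equivalent to the classical
  Type III test for continuous, non-nested predictors — with
  $V = \operatorname{tr}\!\left(H (H + E)^{-1}\right)$, the standard
  $F$ approximation, and the multivariate effect size defined as
  $\eta^2 = V / s$ (for single-df hypotheses, $s = 1$, the $F$
  approximation is exact). The implementation is verified against an
  independent eigenvalue-form oracle and against `car::Manova`. Reported
  degrees of freedom are the exact $(q,\; \nu_e - q + 1)$ for single-df
  hypotheses, computed from the data at hand rather than copied from any
  external report.
* **Mode scores** are the mean of the two z-scored canonical variates.
  Mean versus sum differ by a factor of two, so every downstream
  correlation, test statistic and p-value is identical; the tests assert
  this equivalence numerically.
* **Stratified stability analyses** z-score items within stratum, drop
  subjects missing a stratum from that stratum only, and compare
  coefficient vectors ("thought patterns") by Pearson correlation with
  the usual t-transform p-value.

## The synthetic cohort generator

`simulate_cohort()` provides planted ground truth for every stage, so the
whole pipeline is testable without any data download. The generative
model:

* Latent subject scores $z_k \sim N(0, 1)$, independent across modes.
* Sparse unit canonical vectors with equal-magnitude entries
  ($\pm 1/\sqrt{\text{nnz}}$) on disjoint supports.
* Features $X = \mu + \sum_k a_k z_k u_k^\top + \varepsilon$ and scores
  $Y = \sum_k b_k z_k v_k^\top + \eta$, with $a_k, b_k$ calibrated from
  the realized noise scales so the population correlation of
  $(X u_k, Y v_k)$ equals the requested $\rho_k$ (tested to $\pm 0.03$ at
  $n = 5000$). In the noiseless limit the correlation is exactly 1.
* **Heterogeneous edge variance and support placement.** Per-edge noise
  scales vary lognormally, and the planted supports are drawn from the
  most variable edges (the top 5% by default), with the support of one
  mode sharing a common noise scale. The first choice encodes the same
  premise that motivates the MAD filter — between-subject signal *is*
  between-subject variance, so an association-carrying edge cannot be
  near-constant across subjects; a generator that planted signal in
  low-variance edges would contradict its own model. The second keeps the
  planted direction invariant under column standardization. A consequence
  worth stating plainly: in these simulations the MAD filter is nearly
  lossless (it retains about 95% of planted support edges), so passing
  tests demonstrate the pipeline's behaviour when the filter's premise
  holds, and say nothing about signal that real data might carry in
  low-variance edges.
* Defaults mirror the target study design: 178 subjects, 100 ROIs
  (4,950 edges), 177 timepoints, two planted modes with
  $\rho = (0.57, 0.59)$, u-sparsity 0.004 (20 edges per mode), v-sparsity
  0.3 (4 task scores per mode). Note that the planted $\rho$ are
  *population* values matched to reported sample canonical correlations;
  at $n = 178$ with 247 features, in-sample sparse canonical correlations
  are optimistically biased (about 0.70 for $\rho = 0.59$), the
  permutation null is correspondingly high, and acceptance of the second
  mode is genuinely borderline — single runs may accept one or both
  modes.
* Age is uniform on 18–31 years, sex Bernoulli(0.64), mean frame-wise
  displacement lognormal around 0.15 mm; covariates act additively on
  both blocks with per-feature coefficients (scaled by `confound_sd`),
  and the realized raw-scale coefficients are stored in the ground truth.
  A *null* cohort keeps the covariate effects on the connectivity side
  only, so its two blocks are exactly independent.
* **Experience sampling.** Item propensities $P = Z L$ with a
  $K \times 13$ loading matrix; by default only the last (strongest)
  planted mode is coupled, with an off-task / mental-time-travel pattern
  (negative task focus; positive future, past, self, vivid, detailed).
  Each of the six condition-by-day cells is $P$ plus independent noise of
  standard deviation 1 (per-cell means over a handful of probes are
  noisy; the overall mean, averaging six cells, has noise
  $1/\sqrt{6} \approx 0.41$). With these values the strongest items carry
  per-stratum $R^2$ around 0.1–0.25 — enough that, as in the motivating
  study, the coupled mode's multivariate association is clear and the
  per-condition thought patterns correlate above 0.9. Day 2 and day 3
  carry 2% and 15% attrition. The generator does not simulate trial-level
  probes, raw BOLD physics, motion artifacts, or any empirical
  correlation among item residuals (an item correlation matrix can be
  supplied but none is assumed).
* The raw task table is an exact affine encoding of the planted score
  matrix: every scheduled score (span mean, contrasts, reversed costs,
  efficiencies) is an increasing affine function of its planted column,
  so `assemble_scores()` followed by standardization inverts the encoding
  to machine precision — tested at $10^{-8}$. Span counts are continuous
  rather than integer; rounding would break exact inversion and adds
  nothing to what the tests probe.
* In time-series mode, each subject's planted Fisher-z row is converted
  to a correlation matrix, repaired to positive definite by eigenvalue
  clipping at $10^{-6}$ (failing loudly, naming the subject, if the
  smallest eigenvalue is below $-0.5$), and sampled as multivariate
  normal series — adding the realistic $\sim 1/\sqrt{T}$ estimation noise
  that the direct mode omits.

## The 13-score schedule

The battery's reduction to exactly 13 scores is one consistent reading of
the task set: digit span (mean of forward/backward), verbal fluency
contrast (category − letter), three accuracies (picture naming, four
mountains, matrices), flexibility and inhibition (negated switch and
inhibition costs — negation rather than reciprocal keeps the scores
linear, which is what a linear canonical model should consume), two
efficiency scores (feature matching, paired associates), three semantic
contrasts computed on condition-wise efficiencies (strong − weak,
picture − word, specific − general), and a generation-task score. The
schedule is configuration, not code: `assemble_scores()` consumes an
ordered list of named operator applications over the fixed operator set
(mean, contrast, efficiency, accuracy, negate), so alternative readings
of the battery are expressible without touching the package.

Open choices resolved here and revisitable through the schedule: the
generation task enters as a single raw count; the inhibition cost is
negated like the switch cost so that higher is uniformly better.

## Problem sizes used by the tests

The test suite validates solver identities on small seeded matrices
(oracle comparisons at $10^{-5}$–$10^{-12}$), generator calibration at
$n = 5000$, permutation exactness on 2,000 tiny replicates, family-wise
error on 500 null cohorts ($n = 100$, 105 edge features, 200 permutations
each), the end-to-end mode-specific experience-sampling result on 100
study-scale replicates ($n = 178$, 4,950 features filtered to 247), and
cross-condition stability on 25 such replicates. These sizes were chosen
to give Monte-Carlo standard errors comfortably inside the asserted
bands. The acceptance script (`scripts/acceptance.R`) recomputes the
headline quantities from scratch at the study scale.

## Known limitations

* The diagonal-covariance surrogate means canonical vectors are not
  orthogonalised against within-block covariance; correlated edges can
  share credit.
* Permutation inference on data residualized against shared covariates is
  mildly liberal (discussed above); a nuisance-aware permutation scheme
  is a possible extension.
* The cross-validated penalty surface is flat near its maximum on
  moderately sized cohorts; selected penalties vary across seeds, and
  with them the sparsity of the reported loadings.
* The generator plants signal in variable edges by construction; the
  pipeline's behaviour when signal lives in low-variance edges (where the
  MAD filter would discard it) is untested by design.
* Statistics reported on a single synthetic cohort (canonical
  correlations, Pillai's $F$) describe that simulation, not any human
  dataset; only distributional statements over many replicates mirror the
  motivating study's findings.
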