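---
title: "Predicting behaviour from low- and high-order functional connectomes"
author: "hoconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting behaviour from low- and high-order functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoconn)
```

## The problem

Resting-state fMRI gives, for each participant, a T x R matrix of regional
BOLD time courses (T time points, R parcellation regions; 140 x 90 under a
3-second TR and the cerebellum-free AAL parcellation). The clinical
question this package addresses is whether a continuous behavioural
outcome — the motivating case is a tactile discrimination score on a
0-100 area-under-curve scale in chronic stroke survivors — can be
predicted from the participant's functional connectome, and which network
edges carry that prediction.

The pipeline has four stages, each exposed as a package function and run
end to end by `nested_loocv()` and `finalize_model()`:

1. **Connectome construction** (`lofc()`, `hofc()`). Low-order functional
   connectivity (LOFC) is the Pearson correlation between two regions'
   time courses. High-order functional connectivity (HOFC) is the
   "correlation of the correlation": entry (i, j) correlates row i and
   row j of the LOFC matrix, i.e. it asks whether two regions have
   similar whole-brain connectivity profiles. Edges of one or both
   matrices, vectorized over the upper triangle (`feature_pool()`), form
   the feature pools: 4005 features for LOFC at R = 90, 8010 for
   LOFC + HOFC.
2. **Feature engineering** (`stability_selection()`). Randomized-LASSO
   stability selection: repeatedly subsample subjects, randomly reweight
   feature columns, fit the L1 path, and keep features that enter the
   model in a high fraction of resamples.
3. **Predictive modelling** (`nested_loocv()`). Linear regression (LR) or
   linear-kernel support vector regression (SVR) under nested
   leave-one-out cross-validation: feature selection and hyperparameter
   tuning see only the N - 1 training subjects of each outer fold; a
   majority vote across folds fixes one SVR hyperparameter pair; accuracy
   is the Pearson correlation r between held-out predictions and observed
   scores, with p from the exact t-transform on n - 2 degrees of freedom.
4. **Consensus final model** (`consensus_features()`, `finalize_model()`).
   Features selected in at least half of the folds are re-screened on all
   subjects with the same randomized LASSO, and the surviving edges are
   fit once on everyone, producing the model intended for prospective use
   together with an atlas-named edge table (`name_edges()`,
   `aal90_labels()`).

## The HOFC profile convention

The profile correlation underlying `hofc()` excludes entries i and j from
both rows before correlating (profile length R - 2), so an edge's own
value and the unit self-correlations never contaminate its high-order
score; `profile = "full"` gives the plain row correlation instead. The
exclusion convention is the default because the self-entries are
constants (diagonal) or shared values (the (i, j) entry itself) that
would inflate every profile correlation toward +1. With exclusion the
minimum meaningful parcellation is R = 4; R = 3 is rejected (profiles of
length 1 have no correlation). The implementation is vectorized through
row sums and the Gram matrix of the LOFC and is tested to 1e-10 against a
literal slice-and-correlate oracle.

Correlations are used raw and signed throughout: no Fisher z-transform,
thresholding, or absolute value is applied anywhere, and the upper
triangle is flattened row-major — (1,2), (1,3), ..., (2,3), ... — so
feature indices are stable across runs and pools.

## Stability selection: parameters and their defaults

`stability_control()` exposes the knobs; none of them is prescribed by
the modelling problem itself, so their defaults are the package's own
choices:

* `B = 200` resamples; frequencies have binomial standard error
  below 0.04 at the 0.6 threshold.
* `fraction = 0.5`: half-subsampling is what gives stability selection
  its false-selection control — a feature that merely happens to
  correlate with the outcome in this cohort rarely survives across
  half-subsamples. We verified empirically that permuted-score null runs
  keep every selection frequency below the 0.6 threshold at this value,
  and that raising it to 0.75 (the randomized-LASSO default in the
  scikit-learn tradition) buys per-resample power at a real cost in null
  control; both operating points are useful, which is why the parameter
  is exposed.
* `weakness = 0.5`: column weights drawn uniformly from [0.5, 1]. This is
  the "randomized" in randomized LASSO; it spreads selection over
  correlated features instead of letting one of them absorb the credit
  (tested: duplicating a predictive column leaves both copies within
  0.25 of each other's frequency).
* `threshold = 0.6`: inclusive (a frequency of exactly 0.6 is selected).
* The per-resample L1 path runs over 30 geometric lambdas from
  `lambda_max = max|X'y|/n` down to `1e-3 * lambda_max`, and a feature
  counts as selected in a resample if it is nonzero anywhere on the path
  (`rule = "fixed"` gives the single-lambda alternative). The path is
  truncated once `q` features have entered — `q = ceiling(sqrt(0.4 p))`
  by default, the order dictated by stability-selection error control at
  this threshold. Without the cap the deep end of the path activates
  essentially every feature and null frequencies saturate; with it the
  expected number of false selections at the default threshold is about
  `q^2 / (0.2 p)` (~2 for p = 4005). Feature sets of twelve or fewer
  columns are never capped — they are already screened.
* Standardization of X and centring of y happen inside each resample,
  never globally, so the procedure can run inside cross-validation folds
  without leaking held-out statistics.

## The two regression models

LR is the SVD-based minimum-norm least-squares solution — identical to
the normal equations when the design has full column rank and still
defined when selection returns more features than subjects. SVR minimizes
`0.5 ||w||^2 + C sum(max(0, |r_i| - eps))` with a linear kernel
(via the standard SMO solver in e1071, cross-checked in the tests against
kernlab's independent optimizer on the same primal objective). Features
are z-scored and the response centred with training statistics stored in
the model. `epsilon` is read in standardized-response units (the
effective tube is `epsilon * sd(y_train)`), which keeps the grid
{0.01, 0.1, 1} meaningful on any score scale while leaving predictions on
the original 0-100 scale. The tuning grid crosses it with
`C in 2^{-5, -3, ..., 5}`. A `gamma` value is accepted by `model_spec()`
for configuration fidelity but has no effect under a linear kernel;
supplying one emits a note.

Inner-loop tuning scores each candidate by the Pearson r of its inner
leave-one-out predictions; constant predictions score -1 so a fully
regularized model can never win, and ties resolve toward smaller C, then
smaller epsilon. Because per-fold winners differ at clinical sample
sizes, the final spec is the majority vote over the N inner winners and a
second pass refits every fold under it. The vote couples folds mildly —
fold i's hyperparameters depend on other folds' winners, though never on
subject i's score through its own fold, and the no-leakage property
(perturbing a held-out score changes neither that fold's features nor its
weights) is asserted in the tests. `hyper = "per-fold"` gives the
strictly nested variant. A fold whose selection comes back empty predicts
its training mean — the evaluation then still has N predictions, at the
price of a strong negative contribution from those folds (the training
mean of N - 1 subjects anti-correlates exactly with the held-out score).
Both one- and two-sided p values are reported; the one-sided value is the
one consistent with published tables of this design (0.54 at n = 40 gives
one-sided p = 0.00016, printed as 0.0002).

## The synthetic cohort generator

No clinical cohort ships with the package, so validation runs on
synthetic cohorts with known ground truth (`ground_truth()`,
`random_truth()`, `simulate_cohort()`,
`simulate_connectome_cohort()`). What it emulates, and how:

* **Base connectome**: a 5-factor model `cov2cor(LL' + 2k I)` (k factors,
  loadings standard normal). This gives the blocky community structure of
  resting-state connectomes and guarantees positive definiteness; the
  doubled uniqueness term keeps the smallest eigenvalue (~0.4) above the
  planted deviation range, so deviations rarely have to be shrunk.
* **Between-subject variability**: each subject perturbs the factor
  loadings (`subject_loading_sd = 0.15`, giving edge-level variability of
  about 0.05 SD). Variability generated at the loading level is low-rank,
  as empirical connectome variability is, and the subject matrix stays a
  valid correlation matrix by construction. (For user-supplied base
  matrices, entry-wise jitter plus an eigenvalue-clipping projection is
  used instead.)
* **Planted low-order edges**: a per-subject deviation uniform in
  [-0.3, 0.3] added to the chosen entries. If a deviation breaks positive
  definiteness the whole deviation vector is scaled back just enough to
  restore it — projection by eigenvalue clipping is deliberately *not*
  used here because it smears the sparse planted signal across every
  edge.
* **Planted high-order edges**: perturbing entry (i, j) cannot move the
  exclude-pair HOFC at (i, j) (the pair is excluded from both profiles),
  so each planted high-order edge shifts a fixed random set of 8 entries
  of row i — with fixed random signs and independent entry noise
  (SD 0.15) on top of the shared deviation. The profile correlation
  averages the entry noise out, so the high-order feature reads the
  deviation cleanly while no single low-order edge is a good proxy: this
  is the generative premise that high-order features can add information
  beyond the low-order pool, stated here as an explicit construct of the
  generator, not a claim about any clinical dataset. High-order edges get
  3x the low-order weight by default because profile correlations move on
  a ~3x smaller scale than the raw correlations underneath them.
* **Scores**: latent = planted-edge values (centred on their base-matrix
  baseline) times weights, plus Gaussian noise; then an affine map and
  clipping to [0, 100]. `target_r2` calibrates the noise SD so ordinary
  least squares on the true edge values has a stated oracle R^2.
  `ground_truth()` defaults to offset 22.6 / scale 23.2 — the
  affected-hand tactile-score distribution of a chronic stroke cohort,
  floor effect included — while `random_truth()` defaults to 50 / 10 so
  recovery experiments are not confounded by floor censoring.
* **Time series**: zero-mean multivariate normal draws from the subject's
  target correlation (Cholesky), so the empirical Pearson connectome
  converges to the target as T grows (verified at T = 10000 to within
  0.05). Scores are computed from the targets, not the sampled series.

Reproducibility: every cohort is a pure function of `(truth,
master_seed)`. Child seeds for subject targets, time-series draws and the
noise vector are drawn once from the master seed by a fixed counter
scheme, so cohorts are bit-identical across runs and machines and
subjects are independent streams.

What the generator does **not** emulate: scanner artefacts, head motion,
haemodynamic convolution, autocorrelated noise, lesioned-tissue signal
dropout, site effects, or any spatial embedding of the parcellation.
Passing tests on these cohorts therefore show that the pipeline recovers
the kind of sparse, edge-linear signal it assumes — they cannot show that
any particular clinical dataset contains such signal.

## Validation experiments and their problem sizes

The test suite and `scripts/acceptance.R` run the following experiments;
sizes are the package's chosen balance between statistical resolution and
a laptop-friendly runtime.

* **Oracle equivalence**: 20 seeded random instances (R = 5-10) against
  brute-force pairwise and profile-correlation oracles, tolerance 1e-10.
* **Selection recovery**: 10 planted low-order edges among 4005 features
  (R = 90), 200 connectome-level subjects, oracle R^2 = 0.9, ten cohort
  seeds, with permuted-score nulls. With the default half-subsampling the
  nulls are controlled (max frequency < 0.6 in every cohort), the typical
  planted edge outranks every null feature, and about 70% of the planted
  support crosses the selection threshold. A caveat worth stating plainly: spreading
  R^2 = 0.9 over ten equal edges leaves each edge a population marginal
  correlation of 0.30, and at n = 200 its realized value has SD ~0.08, so
  roughly one edge in fifty dips below the spurious-correlation ceiling
  of 4005 null features in any given cohort; *uniform* recovery of all
  ten edges in nearly every cohort is beyond any subsample-based selector
  at this per-edge power, and the corresponding acceptance check
  documents exactly this boundary.
* **Paper-scale prediction**: n = 40, R = 90, combined pool
  (8010 features), two planted edges (one per pool, effect shares
  equalized), oracle R^2 = 0.9, SVR. For this p >> n experiment the
  selection stage runs at the operating point of the randomized-LASSO
  implementation used in the field's published analyses
  (subsample fraction 0.75, selection threshold 0.25): at n = 39 per
  fold, half-subsampling leaves too little per-resample power for any
  selection, and a validation experiment that cannot select anything
  validates nothing. Signal concentration follows the same power logic —
  each planted edge's marginal correlation (~0.67) must clear the maximum
  spurious correlation over 8010 features at n = 40 (~0.55), which caps
  the number of equal planted edges at two.
* **Pool-comparison trend**: R = 15, n = 40, two low-order + two
  high-order planted edges, five cohort seeds, all four model x pool
  cells; the combined pool should beat the low-order pool in median r for
  both models, because the low-order pool sees the high-order signal only
  through noise-diluted proxies.
* **Null calibration**: 20 globally permuted-score cohorts (LR, reduced
  scale) — mean r near zero and approximately uniform one-sided p values.
  Leave-one-out r under the null is well known to be biased negative
  (training means anti-correlate with held-out scores); the experiment
  measures where this pipeline actually sits.
* **No-leakage and p-convention checks**: instantaneous, described above.

## Known limitations

* LOOCV-based r has high variance at n = 40 and a negative null bias; the
  permutation experiment quantifies but does not remove it.
* The majority-vote protocol shares hyperparameter information across
  folds (documented above; strict nesting available).
* Consensus feature counts depend on the selection threshold; the
  "at least half the folds" rule is inclusive at the boundary.
* The generator's Gaussian, stationary time series are a best case for
  Pearson connectomes; real fMRI autocorrelation would widen the
  effective sampling error of every edge.
* Stability-selection frequencies are reported as-is; no
  false-discovery-bound computation is performed.
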