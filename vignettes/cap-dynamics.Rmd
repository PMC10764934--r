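---
title: "Co-activation pattern dynamics: model, metrics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-activation pattern dynamics: model, metrics and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capdyn)
```

## The model

Resting-state fMRI activity visits a small repertoire of transient
whole-brain configurations. Co-activation pattern (CAP) analysis makes this
explicit: every individual frame (one time point of a T x R
region-of-interest matrix) is treated as a point in ROI space, frames from
all subjects are pooled, and k-means clustering assigns each frame to
exactly one of K recurring spatial patterns. The per-subject label sequence
is then summarized as a discrete-state stochastic process.

`capdyn` implements this pipeline end to end:

1. **Standardization.** Each subject's ROI signals are z-scored column-wise
   (sample SD, denominator T-1). Any consistent SD convention only rescales
   the correlation-based distances used downstream.
2. **Clustering.** Frames are clustered under the distance
   d(x, y) = 1 - Pearson(x, y). For row-standardized frames this equals
   squared Euclidean distance divided by 2(R-1), so Lloyd updates use
   cluster means of row-standardized frames and assignment maximizes the
   correlation with each centroid (spherical k-means geometry; the
   correlation is invariant to the centroid's own scaling). The best of
   `n_init = 5` random initializations by total within-cluster distance is
   kept, with an iteration cap of 500. Each initialization seeds centroids
   by k-means++ D-squared sampling in the correlation distance — the
   default of the mainstream k-means implementations this protocol builds
   on, and necessary in practice: with plain uniform seeding (available as
   `init = "uniform"`), best-of-5 restarts intermittently misses the global
   basin when two states are strongly anti-correlated, splitting one state
   and merging two others. A frame equidistant to
   two centroids goes to the lower index; an emptied cluster is re-seeded
   from the farthest frame, with a message. Cluster labels are arbitrary,
   so CAPs are relabelled by pooled occupancy (largest first) and any
   comparison across runs, k values or atlases goes through spatial
   correlation matching (`match_caps`, exact over permutations for K <= 8).
3. **CAP maps.** For CAP c, each subject's assigned frames are averaged
   into a subject-level mean map; the group Z statistic per ROI is the
   across-subject mean over its standard error (sample SD, subjects
   contributing at least one frame). CAPs visited by fewer than two
   subjects are flagged NA rather than silently zeroed. Network attribution
   reports (i) the proportion of summed |Z| over supra-threshold ROIs
   (|Z| > 1.96 by default) per network and (ii) positive and negative
   supra-threshold mass separately.
4. **Dynamics.** Per subject, from the label sequence:
   dwell time (mean contiguous-run duration x TR, seconds), total dwell
   time, occurrence rate (frame fraction), the empirical transition matrix
   (diagonal = persistence probabilities; no smoothing, unvisited rows NA),
   and the entropy of Markov trajectories.
5. **Inference.** Covariate-adjusted group contrasts (the group coefficient
   of `value ~ group + covariates`), partial Pearson correlations with a
   symptom score, and Benjamini-Hochberg FDR within metric families.
6. **Classification.** Nested cross-validated RBF-SVM on the significant
   dynamic metrics with permutation-based significance.

## Entropy of Markov trajectories

For an irreducible chain P, the entry H_ij is the Shannon entropy of the
random trajectory from state i until first hitting state j. It satisfies
the recursion

H_ij = h_i + sum_{m != j} P_im H_mj,   h_i = -sum_m P_im log2 P_im,

which `trajectory_entropy()` solves as one K x K linear system per
destination (condition number guarded at 1e12). The diagonal is the
first-return entropy and obeys the identity H_jj = H(P) / mu_j, with H(P)
the entropy rate and mu the stationary distribution (Ekroot & Cover 1993);
the package verifies this identity to 1e-9 on random chains, and a
truncated forward-enumeration oracle (aggregating partial trajectories by
their current state until less than 1e-6 probability mass remains un-hit)
reproduces the solve to 1e-3 bits in the test suite. Entropies are reported
in bits (`base = 2`); a nats option exists. Low entropy towards a
destination means that destination is reached along predictable routes —
it is "more accessible".

Per-subject entropy is computed from that subject's own transition matrix,
restricted to visited states; entries requiring unreachable states stay
missing and drop out of group tests pairwise. No pseudo-counts are added by
default (`pseudo = 0`); a Laplace option exists for sensitivity analyses.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 7 | number of CAPs; 6-8 is the typical range, and `compute_validity` reports elbow/silhouette/CH/DB/Dunn over k = 2..20 |
| `tr_seconds` | 2 | repetition time; converts frames to seconds |
| `z_threshold` | 1.96 | supra-threshold cut for network attribution |
| `n_init`, `max_iter` | 5, 500 | k-means restarts and iteration cap |
| covariates | age, sex, education, site, mean_fd | nuisance set for adjusted tests and partial correlations |
| FDR families | per-CAP (K tests) and per-path (K x K tests) | families mirror how per-CAP and path-wise results are reported |
| `outer_folds`, `inner_folds` | 5, 5 | nested CV structure |
| `cost_grid`, `gamma_grid` | 2^{-5..15}, 2^{-15..3} (log2 steps of 2) | RBF-SVM grid searched by inner-fold accuracy |
| `n_perm` | 1000 | label permutations for classification significance |

The fold counts and grid are conventional choices (the analysis protocol
this package follows does not pin them down); both are plain arguments.
"Dwell time" in group statistics means mean run duration; total dwell time
is always emitted alongside because both readings are in circulation.

## Feature selection and leakage

`select_features` keeps metrics whose raw p is below alpha = 0.05, drawn
from dwell time, occurrence rate, persistence probabilities and trajectory
entropies (off-diagonal transition probabilities only on request). Note
that selecting on the full cohort before cross-validating — the protocol
this package reproduces by default — leaks selection information into the
CV estimate; the feature selection and the CV are deliberately separate
functions so a stricter per-fold selection can be composed when the goal is
an unbiased estimate rather than protocol fidelity. Inside the CV itself
there is no leakage: per-fold z-scoring parameters are fitted on training
rows only (they are exported per fold in the report, and the tests assert
they equal the training-row moments exactly).

## The synthetic cohort generator

Real cohorts of this kind are access-restricted, so validation runs on a
generator with known ground truth (`synthetic_truth`, `simulate_cohort`).
It emulates:

- **Spatial structure.** K = 7 unit-norm, zero-mean templates over a
  116-ROI atlas partitioned into the 6 canonical networks, each template
  concentrating signed weight on 1-2 networks, with one anti-correlated
  pair (r = -0.6) mirroring observed opposite-configuration CAP pairs.
- **Temporal structure.** Per-group irreducible Markov chains with
  self-transitions 0.65 (asymmetric off-diagonals, jittered 30%); the
  patient group raises one state's self-transition to 0.80 — a dwell-time
  effect of roughly 5.7 vs 10 s at TR = 2 s. Setting both to 0.65 gives a
  null cohort.
- **Emission.** frame = amplitude x sqrt(R) x template + iid Gaussian noise
  per ROI; amplitude is fixed at 1 and SNR = amplitude / emission_sigma
  (default 2). sqrt(R) makes the signal and noise vector norms directly
  comparable, and emission_sigma = 0 is the exact noiseless limit.
- **Covariates and symptoms.** Age ~ N(33.5, 12.8^2) truncated at 18, 40%
  male, education ~ N(12.4, 3.2^2), six sites, FD log-normal around
  0.12 mm — drawn independently of group by default, so adjusted and
  unadjusted contrasts should agree; patients' HAMD-like score is linear in
  the true dwell time of the effect state (slope 0.8 /s, intercept 14,
  noise SD 5, truncated at 0), centring severities near 21-22 points.

What the generator does **not** emulate: hemodynamic convolution and
temporal autocorrelation beyond the Markov chain, site or scanner mean
shifts, motion artefacts correlated with group, spatially correlated noise.
Passing the recovery suite therefore shows the estimator chain is correct
and well calibrated under the stated generative model — not that any
particular clinical result would replicate on real data.

### What recovery can (and cannot) target

Because each ROI is z-scored over time before clustering, every ROI is
centered at its occupancy-weighted mean across states. The pattern the
pipeline can recover for state c is therefore the mean-removed,
variance-scaled template — computed exactly by `expected_cap_patterns()` —
not the raw generating template. Recovery checks match centroids against
these expected patterns (exhaustive assignment over permutations); at
SNR 2 the matched spatial correlations exceed 0.999 and frame-level
agreement with the latent sequences exceeds 99%.

## Numerical choices and degenerate inputs

- Constant frames (zero variance across ROIs) have no correlation distance
  and are rejected by name; zero-variance ROI columns likewise at
  standardization.
- The stationary distribution is solved by least squares on the augmented
  system (P' - I; 1) mu = (0; 1) after an explicit irreducibility check
  (boolean reachability closure); reducible chains are refused with the
  unreachable states listed.
- BH q-values are computed directly from the step-up definition
  (`min_{j >= i} p_(j) m / j`, capped at 1) so they agree bit-for-bit with
  the defining formula.
- Ties in the SVM grid search resolve to the first grid point (smallest
  cost); AUC uses midpoint ranks so tied decision scores contribute 1/2.
- All stochastic steps (initial centroids, fold assignment, permutations,
  the generator) are seeded through function arguments; identical seeds
  give bit-identical outputs, which the pipeline tests assert via file
  checksums.

## Problem sizes used in validation

The validation suites run the full study geometry — k = 7, 116 ROIs,
T = 240 frames, n = 60 + 60 subjects (28,800 pooled frames) — once for
spatial recovery, 50 replicate cohorts for the planted-effect detection
rate (expected >= 80% at q < 0.05), and 30 null cohorts for calibration
(rejections bounded by the Binomial(30, 0.05) 98th percentile). Statistical
calibration uses 1,000 null simulations at n = 60; classification checks
use n = 200 with a 6-SD separable feature and 199 permutations. These sizes
give stable rates while keeping a full run on one CPU in the minutes range;
the acceptance script uses 20/15 replicate cohorts for the same two rates.

## Known limitations

- Occurrence and dwell metrics are compositional across CAPs; group tests
  treat them marginally, as is conventional, so per-CAP significance is not
  independent across CAPs.
- Per-subject transition matrices from T = 240 frames are noisy for k = 7
  (on average ~5 observed transitions per cell); trajectory entropies
  inherit that noise, which is why group inference pools across subjects.
- The pipeline starts from ROI time series; it deliberately performs no
  fMRI preprocessing (realignment, nuisance regression, scrubbing) and no
  voxel-wise CAP analysis.
- With strong class imbalance the inner grid search by accuracy can favour
  the majority class; stratified folds mitigate but do not remove this.
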