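# capdyn

Co-activation pattern (CAP) dynamics for multi-subject ROI fMRI time
series.

## What it does, and for whom

Resting-state fMRI is often summarized by static functional connectivity,
which averages away how the brain moves between transient configurations.
CAP analysis instead treats every fMRI frame as a point in
region-of-interest (ROI) space, pools frames across subjects, and clusters
them into K recurring spatial patterns; each subject's scan becomes a
label sequence over those patterns. `capdyn` is for researchers with
parcellated time series (for example 116 AAL ROIs grouped into attention,
default-mode, sensorimotor, visual, subcortical and cerebellar networks)
who want to quantify and compare the resulting brain-state dynamics across
clinical groups — e.g. depression cohorts versus healthy controls — and to
ask whether those dynamics classify individuals.

The pipeline:

- **Clustering**: k-means over pooled frames with distance
  d(x,y) = 1 − Pearson(x,y) (equivalently, spherical k-means on
  row-standardized frames; k-means++ seeding, best of 5 restarts), plus
  cluster-number diagnostics (elbow, silhouette, Calinski–Harabasz,
  Davies–Bouldin, Dunn) over k = 2..20.
- **CAP maps**: per-CAP group Z statistics (subject-mean maps divided by
  their standard error), network attribution by supra-threshold |Z| > 1.96
  mass, and CAP-to-CAP spatial similarity.
- **Dynamics**: per subject — dwell time (mean run duration × TR, s),
  occurrence rate, the directional transition matrix P (diagonal =
  persistence), and the entropy of Markov trajectories
  H_ij (the Shannon entropy of the random path from state i until first
  hitting j), obtained by solving
  H_ij = h_i + Σ_{m≠j} P_im H_mj with h_i = −Σ_m P_im log₂ P_im,
  which satisfies the first-return identity H_jj = H(P)/μ_j
  (Ekroot & Cover, 1993).
- **Statistics**: covariate-adjusted group contrasts (OLS group
  coefficient; covariates age, sex, education, site, mean framewise
  displacement), partial Pearson correlations with symptom scores
  (HAMD-17-style), Benjamini–Hochberg FDR within metric families
  (K per-CAP tests; K×K path tests), and demographic tests (Pearson
  chi-square, Mann–Whitney U).
- **Classification**: nested cross-validated RBF-SVM (inner grid search on
  C and gamma by accuracy, fold-wise feature standardization fitted on
  training data only) with permutation-based p-values.
- **Synthetic cohorts**: a hidden-Markov generator with network-structured
  spatial templates, per-group transition matrices, covariates and
  symptom scores linked to a chosen true metric — ground truth for every
  stage.

## Worked example

Simulate a small cohort with a known planted effect (patients dwell longer
in state 0: self-transition 0.80 vs 0.65), then run the whole pipeline:

```r
library(capdyn)

truth  <- synthetic_truth(k = 4, atlas = synthetic_atlas(40), seed = 3)
cohort <- simulate_cohort(truth, n_control = 20, n_patient = 20,
                          t_len = 240, seed = 5)
res <- run_pipeline(cohort, out_dir = "run1", config = default_config(
  k = 4, n_init = 3, outer_folds = 3, inner_folds = 3,
  cost_grid = c(0.1, 1, 10), gamma_grid = c(0.01, 0.1, 1)))

res$model
subset(res$stats, metric == "dwell")[, c("cap_from", "mean_g1", "mean_g2", "t", "p", "q")]
res$classification$report$mean[c("accuracy", "auc")]
```

```
<cap_model> k = 4, 9600 frames, inertia = 2094.7621, seed = 1
cluster sizes: 2626, 2360, 2316, 2298

  cap_from  mean_g1  mean_g2         t            p            q
1        0 5.456728 9.432139 8.2685691 4.080089e-09 1.632036e-08
2        1 5.581245 5.721837 0.9781652 3.360826e-01 3.832589e-01
3        2 5.643506 5.708851 0.8853339 3.832589e-01 3.832589e-01
4        3 5.415644 5.588939 2.3891498 2.361239e-02 4.722477e-02

 accuracy       auc
0.9484127 1.0000000
```

Reading the output: the fitted model has 4 CAPs over 9,600 pooled frames.
In the dwell-time table (means in seconds), CAP 0 — the state carrying the
planted effect — dwells ~5.5 s in controls versus ~9.4 s in patients, and
the covariate-adjusted contrast is strongly significant after BH
correction within the 4-CAP family (q ≈ 2e-8). The other CAPs sit near
their generated baseline of 1/(1−0.65) ≈ 2.9 frames ≈ 5.7 s; CAP 3 lands
right at the significance boundary (q ≈ 0.047) in this particular draw — a
reminder that per-CAP tests on compositional dynamics are not independent.
The nested-CV SVM separates the groups from the selected dynamic features
with ~95% accuracy. `run1/` now contains the serialized config, centroids,
Z maps, per-subject assignments, the long-format dynamics table, the stats
tables and the classification report.

## References

- Ekroot L., Cover T.M. (1993). The entropy of Markov trajectories.
  *IEEE Trans. Inf. Theory* 39(4):1418–1421.
- Liu X., Duyn J.H. (2013). Time-varying functional network information
  extracted from brief instances of spontaneous brain activity. *PNAS*
  110(11):4392–4397.
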