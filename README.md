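# emtspectrum

Tools for placing bulk or single-cell transcriptomes on a two-dimensional
epithelial–mesenchymal (E–M) spectrum and dissecting its multiphasic
structure. Cancer cohorts are heterogeneous in how strongly they express
the epithelial and the mesenchymal transcriptional programs, and the two
programs are not simply anti-correlated: a substantial fraction of samples
activates both at once (hybrid states). This package quantifies that
structure for computational biologists working with RSEM/FPKM expression
matrices and curated E/M signature lists.

## What it computes

* **E and M scores** — single-sample enrichment scores in [−1, 1] per
  gene set, from a kernel-estimated expression CDF, cross-sample ranking,
  symmetric rank weights `|p/2 − r|`, and the Kolmogorov–Smirnov random
  walk statistic (`score_matrix()`).
* **EMT subpopulations** — diagonal-covariance Gaussian mixtures over
  (E, M) scores fitted by EM, with component count (1–9) and covariance
  structure (EII/VII/EEI/VEI/EVI/VVI) selected by BIC
  (−2 logLik + d log n, lower is better), cluster assignment with
  uncertainties, and semantic labels E, I0 (low–low), I1 (hybrid
  high–high), I2 (M-adjacent), M (`select_model()`, `assign_clusters()`,
  `label_semantic()`).
* **EMT paths** — all minimal routes from the E pole to the M pole
  through adjacent clusters, each modelled as a segmented (breakpoint)
  regression of the deviation coordinate v = (E+M)/√2 on the progression
  coordinate u = (E−M)/√2, with Davies and pseudo-score breakpoint tests
  and score-based breakpoint confidence intervals
  (`enumerate_min_paths()`, `fit_emt_path()`).
* **Induction time courses** — triphasic segmented models of E(t) and
  M(t) with starting breakpoints at 2.5 and 10 days, bound models from
  the first-breakpoint confidence interval, and mapping of the fitted
  trajectory to cohort cluster probabilities (`fit_timecourse()`,
  `bound_models()`, `trajectory_cluster_probs()`).
* **Gene subclusters** — semi-supervised subclustering of E/M genes from
  a combinatorial TGF-β/ZEB1 perturbation panel via a 10×10 batch
  self-organizing map, node labelling by annotated-gene majority, Ward
  clustering with an elbow-selected count, and subcluster scoring over
  time (`train_som()`, `classify_nodes()`, `subcluster_nodes()`).
* **Cluster comparisons** — Welch's t tests with Benjamini–Hochberg
  correction and chi-squared subtype-enrichment tests
  (`compare_all()`, `enrichment_chi2()`).
* **Synthetic data** — seeded generators for cohorts with cluster
  structure on a nonlinear E–M path, low–low outgroups, triphasic time
  courses, and logic-gate perturbation panels (`generate_cohort()`,
  `generate_timecourse()`, `generate_perturbation_panel()`,
  `sample_path_spec()`), so the whole pipeline is testable offline.
* **Orchestration** — `run_pipeline()` executes a cohort, time-course,
  perturbation, or simulation analysis from one YAML config with
  deterministic seeds and a checksummed run report.

## Worked example

```r
library(emtspectrum)

sim <- sample_path_spec(n_samples = 1200, seed = 42)  # (E, M) score pairs
sel <- select_model(sim$scores)
sel
#> <emt_gmm_selection> best: EII, K = 5 (BIC = -2112.916)

asg <- assign_clusters(sel$best_fit, sim$scores)
asg
#> <cluster_assignment> 1200 samples, 5 components
#>   E  I0  I1  I2   M
#> 376 162 242 131 289

paths <- enumerate_min_paths(sel$best_fit)
vapply(paths, paste, "", collapse = "-")
#> [1] "E-I0-I2-M" "E-I1-I2-M"

fit_emt_path(sim$scores, asg, paths[[2]])
#> <emt_path> E-I1-I2-M: 1038 samples
#>   path fit adjusted R2: 0.7805 (all samples: 0.2476)
#>   Davies p = 2.23e-308, pseudo-score p = 1.69e-214
```

The selection table says a five-component, shared-spherical-covariance
mixture describes the cohort best; the assignment splits samples into the
two terminal states and three intermediates. Exactly two minimal EMT
paths connect the poles, and modelling the hybrid (upper) path alone
roughly triples the variance explained relative to forcing one model
through all samples (adjusted R² 0.78 vs 0.25) — the signature of a
multiphasic, two-branch spectrum.

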