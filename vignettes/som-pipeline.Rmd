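---
title: "Mapping cognitive training response profiles with self-organizing maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cognitive training response profiles with self-organizing maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cogsom` analyses multivariate working memory assessment profiles — four
age-standardized span scores per child (verbal and visuospatial, short-term
and working memory) — with a topographic map, and asks how an adaptive
training intervention reshapes both individual profiles and the
relationships between the tasks themselves. This vignette is the package's
own account of the method: the model, every tunable that matters, what the
synthetic cohorts do and do not emulate, the numerical choices, and the
design decisions that were genuinely open.

## The batch self-organizing map

A self-organizing map (SOM) is a lattice of nodes, each carrying a weight
vector $m_i$ in the score space. After training, nearby nodes hold similar
profiles, so the map is a smooth, low-dimensional atlas of the profiles
present in a cohort. `batch_train()` implements the batch variant:

1. Every input profile $x(t)$ is assigned to its best matching unit (BMU),
   the node minimizing Euclidean distance.
2. Each node's buffer collects all inputs whose BMU lies within the current
   neighbourhood radius of it on the lattice; the node's weight is replaced
   by the buffer mean. All updates are concurrent; empty buffers leave a
   node's weight untouched; buffers are cleared each cycle.
3. During the ordering phase the radius shrinks linearly,
   $ND(t) = 1 + INS\,(1 - t/n)$ for cycle $t = 1,\dots,n$, ending at exactly
   1; the fine-tuning phase then updates each node only from the inputs it
   is itself the BMU of.

Weights are initialized linearly from the first two principal components:
node $(r, c)$ starts at the data mean plus $a_r\sqrt{\lambda_1}u_1 +
b_c\sqrt{\lambda_2}u_2$ with $a_r, b_c$ spaced over $[-2, 2]$. This is the
conventional linear initialization; together with the batch rule it makes
training fully deterministic — identical data and configuration give
bit-identical maps, which the test suite asserts.

Key parameters (defaults match the published analysis this package
operationalizes):

| parameter | default | meaning |
|---|---|---|
| `grid_rows` x `grid_cols` | 8 x 8 | lattice size; 64 nodes for ~600 children leaves ~10 inputs per node |
| `initial_neighbourhood` (INS) | 2 | starting radius of the boxcar neighbourhood, in lattice units |
| `ordering_steps` | 10 | batch cycles with a shrinking radius (0 = fine-tuning only) |
| `fine_tune_steps` | 2 | BMU-only refinement cycles |
| `topology`, `grid_metric` | rectangular, Chebyshev | neighbourhood geometry (hexagonal / link distance available) |

Three choices here were genuinely open, because the original analysis used
a toolbox whose lattice conventions it does not record. We use a
rectangular lattice with Chebyshev distance and a hard (boxcar)
neighbourhood, because that makes the neighbourhood *set* — the object the
batch buffers are defined over — exactly enumerable and hence exactly
testable against a brute-force reimplementation. A gaussian kernel would
change the semantics from "set membership" to "weighting", which is not
what the buffer formulation describes. The fine-tuning phase's
"neighbourhood below 1" is implemented as *the node itself*, with identical
semantics and no magic constant. Fit is summarized by the quantization
error: the mean Euclidean distance from each input to its BMU.

## Validating the map: K-nearest-node prediction

A map that represents a cohort well should predict an unseen child's score
on one task from the other three. `knn_predict()` finds the `k = 3` nodes
nearest to the observed sub-vector and returns their inverse-distance
weighted mean on the target task ($w_i \propto 1/d_i$; an exact match
returns the zero-distance nodes' mean). Inverse distance is the simplest
rule satisfying "the closest node has the highest weight"; uniform and
inverse-squared weightings are available.

`cross_validate()` repeats: hold out 20% of the cohort, train a map on the
rest, predict every held-out score, record per-task mean absolute errors
(MAE, in standard-score units). Chance level comes from re-pairing
predictions with the wrong children.

**A calibration subtlety we resolved deliberately.** The observed statistic
is an *average over repetitions* that all reuse one cohort. Two naive null
constructions fail against it:

* pooling every individual shuffle MAE into one flat null compares an
  average against single draws — the null is too wide and the test
  essentially never rejects;
* averaging independent per-repetition shuffles into matched null averages
  fixes the variance of the averaging but not its covariance: the observed
  average pairs the same children the same way in every repetition, while
  independent shuffles do not, so the observed statistic retains
  cohort-level variance the null lacks and the test over-rejects (we
  measured roughly a five-fold inflation at 50 repetitions under an
  independent-task null).

The default null (`null_pooling = "cohort"`) therefore draws, per null
replicate, *one* permutation of the whole cohort and applies it
consistently inside every repetition. The observed statistic is then just
the identity pairing within a family of exchangeable cohort-level
pairings, and the add-one p-value $(1 + \#\{null \le obs\})/(1 + S)$ is
calibrated: under an independent-task cohort the measured rejection rate at
$\alpha = .05$ sits inside the exact binomial band (the acceptance suite
re-measures this). The flat scheme is retained behind
`null_pooling = "flat"` for comparability. For the same reason a small p
means *better than chance*; the complementary convention is available via
`direction = "paper"` in `permutation_p()`.

`generalization_errors()` applies a fixed map to an external cohort with
the same shuffled-prediction null (a single dataset, so the subtlety does
not arise), and `compare_error_sets()` tests error differences between two
cohorts by two-sided label permutation.

## Component-plane similarity and its change

Element $k$ of all node weights forms the *component plane* of task $k$ —
the map's representation of that task. Pearson correlations between planes
(`similarity_matrix()`) quantify how similarly two tasks are represented.
To test whether training changes a pair's relationship,
`bootstrap_pair_difference()` resamples node indices with replacement —
jointly for the two tasks within a map, independently between the pre- and
post-training maps, since node identities do not correspond across
separately trained maps — and accumulates $r_{post} - r_{pre}$ over `B =
10000` resamples. The default decision rule is the self-consistent
two-sided one: reject when 0 falls outside the central 95% nearest-rank
interval. The literal "zero in the bottom or top 5%" rule (which totals
10%) is available as `tail_rule = "paper"`. Percentiles use the
nearest-rank method so results are reproducible to the last bit across
platforms.

Because the planes of a trained map are spatially smooth, the 64 node
elements are not 64 independent observations; under cohort-resampling
no-change nulls the bootstrap is mildly conservative. The acceptance suite
measures the rejection rate under such a null and requires it to stay
within three Monte-Carlo standard errors of nominal — conservatism is
tolerated, over-rejection is not.

## Subgroups, trajectories and covariates

`kmeans_nodes()` partitions the 64 node-weight vectors (unweighted by node
occupancy, which is how the analysis we operationalize describes it; an
occupancy-weighted variant would be a different estimand) with
multi-restart K-means, `k = 4` by default, and relabels clusters by
descending centroid grand mean so that cluster 1 is always the
high-performing profile. Participants inherit the cluster of their BMU.
`silhouette_scan()` exposes mean silhouette widths over a range of `k` so
the cluster count can be justified rather than assumed.

`stability_analysis()` probes robustness by retraining. Batch SOM training
is deterministic given the data, so literally retraining on the same cohort
would reproduce the same map every time and tell us nothing; the package
instead retrains on seeded bootstrap resamples of participants — the
standard cluster-stability device — reclusters, reallocates every
participant, and scores agreement between partitions with the adjusted
Rand index (ARI; label-permutation invariant, 1 = identical).

`allocate_timepoints()` maps a paired pre/post cohort into the *baseline*
clusters (the baseline map is never retrained on the training cohort) and
computes per-task gain scores. `interest_groups()` classifies transitions:
movers into clusters 1–3 (only from outside) and stayers in cluster 4;
everything else — including children already in a target cluster at
pre-training, and edge cases such as a decline from cluster 1 into 4 — is
`other` and excluded from group comparisons. `trajectory_report()` runs
one-way ANOVAs with Tukey HSD post-hocs on gains and on an external
covariate (a fluid-intelligence score assessed before training), and
`treatment_time_interaction()` provides the classical two-way mixed ANOVA
(between = treatment, within = time; with only two time levels no
sphericity correction is needed).

## The synthetic cohorts

The study's raw data are available only on request, so the package ships a
simulator whose defaults encode the published summary statistics; every
pipeline stage is exercised on cohorts with known ground truth.

* **Baseline** (`default_baseline_spec()`): a four-profile gaussian mixture
  — high-all (weight .20), average-flat (.30), visuospatial-above-verbal
  (.20), low-all (.30) — with centroids re-centred and within-profile SDs
  solved so the marginal per-task means and SDs reproduce the published
  combined baseline summary (N = 616) exactly in expectation. Within-profile
  inter-task correlation defaults to 0.3, a package choice: no inter-task
  correlations are published for these cohorts, and 0.3 is a typical
  between-task correlation for standardized span tasks in children.
* **Training** (`default_training_spec()`): pre-training marginals
  calibrated to the adaptive sample summary (N = 179); mean gains equal the
  published post-minus-pre differences, spread over profiles by a
  normalized multiplier (1.29, 1.03, 1.08, 0.72 before normalization) so
  higher-performing profiles gain more; i.i.d. gaussian gain noise per
  task, with SD solved from the published post SDs and floored at 3 score
  points — the printed post SDs are partly *below* what profile-linked
  gains already imply, so exact simultaneous calibration of post SDs and
  effect sizes is impossible and the realized effect sizes carry a small
  downward bias on the verbal working memory task. A Gf covariate is drawn
  per profile (means 108.7/88.5/92.3/81.8, SD 9, echoing the published
  interest-group matrix-reasoning means), so higher-gain profiles have
  higher fluid intelligence.

What the simulator does *not* emulate: floor/ceiling effects and
discreteness of real span scores, age structure, missingness, test-retest
practice effects in the control condition, and any non-gaussian tails. A
passing test suite therefore shows the pipeline recovers structure of this
idealized kind at these sample sizes; it does not certify behaviour under
real-data pathologies, which the loader deliberately refuses to paper over
(missing scores are rejected, never imputed).

Recovery experiments that need unambiguous ground truth (cluster recovery,
stability) use `within_sd = 4`, i.e. well-separated profiles; calibration
experiments (effect sizes, marginals) use the published-scale defaults.

## Numerical and reproducibility choices

* All randomness flows through explicit integer seeds; sub-streams are
  derived with `derive_seed()` (a 31-bit rolling hash), so pipeline stages
  are reproducible independently of evaluation order. Two `run_pipeline()`
  executions with one master seed produce byte-identical artifacts, which
  both the unit and acceptance suites assert.
* BMU ties break to the lowest row-major node index; `order()`'s stable
  sort does the same for K-nearest-node selection. This is what makes batch
  training a pure function of its inputs.
* KNN subspace distances are computed as direct differences (not the
  expanded-square form), so an exact sub-vector match yields a distance of
  exactly zero and triggers the zero-distance rule.
* Degenerate inputs are handled explicitly: rank-deficient data fall back
  to mean-plus-jitter initialization with a warning; constant component
  planes are an error (their correlation is undefined); all-singleton
  clusterings score silhouette 0 by convention; ANOVAs on zero-variance
  data return F = 0 when the effect sum of squares is (numerically) zero
  rather than NaN.
* Model serialization writes doubles at 17 significant digits, so a
  write/read roundtrip restores a bit-identical map.
* Problem sizes in the shipped tests and acceptance script are the
  package's scaled study sizes: cohorts of 616 and 179 where calibration is
  the point, 50 cross-validation repetitions with 100 nulls each, B = 1000
  for bootstrap calibration experiments and B = 10000 for the single
  pipeline RSA, 25 stability retrains, and 20-run detection/recovery
  simulations.

## Known limitations

* The ordering-phase schedule, lattice metric and PCA-init span are
  configurable reconstructions of an incompletely documented original; the
  defaults are the package's documented conventions, not claims about the
  original toolbox.
* The node-index bootstrap treats nodes as exchangeable units; with
  spatially smooth planes this under-uses the effective degrees of freedom
  and errs conservative under no-change nulls.
* K-means with many restarts is a heuristic for the global minimum; the
  test suite verifies exact agreement with exhaustive partitioning only up
  to 6 nodes, and stability should always be checked via
  `stability_analysis()` rather than assumed.
* Interest-group ANOVAs inherit the usual caveats of conditioning groups on
  observed change (regression to the mean is not modelled; the package
  deliberately stops at the published analysis rather than latent
  change-score models).
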