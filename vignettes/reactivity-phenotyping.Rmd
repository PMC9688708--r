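---
title: "Clustering physiological reactivity phenotypes from SPA-fNIRS features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering physiological reactivity phenotypes from SPA-fNIRS features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spaclust)
```

## The analysis problem

Systemic physiology augmented fNIRS (SPA-fNIRS) records cerebral
hemodynamics — oxygenated, deoxygenated and total hemoglobin and tissue
oxygen saturation at the prefrontal (PFC) and visual (VC) cortex — together
with systemic parameters (heart rate, mean arterial pressure, SpO₂,
respiration rate, end-tidal CO₂, skin conductance) while subjects perform a
cognitive task under colored light. Individual responses to such a paradigm
vary strongly: some subjects show large skin-conductance surges, others
hardly react; cerebral oxygenation can rise or fall. The question this
package addresses is whether subjects fall into a small number of
*reactivity phenotypes*, discovered without supervision.

The pipeline is:

1. **Feature extraction.** For each of the 14 time-varying parameters,
   compute the area under the curve (AUC) of the baseline-referenced
   signal over the task phase — one scalar per subject, parameter and
   condition — and append the scalar task performance, giving a
   subjects × 15 table per condition.
2. **Scaling and reduction.** Min–max normalize each feature onto
   [0, 1], then project with PCA, keeping the smallest number of
   components explaining ≥ 80% of the variance.
3. **Constrained subset search.** Enumerate every combination of 1 PFC +
   1 VC + 3 systemic features (320 with the default pools), score each per
   condition by the best mean silhouette achieved by k-means over
   k = 2…9, keep combinations whose silhouette exceeds 0.6 in *every*
   condition, and rank the survivors.
4. **Multi-method validity grid.** On the best combination, run six
   clustering methods (k-means, k-medoids, hierarchical, GMM, DBSCAN,
   SOM), evaluate three validity criteria (silhouette,
   Calinski–Harabasz, Davies–Bouldin) over the k range, and take a
   majority vote across criteria on the optimal number of clusters per
   method and condition.

Because cohorts of this kind are rarely deposited, the package ships a
synthetic cohort generator with planted group structure so that the whole
chain is testable end to end, with known ground truth.

## The synthetic cohort generator

`generate_cohort()` simulates, per subject, condition and parameter, the
signal

$$x(t) = \mu_p + A \cdot s(t) + \beta t + \varepsilon(t),$$

where $\mu_p$ is the parameter's resting baseline, $s(t)$ is a saturating
onset ramp $1 - e^{-(t - t_0)/\tau}$ during the task phase and an
exponential return toward baseline during recovery, $A$ is the subject's
response amplitude, $\beta$ a random linear drift slope and
$\varepsilon$ i.i.d. Gaussian noise (an AR(1) option exists via the `ar`
argument). The protocol is 480 s baseline, 540 s task, 900 s recovery at
1 Hz. Phase AUC is insensitive to fine temporal structure over a 540 s
window, so a controllable task-phase integral — not a hemodynamic response
function — is the right level of detail; $\tau$ defaults to 30 s, a typical
onset scale for slow autonomic and hemodynamic task responses.

Group structure is planted through the response amplitudes: each planted
group is a `group_template()` holding a 14-parameter amplitude vector, and
each subject draws its amplitude per parameter as
$A \sim N(A_{g}, \sigma_{A})$ around its group's value. The default
cohort has 30 subjects, 3 groups under blue light and 5 under red.

Three generator choices deserve explanation:

* **Which features carry group structure.** Groups differ only in
  HHb-PFC, O₂Hb-VC, P_ET_CO₂, SC and SpO₂ — the parameters that drive
  subject classification in this paradigm — while the other nine
  parameters share one common response across groups (with realistic
  between-subject spread, so they are plausible-looking noise features
  for the subset search).
* **Amplitude anchors.** The group amplitude scales are loosely anchored
  to published response ranges for this paradigm: one group with small
  skin-conductance responses (around 1 µS) versus one with very strong
  responses (above 11 µS), and O₂Hb-VC group means spanning roughly
  −1.3 to +1 µM. They are configurable defaults, not claims about any
  real cohort.
* **Low-rank group geometry.** The group mean vectors are constructed on
  a two-dimensional latent plane (an equiangular triangle for 3 groups, a
  pentagon for 5, mapped through fixed per-feature loadings). This
  emulates the empirical situation the pipeline is designed for: two
  principal components carry more than 80% of the feature variance while
  the groups stay well separated in the retained score space. Group
  centers scattered across four or five independent directions would
  instead put group-separating variance into components that an 80%
  threshold discards — a geometry the PCA-then-cluster design is simply
  not meant for, and one at odds with the low-dimensional structure
  reported for this kind of data.

At the default separation the nearest pair of group centers is far beyond
6 within-group standard deviations apart, i.e. the planted partition is
unambiguous; `default_templates(separation = s)` scales every group's
deviation from the across-group mean, with `separation = 0` collapsing all
groups onto one distribution.

Task performance is a rounded Gaussian (58 ± 12 correct nouns, clipped at
0), shared across groups: it is a real feature of the paradigm but carries
no group signal, matching its reported negligible influence on
classification.

`generate_feature_table()` is a fast mode that skips the time series and
draws the AUC features directly from the implied Gaussian mixture, with
component means equal to amplitude × task duration. Its labels use the same
per-subject substreams as the full generator, so both modes plant identical
partitions for a given spec. (The time-series route converges to the fast
mode's means only up to the onset-transient correction τ·A, since the ramp
needs τ seconds to saturate.)

What the generator deliberately does **not** emulate: optode physics,
motion artifacts, extracerebral contamination, autocorrelated (1/f)
physiological noise (available as an option but off by default), circadian
or melanopsin-mediated mechanisms of colored light, and any correlation
structure between parameters beyond what the shared group memberships
induce. Passing recovery tests on these cohorts therefore shows the
*pipeline* is correct and sensitive under clean planted structure — not
that real recordings will separate as cleanly.

## Feature extraction choices

* **Baseline reference.** AUC is computed on baseline-subtracted signals;
  the reference level is the mean over the final 120 s of the baseline
  phase (a steady-state window that avoids the initial settling of the
  recording). Both the subtraction and the window are configurable
  (`baseline_window`).
* **Trapezoidal rule.** Standard for sampled physiological signals and
  exact for piecewise-linear ones; AUC is sign-preserving, so
  deactivations yield negative features.
* **Missing data.** No imputation: a missing channel or non-finite task
  sample is a hard error naming the subject and parameter. The analysis
  assumes a complete post-exclusion cohort; `exclude_subjects` in the
  pipeline config drops subjects before analysis.

## Reduction choices

Min–max normalization maps each feature onto [0, 1] (preserving all rank
relationships); a constant column is mapped to zero with a warning rather
than an error so the exhaustive search stays total. PCA then centers but
does **not** re-standardize — min–max is the scaling step — and retains the
smallest m with cumulative explained variance ≥ the threshold (default
0.8, operationalizing "around 80%" as a checkable ≥ 80% rule). Each
loading vector's largest-magnitude element is made positive so score plots
are reproducible across runs and linear-algebra backends. PCA is applied
per evaluated feature subset (each candidate combination is projected on
its own components), with the global variant available by projecting the
full table once and clustering those scores directly.

## Validity indices and consensus

All three indices are implemented from their standard definitions in
Euclidean score space: silhouette $s(i) = (b - a)/\max(a, b)$ with the
singleton convention $s = 0$; Calinski–Harabasz
$(B/(k-1))/(W/(n-k))$, with $W = 0$ reported as an infinite
"perfect separation" sentinel rather than an error so sweeps survive
degenerate fixtures; Davies–Bouldin as the mean worst-case ratio of summed
spreads to centroid distance. The test suite checks all three against
independent brute-force implementations on hundreds of random instances.

`optimal_k()` breaks ties toward smaller k (parsimony), and
`consensus_k()` takes the majority among the three criteria, falling back
to the silhouette vote on a three-way split — the subset search itself is
silhouette-driven, so silhouette is the natural senior criterion. The
distance metric and singleton convention are recorded in every
`validity_report()` for auditability, since different software defaults
exist for both.

## Clustering method defaults

The methods all return hard labels (`0..m-1`, with `-1` reserved for
DBSCAN noise):

* **k-means**: Lloyd with 50 seeded restarts, best objective kept.
* **k-medoids**: PAM (build + swap) on Euclidean distances — the medoid,
  the most centrally located data point, replaces the mean.
* **Hierarchical**: Ward linkage by default (configurable to
  complete/average), dendrogram cut at k.
* **GMM**: full-covariance Gaussian mixture, hard labels by maximum
  responsibility; fitting uses model-based hierarchical initialization
  followed by EM (deterministic given the data, which we prefer over
  random restarts for reproducibility), falling back to diagonal and
  spherical covariance structures when the full model is degenerate at
  small n.
* **SOM**: a 1 × k map used *as* a clustering — each unit is one cluster
  and points are assigned to their best-matching unit. The codebook is
  initialized along the first principal component and trained online with
  a Gaussian neighborhood whose radius decays toward zero, so the final
  epochs are plain competitive learning.
* **DBSCAN**: min_pts defaults to 3 (a small-cohort choice); the epsilon
  grid defaults to 20 quantiles of the pairwise-distance distribution,
  each run scored by the mean silhouette of its non-noise points, and the
  best run kept. Noise points are excluded from validity indices and from
  the cluster count — which is exactly how a density method ends up
  reporting fewer clusters than the other methods when a couple of
  subjects are too dissimilar from everyone else.

None of these hyperparameters are claims about how any original analysis
was configured; they are documented package defaults, surfaced through
`params`/the pipeline config.

## The subset search

Task performance is excluded from the default systemic pool — it is not a
systemic physiological parameter and its influence on classification is
negligible by construction — but can be added via `feature_pools()`. The
per-combination score is the *maximum* over k of the mean silhouette
(consistent with reporting an optimal k per combination), the pass filter
is strict (`> 0.6` in every condition), and the cross-condition ranking is
the mean of per-condition best silhouettes (a min-across-conditions
alternative is a one-line change on the score list). Scoring uses k-means
only, with 10 restarts per k (restarts are cheap insurance at n = 30;
the full 50-restart configuration is reserved for the final validity
grid); the other five methods enter after the best combination is fixed.

## Determinism

A single master seed fans out to named substreams: one per pipeline stage,
one per subject (by counter offset, so enlarging a cohort never reshuffles
earlier subjects), one per combination, one per k. Two runs of the same
config produce byte-identical report artifacts; numbers are serialized
with 17 significant digits so write-then-read round trips are exact.

## Problem sizes in the test suite

The suite exercises the pipeline at the scale it is designed for:
cohorts of 18–30 subjects, 20 seeded replicates for the recovery and
search-recovery properties, 200 random instances for the index oracles,
and reduced feature pools (2 × 2 × C(4,3) = 16 combinations) where a full
320-combination search would add nothing to the property under test.

## Known limitations

* The search is exhaustive over the constrained space by design; it does
  not scale to pools much larger than the default 14 parameters, and no
  greedy/wrapper alternative is provided.
* Consensus is a majority vote over exactly three criteria; adding
  criteria would need a generalized vote.
* DBSCAN's silhouette-scored sweep may prefer tight solutions that
  relegate borderline members of true clusters to noise; its cluster
  counts are therefore not directly comparable to the k-requiring
  methods, which is the point the validity grid makes visible.
* With ~30 subjects, GMM with full covariances at large k is close to
  unidentifiable; the covariance-structure fallback keeps it defined, but
  its labels should be read with that in mind.
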