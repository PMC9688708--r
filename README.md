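# spaclust

Unsupervised clustering of physiological reactivity phenotypes from
SPA-fNIRS recordings.

## What it is for

When subjects perform a cognitive task (e.g. a verbal fluency task) under
colored light exposure, their cerebrovascular and systemic physiological
responses vary strongly between individuals: skin conductance may surge by
more than 11 µS in some subjects and barely move in others, cerebral
oxygenation may rise or fall. `spaclust` asks whether such a cohort splits
into a small number of *reactivity phenotypes*, using only the measured
signals. It is aimed at researchers working with systemic physiology
augmented fNIRS (SPA-fNIRS): concurrent measurement of hemoglobin species
([O₂Hb], [HHb], [tHb]) and tissue oxygenation (StO₂) at the prefrontal
(PFC) and visual cortex (VC), plus heart rate, mean arterial pressure,
SpO₂, respiration rate, end-tidal CO₂ (P_ET_CO₂) and skin conductance
(SC).

## The method

For each subject, parameter and condition, the task-phase response is
summarized by the baseline-referenced area under the curve

AUC = ∫_task (x(t) − x̄_baseline) dt,

giving a subjects × 15 feature table per condition (14 AUC features +
task performance). Features are min–max normalized onto [0, 1] and
projected with PCA, retaining the smallest number of components with
cumulative explained variance ≥ 80%. An exhaustive constrained search then
scores every combination of 1 PFC + 1 VC + 3 systemic features (320 with
the default pools) by the best k-means mean silhouette over k = 2…9 per
condition, keeps combinations with silhouette > 0.6 in *every* condition,
and ranks them. On the best combination, six clustering methods (k-means,
k-medoids, hierarchical/Ward, Gaussian mixture, DBSCAN, 1×k SOM) are
evaluated with three validity criteria — silhouette s(i) = (b−a)/max(a,b),
Calinski–Harabasz (B/(k−1))/(W/(n−k)), Davies–Bouldin
(1/k)Σᵢ maxⱼ (Sᵢ+Sⱼ)/Mᵢⱼ — and the optimal number of clusters is decided
per method by majority vote across criteria.

Because such cohorts are typically not publicly deposited, the package
includes a synthetic two-condition cohort generator
(`generate_cohort()` / `generate_feature_table()`) that plants known
reactivity groups (by default 3 under blue light, 5 under red, in a
30-subject cohort) through group-specific task-response amplitudes, so the
full pipeline is testable against ground truth. See the vignette
(`vignettes/reactivity-phenotyping.Rmd`) for the generator's signal model
and every tunable default.

## Worked example

```r
library(spaclust)

config <- pipeline_config(
  input_mode = "simulate",
  cohort = cohort_spec(n_subjects = 30, seed = 1),
  seed = 1)
report <- run_pipeline(config)
print(report)
```

```
<spa_run_report>
  best combination: HHb-PFC, O2Hb-VC, PETCO2, SC, SpO2 
  blue: consensus k = 3, mean silhouette 0.94, 100% subjects > 0.6, ARI vs planted 1.00
  red: consensus k = 5, mean silhouette 0.91, 100% subjects > 0.6, ARI vs planted 1.00
```

Reading this: out of 320 candidate feature combinations, the search ranked
`HHb-PFC, O2Hb-VC, PETCO2, SC, SpO2` best across both conditions; on that
combination the three validity criteria agreed on 3 subject groups under
blue light and 5 under red (exactly the planted counts), the mean
silhouette of the consensus partitions was 0.94/0.91, every subject's own
silhouette exceeded the 0.6 "well-separated" cutoff, and the recovered
partitions matched the planted groups perfectly (adjusted Rand index 1.0).

`report$search_table` is the ranked combination table (features, best k
and silhouette per condition), `report$validity_grid` the method ×
criterion grid of optimal k with the per-method consensus, and
`report$correlations` the Pearson correlations between the cerebrovascular
and systemic members of the best combination. With
`output_dir` set, all tables are written as TSV plus a JSON provenance
file, and two runs of the same config are byte-identical.

A thin command-line wrapper is available at
`inst/scripts/spaclust.R`:

```sh
Rscript inst/scripts/spaclust.R --seed 7 --methods kmeans,dbscan --out results/
```

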