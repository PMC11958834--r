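# covanet

Condition-specific protein covariation networks from time-course
immunofluorescence feature quantities — and their comparison, clustering,
and PPI-based expansion for combination-target nomination.

## The problem

Image-based profiling of a drug response stains one protein per well,
fixes cells along a time course (e.g. 5–60 min), and quantifies per-cell
*feature quantities* per compartment: mean intensity in the nucleus,
cytoplasm, plasma membrane, and in intensely stained "domains" (large)
and "aggregates" (small), plus areas, circularities, and per-well
formation rates. Because proteins are stained in separate wells,
cross-protein structure lives only in the aggregated time courses. The
questions covanet answers:

1. Which feature quantities covary over the time course, per condition?
   Modelled as a Gaussian graphical model fitted by the **graphical
   lasso**: edges are partial correlations, the penalty ρ controls
   sparsity (higher ρ, fewer edges).
2. Where do two condition networks differ? Scored per node by the
   **correlation anomaly score** `a_i = max(d_i^AB, d_i^BA)`, where
   `d_i^AB` is the expected Kullback–Leibler divergence between the two
   models' Gaussian conditionals of feature `i` given the rest — a
   closed-form function of the precision/covariance blocks that is large
   when the connectivity and correlation strength of `i`'s first
   neighbors change.
3. Which proteins outside the panel are implicated? Densely connected
   overlapping **link communities** (selected when their mean degree
   `2|E_i|/|V_i|` strictly exceeds the whole-graph mean degree) are
   expanded through a BioGRID-format PPI graph to first neighbors that
   (i) share a GO term enriched in the cluster, (ii) touch >50% of the
   cluster's high-anomaly proteins, and (iii) do both at ≥2 penalties.

A first-class synthetic-data module generates everything the pipeline
consumes — feature tables with known sparse precision structure and a
planted node-neighborhood perturbation, microscopy fields with known
object inventories, PPI/GO fixtures with a planted candidate and decoys —
so the whole chain is testable offline against ground truth.

## Worked example

Simulate a three-condition study in which the drug condition perturbs the
precision-matrix neighborhood of feature 7 (`P03|nucleus`) and the rescue
condition reverts to control; fit one network per condition at a common
penalty; score all condition pairs:

```r
library(covanet)

spec <- synth_spec(
  n_proteins = 5, compartments_per_protein = c("nucleus", "cytoplasm", "aggregate"),
  n_conditions = 3, time_points_min = seq(3, 60, by = 3),
  cells_per_well = 100, wells_per_timepoint = 10,
  anomaly_nodes = 7L, seed = 42
)
spec
#> Synthetic covariation study spec
#>   5 proteins x 3 compartments = 15 features
#>   3 conditions (control, treated, rescued), 20 time points, 10 wells x 100 cells
#>   sparsity 0.30, anomaly at node(s) 7 (magnitude 1.00), seed 42

sim <- simulate_feature_table(spec)   # 900,000 single-cell records

models <- lapply(spec$condition_labels, function(cond) {
  fm <- assemble_feature_matrix(sim$records, cond)   # 200 x 15, standardized
  graphical_lasso(feature_correlation(fm), rho = 0.05,
                  keys = fm$keys, condition = cond)
})
names(models) <- spec$condition_labels
models$treated
#> precision_model: condition 'treated',  M = 15, rho = 0.05, 67 edge(s)

hm <- anomaly_heatmap(models, rho = 0.05)
round(hm$scores[1:5, ], 4)
#>                              control vs treated treated vs rescued control vs rescued
#> P03|nucleus|mean_intensity               0.0902             0.1657             0.0162
#> P01|aggregate|mean_intensity             0.0608             0.1204             0.0326
#> P02|cytoplasm|mean_intensity             0.0861             0.0556             0.0400
#> P04|nucleus|mean_intensity               0.0843             0.0320             0.0363
#> P03|cytoplasm|mean_intensity             0.0615             0.0261             0.0543
```

The planted feature `P03|nucleus` tops both drug-containing comparisons
and drops to near zero in `control vs rescued` — the perturbed node is
flagged exactly where the design says conditions differ, and the scores
quantify how strongly its neighborhood changed. Across 100 seeded
replicates of this design the planted node is the top-scoring node 96
times (see the acceptance script below).

One call runs the whole pipeline (simulation → networks across a ρ grid →
anomaly tables → cluster selection → expansion) with a single seed and a
checksummed manifest, and renders figures:

```r
manifest <- run_pipeline(run_config(out_dir = "run1", seed = 1))
report_pipeline("run1")
```

`cliffs_delta(x, y)` provides the nonparametric effect size used for
single-cell distribution comparisons.

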