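---
title: "Models and methods behind covanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind covanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covanet)
```

## The problem

Immunofluorescence time courses measure, per protein and per cellular
compartment, scalar *feature quantities* — mean intensity, area,
circularity, domain/aggregate formation rates — for cells fixed at a grid
of times after a treatment. Because each protein is stained in separate
wells, no single cell ever carries measurements for two proteins:
cross-protein structure exists only at the level of the well-aggregated
time course. covanet builds, per treatment condition, a *covariation
network* over these feature quantities: a Gaussian graphical model whose
edges are partial correlations estimated by the graphical lasso. It then
compares condition networks node by node with a correlation anomaly score,
extracts densely connected overlapping clusters from the drug-condition
network, and expands them through a protein–protein interaction (PPI)
database under Gene Ontology (GO) and anomaly-adjacency filters to
nominate combination-treatment targets.

The package is organized so that every stage is testable without any
external download: a synthetic-data module generates feature tables with
known sparse precision structure, microscopy fields with known object
inventories, and PPI/GO fixtures with planted expansion candidates.

## The statistical model

For one condition, let $x \in \mathbb{R}^M$ collect the standardized
feature quantities of one sample (one time point in one well). We model
$x \sim \mathcal{N}(0, \Sigma)$ with sparse precision matrix
$\Lambda = \Sigma^{-1}$. Given the empirical correlation matrix
$S = \frac{1}{N} X^\top X$ of the standardized $N \times M$ data matrix,
the graphical lasso estimate maximizes

$$\log\det\Lambda - \operatorname{tr}(S\Lambda) -
  \rho \sum_{i \neq j} |\Lambda_{ij}|,$$

with the L1 penalty on off-diagonal entries only, so the diagonal is
unpenalized and a penalty $\rho \ge \max_{i\neq j}|S_{ij}|$ provably
yields the diagonal solution $\Lambda = \mathrm{diag}(1/S_{jj})$ — a
useful end-member check. Edges carry the partial correlations
$r_{ij} = -\Lambda_{ij}/\sqrt{\Lambda_{ii}\Lambda_{jj}}$. Because the
input is always standardized to a correlation matrix, $\rho$ is
scale-free and comparable across conditions.

The solver is block coordinate descent over columns (each column a lasso
regression, solved in compiled code), with two details that matter for
reproducibility:

* **Convergence** is declared on the true duality gap
  $\operatorname{tr}(S\Lambda) + \rho\|\Lambda\|_{1,\text{off}} - M$,
  computed from the exact inverse of the working covariance $W$. The
  working $W$ is dual feasible by construction (each column update keeps
  $|w_{12}-s_{12}|_\infty \le \rho$ and the diagonal fixed at
  $\mathrm{diag}(S)$), so the gap is a genuine optimality bound and is
  nonnegative up to round-off. The default tolerance is `1e-4`
  (configurable); with a tolerance of `1e-9` the solution is
  permutation-equivariant to below `1e-6`, which the tests assert.
* **Exact zeros** are taken from the lasso coefficients' support, so the
  sparsity pattern is not blurred by the final dense inversion; an edge
  floor of `1e-8` separates solver zeros from tiny estimates downstream.

Penalty sweeps are warm-started along the ascending $\rho$ path; the
tests check that warm-started and cold solutions agree and that edge
counts do not increase with $\rho$.

## The correlation anomaly score

For two fitted models $A$ and $B$ over the same features, partition each
precision and covariance with node $i$ permuted last,

$$\Lambda = \begin{pmatrix} L & l \\ l^\top & \lambda \end{pmatrix},
  \qquad
  \Sigma = \begin{pmatrix} W & w \\ w^\top & \sigma \end{pmatrix},$$

so that $p(x_i \mid z)$ (with $z$ the other $M-1$ features) is Gaussian
with mean $-l^\top z/\lambda$ and variance $1/\lambda$. The directed
divergence of node $i$ is the expected Kullback–Leibler divergence of the
two conditionals under $A$'s marginal for $z$:

$$d_i^{AB} = w_A^\top (l_B - l_A) + \frac{1}{2}\left\{
  \frac{l_B^\top W_A l_B}{\lambda_B} - \frac{l_A^\top W_A l_A}{\lambda_A}
  \right\} + \frac{1}{2}\left\{\ln\frac{\lambda_A}{\lambda_B} +
  \sigma_A(\lambda_B - \lambda_A)\right\},$$

and the anomaly score is $a_i = \max(d_i^{AB}, d_i^{BA})$. The closed
form follows from the Gaussian-conditional KL identity together with the
block-inverse relations $w_A = -W_A l_A / \lambda_A$ and
$\sigma_A = (1 - w_A^\top l_A)/\lambda_A$; the test suite verifies it
against a Monte-Carlo estimate of the defining expectation (shared
standard-normal draws, $10^6$ per node) within three Monte-Carlo standard
errors, and asserts the structural properties: $a_i \ge 0$, symmetry in
$(A, B)$, exact zero for identical conditionals, permutation
equivariance, and locality (a node whose precision row is unchanged
scores zero).

Scores are always compared between models fitted at a *common* $\rho$;
comparing across penalties would confound sparsity with anomaly. Scores
within $10^{-9}$ below zero are clamped to zero. Whether small glasso
entries should be thresholded before the block extraction is not
prescribed anywhere; this implementation uses the raw converged
$\Lambda$, which keeps the score continuous in the data.

## The synthetic study

The generator's defaults describe the study design the pipeline is meant
for: 3 conditions (control, treated, rescued), fixation times
5–60 min (9 points), 2 replicate wells per time point, 200 cells per
well, and a panel of 35 proteins × 3 compartments. Its model is exactly
the model the estimator assumes, by design:

* A base precision matrix with a requested fraction (default 0.3) of
  nonzero off-diagonal entries, magnitudes uniform in 0.2–0.8 with random
  signs, made positive definite by diagonal dominance (diagonal = absolute
  row sum + margin 1.0, which also lower-bounds the spectrum by the
  margin). Diagonal dominance is deterministic and seed-stable, unlike
  rejection sampling.
* The *treated* condition perturbs the neighborhood of designated nodes:
  each nonzero coupling in the node's row/column is re-signed and
  rescaled by $1 + \text{magnitude}$, with diagonal repair preserving
  each affected row's dominance margin. At magnitude 1 every neighbor
  coupling reverses sign and doubles — a maximal, deterministic change in
  the node's conditional dependence structure, emulating the "connectivity
  and correlation strength of first neighbors" contrast the anomaly score
  is designed to detect. The *rescued* condition reverts to the control
  precision, so the three condition pairs reproduce the
  control/drug/rescue logic: the drug-containing pairs light up at the
  planted node and the control-vs-rescue pair stays dark.
* Each (time, well) receives one latent draw from the condition's
  covariance plus a smooth per-feature degree-2 polynomial trend
  (SD 0.5 in latent units, identical across conditions, with an optional
  onset step); each cell reports the latent value plus independent
  Gaussian noise (SD 1.0). Medians across a few hundred cells therefore
  track latent + trend with noise attenuated by $\approx 1.25/\sqrt{n}$.
  Gaussianity is a modeling convenience, not a claim about real feature
  distributions; what passing tests show is that the estimator recovers
  the structure *its own model class* generates, with realistic
  aggregation noise and trend confounding, not that it is robust to
  arbitrary real-data distributions.

Rendered image fields place cells on a jittered grid (spacing chosen so
polygons cannot overlap), draw nuclei as Gaussian blobs, cell bodies as
random convex polygons, and puncta as discs of two size classes placed
inside each polygon's inradius; signal is spread over z planes with a
Gaussian focal profile and corrupted by Poisson shot noise plus Gaussian
read noise (a standard fluorescence model; optics beyond Gaussian blur,
photobleaching and drift are out of scope). Ground truth inventories
every object, which is what the segmentation and detection tests score
against.

## Image analysis choices

Nuclei: Otsu threshold, distance-transform watershed to split touching
blobs, minimum area 40 px². Cells: seeded propagation over the
thresholded cell-marker foreground (one cell per nucleus, cells tile the
foreground); a nucleus outside the foreground falls back to its 2 px
dilation with a warning. Cytoplasm is the pixel-exact set difference
cell − nucleus; the PM ring is the inner boundary band of width 3 px
(configurable) — a standard proxy, since the plasma-membrane mask itself
is never defined by the measurement. Puncta: h-maxima on a
1 px-Gaussian-smoothed copy (h = 3 × robust SD), each maximum grown to
the connected region above halfway between its peak and the cell's median
level, an absolute floor of 5 robust SDs over the image median rejecting
residual noise maxima; area ≥ 50 px² classes a detection as "domain",
smaller as "aggregate", and aggregates touching the PM ring are also
recorded as PM-associated. The 50 px² split and the h factor are declared
defaults (the source imaging software's parameters are proprietary and
unpublished — these values are chosen for the generator's scale, not
inferred). Circularity is $4\pi A/P^2$ with the perimeter measured along
the traced boundary chain (orthogonal steps 1, diagonal steps $\sqrt 2$);
interior holes are not traced, so an annulus scores by its outer
boundary. Empty compartments report missing intensity, never zero, so
aggregation is not biased.

## Clustering and expansion choices

Protein-level graphs (any subnode edge implies a protein edge; maximum
absolute partial correlation retained) are decomposed into *link
communities*: edges sharing a node are scored by the Jaccard similarity
of the inclusive neighborhoods of their non-shared endpoints,
single-linkage clustered, and cut at the height maximizing partition
density (ties resolved toward the lowest cut). Edge clusters partition
the edge set while vertex sets may overlap, which is the property the
downstream selection rule needs; the backend is interchangeable with any
overlapping-cluster generator because selection depends only on
$(|E_i|, |V_i|)$. A cluster is selected iff its mean degree
$2|E_i|/|V_i|$ strictly exceeds the whole-graph mean degree $2|E|/|V|$ —
strictness means the whole graph never selects itself.

Enrichment of GO terms in a cluster uses the one-sided hypergeometric
test over terms held by at least two cluster proteins, BH-adjusted within
the cluster, enriched at $q \le 0.05$; unannotated proteins count as
term-free. The test, threshold, and background (the annotation universe)
are declared defaults, as no specific test is prescribed by the method's
sources. Expansion candidates are PPI first neighbors of the cluster,
filtered by (i) sharing an enriched GO term, (ii) PPI adjacency to
strictly more than 50% of the cluster's high-anomaly proteins ("high" =
at or above the within-cluster 80th percentile of protein-level scores,
configurable), and (iii) passing both at ≥ 2 penalty values. Ties in the
nomination ranking break by link fraction, then PPI degree, then symbol.

## Pipeline, determinism, and problem sizes

`run_pipeline()` executes simulate → network → anomaly → expand from one
configuration with a single master seed; every stochastic stage derives
its seed from it. Stage outputs are TSVs whose checksums (computed over
row-sorted content, so cosmetic ordering cannot break comparisons) are
recorded in a JSON manifest together with the configuration hash, dropped
features, warnings and timings; re-running a completed configuration
verifies checksums and performs zero recomputation. The default run uses
a 13-protein panel (M = 39 features) and the penalty grid
$\{0.80, 0.86, 0.92, 0.96\}$ bracketing the representative 0.92. With the
generator's moderate covariation strength, high-penalty networks are
sparse — selected clusters typically surface at the lower end of the
grid, and the nomination stage requires clusters at ≥ 2 penalties, which
a denser (lower-$\rho$, larger-panel) configuration exercises; the
fixture-based tests cover the nomination logic exactly.

The test suite and the acceptance script use these problem sizes, chosen
to exercise the estimators well inside a desk-scale compute budget:
planted-anomaly recovery with M = 15 features and N = 200 samples
(20 time points × 10 wells, 200 cells per well) over 100 seeded
replicates at $\rho = 0.05$, a penalty low enough to retain the
generator's moderate partial correlations; support-recovery F1 with
M = 10, N = 200 over 20 seeds on a 13-point penalty grid scored against
the true support; the Monte-Carlo oracle with $10^6$ draws per node over
100 random model pairs with $M \le 6$; and 50 rendered fields for
segmentation accuracy. On one CPU the whole suite runs in about three
minutes.

## Known limitations

* The Gaussian, single-latent-draw-per-well generative model cannot show
  robustness to heavy-tailed intensities, segmentation artifacts, or
  between-well batch effects; it validates the estimator in its own model
  class.
* The anomaly score has no null calibration here (raw scores only), so
  "high anomaly" is a within-comparison quantile, not a significance
  statement.
* Time-lagged or dynamic network structure is out of scope; samples are
  treated as exchangeable rows.
* The link-communities backend reproduces overlapping membership but not
  necessarily the exact clusters another overlapping-cluster algorithm
  would produce; conclusions should rest on the selection rule, which is
  backend-independent.
* Real BioGRID/GO snapshots are much larger and noisier than the
  fixtures; parser dialects cover the documented column contracts, not
  every historical format variant.
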