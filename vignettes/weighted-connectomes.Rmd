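---
title: "Methods: weighted connectome construction, edge statistics and null-normalized topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted connectome construction, edge statistics and null-normalized topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
edge-weighting models, the filtering and consensus rules, the statistical
machinery, the null models, and — because several of these are
underdetermined by common practice — the design choices the package makes
and why. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Edge-weight construction

A structural connectome assigns each node pair (i, j) a weight summarizing
the tractography streamlines connecting them. The package builds eight
weightings from a per-streamline table (endpoints, length in mm, COMMIT
weight, SIFT2 weight, per-streamline medians of R1, FA, RD, ICVF):

* **NoS** — streamline count. **LoS** — mean streamline length (mm).
* **SIFT2** — sum of SIFT2 streamline weights (fiber density).
* **COMMIT** — the length-weighted sum
  $\alpha_{ij} = \sum_{k=1}^{N_{ij}} x_{ijk}\, l_k \,/\, \bar L_{ij}$,
  interpretable as total intra-axonal cross-sectional area. With equal
  streamline lengths this reduces algebraically to the plain weight sum,
  an identity the tests assert.
* **Tractometry (R1, FA, RD, ICVF)** — the median of the metric along each
  streamline (an input column; the voxel-level sampling is out of scope)
  averaged across streamlines per pair.
* **FC** — Fisher-Z-transformed Pearson correlation of node time series,
  with r clipped to |r| ≤ 1 − 1e−15 so edge weights are always finite.

Filtering follows the tractography-processing convention: streamlines with
COMMIT weight below **1e−12** (machine-precision zero) are false positives
and are removed before COMMIT and tractometry construction, while NoS, LoS
and SIFT2 are built from the unfiltered table — the COMMIT filter is
defined on COMMIT weights only. Uniformity across weightings is then
restored at the *edge* level: within each subject, any edge whose COMMIT
weight is below threshold is zeroed in **all** weightings, so every
subject carries a single binary connectivity map. A **50% consensus mask**
(edge kept iff nonzero in at least half the subjects; ties at exactly half
are kept, the natural reading of "at least half" with an even cohort)
defines the group edge set, and group weights are subject-wise means
**excluding zero-valued edges**.

**Node-volume normalization.** NoS, SIFT2 and COMMIT are divided by node
volume, but the combining rule for the two endpoint volumes is not a
settled convention. The package divides by the *mean* endpoint volume,
$W'_{ij} = 2W_{ij}/(v_i + v_j)$: symmetric in the endpoints, the identity
for unit volumes, and differing from the endpoint-sum rule only by a
global factor of 2 (irrelevant to every rank-based statistic downstream).
Normalization happens before group averaging.

## 2. Edge statistics

**Variability.** The quartile coefficient of dispersion,
$CQD = (Q_3 - Q_1)/(Q_3 + Q_1)$, is the variability measure because edge
weights are heavy-tailed and a ratio of quartiles is insensitive to
outliers and to overall scale (CQD is invariant to positive rescaling and
bounded by 1 for nonnegative data — both property-tested). Quartiles use
linear interpolation between order statistics (R's default type 7); no
alternative convention is implied anywhere, and all frozen expected values
in the tests are derived under this rule. Intra-subject CQD pools a
subject's nonzero masked edges; inter-subject CQD is computed per edge
across subjects, excluding zeros, and reported as NA below two usable
values.

**Length binning.** The observed edge-length range is split into five
linear bins of width $w = (\max - \min)/8$ plus one final bin of width
$3w$ that absorbs the sparse long-edge tail. Values on a boundary fall to
the lower bin; the global maximum belongs to bin 6. Statistics (CQD or a
Spearman correlation against a second weighting) are computed per bin, and
optionally divided by the within-network maximum over bins ("proportion of
max").

**Residualization and correlation.** Edge length is a strong common cause
of edge weight in every weighting, so inter-network comparisons are run on
ordinary-least-squares residuals of value on length; the residuals'
correlation with length is zero to 1e−10 by construction (asserted).
Correlations are Spearman with average ranks for ties; NA pairs are
pairwise-deleted.

**Permutation testing.** The one-sided p value for an edgewise Spearman
correlation is $(1 + \#\{\text{null} \ge \text{obs}\})/(n_{perm} + 1)$
under uniform random permutation of one vector. The +1 convention keeps
p ≥ 1/(n_perm+1) and strictly positive. Two details deserve care:

* The permutation scheme is an *unrestricted* edge-label permutation. It
  does not preserve spatial autocorrelation, so its p values are
  anti-conservative for spatially smooth maps; spatially constrained
  ("spin") nulls are deliberately out of scope.
* The default one-sided direction is taken from the sign of the observed
  statistic, which is how exploratory edgewise correlations are usually
  reported — but under the null that sign-chosen p is uniform on (0, ½),
  not (0, 1). When the alternative is known a priori, pass
  `direction = "greater"` or `"less"`; that fixed-tail test is exactly
  calibrated (its null p values are uniform, verified by simulation with a
  KS test in the acceptance suite).

## 3. Null models

Topology measures are normalized against surrogates that preserve
low-order structure:

* **Degree-preserving (binary)**: Maslov–Sneppen double-edge swaps
  (a–b, c–d) → (a–d, c–b), rejecting self-loops and multi-edges. Budgets
  are *attempted* swaps — 100 per edge for binary ensembles, 1e6 per
  surrogate for weighted ones — because accepted-swap budgets are not
  comparable across graphs. Degree sequences are preserved exactly
  (integer equality, asserted on every surrogate).
* **Degree- and strength-preserving (weighted)**: the binary topology is
  rewired, then the network's *own weight multiset* is re-placed on the
  rewired edges by simulated annealing so node strengths approximate the
  original strength sequence. The weight multiset is untouched (sorted
  equality asserted); only the placement changes.

**Annealing schedule.** Energy is $E = \sum_i (s_i - s_i^{target})^2$;
proposals swap the weights of two random edges with incremental ΔE
updates; cooling is geometric per sweep (one sweep = |E| proposals). The
schedule is a free parameter, and a near-greedy one (initial temperature
≈ 1e−3 of initial energy) reliably finds near-zero energies but can stall
on plateaus where the achieved-vs-target strength correlation saturates
below 0.99. The package defaults are therefore hotter and more patient —
T₀ = 0.05·E₀, cooling 0.996, up to 2e4 sweeps, early stop after 400
stagnant sweeps — which reach the brute-force optimum on all n ≤ 6
enumeration checks and correlation ≈ 1.0 on 100-node networks. Surrogate
ensembles that need hundreds of nulls pass a smaller `maxSweeps`; the
quality trade-off is theirs to choose. All of this runs in compiled code
with R's RNG, so results are a pure function of the seed.

## 4. Topology

* **Clustering** is the Onnela geometric-mean triangle intensity on
  weights max-normalized to [0, 1] — the convention of the standard
  brain-connectivity toolboxes; the binary reduction (triangle fraction)
  is property-tested.
* **Paths** use the transform $L_{ij} = -\log(W_{ij}/w_{max})$.
  Max-normalization makes all lengths nonnegative (the strongest edge has
  length 0); absent edges are infinite. Characteristic path length
  averages shortest-path distances over reachable ordered pairs and flags
  disconnected inputs. One degenerate case is worth knowing: a network
  with *all weights equal* has every length 0 and a path length of 0, so
  null-normalized path ratios are undefined there — realistic continuous
  weights never hit this.
* **Betweenness/closeness** run on the −log lengths (chosen over inverse
  weights for consistency with the path-length transform). Shortest-path
  *counting* is ill-posed with exact zero-length edges, so the zero-length
  (max-weight) edges are nudged to an ε far below the graph's own length
  scale but far above double-precision rounding
  (max(10⁻⁶·min positive length, 10⁻⁵)); the brute-force path-counting
  oracle in the tests uses the identical convention, and agreement is
  exact.
* **Eigenvector centrality** is power iteration on W (tolerance 1e−10,
  max 1e4 iterations, small diagonal shift to guard bipartite-like
  spectra), erroring with the iteration count on non-convergence.
* **Small-worldness** is $S = (C/C_{null})/(L/L_{null})$ with clustering
  normalized *within node* by the null mean and then averaged — not
  averaged first — so nodes with atypical clustering do not dominate.
  Nodes whose null-mean clustering is zero are excluded and counted.
* **Rich club.** For each degree level k, the subnetwork of nodes with
  binary degree > k (the binary map is shared across weightings, so core
  identification depends only on degree). Binary:
  $\phi(k) = 2E_{>k}/(N_{>k}(N_{>k}-1))$. Weighted: subnetwork weight sum
  divided by the sum of the $E_{>k}$ largest weights anywhere in the
  network (the ranked-weight estimator). Normalization divides by the
  null-ensemble *mean* per k; detection is the strict criterion
  $\phi_{norm} > 1$ over contiguous k ranges, with no significance test.
  Note that a flat weight multiset makes $\phi^w \equiv 1$ wherever
  defined — the ranked-weight denominator then equals the numerator — so
  the weighted curve does *not* reduce to the binary curve for equal
  weights; the tests assert the correct identity.
* **Stable range.** At high k the subnetwork shrinks to a handful of
  nodes and $\phi^w$ becomes a ratio of small random sums; its own
  sampling spread exceeds a few percent no matter how many nulls are
  averaged. Calibration-style checks (e.g., that weight shuffling on a
  fixed topology abolishes detection to within ±0.05) are therefore
  evaluated over the *supported* k range — subnetworks of at least a third
  of the nodes — and curves beyond it should be read qualitatively.
* **Hubness** scores 0–5: +1 for the top ⌈0.2N⌉ nodes by strength,
  betweenness, closeness and eigenvector centrality, +1 for the bottom
  ⌈0.2N⌉ by clustering. Rank ties break deterministically by node index,
  which makes scores on perfectly symmetric graphs an explicit contract
  (the first ⌈0.2N⌉ nodes take every point) rather than an accident of
  sort order.

## 5. The synthetic-cohort generator

The generator exists so that every pipeline stage is testable without
imaging data. It emulates, per subject and at the group level:

* a **parcellation** of N nodes (default 90) in 8 canonical modules, nodes
  placed in a 150 mm cube as Gaussian scatter (sd 12 mm) around uniform
  module centers, volumes log-normal around 1,000 mm³ (sdlog 0.15);
* a **binary topology** with edge probability ∝
  $e^{-\lambda d_{ij}}(1 + \beta\,[\text{same module}])$ (defaults
  λ = 0.01 /mm, β = 1), rescaled to a target density (default 0.35) and
  forced connected by the Euclidean minimum spanning tree;
* a **streamline table** per edge: log-normal streamline counts (median
  12, dispersion σ = 1) decreasing with distance; lengths jittered 5%
  around the Euclidean distance (truncated positive); per-streamline
  COMMIT/SIFT2 weights as gamma shares of heavy-tailed log-normal edge
  totals (sdlog 1.5 and 1.2 — COMMIT the most dispersed, matching its
  strongest observed scaling effects); a configurable fraction (default
  0.3) of COMMIT false positives below 1e−12 to exercise the filters; and
  near-normal tractometry values (e.g. R1 = 1.00 ± 0.05) so streamline
  weightings are heavy-tailed (skewness > 1) while tractometry is
  near-normal (|skewness| < 0.5), both asserted;
* **couplings** imposed through a Gaussian copula: a latent correlation
  $\rho_z = 2\sin(\pi\rho_s/6)$ reproduces a target Spearman $\rho_s$
  through any monotone marginal. The noise component is orthogonalized
  against the conditioning scores (the `mvrnorm(empirical = TRUE)` device)
  so the latent correlation is enforced *empirically*, and targets are
  recovered to within a few hundredths rather than up to sampling noise.
  Default length-coupling targets follow the observed sign pattern:
  negative for NoS (−0.5), SIFT2 (−0.4), COMMIT (−0.6) and RD (−0.3),
  positive for R1 (+0.35), FA (+0.3), ICVF (+0.3). The COMMIT–R1 coupling
  is imposed on the length-independent component, tercile-wise: −0.55 on
  the shortest third of edges, 0 in the middle, +0.25 on the longest —
  reproducing the characteristic bin-wise sign flip while keeping the
  overall residualized correlation negative;
* **subjects** as one shared base table plus per-subject edge dropout
  (default 5%) and multiplicative log-normal weight noise (default
  sd 0.2; tractometry receives proportionally scaled additive noise so its
  inter-subject dispersion stays an order of magnitude below the
  streamline weightings, as observed in real cohorts);
* **FC** via a time-series route: per subject, `fcT` samples (default
  400) from $N(0, \Sigma)$ with $\Sigma = I + c\,s\,A$, where A carries
  rank-transformed group-COMMIT weights on the SC edges, c is the coupling
  (default 0.6) and s scales A just inside positive definiteness
  (nearest-PD repair as fallback); FC is then the Fisher-Z correlation of
  the samples, so finite-T noise and the Z transform behave as they do in
  real data.

Seeding is stream-of-seeds: one master seed, fixed-offset child seeds per
operation and per subject, every RNG use wrapped so library calls never
perturb the caller's stream; all outputs are pure functions of
(config, seed), asserted by identity tests.

**What passing tests do and do not show.** The generator reproduces the
*statistical couplings* of real cohorts, not their biophysics: there is no
gyral-bias or crossing-fiber structure in the false positives, lengths are
Euclidean rather than curvilinear (so LoS tracks geometric distance almost
perfectly), FC is driven by the COMMIT group network alone (so
residualized FC couplings are strongest for COMMIT and near zero for the
other streamline weightings, unlike real data where all three are
comparable), and subject noise has no spatial autocorrelation. Passing
recovery tests shows the pipeline measures what the generator planted; it
does not validate any biological claim about real MRI data.

## 6. Scales used in the tests

The test and acceptance runs use desk scales chosen as the package's own
trade-off between statistical resolution and turnaround: cohorts of 90
nodes × 10 subjects (≈1,400 consensus edges; pooled subject-level edge
sets ≥ 10,000), coupling-magnitude recovery on a 170-node draw (≥ 5,000
independent edges, where ±0.05 checks have headroom over the ≈0.014
sampling sd), 200-null rich-club ensembles with a 1,500-sweep annealing
budget, 25–50-null small-world ensembles, and 500–5,000 permutations.
Full-scale constants (50/1,000 nulls, 1e6 rewires, 10,000 permutations,
414 nodes, 50 subjects) are pinned by the `"paper"` preset of
`validateConfig()`.

## 7. Known limitations

* The permutation null ignores spatial autocorrelation (see §2).
* Weighted rich-club normalization against rewire-then-anneal surrogates
  conflates topology and weight placement when the binary graph itself has
  a topological core: rewiring pulls hub–hub edge counts toward the
  configuration-model expectation, which biases null $\phi^w$ downward at
  high k for *any* weight placement. Interpret weighted detection jointly
  with the binary curve.
* Group averaging excludes zeros, so group weights at low-consensus edges
  are means over few subjects and correspondingly noisy; the consensus
  mask is the guard.
* The annealed placement is a near-optimum, not a uniform sample from the
  strength-constrained ensemble; null means inherit whatever bias that
  optimization character carries.
* Tractometry edge values are modeled directly at the edge level; the
  within-streamline median (the "median-then-mean" rule) is exercised on
  input columns, not recomputed from voxel samples.
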