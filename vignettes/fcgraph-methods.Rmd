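---
title: "Methods: paired graph analysis of functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired graph analysis of functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcgraph)
```

## The analysis model

`fcgraph` treats a resting-state session as a multivariate time series over
a fixed parcellation — by default 14 regions: ten pain-network parcels
(bilateral Brodmann areas 1, 2, 3, 13, 32) and four default-mode parcels
(mPFC, PCC, bilateral lateral parietal cortex). The session's functional
network is the Pearson correlation matrix of the ROI signals; topology
enters through **proportional density thresholding**: at connection density
$k$, the $E = \mathrm{round}(k \cdot N(N-1)/2)$ strongest edges are kept
and binarized. Thresholding by density rather than by a fixed correlation
cutoff equates edge counts across subjects and sessions, so any difference
in a graph index reflects a difference in *arrangement*, not in overall
correlation level. The default sweep spans 5%–40% in 5% steps: below ~5%
the 14-node graph fragments into uninformative pieces, above ~40%
increasingly weak (likely spurious) correlations enter; the 25% point is
used as the reference density for nodal comparisons.

On each binary graph six indexes are computed from first principles:
degree; clustering coefficient $C_i = 2t_i/(k_i(k_i-1))$; nodal average
path length (mean hop distance to reachable peers); local efficiency (the
global efficiency of the subgraph induced by a node's neighbors, the
Rubinov–Sporns convention); nodal global efficiency
$\frac{1}{N-1}\sum_{j \ne i} 1/d_{ij}$; and betweenness centrality via
Brandes' exact accumulation, unnormalized by default.

**Small-worldness.** Each thresholded graph is referenced against
degree-preserving random networks obtained by Maslov–Sneppen double-edge
swaps: $1000 \times E$ attempted swaps, each accepted only if it keeps the
graph simple. With $\gamma = C/C_\mathrm{rand}$ and
$\lambda = L/L_\mathrm{rand}$ (mean clustering and characteristic path
length, real vs. reference), small-worldness is $\sigma = \gamma/\lambda$.
The degree-matched null is essential: an Erdős–Rényi reference with the
same density but a different degree sequence would conflate degree
heterogeneity with topology. A phrase like "rewiring each edge 1000 times"
is interpreted as attempted double-edge swaps because that is the only
standard rewiring that preserves both density and the degree sequence;
single-endpoint rewiring would not.

**Paired testing.** Every (ROI, index) cell and every per-density
$\sigma$ is compared across sessions with the Wilcoxon signed-rank test on
within-subject differences. At the sample sizes of paired clinical imaging
(here $n = 8$), the test is computed *exactly* — the null distribution of
$W$ is the distribution of rank-subset sums over all $2^m$ sign
assignments — whenever at most 12 nonzero, tie-free differences remain.
With ties or larger samples it falls back to the tie-corrected normal
approximation (no continuity correction by default, so the approximate and
exact paths agree closely where both apply; `correct = TRUE` restores the
conservative convention). Zero differences are dropped (Wilcoxon's
original convention rather than Pratt's). No multiplicity correction is
applied by default — the per-cell α = 0.05 flag mirrors exploratory
practice in small studies — and Benjamini–Hochberg is available via
`correction = "BH"` for stricter use.

## The synthetic cohort generator

The generator exists so that the full pipeline — and its statistical
behavior — can be exercised without access to clinical fMRI. Its defaults
encode the paired study design the package targets: 8 subjects, two
sessions each, 150 volumes per session at TR 3 s (a 7.5-minute scan), over
the 14-ROI set.

The signal model is deliberately the *minimal* one carrying the structure
the analysis consumes:

* zero-mean multivariate Gaussian volumes with a target inter-ROI
  correlation matrix (cross-ROI structure);
* an AR(1) temporal filter, re-standardized as
  $x_t = \phi x_{t-1} + \sqrt{1-\phi^2}\,\varepsilon_t$ with correlated
  innovations and a stationary start, so the lag-0 cross-correlation target
  is preserved exactly while consecutive volumes correlate at $\phi$
  (default 0.3, a moderate smoothness plausible for BOLD at a 3-s TR);
* per-subject heterogeneity as additive Gaussian jitter (s.d. 0.05) on the
  off-diagonal correlations, *shared between a subject's two sessions* —
  this is what makes the paired design meaningful, since indexes correlate
  within subject;
* injectable effects: a post-session increment δ on chosen (target,
  partner) correlations, standing in for a treatment-induced connectivity
  change. No calibrated effect size is claimed anywhere; δ is a free
  parameter because the magnitude of real treatment effects on these
  indexes is unknown.

The default base correlation matrix is block-stylized: homotopic pairs 0.6,
within-DMN 0.45, within-pain 0.35, between-network 0.15 — ordinary
magnitudes for resting-state ROI correlations, with the DMN set slightly
more coherent than the pain network. After jitter or effects the matrix is
repaired to the nearest correlation surrogate by eigenvalue clipping at
$10^{-8}$ and re-normalization to unit diagonal — cheap and accurate at
14 × 14.

What the generator does **not** emulate: hemodynamic response shape,
scanner drift and motion artifacts, non-Gaussian tails, spatial
autocorrelation within parcels, or session-order effects. Tests passing on
synthetic cohorts therefore demonstrate the *procedural* correctness and
statistical calibration of the pipeline, not robustness to fMRI artifacts
— on real data, the preprocessing that precedes this package carries that
burden.

Seed management: one master seed; each subject/session (and each null
stream) consumes a sub-stream derived by fixed arithmetic offsets, so
output is bit-identical regardless of evaluation order.

## Numerical choices and degenerate cases

* **Edge rounding**: round-half-up on $k \cdot N(N-1)/2$, minimum one
  edge. At 14 nodes and $k = 0.25$ this gives
  $\mathrm{round}(22.75) = 23$ edges.
* **Edge ranking**: signed correlation descending (strongest positive
  first), the common resting-state convention; `ranking = "absolute"`
  ranks by magnitude instead. Because ranking is invariant under monotone
  transforms, the optional Fisher z-transform never changes a thresholded
  graph; it is exposed but off by default.
* **Ties at the density cutoff** are broken lexicographically on node
  index pairs, with a warning — deterministic across platforms.
* **Disconnected graphs** (inevitable at 5% density on 14 nodes):
  path-length statistics average over reachable pairs only; efficiencies
  use $1/\infty = 0$; isolated nodes have undefined average path length
  (`NA`, excluded from tests with a warning). These are the standard
  connectome conventions and keep every density of the sweep computable.
* **Triangle-free null ensembles** make $\gamma$ (and so $\sigma$)
  undefined; the record is kept with `NA` and the paired comparison for
  that density reports an `NA` p-value when fewer than two complete pairs
  remain.
* **Null ensemble size** defaults to 1 — one random reference per graph,
  the convention of small clinical studies — but this is noisy;
  `ensemble_size = 20` is recommended and used in the package's own
  examples. Both are configuration, not separate code paths.
* **Local efficiency** follows the neighbor-induced-subgraph definition.
  Note that some libraries (igraph among them) measure distances in the
  ego-removed full graph instead; the two differ whenever a detour through
  a non-neighbor shortens a path. The test suite's library oracle is
  composed from subgraph-induction primitives for exactly this reason.

## Open design points, as resolved here

* The connectivity estimator of the upstream toolboxes is not uniquely
  determined; plain Pearson correlation is the default, without claiming
  fidelity to any particular preprocessing product.
* Whether nodal indexes should be compared per density or aggregated over
  the sweep is genuinely ambiguous in practice. The default compares at
  the 25% reference density (producing one row per ROI × index);
  `density_mode = "each"` and `"aggregate"` expose the alternatives.
* Betweenness is reported unnormalized (hub "load"); normalization by
  $(N-1)(N-2)/2$ is a flag.

## Problem sizes used by the test suite

The suite validates metrics against an independent graph library on 500
random graphs of 5–8 nodes across all densities, and against brute-force
path enumeration on every graph of ≤ 6 nodes, to $10^{-10}$; exact
signed-rank p-values against literal $2^m$ enumeration for $m \le 10$;
degree-sequence preservation over 1000 rewiring trials; small-worldness
sanity on Watts–Strogatz ($N = 100$, $k = 6$, $p = 0.05$; $\sigma > 1$)
and Erdős–Rényi ($G(100, 0.3)$; $\sigma \approx 1$) families over 20 seeds
each; and calibration of the full testing procedure over 1000 replicate
null cohorts (per-cell flag rate ≈ 4% at α = 0.05 — slightly conservative
because the exact p-value distribution at $n = 8$ is discrete) plus
detection of a strong injected effect (δ = +0.35 to six partners) in
≥ 80% of 100 replicates.

## Known limitations

* Binary undirected graphs only; no weighted metrics, modularity,
  rich-club, or assortativity.
* The lattice-referenced small-world variants (ω, SWP) are out of scope;
  only $\sigma = \gamma/\lambda$ is computed.
* With $n = 8$ pairs the attainable two-sided p-values are coarse (the
  floor is $2/2^8 = 0.0078$); power against subtle effects is inherently
  low, and the package makes no attempt to hide that.
* The generator's Gaussianity means heavy-tailed BOLD artifacts are not
  represented; calibration results transfer to real data only insofar as
  the rank-based test is distribution-free.
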