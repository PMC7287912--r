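# fcgraph

Graph-theoretic analysis of longitudinal (pre/post-treatment) resting-state
functional brain connectivity, for paired-design studies over a small
region-of-interest (ROI) parcellation.

Clinical resting-state fMRI studies often ask whether a treatment changes
the *topology* of functional networks rather than any single pairwise
correlation. The workflow this package implements is the standard one for
that question, end to end:

1. **Connectivity.** For each subject and session, the ROI-level BOLD time
   series (volumes × ROIs) yield a Pearson correlation matrix — the
   weighted adjacency of a 14-node network spanning a pain network
   (bilateral Brodmann areas 1, 2, 3, 13, 32) and the default mode network
   (mPFC, PCC, bilateral lateral parietal cortex).
2. **Proportional thresholding.** The matrix is binarized by keeping the
   strongest *E* = round(*k* · *N*(*N*−1)/2) edges at each connection
   density *k* of a sweep (5%–40% in 5% steps by default), so every
   subject's graph has the same edge count at a given density.
3. **Graph indexes.** On each binary graph: degree *k_i*, clustering
   coefficient *C_i* = 2*t_i* / (*k_i*(*k_i*−1)), nodal average path
   length, local efficiency (efficiency of the neighbor-induced subgraph),
   nodal global efficiency (mean 1/*d_ij*), and betweenness centrality
   (Brandes' algorithm, exact).
4. **Small-worldness.** Each graph is compared against degree-preserving
   randomized references (Maslov–Sneppen double-edge swaps, 1000 attempted
   swaps per edge): with γ = *C*/*C*<sub>rand</sub> and
   λ = *L*/*L*<sub>rand</sub>, the small-worldness index is σ = γ/λ; σ > 1
   indicates small-world organization.
5. **Paired statistics.** Every (ROI, index) cell — and σ at each density —
   is compared across sessions with the Wilcoxon signed-rank test, exact by
   full sign-assignment enumeration at small samples, and summarized with
   direction flags and pre-normalized (post/pre) medians for a radar-style
   overview.

Raw clinical fMRI is rarely shareable, so the package also ships a
**synthetic paired-cohort generator**: zero-mean Gaussian ROI series with a
controllable inter-ROI correlation structure, AR(1) temporal smoothness,
shared per-subject jitter, and injectable post-session connectivity
effects. Every stage of the pipeline is testable against it.

## Worked example

Simulate the default paired cohort (8 subjects × 2 sessions × 14 ROIs ×
150 volumes at TR 3 s) with a known post-session effect — a +0.35
correlation boost between the left lateral parietal cortex and six
somatosensory partners — and run the full analysis:

```r
library(fcgraph)

partners <- c("BA1_L", "BA1_R", "BA2_L", "BA2_R", "BA3_L", "BA3_R")
cohort <- generate_cohort(cohort_config(
  effects = list(effect_spec("LateralParietal_L", partners, delta = 0.35)),
  seed = 42
))
res <- run_pipeline(cohort, run_config(null = null_config(ensemble_size = 20),
                                       seed = 43))
dplyr::filter(tibble::as_tibble(res$comparison), significant)
```

```
   roi             metric densi…     W p_value direction median_pre median_post
 5 LateralParieta… betwe…   0.25    36 0.00781 increase       0.5        38.2
 6 LateralParieta… degree   0.25    36 0.0112  increase       2          7.5
 7 LateralParieta… globa…   0.25    36 0.00781 increase       0.231      0.769
...
```

The injected target is recovered: degree at `LateralParietal_L` rises from
a median of 2 to 7.5 edges (exact Wilcoxon p = 0.011; W = 36 is the maximal
statistic for 8 untied pairs, whose two-sided p floor is
2/2⁸ = 0.0078125), and its betweenness and global efficiency rise with it.
`res$radar` expresses each flagged index as a post/pre median ratio
(e.g. degree 3.75, i.e. a 3.75-fold increase over the pre-treatment
median), `autoplot(res$sweep)` draws the σ(k) curves, and
`write_results(res, dir)` exports all tables plus a provenance block that
reproduces the run bit-identically.

With no injected effect the same pipeline is calibrated: across replicate
null cohorts the per-cell flag rate at α = 0.05 stays near 4% (the exact
test is slightly conservative at n = 8 because the p-value distribution is
discrete).

A thin command-line wrapper with `simulate` and `run` subcommands is
installed at `inst/scripts/fcgraph-pipeline.R`.

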