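---
title: "Methods: functional connectome graph analysis across WMH severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional connectome graph analysis across WMH severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wmhnet)
```

This vignette is the package's own account of the science it
implements: the model and its assumptions, the tunable parameters and
their defaults, what the synthetic cohort does and does not emulate,
the numerical conventions, and the known limitations. It states no
empirical result that the test suite does not itself compute.

## 1. The analysis model

The pipeline compares resting-state functional brain networks between
two severity strata of cerebral small vessel disease, defined on the
Fazekas scale: periventricular and deep white-matter hyperintensities
are each graded 0–3 and summed; totals 1–2 form the low-severity group
A, totals 3–6 the high-severity group B (`fazekas_group()`; a total of
0 is "ungrouped" — only WMH-positive subjects are enrolled).

Per subject, the N = 90 AAL regional BOLD series are temporally
cleaned, correlated (Pearson), variance-stabilized (Fisher z =
artanh r), and binarized at a *sparsity* threshold s: exactly
`round(s·N(N−1)/2)` strongest edges are kept. Because absolute
correlation levels differ between people, fixing the edge *count*
rather than an r cutoff is the standard way to compare topology across
subjects; the cost is that only the rank order of correlations matters
(a fact that drives a limitation discussed in §6).

On each binary graph we compute:

* **Cp**, mean clustering coefficient: for node i,
  `2·t_i / (k_i(k_i−1))` with `t_i` triangles through i; degree < 2
  contributes 0 (GRETNA convention). Local segregation.
* **Lp**, characteristic path length: mean breadth-first distance over
  ordered pairs. Global integration.
* **Eglob** = mean of `1/d(i,j)`; **NodalE**(i) = mean of `1/d(i,j)`
  over j ≠ i (their node-mean identity `mean(NodalE) = Eglob` holds
  exactly and is tested); **Eloc**(i) = global efficiency of the
  subgraph induced by i's neighbors.
* **γ, λ, σ**: Cp and Lp normalized by their means over an ensemble of
  degree-preserving random graphs, σ = γ/λ. Small-worldness is
  γ > 1 with λ ≈ 1, equivalently σ > 1.

Profiles are computed at sparsities 0.05–0.40 in steps of 0.05 and
summarized by the **arithmetic mean across thresholds**. This summary
convention is validated against a published per-threshold table bundled
with the package (`reference_global_metrics()`): the means of the eight
printed per-threshold values reproduce the printed summary figures
(e.g. Cp 0.177/0.167, Lp 3.46/3.65, γ 1.99/1.91) to one unit in the
last printed digit — the published figures appear to be truncated, not
rounded (mean Cp_A is 0.177625), hence the one-unit tolerance. An
AUC-style summary (mean × grid width) is available in
`global_profile()$auc`.

## 2. Statistical layer

Group comparisons are gated on normality: Welch's t-test iff both
groups pass Shapiro–Wilk at α = 0.05, otherwise Mann–Whitney U
(`normality_gate()`; a constant sample has undefined normality and
takes the nonparametric branch). Summaries follow the convention
mean ± SD when normal, median (IQR) otherwise. For the U branch the
*standardized* U is reported so that swapping groups flips the
statistic's sign in both branches.

Multiplicity is controlled by Benjamini–Hochberg step-up FDR within two
separate families: the 7 global metrics, and the 90 nodal-efficiency
tests. Note that BH is order-preserving and dominates the raw
p-values, but it is **not** an idempotent map (counterexample:
p = (0.01, 0.5) → q = (0.02, 0.5) → q′ = (0.04, 0.5)); the test suite
asserts idempotence only on tied inputs, where it holds.

"Binary linear regression for age correction" is read as logistic
regression of group membership on metric + age
(`age_adjusted_group_effect()`), the only interpretation consistent
with a binary outcome and an age covariate; perfect separation is
flagged, not raised. Cognition analyses use partial correlation —
Pearson correlation of the OLS residuals of x and y on
[intercept, age, sex, education], with p from
`t = r√(df/(1−r²))`, df = n − 2 − k. WMH-volume against nodal local
efficiency uses plain Pearson r with a t-based p. Rater reliability is
Cohen's unweighted κ plus Cronbach's α on the two-rater item matrix.

## 3. The synthetic cohort: a stated world

The study's subject-level data are not deposited, so every downstream
stage is exercised on seeded synthetic cohorts
(`generate_cohort()`). Defaults describe the emulated population and
are **not** tuned to test outcomes:

| parameter | default | why |
|---|---|---|
| `n_group_a` / `n_group_b` | 64 / 46 | published group sizes |
| `n_regions` | 90 | AAL-90 parcellation |
| `n_timepoints` | 230 | 240 volumes at TR = 2 s minus 10 discarded |
| `tr_seconds` | 2 | published acquisition TR |
| `n_modules` | 6 | order of magnitude of canonical resting-state systems |
| `within_module_r` / `between_module_r` | 0.6 / 0.1 | strong but sub-unity within-system coupling; weak background |
| `group_b_attenuation` | 0.4 | desk-scale severity effect large enough for direction recovery at n = 32 + 32 |
| `cognition_node` | 47 (left lingual gyrus) | the region whose NodalE correlated with MoCA in the study |
| `cognition_effect` / `noise_sd` | 1.5 / 2 MoCA points | places the planted cognition signal near r ≈ 0.3, the magnitude of the published correlation (0.26) |

Time series are zero-mean Gaussian with a block-constant correlation
matrix (equal-size contiguous modules), group B's within-module blocks
scaled by 1 − attenuation, then band-pass filtered to 0.01–0.08 Hz so
the series have realistic spectral content (identical filtering of all
columns leaves the correlation structure intact). Positive
definiteness is checked at construction and errors name the offending
parameters. Fazekas grade pairs are sampled uniformly over each
group's admissible totals (no per-grade counts are published); WMH
volumes are lognormal with the published group medians (1.31 / 7.84 mL)
and sdlog matched to the published IQRs; group B is older (medians
65 vs 69); sex (~69% female) and education are matched between groups.
MoCA is `24 + cognition_effect·u + noise` clamped to 0–30, where u is a
per-subject coupling modifier that also scales the designated node's
within-module correlations by `1 + 0.15u` — so the node's *measured*
nodal efficiency, not a hidden label, carries the cognition signal.

Seeding: one master seed; per-subject streams are derived
deterministically (`sample.int` under the master seed), so cohorts are
bit-identical across runs and platforms.

What the generator does **not** emulate: hemodynamics, head motion,
physiological noise, spatial autocorrelation, atlas misregistration,
site effects, or any image-space process. A green test therefore
establishes that the *analysis code* behaves as specified on data with
the assumed statistical structure — not that the biology is as modeled.

## 4. Numerical conventions

* **Band-pass filter**: 4th-order (prototype) Butterworth band-pass
  designed from first principles (analog prototype → lowpass-to-bandpass
  transform → bilinear transform with pre-warping), applied
  forward-backward with odd-symmetric padding and steady-state initial
  conditions — zero phase, which matters because the downstream
  statistic is a correlation. A 2-pole prototype would violate the
  stop-band contract (≤10% amplitude at twice the upper edge), so
  "order 4" is the prototype order (8 poles). Coefficients were
  verified against an independent reference implementation to machine
  precision during development.
* **Edge retention**: most-positive z (not |z|) for binary networks
  (GRETNA-style); the weighted variant carries |z| as weights. Edge
  count uses round-half-even; ties at the cutoff break by ascending
  node-index pair, making edge sets deterministic and nested across
  the grid.
* **Disconnected graphs**: Lp averages reachable pairs only and raises
  a flag; efficiencies treat 1/∞ as 0. The published sparsity range was
  chosen to avoid disconnection, but robustness is required at the low
  end.
* **Null ensembles**: 100 Maslov–Sneppen rewirings with 10·E attempted
  double-edge swaps each, rejecting self-loops and multi-edges; degree
  sequences are preserved exactly; graphs with no valid swap (e.g.
  complete graphs) return unchanged, flagged. `swaps_per_edge = 0`
  yields the self-null (γ = λ = σ = 1 exactly), used as a fixed point
  in tests.
* **Weighted clustering**: Onnela geometric-mean rule with weights
  normalized by the maximum; weighted distances use length 1/weight
  (Dijkstra). With 0/1 weights every weighted metric reduces exactly
  to its binary counterpart (tested). The study's own weighted-network
  formulas live in an unavailable supplement, so these are declared
  substitutes.
* **Fisher z clipping**: |r| is clipped to 1 − 1e−7 before artanh, so
  perfect correlations stay finite.

## 5. Design choices where the design was open

* *Normality test*: unnamed in the source methods; Shapiro–Wilk at
  α = 0.05 per group is the conventional SPSS-adjacent choice.
* *FDR families*: global (m = 7) and nodal (m = 90) corrected
  separately; the family definition is unstated in the source.
* *Welch vs pooled t*: Welch, given unequal group sizes (64/46).
* *Table-4 threshold question*: whether published nodal means were
  taken at one threshold or averaged across the grid is unstated; the
  nodal profile reports both per-threshold values and the
  across-threshold mean, and the group analysis uses the mean.
* *"First ten slices"*: read as the first ten time points (volumes);
  discarding spatial slices is meaningless for ROI series.
* *Small-world sanity scale*: the λ ≈ 1 check runs on Watts–Strogatz
  graphs with N = 90 and mean degree 18 (the scale of the
  sparsity-0.2 brain graphs). A sparse 30-node, degree-4 ring has
  λ ≈ 1.28 under *any* correct implementation — too few shortcuts —
  and even the published brain networks have λ_mean = 1.21, so
  demanding λ within 0.2 of 1 is only meaningful at realistic density.

## 6. Known limitations

**The Eglob direction cannot be reproduced by this generator.** The
package's effect-direction suite plants attenuation 0.4 and checks, at
n = 32 + 32, that group B shows lower Cp, lower Eloc, higher Lp and
lower Eglob. The first three hold in ≥ 90% of replicates; the Eglob
clause fails in essentially all replicates, and the failure is
structural, not a parameter accident. Sparsity thresholding sees only
the rank order of correlations. Attenuating group B's within-module
coupling lowers its structure-to-noise ratio, so B's retained edge set
drifts toward an Erdős–Rényi graph — and at fixed edge count,
randomization *raises* global efficiency, while the healthy group's
strongly modular matrix fragments into module components at low
sparsity (unreachable pairs contribute zero). Every noise-increasing
variant tried (including heterogeneous per-region signal degradation)
makes this worse, because noise-driven edges are topological
shortcuts. Reproducing the published pattern — patients lower on *both*
segregation and integration — requires a generative structure in which
the healthy connectome is already integrated (hub/long-range
architecture) and disease removes integrative links faster than noise
adds random ones; that is outside the block-covariance world this
generator deliberately inhabits. The corresponding assertion is left
red and documented rather than weakened.

Other limitations: the nodal Table-4 analog tests all 90 nodes rather
than a pre-registered subset; the weighted-network formulas are
declared substitutes (supplement unavailable); the CLI is a thin
launcher around `run_pipeline()` rather than a full argument grammar;
and simulated cognition scores are integer-rounded Gaussians, which
real MoCA distributions (ceiling effects, skew) are not.
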