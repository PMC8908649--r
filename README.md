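# wmhnet

Graph-theoretical analysis of resting-state functional brain networks
across white matter hyperintensity (WMH) severity in cerebral small
vessel disease (CSVD).

## The problem

WMH, the lesion load visible on FLAIR MRI, is a hallmark of CSVD and is
closely linked to cognitive decline. One way to ask *how* lesion load
degrades cognition is to treat the brain as a network: parcellate the
cerebrum into N = 90 regions (AAL atlas), correlate their resting-state
BOLD time courses, threshold the correlation matrix into a graph, and
compare graph topology between patients with low (Fazekas total 1–2,
"group A") and high (3–6, "group B") WMH grades.

`wmhnet` implements that full workflow as a tested, seedable pipeline:

1. **Synthetic cohorts** (`cohort_params()`, `generate_cohort()`):
   two Fazekas-graded groups with modular inter-regional covariance;
   group B's within-module coupling is attenuated; WMH volumes, ages,
   MoCA/MMSE scores are simulated around published group anchors, with
   MoCA coupled to the left lingual gyrus's connectivity.
2. **Temporal preprocessing** (`preprocess_timeseries()`): discard
   initial volumes, linear detrend, zero-phase Butterworth band-pass
   0.01–0.08 Hz, nuisance regression.
3. **Connectivity** (`pearson_matrix()`, `fisher_z()`,
   `binarize_at_sparsity()`): Fisher-z correlation matrices thresholded
   at sparsities 0.05–0.40 (step 0.05), keeping exactly
   `round(s·N(N−1)/2)` strongest edges.
4. **Graph metrics** (`binary_metrics()`, `small_world_indices()`,
   `global_profile()`, `nodal_profile()`): clustering coefficient Cp,
   characteristic path length Lp, global/local/nodal efficiency, and
   the small-world ratios γ = Cp/Cp_rand, λ = Lp/Lp_rand, σ = γ/λ
   against degree-preserving (Maslov–Sneppen) null ensembles.
   A network is small-world when γ > 1 with λ ≈ 1 (σ > 1).
5. **Statistics** (`compare_groups()`, `run_group_analysis()`):
   Shapiro–Wilk-gated Welch-t / Mann–Whitney comparisons with
   Benjamini–Hochberg FDR, logistic age adjustment, WMH-volume vs local
   efficiency correlations, and partial correlations of nodal
   efficiency with MoCA/MMSE controlling age, sex and education.

## Worked example

```r
library(wmhnet)

cfg <- load_run_config(system.file("extdata", "demo_config.json",
                                   package = "wmhnet"),
                       overrides = list(out_dir = tempdir()))
bundle <- run_pipeline(cfg)
bundle$analysis
```

Output printed by the demo run (seed 1, 16 + 16 subjects, 90 regions,
T = 120, sparsities {0.1, 0.2}, 20 nulls):

```
<group_analysis> n_A = 16, n_B = 16
global metric comparisons:
  metric       group_a       group_b      test_used    p_raw    p_fdr
1     cp 0.694 ± 0.033 0.446 ± 0.028         t_test 4.10e-20 2.87e-19
2     lp 2.844 ± 0.303 2.382 ± 0.083         t_test 1.69e-05 1.69e-05
3  gamma 4.569 ± 0.527 2.287 ± 0.361         t_test 5.79e-14 1.35e-13
4 lambda 1.360 ± 0.133 1.139 ± 0.035         t_test 5.80e-06 6.77e-06
5  sigma 3.354 ± 0.495 1.998 ± 0.316         t_test 1.31e-09 2.29e-09
6  eglob 0.386 (0.063) 0.490 (0.012) mann_whitney_u 1.41e-06 1.97e-06
7   eloc 0.810 ± 0.026 0.637 ± 0.023         t_test 1.27e-18 4.46e-18
nodal comparisons: 90 nodes, 85 FDR-significant
```

Read: both groups are small-world (γ ≫ 1, σ > 1), and the high-WMH
group shows the segregation loss the analysis targets — lower
clustering (Cp 0.45 vs 0.69), lower local efficiency (Eloc 0.64 vs
0.81), smaller σ. Normally distributed metrics are tested with Welch's
t and shown as mean ± SD; non-normal ones with Mann–Whitney U and shown
as median (IQR). (At this toy scale group B's Eglob comes out *higher*
— a known property of the block-covariance generator under rank-based
thresholding, analyzed in the vignette's limitations section.)

Every artifact (cohort CSVs, per-subject metric profiles, the four
result tables `table3_global.csv` … `table6_cognition_corr.csv`,
config and run log) lands under `out_dir/run_id/`, and reruns with the
same config and seed are byte-identical.

A command-line launcher is installed too:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","wmhnet.R",package="wmhnet"))')" \
    run-all --config inst/extdata/demo_config.json --seed 1 --out /tmp/run
```

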