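# migconn

Resting-state functional connectivity analysis of chronic versus episodic
migraine, packaged as a tested, reusable R pipeline.

## The scientific problem

Chronic migraine (CM; ≥ 15 headache days per month, of which ≥ 8 migraine
days, for more than 3 months) is far more disabling than episodic migraine
(EM), yet the brain mechanism behind chronification is unclear. A data-driven
way to look for it is whole-brain resting-state fMRI: decompose the BOLD
signal of a patient cohort into large-scale networks, quantify each network's
connectivity per patient, and ask which networks differ between CM and EM —
with particular attention to a "pain matrix" component (anterior cingulate,
anterior insula, thalamus, dorsolateral prefrontal cortex, precuneus) and to
seed regions implicated in migraine physiology (hypothalamus, dorsal raphe
nucleus, periaqueductal gray).

`migconn` implements that analysis end to end:

1. **Preprocessing** — framewise displacement (FD) from 6-parameter motion
   traces, censoring of frames with FD > 0.5 mm, discarding of the first
   12 s, global intensity normalization to a grand mean of 10,000, zero-phase
   Butterworth band-pass (0.009–0.08 Hz), 6 mm FWHM Gaussian smoothing.
2. **Node definition** — temporal-concatenation group ICA (PCA reduction +
   fixed-point ICA with logcosh contrast); signal/noise labelling by spatial
   cross-correlation against reference networks (threshold 0.25); subject
   time series by dual-regression stage 1.
3. **Network construction** — edges are ridge-regularized partial
   correlations between node time series,
   `r_ij = -P_ij / sqrt(P_ii P_jj)` with `P = (S + λ c I)^{-1}`;
   power soft threshold `w = |r|^β` (β = 6); Fisher `z = artanh(w)`;
   node statistic is degree centrality `DC_i = Σ_{j≠i} z_ij`.
4. **Inference** — per-node permutation test of
   `mean DC(CM) − mean DC(EM)` (5000 label permutations, two-sided,
   add-one p), Benjamini–Hochberg FDR across nodes; nested multivariable
   linear models adjusting for age, sex, aura, allodynia, depression,
   anxiety, disease duration, headache intensity and acute drug use; Pearson
   correlations with clinical scores; group × moderator interaction models.
5. **Seed analysis** — 3 mm spheres at the standard MNI centroids of the
   hypothalamus (0, −4, −9), PAG (1, −31, −9) and DRN (1, −32, −17);
   per-subject Fisher-z seed-to-network correlation, permutation + FDR
   contrast across the three ROIs.
6. **Baseline statistics** — clinic-table comparisons: Mann–Whitney for
   continuous rows, chi-square (no continuity correction) for binary rows,
   switching to Fisher's exact test when the smallest expected cell count
   drops below 2.5.

Because patient scans cannot be shipped, the package includes a first-class
**synthetic cohort generator**: node time series are drawn from Gaussian
processes with known (planted) precision matrices, with the CM group's
precision entries incident to one network scaled by `1 + effect_size`;
motion traces carry plantable FD spikes; ROI series have group-specific
planted couplings; the phenotype table emulates a migraine clinic cohort
(every CM subject has ≥ 15 headache days by construction). Every stage of
the pipeline is validated against this generator and against brute-force
oracles.

## Worked example

Simulate a 62-patient cohort (44 EM, 18 CM; TR = 3 s, 100 volumes, 7 network
nodes) with a planted connectivity increase on node 3 in the CM group, and
run the whole pipeline:

```r
library(migconn)
spec <- cohort_spec(n_em = 44, n_cm = 18, n_nodes = 7, n_volumes = 100,
                    tr_s = 3, effect_node = 3, effect_size = 0.5, seed = 7)
res <- run_pipeline(run_config(spec = spec, b = 5000, seed = 7))
res$permutation
#> permutation test (CM - EM), 5000 permutations
#>           observed          p      p_fdr significant
#> dc_1  1.558112e-03 0.52029594 0.75472905       FALSE
#> dc_2  1.486859e-03 0.53909218 0.75472905       FALSE
#> dc_3  2.265514e-03 0.00019996 0.00139972        TRUE
#> dc_4 -5.043771e-04 0.86482703 0.99560088       FALSE
#> dc_5  1.227806e-05 0.99560088 0.99560088       FALSE
#> dc_6  2.645076e-03 0.22855429 0.53329334       FALSE
#> dc_7  2.872356e-03 0.19416117 0.53329334       FALSE
```

Only the planted node survives FDR: its degree centrality is higher in CM
(observed contrast 0.0023 in Fisher-z units), with permutation p = 0.0002
and FDR-corrected p = 0.0014. The seed analysis against that node shows the
planted three-ROI structure — hypothalamus coupling stronger in CM, DRN
stronger in EM, PAG null:

```r
res$roi$contrast
#> permutation test (CM - EM), 5000 permutations
#>                 observed          p      p_fdr significant
#> hypothalamus  0.41932886 0.00019996 0.00029994        TRUE
#> drn          -0.42989097 0.00019996 0.00029994        TRUE
#> pag           0.02595751 0.36312737 0.36312737       FALSE
```

`res$baseline` holds the clinic-style baseline table (for this cohort, e.g.
headache days 6.9 ± 3.7 in EM vs 22.6 ± 6.0 in CM, Mann–Whitney
p = 7.7e-10), and `res$adjusted` the covariate-adjusted group p-values per
node and model.

The statistical core also runs directly on printed summary data:

```r
chi_square_2x2(rbind(c(36, 8), c(11, 7)))$p   # 0.0840 (female sex, EM vs CM)
fisher_exact_2x2(rbind(c(4, 40), c(4, 14)))$p # 0.2145 (migraine with aura)
bh_fdr(c(0.0066, 0.31, 0.44, 0.58, 0.67, 0.78, 0.35))$adjusted[1]  # 0.0462
```

## Layout

- `R/` — implementation (cohort generator, preprocessing, group ICA,
  connectome, inference, ROI seeds, clinical statistics, pipeline I/O)
- `tests/testthat/` — unit, property and acceptance tests with independent
  brute-force oracles
- `vignettes/migraine-connectivity.Rmd` — the methods vignette: model,
  parameter choices, generator design, numerical decisions, limitations
- `scripts/acceptance.R` — reproduction script (see above)
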