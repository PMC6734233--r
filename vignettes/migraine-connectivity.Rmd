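---
title: "Methods: group connectivity analysis of chronic and episodic migraine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group connectivity analysis of chronic and episodic migraine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migconn)
```

## The model

`migconn` compares whole-brain resting-state functional connectivity between
chronic-migraine (CM) and episodic-migraine (EM) patients. The analysis
treats each large-scale brain network — a spatially independent component of
the group BOLD signal — as one node of a weighted undirected graph and asks
whether any node's total connectivity differs between groups.

For one subject with node time series $x_1, \dots, x_K$ (each of length $T$
after preprocessing), edges are **partial correlations with L2 (ridge)
regularization**: columns are standardized, the sample covariance $S$ is
regularized to $S + \lambda c I$ (with $c$ the mean of $\mathrm{diag}(S)$),
inverted to a precision matrix $P$, and

$$r_{ij} = -\,\frac{P_{ij}}{\sqrt{P_{ii}\,P_{jj}}}.$$

At $\lambda = 0$ this is exactly the correlation of residuals after
regressing out all other nodes (a property the test suite checks against a
brute-force oracle to $10^{-10}$). The ridge stabilizes the inversion at
fMRI-typical $T \approx 100$.

Edges are then **soft-thresholded**, $w_{ij} = |r_{ij}|^\beta$, which
down-weights weak edges smoothly instead of binarizing the graph, and
variance-stabilized with **Fisher's transform** $z_{ij} =
\operatorname{artanh}(w_{ij})$. The node statistic is **degree centrality**,
$DC_i = \sum_{j \ne i} z_{ij}$.

Group inference is a **permutation test**: the statistic is the difference
of group means of $DC$ (CM minus EM) per node; group labels are permuted
preserving group sizes; the two-sided p-value uses the add-one formula
$p = (1 + \#\{|T_b| \ge |T_{\mathrm{obs}}|\})/(B + 1)$, which cannot be
zero. P-values are corrected across nodes with Benjamini–Hochberg FDR. The
difference of group means is the minimal statistic consistent with testing
whether a node's DC lies outside the central 95% of a label-permutation
null; the null is per node, not pooled, so nodes with different edge-weight
variances are each calibrated against their own distribution.

Covariate adjustment fits, per node and per nested covariate set, the
ordinary linear model $DC \sim \text{group} + \text{covariates}$ and reports
the group coefficient's two-sided p, FDR-corrected across nodes within each
set. The p-values are parametric by default; a Freedman–Lane permutation
variant (permuting residuals of the covariates-only model) is available via
`method = "freedman_lane"` and agrees with the parametric p on
well-behaved data.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fd_threshold_mm` | 0.5 | mm | standard scrubbing threshold for framewise displacement |
| `discard_initial_s` | 12 | s | scanner saturation period (4 volumes at TR = 3 s) |
| `target_mean` | 10,000 | intensity | conventional grand-mean scaling |
| `band_low_hz`, `band_high_hz` | 0.009, 0.08 | Hz | resting-state fluctuation band |
| `smoothing_fwhm_mm` | 6 | mm | typical smoothing for 2–4 mm voxels |
| `head_radius_mm` | 50 | mm | converts rotation differences to arc length in the FD sum |
| `ridge_lambda` | 0.1 | relative to mean diagonal covariance | stabilizes inversion at short T; 0 recovers classical partial correlation |
| `soft_power_beta` | 6 | — | power-adjacency convention; weights unsigned by default |
| `b` | 5000 | permutations | permutation-null resolution (p granularity 1/5001) |
| `alpha`, `q` | 0.05 | — | uncorrected level / FDR level |
| ROI radius | 3 | mm | hypothalamus/DRN/PAG are small nuclei; larger spheres would bleed into neighbouring tissue |

Two interpretive choices were genuinely open and are settable:

- *Soft threshold family.* Both a power adjacency ($|r|^\beta$) and a
  sigmoid adjacency are established; the power form is the default and the
  sigmoid is available through `network_params(soft_method = "sigmoid")`.
- *Subject time series from group components.* Dual-regression stage 1
  (per-frame least-squares loadings of the group maps) is used because it is
  deterministic given the maps and exact for noiseless data; extracting
  subject blocks of the concatenated ICA mixing matrix is the main
  alternative and is not implemented.

Order of operations: Fisher z is applied to the *soft-thresholded* weights,
and degree centrality to the z-stage weights. Raising $|r|<1$ to $\beta = 6$
compresses weights toward zero, so typical $z$ values are small; this is a
monotone reparametrization and does not affect permutation inference, but
absolute DC values should not be compared across different $\beta$.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
patient data. Its defaults emulate the study conditions this pipeline
targets: 44 EM and 18 CM subjects, TR = 3 s, 100 volumes, $K = 7$ network
nodes.

**Node series.** Each subject's $T \times K$ series is drawn i.i.d. in time
from $\mathcal N(0, P_g^{-1})$, where $P_g$ is the group's planted precision
matrix — the simplest process whose partial correlations are exactly
controlled. An optional AR(1) coefficient adds temporal colouring
(disabled by default: the analysis operates on correlations, not spectra).

**Planted topology.** One node (the "hub", standing in for the pain-matrix
component) has weak partial correlation 0.16 with every other node; the
remaining six nodes form three strongly coupled pairs (partial correlation
0.45), emulating systems with their own tight within-system coupling. The
group effect scales every precision entry incident to the hub by
$(1 + \text{effect\_size})$ in CM, which scales those partial correlations
by the same factor while leaving all other edges untouched. Both group
precisions must be symmetric positive definite or generation is refused.
The default coupling strengths were fixed once, at design time, by two
requirements: (i) both precisions stay well-conditioned after the CM
scaling (near-singular precisions inflate within-group DC variance and
destroy power), and (ii) a moderate effect on the hub is detectable at the
default sample sizes while its unavoidable one-edge spill-over onto each
neighbour stays buried in the neighbours' own strong-pair edge noise. The
strong pairs are what keeps the planted effect *node-specific* in practice.

**Motion.** Traces are smooth low-amplitude sinusoidal drifts (FD well
below 0.5 mm) plus optional spikes at Bernoulli-sampled frames. A spike is
a decaying displacement transient (0.8, 0.45, 0.25, 0.1 mm) so that only
the spike frame's inbound FD exceeds the threshold, and censoring that
frame leaves no above-threshold transition — making scrubbing exact and
idempotent. Spikes closer together than the transient length are thinned
to the first of the cluster; recorded spike frames in `truth` always match
what scrubbing removes.

**ROI series.** Each subject carries hypothalamus/DRN/PAG series generated
as $\rho\,\tilde h + \sqrt{1-\rho^2}\,\varepsilon$ around the standardized
hub series $\tilde h$, with group-specific couplings $\rho$ (defaults:
hypothalamus 0.1 EM / 0.5 CM, DRN 0.5 EM / 0.1 CM, PAG 0.3 in both) — the
qualitative three-ROI structure of a CM-hyperconnected hypothalamus, an
EM-dominant raphe coupling, and a null PAG.

**Phenotypes.** Group-specific prevalences and distributions resemble a
migraine clinic cohort; every CM subject has ≥ 15 monthly headache days by
construction (the chronic-migraine definition) and every EM subject fewer.
Disease duration is drawn identically in both groups, giving a
by-construction null for clinical correlation checks. Covariates are
conditionally independent of the planted network effect given group.

**4D volumes.** For imaging-stage tests, volumes are
$\sum_k m_k \otimes x_k + \text{noise}$, where the $m_k$ are spatially
disjoint dipole blobs (a positive and an equal negative lobe), so each map
has exactly zero spatial mean and the maps are pairwise uncorrelated —
which is what makes noiseless ICA recovery exact rather than approximate.

**What the generator does not emulate:** physiological (cardiac or
respiratory) noise, scanner drift fields, realistic rigid-body resampling of
head motion, spatial autocorrelation of BOLD noise, or any dependence of
covariates on connectivity. Passing tests therefore demonstrate that the
*statistical machinery* is correct and calibrated under the stated model;
they do not certify performance on real scans, where confound structure is
richer.

## Numerical choices

- **FD formula:** sum of absolute backward differences of the six motion
  parameters, rotations converted to displacements on a 50 mm sphere. FD is
  invariant to constant offsets in any parameter. Scrubbing removes the
  *later* frame of each high-FD transition; no ±1-frame augmentation.
- **Band-pass:** zero-phase (forward–backward) Butterworth, order 2 per
  pass. The transfer contract (in-band sinusoids retain ≥ 90% amplitude,
  an octave outside ≤ 10%, DC removed) is verified on long test series;
  on very short series low-frequency edge transients are the known cost of
  any causal-filter implementation.
- **Smoothing:** separable Gaussian, $\sigma = \text{FWHM}/(2\sqrt{2\ln 2})$
  per axis, kernel truncated at $4\sigma$ and renormalized; image sum is
  conserved away from boundaries. FWHM below 1% of a voxel is treated as
  the identity.
- **ICA:** PCA reduction (via SVD of the concatenated series) to $K$
  dimensions, then fixed-point iteration with the logcosh contrast and
  symmetric decorrelation, tolerance $10^{-8}$, random orthonormal
  initialization from the run seed. Component sign is fixed so each map's
  largest-magnitude voxel is positive; `match_components` resolves
  permutation against reference maps by exhaustive assignment (fine for
  $K \le 8$). $K$ is configured, not estimated: automatic dimensionality
  estimates are seed- and sample-dependent, and a fixed $K$ keeps runs
  reproducible.
- **Signal/noise labels:** only the 0.25 absolute-correlation rule decides
  labels; spatial kurtosis and boundary ("edge-ring") loading are reported
  as advisory columns. Template matching uses absolute correlation, so a
  sign-flipped match is still a match.
- **Ties and degeneracies:** sub-region ranking breaks ties alphabetically;
  fully tied Mann–Whitney samples return p = 1; constant binary phenotype
  columns are reported with p = 1 and flagged; seed correlations with
  $|r| \ge 1 - 10^{-12}$ raise a degeneracy error rather than an infinite z.
- **Exact permutation mode:** for small cohorts the test enumerates all
  label assignments and returns the exact p, used as the convergence target
  for the sampled mode.
- **Baseline-table test selection:** chi-square without continuity
  correction, switching to Fisher's exact test when the minimum expected
  cell count is below 2.5. The two-sided Fisher p sums hypergeometric
  probabilities not exceeding the observed table's (the probability-ordering
  rule, matching the enumeration oracle), not the doubling rule.

## Problem sizes used in the test suite

Module tests run on cohorts of 4–20 subjects with 30–100 frames. The
calibration and recovery experiments use the full study geometry:
200 null cohorts (44/18 subjects, 96 retained frames, 7 nodes, 1000
permutations) for the type-I check; 50 replicate cohorts for planted-effect
recovery (≥ 90% exclusive detection required) and for the three-ROI
contrast structure (≥ 80%); ICA recovery uses a $20^3$-voxel grid. These
sizes give stable rates while keeping the default suite in the
tens-of-seconds range on one core.

## Known limitations

- The imaging front end assumes inputs are already co-registered on a
  common grid; motion correction, registration, bias-field correction,
  brain extraction, slice timing and ICA-based nuisance removal are
  upstream concerns and not re-implemented.
- Degree centrality is the only graph statistic; no betweenness, modularity
  or small-world measures.
- ROI masks are coordinate spheres, a stated stand-in for hand-drawn or
  atlas-derived masks of these small nuclei.
- The multivariable models are ordinary least squares; with strongly
  non-Gaussian DC distributions the Freedman–Lane option is the safer
  choice.
- Exhaustive component matching limits `match_components` to $K \le 8$.
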