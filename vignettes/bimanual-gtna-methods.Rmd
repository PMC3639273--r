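---
title: "Methods: partial-correlation networks and graph metrics for bimanual task fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partial-correlation networks and graph metrics for bimanual task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimanet)
```

## The scientific problem

During bimanual wrist coordination, older adults recruit the same core
motor network as young adults (sensorimotor cortices, SMA, premotor
cortex, cerebellum) plus a secondary set of overactivated regions, while
matching the young group's behavioural output. `bimanet` implements the
graph-theoretical network analysis (GTNA) pipeline that asks whether the
*functional connectivity* inside these networks — not just their
activation — differs with age and with task difficulty (in-phase IP
vs. anti-phase AP movement modes).

The analysis unit is a network of regions of interest (ROIs): network N1
(21 nodes, active in both groups) and N2 (12 nodes, overactivated in the
elderly), shipped as node tables with anatomical labels, hemispheres and
MNI peak coordinates. For each subject and condition, an ROI-average BOLD
time series feeds a partial-correlation estimate; significance
thresholding yields binary and weighted graphs; graph metrics summarize
topology; and a split-plot AGE x PHASE ANOVA tests group effects.

## Connectivity model

Let `X` be the ROI x scan matrix of one subject and condition. With
sample covariance `C` and precision `Omega = C^-1`, the partial
correlation between nodes i and j is

    rho_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj),

the correlation of i and j after regressing out all other nodes. This is
the estimator's defining property, and the test suite verifies it against
the residual-regression definition to 1e-8. Partial rather than full
correlations are used so that indirect dependencies through third regions
do not masquerade as edges.

Edges are declared by a two-sided test of `rho_ij = 0` using
`t = rho * sqrt(df / (1 - rho^2))` with `df = n_samples - N`: the usual
`n - 2` correlation degrees of freedom reduced by the `N - 2` partialled
covariates. The source analysis does not state its test, so this standard
choice was validated against a permutation null in the test suite.
Graphs are built at five alpha levels (1e-4, 5e-4, 1e-3, 5e-3, 1e-2) so
that conclusions can be checked across network densities; because p is
monotone in `|rho|` at fixed df, edge sets are nested across alphas.

Design choices a user should know:

* **Signed weights.** Negative partial correlations can form edges and
  keep their sign in the weighted graph (the connection-strength sum has
  no absolute value). A `signed = FALSE` switch stores magnitudes
  instead; the choice is recorded in the run manifest.
* **Scan exchangeability.** Concatenated condition epochs are treated as
  independent samples, with no autocorrelation correction of the test df,
  matching the apparent practice of the reference analysis.
* **No ridge by default.** Covariance regularization exists only as an
  explicit opt-in for near-singular inputs and is recorded in the result.
* **No multiple-testing correction across edges**: robustness is assessed
  across the five thresholds instead.

## Graph metrics

All topology metrics operate on the binary graph; strength is the single
weighted metric, per the reference method. For node i with degree `K_i`:

* clustering `C_i` = edges among neighbours / `K_i (K_i - 1) / 2`
  (0 when `K_i < 2`);
* local efficiency = mean inverse distance among neighbours computed in
  the neighbour-induced subgraph with node i removed (0 when `K_i < 2`);
* path length `L_i` = mean hop distance to *reachable* peers; unreachable
  pairs are excluded, never imputed, and an isolated node's `L_i` is
  missing and excluded from the network mean. Global efficiency (mean of
  `1/d` with `1/Inf = 0`) is always reported alongside as the
  disconnection-robust companion;
* betweenness `b_i` counts unordered pairs' shortest-path fractions,
  unnormalized (magnitudes near 21 for a 21-node network, matching the
  scale of published group means), via Brandes' algorithm;
* strength `S_i` = sum of signed partial-correlation weights.

Every metric is verified in the tests against brute-force enumeration
(Floyd-Warshall distances, exhaustive shortest-path listing) on hundreds
of random graphs up to 9 nodes, and cross-checked against igraph.

Small-worldness uses analytic random-graph references with matched node
count `N` and mean degree `K`: `C_rand = K / N` and
`L_rand = ((ln N - gamma) / ln K) + 0.5` (`gamma` = 0.5772156649, the
Euler-Mascheroni constant) — the Fronczak correction of the
Watts-Strogatz estimate, which estimates the mean rather than the maximal
shortest path. Ratios are computed per subject and then averaged; whether
the original analysis averaged per subject or normalized group means is
not stated, and the two differ slightly. The estimate requires `K > 1`;
at very sparse thresholds the ratios are reported missing.

## Group statistics

The 2x2 ANOVA treats AGE as between-subjects and PHASE as
within-subjects — the only coherent reading for two distinct groups of 16
measured in both conditions. AGE is tested against the
subjects-within-groups stratum (df 1, 30 at full cohort size), PHASE and
AGE x PHASE against the subject-by-phase stratum. The implementation is
the closed-form balanced split-plot decomposition, verified against
`aov(value ~ group * condition + Error(subject))` and calibrated by
Monte-Carlo (type-I error 0.05 +/- 0.01 for each effect at 5,000 null
replicates). Note that the published interhemispheric sub-analysis prints
F(1, 15) degrees of freedom, which is inconsistent with a between-group
factor over 32 subjects; this package reports the split-plot df and
leaves the discrepancy visible rather than matching it.

The interhemispheric sub-analysis averages edge weights over crossing
(L-R) edges only; a subject without crossing edges is recorded missing,
never zero. Tukey post hoc comparisons of the four cell means use the
within-subject mean square for same-group comparisons and the composite
`(MS_subjects + MS_within) / 2` with Satterthwaite df for between-group
comparisons — the post hoc error term of the original is unstated, so the
within-stratum choice is documented here as this package's convention.
Kinematics correlations are plain Pearson tests flagged at p < 0.01 on
pairwise-complete data; the count of evaluated correlations is attached
so users can apply their preferred multiplicity correction (the original
corrected "for number of correlations evaluated" without naming a
procedure).

## The synthetic cohort generator

No raw fMRI is distributed with the study, so the package ships a
generator that emulates the *statistical structure the analysis
consumes*, plus ground truth for recovery tests. It is a Gaussian
graphical model with AR(1) temporal filtering and a boxcar task mean —
deliberately not an HRF-convolved biophysical simulator, because the
pipeline only uses second-order structure of condition epochs.

* **Design**: 2 groups x 16 subjects; 4 runs of 6 blocks per condition
  (AP, IP, REST) x 7 scans at TR = 3 s — 126 scans (378 s) per run, 168
  scans per condition per session, block order randomized per run under a
  seed.
* **Connectivity ground truth**: per group-and-condition sparse precision
  matrices built from explicit support + target partial correlations
  (`precision_model()` / `build_precision()`). Construction works in the
  normalized form `Omega = D^(1/2)(I - s P)D^(1/2)`; if the exact targets
  are not positive definite, the off-diagonal scale is bisected down
  (equivalent to diagonal loading plus rescaling) and the model errors
  out when implied correlations would drift more than 0.02 from target —
  never a silent clip.
* **Default contrasts**: the young IP model offers 20% of node pairs at
  nominal `|r|` 0.25; the old group gets +0.10 support density and +0.10
  magnitude; AP gets +0.05 density over IP. The age increments follow the
  stated design of a detectable AGE effect at n = 16 per group; the AP
  increment mirrors the reported difficulty effect and was fixed once at
  a plausible magnitude.
* **Per-node budget**: each node carries at most 0.85 total absolute
  partial correlation; edges take the nominal magnitude truncated to both
  endpoints' remaining budgets (dropped below 0.08). By Gershgorin's
  bound this guarantees positive definiteness for any sign pattern, and
  it mirrors how sparse precision matrices behave — hubs divide shared
  variance among neighbours. A consequence worth knowing: at the default
  magnitudes the old models express the age contrast mainly through
  stronger (and somewhat fewer, budget-limited) true edges, while the
  *recovered* networks — what the analysis actually measures — show the
  old group denser and stronger, as in the reference findings. Edge signs
  are mostly positive (p = 0.8), matching positive published mean
  strengths.
* **Noise**: innovations are multivariate normal with covariance
  `solve(Omega)`, filtered by a variance-preserving AR(1)
  (`phi = 0.3`, typical at TR = 3 s), reset at run boundaries; a constant
  task amplitude (0.5 BOLD a.u.) is added to task blocks. Mean shifts and
  AR filtering leave the partial-correlation target intact.
* **Kinematics**: phase error and SD of relative phase draw from
  condition-specific normals (AP: 15 +/- 4 and 18 +/- 4 deg; IP: 8 +/- 3
  and 10 +/- 3 deg), identical across groups — emulating the per-subject
  frequency titration that matched group performance by design. An
  optional linear coupling to a standardized connectivity summary
  supports correlation power studies.
* **Seeding**: one master seed; per-subject, per-condition streams derive
  through a documented counter-based hash (`derive_seed()`), so cohorts
  are bitwise reproducible and subjects independent.

What the generator does *not* emulate: voxel-level images, motion or
physiological artifacts, HRF dynamics, per-subject movement-frequency
titration (the analysis pools across frequencies), and non-Gaussian
tails. Passing recovery tests therefore demonstrates correctness of the
estimation and testing machinery under the model's assumptions, not
robustness to real-data artifacts.

## Numerical choices and degenerate inputs

* Sphere rasterization includes a voxel when its centre is within the
  radius (inclusive); the voxel containing the sphere centre is always
  included, so a radius-0 sphere returns exactly that voxel. The
  rasterization grid is a parameter because the original voxel grid is
  unspecified (functional 2.5 x 2.5 x 2.8 mm vs. anatomical 1 mm).
* Hemisphere labels come from the node table's Side column, never from
  the sign of x: near-midline cerebellar vermis nodes keep their printed
  assignment.
* The average time series supports both conventions described for ROI
  summaries — voxel mean (default) and first SVD eigenvariate (RMS-scaled,
  sign-aligned to the voxel mean) — because the published description is
  ambiguous between them; the method in force is recorded in the run
  manifest.
* ANOVA degeneracies: all-equal inputs give F = 0, p = 1; a zero error
  stratum under a real effect gives an explicit F = Inf, p = 0.
* Epochs concatenate across runs without boundary tapering, and
  partial-correlation estimation treats scans as exchangeable.
* Linear detrending is the only temporal filter offered; SPM-style
  whitening and filter banks are upstream concerns out of scope here.

## Problem sizes used by the validation suite

The shipped tests and the acceptance script validate at desk scale,
chosen as the smallest sizes at which each property is sharp: oracle
equivalence on 200 random graphs of up to 9 nodes; residual-definition
agreement at 6 nodes; precision recovery at 20,000 scans; support
recovery at 10,000 scans; small-world self-consistency on 100
Erdos-Renyi graphs of 50 nodes; AGE-effect power over 100 simulated
cohorts of 2 x 16 subjects; ANOVA calibration over 5,000 null
replicates. The published group-level results themselves derive from 32
subjects' raw fMRI that is not publicly deposited, so the package's
claims are parameter recovery and internal consistency, not numerical
reproduction of the published group means.

## Known limitations

* Partial-correlation magnitude and support density are mathematically
  coupled (positive definiteness); dense networks of uniformly strong
  partial correlations do not exist, in simulation or in brains. The
  generator's budget rule makes this constraint explicit.
* The split-plot ANOVA assumes balanced complete data; unbalanced cohorts
  are rejected rather than approximated (no Type-III/REML pathway).
* With two within-subject levels there is no sphericity issue, but the
  ANOVA would need generalization for designs with more conditions.
* Graph metrics are defined for undirected binary graphs (plus weighted
  strength); weighted clustering/path variants are deliberately absent
  because the reference quantities are binary-graph quantities.
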