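---
title: "Dynamic connectivity states and graph topology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic connectivity states and graph topology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dynfc` implements the analysis chain used to characterise time-varying
functional network connectivity (dFNC) in resting-state fMRI cohorts:
independent-component time courses are cleaned, correlated in tapered sliding
windows, decomposed into recurring connectivity *states* by k-means under the
Manhattan distance, and summarised per subject by fractional occupancy, mean
dwell time and number of state transitions; in parallel, each windowed
connectivity matrix is binarised over a sparsity-threshold series and its
small-world topology is summarised by the across-window variance of
area-under-curve (AUC) metrics. Group contrasts (patients vs controls) use
the Mann-Whitney U test with a rank-biserial effect size, nodal results are
FDR-corrected, and disability associations use Spearman correlation.

This vignette is the package's account of the underlying models, the
parameters that matter, the numerical choices, and what the synthetic-cohort
generator does and does not emulate.

## Time-course cleaning

Each subject enters as a T x C matrix of component time courses (the study
design this package targets uses C = 43 components grouped into eight
resting-state networks, T = 230 volumes at TR = 2 s). Four steps run in a
fixed order, each recording itself in the set's processing history (running
the same step twice is an error):

1. **Polynomial detrending** (order 3): each column is replaced by its
   residual from a least-squares cubic fit, removing linear, quadratic and
   cubic drift.
2. **Nuisance regression**: ordinary least squares on an intercept, the six
   realignment parameters and their backward-difference temporal derivatives
   (first row zero). Rank-deficient designs drop the dependent columns with
   a warning.
3. **Despiking**: running-median filtering. A point deviating from its
   centred window median (window 5) by more than 3 robust standard
   deviations (1.4826 x the window MAD) is replaced by that median. Edge
   windows shrink symmetrically, so the end points are never touched, and a
   zero MAD never triggers a replacement on its own. The algorithm is
   deliberately parameter-light and deterministic.
4. **Band-pass filtering**: a 5th-order Butterworth band-pass between 0.01
   and 0.15 Hz applied forward and backward (zero phase; the effective
   amplitude response is the square of the single-pass response). Columns
   are demeaned and extended by odd-symmetric padding of 3 x order samples
   at both ends before filtering, which suppresses the edge transients a
   0.01 Hz cutoff would otherwise leave in a 230-sample series. The two-pass
   design attenuates a 0.2 Hz sinusoid to below 0.06 of its amplitude while
   passing 0.05 Hz within 5%.

Framewise displacement, used only as a covariate, is the sum of absolute
backward differences of the translations plus 50 mm times that of the
rotations, averaged over frames — the sphere-radius convention, pinned
because the downstream use (a per-subject scalar covariate) only requires a
consistent summary.

## Windowed connectivity

Static connectivity is the Fisher-z (atanh) of the full-series Pearson
correlation for each of the C(C-1)/2 component pairs (903 for C = 43),
stored everywhere in one canonical ordering: the row-major upper triangle.

Dynamic connectivity slides a tapered window along the series. The taper is
a rectangle of `width_tr` samples convolved with a 4-sample Gaussian kernel
(sigma = 3 TR), giving an effective support of `width_tr + 3` samples; only
full-support placements are used, so T = 230, width 30 TR, step 1 TR yields
exactly 198 windows. Per window the package computes the taper-weighted
covariance and, when an L1 penalty is in force, its graphical-lasso estimate
(block coordinate descent, written in compiled code in this package). The
penalty is selected once per subject by maximising the mean held-out
Gaussian log-likelihood over ten random 80/20 splits of the windows on a
log-spaced grid in [0.01, 1]. At zero penalty the estimator reduces exactly
to the tapered sample correlation, which is also the fast path used for
large simulation studies. Window correlations of exactly +/-1 — reachable in
33-sample windows — are clamped to +/-(1 - 1e-7) before the z-transform; in
the static analysis the same event signals duplicated components and errors
instead.

Age, sex (female = 0, male = 1) and mean FD are regressed out of the
z-transformed window vectors pair by pair, pooled across windows and
subjects, with covariates mean-centred so that adding back the fitted
intercept returns values on the original connectivity scale. Pooling across
window index (rather than a separate regression per window position) is the
simpler model and the one assumption-light choice available; the per-index
variant is a sensitivity analysis, not the default.

## State decomposition

All subjects' window vectors are stacked and clustered jointly by k-means
under the city-block (Manhattan) distance, with element-wise medians as
centroid updates — the exact L1-optimal centroid. Each replicate starts from
k-means++ seeding computed under the L1 distance; five replicates and a cap
of 150 Lloyd iterations are the defaults, and the best replicate by total
within-cluster distance wins. An empty cluster is re-seeded at the point
farthest from its centroid (first index on ties), keeping the algorithm
deterministic for a fixed seed. A single-stage clustering of all windows is
used; no subject-exemplar pre-clustering pass.

The number of states K is chosen by the elbow criterion on the ratio of the
total within-cluster distance to the cluster-size-weighted distance of
centroids from the pooled (median) centroid, over candidate K = 2..8: the
selected K maximises the discrete second difference (maximum curvature) of
the ratio curve. A flat curve falls back to the smallest candidate with a
warning. The ratio itself is standard; the curvature rule is the package's
pinned tie-break, chosen because it is parameter-free.

States are reported in order of increasing mean absolute centroid
connectivity, so state 1 is always the weakly connected ("low") state. The
per-subject summaries are fractional occupancy (share of windows per state),
mean dwell time (mean length of maximal runs, in windows; multiply by step
x TR for seconds) and the number of transitions between unequal consecutive
labels.

## Graph topology

A connectivity vector is binarised at a *sparsity* (network density)
threshold s by keeping the round(s x P) pairs with the largest absolute
connectivity (ties broken by canonical pair order) — the density convention,
matching the 0.10-0.38 range of the threshold series (29 values, step 0.01).
Global metrics are the mean nodal clustering coefficient (Cp) and the
characteristic path length (Lp, averaged over reachable pairs only, with the
count of unreachable pairs reported); Gamma and Lambda normalise these by
their means over Maslov-Sneppen degree-preserving rewirings (100 nulls for
static analyses, 10 per window in the dynamic analysis, 10 x edge-count
attempted swaps each), and Sigma = Gamma/Lambda is the small-worldness.
Nodal metrics are degree (unnormalised edge count), nodal clustering and
nodal efficiency (mean inverse distance, 1/Inf = 0). Metrics are integrated
over the threshold series by the trapezoid rule, and a subject's dynamic
topology is summarised by the *population* variance (divide by W) of the W
per-window AUC values.

## Statistics

State-level and global topological measures are compared between groups by
the two-sided Mann-Whitney U test, uncorrected; nodal measures are corrected
across nodes by Benjamini-Hochberg FDR. The U test's p-value is exact (full
enumeration) for tie-free samples with n1 + n2 <= 16 and uses the
tie-corrected normal approximation otherwise; the effect size is the
absolute rank-biserial correlation |1 - 2U/(n1 n2)|. Spearman correlations
against the disability score use exact permutation p-values for n <= 9 and
the t approximation otherwise. The static connectivity analysis uses
per-pair ANCOVA (group + age + sex + mean FD) with FDR across the 903
pairs. Demographic tables use the pooled-variance t (also available from
summary statistics alone) and the phi coefficient with a 1-df chi-square
p-value; a Kolmogorov-Smirnov check against a moment-matched normal decides
between mean +/- SD and median (IQR) reporting.

## The synthetic cohort generator

No public dataset accompanies the analysis this package implements, so the
generator plants known structure and the pipeline is validated by parameter
recovery. Every parameter of the generator is a stand-in chosen at design
time, not an estimate from real data.

A subject is a hidden-Markov sequence over `k_true = 3` connectivity states
*at time-point resolution* — windows therefore straddle transitions exactly
as they do in real data, which is the regime the estimator must survive.
Emissions are zero-mean multivariate normal with a block-structured
covariance per state built from network-block correlation levels (shrunk
toward the identity by binary search only if a requested template is not
positive definite):

* **low**: within-network 0.05, between 0 — near-unstructured;
* **moderate**: within 0.6 in DMN, VIS and ATN, 0.05 elsewhere;
* **strong**: within 0.6 in all eight networks, between 0.05, with negative
  VIS-FPN and VIS-SCN blocks (-0.4).

The templates differ mainly in *which* blocks are active, keeping all three
positive definite without shrinkage and well separated under the L1 distance
on window vectors. Patients' transition matrix is sticky and biased toward
the low state (stationary occupancy ~0.70/0.17/0.13, ~4 expected transitions
per 230 volumes, low-state dwell ~100 TR); controls favour the moderate
state and switch more (~0.21/0.55/0.24, ~6 transitions). Dwell times are
long relative to the 33-sample effective window so that most windows have an
unambiguous dominant state. On top of the emissions the generator adds a
random cubic drift (amplitude 0.4), white observation noise (sd 0.2), and
mean-reverting random-walk motion (AR(1), phi = 0.98) whose scale yields
mean FD near 0.04-0.05 mm; demographic fields mimic a 30-patient/45-control
cohort (sex 27/3 vs 33/12, ages ~38 +/- 12 vs ~42 +/- 11 truncated to
18-65, tissue volumes near the corresponding group means). Patients'
disability score is `6 x (true low-state occupancy) + noise(sd 0.8)`,
clipped to the 0-10 half-point grid, so disability is positively coupled to
low-state occupancy; controls carry no score.

What the generator does **not** emulate: hemodynamics and autocorrelated
neural dynamics within a state, spatial structure of components, scanner
physics, missing data, and any realistic relation between motion and signal.
Passing the recovery suite therefore shows the estimator recovers planted
Markov block-covariance structure under drift, noise and windowing — not
that it is robust to everything real data can do.

### Ground truth at window resolution

Because states switch at time-point resolution, a window that straddles a
transition has no single true label. Window-level accuracy is therefore
measured against `window_truth_states()`: the modal true state of each
window, counted only where that state occupies at least 75% of the window.
Fractional-occupancy recovery at T = 230 is likewise measured against the
modal-window truth, since even a perfect window labeller deviates by ~0.05
from the time-point occupancy at this series length purely through
windowing; the long-series invariant (T = 2000, where that discrepancy
vanishes) is tested against the generator's time-point truth directly.

## Numerical and scale choices

* Randomness: every stochastic step (simulation, k-means seeding, held-out
  splits, null rewirings) draws from R's RNG under an explicit seed;
  per-subject seeds derive deterministically from the master seed.
* The recovery studies in the test suite run the full cohort size
  (75 subjects, T = 230, C = 43) with the zero-penalty window estimator,
  two k-means replicates and an early-stop tolerance of 8 label changes
  (0.05% of the 14,850 stacked windows); the graphical lasso and the
  5-replicate default are exercised at smaller problem sizes. These are the
  package's chosen problem sizes for its own validation studies.
* Dwell time defaults to window units, with seconds available as
  `windows x step_tr x TR`.
* Lp on fragmented graphs averages finite distances only; fully
  disconnected graphs are an error, not a sentinel value.
* The binarisation edge count uses round-half-up, and `round(s x P) = 0`
  is an error rather than an empty graph.

## Known limitations

* The graphical-lasso penalty grid and selection rule are pinned
  conventions; with 33-sample windows and C = 43, held-out likelihood can
  be noisy and selection is per subject, not per window.
* The elbow rule, like all internal cluster-number criteria, can be
  indecisive when states are weakly separated; the curve is always returned
  for inspection (`tidy()` / `autoplot()`).
* Confound regression pools window positions; systematic within-scan
  drift of connectivity with window index is not modelled.
* The dynamic-topology null count (10 per window) trades Monte Carlo error
  in Gamma/Lambda/Sigma for runtime; raise it for final analyses.

## A minimal run

```{r, eval = FALSE}
library(dynfc)

cohort <- generate_cohort(synthetic_config(seed = 1))
bundle <- run_pipeline(cohort, k = "auto", seed = 1)

glance(bundle$state_model)
bundle$dynamics_tests
make_report(bundle)
```
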