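---
title: "Benchmarking rs-fMRI noise-regression techniques on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking rs-fMRI noise-regression techniques on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Head motion and physiological fluctuations (respiration, cardiac pulsation)
contaminate resting-state fMRI time series and inflate or distort apparent
functional connectivity. Older adults in clinical cohorts often show a
distinctive continuous, tremor-like high-frequency motion pattern: framewise
displacement (FWD) exceeds the conventional 0.2 mm threshold on most frames
while only a small fraction of frames exceed 0.5 mm. Which nuisance-regression
strategy works best for such data is an empirical question, and answering it
requires (a) the candidate techniques, (b) quality metrics that reward signal
preservation and punish residual artifact, and (c) data with known ground
truth on which both can be validated.

`rsdenoise` implements all three layers: a synthetic cohort generator with
planted networks, motion-coupled artifacts and physiological noise; five
denoising techniques; seed-based network mapping; five quality metrics with
identifiability sub-scores; and nonparametric technique ranking.

## The synthetic cohort

`make_phantom_atlas()` carves an ellipsoidal brain into CSF, white matter,
a cortical grey-matter band, a 2-voxel edge shell (the brain mask minus its
2-voxel erosion — activation there is the canonical motion-artifact marker),
M reference networks (pairs of spherical grey-matter blobs) and S seed
regions, each seed a subset of its mapped network. The default benchmark uses
S = 6 seeds on M = 4 networks; the atlas scales to the 22-seed / 14-network
layout of a full study (`make_phantom_atlas(c(32,32,32), 22, 14, seed)`).

`simulate_subject()` composes each voxel time series as

```
baseline
 + network_amplitude  * sum_k network_map_k * network_tc_k
 + artifact_amplitude * w_edge(v) * FWD_std(t)
 + physio_amplitude   * (compartment weights x {resp, card})
 + drift_amplitude    * Legendre drift
 + N(0, thermal_sd)
```

with these modelling choices:

* **Network time courses** are white noise hard-masked in the DFT domain to
  the 0.01–0.08 Hz passband (band-limited Gaussian processes), unit sd.
* **Shared variance**: a fraction `physio_leak = 0.3` of the band-limited
  respiratory signal is mixed into every network time course. This is the
  realistic aliasing of slow respiratory volume changes into "neuronal"
  fluctuations, and it is what makes aggressive and non-aggressive component
  regression genuinely different on these phantoms.
* **Motion**: `smooth` subjects drift slowly (median FWD ≈ 0.02 mm);
  `hf_tremor` subjects add frame-to-frame jitter (translations 0.06 mm,
  rotations 0.0008 rad per frame) chosen analytically so the expected FWD is
  ≈ 0.34 mm with ~90% of frames above 0.2 mm and ~6% above 0.5 mm — the
  tremor phenomenology of older clinical cohorts.
* **Motion artifact**: spatial weight `exp(-(depth-1)/2)` of the
  distance-to-edge (scale 2 voxels), time course equal to the standardised
  FWD series. Note this makes the artifact *nonlinear* in the six motion
  parameters (FWD is a sum of absolute differences), so motion-parameter
  regression can only partially remove it; data-driven (ICA) techniques can
  model it directly.
* **Physiology**: respiratory-like (0.01–0.05 Hz) and cardiac-like
  (0.06–0.15 Hz) processes with compartment weights WM (0.8, 0.4),
  CSF (1.0, 0.8) and global (0.3, 0).
* **Amplitudes** (arbitrary units on a baseline of 1000): network 10 (~1%
  BOLD-like fluctuation), artifact 20, physio 8, drift 20, thermal sd 5.
  The source study does not quantify these for its cohort; they are free
  parameters of the generator, fixed once at field-plausible values.

What the generator does **not** emulate: hemodynamic response shape, EPI
distortion, slice timing, spatial autocorrelation of thermal noise,
scanner/site effects, and — importantly — imperfect noise-component
classification (labels are ground truth in synthetic runs; the classifiers
themselves are external inputs by design). Benchmarks on these phantoms
therefore validate the *machinery* (designs, projections, metrics, tests)
and the relative behaviour of techniques under known noise, not clinical
effect sizes.

## The five techniques

1. **censoring** — one OLS fit of: 24 motion parameters (Friston set:
   parameters, one-frame lags, squares of both), one spike regressor per
   frame with FWD ≥ 0.5 mm, WM and CSF mean signals, Legendre detrending
   (order 3), and sine/cosine regressors at every DFT frequency outside
   0.009–0.08 Hz (bandpass-as-regression, simultaneous with censoring).
2. **censoring_gs** — adds the global (whole-brain mean) signal.
3. **aggressive_aroma** — spatial ICA on a copy smoothed with the wide (6 mm)
   kernel; the noise-labelled component time courses are fully regressed
   from the narrow-kernel (4 mm) data; then a post-hoc DFT bandpass.
4. **nonaggressive_aroma** — identical ICA, but partial regression: all
   components are fit jointly and only the noise components' unique
   contribution is subtracted, so variance shared with retained components
   is kept.
5. **sock_style** — the noise-component time courses are appended to the
   technique-1 confound set (without spike regressors) in a single fit.

Censored frames are spike-regressed, never deleted, so every technique
returns a full-length series and all metrics see the same number of frames.
The bandpass is implemented inside the design for techniques 1, 2 and 5 and
as a DFT-mask filter after component regression for the ICA paths, mirroring
the per-technique ordering of the reference pipelines.

### Numerical choices

* **OLS**: pivoted QR on the centred design plus intercept; collinear
  columns dropped with a warning; voxel means restored. Residuals are
  orthogonal to the design to ~1e-12 and the projection is idempotent.
* **Partial regression** uses the SVD pseudoinverse of the centred mixing
  matrix; rank deficiency is reported with the condition number.
* **Spatial ICA**: PCA whitening over timepoints, symmetric FastICA with the
  tanh contrast, deterministic random orthogonal initialisation from the
  seed. Automatic dimensionality places the cut at the last clear drop
  (ratio > 1.5) in the eigenspectrum within the first T/4 components.
  A 95%-variance rule is deliberately *not* used: with appreciable thermal
  noise it pulls dozens of near-Gaussian components into the unmixing, and
  symmetric FastICA cannot separate sources with no non-Gaussian structure
  (the iteration cycles instead of converging). On persistent
  non-convergence the implementation retries from fresh deterministic
  initialisations and then shrinks the dimension geometrically before
  failing.
* **Design-size budget**: at short run lengths the out-of-band frequency
  regressors dominate the design (e.g. ~75 of 120 columns at T = 120,
  TR 2.5 s), leaving little room for spike regressors; a subject with many
  censored frames can exceed K < T and fails with an explicit error. The
  pipeline logs and excludes such subjects (aborting if more than 10% fail),
  and `bandpass = FALSE` is available for deliberately short test runs.
  At the study's native length (T = 288) the budget is never binding.

## Connectivity mapping and thresholding

Seed maps are Pearson correlations of every brain voxel with the seed-mean
time course, clipped at |r| ≤ 1 − 1e−7 and Fisher-z transformed. Thresholding
fits a two-component Gaussian mixture (null + active) to the in-mask z values
by EM with deterministic initialisation — means at the 25th/75th percentiles,
pooled sd, equal weights — and thresholds at the smallest z above the lower
mean where the posterior of the higher-mean component exceeds 0.5 (computed
in log-density space; a vanishing component or zero spread falls back to
"no suprathreshold voxels"). Only the positive tail is thresholded; negative
tails are reported descriptively through the sub-scores.

## Quality metrics

* **Reproducibility** (`split_half_reproducibility`): 500 random split-half
  permutations; per permutation, the spatial correlations between the two
  halves' per-seed mean maps form an S×S matrix whose diagonal is pooled per
  seed and whose off-diagonal entries are pooled as the null; each seed's
  pseudo-z is `(mean(diag) − mean(null)) / sd(null)`. This per-seed pooled
  standardisation is the simplest reading of the pseudo-z construction; a
  per-permutation variant would standardise each permutation separately and
  is intentionally not the default.
* **Identifiability**: mean |z| inside the mapped reference network divided
  by mean |z| outside (within the brain), on *unthresholded* maps.
  Sub-scores: true-positive connectivity (mean r inside the target network),
  false-positive (grey matter outside the target), and WM/CSF connectivity —
  averaged on the Fisher-z scale and reported back-transformed as r.
* **Edge activity**: percentage of edge-shell voxels that are suprathreshold
  after GMM thresholding (denominator = edge-mask size).
* **Spatial smoothness**: 3D DFT amplitude spectrum split by spheres at
  radii j/7 of the maximum frequency radius (j = 1..6, DC excluded); each
  radius contributes mean|F|(inside)/mean|F|(outside) and the statistic is
  the mean of the six ratios. The direction is fixed so that Gaussian
  smoothing *increases* the statistic; the absolute scale is this package's
  own normalisation (the reference implementation's internal scaling is not
  derivable from its description), so only orderings are meaningful.
* **tDOF loss**: censoring loses one frame per censored time point;
  component techniques lose one temporal degree of freedom per
  noise-labelled component.

Reproducibility is a cohort-level quantity (it compares subject groups), so
the benchmark table carries it per (technique, seed) and the subject-level
metric table only mirrors the technique mean for convenience;
`rank_techniques()` tests reproducibility on the per-seed values and all
other metrics on per-subject values.

## Statistical comparison

Per metric: Kruskal-Wallis across techniques (tie-corrected H, chi-square
p), then all 10 pairwise two-sided Mann-Whitney U tests (exact for small
tie-free samples, normal approximation with tie and continuity correction
otherwise), Bonferroni-corrected within the 10-test family of that metric
(not across metrics). Directions of goodness: higher is better for
reproducibility, identifiability, smoothness and true-positive connectivity;
lower is better for edge activity, tDOF loss and false-positive/WM/CSF
connectivity (signed r; strong negative compartment coupling is reported but
not folded into |r|).

## The default benchmark and what it shows

```{r}
library(rsdenoise)
res <- run_pipeline(default_pipeline_config(rng_seed = 1), out_dir = "bench")
glance(res$comparison)
autoplot(res$comparison)
```

The default configuration is deliberately desk-scale: a 24³ grid, 12
subjects (half tremor-like), T = 120 frames, 500 permutations — minutes on
one CPU. The acceptance script raises the run length to the study-native
T = 288. On these phantoms the component techniques dominate: the planted
artifact is |Δp|-shaped, outside the span of motion-parameter regression,
and the ICA isolates it as a well-separated component. With ground-truth
labels, partial (non-aggressive) regression removes that component nearly as
completely as full regression, so the two AROMA variants differ mainly
through the shared respiratory variance — aggressive removal gives better
reproducibility and lower false-positive/WM coupling at a small cost in
true-positive strength. Plain censoring retains the most edge activity here;
in real cohorts imperfect component classification shifts this balance
against non-aggressive regression, a regime outside this generator's scope
(labels are ground truth by design).

## Known limitations

* No hemodynamic model, slice timing, distortion or site effects.
* Thermal noise is spatially white; real scanner noise is smoothed by
  reconstruction.
* Ground-truth component labels bound the benchmark from above: classifier
  errors, the main real-world failure mode of non-aggressive cleanup, are
  not simulated.
* The smoothness statistic's absolute scale is package-specific; compare
  orderings, not magnitudes, against other implementations.
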