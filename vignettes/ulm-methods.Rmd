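---
title: "Methods: super-resolution ultrasound localization microscopy with ulmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: super-resolution ultrasound localization microscopy with ulmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Ultrasound localization microscopy (ULM) reconstructs the microvasculature
far below the diffraction limit by localizing and tracking individual
intravascular microbubble contrast agents across thousands of ultrafast
(here 1,000 Hz) imaging frames. The raw input is a stack of beamformed
complex in-phase/quadrature (IQ) frames on a coarse native grid; the output
is a set of bubble trajectories and super-resolved density, velocity and
flow-direction rasters on a fine isotropic grid (4.928 µm per pixel), from
which regional hemodynamic metrics are computed and compared between
animal groups.

The processing chain is:

1. **Clutter filtering.** The stack is reshaped into the Casorati matrix
   `X` (space × time) and decomposed; tissue clutter is slowly varying and
   spatially coherent, so it concentrates in the leading singular
   components. The filtered stack is the reconstruction from components
   above an adaptively chosen cutoff. We work through the `n_t × n_t` Gram
   matrix `X^H X`, whose eigendecomposition yields the temporal singular
   vectors and squared singular values at a fraction of the cost of a full
   SVD when `n_t` is much smaller than the pixel count.
2. **Noise equalization.** Electronic noise grows with depth (time-gain
   compensation); the per-depth noise amplitude is estimated as the
   per-depth median magnitude of the clutter-filtered stack (bubbles are
   sparse, so the median tracks the Rayleigh noise level), median smoothed
   over 9 depth samples, and divided out. An estimator based on the
   trailing quartile of singular components was tried first and rejected:
   the adaptively fitted leading components absorb proportionally more
   variance at noisier depths, compressing the recovered profile enough to
   violate the flatness contract.
3. **Localization.** The point-spread function (PSF) is modelled as an
   elliptical 2D Gaussian fitted to isolated bubble patches. Each magnitude
   frame (optionally after matching-pursuit bubble separation) is upsampled
   with natural cubic splines to the 4.928 µm grid, cross-correlated
   (zero-normalized) with the rasterized PSF, and candidate bubbles are the
   8-connected regional maxima of the correlation map above a threshold
   (default 0.6), refined to sub-pixel positions by per-axis parabolic
   interpolation of the correlation peak.
4. **Tracking.** Localizations in consecutive frames are linked by solving
   a gated linear assignment problem (Hungarian algorithm) that minimizes
   total squared displacement, with a non-assignment alternative at cost
   `gate²` (default gate 30 µm ≈ 1.5× the displacement of a 20 mm/s bubble
   at 1 kHz). There is no gap closing, merging or splitting: a missed frame
   terminates a track. Tracks shorter than 10 frames (10 ms) are discarded.
5. **Maps and metrics.** Tracks are accumulated as supercover lines into
   density/velocity/direction rasters. Regions of interest are closed
   Hobby splines through control vertices; per ROI we compute vascularity
   (percentage of perfused pixels), median velocity, and the sum-of-angles
   tortuosity metric SOAM (total turning angle divided by path length,
   rad/mm). Tracks are split into arteriole/venule subsets by the sign of
   the mean velocity vector against a per-ROI cortical surface normal, and
   single-vessel velocity profiles are fit with the Poiseuille parabola
   `v(r) = v_peak (1 − ((r−c)/R)²)`.
6. **Histology.** Two-channel (vessel tracer / amyloid) section images are
   segmented by an adaptive threshold — positive where intensity exceeds
   1.5× the median within a sliding 101-pixel window — which cancels smooth
   illumination fields exactly; vessel-channel components that overlap the
   plaque mask by more than 50% are excluded as fluorescence bleed-through.
7. **Statistics.** Per-animal replicates are averaged first; groups are
   compared with one-way ANOVA (also reproducible directly from printed
   `n`, mean, SD via the algebraically identical summary form), two-way
   ANOVA with sequential (Type I) sums of squares in the order position,
   genotype, interaction; Benjamini–Hochberg step-up adjustment;
   two-sample Kolmogorov–Smirnov; and Pearson correlation.

## The synthetic phantom: what it emulates, and what a green test means

No raw in-vivo data are available, so every stage is verified against a
ground-truthed phantom (`make_vessel_tree()`, `simulate_tracks()`,
`render_iq()`): tube vessels with laminar Poiseuille flow at mm/s speeds
(bubbles seeded uniformly over the cross-sectional area, so the true mean
speed is analytically `v_peak/2`), Gaussian bubble echoes with log-normal
amplitude spread (sdlog 0.3), a low-rank smooth tissue-clutter background
~30× brighter than the bubbles, circular complex noise whose amplitude
doubles over the imaging depth, and multiplicative cardiac modulation at
7 Hz (420 beats/min, the reported scale for anesthetized mice). Defaults:
128 × 128 native grid at 19.712 µm (4× the 4.928 µm output grid, so the
upsampling stage is genuinely exercised).

The phantom does **not** emulate acoustic wave propagation, speckle
statistics, nonlinear bubble oscillation, aberration, or tissue motion.
Green phantom tests therefore establish the correctness of the *analysis*
(localization accuracy, assignment optimality, metric algebra, statistical
calibration) — not the fidelity of any acquisition.

A bubble's radial position in its vessel is frozen for its lifetime, which
makes the per-track true speed a scalar oracle. Bubble amplitude/phase
draws are keyed to the bubble id and clutter/noise use dedicated RNG
sub-streams, so rendering a subset of tracks reuses the identical
background — making superposition an exact, testable identity.

## Numerical and design choices

* **Adaptive SVD cutoff.** The cutoff is the largest gap between
  consecutive log10 singular values, guarded by a prominence rule (≥ 0.15
  decades and ≥ 3× the median gap; otherwise the spectrum is declared
  degenerate). We initially implemented the commonly described
  max-distance-to-chord knee on the log spectrum, but on stacks whose
  bubble/noise tail decays slowly over hundreds of components the global
  chord drags the knee deep into the tail (cutoff ~69 of 400 on a rank-3
  clutter phantom); the dominant log-gap recovers the planted rank and is
  equally deterministic.
* **Sub-pixel refinement.** The raw correlation peak is broad compared to
  the 4.928 µm grid, so a plain 3×3 weighted centroid stays essentially
  pinned to the grid (median error ≈ 0.6 px), and even a
  baseline-subtracted centroid keeps a positional bias (≈ 0.14 px) large
  enough to bias frame-to-frame speeds by >5% at 3 mm/s. Per-axis
  parabolic interpolation of the peak (median error ≈ 0.07 px ≈ 0.35 µm on
  20 dB phantoms) is used instead — the standard refinement for smooth
  correlation peaks.
* **NCC threshold 0.6** was chosen at the plateau of the phantom
  detection-ROC; it is configurable everywhere.
* **Correlation on the envelope.** Cross-correlation runs on the magnitude
  (envelope) of the filtered IQ data, not the complex samples.
* **Histology threshold factor 1.5 / window 101 px** follow the phantom
  Dice optimum; the adaptive threshold quantizes intensities to 16 bits for
  the exact sliding-window median (two-level histogram, C++).
* **SOAM units.** We report rad/mm and label it "a.u."; absolute
  comparability with published a.u. scales is not claimed.
* **Sequential (Type I) sums of squares** are used for the two-way ANOVA
  because the designs are unbalanced, which makes the SS type material; the
  published reporting order (position, genotype, interaction) fixes the
  entry order reproducibly.
* **Ties and determinism.** The assignment solver processes rows in index
  order (deterministic tie-break); all generators take explicit integer
  seeds, and the pipeline fans one global seed out to fixed per-stage
  offsets.
* **Degenerate inputs** raise errors rather than guessing: flat spectra
  (no knee), zero-variance correlation windows, flat velocity profiles
  (radius → ∞), empty ROI masks, single-point tracks.
* **Formats.** No HDF5 or TIFF R binding is assumed: IQ stacks persist as
  float32 binary + JSON sidecar, rasters as uncompressed baseline TIFF
  written/read by a small built-in codec (cross-validated against an
  external reader in the tests). Configs and ROIs are JSON.
* **Open points decided here.** Native (pre-interpolation) pixel spacing is
  taken as 4× the output grid (19.712 µm). Trailing (noise-side) singular
  components are *not* removed — only the tissue-side cutoff is applied.
  Track membership in an ROI uses the majority-of-centroids rule.
  Velocity rasters store the per-pixel *mean* step speed. The curve tool
  implements closed Hobby splines only (ROIs are closed outlines), with
  tension fixed at 1.

## Known limitations

Slow near-wall bubbles are partially suppressed by any clutter filter
(they are temporally coherent), so full-pipeline velocity distributions are
biased against the slowest flow; the per-track velocity acceptance is
therefore evaluated on tracks matched to their ground-truth bubbles.
Overlapping echoes closer than ~1 PSF width merge unless bubble separation
is enabled; the matching-pursuit separator is a contract-compatible
stand-in, not a reimplementation of any published separation technique.
The linker's no-gap policy fragments tracks under dropout rather than
bridging them — a deliberate trade of completeness for exact
specifiability.
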