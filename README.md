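# ulmr — super-resolution ultrasound localization microscopy in R

`ulmr` implements a complete, tested analysis pipeline for **ultrasound
localization microscopy (ULM)** of the cerebral vasculature: the technique
that turns thousands of ultrafast (1 kHz) contrast-enhanced ultrasound
frames into super-resolved maps of the brain's microvessels by detecting and
tracking individual microbubbles. It is aimed at researchers who want to
quantify regional cerebrovascular change — e.g. between wild-type and
Alzheimer-model mice — from beamformed IQ data, and at methodologists who
want every stage of such a pipeline verifiable against ground truth.

Because raw in-vivo acquisitions are rarely shareable, `ulmr` ships a
ground-truthed **synthetic vascular flow phantom**: tube vessels with
laminar Poiseuille flow `v(r) = v_peak (1 − r²/R²)`, Gaussian bubble echoes,
a low-rank tissue-clutter background, depth-graded noise and cardiac
pulsatility. Every stage of the pipeline is tested against this phantom's
known truth.

**Pipeline:** SVD clutter filtering of the Casorati (space × time) matrix
with an adaptive rank cutoff → depth noise equalization → PSF fitting,
microbubble separation and sub-pixel localization by zero-normalized 2D
cross-correlation (4.928 µm grid) → frame-to-frame linking as a gated linear
assignment problem (minimum track length 10 frames) → accumulation into
density / velocity / direction rasters → Hobby-spline ROIs with vascularity,
median velocity, sum-of-angles tortuosity (SOAM), arteriole/venule
directional splitting and Poiseuille profile fits → a statistics module
(one-/two-way ANOVA, also directly from printed `n`, mean ± SD summaries;
Benjamini–Hochberg; Kolmogorov–Smirnov; Pearson). A histology module
quantifies amyloid- and vessel-positive area fractions in two-channel
section images with a sliding-median adaptive threshold and a
bleed-through exclusion mask.

See `vignettes/ulm-methods.Rmd` for the model, assumptions, parameter
defaults and design decisions.

## Worked example

```r
library(ulmr)

# 1. simulate a straight 25-um-radius vessel, Poiseuille flow, v_peak 8 mm/s
geom  <- make_vessel_tree("straight", radius_um = 25, peak_velocity_mms = 8)
truth <- simulate_tracks(geom, duration_s = 0.6, frame_rate = 1000,
                         bubble_rate = 0.05, seed = 7)

# 2. render IQ frames: rank-3 tissue clutter ~30x brighter than the bubbles,
#    depth-graded noise, 7 Hz pulsatility
cfg   <- phantom_config(clutter_rank = 3, clutter_amp = 30,
                        noise_sigma = 0.05, seed = 8)
stack <- render_iq(truth, cfg, n_frames = 600)

# 3. clutter filter + depth equalization
filt <- svd_filter(stack, rank_mode = "adaptive")
filt$decomposition$cutoff      # 3  (recovers the planted clutter rank)
eq   <- noise_equalize(filt$stack)

# 4. localize and track
psf    <- psf_model(c(40, 30))                      # axial/lateral sigma, um
locs   <- localize_stack(eq, psf, ncc_threshold = 0.6)
tracks <- build_tracks(locs, frame_rate = 1000, gate_um = 30, min_len = 10)

# 5. super-resolved map + regional metrics over an ROI around the tube
grid <- list(nz = 509, nx = 509, spacing_um = 4.928)
map  <- accumulate(tracks, grid)
roi  <- roi_polygon(rbind(c(1150, 200), c(1150, 2300),
                          c(1380, 2300), c(1380, 200)),
                    grid, label = "tube", surface_normal = c(1, 0))
vascularity(map, roi)       # 2.33 %
median_velocity(map, roi)   # 6.79 mm/s
roi_soam(tracks, roi)       # 207 a.u. (rad/mm; jittery short tracks)

# 6. reproduce a published group comparison from printed summaries
anova_oneway_summary(data.frame(n = c(9, 8), mean = c(5.32, 4.82),
                                sd = c(0.50, 0.36)))
#> F(1, 15) = 5.463, p = 0.0337
```

What the numbers mean: the adaptive cutoff equals the planted clutter rank,
so tissue is removed without touching the bubbles; 600 frames of a sparse
bubble stream yield 3,936 localizations linked into 47 tracks; the ROI's
vascularity is the perfused fraction of its area (a thin 50 µm tube fills
only ~2% of a 230 µm-tall box); the median per-pixel speed (6.79 mm/s) sits
between the tube's mean (4 mm/s) and peak (8 mm/s) because fast centerline
bubbles dominate detections; and the summary-statistic ANOVA reproduces a
published `F(1,15) = 5.472` to 0.2% from the printed means ± SD alone.

## Full pipeline in one call

```r
res <- run_end_to_end(run_config(duration_s = 0.5, seed = 1), out_dir = "out/")
res$metrics     # one row per (ROI, subset in all/arteriole/venule)
```

A command-line front end is in `inst/cli/ulm.R`
(`Rscript ulm.R run --config run.json --out out/`).

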