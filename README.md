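# mpdetect

Landing-event detection and mass calibration for mass photometry
(interferometric scattering microscopy, iSCAT).

Mass photometry weighs single proteins: each molecule landing on the
coverslip produces a sudden, persistent, diffraction-limited dip in the
normalized interferometric image, whose fractional depth (the
*interferometric contrast*) is proportional to molecular mass. `mpdetect`
is for people who want a tested, scriptable reimplementation of that
analysis — e.g. to study oligomer distributions such as the monomer/dimer/
octamer equilibrium of the bacterial arginine kinase McsB — and for
benchmarking detection settings on movies with known ground truth.

The package provides:

* **Movie I/O and preprocessing** — multi-page float32 TIFF (or raw
  float32 binary) with a JSON metadata sidecar; frame averaging and pixel
  binning (1 kHz / 23.4 nm raw → 500 Hz / 70.2 nm effective).
* **Ratiometric background removal** —
  `r_t = mean(I[t, t+navg)) / mean(I[t-navg, t)) − 1`, which cancels the
  static glass speckle exactly.
* **Two-filter detection** — filter 1 scores each pixel/frame for a
  significant intensity jump between the before/after blocks (`−ln p`,
  threshold `T1`); filter 2 scores the radial symmetry of the local
  contrast neighborhood in [0, 1] (threshold `T2`); mask clusters become
  candidates, duplicates are merged by non-maximum suppression. Production
  settings: `navg = 21`, `T1 = 1.2`, `T2 = 0.15`.
* **PSF fitting** — fixed-shape model `w·S(k1 r)·G(σ1) + (1−w)·S(k2 r)·G(σ2)`
  with `S(x) = 2J1(x)/x`; per-event nonlinear least squares over amplitude,
  sub-pixel position and offset. The amplitude magnitude is the contrast.
* **Mass calibration** — `mass = (contrast − intercept) / slope` with the
  study constants (slope 5.023e-5 kDa⁻¹, intercept 1.261e-4: 42 kDa ↔
  2.2e-3, 84 kDa ↔ 4.3e-3), OLS calibration from standards tables, and
  number-weighted mass distributions with n-mer assignment.
* **Synthetic movies and a benchmark** — ground-truth landing events
  (1000 frames, 100 events, exclusion 12 px / 26 frames), a noise
  calibration anchored at the monomer operating point (57.2% true
  positives), replicate TP/FP statistics and `navg`/`T1`/`T2` sweeps.

## Worked example

Simulate a dimer-contrast benchmark movie, detect and fit its landing
events, and summarize the masses:

```r
library(mpdetect)

params <- simulation_params(contrast = mass_to_contrast(84),  # 4.3e-3
                            noise_sigma = 2.4e-3, seed = 1)
sim <- simulate_movie(params)
sim$movie
#> <mp_movie> 128 x 128 px, 1000 frames @ 500 Hz, 70.2 nm/px

res <- analyze_movie(sim$movie)     # ratiometric -> detect -> fit
res$events[1:3, c("frame", "row", "col", "contrast", "converged", "edge")]
#>   frame   row   col contrast converged edge
#> 1    28  70.6  46.3  0.00409 TRUE      FALSE
#> 2    57  19.6  48.9  0.00428 TRUE      FALSE
#> 3    62  33.7  80.9  0.00455 TRUE      FALSE

m <- match_detections(res$events, sim$truth)
sprintf("TP %d / FP %d of %d planted events", m$tp, m$fp, nrow(sim$truth))
#> "TP 100 / FP 3 of 100 planted events"

build_mass_distribution(res$events, calibration_model(), monomer_mass_kda = 42)
#> <mass_distribution> 103 events, 7 unassigned, bin 5 kDa
#>   n_mer count fraction
#> 1     1     2   0.0194
#> 2     2    94   0.913
```

All 100 planted 84 kDa events are recovered; their fitted contrasts
convert to ~84 kDa and 94 of them land in the 2-mer bin (a few fall to the
unassigned tail, and the three false alarms read as small masses).

A thin command-line front-end with `simulate` / `detect` / `mass` /
`benchmark` subcommands lives at `inst/scripts/mpdetect.R`; configuration
is YAML (see `read_pipeline_config()`).

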