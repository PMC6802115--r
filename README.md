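# ffosheets

Do membrane-bound protein assemblies seen by 3D single-molecule
localization microscopy form two-dimensional lattices of filamentous
oligomers? `ffosheets` implements the quantitative argument for GAS7, an
F-BAR protein of phagocytic cups, whose crystal packing predicts flat
filamentous oligomers (FFOs): strings of ~22 nm dimers at 5 nm spacing and
a 40° tilt, packed side by side into sheets. The package is for
microscopists and image analysts who want to run — or stress-test — that
style of point-pattern inference on their own localization data.

## What it computes

**Geometry.** The lattice model (`sheet_model_params()`) fixes the crystal
constants. Its first consequence is the filament width,

```
w = L · sin(θ) = 22 nm · sin(40°) ≈ 14.1 nm,
```

matching the ~14 nm seen crystallographically (`filament_width()`).

**Neighbour statistic.** For signals with 3D positions `x_i`, the statistic
counts, for every ordered pair, the shell `i` with
`5i ≤ ‖x_a − x_b‖ < 5(i+1)`, `i = 2..9` (10–50 nm). Counts are expressed as
the *fold increase* over the mean of 20 complete-spatial-randomness (CSR)
simulations of the same number of points in the same region, with ±SD bands
(`neighbor_counts()`, `random_null()`, `fold_increase()`). Simulated
free-dimer and FFO-sheet observations — full labelling, 10% detection,
20/40 nm xy/z Gaussian localization error — provide the model curves
(`model_curves()`), and `classify_pattern()` assigns an observation to
random / dimer / sheet by nearest summed squared per-shell z-score.

**Localization processing.** ThunderSTORM-compatible CSV input, per-frame
same-pixel merging, drift correction by histogram cross-correlation or
fiducial tracking, 60 nm z-slices, and anisotropic mixed-Gaussian density
rendering (σ_z = 2 σ_xy).

**Periodicity.** Windowed 2D power spectra of striation images and the
dominant in-band period with sub-bin refinement (`power_spectrum()`,
`dominant_period()`), closing the loop with the ~5 nm striation pitch of
the lattice.

## Worked example

Simulate a 40%-sheet observation at the study conditions, compare it to its
matched CSR null, classify it, and recover the striation pitch:

```r
library(ffosheets)
params <- sheet_model_params()
filament_width(params)
#> [1] 14.14133

box <- c(2000, 2000, 300)                       # nm
obs <- simulate_sheet(30000, box, params, seed = 7) |>
  thin_detection(p = params$detection_prob, seed = 8) |>
  add_localization_noise(params, seed = 9)
obs
#> 3D point pattern: 3029 points in a 2000 x 2000 x 300 nm box
#> free-dimer      sheet
#>       1804       1225

null  <- random_null(n_points(obs), box, n_trials = 20, seed = 10)
curve <- fold_increase(neighbor_counts(obs), null)
as.data.frame(round(curve, 2))
#>   bin_index lo_nm hi_nm fold   sd
#> 1         2    10    15 3.53 0.15
#> 2         3    15    20 3.90 0.13
#> 3         4    20    25 4.05 0.07
#> ...
#> 8         9    45    50 3.77 0.05

classify_pattern(obs, box, params, seed = 11)
#> [1] "sheet"
#> attr(,"scores")
#>      random       dimer       sheet
#> 14873.52609 15893.57455    13.45576
```

The fold column says sheet-like observations carry ~3.5–4× more neighbours
at 10–50 nm than equally many random points would — the signature of
molecules concentrated in one thin lattice patch — and the classifier
agrees by a three-orders-of-magnitude score margin. A CSR observation stays
at fold ≈ 1 in every shell.

```r
img <- render_striation_image(params)           # noise-free sheet image
dominant_period(power_spectrum(img), band = c(3, 10))
#> Dominant period 5.01 nm along (1.00, 0.00), peak SNR 5.2e+09
```

`plot_fold_curves()` overlays observed, dimer and sheet curves with their
dashed ±SD bands. A thin command-line front end wrapping the same functions
ships at `inst/cli/ffosheet` (subcommands `simulate`, `analyze`, `render`,
`fft`, `classify`, YAML-configured).

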