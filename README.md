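# dectpellet

Automated material differentiation of retained shotgun pellets from
dual-energy CT (DECT).

Shotgun wounds are common in both trauma care and forensic practice, and
the pellet material matters clinically: lead is toxic, and steel (soft
iron) pellets are ferromagnetic, contraindicating MRI until identified.
Conventional CT cannot tell pellet metals apart — their Hounsfield values
saturate and overlap — but DECT acquires two co-registered volumes at
different tube voltages, and the **dual-energy index**

```
DEI = (I_low − I_high) / (I_low + I_high + 2000)
```

is a normalized spectral signature: zero for water, ≈ 0.21 for steel and
≈ 0.19 for copper at 100/140 kVp, and near zero for the high-Z metals
(lead, tungsten, bismuth), which therefore cannot be separated from each
other but are cleanly separated from steel and copper.

`dectpellet` implements the complete analysis for radiologists and
forensic researchers working with gelatine-block or cadaveric DECT data:

* **DEI volumes** from co-registered extended-scale HU pairs, with a
  denominator guard and validity mask (`compute_dei_volume()`).
* **Automated pellet segmentation**: fixed 2000 HU threshold on the
  high-kVp volume, in-plane erosion by a diameter-4 disk (strips the
  partial-volume shell), 26-connected 3D component labelling, per-pellet
  mean/SD DEI and centroids (`analyze_volume()` and the individual stages).
* **Group statistics**: per-material summaries, pairwise two-sided
  Wilcoxon rank-sum matrix (exact for small groups), box plots, and
  category classification with a ferromagnetic flag (`wilcoxon_matrix()`,
  `classify_category()`).
* **Attenuation physics**: packaged NIST mass-attenuation tables
  (30–150 keV) for Fe, Cu, W, Pb, Bi and water, log–log interpolation,
  theoretical HU and theoretical DEI (`theoretical_dei()`).
* **Synthetic phantoms**: a seeded generator of calibrated dual-energy
  gelatine blocks with spherical pellets, supersampled partial volume,
  Gaussian noise and ground-truth sidecars (`default_phantom()`,
  `generate_block()`), so the whole pipeline is testable without scanner
  data.
* **File workflow**: NIfTI + JSON-sidecar I/O, CSV tables, run logs with
  config hashes, and a thin CLI (`inst/scripts/dect-pellet.R` with
  `simulate` / `dei` / `segment` / `analyze` / `pipeline` subcommands).

## Worked example

Simulate the five-material calibrated phantom (one gelatine block per
material, reference pellet counts, 3 mm pellets) at a compact block size,
run the full pipeline, and inspect the statistics:

```r
library(dectpellet)
st <- run_phantom_study("paper-100-140", seed = 1, block_size = c(48, 48, 70))
st$summary[, c("material", "n", "mean", "sd")]
#>   material  n    mean       sd
#> 1       Fe  5 0.21189 0.006854
#> 2       Pb  4 0.00825 0.000703
#> 3       Cu 13 0.18786 0.002847
#> 4        W  6 0.01265 0.003795
#> 5       Bi  8 0.00795 0.002011
```

All 36 generated pellets are detected; the recovered material means sit
within a few thousandths of the calibration truth (steel 0.212,
copper 0.187, lead/bismuth 0.008, tungsten 0.012), because erosion removes
the partial-volume shell before averaging.

```r
st$wilcoxon
#> Pairwise two-sided Wilcoxon rank-sum p-values (alpha = 0.05)
#>       Fe    Pb    Cu     W    Bi
#> Fe 1.000 0.016 0.000 0.004 0.002
#> Pb 0.016 1.000 0.001 0.114 0.933
#> Cu 0.000 0.001 1.000 0.000 0.000
#> W  0.004 0.114 0.000 1.000 0.029
#> Bi 0.002 0.933 0.000 0.029 1.000
```

Steel and copper separate from everything (p ≤ 0.016); lead vs bismuth is
far from significant (p = 0.93) — the two are spectrally indistinguishable.

```r
st$classification[, c("material", "category", "ferromagnetic")]
#>   material                       category ferromagnetic
#> 1       Fe                          steel          TRUE
#> 2       Pb high-Z indeterminate (Pb/W/Bi)         FALSE
#> 3       Cu                         copper         FALSE
#> 4        W high-Z indeterminate (Pb/W/Bi)         FALSE
#> 5       Bi high-Z indeterminate (Pb/W/Bi)         FALSE
```

Only steel raises the ferromagnetic (MRI-hazard) flag. For a file-based
run producing NIfTI volumes, CSVs, a box plot and a reproducible JSON run
log, see `run_pipeline()`; for physics-side predictions,
`theoretical_dei(dect_materials()$Fe, 60, 140)`.

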