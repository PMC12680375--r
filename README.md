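# pcpquant

Quantitative analysis of planar cell polarity (PCP) in epithelial tissue
images. Given a segmented membrane channel, `pcpquant` measures a per-cell
polarity axis and magnitude with a shape-normalised PCA estimator, and
provides the surrounding analysis chain: tissue-graph extraction from label
masks, microtubule orientation and dispersion from a cytoskeletal channel,
junction-class intensity enrichment, cell-row assignment from a tissue
boundary, dual-timer stable-fraction estimation, axial circular statistics
and Hotelling T² group comparisons. A synthetic-tissue generator with exact
per-cell and per-junction ground truth makes every estimator testable
end-to-end.

## Method in brief

A polarised membrane protein follows an axial intensity profile
`I(θ) = B + A·cos(2(θ − ψ))` around the cell perimeter. Each membrane-band
pixel is first mapped into the cell's fitted-ellipse frame (rotate by −φ,
scale by 1/a and 1/b) so that cell shape cannot masquerade as polarity.
Pixels become intensity-weighted pseudo-points `q = Î·(cos θ, sin θ)`; the
principal eigenvector of their second-moment matrix about the origin gives
the polarity axis ψ, and `M = (λ₁ − λ₂)/(λ₁ + λ₂)` gives a magnitude in
[0, 1] that is 0 for uniform intensity and independent of cell
eccentricity.

## Worked example

Simulate a tissue with a known 30° polarity axis, measure it back, and
summarise junction-class enrichment:

```r
library(pcpquant)

tis <- generate_tissue(tissue_spec(n_cols = 10, n_rows = 10,
                                   cell_diameter = 24, seed = 42))
fld <- polarity_field(mode = "uniform", psi0 = 30, amplitude = 100,
                      baseline = 100, background = 20, noise_sd = 5)
ren <- render_channels(tis, fld)

pol <- cell_polarity(ren$graph, ren$channels$sfGFP, background = "estimate")
geo <- cell_geometry(ren$graph)

# exclude border cells (censored membrane bands) and invalid fits
ok <- pol$valid & is.finite(pol$psi) & !geo$on_border[match(pol$cell, geo$cell)]
sum(ok)
#> [1] 72

aggregate_wing(pol[ok, ])
#> $magnitude
#> [1] 0.1691596
#>
#> $angle
#> [1] 33.53582
#>
#> $vector
#> [1] 0.06590118 0.15579478
#>
#> $n
#> [1] 72

median(axial_diff(pol$psi[ok], 30))
#> [1] 3.036964
```

The tissue-wide axial mean (33.5°) recovers the simulated 30° axis and the
median per-cell axial error is 3.0° at 5% noise. Junctions perpendicular to
the polarity axis are enriched:

```r
cls <- classify_junctions(ren$graph, boundary_axis = 0)
summarize_junction_intensity(ren$graph, cls, ren$channels$sfGFP,
                             background = 20)$by_class
#>           class mean_intensity   n
#> 1    horizontal       137.0278 178
#> 2 medio-lateral       174.7996  91
```

Real data enter through `read_label_mask()` (TIFF/PNG) or as
in-memory matrices via `run_config()` + `run_pipeline()`, which chain
segmentation parsing, polarity, dual-timer, microtubule and row-assignment
stages and can write JSON/CSV outputs. A command-line entry point is
installed at `inst/cli/pcpquant.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/pcpquant.R", package="pcpquant"))')" simulate --out-dir out --seed 1
```

## Testing and reproducing the results

```r
testthat::test_dir("tests/testthat", package = "pcpquant",
                   load_package = "installed")
```

runs the full suite (~300 assertions, ~20 s), including one acceptance
block per validation criterion in `tests/testthat/test-acceptance.R`:
angle recovery, magnitude monotonicity and zero floor, eccentricity
independence, agreement with a brute-force axis-scan oracle, microtubule
orientation/dispersion recovery against the closed-form von Mises target,
stripe-phantom calibration, BFS row-assignment oracle, junction enrichment,
stable-fraction recovery, Hotelling null calibration and boundary
repolarisation.

The same quantities can be recomputed against the installed package with
any seed:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

which writes each metric as `{"value": ..., "n": ...}`.
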