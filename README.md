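# haloquant

Quantification of chromogenic halo assays on agar plates.

Functional screening of clone libraries on chromogenic substrates (e.g.
AZCL-xylan) reports enzymatic activity as a blue halo around the inoculated
spot. Scoring such screens by eye is qualitative; haloquant makes it
quantitative. From a back-lit plate photograph it measures each halo's area
in cm² and assembles the results into the tables a screening campaign
needs: a clones × conditions density matrix, a ranked clone list, and a
hit-rate summary.

The pipeline:

1. **Color.** 8-bit sRGB photographs are converted to CIELAB (D65
   illuminant, 2° observer). The blue–yellow axis b\* isolates the dye:
   halo pixels carry negative b\*.
2. **Segmentation.** Pixels with −20 < b\* < −5 (strict bounds;
   `extend_blue` drops the lower one) form the positive mask.
3. **Detection.** After closing and size-limited hole filling, 8-connected
   components are kept if they are large enough and *rounded*:
   circularity 4πA/P² ≥ 0.6, which accepts disks and rejects grid lines.
   A manual circular-mask mode covers halos the automatic path misses.
4. **Calibration.** A line of known physical length (the spacing between
   two grid lines) fixes mm/pixel; areas follow as
   `pixels × (mm/px)² / 100` cm².
5. **Screening tables.** Per-clone areas become a clones × (temperature,
   day) density matrix; clones active at *all* requested temperatures form
   tier 1, ordered by total halo area; hit rates are reported to one
   decimal.

A seeded synthetic plate generator with exact ground truth
(`generate_plate()`) validates the whole chain end to end, and small
sequence utilities cover the ORF arithmetic reported alongside a screen
(protein length = bp/3 − 1, standard-code translation, average molecular
mass = Σ residue masses + H₂O).

## Worked example

Simulate a plate with two halos, run the pipeline, and compare with ground
truth:

```r
library(haloquant)

halos <- data.frame(cell_id = c("r1c1", "r2c3"), center_x = c(50, 250),
                    center_y = c(50, 150), radius_px = c(20, 30),
                    target_b = c(-12, -16), halo_L = 58)
spec <- synthetic_plate_spec(width = 300, height = 400, halos = halos,
                             noise_sigma = 3)
res <- generate_plate(spec, seed = 7)

lab     <- srgb_to_lab(res$image)
mask    <- blue_mask(lab, segmentation_params())
regions <- detect_halos(mask, res$ground_truth$layout, detection_params())
regions$area_cm2 <- region_area_cm2(regions$pixel_count,
                                    res$ground_truth$calibration)
regions[, c("region_id", "cell_id", "pixel_count", "circularity", "area_cm2")]
#>   region_id cell_id pixel_count circularity area_cm2
#> 1         1    r1c1        1264    1.005859 0.213616
#> 2         2    r2c3        2828    1.000200 0.477932

res$ground_truth$halos[, c("cell_id", "pixel_count", "area_cm2")]
#>   cell_id pixel_count area_cm2
#> 1    r1c1        1264 0.213616
#> 2    r2c3        2828 0.477932
```

Both halos are recovered with their exact rasterized pixel counts: at this
noise level the only error source is sub-pixel rasterization. The areas
(0.21 and 0.48 cm²) follow from the 13 mm / 100 px grid calibration.

Screen bookkeeping:

```r
summarize_screen(563, sprintf("LP%d", 1:12))
#> 12 / 563 clones positive (2.1%)
orf_protein_length(1137)
#> [1] 378
```

Batch runs over real photographs go through `run_quantify()` with a JSON
configuration (images + conditions, grid layout, calibration; see
`?run_quantify` for the schema), which writes `regions.csv`,
`records.csv`, `density_matrix.csv`, `summary.json`, and a `params.json`
provenance record. A thin command-line front end with `segment`, `detect`,
`quantify`, `report`, `simulate`, and `seqstats` subcommands is installed
at `inst/cli/haloquant.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/haloquant.R", package="haloquant"))')" \
    quantify --config run.json
```

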