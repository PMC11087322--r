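---
title: "Quantifying chromogenic halos: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromogenic halos: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haloquant)
```

## The measurement problem

Functional screens of clone libraries on chromogenic agar — for example,
AZCL-xylan plates, where hydrolysis of the cross-linked substrate releases a
soluble blue dye — score activity as a roughly circular blue halo around the
inoculated spot. The halo's area is the activity proxy, and comparing clones
across incubation temperatures and days requires that area in physical
units, not pixels. haloquant turns a back-lit plate photograph plus a small
amount of metadata (the cell grid, a calibration length) into per-clone halo
areas in cm², and those areas into a clones × conditions *density matrix*
that drives clone ranking and hit-rate summaries.

## Color model

Photographs are assumed 8-bit sRGB as delivered by a consumer camera, with
no ICC handling: the acquisition setup this emulates used a fixed phone
camera over a plate back-lit by a cold LED lamp, with in-camera processing
left on automatic. `srgb_to_lab()` decodes the sRGB gamma (the standard
piecewise curve with linear toe), applies the sRGB→XYZ matrix for the D65
white, and evaluates the CIE 1976 L\*a\*b\* functions against the D65 2°
white point (X~n~ = 95.047, Y~n~ = 100, Z~n~ = 108.883). The piecewise
threshold in f(t) uses the exact rational constants ((6/29)³ and friends),
so results are reproducible to machine precision across platforms; the test
suite checks agreement with an independently coded scalar implementation to
1 × 10⁻⁶ and an 8-bit round trip through `lab_to_srgb()` to ±1 count.

In this space the blue–yellow axis b\* isolates the dye signal: blue halo
pixels carry negative b\*, agar and growth carry b\* near zero or positive.
Because exposure and white balance are automatic and uncorrected, absolute
b\* values are not strictly comparable *across* photographs; the pipeline
mirrors the acquisition protocol and applies no per-image correction. That
is a known limitation, not an oversight: within one image the band
threshold is stable, and all cross-condition comparisons in the density
matrix operate on areas, not intensities.

## Segmentation and the b\* band

`blue_mask()` scores a pixel positive iff −20 < b\* < −5 (strict
inequalities), the band in which halo blue sits on a back-lit plate: values
near −5 shade into the background, values below −20 are rarely produced by
the dye at assay concentrations. Whether pixels *bluer* than −20 should
count is genuinely ambiguous — the band may describe the observed range
rather than an exclusion — so both behaviours are available:
`extend_blue = TRUE` drops the lower bound. The default keeps the strict
band; nothing in the pipeline depends on the choice when halos are rendered
(or photographed) inside the band.

## Rounded-region detection

"Rounded areas of high density of negative b\*" is operationalized as:

1. **Closing** with a disc brush of radius `closing_radius_px` (default
   2 px) bridges pixel dropouts caused by sensor noise.
2. **8-connected labeling.** Components are labeled with 8-connectivity
   (diagonal contact joins).
3. **Size-limited hole filling.** A hole (enclosed background region) is
   filled only when its area is at most `max_hole_frac` (default 0.5) of
   the surrounding component's area. Unconditional filling would be wrong
   in an instructive way: if the plate's grid ink happens to fall inside
   the b\* band, the line lattice is one connected component whose "holes"
   are the entire grid cells, and filling them turns the lattice into a
   solid plate-sized blob with high circularity. Dropout holes inside a
   real halo are orders of magnitude smaller than the halo and are always
   filled; lattice cells are much larger than the lattice and never are.
4. **Filtering.** Components below `min_area_px` (default 50 px, well
   under any real halo at the intended imaging scale) or with circularity
   4πA/P² below `min_circularity` (default 0.6) are discarded. The
   perimeter P is estimated by counting exposed pixel edges (the Manhattan
   boundary length) and scaling by π/4, the Cauchy–Crofton factor that
   makes the estimate unbiased for smooth convex outlines; rasterized
   disks of radius 10–40 px score 0.92–0.98 under this estimator, while a
   2-px line scores far below the threshold. Axis-aligned rectangles can
   exceed 1 — harmless here, since the filter is a lower bound and such
   shapes do not arise from noise.
5. **Cell assignment.** Each surviving region is assigned to the grid cell
   containing its centroid (pixel centers at half-integer coordinates,
   half-open 0-based cell rectangles). The assay expects at most one halo
   per inoculated square, so only the largest region per cell is kept and
   extras are messaged.

The manual fallback, `pixel_count_in_circle()`, reproduces the
round-mask measurement mode: positive pixels whose centers fall within a
user-supplied circle are counted, with no shape filtering. It is
non-interactive by design — circles come from configuration, so a manual
measurement is exactly reproducible.

## Calibration

One line of known physical length — in practice the pixel distance between
two consecutive grid lines, whose physical spacing is measured with a ruler
— fixes `mm_per_pixel`; areas follow as
`pixel_count × mm_per_pixel² / 100` cm². Pixels are assumed square (a
single scalar scale), matching a camera mounted square over the plate;
lens-distortion and perspective correction are out of scope. Rendering the
same physical scene at k× resolution multiplies pixel counts by ≈k² and
leaves cm² areas unchanged; with disks of radius ≥ 20 px the residual
rasterization effect is below 1%. Sub-pixel alignment matters at small
radii: a radius-15 disk centered on a pixel corner can deviate by ~1.3%
from πr², which is why the validation uses radius ≥ 10 px for detection but
larger disks when asserting tight area agreement.

## Density matrix, ranking, and hit rate

`build_density_matrix()` lays per-clone areas out as a complete rectangular
clones × (temperature, day) table, zero-filled where no halo was detected
— absence of an extractable halo is a measured zero, not missing data.
Duplicate (clone, condition) records and unknown clones are hard errors.

`rank_clones()` encodes the selection logic of a two-step screen: on a
chosen day, tier 1 comprises clones with a halo at *every* requested
temperature (the fast, thermally broad responders); within a tier, clones
order by descending total area, ties broken alphabetically, so the ranking
is reproducible run to run. `summarize_screen()` reports the hit rate to
one decimal with halves rounded away from zero (12 of 563 → 2.1%); for
every screen size up to 1000 the rounded rate still recovers the exact
positive count, a property the suite verifies exhaustively.

## The synthetic plate generator

`generate_plate()` exists so the whole pipeline can be validated without
photographs: it composes a scene in CIELAB — uniform agar background
(default L\* 82, slightly warm), thin grid lines (default 2 px wide, deep
blue, at 100 px / 13 mm spacing, forming the 13 mm squares into which
screening plates are commonly ruled), and halos as solid disks at a target
b\* — then encodes to 8-bit sRGB and adds Gaussian sensor noise on the
encoded channels, which is where a phone camera's noise and quantization
actually live. An optional linear L\* ramp emulates imperfect
back-lighting. Ground truth (exact rasterized pixel counts, areas from the
implied calibration, the noise-free mask) is computed before noise, so
distinct seeds change only the noise.

Default geometry is a 5 × 4 grid of 100-px cells — room for the 12 positive
plus 8 control clones of a typical confirmation plate — at 0.13 mm/px,
about the resolution of a phone photograph of a 9 cm dish.

What the generator deliberately does *not* model: agar texture, specular
highlights, condensation, halo edge gradients (real halos fade; synthetic
disks are hard-edged), or cross-image exposure drift. Passing the synthetic
benchmarks therefore demonstrates that segmentation, geometry, calibration
and bookkeeping are correct, not that the b\* band is optimal for any
particular camera or substrate — that remains a per-assay calibration.

For noisy validation the halo b\* targets are drawn from [−18, −7], one
noise standard deviation inside the (−20, −5) band: a halo rendered *at*
the band edge loses pixels to thresholding at any noise level by
construction, which would measure the noise model rather than the
pipeline. Noise-free checks use the full radius range (10–40 px), where
detection is exact.

## Validation problem sizes

The test suite and the acceptance script use: 1000 random RGB triplets
against the scalar color oracle; an 18³-point RGB lattice for the round
trip; 50 random images for segmentation equivalence; 20 seeded 300 × 400 px
plates (10 noiseless, 10 at σ = 5) with 3–8 halos each for end-to-end area
recovery (observed: precision = recall = 1.0, area error 0% noiseless,
< 2% at σ = 5); and a 1×/2× render pair for scale invariance (< 0.7%
deviation). These sizes keep a full run in tens of seconds while leaving
the tolerances meaningfully tight.

## Sequence utilities

The screen's endpoint is usually a sequenced ORF, so the package carries
the corresponding arithmetic: `orf_protein_length()` (n/3 − 1, stop codon
excluded), `translate_orf()` (standard genetic code, internal stops are
errors), and `average_molecular_mass()` (isotope-averaged residue masses
plus one water, reported in kDa to one decimal, initiator methionine
included). A 1137 bp ORF encodes 378 residues; translating a full ORF and
summing masses reproduces the convention under which such a protein is
reported at ~40-odd kDa. Tests cross-check translation against Biostrings
and masses against seqinr's calculator; fetching a live GenBank accession
(`fetch_ncbi_fasta()`) is left to sessions with network access.
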