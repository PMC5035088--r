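# mmpipe

Automated analysis of **mother machine** (MM) time-lapse image stacks in R.

The mother machine is a microfluidic device for long-term single-cell
imaging of rod-shaped bacteria: arrays of dead-ended growth channels, one
cell wide, open into a nutrient trench. The trapped "mother" cell divides
continuously at the dead end while its progeny are pushed out and flushed
away, so a single position yields thousands of generations of single-cell
data — far more than manual analysis can handle, and a geometry that
defeats general 2D colony-segmentation tools.

`mmpipe` implements the full analysis chain, exploiting the device's rigid
geometry by reducing every stage to 1D mean-intensity profiles:

1. **Registration** — per-frame drift against frame 1 from the argmax of
   the cross-correlation of horizontal/vertical profiles.
2. **Orientation correction** — the chip's rotation angle
   θ = arctan(mean strip shift / strip width) from cross-correlated
   vertical-profile differences of image strips, with outlier rejection.
3. **Channel detection** — the channel interval *i*<sub>C</sub> from the
   dominant spectral period, the width *w*<sub>C</sub> from
   cross-correlating rising against falling edge signals, and per-channel
   boxes from a phase-matched binary reference comb weighting the edges.
4. **Cell detection** — cells as 1D `[top, bottom)` intervals between
   adjacent maxima of a baseline-corrected channel profile, filtered by
   physical length (≥ 1 µm), *blackness* (Otsu dark fraction ≥ 50%) and
   *prominence* (spline-envelope gap).
5. **Tracking** — per frame pair, each cell takes one fate — same (S),
   divided (D), lost (L), with unexplained cells appearing de novo (N) —
   by greedy least-cost selection under non-crossing order constraints.
6. **Quantification** — division times between consecutive divisions on a
   lineage path, growth rate μ = ln(2)/*t*<sub>d</sub> with physiological
   bounds 0.01–1.0 h⁻¹, precision/recall against reference annotations,
   background-corrected fluorescence, TSV export and kymographs.

A synthetic scene generator (`scene_config()` / `generate_stack()`)
renders MM stacks with complete ground truth — geometry, per-frame cell
extents, lineage, drift, rotation — so the entire pipeline is validated
without any external dataset.

## Worked example

Generate a synthetic study stack (20 channels, 120 frames at 5-minute
intervals, scripted doubling time 1.3 h) and analyse it end to end:

```r
library(mmpipe)

cfg <- scene_config(T_frames = 120, seed = 42)
gs  <- generate_stack(cfg, doubling_time_h = 1.3)
an  <- mm_analyze(gs$series)
summary(an)
#> <mm_analysis> position synthetic
#>   frames: 120 analyzed / 120 total; rotation 0.49 deg
#>   channels: 20 | sightings: 10367 | tracks: 1001 | divisions: 431
#>   division time: 1.28 +/- 0.28 h (n = 342, mu in [0.01, 1.00] 1/h)
#>   growth rate: 0.54 1/h
sum(gs$truth$divisions$observable)
#> [1] 445
```

Reading the output: the scripted 0.5° chip rotation is recovered as
0.49°; all 20 growth channels are found; 431 of the 445 observable
scripted division events are reconstructed (96.9%); and the mean division
time over the 342 events inside the physiological growth-rate bounds is
1.28 h against the scripted 1.3 h — within one 5-minute frame interval,
the quantisation limit of the data. `export_table(an$lineage, "out.tsv")`
writes one row per cell sighting; `plot(an, gs$series, channel = 1,
path = "kymo.png")` renders a kymograph with the lineage overlay.

Real data enters through `load_stack()` (TIFF/OME-TIFF; pixel size from
OME metadata or supplied explicitly), and `subsample()` mimics longer
imaging intervals for data-requirement studies. A thin command-line
wrapper with `analyze`, `generate`, `kymograph` and `evaluate`
subcommands is installed under `inst/scripts/mmpipe`.

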