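---
title: "Profile-based analysis of mother machine time-lapse stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-based analysis of mother machine time-lapse stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpipe)
```

## The problem

The mother machine (MM) is a microfluidic device for long-term live-cell
imaging of rod-shaped bacteria: an array of dead-ended growth channels,
each one cell wide, opens into a nutrient supply trench. The "mother"
cell trapped at the dead end divides continuously; its progeny are
pushed towards the open end and flushed away. A multi-day experiment
yields tens of thousands of frames per position, far beyond what manual
analysis can handle, and general-purpose colony segmentation tools fail
on the tight contact between cells and device walls.

`mmpipe` automates the whole chain: registration, orientation
correction, channel detection, 1D cell detection, lineage tracking and
single-cell quantification. The central design commitment, which every
stage shares, is to reduce 2D images to 1D mean-intensity profiles
wherever possible: the MM's geometry is so constrained (a periodic
vertical channel comb; cells stacked along a single axis) that profiles
carry the needed information at a fraction of the cost and with fewer
failure modes than 2D segmentation.

## Pipeline stages and their models

### Registration

Stage drift is estimated by cross-correlating horizontal and vertical
mean-intensity profiles separately, yielding an integer-pixel shift
vector per frame. Integer precision is deliberate: all downstream
analysis is 1D with tolerances of a pixel or more, and sub-pixel
resampling would smear the profiles. Vacated pixels after correction
are filled with the median intensity, which approximates background.
Flat (structure-free) profiles are flagged as degenerate and report
zero shift.

The pipeline combines two estimates per frame: the direct estimate
against the frame-1 reference, and the accumulated chain of
adjacent-frame estimates. The direct estimate is exact while the scene
still resembles frame 1, but the channel comb is periodic, and once the
channels fill with dark cells a frame-1 correlation can lock onto a
half-period offset; adjacent-frame estimates are immune to gradual
content change but accumulate error over hundreds of frames. The
pipeline therefore uses the direct estimate whenever it agrees with the
chain within 2 px (which also resets the chain) and falls back to the
chain otherwise.

### Orientation correction

The chip may be mounted with a small rotation. The image is cut into
`N` vertical strips of width `d = W/N` (default 16, reduced for narrow
images so every strip keeps at least ~40 columns); each strip's
smoothed vertical profile is differenced, adjacent difference profiles
are cross-correlated, and the angle is `atan(mean(kept shifts)/d)`.
Three robustness choices matter in practice:

* the per-strip correlation peak is refined by parabolic interpolation,
  because integer lags quantise the angle to about `atan(0.5/d)` -
  too coarse for the 0.2 degree accuracy the correction needs;
* the lag search is bounded by `d * tan(15 deg)`: a mounted chip cannot
  be rotated further, and without the bound a strip pair with
  dissimilar content (e.g. a cell-packed strip next to a channel-free
  margin) can return an arbitrarily large spurious shift;
* outliers are removed by the two-sigma-from-median rule with a
  MAD-based spread estimate; a plain standard deviation is itself
  inflated by exactly the outliers the rule is meant to reject.

The angle is estimated once on the first registered frame and applied
to all frames (chip rotation is physically constant; per-frame
re-estimation is available as an option but adds jitter).

### Channel detection

The channel array is strictly periodic, so its interval `i_C` is the
dominant period of the horizontal profile's spectrum; spectral peaks
are refined parabolically and the integer comb spacing is then pinned
by the autocorrelation peak of the edge signal, because spectral
resolution alone (one part in the number of visible periods) is not
sufficient on narrow crops. A frame whose "dominant" peak does not
stand clearly above the median spectral power (factor 20) carries no
array and is rejected.

The array's vertical extent is the largest run of horizontal strips
whose own dominant period matches the global one; a strip packed with
cells may lock onto a harmonic of the comb (the two bright wall halos
per channel), so harmonic matches (k = 1..3) are accepted as the same
structure, and gaps of up to two strips flanked by solid matching runs
are closed - the aggregate cell layout can dominate an individual
strip's spectrum. An upfront significance check (the channel-frequency
peak must stand an order of magnitude above the median spectral power)
makes structure-free images fail loudly. The integer comb spacing is
additionally guarded against harmonic locks: a multiple of the
candidate interval is adopted only when its per-overlap
autocorrelation is decisively stronger, since a true comb
autocorrelates comparably well at every multiple of its period.

Within the cropped array, channels are brighter than the device
material, so the derivative of the horizontal profile has a positive
peak at each left flank and a negative peak at each right flank.
Splitting the derivative into rising (`c_l`) and falling (`c_r`) parts,
the channel width `w_C` is the lag maximising their cross-correlation
restricted to `(0, i_C)`. A binary reference comb with teeth at both
expected flanks of every channel is phase-matched to `c_l + c_r`,
giving the phase `phi`; multiplying the shifted comb into the edge
signal yields a robustified channel signal whose per-tooth support
separates real channels from channel-free border regions (threshold:
half the mean per-tooth support). Finally each flank is snapped to the
local edge-signal peak within 2 px, which removes the one-to-two pixel
bias that the halo's secondary edges induce in the global correlation
estimates.

Interval and width are properties of the device, not of a frame. The
pipeline therefore estimates them once on the first analysable frame -
in a normal experiment the seeding frame, where channels are sparsely
populated - and re-estimates only phase and extent per frame. On
densely packed frames the edges of the cell bodies otherwise compete
with the wall edges and can win the width correlation. Channels are
given stable identities across frames by matching box positions to the
reference within half an interval.

### Cell detection

Cells inside a channel crop are 1D objects: dark intervals on the
vertical intensity profile, separated by bright constrictions. The
profile is baseline-corrected by subtracting a maximally smoothed copy
of itself (Hamming window spanning the whole profile) and smoothed
again (5-tap window). Local extrema are found with a sliding window
whose width defaults to the minimum cell length in pixels - wiggles
below the minimal cell scale cannot be cell boundaries - with plateaus
collapsing to their centre and forced max/min alternation. Maxima whose
contrast over their neighbouring minima is below 5% of the crop's
intensity range are pruned as noise (a real constriction is several
times brighter); this prevents long cells from being split in half by
noise-scale wiggles on their flat interiors.

Adjacent maxima pairs become cell candidates. Each candidate boundary
is then refined inward to the half-height crossing between the
bracketing maximum and the dip minimum. This deviates from the simplest
convention (boundaries at the maxima themselves) for a measured reason:
for cells bordering a wide bright region - the last cell before the
open end, the mother below the dead-end medium pocket - the nearest
maximum can sit 10 px or more into the bright region, and the diluted
extent pulls the blackness score below its threshold, silently dropping
exactly the cells where divisions are most often missed. The half-height
extent is also the more physical length estimate (the 1D analogue of
full width at half maximum).

Candidates pass three independent filters:

* **length**: at least `min_length_um` (default 1 um) - rejects debris
  and split fragments;
* **blackness**: the fraction of the candidate's extent classified dark
  by Otsu binarisation of the crop must be at least 0.5 - rejects
  bright inter-cell gaps (a polarity flag handles contrast-inverted
  data);
* **prominence**: the gap between spline envelopes through the cleaned
  profile's maxima and minima, evaluated at the candidate centre, must
  exceed a floor (default 2% of the crop's range, far below the
  blackness criterion) - rejects numerically flat jitter dips.

Candidates whose centroid falls outside the detected array rows (crop
margin, strip-rounding rows) are discarded.

### Tracking

Between consecutive frames each cell has exactly one fate: same (S),
divided into two adjacent daughters (D), or lost (L); unexplained cells
in the next frame appear de novo (N). Fates are priced and the cheapest
feasible combination is selected greedily - least-cost fates are picked
until every cell in both frames is covered - under the one-fate
constraints and a non-crossing constraint (cells cannot swap order in a
1D channel, so the selected link set must be monotone in both frame
indices; N and L guarantee feasibility).

The exact functional forms of the published costs are not available, so
this package defines documented parametric ones: quadratic position
deviation against the history-predicted position (normalised by
`pos_scale_px`, default 8 px, inflated proportionally when a skipped
frame is bridged) plus quadratic relative length deviation against the
elongation-predicted length (normalised by `len_scale`, default 0.15).
The division cost uses the daughter pair's summed length and midpoint,
plus a small constant (`div_penalty`, default 1) so a division is only
chosen when the length evidence supports it. Appearance and loss are
constants (default 20), well above typical movement and division costs,
so they fire only when no plausible link exists. Histories (velocity,
elongation factor) are exponentially weighted means over the last three
sightings; cold starts use zero velocity and unit growth. Ties are
broken towards smaller indices, making tracking deterministic. The cost
API is isolated in `build_costs()`, so alternative forms can be swapped
in without touching the solver.

On random plausible frame-pair instances (stacked cells evolving by
growth, division and loss) the greedy solution is identical to the
exhaustive optimum in ~99% of cases; on adversarial random cost
matrices it is not, which is inherent to greedy selection and not the
population the tracker faces.

### Quantification

A division time is the time between consecutive divisions on a lineage
path, i.e. from a track's birth-by-division to its own division. Tracks
whose birth was not observed (present at the first frame, or appearing
de novo mid-series) contribute no division time: including their
censored intervals would bias the statistics. Events whose implied
growth rate `mu = ln(2)/t_d` falls outside physiological bounds
(default 0.01-1.0 per hour) are excluded as artifacts. The growth rate
is reported as `ln(2) / mean(t_d)`.

Precision/recall against reference division annotations pairs events
greedily by ascending Manhattan distance in the (occurrence frame,
division age in frames) plane, with a per-coordinate offset cap.
Fluorescence is quantified as the bounding-box mean minus the device
background, measured between the growth channels (central half of each
inter-channel gap, same rows), so channel interiors never contaminate
the background. A moving-average growth-rate curve (window 25 events)
is reported as undefined wherever a time bin has fewer than 5 events
(the threshold is a package default; the idea is that sparse stretches
must not show rates driven by single artifacts). Kymographs concatenate
a channel's crops over time with one polyline per track.

## The synthetic scene generator

Every pipeline stage is validated against synthetic stacks with full
ground truth, generated by `scene_config()` / `generate_stack()`. The
generator emulates what the algorithms actually rely on:

* a periodic array of bright channels (default: 20 channels at 30 px
  interval, 10 px width) on a darker device, with bright wall halos on
  the innermost lumen columns and a bright feed trench across the open
  ends - static device features that real phase-contrast MM images
  show and that the profile algorithms key on;
* dark rod-shaped cells (narrower than the lumen, with bright medium
  alongside, as in phase contrast) that elongate exponentially at
  `ln(2)/t_d` with 5% per-cell rate jitter, divide when reaching a
  per-cell threshold around 3.0 um (s.d. 0.2 um) at an asymmetry ratio
  drawn around 0.5 (s.d. 0.05, truncated), stack towards the open end
  with a 0.25 um constriction gap, and are flushed once they would
  protrude past it; a 0.35 um bright medium pocket separates the mother
  from the dead-end wall;
* global rotation (default 0.5 degrees), a bounded random-walk drift
  (step s.d. 0.3 px, bound 8 px), a smooth multiplicative illumination
  plane (10%), additive Gaussian noise (4% of the dynamic range), a
  1 px Gaussian blur so profiles have realistic extrema, and 16-bit
  quantisation so written stacks round-trip bit-identically.

The kinetic defaults reproduce the biological regime of a slow-growing
rod bacterium (doubling time 1.3 h at 5-minute imaging; lengths around
3 um before and 1.5 um after division). Division events whose lower
daughter is flushed in the same simulation step are recorded but
flagged unobservable: they are never rendered as a two-cell
configuration, so no image-based method could count them, and recovery
is assessed against the observable count.

What the generator does **not** model: phase-contrast halo optics
beyond the simple bright wall lines, focus drift, cell bending or
width variation, segmentation-relevant texture inside cells, or
cross-channel crosstalk. Passing the recovery tests therefore shows
that the algorithms are correct for the geometry and contrast structure
of MM data, not that their thresholds are tuned for any particular
microscope.

## Numerical choices and degenerate inputs

* Cross-correlation is linear (zero-padded FFT), on mean-subtracted
  signals; ties break towards the smallest-magnitude lag; flat signals
  return zero with a degeneracy flag.
* Spectral peaks and rotation-strip correlation peaks are refined by
  parabolic interpolation over three samples.
* Otsu thresholds use a 256-bin histogram over the observed range; tie
  plateaus (empty intensity gaps) resolve to the middle split, which
  maximises the classification margin.
* Smoothing is convolution with a unit-sum Hamming window; boundaries
  are handled by reflection to avoid edge droop that would fake
  extrema. Window lengths not fixed by the method itself (the
  full-profile baseline window is) are package defaults: 15 for
  rotation strips, 3 for the channel-edge profile, 5 for cleaned cell
  profiles.
* Frames whose structure detection fails are skipped with a warning;
  the tracker bridges the gap as a single step with the position
  tolerance inflated by the gap length. Two divisions cannot be chained
  across a skipped frame.
* Frames are 1-based in R code and in user-facing tables; pixel
  coordinates are 0-based half-open intervals.

## Problem sizes used in the validation suite

The acceptance-level checks run on full-size study conditions: a
20-channel, 240-frame stack at 5-minute intervals for parameter
recovery; the same conditions over replicate seeds and subsampling
strides 1-6 for the interval-degradation trend; 100 random device
configurations for channel localisation; 200 random synthetic channels
for detection accuracy; and exhaustive brute-force enumeration on small
instances for the operation-level oracles. Unit tests use smaller
scenes of the same structure.

## Known limitations

* The tracker's cost coefficients are package defaults, not fitted to
  any dataset; grossly different imaging intervals may need rescaling
  (`tracking_params()`).
* Registration keys on static device structure in the profiles; a
  field of view with almost no device contrast degrades both the direct
  and the chained estimate.
* Rotation estimation assumes the array spans a reasonable fraction of
  the image width; on very narrow crops the angular precision degrades
  with the strip width.
* Division times are quantised by the imaging interval; at long
  intervals the tracker increasingly merges or misses events, which is
  precisely the degradation the stride study measures.
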