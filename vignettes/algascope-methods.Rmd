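---
title: "Methods: automated recognition of freshwater algae micrographs"
author: "algascope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated recognition of freshwater algae micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(algascope)
```

## The problem

Freshwater algae are sensitive, fast-responding indicators of water
quality, and routine monitoring means identifying and counting them in
bright-field micrographs — slow, expert work when done by eye. `algascope`
implements an automated chain for five common genera spanning three
divisions: *Navicula* (a diatom with an elongated boat-shaped frustule),
*Scenedesmus* (a green alga forming flat four-celled coenobia), and the
cyanobacteria *Microcystis* (irregular colonies of small granular cells),
*Oscillatoria* (long unbranched filaments with regular transverse septa)
and *Chroococcus* (pairs of hemispherical cells in a mucilaginous sheath).
The chain is: preprocessing, Canny-edge segmentation, a 21-dimensional
shape/texture feature vector per detected object, and a small
feed-forward neural network classifier with a rejection class for foreign
objects.

No imagery ships with the package. Instead a seeded synthetic micrograph
generator emulates the five morphologies with per-pixel ground truth, so
every stage — and the end-to-end benchmark — is reproducible from a single
integer seed.

## Preprocessing

Images are kept as floats in $[0,1]$ throughout; quantization to 8 bits
happens only at file I/O.

1. **Contrast enhancement.** Histogram equalization maps intensities
   through the 256-bin cumulative distribution; for RGB input the value
   channel is equalized and the channels rescaled proportionally, so hue
   is untouched. The mapping is monotone and a constant image is a fixed
   point.
2. **Grayscale.** ITU-R BT.601 luminance, $0.299R + 0.587G + 0.114B$.
3. **Binarization with complement.** Otsu's global threshold, then
   complement, so dark organisms on the bright field become foreground.
   Two guards make the automatic threshold well-posed. First, a constant
   image has no threshold and yields an all-background mask with a
   warning. Second, Otsu's criterion assumes a bimodal histogram; on an
   object-free frame it happily splits the noise distribution in half and
   fabricates foreground. We therefore require the two class means it
   produces to differ by at least `minContrast = 0.15` of full range —
   sensor noise spans a few hundredths, genuine object/background
   contrast several tenths, so the floor sits far from both.

   Because histogram equalization is a monotone intensity map,
   thresholding the raw grayscale is exactly equivalent to thresholding
   the equalized image at the mapped threshold. The threshold is
   therefore computed on the raw intensities, whose histogram retains the
   physical bimodality that equalization, by construction, flattens; the
   resulting masks are identical either way.
4. **Median filter.** A 3×3 median (for a binary image: majority of the
   nine neighbours, borders replicated) removes salt noise while
   preserving solid regions up to one-pixel boundary smoothing.

## Segmentation

The Canny detector runs on the preprocessed binary image:

* Gaussian smoothing with $\sigma = 1.4$ px (kernel truncated at
  $3\sigma$, borders replicated);
* Sobel first derivatives $G_x, G_y$; gradient magnitude
  $g = (G_x^2 + G_y^2)^{1/2}$ and direction $\alpha = \mathrm{atan2}(G_y,
  G_x)$, quantized into four sectors (0°, 45°, 90°, 135°) for
  non-maximal suppression. The suppression comparison is strict on one
  side, so a perfectly symmetric step yields a one-pixel line rather
  than a tied pair;
* double thresholding at 0.10 and 0.25 of the maximum magnitude, then
  hysteresis: the weak∪strong mask is labelled with 8-connectivity and a
  component is kept iff it contains a strong pixel — an exact, vectorized
  equivalent of transitive edge linking.

Morphological cleanup turns edge chains into solid regions, in order:
3×3 dilation (closes small gaps), hole filling, 3×3 erosion (restores
scale), removal of border-touching regions, and exclusion of components
smaller than 50 px (strictly: a 49-px component is dropped, a 50-px one
kept).

**Touching objects.** A component whose bounding rectangle is longer than
50 px and at least 50 px in the perpendicular direction is flagged as a
probable cluster and passed to a distance-transform watershed: catchment
markers are the regional maxima of the distance map, detected in a 15-px
neighbourhood, and basins whose separating saddle is shallower than 4 px
of distance are merged. The depth criterion is what distinguishes a
genuinely overlapping pair (two disks of radius 35 whose centres sit
40 px apart have a saddle ≈ 6.3 px deep — split) from a scalloped colony
outline or the rasterized ridge line of a filament (saddles of a pixel or
two — kept whole). If the watershed returns a single region the component
is emitted unsplit, flagged. Detected components are paired with the
original colour image: each is cropped to its bounding box, background
pixels zeroed, and indexed consecutively from 1.

## Features

All geometric features are measured on the *aligned* mask, making them
invariant to the organism's orientation in the frame.

**Alignment.** The object's inclination is the angle of its longest
chord: the boundary-pixel pair at maximal Euclidean distance, found by
exhaustive search (squared distances are exact integers). Rasterization
blunts tips, creating near-ties — pairs within half a pixel of the
maximum whose directions scatter a few degrees about the true axis — so
the reported angle is the circular mean of the near-ties' undirected
directions (via angle doubling), which is unbiased when tip pixels
scatter symmetrically. The reference line is horizontal ($m_2 = 0$), so
$\theta = \tan^{-1} m_1$ is translation invariant and lies in
$(-90°, 90°]$. The object is rotated by $-\theta$ about its mask
centroid: colour planes bilinearly, the mask as bilinear coverage
lightly smoothed and thresholded at 0.5 (plain nearest-neighbour
sampling staircases the boundary and inflates chain-code perimeters).
One corrective pass runs when the re-measured residual exceeds 1°; if
the aligned object is taller than wide (possible for near-square
outlines whose chord is a diagonal), a quarter turn restores the
major ≥ minor convention.

**The 21 features.**

| # | feature | definition |
|---|---------|------------|
| F1 | shape index | 0 circular, 1 elongated/spiral, −1 irregular |
| F2 | major axis | horizontal extent of the aligned mask (px) |
| F3 | minor axis | maximum vertical extent over columns (px) |
| F4 | area | foreground pixel count (px²) |
| F5 | perimeter | closed boundary chain length (px) |
| F6–F8 | ratios | F3/F2, F4/F2, F5/F2 |
| F9–F13 | width factors | $R_c = W_c / L$ over five equal strips |
| F14–F21 | texture | PCA scores of the polar Fourier descriptor |

The shape index uses circularity $C = 4\pi A / P^2$ and elongation
$E$ = major/minor: circular when $C \ge 0.75$, else elongated when
$E \ge 2.8$, else irregular. The thresholds were calibrated once against
three reference shapes — a filled disk ($C \approx 0.91$ as measured by
the chain-code perimeter, which overestimates ideal contours by
5–15%), a 200×12 bar ($E \approx 17$), and an L of two 80×30 bars
($C \approx 0.49$, $E \approx 2.7$) — so that the three categories
separate cleanly under the package's own perimeter metric.

The perimeter traces the outer boundary as a closed 8-connected chain
(Moore neighbour tracing with a lookahead stopping criterion that is
robust to contours pinched at the start pixel) and sums unit steps for
axial moves and $\sqrt 2$ for diagonal ones. The width profile slices the
aligned horizontal span into five equal strips; $W_c$ is the maximum
vertical extent within strip $c$ and $L$ the major-axis length, so a
100×40 rectangle gives the constant profile 0.4 and a disk a symmetric
dome peaking at 1.

**Texture.** The masked grayscale crop is resampled to 64×64,
mean-subtracted (otherwise the window leaks the DC offset into the
lowest-frequency bins and swamps everything), Hann-windowed, and its
power spectrum taken with the DC bin zeroed. The spectrum is accumulated
into polar bins $S(r, \phi)$ — 16 radial bins up to Nyquist, 16 angular
bins over $[0, \pi)$ (the spectrum of a real image is symmetric). The
radial marginal $P_1(r)$ captures the energy-versus-frequency profile
(fine granules versus coarse septa), the angular marginal $P_2(\phi)$
directionality (striation orientation); each is normalized to unit sum
and the concatenation $[P_1 \| P_2]$ is the 32-dimensional raw
descriptor. A constant crop has only DC energy and yields the zero
descriptor.

**PCA.** The descriptor is compressed to 8 components by eigendecomposing
the covariance of the *training* descriptors only (fitting on test data
would leak); components carry a deterministic sign convention (largest
loading positive) and descending eigenvalues. Test objects are projected
with the frozen model.

## Classifier

A single-hidden-layer feed-forward network sized 21-8-5 with hyperbolic
tangent on both layers. Inputs are standardized by the training-split
mean and standard deviation (stored with the model) — unavoidable when
features mix pixels, squared pixels and unit ratios. Targets are coded
+1 for the true class and −1 elsewhere, matching the tanh range.

Training is online backpropagation of squared error with momentum,
$\Delta w(t) = -\eta\, \partial E / \partial w + \mu\, \Delta w(t-1)$,
with $\eta = 0.05$, $\mu = 0.05$, presentation order reshuffled each
epoch from the run seed, at most 400 epochs. A stratified 10% of the
training data is held out; training stops when the held-out RMSE has
risen for 10 consecutive epochs (a single noisy uptick should not stop
training), and the weights of the best-validation epoch are restored.
Backpropagated gradients are verified against central finite differences
in the test suite.

Prediction takes the argmax of the five outputs; when the maximum
activation falls below the rejection threshold (default 0) the object is
labelled *Unidentified*. Evaluation builds the 6×6 confusion matrix
(five genera plus Unidentified), per-class accuracies (diagonal over row
sum) and overall accuracy (diagonal sum over N), so an Unidentified
prediction counts as an error for a true-genus row.

## The synthetic generator

Each scene is a bright background (mean 210/255) with a smooth random
illumination gradient (±6% across the frame) and Gaussian pixel noise
(sd 8/255), carrying dark objects (mean intensity ≤ ~120/255) at
rejection-sampled non-touching positions; a forced-overlap mode instead
places a pair with 20–40% mask intersection for the separation stage.
The default canvas is 640×512 — half the resolution of the source
imagery the pipeline targets, a deliberate economy since every stage is
resolution-independent. The archetypes:

* **Navicula** — a lens (intersection of two circular arcs), length
  95–140 px, aspect 3–6, with fine transverse striations (period 4–7 px);
* **Scenedesmus** — four vertically elongated elliptical cells
  overlapping side by side, cell half-height 16–24 px;
* **Microcystis** — a lobed near-circular blob (radius 28–42 px) packed
  with small dark granules (~1 per 50 px²);
* **Oscillatoria** — a capsule filament, length 170–260 px, aspect ≥ 8.4,
  with regular dark septa (period 6–9 px);
* **Chroococcus** — a dividing pair of cells (radius 18–25 px) in a
  shared sheath, a gently waisted peanut outline;
* **Debris** — an irregular lobed fragment with flat aperiodic texture,
  for the rejection path.

Orientation is uniform in $[0°, 180°)$; every archetype's area clears the
50-px segmentation floor several-fold. All stochastic parameters flow
from one explicit seed (per-scene seeds are drawn from a master seed with
disjoint draws for the training and test splits), so datasets are
byte-identical across runs; the benchmark generates, processes and
discards scenes one at a time, which keeps memory flat at study scale.

What the generator does *not* emulate: optics (no point-spread function,
no depth-of-field blur or halo), occlusion and dense colonies beyond the
two-object overlap mode, within-genus morphological plasticity beyond
the parameter ranges above, debris that mimics algal texture, and
staining/illumination pathologies. Passing the synthetic benchmark
therefore demonstrates that the chain — detection, isolation, invariant
measurement, learning — is implemented correctly and is learnable at
realistic contrasts; it does not validate taxonomic accuracy on real
lake samples.

## Numerical choices and degenerate inputs

* Constant images: no edges, all-background masks (with a warning from
  the binarizer), zero texture descriptors.
* Strict NMS on one side; half-pixel chord tie window; watershed saddle
  tolerance 4 px; contrast floor 0.15 — each discussed above where it
  arises.
* The chain-code perimeter is orientation-biased by up to ~8% on tilted
  straight edges; features are measured after alignment, where the
  residual tilt is ≤ ~1–2°, and the smoothed mask rotation keeps repeated
  resampling from accumulating boundary wiggle.
* Features whose supporting extent is only a few pixels (e.g. the width
  of a 16-px filament) are quantized at the ±1 px level; the 5%
  stability bands quoted in the tests apply to features resolved by
  ~20 px or more.
* Empty feature strips cannot occur for connected aligned objects but
  would yield $R_c = 0$.

## Study sizes

The bundled benchmark uses the study protocol: 40 training and 50 test
single-alga images per genus (200 training, 250 test scenes), each
640×512, processed end to end; `scripts/acceptance.R` reruns it from one
seed and writes the overall accuracy. The test suite exercises the same
stages on smaller instances chosen so each property is measurable in
seconds.

## Known limitations

* The *Unidentified* rejection rule is mechanical (maximum activation
  below threshold). With one-versus-rest ±1 targets and clean, well
  separated training clusters, tanh outputs saturate on inputs far from
  all classes, so at the default threshold of 0 little debris is
  actually rejected; reliable foreign-object rejection would need
  negative training examples or a calibrated confidence model, both out
  of scope.
* Chord-based alignment canonicalizes elongated outlines well but is
  ambiguous for near-square ones; the quarter-turn correction restores
  the axis convention, yet features of such objects are inherently less
  orientation-stable.
* The watershed separates overlapping pairs whose waist is several
  pixels deep; heavily merged colonies (waist depth under the 4-px
  tolerance) come through unsplit, flagged.
* One image is processed at a time; there is no tracking, counting
  statistics, or multi-frame logic.
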