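---
title: "Resistivity mapping for LSFG waveforms: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resistivity mapping for LSFG waveforms: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsfgbom)
```

## The waveform model

Laser speckle flowgraphy (LSFG) reports blood flow as the mean blur rate
(MBR), an arbitrary-unit scalar per pixel per frame; a standard acquisition
is 118 frames over 4 s. Within a region of interest the spatially averaged
MBR trace is pulsatile at the cardiac frequency, and the relative size of
that pulsation carries information about downstream vascular resistance —
the same physiological signal the Doppler pulsatility index
(PI = (peak − trough)/mean velocity) captures.

The package quantifies it as follows. For a trace $Y = (y_1,\dots,y_T)$ at
times $t_1 < \dots < t_T$:

1. $\mathrm{MBR}_{avg} = \bar y$, and the trace is centered on it.
2. The centered trace is modelled on a sine/cosine dictionary at grid
   frequencies $f_1,\dots,f_M$: $Y = FX$ with
   $X = (a_1,\dots,a_M,\,b_1,\dots,b_M)$ and spectral magnitude
   $P(f_i) = \sqrt{a_i^2 + b_i^2}$.
3. Beat strength $BS = C \cdot \max_i \{ P(f_i) : f_i \in \text{band} \}$.
4. $\mathrm{BOM} = BS / \mathrm{MBR}_{avg}$.

BOM is dimensionless, scale-invariant (multiplying the trace by $k > 0$
leaves it unchanged) and requires no heartbeat segmentation, unlike the
legacy per-beat parameters (blowout score/time). For a sinusoidal waveform
of amplitude $A$ about mean $m$, the spectral peak is $A$, so with $C = 2$,
$\mathrm{BOM} = 2A/m$ = peak-to-peak over mean — exactly the PI analogue.
That is why $C = 2$ is the default: $BS$ is *proportional* to peak-to-peak
pulsatile flow, and $C = 2$ fixes the proportionality so that the phantom's
pulse ratio is recovered identically. $C$ is configurable; absolute BOM
values from other implementations may differ by a global scale.

### Why the spectrum estimator is sparse

The reporting grid is $0.1, 0.2, \dots, 10$ Hz ($M = 100$), but a 4-s
window has a Rayleigh resolution of only $1/4\,\mathrm{s} = 0.25$ Hz:
adjacent dictionary columns are strongly correlated, and with $2M = 200$
unknowns against $T = 118$ samples the dense problem is underdetermined.
Any dense minimum-norm or ridge solution therefore *spreads* a single
tone's energy across neighbouring frequencies — numerically, a 3-unit tone
at 1.0 Hz retains only ~1.2 units at its own bin under a small-ridge dense
solve. A maximum-based statistic like $BS$ would be badly biased.

The default estimator is therefore a greedy sparse fit (orthogonal
matching pursuit): atoms are selected one at a time by the residual energy
a single-frequency sine/cosine least-squares fit explains, each atom's
frequency is then refined continuously within half a grid step (golden
section/parabolic search on the same criterion), all selected atoms are
refit jointly, and the refined atoms are finally binned to the nearest
grid frequency (coefficients add coherently within a bin, so split atoms
recombine to the physical amplitude). Three numerical details matter:

* The joint refit carries an **intercept column**. Centering removes the
  mean of the *sampled window*, which differs from the tone's own DC when
  the window holds a non-integer number of periods; without the column
  that residual DC leaks into the atom amplitudes at the $10^{-3}$ level.
* Stopping: at most `max_components` atoms (default 10), or when residual
  energy falls below `tol` (default $10^{-10}$ relative), or when the best
  candidate atom explains less than `tol` of the total energy.
* Ties at the spectral maximum break toward the lower frequency, making
  the reported peak frequency deterministic.

On noise-free single tones this estimator recovers on-grid amplitudes to
machine precision and half-grid-step off-grid amplitudes to a few
hundredths of a percent. A dense ridge solver
(`estimator = "ridge"`, penalty $10^{-6} T$ by default) is retained for
comparison and raises an informative error when asked to solve the
singular unpenalized problem. An $L_1$-penalized variant would slot in at
the same interface but is not provided.

Recovery of a phantom's pulse ratio is exact only when the temporal mean
is: for cardiac frequencies whose period does not divide the window, the
sampled mean differs from the generative mean by $O(1/(2\pi f T_{dur}))$,
which propagates into BOM at the $10^{-3}$ relative level. This is a
property of the finite window, not of the estimator.

The cardiac band defaults to 0.5–3 Hz (30–180 bpm), wide enough for any
resting heart rate while excluding respiratory and high-frequency noise;
the in-band restriction is what makes $BS$ robust to out-of-band artifacts.

## The synthetic phantom

`phantom_spec()` emulates the features of an LSFG acquisition that the
analysis depends on, with known ground truth:

* regional mean flow levels (background tissue, a disk for the optic nerve
  head, bright vessel segments over darker tissue), rendered hard-edged in
  draw order (later regions win) so region membership is unambiguous;
* a cardiac pulsation `mean * (1 + (pulse_ratio/2) sin(2π f t + phase) +
  harmonics)` on the uniform grid $t_j = j \cdot duration/n\_frames$ —
  `pulse_ratio` (peak-to-peak over mean) *is* the ground-truth BOM at
  $C = 2$; the default 1.2 Hz corresponds to 72 bpm, a typical resting
  heart rate;
* multiplicative speckle noise: each sample is multiplied by an i.i.d.
  gamma variate with mean 1 and shape $k$. A one-parameter multiplicative
  family is the simplest model that is intensity-proportional (as speckle
  is) and reproduces the sample-count-dependent bias phenomenon; $k$ is a
  calibration knob, not a claim about any instrument — $k = 50$ gives a
  per-pixel coefficient of variation of ~14%, $k = 100$ ~10%, $k = \infty$
  is noise-free.

What the phantom does **not** emulate: optics-level speckle statistics and
their spatial correlation, eye movement, blinks and eyelash shadows,
heart-rate variability, and the choroidal/retinal layering of real fundus
images. Passing tests therefore demonstrate the correctness of the
*algorithms* under a controlled noise model, not clinical performance.

## Flow-driven SLIC superpixels

The temporal-mean MBR map is segmented by a SLIC adaptation in which flow
replaces color. Cluster centers start $S$ pixels apart with alternate rows
staggered by $\lfloor S/2 \rfloor$ (hexagonal packing; staggered centers
that would leave the frame are clipped to the last column, preserving the
$\lceil H/S\rceil \cdot \lceil W/S\rceil$ count). Each center claims
pixels inside its $2S \times 2S$ search window by

$$D = \sqrt{(d_{mbr}/compactness)^2 + (d_{xy}/S)^2},$$

assignments and centroids alternate until no pixel changes cluster (an
exact stopping rule, with a `max_iter = 50` safety cap), and a post-pass
enforces 4-connectivity. The default $S = 14$ keeps superpixels at about
$S^2 \approx 200$ pixels, small enough to preserve large retinal vessels.

Design choices where the standard algorithm leaves room:

* **Flow normalization.** $d_{mbr}$ is divided by the map's interquartile
  range, floored at the median flow level, making `compactness` unit-free.
  The floor matters twice: a minority structure narrower than a quartile
  (a vessel tree occupying <25% of pixels) would otherwise zero the IQR,
  and a *structureless* map — pure speckle around a constant level, whose
  IQR is just the noise scale — would otherwise have its noise amplified
  to order one, fragmenting the segmentation. With the floor, genuine
  contrasts (tens of percent of the flow level) still dominate the spatial
  term at the default `compactness = 0.1`, while temporal-mean speckle
  (~1% at realistic noise) is suppressed and the segmentation degrades
  gracefully to a near-regular grid.
* **Compactness 0.1** (flow-dominant): chosen so that a two-valued step
  edge aligned with the grid is never straddled (boundary recall 1);
  configurable.
* **Connectivity.** Pixels are claimed independently, so a label can end
  up with detached fragments — e.g. a tissue cluster whose search window
  spans a crossing vessel leaves a strip on the far side. Every
  non-largest 4-connected fragment of a label is merged into the adjacent
  label with the most similar mean flow (largest as tie-break), so such a
  strip rejoins tissue rather than the vessel; a label whose
  largest fragment is below `min_size_frac * S^2` (default a quarter of
  the nominal size) is absorbed entirely. After the pass every label is
  4-connected and labels are dense `1..K` — these are invariants the test
  suite audits with an independent flood-fill oracle.
* **Degenerate maps** are legal: a constant map yields a near-regular
  grid (on 280 × 280 at $S = 14$: 400 superpixels of 196 pixels each);
  an all-zero map falls back to a unit flow scale.
* Coordinates are 1-based row/column pixel centers, R's convention.

`superpixel_bom_map()` then averages the stack over each superpixel per
frame and computes one BOM per superpixel — $K$ spectra instead of
$H \times W$, which is the efficiency that makes mapping practical.
`pixelwise_bom_map()` is the exhaustive oracle; at $S = 1$ the two agree
to within $10^{-9}$ by construction, which the suite checks.

## Rubber bands and regional parameters

`make_mask()` rasterizes an ellipse by the center-inclusion inequality and
a rectangle by half-open index ranges (a 200 × 200 band encloses exactly
40,000 pixels). Vessels and tissue inside the optic-nerve-head band are
split by Otsu's histogram threshold on the temporal-mean map (the
implementation delegates to EBImage; an exhaustive between-class-variance
search serves as the test oracle); the vessel class is the brighter one,
and the two masks partition the band. A constant map has no threshold and
degrades, with a warning, to all-tissue — downstream, empty regions are
dropped from the report rather than failing the whole run.

For the rubber-band method the region's trace is averaged first and one
BOM computed (averaging-then-spectrum, the order used throughout). For the
superpixel method the map is segmented once and a region's value is the
*unweighted* mean of the BOMs of superpixels whose centroids fall inside
the region's mask — centroid membership is deterministic and cheap, and
unweighted averaging mirrors how the per-superpixel bias analysis weights
its terms ($1/n$ each). Both choices are switchable policies rather than
claims; majority-overlap membership and size-weighted means would be the
natural alternatives.

## The noise bias between the methods

The two methods differ in averaging order: rubber band averages ~40,000
pixels *before* the spectrum, superpixels average ~200. Spatial averaging
over $n$ pixels shrinks speckle variance by $1/n$
(`spatial_mean_convergence()` demonstrates the law), so the rubber-band
trace is effectively noise-free while a superpixel trace retains noise —
and a *maximum* of spectral magnitudes is inflated by noise. Hence
superpixel BOM ≥ rubber-band BOM in expectation, with the gap shrinking
as $S$ (and the per-superpixel sample count) grows.

`bias_experiment()` reproduces this empirically rather than algebraically:
a constant-resistivity phantom gives both methods the same ground truth,
each replicate draws a fresh noisy stack, and the direction of
`mean(bom_sp - bom_rb)` is tested with a one-sided sign test — chosen
because the claim is an inequality, not an effect size, and the sign test
is distribution-free. Replicate seeds derive as `seed + i - 1`, so
experiments sharing a base seed see identical stacks and comparisons
across `S` are paired. The magnitude of the bias depends on the noise
shape $k$, which no measurement pins down here, so only its sign and its
monotone decrease with superpixel size are asserted.

The suite runs the bias experiment at $S = 14$ with 100 replicates on a
200 × 200 constant-flow phantom at $k = 50$, and the $S \in \{8, 14, 28\}$
sweep with 40 paired replicates per spacing; the two-region recovery tests
use 120 × 120 frames at $k = 100$ ("moderate": ~1% standard error on the
temporal-mean map, well inside the 5% recovery tolerance). These sizes
keep the full suite in the minutes range on a single core while leaving
Monte-Carlo margins wide.

## Repeatability and method comparison

`coefficient_of_variation()` (100·sd/mean) is the repeatability measure
across repeated acquisitions; `fit_line()` regresses superpixel on
rubber-band BOM by ordinary least squares, reporting slope, intercept and
$R^2$ with broom-style `tidy()`/`glance()` methods. On simulated sweeps
the slope lands near 1 with a non-negative intercept (the noise bias); the
intercept's size is cohort- and instrument-dependent and is not a target.

## File formats

Stacks travel as multi-page TIFF (one 32-bit page per frame, page order =
time order) with a YAML sidecar carrying frame times, the full-scale
factor, the seed and the generating phantom spec. The available TIFF
encoder stores normalized samples, so values are scaled by a power-of-two
full-scale factor on write and restored on read; round-trip agreement is
~$5 \times 10^{-10}$ relative, far beyond single-precision fidelity, and
units are never otherwise rescaled. Without a sidecar, times default to
the standard 118-frame/4-s pattern. Reports export as CSV, run summaries
as YAML tagged with a configuration hash, and every source of randomness
flows from the single run seed.

## Known limitations

* BOM from a mixed region (vessels + tissue) is the spectrum of the mixed
  trace, not a mean of member BOMs; only when the constituents share a
  cardiac phase does it land between the regional values.
* The sparse fit reports at most `max_components` spectral lines; dense
  broadband spectra are out of its design envelope (the ridge estimator
  covers exploratory use).
* Off-grid cardiac frequencies recover to ~0.1% via refinement, but the
  finite window still biases the temporal mean as noted above.
* The phantom's noise is spatially independent; real speckle has spatial
  correlation, which would slow the $1/n$ averaging law and move the bias
  magnitudes (not their sign).
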