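# lsfgbom

Ocular blood-flow **resistivity mapping** for laser speckle flowgraphy
(LSFG) image sequences.

LSFG records the mean blur rate (MBR) — an arbitrary-unit index of blood
flow — per pixel, typically in 118 frames over 4 s. The pulsatile component
of the MBR waveform carries information about vascular resistance, which is
clinically relevant for diseases such as retinal vein occlusion. This
package computes the heart-rate-independent resistivity index **BOM**
("beat strength over MBR") and turns it into two-dimensional maps. It is
intended for researchers working with LSFG-like pulsatile flow imaging, and
ships a fully synthetic pulsatile phantom so every stage can be exercised
and validated without clinical data.

## The method

For a region's spatially averaged MBR trace
`Y = (y_1, ..., y_T)` on times `t_1 < ... < t_T`:

1. `MBR_avg = mean(Y)`; the trace is centered on it.
2. The centered trace is expanded on a sine/cosine dictionary at grid
   frequencies `f_1, ..., f_M` (default `0.1, 0.2, ..., 10` Hz, `M = 100`):
   `Y = F X` with `X = (a_1..a_M, b_1..b_M)`, and spectral magnitudes
   `P(f_i) = sqrt(a_i^2 + b_i^2)`. Because the grid spacing is far below
   the Rayleigh resolution of a 4-s window, the coefficients are estimated
   by a *sparse* greedy fit (orthogonal matching pursuit with continuous
   frequency refinement) rather than a dense solve; see the methods
   vignette for why this matters.
3. Beat strength is the scaled in-band spectral maximum,
   `BS = C · max { P(f_i) : f_i in band }`, with cardiac band
   0.5–3 Hz (30–180 bpm) and `C = 2` by default.
4. `BOM = BS / MBR_avg` — the LSFG analogue of the Doppler pulsatility
   index (peak-to-peak / mean flow for a sinusoidal waveform). Higher BOM
   means higher resistivity.

Two spatial averaging schemes are implemented and compared:

* **Rubber band** (the conventional ROI): average the stack over an
  ellipse/rectangle per frame, then compute one BOM. Regional parameters:
  BOM.A (entire optic nerve head), BOM.T (ONH tissue), TCR (ONH retinal
  vessels, delineated by an automatic Otsu histogram threshold), BOM.CHD
  (choroid).
* **Superpixel**: the temporal-mean map is segmented by a SLIC adaptation
  in which flow takes the place of color (default grid spacing `S = 14`,
  about 200 pixels per superpixel); one BOM per superpixel yields a
  resistivity map, and a region's value is the mean over superpixels whose
  centroids fall inside it.

Because a superpixel averages ~200 pixels instead of tens of thousands,
residual speckle noise inflates its spectral maximum: superpixel BOM is
systematically *higher* than rubber-band BOM. `bias_experiment()`
reproduces this bias Monte-Carlo-style and quantifies how it shrinks as
superpixels grow.

## Worked example

```r
library(lsfgbom)

# A synthetic fundus: pulsatile tissue with a brighter, more resistive
# vessel crossing the optic nerve head, plus mild speckle noise.
spec <- phantom_spec(
  height = 120, width = 120, cardiac_freq_hz = 1.5,
  regions = list(
    region_background(mean_mbr = 25, pulse_ratio = 0.5, name = "tissue"),
    region_vessel(from = c(1, 60), to = c(120, 60), half_width = 8,
                  mean_mbr = 45, pulse_ratio = 0.7, name = "vessel")),
  noise_shape = 100, seed = 42)
ground_truth_bom(spec)
#> tissue vessel
#>    0.5    0.7

stack <- generate_sequence(spec)
onh <- rb_ellipse(center = c(60, 60), semi_axes = c(40, 40))

region_boms(stack, onh_band = onh, method = "rubber_band")
#> # A tibble: 3 × 6
#>   region method      mbr_avg    bs peak_freq_hz   bom
#> 1 BOM.A  rubber_band    30.4  17.6          1.5 0.579
#> 2 BOM.T  rubber_band    25.0  12.5          1.5 0.500
#> 3 TCR    rubber_band    45.0  31.4          1.5 0.699

region_boms(stack, onh_band = onh, method = "superpixel")
#> # A tibble: 3 × 7
#>   region method     mbr_avg    bs peak_freq_hz   bom n_superpixels
#> 1 BOM.A  superpixel    29.0  16.3          1.5 0.542            27
#> 2 BOM.T  superpixel    25.0  12.5          1.5 0.500            21
#> 3 TCR    superpixel    43.1  29.6          1.5 0.688             6
```

The tissue and vessel BOMs land on their ground truths (0.5 / 0.7 within a
few percent at this noise level); the vessel class is found automatically
from the temporal-mean map. `superpixel_bom_map()` returns the full
two-dimensional BOM field (`autoplot()` renders it).

The speckle-noise bias between the methods, on a constant-flow phantom
where the only systematic difference can come from noise:

```r
bias <- bias_experiment(
  phantom_spec(120, 120, regions = list(region_background(30, 0)),
               noise_shape = 50),
  rb_rect(c(1, 1), 120, 120), n_replicates = 12, seed = 1)
bias
#> <lsfg_bias_experiment: 12 replicates, k = 50, S = 14,
#>   mean(BOM_SP - BOM_RB) = 0.006495, sign-test p = 0.000244>
```

Superpixel BOM exceeds rubber-band BOM in every replicate, as the
averaging-order argument predicts.

A thin command-line wrapper is installed as `exec/lsfgbom` with
subcommands `simulate`, `analyze`, `map` and `compare`.

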