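---
title: "Methods: membrane-localization metrics and binding analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane-localization metrics and binding analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmquant)
```

pmquant quantifies how strongly a fluorescently tagged lipid-binding
module localizes to the plasma membrane in cells, and how tightly it binds
defined lipid vesicles in vitro. This vignette records the models the
package implements, the assumptions behind them, and the design decisions
taken where the underlying protocols leave room.

## The annulus procedure

A confocal image of a cell expressing a membrane-binding probe shows a
bright rim (plasma membrane) around a dimmer, roughly uniform cytosol.
The localization metrics need the mean intensity of each compartment, so
the image is reduced to three masks:

1. **Cell footprint.** The image is thresholded (Otsu by default),
   binarized, internal holes are filled, and the largest connected
   component is kept. Hole filling matters: the nucleus often excludes the
   probe, and an unfilled void would acquire its own spurious "membrane"
   rim under erosion. Keeping the largest component encodes the
   one-cell-per-analysis convention; fields with several comparable cells
   should be cropped first.
2. **Interior.** The footprint is eroded `n` times, removing one pixel of
   rim per pass.
3. **PM annulus.** The eroded image is subtracted from the footprint; the
   ring left along the periphery represents plasma-membrane fluorescence.
   Annulus and interior partition the footprint exactly — an invariant the
   constructor enforces and the test suite property-checks.

The erosion count tracks a fixed physical rim width across magnifications:
`erosions_for_physical_width()` returns `round(0.4 µm / pixel_size)`
clipped to 2–4, i.e. a ~400 nm rim — comfortably wider than the optical
section of a membrane but narrow enough that the annulus is dominated by
membrane signal.

### Structuring element

Iterating the classical 3×3 square element (the 8-connected erosion of
ImageJ's binary erode) measures depth in the Chebyshev metric: after `n`
passes the rim is `n` pixels wide along the image axes but `n√2` wide
along diagonals. On round cells the annulus therefore swallows cytosol in
the diagonal sectors and the membrane mean is biased low — on our
synthetic cells this alone costs about 3 percentage points of %PM, larger
than the 2-point recovery the pipeline aims for. The default element is
therefore `"octagon"`: square and diamond (4-connected) erosions
alternate, which approximates the Euclidean distance (worst-case width
error ~6% instead of ~41%) and brings the median %PM recovery error on
noisy synthetic cells to ~1.1 points. `element = "square"` reproduces
ImageJ behaviour exactly when matching historical analyses; on
axis-aligned rectangles all three elements coincide.

## Localization metrics

With `I_PM` the pixel mean over the annulus and `I_Cyt` the cytoplasmic
mean:

- `%PM = 100 · I_PM / (I_PM + I_Cyt)`, in (0, 100];
- PM index = `I_PM / I_Cyt`;
- dissociation index = PM index before / PM index after a treatment.

Both ratios are invariant under detector gain but *not* under an additive
offset, which pulls them monotonically toward 50% / 1. The package
therefore offers (off by default, since the classical protocol computes
ratios on raw intensities) subtraction of the mean intensity outside the
cell mask.

Decisions where the protocol is underdetermined:

- **Cytoplasm definition.** Default: the whole eroded interior — less
  operator-dependent than hand-picked regions. The practice of averaging
  two sampled cytoplasmic regions is reproduced by
  `cytoplasm = "rois"` with seeded square ROIs.
- **Nuclei and puncta** are *not* excluded from the cytoplasm; no
  exclusion rule is part of the procedure, and the synthetic generator
  lets one measure the resulting bias directly.
- **Dissociation-index orientation.** Defined before/after, so that
  membrane release reads as an index above 1; `orientation =
  "after_before"` inverts it. This orientation is an assumption, flagged
  here and in the function documentation.
- **Time series.** Each frame is re-segmented (intensity drifts as the
  probe redistributes); a frame whose segmentation fails falls back to the
  most recent successful masks, which is safe because cells move little
  over a few minutes.
- Degenerate inputs error loudly: uniform images (no threshold exists),
  foregrounds below `min_area`, erosion counts that empty the mask, and
  zero-intensity compartments (`I_Cyt = 0` flags the PM index as
  undefined rather than reporting infinity).

## Synthetic cells

`simulate_cell()` paints a harmonic-perturbed disc —
`R(θ) = r(1 + a·cos(kθ))`, default amplitude 0.06, order 3, to exercise
non-convex erosion — with a rim of nominal width 0.4 µm at 200 AFU over a
50 AFU cytosol and 5 AFU background, at 0.1 µm/pixel on a 128×128 frame
(16-bit quantization on export). Pixel size and bit depth are realistic
conventions for a zoomed 63× confocal scan, chosen once as generator
defaults, not measurements. Noise follows the standard fluorescence-camera
model: Poisson on the signal (AFU treated as photon counts; at 200 AFU
the rim SNR is ~14) followed by additive Gaussian read noise (default
SD 2 AFU). Ground truth (`I_PM`, `I_Cyt`, %PM, masks) is computed from the
noiseless painted pixels, so with a dim nucleus or bright puncta the truth
reflects what was actually painted. Puncta are confined to the interior
mask — intracellular vesicles must never contaminate the rim.

`simulate_timeseries()` renders membrane release after phosphatase
recruitment as `M(t) = C₀ + (M₀ − C₀)·e^{−kt}` (default k = 0.01 /s,
frames every 5 s); with `cytosol_gain` the lost rim signal reappears in
the cytosol so total painted fluorescence is conserved — the behaviour of
a probe that translocates rather than bleaches.

What the generator does **not** emulate: point-spread blur (no PSF
convolution; edges are sharp), photobleaching, z-structure, cell motion,
neighbouring cells, or autofluorescence gradients. Passing the recovery
tests therefore shows the estimator is unbiased for well-resolved,
isolated cells with flat backgrounds — not that it is robust to blur or
crowding in real fields.

## In-vitro binding

**Co-sedimentation.** Percent binding is `100·pellet/(pellet +
supernatant)`; when a carrier-vesicle control lane is given, its raw
percentage is subtracted and the result floored at zero. The subtraction
form is an assumption (the convention "with respect to control vesicles"
is not formulaic); the floor prevents negative binding from noisy faint
lanes.

**Charge-matched compositions.** Comparing phosphoinositide classes at
equal charge requires a per-class charge value. The default proxy is the
count of ring phosphomonoesters (mono/bis/tris = 1/2/3) — the convention
under which 5 mol% of a bisphosphate PIP is equivalent to 3.3 mol% of
PIP₃, matching standard charge-matched vesicle designs. A physiological
net-charge table (−3/−4/−6 at pH 7.4) is available; only charge *ratios*
enter the computation, so the sign convention is immaterial. Reported
mol% is rounded to one decimal; round trips are involutive up to that
rounding.

**SPR.** Sensorgrams are corrected by pointwise subtraction of the
control-surface channel (linear interpolation onto the active grid;
non-overlapping grids are an error, extrapolation beyond 0.5 s is
refused). `R_eq` is the mean over the final 10% of the association phase
(minimum 5 samples) — a deliberate plateau estimate that underestimates
the asymptote if the injection ended while still rising, which the
documentation flags rather than hides. The isotherm fit uses
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`, ftol = ptol =
1e-14 so that noiseless round trips recover parameters to better than
1e-6 relative) with data-driven starts: `R_max ← 1.1·max(R_eq)`, `K_d ←`
the concentration whose response is nearest half of that; both bounded
above zero. If the tested concentrations do not span the fitted `K_d` the
fit warns of ill-conditioning. Kinetics are analysed separately per the
1:1 Langmuir model: each dissociation phase is fit as a single
exponential (estimates averaged into `k_d`), each association phase as
`R_eq(1 − e^{−k_obs t})`, and `k_a` is the slope of `k_obs` against
concentration — whose intercept re-estimates `k_d` and serves as an
internal consistency check, as does `k_d/k_a` against the isotherm `K_d`
(they agree to 1e-3 relative on noiseless data). Mass-transport
limitation and bivalent binding are out of scope; concentrations are
molar throughout.

**Statistics.** Group summaries report mean ± SEM (`sd/√n`; single
observations are flagged, not silently dropped). One- and two-way ANOVA
use the classical F tests; per-group significance flags come from Welch
t-tests against the reference group without multiplicity correction,
matching the single-threshold reporting style common in this literature
(a Bonferroni option exists). Zero-variance designs are reported as
degenerate (F = 0, p = 1 for null effects; F = ∞, p = 0 for saturated
ones) instead of NaN.

## Problem sizes and verification

The test suite validates every simulator against closed forms, every
morphological operation against a brute-force set-arithmetic oracle on
shapes up to 64×64, and the statistics against explicit sums-of-squares
and permutation (10⁴ resamples) oracles. Parameter-recovery runs use 50
seeded noisy cells at 128×128 (median |estimated − true| %PM ≈ 1.1
points, bound at 2) and 20 no-decay time series of 10 frames for the
dissociation-index null; the full suite runs in under ten seconds on one
core. All randomness flows through explicit integer seeds — there is no
hidden global state, and identical seeds give bit-identical outputs.

## Known limitations

- Segmentation assumes one dominant, well-separated cell; touching cells
  are not split.
- The annulus is 2-D; membrane above/below the nucleus projects into the
  "cytoplasm" in real confocal sections, biasing `I_Cyt` upward — a
  limitation of the method itself, not just of this implementation.
- The kinetic model is strict 1:1 Langmuir; heterogeneous surfaces or
  avidity effects on multivalent membranes violate it, which is why the
  isotherm `K_d` is reported as *apparent*.
- `R_eq` extraction is biased low for injections shorter than ~3/k_obs;
  prefer longer association phases or the kinetic route in that regime.
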