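# pmquant

Quantitative tools for membrane-targeting studies of peripheral
lipid-binding proteins — the kind of work where a fluorescently tagged
domain (for instance a C2 domain that reads phosphoinositides and
phosphatidylserine) is scored for how strongly it decorates the plasma
membrane in cells, and for how tightly it binds defined lipid vesicles in
vitro. The package is aimed at cell biologists and biochemists who have
confocal images, Biacore sensorgrams and pelleting-assay gels and want the
standard numbers computed reproducibly from them.

## What it computes

**Cellular localization (image path).** From a confocal image the cell is
thresholded, binarized, hole-filled and reduced to its largest connected
component; eroding the binary mask and subtracting the eroded copy leaves
an annulus around the cell periphery representing plasma-membrane
fluorescence, while the eroded interior defines the cytoplasm. The erosion
count tracks a ~400 nm physical rim across zoom levels. From the two mean
intensities `I_PM` and `I_Cyt`:

- percent plasma-membrane localization
  `%PM = 100 · I_PM / (I_PM + I_Cyt)`
- PM index `I_PM / I_Cyt`
- dissociation index = (PM index before) / (PM index after) a treatment,
  e.g. rapamycin-induced recruitment of a phosphoinositide phosphatase;
  values above 1 mean the probe left the membrane.

**In-vitro binding (biochemistry path).**

- co-sedimentation percent binding `100 · pellet / (pellet + supernatant)`,
  optionally corrected against a carrier-lipid control lane;
- charge-matched vesicle design: the mol% of one phosphoinositide class
  carrying the same headgroup charge as a reference class (5 mol% of a
  bisphosphate PIP ↔ 3.3 mol% of PIP₃);
- SPR analytics: control-surface subtraction, plateau `R_eq` extraction,
  nonlinear least-squares fitting of the Langmuir isotherm
  `R_eq = R_max / (1 + K_d/[P])`, and separate association/dissociation
  kinetics (`k_obs = k_a[P] + k_d`);
- group statistics: means ± SEM, one- and two-way ANOVA with
  reference-group significance flags.

**Synthetic ground truth.** Every analysis stage has a matched simulator —
cells with a bright membrane rim, diffuse cytosol, optional nucleus and
puncta under Poisson + Gaussian camera noise; exponential membrane-release
time series; Langmuir sensorgrams and isotherms; two-band gel lanes — so
the whole pipeline is testable without microscope or instrument data.

## Worked example

```r
library(pmquant)

# a noisy synthetic cell with known 80% PM localization
cell  <- simulate_cell(seed = 42)
mask  <- segment_cell(cell$image)
masks <- make_pm_annulus(mask, erosions_for_physical_width(pixel_size(cell$image)))
quantify_localization(cell$image, masks)
#> # A tibble: 1 × 7
#>    i_pm i_cyt pm_index percent_pm n_pm_px n_cyt_px pm_index_defined
#>   <dbl> <dbl>    <dbl>      <dbl>   <int>    <int> <lgl>
#> 1  187.  50.0     3.74       78.9    1324     6544 TRUE
```

The pipeline recovers 78.9 %PM against a ground truth of 80 — the annulus
mean (187 AFU) sits slightly below the painted membrane intensity (200 AFU)
because the carved rim inevitably includes a little cytosol at the inner
boundary.

```r
# saturation SPR responses at 8 concentrations (10–3000 nM), fitted isotherm
iso <- simulate_isotherm(Kd = 340e-9, Rmax = 100,
                         concs = c(10, 30, 100, 300, 600, 1000, 2000, 3000) * 1e-9,
                         noise_sd = 1.5, seed = 42)
fit_isotherm(iso)
#> <isotherm_fit> Kd = 3.35e-07 M (335 nM), Rmax = 100.6 RU, RSS = 9.05, n = 8
```

With 1.5 RU of noise the fit returns 335 nM for a generating apparent
affinity of 340 nM. `tidy()`, `glance()` and `autoplot()` work on the fit
object.

```r
# rapamycin-style depletion series: membrane signal decays at 0.01 /s
ts <- simulate_timeseries(n_frames = 10, pm_decay_rate = 0.01, seed = 42)
dissociation_index(ts)
#> # A tibble: 1 × 3
#>   pm_index_before pm_index_after dissociation_index
#> 1            3.74           2.31               1.62
```

A dissociation index of 1.62 > 1 reports loss of membrane localization; a
no-decay control scores 1 within noise.

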