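# reec

Modelling and quantification tools for **restricted exchange environment
chambers (REECs)** — shallow (~100 µm) culture chambers in which a cell
monolayer receives oxygen and nutrients only through a small central
aperture, so that the cells themselves generate stable radial gradients
of O₂ and metabolites, an experimentally accessible 2-D analog of the
tumor microenvironment. The package is written for quantitative
microscopists and modellers who run such chambers (or similar
diffusion-limited cultures) and want to (a) predict the gradients their
cells create and (b) quantify the radial structure of the fluorescence
read-outs they measure.

## What it computes

**Transport model.** The concentration *C*(*r*, *t*) of a consumed
species on the chamber annulus (aperture radius *r*₁, wall radius *r*₂)
obeys the radially symmetric diffusion–consumption equation

    ∂C/∂t = (1/r) ∂/∂r ( r D ∂C/∂r ) − n k f(C),
    f(C) = C_bulk · C / (C + C_bulk)

with boundary conditions *C*(*r*₁, *t*) = C_bulk (the aperture is a
constant source), ∂C/∂r(*r*₂, *t*) = 0 (no flux through the wall), and
the uniform initial condition *C*(*r*, 0) = C_bulk set the moment the
chamber top is placed. Here *n* is the volumetric cell density and *k*
the per-cell rate constant calibrated from the measured maximum per-cell
consumption rate, A_max = k·C_bulk. At steady state the gradient decays
over the characteristic length **λ = √(D/(n·k))**. The solver is
conservative finite volumes in *r* with stiff implicit time integration
(`deSolve`); steady state is declared when the relative RMS change
between successive minute-spaced profiles falls below 0.1%. A
closed-form modified-Bessel solution for the dilute (linear-uptake)
limit and a Fick's-law column model for the concentration actually
presented at the aperture are included.

**Quantification pipeline.** Mirrors the standard analysis of segmented
chamber images: per-cell intensities binned into 50-µm annuli (MFI ±
SEM), raster-image radial profiles, normalization conventions
(first-point / max / external control; absolute or disk-relative
distances), 5-point moving-average smoothing, hypoxic-front detection
(distance at which a hypoxia reporter first reaches 90% of its maximum),
fold changes versus control, disk-area change, Pearson channel
correlation, and replicate aggregation.

**Synthetic data.** A seeded generator samples cells from an
inhomogeneous Poisson process on the annulus, assigns
concentration-dependent reporter intensities with multiplicative
log-normal noise, emulates disk formation phenomenologically, and
renders 16-bit images (Gaussian spots, optional tile-stitching
artifact), so the entire pipeline is testable end to end without
laboratory data.

## Worked example

Reference oxygen parameters (D = 3370 µm²/s, A_max = 2.98×10⁷
molecules·cell⁻¹·s⁻¹ from a mito-stress test, C_bulk = 171 µM) over a
confluent monolayer (2×10⁵ cells/cm², 100 µm chamber):

```r
library(reec)

oxy  <- oxygen_params()
cons <- consumer_field()

per_cell_rate(oxy)
#> [1] 289.3805                      # k, um^3 cell^-1 s^-1
characteristic_length(oxy, cons)
#> [1] 763.0717                      # lambda, um
column_model(column_spec())
#> [1] 170.6582                      # uM at the cell layer under the aperture
#> attr(,"drop_uM") 7.341849         # drop down the 250-um column from 178 uM

steady <- solve_steady_state(oxy, cons)
steady
#> steady state (converged at 0.35 h)
#> oxygen profile at t = 172800 s: 566 nodes, 350-6000 um, C in [0.07443, 171] uM
front_from_concentration(steady$profile, 44.5)
#> [1] 753.2818                      # um from the aperture edge to 5%-O2 level
```

So the model predicts the cell layer under the aperture sees ~171 µM
O₂, gradients converge well inside two hours, and oxygen falls below
the 44.5 µM reporter threshold within ~750 µm of the opening edge —
hypoxia sets in less than a millimetre from the source.

Recovering that structure from synthetic "microscopy" data:

```r
cells <- sample_cells(uniform_density(2e-3), seed = 1)   # 225,127 cells
cells <- assign_intensities(cells, steady$profile,
                            intensity_model("hypoxia", noise_sigma = 0.2),
                            seed = 2)
prof <- smooth_profile(bin_cells(cells, "reporter", bin_width = 50),
                       window = 5)
hypoxic_front(prof, fraction = 0.9)
#> front at 1708 (90% of max 1022), crossing bin 35
```

The 90%-of-max reporter front recovered from a quarter-million noisy
synthetic cells (1708 µm from the chamber centre) lands within a
fraction of a bin of the front computed directly from the concentration
profile at the matched threshold.

## Package layout

- `R/transport.R` — parameter objects, unit conversion, closed forms
  (k, λ, column model, chamber volume)
- `R/simulator.R` — the finite-volume transient/steady solver, Bessel
  closed form, concentration-front extraction
- `R/profiling.R` — binning, normalization, smoothing, fronts, areas,
  correlation, aggregation, CSV I/O
- `R/synthdata.R` — seeded synthetic cell tables, disk series, image
  rendering
- `R/config.R`, `R/cli.R`, `exec/reec` — configuration files and the
  command-line pipeline
- `vignettes/reec-methods.Rmd` — the model, its assumptions, numerical
  choices, and known limitations
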