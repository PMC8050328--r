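---
title: "Methods: the REEC diffusion-consumption model and radial profiling pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the REEC diffusion-consumption model and radial profiling pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes and why:
the transport model and its assumptions, the parameters that matter, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the limitations we know about.

## The physical setting

A restricted exchange environment chamber (REEC) confines a cell
monolayer under a shallow (~100 µm) ceiling with a single small aperture
(~0.7 mm diameter). Oxygen and nutrients reach the cells only by
diffusing in through the aperture, while the cells consume them
everywhere; the interplay creates stable, radially symmetric
concentration gradients centred on the opening. Cells near the opening
stay normoxic, distal cells become hypoxic, and over days the culture
reorganizes into a disk around the aperture.

## Transport model

### Governing equation

We model one species at a time (oxygen and glucose are treated
independently — there is no metabolic coupling in the model) on the
annulus between the aperture radius $r_1$ and the chamber wall $r_2$:

$$\frac{\partial C}{\partial t} =
  \frac{1}{r}\frac{\partial}{\partial r}\!\left(r D
  \frac{\partial C}{\partial r}\right) - n\,k\,f(C), \qquad
  f(C) = C_\mathrm{bulk}\frac{C}{C + K_m}.$$

The sink is a saturating (Michaelis–Menten-type) uptake law. The
per-cell rate constant $k$ is calibrated from the measured maximum
per-cell consumption rate via $A_{\max} = k\,C_\mathrm{bulk}$, i.e.
$k = A_{\max} / (N_A\,C_\mathrm{bulk})$ as a clearance in
µm³ cell⁻¹ s⁻¹. Note a wrinkle in this rate law: with the
half-saturation constant $K_m$ hard-wired to $C_\mathrm{bulk}$ (as the
form above implies), consumption at $C = C_\mathrm{bulk}$ is
$n\,A_{\max}/2$, not $n\,A_{\max}$ — the "maximum" rate is approached
only as $C \gg C_\mathrm{bulk}$. The two conventions differ by a factor
of two that the published parameterization does not reconcile. We
implement the law exactly as written, but expose `half_saturation` as an
explicit parameter of `transport_params()` (default $C_\mathrm{bulk}$)
so users who prefer a literature $K_m$ can supply one.

Boundary and initial conditions: fixed concentration
$C(r_1, t) = C_\mathrm{bulk}$ at the aperture (the upper compartment is
a large, well-mixed reservoir), zero flux at the wall, and the uniform
state $C(r, 0) = C_\mathrm{bulk}$ — the moment the chamber top lands,
the whole chamber still holds fresh media.

At steady state the gradient decays over the characteristic length
$\lambda = \sqrt{D/(n k)}$; for reference oxygen parameters
$\lambda \approx 763$ µm.

### Which boundary value: 178 or 171 µM?

Air-saturated media holds 178 µM dissolved O₂, but the cells directly
beneath the aperture consume oxygen on its way in, so the aperture
presents slightly less. `column_model()` quantifies this with a 1-D
steady Fick's-law flux balance over the 250 µm column between the
oxygenated media above the chamber cover glass (100 µm chamber + 150 µm
glass) and the monolayer: the flux down the column equals the areal
consumption $J = \sigma A_{\max}$, giving
$C_\mathrm{cell} = C_\mathrm{top} - J L / D \approx 171$ µM (a drop of
~7.3 µM). We therefore use **171 µM** as the default Dirichlet value
(and as the $C_\mathrm{bulk}$ that calibrates $k$) in the dynamic
model; both are plain parameters. Consumption in this column model is
confined to the bottom boundary — the closed-form linear solution, not
a discretized solver — because the column holds media, not cells.

### Parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| $D$ (O₂) | 3370 | µm²/s | oxygen in media at 37 °C |
| $A_{\max}$ (O₂) | 2.98×10⁷ | molecules cell⁻¹ s⁻¹ | mito-stress-test OCR, 4T1 cells |
| $C_\mathrm{bulk}$ (O₂) | 171 | µM | aperture value from the column model |
| $D$ (glucose) | 616 | µm²/s | glucose in media |
| $A_{\max}$ (glucose) | 6.47×10⁷ | molecules cell⁻¹ s⁻¹ | literature uptake rate |
| $C_\mathrm{bulk}$ (glucose) | 25000 | µM | high-glucose DMEM |
| $\sigma$ | 2×10⁵ | cells/cm² | confluent monolayer plating density |
| chamber height | 100 | µm | nominal spacer height |
| as-built height | 138.4 | µm | measured mean incl. epoxy; use for volume |
| $r_1$, $r_2$ | 350, 6000 | µm | aperture radius, O-ring inner radius |

The volumetric density the PDE needs is derived as
$n = \sigma / h = 2\times10^{-5}$ cells/µm³; the published record never
states $n$ directly, and deriving it from the plating density and the
nominal 100 µm height is the only self-consistent reading. All unit
conversions (molecules↔mol, cm⁻²↔µm⁻², µM↔mol/µm³) are centralized in
one internal module; the internal unit system is {µm, s, µM, cells}.

## Numerical scheme

- **Space**: conservative finite volumes on a uniform radial grid,
  default spacing 10 µm (λ/76 for reference oxygen — the solver warns
  if the spacing exceeds λ/10). Interface fluxes $r D\,\partial C /
  \partial r$ are differenced so the cylindrical divergence is exact for
  the discrete profile; the outer-wall flux is identically zero.
- **Time**: `deSolve::ode.1D` with `lsoda` and a banded Jacobian.
  The consumption timescale $1/(nk) \approx 173$ s is fast relative to
  the 48 h horizon, so implicit stiff integration is the natural
  choice; tolerances are `rtol = 1e-8`, `atol = 1e-8 C_bulk`.
- **Convergence**: profiles are inspected every 60 s of simulated time;
  steady state is declared at the first interval whose relative RMS
  change, normalized by $C_\mathrm{bulk}$, falls below 0.1%. The
  published criterion states the threshold but neither the cadence nor
  the normalization; one minute and $C_\mathrm{bulk}$ are our choices,
  fixed once. The profile returned as "steady" is the final-horizon
  snapshot (cheapest accurate stationary state — by then the change per
  interval is orders of magnitude below tolerance); the first-crossing
  time is reported separately as `convergence_time`.
- **Positivity**: negative values smaller in magnitude than
  $10^{-9} C_\mathrm{bulk}$ are clamped to zero as round-off; anything
  larger aborts with a solver-instability error, so instability is never
  silently smoothed away. The same guard caps round-off excursions above
  $C_\mathrm{bulk}$ (the maximum principle bounds the true solution to
  $[0, C_\mathrm{bulk}]$).
- **Verification**: the solver is cross-checked in the test suite
  against two independent oracles — the modified-Bessel closed form
  $C(r) \propto I_0(r/\lambda)K_1(r_2/\lambda) +
  K_0(r/\lambda)I_1(r_2/\lambda)$ for linear uptake (evaluated with
  exponentially scaled Bessel functions for numerical stability), and a
  damped-Newton finite-difference solution of the nonlinear steady
  boundary-value problem. Agreement is well inside 1%, and halving the
  grid moves the steady profile by ~2×10⁻⁶ RMS.

## Quantification pipeline

Design decisions where the conventional analysis leaves room:

- **Bins** are half-open $[lo, hi)$, constant width (default 50 µm),
  starting at 0 at the opening centre. Empty bins are gaps (`NA`), never
  zeros, and aggregation skips gaps per bin rather than imputing.
- **SEM** of a single-observation bin is undefined (`NA`), deliberately
  distinct from an observed SEM of 0.
- **Front detection** (`hypoxic_front`) takes the *first* outward
  crossing of fraction×max, linearly interpolated between bin centres;
  exact ties resolve to the smaller distance, and a profile already
  above threshold in its first bin fronts at that bin's centre. The
  model-side analog (`front_from_concentration`) finds where dissolved
  O₂ first falls *below* a threshold and reports the distance from the
  aperture edge ($r - r_1$), matching the "distance from the hole"
  convention; radii themselves are always absolute from the chamber
  centre.
- **Smoothing** is a centred moving average (default 5 points,
  truncated at the ends) — the filter conventionally applied against
  tile-stitching oscillation; the historical analyses do not specify
  the filter type beyond "5-point window".
- **Pixel profiles** average pixels within the same 50 µm annuli rather
  than at each discrete radius; with µm-scale pixels the difference is
  far below the bin width.
- Cells detected beyond the chamber wall (real stitched mosaics contain
  them) are excluded with a logged count, not an error.

## Synthetic-data generator

The generator exists so that every pipeline operation is exercised by
data whose ground truth is known exactly. It emulates:

- **Placement**: an inhomogeneous spatial Poisson process on the
  annulus (uniform in angle, thinned in radius), at the reference
  plating density 2×10⁻³ cells/µm² by default — about 2.3×10⁵ cells per
  chamber, matching the order of 10⁴–10⁵ segmented cells per imaged
  disk.
- **Response**: reporter intensity
  $I = I_{\max}(1 - C/C_\mathrm{bulk})$, clipped at zero — a linear
  hypoxia-reporter convention; a sigmoidal alternative with threshold at
  44.5 µM (the 5%-O₂ equivalent of 178 µM at ~20% incubator O₂, the
  highest O₂ at which reporter-positive controls are observed) is
  provided because reporter chemistry is thresholded. No quantitative
  dose–response for the real reporters exists, so these are
  conventions, not fits.
- **Noise**: multiplicative log-normal, $\sigma = 0.2$ on the log scale
  by default. Note the generative mean is
  $e^{\sigma^2/2}\,\mathrm{response}(C)$ (+2% at σ = 0.2) — the
  self-consistency tests compare against that expectation; 90%-of-max
  front detection is scale-invariant and unaffected.
- **Artifacts**: optional multiplicative sinusoidal tile modulation
  (the checkerboard stitching artifact) and Poisson shot noise in
  rendered images.
- **Disk formation**: purely phenomenological — density interpolates
  from uniform to a logistic-edged disk. There is no mechanistic
  migration/proliferation/death model, by design.

It does **not** emulate segmentation errors, spatially structured
background, cell clumping/size variation, reporter photobleaching, or
optical blur beyond an isotropic Gaussian. Passing the recovery tests
therefore shows the *pipeline* is correct and unbiased at realistic
noise, not that real micrographs will behave as well.

All randomness flows from one explicit seed through deterministic
sub-seed derivation, so fixtures are bit-reproducible.

## Problem sizes

The test suite solves the PDE on the default 10 µm grid (566 nodes;
the grid-convergence check also runs 5 µm), and the stochastic
front-recovery checks use 50 seeds × ~2.3×10⁵ cells per condition.
These sizes make the full suite run in well under a minute of solver
time while leaving Monte-Carlo errors far smaller than the 50 µm bin
width they are compared against.

## Known limitations

- **Front distance is sublinear in λ on the annulus.** Quartering
  $A_{\max}$ doubles λ exactly, and in planar geometry would double the
  front distance; on the annulus, cylindrical spreading (the steady
  profile decays like $K_0(r/\lambda)$, roughly
  $e^{-r/\lambda}/\sqrt{r}$) compresses the effect, and under reference
  conditions the recovered 90%-front moves out by ~1.65× rather than
  2×. The often-quoted intuition "half the consumption, twice the
  front" is a planar approximation that holds only when
  $\lambda \ll r_1$; comparisons with measured ~2-fold front shifts
  should keep in mind that the wet-lab consumers (cytokine-stimulated
  macrophages) have an unmeasured consumption ratio, so the model
  fold-change and the measured one are not the same quantity.
- The solver is strictly axisymmetric 1-D; eccentric apertures,
  convection, or non-radial cell distributions are out of scope.
- Consumers are static during a run: consumption does not decline where
  cells die, so long-horizon steady profiles in the far field are
  conservative (real chambers lose distal consumers over days).
- Oxygen and glucose are uncoupled; metabolic shifts (e.g. hypoxia
  raising glycolytic glucose draw) are not modelled.
- The column model assumes a quiescent, purely diffusive column;
  any convective mixing above the chamber would shrink the 7 µM drop.
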