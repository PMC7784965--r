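---
title: "Rate inversion and isotope budgets in layered sulfidic mats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate inversion and isotope budgets in layered sulfidic mats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulfmat)
```

## The system and the measurement model

A sulfidic cyanobacterial mat is a stack of reactive layers a few
millimetres thick: a diffusive boundary layer (DBL) in the overlying water,
often a white film of sulfur-oxidizing bacteria (SOB), a cyanobacterial
layer whose members run anoxygenic photosynthesis (AP, sulfide as electron
donor) or oxygenic photosynthesis (OP) depending on light and sulfide, and a
sulfide-production zone of sulfate/sulfur reducers (SRB) below. Transport is
diffusive; depth is the only resolved dimension. All of the package's rate
arithmetic therefore rests on two relations:

* Fick's first law, `J = -D dC/dz` (fluxes from local gradients), and
* Fick's second law at steady state, `D C'' + R(z) = 0` (volumetric net
  rates from curvature).

Units are fixed package-wide: depths in mm (0 at the mat surface, positive
downward, water column negative), concentrations in µmol L⁻¹ (numerically
equal to nmol cm⁻³), D in cm² s⁻¹, fluxes in nmol cm⁻² s⁻¹ (positive
downward; ×864 gives mmol m⁻² d⁻¹), volumetric rates in nmol cm⁻³ s⁻¹
(positive = production).

## Speciation

H₂S microsensors sense only the protonated species, so total sulfide is
reconstructed from the co-located pH: `S_tot = [H₂S]/α₀(pH)` with
`α₀ = 1/(1 + 10^(pH − pK1))`. `pk1_h2s()` evaluates the Millero (1988)
temperature/salinity parameterization (pK1 = 6.98 for fresh water at 25 °C);
a fixed pK1 can be supplied instead, since the ionic strength of a given
spring water is rarely known precisely. S²⁻ is neglected: its pK is far
above mat pH, so the error is below 10⁻⁴ at pH ≤ 9.

The tabulated diffusion coefficients (1.35 × 10⁻⁵ cm² s⁻¹ for sulfide,
1.78 × 10⁻⁵ for O₂) are the temperature- and salinity-corrected values for
the reference incubation condition, which this package fixes at 14 °C and
salinity 1 — representative karst-spring water; change the reference if your
system differs. Away from the reference, a Stokes–Einstein rescaling
`D ∝ T_K/η(T)` is applied with a Vogel-type viscosity correlation. Porosity
and tortuosity are taken as 1 throughout (loose phototrophic mats, not
compacted sediment); users working with consolidated material should scale
D themselves.

`diffusion_time()` uses the mean-squared-displacement convention
`t = L²/(2D)`: 1 mm at 10⁻⁵ cm² s⁻¹ gives 500 s ≈ 8 min, the timescale that
couples photosynthate excretion to the sulfide producers a millimetre below.
The `L²/D` convention is available but not the default.

## The rate-profile model

`fit_rate_profile()` is the package's central estimator. The fitted object
assumes the mat is a stack of zones with constant net volumetric rate; the
steady concentration is then piecewise quadratic, continuous and
flux-continuous at the zone boundaries, with the measured concentrations at
the first and last depth of the fit interval as boundary conditions. Each
zone's rate enters the solution linearly, so the fit is ordinary least
squares on closed-form basis functions and needs no iteration. Fitting the
integrated model rather than double-differencing the data is what makes the
inversion usable at 180–450 µm sensor spacing with µM-level noise; the naive
second difference (`finite_difference_rates()`) is retained only as a debug
cross-check.

Two exact identities follow from the model and are asserted in the test
suite rather than assumed: the fitted flux `J(z) = -D C'(z)` satisfies
`J(bottom) − J(top) = ∫R dz` to machine precision, and a parabolic profile
over one zone returns exactly `R = −D C''`. Sign conventions: a local
concentration minimum (convex-up curvature) is consumption (R < 0);
`layer_balance()` reports a layer's net consumption as `J(top) − J(bottom)`,
so an interior source with fluxes diverging upward and downward yields a
production equal to the sum of the outgoing magnitudes.

**Zonation.** How many zones, and where? With the zone boundaries known
(e.g. from the visible layering) they are passed directly; otherwise
`select_zonation()` searches. Model-selection here is delicate: the
boundary conditions are pinned to two noisy measurements, and free knots are
chosen by search, so information criteria face strong selection bias. We
found plain BIC to overfit badly on short noisy profiles (more than one zone
on pure-noise flat profiles in the majority of random draws), and therefore
default to the sequential F-test used by the classical porewater-profile
inversion programs: `m + 1` zones replace `m` only when the RSS reduction is
significant (default α = 0.01), each added zone charged one rate and one
knot parameter. BIC remains available (`criterion = "bic"`). With the
F-test, a flat noisy profile selects one zone with a near-zero rate, and a
genuine two-zone contrast is found with its boundary within one sensor
step.

**Flux windows.** Interfacial fluxes use the DBL: `dbl_window()` picks the
longest near-linear (R² ≥ 0.98) run of overlying-water points ending at the
surface, minimum three points; `local_flux()` warns when the window is
detectably curved. `layer_balance()` widens its boundary windows until each
holds three points.

## Light–dark shift rates

Immediately after darkening, diffusion has not yet re-adjusted, so the
instantaneous concentration change at a depth equals the gross rate that was
running there: `gross_rate_lightdark()` fits a line to the first seconds
after the shift (default 3 s window at 0.5 s sampling; the sensors respond
in < 2 s) and returns the slope magnitude — O₂ decline for gross OP, S_tot
rise for gross AP. The estimate is biased low as the window grows, because
diffusive relaxation progressively cancels the imbalance; the bias direction
is monotone and is verified against the transient forward model in the
tests. A curvature check warns when the window is visibly nonlinear.

## Stoichiometric carbon budgets

Four balanced reactions convert measured rates to predicted CO₂ fixation:
OP fixes 1 C per O₂ produced; AP oxidizes sulfide to S⁰ and fixes 0.5 C per
sulfide (each sulfide donates 2 electrons, 4 are needed per C). The
measured gross AP rate is a sulfide consumption rate, so the package
multiplies it by 0.5 by default; because rate bookkeeping conventions differ
(some authors express AP in O₂-equivalents, which doubles rather than halves),
the multiplier is an explicit, logged argument rather than a constant.

Aerobic sulfide oxidation by SOB is bracketed by two end members at a fixed
16.9 % energy-conservation efficiency: incomplete oxidation to S⁰
(0.4 O₂, 0.1 C per sulfide) and complete oxidation to SO₄²⁻ (1.5 O₂, 0.5 C
per sulfide). An observed S_tot:O₂ consumption-flux ratio `r` pins the
mixture: `0.4 f + 1.5 (1 − f) = 1/r` gives the fraction `f` of sulfide
stopping at S⁰ and the mixed carbon yield `0.1 f + 0.5 (1 − f)`. At
`r = 2.3` the yield is 0.113 mol C (mol S)⁻¹ — predominantly incomplete
oxidation; at `r = 0.85`, predominantly complete. Ratios outside
[2/3, 2.5] are chemically impossible for this pathway and raise a typed
condition (`sulfmat_infeasible_ratio`) carrying the nearest end member —
in a living mat such an imbalance is resolved by SOB migration, which the
simulator mimics with `relocate_sob()`. The budget's AP fraction is
computed in C-fixation units by default (an electron-unit option exists).

## Isotope-labelling arithmetic

Conversions use `x = R/(1+R)`, `R = R_VPDB (δ/1000 + 1)`,
`R_VPDB = 0.0111802`. Natural-abundance baselines are always each pool's own
first time point. The bulk CO₂ assimilation flux is
`F = (dx_mat/dt) · C_areal / mean(x_DIC − x_nat)`; the mat slope is a finite
difference between interval endpoints, the DIC excess a trapezoidal mean,
and the mat's areal carbon content is a required user input (it cannot be
inferred from the series). DOC is reported only as the ¹³C/¹²C ratio
relative to the first time point, because persulfate conversion
efficiencies vary across DOC compounds and absolute quantification would be
spurious.

`fa_rur()` implements the relative uptake-rate statistic: per interval, each
fatty acid's Δδ¹³C/Δt divided by the group sum. Negative slopes are kept
with their sign; when the group sum is not positive the statistic is
*undefined* and returned as such — renormalising or censoring would
fabricate signal. Guild tables (cyanobacteria: even-numbered ω9
monounsaturated and polyunsaturated FAs; SRB: odd/branched FAs in three
response subgroups; SOB: even-numbered ω7) are shipped as fixed assignments;
the subgroup split reflects observed response patterns and is not re-derived
from data.

## The forward models

`mat_scenario()` describes a layered 1D column with Dirichlet boundary
concentrations at both ends (overlying water above; a sulfide reservoir
below, mimicking a thin mat over a feed chamber). `solve_steady_state()`
discretises `D C'' + R = 0` on a uniform grid (default 20 µm — an order
finer than the 180 µm sensor spacing, so that downsampling to "measured"
resolution via `sample_profiles()` is a separate explicit step) and solves
the sparse tridiagonal system. Substrate-limited consumption terms are
attenuated by a Monod factor `C/(C+K)` with K = 1 µmol L⁻¹ — small enough to
act as an on/off switch at the profile scale, large enough to keep the
nonlinearity smooth; the system is solved by damped Newton iteration on a
smoothed positive part, followed by one linear solve with the frozen
effective rates so that the recorded truth (effective rate field, half-cell
boundary fluxes) satisfies discrete flux conservation exactly. Observed
convergence on smooth sources is second order in the grid spacing.

`simulate_lightdark()` integrates the transient with unconditionally stable
backward Euler (default dt = 0.05 s for shift experiments; the scheme's
steady limit is exact, so long relaxations can use large steps). The Monod
attenuation is frozen at its pre-switch state to keep the operator linear
through the shift; at the instant after darkening the local `dC/dt` equals
minus the removed photosynthetic term, which is the oracle the light–dark
tests use.

`simulate_diel_sip()` generates label trajectories over a phase schedule
(dark / AP-dominated / OP-dominated, default light steps 0, 7, 19, 89, 315
µmol photons m⁻² s⁻¹): the mat atom fraction integrates the imposed fixation
flux scaled by the DIC excess (the exact inverse of `mat_cfix_flux()`), DOC
enrichment rises only under OP and decays first-order in the dark, and each
fatty acid integrates its guild's phase-specific labelling rate. Default
magnitudes are chosen to be realistic for an active phototrophic mat: DIC
label at 6 % atom fraction, areal carbon 1000 mmol C m⁻² (~12 g C m⁻²),
fixation fluxes 0.2–4 mmol C m⁻² h⁻¹ rising with light, SRB subgroup FA1
labelled only under OP and FA3 fastest under AP. All stochastic output is
seeded; truth records ride along with every generated data set.

## What the synthetic data do and do not show

The generators emulate the *structure* of real measurements: layered
concave/convex steady profiles, diffusive light–dark transients, diel label
trajectories with phase-switching guilds, Gaussian sensor noise. They do not
emulate sensor drift or calibration error, porosity gradients, advection,
photosynthesis–irradiance saturation, carbonate-system feedbacks, or
population dynamics. Passing the forward→inverse tests therefore
demonstrates that the estimators are unbiased and correctly scaled on data
satisfying the model assumptions — it does not validate those assumptions
for any particular field site. Problem sizes in the tests (≈ 185-node
grids, 16-point sampled profiles, 25-point diel series) were chosen to
mirror realistic measurement resolution.

## Numerical choices and degenerate inputs

* Interpolation between profiles is linear, never extrapolated.
* Negative sensor readings within 2× the stated sensor noise are clipped to
  zero with a warning; larger negatives are rejected outright.
* Steady-state comparisons use a symmetric relative deviation with a 1 µM
  floor (default tolerance 0.05 — the acceptance criterion for "profiles
  stopped changing" is the analyst's choice, not a physical constant).
* `fa_rur()` with a non-positive denominator and `sob_partition_from_ratio()`
  outside the feasible window return typed signals instead of clamped
  numbers.
* Fits require at least two points per zone and three per flux window;
  singular designs raise numerical-failure errors rather than returning
  NaN.

## Limitations

1D diffusion only; porosity 1; fixed-concentration boundaries (no exchange
resistance at the bottom chamber); no mechanistic SOB motility (migration is
a discrete rule); end-member stoichiometries are taken as printed constants
rather than derived from Gibbs energies. The per-measurement adjustment of
oxidation stoichiometry is driven solely by the S_tot:O₂ flux ratio; finer
adjustments using local concentrations and pH would require a thermodynamic
model outside this package's scope.
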