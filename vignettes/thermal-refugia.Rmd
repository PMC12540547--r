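---
title: "Modelling per-tree thermal refugia: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling per-tree thermal refugia: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermascape)
```

## The problem

Vegetation creates the thermal landscape that arboreal animals actually
experience: a dense crown intercepts solar radiation, damps wind, and can
keep a perched bird many degrees cooler than an exposed site a few metres
away. thermascape turns a structural map of every tree in a stand —
derived from airborne LiDAR — into a per-tree score of hyperthermia risk:
the number of summer days on which a resting bird's steady-state body
temperature T~b~ would exceed 42 °C, roughly 2 °C above the normothermic
diurnal set point of the modelled species. This vignette records the
models, the reasoning behind each default, and the limits of what the
accompanying tests demonstrate.

## Canopy structure from point clouds

**Ground surface.** Heights above ground are measured against a surface
fitted to the classified ground returns: a least-squares plane per node
of a coarse grid (2 m by default), each fitted to the ground points of
the node's 3×3 cell neighbourhood, evaluated between nodes by bilinear
interpolation. The estimator is exact for planar terrain — which is also
how it is tested, against analytic flat and sloped planes — and tracks
smooth relief with wavelengths longer than a few node spacings. Negative
normalized heights, which arise only from interpolation noise, are
clamped to zero. Degenerate inputs (fewer than three ground points, or
collinear ones) are refused with a message naming the deficiency, and
points classified as noise are dropped before any processing.

**CHM.** The canopy height model grids the maximum height of
*first-return vegetation points* per 0.5-m cell; cells without such a
return are nodata. First returns are the right population because only
the first echo of a pulse can come from the outer canopy surface; a cell
seeded only by later returns stays empty.

**Treetops.** A variable circular window scans the CHM: a cell above the
2-m inclusion threshold is a treetop if it strictly dominates every cell
within radius *r(h) = a + b·h* (defaults a = 1 m, b = 0.05, floored at
1 m). The linear rule encodes that taller trees have wider crowns; the
coefficients are configurable because no universal values exist.
Tie handling: plateaus — connected sets of equal-height cells that
jointly dominate their windows — are collapsed to the member nearest the
plateau centroid and reported once, so a flat-topped crown yields one
tree, and a perfectly flat CHM yields none (no strict maximum exists).

**Crowns.** Marker-based watershed on the inverted CHM: cells above 2 m
are processed in order of decreasing height and each attaches to the
crown of its highest already-labelled 8-neighbour, so basins grow
downhill from each apex and meet along valleys; for two equal,
symmetric, touching crowns the boundary falls on the equidistant line
(tested to within one cell). Cells unreachable from any marker stay
unlabelled, and markers whose basin contains no above-threshold cell are
dropped. The implementation is authored here because no installed
package provides a marker-based watershed; it is validated against
analytic crown footprints.

**Density ratio.** Foliage density per tree is the share of vegetation
returns in the upper canopy: with H the apex height and the upper canopy
defined as heights above H/2 inside the crown footprint,
d = N~upper~/(N~upper~ + N~lower~). Both the dividing fraction (0.5) and
an optional height-proportional weighting are configurable and recorded
in the output metadata, because published workflows describe the metric
as a *weighted* ratio without printing the weights; unit weights are the
default. The metric recovers known synthetic ratios to within ±0.05 at
500+ returns per crown (a binomial sampling bound) and is invariant in
expectation under uniform thinning.

**Categories.** Trees map into 100 canopy height × density categories:
height bins 2–3, 3–4, 4–6, 6–8, 8–10, 10–12, 12–14, 14–16, 16–18,
18–20 m crossed with density bins of width 0.1. Bins are half-open
[lo, hi) with the last bin closed, so every legal value lands in exactly
one category; heights at or below 2 m or above 20 m are outside the
modelled range and are errors at the categorisation step (the
segmentation wrapper leaves such trees uncategorised rather than
failing).

## Perch microclimate

The paper-scale canopy models whose outputs this stage reproduces are
large packages in their own right; thermascape implements a transparent
surrogate with the same inputs (air temperature, humidity, wind,
shortwave; canopy height and density) and outputs (perch-level air
temperature, transmitted shortwave, wind, radiant temperatures), with
every coefficient exposed in `microclimate_params()`:

* **PAI bridge.** pai = pai_max · density, with pai_max = 4 m² m⁻² (a
  dense savanna canopy). Monotone and linear for want of a calibration;
  anything steeper only strengthens the density contrasts.
* **Shortwave.** Beer–Lambert extinction, k_ext = 0.5 (spherical
  leaf-angle distribution), through the PAI above the perch. The perch
  sits at mid-canopy (perch_fraction = 0.5), matching the use of
  mid-canopy height as a model input; foliage is vertically uniform by
  default (a top-weighted profile is selectable).
* **Air temperature.** The within-canopy offset is scaled by canopy
  cover (1 − τ), where τ is whole-canopy transmittance: by day
  `(1 − τ)·(c_heat·S_perch/1000 − c_shade·max(Tair − 25, 0))` with
  c_heat = 2 °C per kW m⁻² and c_shade = 0.3, clamped to ±5 °C; by night
  `(1 − τ)·c_night` with c_night = 0.5 °C (longwave trapping). Scaling
  the whole offset by cover makes the open-site limit exact — a
  zero-density canopy reproduces the forcing identically, which the
  module's convergence property requires; an earlier formulation that
  applied the radiative warming term unscaled violated that limit and
  was rejected.
* **Wind.** Exponential decay with overlying PAI (a_w = 0.4), floored at
  0.3 m s⁻¹ (canopies are never perfectly still) and capped at the
  above-canopy speed.
* **Radiant environment.** Ground-surface temperature follows the
  shortwave transmitted through the full canopy
  (c_soil = 15 °C per kW m⁻²); sky radiant temperature is a fixed
  clear-sky offset of −20 °C from air temperature, because the forcing
  series carries no longwave. Humidity passes through unchanged —
  within-canopy humidity variation is deliberately out of scope.

These choices give the monotonicities the science demands and the tests
assert: transmitted light, operative temperature and body temperature
all decrease with density, and all canopy deltas vanish as density → 0.
Published below-canopy temperature models report mean absolute errors
around 2.8 °C; the surrogate makes no stronger accuracy claim, and no
test asserts absolute microclimate accuracy — only limits, bounds and
orderings.

## Heat budgets

**Convection.** Ranz–Marshall sphere correlation
Nu = 2 + 0.6·Re^0.5^·Pr^1/3^, h = Nu·k_air/d, with mild temperature
dependence of air properties. Still air gives the conduction limit
Nu = 2.

**Black bulb.** The 60-mm matt-black sphere (absorptance and emissivity
0.95) is solved for the root of
αS·A~proj~ + εσA(½T~sky~⁴ + ½T~gnd~⁴) − εσA·T~e~⁴ − hA(T~e~ − T~air~) = 0,
temperatures in kelvin inside radiation terms, view factors to sky and
ground both 0.5, no reflected-shortwave term by default. Bracketed root
finding on [T~air~ − 60, T~air~ + 80] °C to a flux residual below
10⁻³ W; forcing with no root in that bracket is refused as
non-physical. In an isothermal radiation-free cavity the solution is
the air temperature to 10⁻⁴ °C, and the solver agrees with a 0.01-°C
brute-force scan to better than 0.02 °C. The modelled bulb core
conductivity (0.025 W m⁻¹ °C⁻¹, essentially air) does not enter the
steady-state balance of a body with no internal generation, so it is
carried as metadata on the output.

**Endotherm.** The bird is a prolate ellipsoid (axis ratio per species)
of volume mass/density; heat leaves the core through a plumage layer of
conductance G = k~plume~·A~skin~/depth, then by thermal radiation and
convection from the feathered surface, which also absorbs solar and
longwave radiation. Because the surface balance determines the surface
temperature for a given T~b~ independently of metabolism and
evaporation, the budget reduces to M − E = G·(T~b~ − T~s~(T~b~)), and
the solver cascades through the physiological stages: (1) at
normothermic T~b~ and baseline evaporation, metabolism adjusts — if the
required M is at least basal, the bird is below or in thermoneutrality
and the state is returned; (2) otherwise M pins at basal and T~b~ rises
by bisection toward the 46 °C cap (0.005 °C tolerance; the plumage path
is re-evaluated at every step); (3) at the cap, evaporation rises to
close the budget up to the species ceiling; (4) beyond the ceiling the
state is returned saturated with its nonzero residual — the
lethal-exceedance regime. Every non-saturated state closes its balance
to well under 10⁻³ W, T~b~ is continuous and monotone in each radiative
driver, and halving the bisection tolerance moves T~b~ by far less than
0.02 °C. Letting T~b~ rise before ramping evaporation follows the
facultative-hyperthermia reading of resting birds in heat: moderate
hyperthermia is a water-saving strategy, so the exposure metric —
*days on which T~b~ exceeds 42 °C* — is reached before the evaporative
ceiling matters. A respiratory/cutaneous split is deliberately not
modelled: the exposure metric needs T~b~ only. There is no transient
thermal-inertia model, no torpor branch, and no postural or
feather-erection behaviour.

**Species files.** Two YAML parameter sets ship with the package, a
~40-g bulbul (normothermic T~b~ 40.4 °C) and a ~200-g hornbill
(39.9 °C). Their morphometrics are synthetic placeholders in the
realistic range for each species and are labelled as such in the files.
Where the two differ, the differences encode real comparative
physiology rather than tuning: the bulbul is a dark passerine (solar
absorptance 0.85 vs 0.70 for the pale hornbill) whose basal metabolism
follows the passerine-level allometry default 0.029·m^0.72^ W; the
hornbill's basal rate is set explicitly below that allometry
(non-passerines run cooler metabolically) and its *effective* plumage
conductivity is raised to fold in dry heat loss through the bare bill
and facial skin, a documented radiator in hornbills. With these
defaults the 40-g species is the more heat-exposed across the whole
category grid — the asymmetry the exposure tests track. T~b,max~ is
46 °C for both: above the 42 °C reporting threshold, below avian lethal
limits, configurable.

**Dehydration.** Time to lethal dehydration is the time for cumulative
evaporative water loss to reach 15 % of body mass: fraction·mass/rate
for a constant rate, or a step-wise integral over an operative
temperature series. One watt of evaporative cooling costs ≈ 1.5 g of
water per hour (latent heat 2.406 kJ g⁻¹).

## Exposure accounting

Exposure runs once per *occupied* canopy category — represented by its
bin-midpoint height and density — over every hour of the austral summer
(October–March), and the daily-maximum T~b~ series is broadcast to the
category's member trees; the tests verify this broadcast is identical
to solving per tree. Days count as exposure when the daily maximum
*strictly* exceeds the threshold ("T~b~ > 42 °C"), so counts are
monotone non-increasing in the threshold. When the forcing spans
several summers, per-summer counts are averaged (units: d summer⁻¹);
both reductions — average and pooled — are recoverable from the daily
series. Landscape summaries report the tree fractions in the exposure
classes ≤ 10, 11–70 and > 70 d summer⁻¹ (boundaries configurable) and a
histogram of seasonal maximum T~b~ in 0.5-°C bins, expressed as numbers
of trees. Exposure maps paint each crown's cells with its tree's value
on the CHM grid, background nodata; identical inputs give bit-identical
rasters. Climate scenarios are twelve additive monthly air-temperature
deltas plus a multiplicative humidity scaling clamped to [0, 100] %
(multiplicative so that scaling can never produce unphysical humidity);
the shipped end-century default is +4.3 °C in all months, a
high-emissions end-of-century magnitude for interior southern Africa.

## Validation statistics

The harness compares predicted and observed daily-maximum series two
ways: a two-sample Kolmogorov–Smirnov test — D as the supremum ECDF
distance evaluated at the pooled support, p from the asymptotic
two-sample distribution with the effective-sample-size refinement,
appropriate at season length (~180 days) and cross-checked against the
reference implementation — and per-interval day counts in 2-°C bins
anchored at even Celsius values (the anchoring is a convention; nothing
downstream depends on it), reported as predicted-minus-observed errors
with their mean and SD. No ties/discreteness correction is applied to
D; both ECDFs are simply evaluated at the pooled support.

## The synthetic-data module

The generators define the conditions under which everything above is
tested, so their defaults are fixed and documented rather than tuned:

* **Stands.** Tree heights follow a mixture over the classes 2–3, 3–4,
  4–6, 6–8, 8–16, 16–20 m with weights 0.372, 0.282, 0.21, 0.089,
  0.045, 0.002 — a savanna dominated by 2–6-m trees with very few
  emergents — and density ratios a clamped normal (mean 0.58, sd 0.12)
  putting most trees in 0.5–0.7. Crowns are paraboloids of revolution
  (concave-down profiles give realistic CHM apexes for local-maxima
  detection); crown radius grows linearly with height with jitter,
  clamped to 0.6–3.5 m, and is exposed as a free parameter because no
  empirical radius law is assumed. Crown returns are sampled so the
  fraction above half the apex height is Bernoulli with the tree's true
  density ratio — making density recovery a binomial oracle — with
  roughly 40 % of returns on the crown surface as first returns, plus a
  guaranteed first return at the apex (the treetop reflects the pulse),
  so no return ever exceeds the true height and the CHM recovers apexes
  at cell precision. Terrain is a plane by default, with optional
  low-frequency sinusoidal relief to exercise height normalization.
  Apex placement is dart throwing under a minimum-spacing constraint,
  with an explicit infeasible-packing error.
* **Weather.** Daily minima/maxima follow a seasonal climatology
  (January means 32.6/20.6 °C, winter means 25.9/5.6 °C — a mesic
  lowveld savanna) plus AR(1) day-to-day anomalies with coefficient 0.5
  and innovation SDs 1.5/1.2 °C: heatwaves persist over several days,
  which is what exposure-day statistics are sensitive to. Within each
  day, air temperature is a sinusoid (min 03:00, max 15:00), solar is a
  half-sine over a seasonally varying day length, humidity is in
  anti-phase with temperature, and all series are deterministic under a
  fixed seed.
* **Bulb pseudo-observations.** The true series is linearly resampled
  to the logger interval (20 min) and iid Gaussian sensor noise is
  added. One caution, discovered with the Monte-Carlo oracle and frozen
  into the tests: because daily *maxima* are order statistics, iid
  per-sample noise of SD 0.5 °C inflates them by ~0.55 °C (the max of
  ~7 near-peak draws), a shift the KS test detects in about half of
  replicates at n = 90; at SD ≤ 0.25 °C the distributions are
  indistinguishable in essentially every replicate. Validation studies
  using noisy loggers should expect this artefact.

What the synthetic stands do **not** emulate: return-intensity physics
and waveform effects, occlusion (lower-crown returns are sampled
regardless of canopy above), irregular or wind-thrown crown shapes,
understorey vegetation below 2 m, flight-line geometry and strip
misalignment, and classification error (clouds arrive pre-classified).
Passing tests therefore demonstrate algorithmic correctness under known
geometry — exact tree counts at non-overlapping spacing, ±0.05 density
recovery, monotone physics — not sensor-level robustness on real
acquisitions, where crown overlap and occlusion will erode recall and
bias density estimates in ways these tests do not measure.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script use stand sizes of 1–200
trees (200 for the exact-recovery check, at ~10⁵ returns), 500–1000
random environments for the solver batteries, and landscape exposure
runs of ~60 trees over 29–45 mid-summer days — sizes chosen so the full
suite completes in well under a minute per file while every property is
exercised at meaningful sample size; the per-summer units make results
comparable across window lengths. Rasters use the upper-left-origin,
row-major convention with half-open cells; all radiation arithmetic is
in kelvin, all interfaces in °C; all root finding is bracketed (no
Newton steps), with tolerances stated above. Generators restore the
caller's RNG state, so seeded pipelines compose without clobbering the
session stream.

## Known limitations

The microclimate stage is a coefficient-level surrogate, not a
turbulence-resolving canopy model; humidity never varies within the
canopy although high humidity genuinely raises hyperthermia risk; the
endotherm is steady-state, so short thermal transients and heat storage
are invisible; species morphometrics are placeholders pending measured
values; and end-century forcing is a uniform monthly delta rather than
a downscaled projection, so any change in variability — arguably where
heatwaves live — is not represented. Exposure maps inherit every
segmentation error: an undersegmented thicket becomes one large
"crown" with a blended density.
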