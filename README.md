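# thermascape

Maps **thermal refugia for birds at the scale of individual tree canopies**
in savanna landscapes. Given an airborne-LiDAR point cloud and hourly
above-canopy weather, the package scores every tree taller than 2 m by the
number of summer days on which a resting bird perched inside its canopy is
predicted to exceed the hyperthermia threshold, body temperature
T<sub>b</sub> > 42 °C, under current and perturbed (end-century) climate.
It is aimed at thermal ecologists and protected-area managers who want to
turn vegetation-structure maps into species-specific exposure maps.

## What it computes

The pipeline has five stages, each usable on its own:

1. **Canopy structure.** Point heights are normalized against a fitted
   ground surface, first returns are gridded into a 0.5-m canopy height
   model (CHM), treetops are found as variable-window local maxima
   (window radius *r(h) = a + b·h*), crowns are delineated by
   marker-based watershed on the inverted CHM, and each tree gets a
   **canopy density ratio** — the share of its returns in the upper half
   of the crown, *d = N<sub>upper</sub> / (N<sub>upper</sub> +
   N<sub>lower</sub>)* ∈ [0, 1]. Trees are binned into 100 canopy
   height × density categories (10 height bins from 2–3 m to 18–20 m × 10
   density bins of width 0.1).

2. **Perch microclimate.** The density ratio maps linearly onto a plant
   area index (PAI); shortwave reaching a mid-canopy perch follows
   Beer–Lambert extinction, *S = S₀·exp(−k·PAI<sub>above</sub>)*; the
   within-canopy air-temperature offset scales with canopy cover
   (warming by absorbed radiation, shade cooling when the air is hot,
   slight nocturnal longwave trapping); wind decays exponentially with
   overlying foliage.

3. **Black-bulb operative temperature.** A 60-mm matt-black sphere
   (core conductivity 0.025 W m⁻¹ °C⁻¹) is solved for its steady-state
   equilibrium: *αS·A<sub>p</sub> + εσA(½T<sub>sky</sub>⁴ +
   ½T<sub>gnd</sub>⁴) = εσA·T<sub>e</sub>⁴ + hA(T<sub>e</sub> −
   T<sub>air</sub>)*, with Ranz–Marshall sphere convection.

4. **Endotherm heat budget.** A bird is a prolate ellipsoid with a
   plumage conductance layer. The solver mirrors avian thermoregulation
   in stages: defend normothermic T<sub>b</sub> by raising metabolism;
   under heat stress hold metabolism at basal and let T<sub>b</sub> rise
   toward a 46 °C cap; then spend evaporative water up to a physiological
   ceiling; beyond that the state is flagged as a lethal exceedance.
   Shipped parameter files describe a ~40-g bulbul and a ~200-g hornbill.

5. **Exposure accounting.** The models run once per occupied canopy
   category per hour over the austral summer (October–March), daily
   maximum T<sub>b</sub> is reduced to exposure days (strictly > 42 °C),
   broadcast to member trees, summarized into landscape fractions and
   0.5-°C maximum-T<sub>b</sub> histograms, and painted onto the crown
   grid as exposure maps. A climate scenario is twelve monthly air
   temperature deltas plus a humidity scaling.

A seeded **synthetic-data module** generates classified savanna point
clouds with per-tree ground truth, diurnal weather series, scenario
perturbations and noisy pseudo-observed black-bulb records, so every
stage is testable without field data. A **validation module** implements
the two-sample Kolmogorov–Smirnov comparison of daily-maximum
distributions and per-2-°C day-count error summaries.

## Worked example

```r
library(thermascape)

# 1. a synthetic savanna stand with known ground truth
spec <- stand_spec(extent_m = c(80, 80), n_trees = 12, seed = 7,
                   min_tree_spacing_m = 9, crown_point_density_per_m3 = 60)
stand <- generate_stand(spec)
seg <- segment_trees(stand$cloud, resolution_m = 0.5)
seg$crowns[1:4, c("tree_id", "apex_height_m", "crown_area_m2",
                  "density_ratio", "height_label", "density_label")]
#>   tree_id apex_height_m crown_area_m2 density_ratio height_label density_label
#> 1       1     12.016030         22.25     0.6265831       12-14m       0.6-0.7
#> 2       2      8.790148         14.25     0.5416113        8-10m       0.5-0.6
#> 3       3      6.461827          7.00     0.6127301         6-8m       0.6-0.7
#> 4       4      6.353214          9.50     0.7409887         6-8m       0.7-0.8

# 2. hourly January forcing, one canopy class, hottest hour
w <- generate_weather(n_days = 31, month_start = 1, seed = 3)
cls <- canopy_class(canopy_height_m = 5, density_ratio = 0.65)
mc <- within_canopy_air(w, cls)
hot <- which.max(w$Tair_C)

# 3. black-bulb operative temperature at that hour
solve_operative_temperature(mc[hot, , drop = FALSE])[1]
#> [1] 35.23849

# 4. body temperature of a resting 40-g bulbul at that hour
bulbul <- default_species("bulbul")
solve_endotherm(mc[hot, , drop = FALSE], bulbul)
#> <thermo_state> Tb 42.17 degC, Te 34.73 degC, M 0.413 W, E 0.150 W

# 5. exposure days per tree, current vs +4.3 degC end-century climate
cur <- thermal_exposure(seg$crowns, w, bulbul)
fut <- thermal_exposure(seg$crowns, w, bulbul,
                        scenario = default_endcentury_scenario())
summarize_landscape(cur, fut)
#> <landscape_summary> 12 trees, Tb threshold 42 degC
#> exposure classes (current):
#>    class n_trees   fraction
#>   <=10 d      11 0.91666667
#>  11-70 d       1 0.08333333
#>    >70 d       0 0.00000000
#> scenario: mean +24.9 exposure days, mean +3.07 degC max Tb
```

Reading the output: segmentation recovered the planted trees with their
heights, crown areas and density ratios; at the hottest January hour a
black bulb in a density-0.65 canopy reads 35.2 °C while the bulbul —
whose heat budget includes metabolic heat and plumage insulation — is
already hyperthermic at T<sub>b</sub> 42.2 °C with metabolism pinned at
basal (0.41 W). Over the month, 11 of 12 canopies keep the bird above
42 °C on at most 10 days; a +4.3 °C end-century perturbation adds on
average ~25 exposure days and ~3.1 °C to the seasonal maximum
T<sub>b</sub>.

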