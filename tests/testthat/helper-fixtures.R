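# Shared fixtures: hand-built microclimates, random environments, analytic
# CHM surfaces and a brute-force operative-temperature oracle.

make_env <- function(Tair = 30, S = 0, wind = 1, Tsky = Tair - 20,
                     Tgnd = Tair, perch = 2) {
  data.frame(Tair_canopy_C = Tair, solar_canopy_Wm2 = S, RH_pct = 50,
             wind_canopy_ms = wind, T_sky_C = Tsky, T_ground_C = Tgnd,
             perch_height_m = perch)
}

rand_envs <- function(n, seed) {
  set.seed(seed)
  tair <- runif(n, 10, 45)
  data.frame(
    Tair_canopy_C = tair,
    solar_Wm2 = NA,  # unused
    solar_canopy_Wm2 = runif(n, 0, 1100),
    RH_pct = runif(n, 10, 90),
    wind_canopy_ms = runif(n, 0.1, 8),
    T_sky_C = tair - runif(n, 5, 30),
    T_ground_C = tair + runif(n, -2, 25),
    perch_height_m = 2
  )
}

# Independent oracle: scan candidate Te on a fine grid and return the value
# with the smallest absolute energy-balance residual for a black bulb.
brute_force_te <- function(env, bulb = black_bulb_params(), step = 0.01) {
  tair <- env$Tair_canopy_C
  te <- seq(tair - 60, tair + 80, by = step)
  r <- bulb$diameter_m / 2
  a_tot <- 4 * pi * r^2
  a_proj <- pi * r^2
  h <- convective_coefficient(bulb$diameter_m, env$wind_canopy_ms, tair)
  sb <- 5.670374419e-8
  q_in <- bulb$shortwave_absorptance * env$solar_canopy_Wm2 * a_proj +
    bulb$emissivity * sb * a_tot *
      (0.5 * (env$T_sky_C + 273.15)^4 + 0.5 * (env$T_ground_C + 273.15)^4)
  resid <- q_in - bulb$emissivity * sb * a_tot * (te + 273.15)^4 -
    h * a_tot * (te - tair)
  te[which.min(abs(resid))]
}

# Ideal CHM of one paraboloid crown: surface z(d) = h (1 - (d/r)^2) sampled
# at cell centres, NA outside the crown footprint.
chm_paraboloid <- function(h, r, res = 0.5, pad_m = 3, apex = NULL,
                           extent = NULL) {
  ext <- extent %||% rep(2 * (r + pad_m), 2)
  # default apex on a cell centre so the maximum is a unique cell
  apex <- apex %||% ((floor(ext / (2 * res)) + 0.5) * res)
  ncol <- ceiling(ext[1] / res); nrow <- ceiling(ext[2] / res)
  ras <- canopy_raster(matrix(NA_real_, nrow, ncol), res,
                       origin = c(0, nrow * res), layer = "chm")
  xs <- res * (seq_len(ncol) - 0.5)
  ys <- nrow * res - res * (seq_len(nrow) - 0.5)
  d2 <- outer(ys, xs, function(y, x) (x - apex[1])^2 + (y - apex[2])^2)
  v <- h * (1 - d2 / r^2)
  v[d2 > r^2] <- NA_real_
  ras$values <- v
  ras
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weather series with fixed daily extremes and no noise.
flat_weather <- function(n_days, tmax, tmin, month_start = 1, seed = 1) {
  p <- weather_params(tmax_annual_mean = tmax, tmax_annual_amp = 0,
                      tmin_annual_mean = tmin, tmin_annual_amp = 0,
                      noise_sd_max = 0, noise_sd_min = 0)
  generate_weather(n_days, month_start = month_start, params = p, seed = seed)
}

# A small stand whose trees are far enough apart for exact recovery.
# Heights start at 2.2 m, bounded away from the 2-m inclusion threshold:
# a tree of height 2.00x m is ambiguous at the noise level of the fitted
# ground surface, which is a property of the threshold, not the detector.
separated_stand <- function(n_trees, seed, extent = NULL,
                            crown_r = 1.2, point_density = 60) {
  extent <- extent %||% rep(ceiling(sqrt(n_trees) * 8) + 14, 2)
  stand_spec(
    extent_m = extent, n_trees = n_trees,
    height_law = list(breaks = c(2.2, 3, 4, 6, 8, 16, 20),
                      weights = c(0.372, 0.282, 0.21, 0.089, 0.045, 0.002)),
    crown_radius_law = list(a = crown_r, b = 0, sd = 0),
    min_tree_spacing_m = 2 * crown_r + 4,
    crown_point_density_per_m3 = point_density,
    seed = seed
  )
}

# Minimal hand-built crown set: one crown covering `cells` of a grid.
manual_crown_set <- function(apex_height, labels, res = 0.5,
                             origin = c(0, nrow(labels) * res)) {
  apex_cell <- which(labels == 1L, arr.ind = TRUE)[1, ]
  structure(
    data.frame(tree_id = 1L, apex_row = apex_cell[1], apex_col = apex_cell[2],
               apex_x = origin[1] + res * (apex_cell[2] - 0.5),
               apex_y = origin[2] - res * (apex_cell[1] - 0.5),
               apex_height_m = apex_height,
               n_cells = sum(labels == 1L),
               crown_area_m2 = sum(labels == 1L) * res^2,
               density_ratio = NA_real_, height_bin = NA_integer_,
               density_bin = NA_integer_, height_label = NA_character_,
               density_label = NA_character_),
    labels = labels,
    geometry = list(resolution = res, origin = origin),
    class = c("crown_set", "data.frame")
  )
}

# Exposure records built by hand (for summary/rendering arithmetic).
manual_records <- function(tree_id, n_days, max_tb, threshold = 42) {
  structure(
    data.frame(tree_id = tree_id, height_bin = 1L, density_bin = 1L,
               height_label = "2-3m", density_label = "0.0-0.1",
               n_days_above_threshold = n_days, max_Tb_C = max_tb,
               season_label = "2021", species = "test", scenario = "current"),
    threshold_C = threshold,
    class = c("exposure_records", "data.frame")
  )
}
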