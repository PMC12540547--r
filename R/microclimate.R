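#' Canopy class at which a perch microclimate is evaluated
#'
#' A canopy height x density combination plus the perch position. The
#' density ratio is converted to a total plant area index (PAI) with the
#' linear map [density_to_pai()]; the perch defaults to mid-canopy, and
#' foliage is assumed vertically uniform, so the PAI above the perch is
#' `pai_total * (1 - perch_fraction)` (a top-weighted profile is also
#' available).
#'
#' @param canopy_height_m canopy height (m, > 0). A height of 0 with
#'   density 0 describes open ground.
#' @param density_ratio canopy density ratio in `[0, 1]`.
#' @param pai_max PAI of a density-1 canopy (m2 m-2).
#' @param perch_fraction perch height as a fraction of canopy height,
#'   in `(0, 1]`.
#' @param foliage_profile `"uniform"` (default) or `"top_weighted"`
#'   (two-thirds of the foliage in the upper half of the crown).
#' @return List of class `canopy_class` with the derived `pai_total` and
#'   `pai_above_perch`.
#' @export
canopy_class <- function(canopy_height_m, density_ratio, pai_max = 4,
                         perch_fraction = 0.5,
                         foliage_profile = c("uniform", "top_weighted")) {
  stopifnot_scalar_number(canopy_height_m, "canopy_height_m", lo = 0)
  stopifnot_scalar_number(perch_fraction, "perch_fraction", lo = 1e-6, hi = 1)
  foliage_profile <- match.arg(foliage_profile)
  pai <- density_to_pai(density_ratio, pai_max)
  above_frac <- if (foliage_profile == "uniform") {
    1 - perch_fraction
  } else {
    # top-weighted: F(z) below height-fraction z holds z^2 of the foliage
    1 - perch_fraction^2
  }
  structure(list(
    canopy_height_m = canopy_height_m,
    density_ratio = density_ratio,
    pai_total = pai,
    perch_fraction = perch_fraction,
    foliage_profile = foliage_profile,
    pai_above_perch = pai * above_frac,
    perch_height_m = canopy_height_m * perch_fraction
  ), class = "canopy_class")
}

#' Map a canopy density ratio to plant area index
#'
#' Monotone linear bridge between the dimensionless LiDAR density ratio
#' and a physical PAI: `pai = pai_max * density`. `pai_max` defaults to
#' 4 m2 m-2, a dense savanna canopy.
#'
#' @param density_ratio density ratio in `[0, 1]` (vectorized).
#' @param pai_max PAI at density 1 (m2 m-2).
#' @return PAI in m2 m-2.
#' @export
density_to_pai <- function(density_ratio, pai_max = 4) {
  if (any(!is.finite(density_ratio)) ||
      any(density_ratio < 0 | density_ratio > 1)) {
    stop("density ratio must be in [0, 1]")
  }
  pai_max * density_ratio
}

#' Beer-Lambert shortwave transmission through foliage
#'
#' `S_transmitted = S * exp(-k_ext * pai_above)`; with no foliage above
#' the perch the incident flux passes unchanged.
#'
#' @param solar_Wm2 incident shortwave above the canopy (W m-2, >= 0).
#' @param pai_above plant area index above the receiving level (m2 m-2).
#' @param k_ext extinction coefficient (default 0.5, spherical leaf-angle
#'   distribution).
#' @return Transmitted shortwave (W m-2).
#' @export
transmitted_shortwave <- function(solar_Wm2, pai_above, k_ext = 0.5) {
  if (any(solar_Wm2 < 0) || any(pai_above < 0) || k_ext < 0) {
    stop("solar, PAI and k_ext must be nonnegative")
  }
  solar_Wm2 * exp(-k_ext * pai_above)
}

#' Coefficients of the within-canopy microclimate surrogate
#'
#' All tunables of [within_canopy_air()]; see the methods vignette for the
#' reasoning behind each default.
#'
#' @param k_ext shortwave extinction coefficient (per unit PAI).
#' @param c_heat daytime canopy-air warming per kW m-2 of shortwave
#'   reaching the perch (degC).
#' @param c_shade daytime shade cooling per degC of air temperature excess
#'   over `t_ref_shade` (dimensionless).
#' @param t_ref_shade reference air temperature above which shading cools
#'   the canopy air (degC).
#' @param cap_C maximum magnitude of the within-canopy air temperature
#'   offset (degC).
#' @param c_night nighttime longwave-trapping warming of a fully closed
#'   canopy (degC).
#' @param a_w wind attenuation coefficient (per unit PAI above the perch).
#' @param wind_floor_ms minimum within-canopy wind speed (m s-1); canopies
#'   are never perfectly still.
#' @param c_soil ground-surface warming per kW m-2 of shortwave reaching
#'   the ground (degC).
#' @param sky_offset_C clear-sky radiant temperature minus air temperature
#'   (degC, negative).
#' @return List of class `microclimate_params`.
#' @export
microclimate_params <- function(k_ext = 0.5, c_heat = 2, c_shade = 0.3,
                                t_ref_shade = 25, cap_C = 5, c_night = 0.5,
                                a_w = 0.4, wind_floor_ms = 0.3, c_soil = 15,
                                sky_offset_C = -20) {
  structure(as.list(environment()), class = "microclimate_params")
}

#' Downscale above-canopy weather to a perch microclimate
#'
#' Transforms each step of an above-canopy weather series into the
#' environment at a perch inside a canopy of the given height and density.
#' Shortwave is attenuated by Beer-Lambert extinction through the foliage
#' above the perch. The within-canopy air temperature offset is scaled by
#' canopy cover `(1 - tau_total)` (where `tau_total` is the whole-canopy
#' shortwave transmittance), so an open site reproduces the forcing
#' exactly: by day the offset is warming by absorbed radiation at the
#' perch minus shade cooling when the air is hot, bounded by `cap_C`; by
#' night a closed canopy traps longwave and stays slightly warmer. Wind
#' decays exponentially with overlying PAI (floored), ground-surface
#' temperature follows the shortwave transmitted through the full canopy,
#' the sky radiant temperature is a fixed clear-sky offset below air
#' temperature, and humidity passes through unchanged.
#'
#' @param w a `weather_series` (or any data.frame with `Tair_C`, `RH_pct`,
#'   `wind_ms`, `solar_Wm2`).
#' @param cls a [canopy_class].
#' @param params a [microclimate_params].
#' @return data.frame of class `microclimate` with one row per weather
#'   step: `Tair_canopy_C`, `solar_canopy_Wm2`, `RH_pct`, `wind_canopy_ms`,
#'   `T_sky_C`, `T_ground_C`, `perch_height_m` (plus `timestamp` when the
#'   input has one).
#' @export
within_canopy_air <- function(w, cls, params = microclimate_params()) {
  if (!inherits(cls, "canopy_class")) stop("`cls` must be a canopy_class")
  p <- params
  tau_total <- exp(-p$k_ext * cls$pai_total)
  cover <- 1 - tau_total
  s_perch <- transmitted_shortwave(w$solar_Wm2, cls$pai_above_perch, p$k_ext)
  s_ground <- transmitted_shortwave(w$solar_Wm2, cls$pai_total, p$k_ext)

  day <- w$solar_Wm2 > 0
  offset_day <- cover * (p$c_heat * s_perch / 1000 -
                           p$c_shade * pmax(w$Tair_C - p$t_ref_shade, 0))
  offset_night <- cover * p$c_night
  offset <- clamp(ifelse(day, offset_day, offset_night), -p$cap_C, p$cap_C)

  out <- data.frame(
    Tair_canopy_C = w$Tair_C + offset,
    solar_canopy_Wm2 = s_perch,
    RH_pct = w$RH_pct,
    wind_canopy_ms = pmin(w$wind_ms,
                          pmax(p$wind_floor_ms,
                               w$wind_ms * exp(-p$a_w * cls$pai_above_perch))),
    T_sky_C = w$Tair_C + p$sky_offset_C,
    T_ground_C = w$Tair_C + p$c_soil * s_ground / 1000,
    perch_height_m = cls$perch_height_m
  )
  if (!is.null(w$timestamp)) out <- cbind(timestamp = w$timestamp, out)
  class(out) <- c("microclimate", "data.frame")
  attr(out, "canopy_class") <- cls
  out
}

# Open-air microclimate (no canopy): convenience for bulb validation runs.
open_microclimate <- function(w, params = microclimate_params(),
                              reference_height_m = 2) {
  cls <- canopy_class(reference_height_m, 0)
  within_canopy_air(w, cls, params)
}
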