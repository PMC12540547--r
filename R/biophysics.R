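#' Black-bulb parameters
#'
#' A matt-black copper sphere with a central logger, the standard field
#' proxy for operative temperature. The core conductivity default of
#' 0.025 W m-1 degC-1 (close to the conductivity of air) mimics a bulb
#' whose interior behaves like the air it encloses; at steady state a
#' sphere with no internal heat generation reaches a uniform equilibrium
#' set by its surface fluxes, so the conductivity is carried as metadata
#' on solver output rather than entering the balance.
#'
#' @param diameter_m bulb diameter (m), default 60 mm.
#' @param shortwave_absorptance solar absorptance of matt black paint.
#' @param emissivity thermal emissivity.
#' @param core_conductivity_Wm1K1 conductivity of the modelled bulb core.
#' @return List of class `black_bulb_params`.
#' @export
black_bulb_params <- function(diameter_m = 0.06, shortwave_absorptance = 0.95,
                              emissivity = 0.95,
                              core_conductivity_Wm1K1 = 0.025) {
  stopifnot_scalar_number(diameter_m, "diameter_m", lo = 1e-6)
  stopifnot_scalar_number(shortwave_absorptance, "shortwave_absorptance", 0, 1)
  stopifnot_scalar_number(emissivity, "emissivity", 0, 1)
  stopifnot_scalar_number(core_conductivity_Wm1K1, "core_conductivity_Wm1K1",
                          lo = 1e-6)
  structure(as.list(environment()), class = "black_bulb_params")
}

#' Forced-convection coefficient for a sphere
#'
#' Ranz-Marshall correlation `Nu = 2 + 0.6 Re^0.5 Pr^(1/3)`, with
#' `h = Nu k_air / d`. In still air `Nu = 2`, the conduction limit.
#'
#' @param diameter_m characteristic diameter (m, > 0).
#' @param wind_ms wind speed (m s-1, >= 0), vectorized.
#' @param Tair_C air temperature (degC); air properties are evaluated with
#'   a mild temperature dependence around 20 degC.
#' @return Convective coefficient h (W m-2 K-1).
#' @export
convective_coefficient <- function(diameter_m, wind_ms, Tair_C = 20) {
  stopifnot_scalar_number(diameter_m, "diameter_m", lo = 1e-9)
  if (any(wind_ms < 0)) stop("wind speed must be >= 0")
  tk <- c_to_k(Tair_C)
  k_air <- 0.026 * (tk / 293.15)^0.86      # W m-1 K-1
  nu_air <- 1.55e-5 * (tk / 293.15)^1.75   # m2 s-1
  pr <- 0.71
  re <- wind_ms * diameter_m / nu_air
  nu <- 2 + 0.6 * sqrt(re) * pr^(1 / 3)
  nu * k_air / diameter_m
}

# One-row microclimate accessor tolerant of plain lists.
.env_field <- function(env, field) {
  v <- env[[field]]
  if (is.null(v)) stop("environment is missing field `", field, "`")
  as.numeric(v[1])
}

#' Solve the black-bulb operative temperature
#'
#' Finds the equilibrium temperature of the sphere from its steady-state
#' energy balance
#' `alpha S A_proj + eps sigma A (0.5 T_sky^4 + 0.5 T_ground^4)
#'  - eps sigma A Te^4 - h A (Te - Tair_canopy) = 0`
#' (temperatures in kelvin inside the radiation terms; view factors to sky
#' and ground both 0.5; `A_proj = pi r^2`, `A = 4 pi r^2`), by bracketed
#' root finding to an absolute flux residual below 1e-3 W. In an
#' isothermal, radiation-free environment the solution is exactly the air
#' temperature.
#'
#' @param env one step of a [within_canopy_air()] microclimate (one-row
#'   data.frame or list with `Tair_canopy_C`, `solar_canopy_Wm2`,
#'   `wind_canopy_ms`, `T_sky_C`, `T_ground_C`).
#' @param bulb a [black_bulb_params].
#' @return Operative temperature Te (degC), with the bulb parameters
#'   (including the core conductivity) attached as attribute `"params"`.
#' @export
solve_operative_temperature <- function(env, bulb = black_bulb_params()) {
  tair <- .env_field(env, "Tair_canopy_C")
  s <- .env_field(env, "solar_canopy_Wm2")
  wind <- .env_field(env, "wind_canopy_ms")
  tsky <- .env_field(env, "T_sky_C")
  tgnd <- .env_field(env, "T_ground_C")

  r <- bulb$diameter_m / 2
  a_tot <- 4 * pi * r^2
  a_proj <- pi * r^2
  h <- convective_coefficient(bulb$diameter_m, wind, tair)
  eps <- bulb$emissivity
  q_in <- bulb$shortwave_absorptance * s * a_proj +
    eps * .sigma_sb * a_tot * (0.5 * c_to_k(tsky)^4 + 0.5 * c_to_k(tgnd)^4)
  f <- function(te) {
    q_in - eps * .sigma_sb * a_tot * c_to_k(te)^4 - h * a_tot * (te - tair)
  }
  lo <- tair - 60; hi <- tair + 80
  if (f(lo) < 0 || f(hi) > 0) {
    stop("no equilibrium in [Tair-60, Tair+80]: non-physical forcing")
  }
  te <- stats::uniroot(f, c(lo, hi), tol = 1e-7)$root
  attr(te, "params") <- bulb
  te
}

#' Operative temperature over a microclimate series
#'
#' @param mc a multi-row [within_canopy_air()] result.
#' @param bulb a [black_bulb_params].
#' @return data.frame with `timestamp` (if present) and `Te_C`; bulb
#'   parameters in `attr(, "params")`.
#' @export
operative_temperature_series <- function(mc, bulb = black_bulb_params()) {
  te <- vapply(seq_len(nrow(mc)), function(i) {
    as.numeric(solve_operative_temperature(mc[i, , drop = FALSE], bulb))
  }, numeric(1))
  out <- if (!is.null(mc$timestamp)) {
    data.frame(timestamp = mc$timestamp, Te_C = te)
  } else {
    data.frame(Te_C = te)
  }
  attr(out, "params") <- bulb
  out
}

#' Species parameters for the endotherm heat budget
#'
#' Physiological and morphological traits of a modelled bird. The shipped
#' parameter files (`bulbul.yaml`, ~40 g frugivore/insectivore, and
#' `hornbill.yaml`, ~200 g) carry synthetic placeholder morphometrics in
#' the realistic range for each species; normothermic body temperatures
#' are 40.4 and 39.9 degC respectively. If `basal_met_W` is omitted it is
#' filled from the allometry `0.029 * mass_g^0.72` W.
#'
#' @param name species label.
#' @param mass_g body mass (g).
#' @param Tb_norm_C normothermic diurnal body temperature (degC).
#' @param Tb_max_C solver cap on body temperature (degC), above the
#'   hyperthermia reporting threshold and below lethal limits.
#' @param basal_met_W basal metabolic heat production (W), or `NULL` for
#'   the allometric default.
#' @param plumage_depth_m plumage layer depth (m, > 0).
#' @param plumage_conductivity_Wm1K1 effective plumage conductivity.
#' @param shortwave_absorptance plumage solar absorptance.
#' @param emissivity thermal emissivity of the plumage surface.
#' @param body_density_kgm3 body density (kg m-3).
#' @param shape_elongation prolate-ellipsoid axis ratio (long/short, >= 1).
#' @param baseline_ewl_W minimal cutaneous+respiratory evaporative heat
#'   loss (W).
#' @param max_ewl_W physiological ceiling on evaporative heat loss (W).
#' @return List of class `species_params`.
#' @export
species_params <- function(name, mass_g, Tb_norm_C, Tb_max_C = 46,
                           basal_met_W = NULL, plumage_depth_m,
                           plumage_conductivity_Wm1K1 = 0.035,
                           shortwave_absorptance = 0.8, emissivity = 0.95,
                           body_density_kgm3 = 1000, shape_elongation = 1.8,
                           baseline_ewl_W, max_ewl_W) {
  stopifnot_scalar_number(mass_g, "mass_g", lo = 1e-3)
  stopifnot_scalar_number(plumage_depth_m, "plumage_depth_m", lo = 1e-6)
  stopifnot_scalar_number(shape_elongation, "shape_elongation", lo = 1)
  if (is.null(basal_met_W)) basal_met_W <- 0.029 * mass_g^0.72
  if (Tb_norm_C >= Tb_max_C) stop("Tb_norm_C must be below Tb_max_C")
  if (baseline_ewl_W > max_ewl_W) stop("baseline EWL must not exceed max EWL")
  structure(list(
    name = name, mass_g = mass_g, Tb_norm_C = Tb_norm_C, Tb_max_C = Tb_max_C,
    basal_met_W = basal_met_W, plumage_depth_m = plumage_depth_m,
    plumage_conductivity_Wm1K1 = plumage_conductivity_Wm1K1,
    shortwave_absorptance = shortwave_absorptance, emissivity = emissivity,
    body_density_kgm3 = body_density_kgm3,
    shape_elongation = shape_elongation,
    baseline_ewl_W = baseline_ewl_W, max_ewl_W = max_ewl_W
  ), class = "species_params")
}

#' Read species parameters from a YAML file
#'
#' @param path YAML file with the fields of [species_params()]; see the
#'   shipped files under `system.file("extdata/species", package =
#'   "thermascape")`.
#' @return A `species_params` object.
#' @export
read_species_params <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(species_params, y)
}

#' @rdname read_species_params
#' @param species `"bulbul"` or `"hornbill"`.
#' @export
default_species <- function(species = c("bulbul", "hornbill")) {
  species <- match.arg(species)
  read_species_params(system.file("extdata", "species",
                                  paste0(species, ".yaml"),
                                  package = "thermascape", mustWork = TRUE))
}

# Prolate-ellipsoid surface area with semi-axes a >= b = c.
.prolate_area <- function(a, b) {
  if (a <= b * (1 + 1e-9)) return(4 * pi * b^2)
  e <- sqrt(1 - (b / a)^2)
  2 * pi * b^2 * (1 + (a / (b * e)) * asin(e))
}

# Body/plumage geometry derived from mass, density, elongation, plumage depth.
.bird_geometry <- function(sp) {
  vol <- sp$mass_g / 1000 / sp$body_density_kgm3
  e <- sp$shape_elongation
  b <- (3 * vol / (4 * pi * e))^(1 / 3)
  a <- e * b
  t <- sp$plumage_depth_m
  a_skin <- .prolate_area(a, b)
  a_out <- .prolate_area(a + t, b + t)
  list(
    a_skin = a_skin, a_out = a_out, a_proj = a_out / 4,
    # geometric-mean diameter of the feathered body for the convection law
    d_conv = 2 * ((a + t) * (b + t)^2)^(1 / 3),
    conductance_WK = sp$plumage_conductivity_Wm1K1 * a_skin / t
  )
}

# Radiative + solar heat absorbed at the plumage surface (W).
.q_absorbed <- function(env, geo, absorptance, emissivity) {
  s <- .env_field(env, "solar_canopy_Wm2")
  tsky <- .env_field(env, "T_sky_C")
  tgnd <- .env_field(env, "T_ground_C")
  absorptance * s * geo$a_proj +
    emissivity * .sigma_sb * geo$a_out *
      (0.5 * c_to_k(tsky)^4 + 0.5 * c_to_k(tgnd)^4)
}

# Plumage surface temperature for a given core Tb: the unique root of
# G (Tb - Ts) + Q_abs - eps sigma A Ts^4 - h A (Ts - Tair) = 0.
.surface_temperature <- function(tb, tair, h, geo, emissivity, q_abs) {
  f <- function(ts) {
    geo$conductance_WK * (tb - ts) + q_abs -
      emissivity * .sigma_sb * geo$a_out * c_to_k(ts)^4 -
      h * geo$a_out * (ts - tair)
  }
  lo <- min(tair, tb) - 80
  hi <- max(tair, tb) + 150
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Steady-state endotherm heat budget
#'
#' Solves the staged energy balance of a resting bird: metabolic heat
#' production `M` plus absorbed radiation must leave through thermal
#' radiation, convection and evaporation, with the core-to-surface route
#' through the plumage (`G (Tb - Ts)` with plumage conductance `G`). The
#' cascade mirrors avian thermoregulation: (1) at normothermic `Tb` with
#' baseline evaporation, compute the metabolic rate the balance requires;
#' if it is at least basal the bird is below or in thermoneutrality and
#' defends `Tb_norm`. (2) Otherwise the bird is heat stressed: hold `M`
#' at basal and let `Tb` rise (bisection) toward `Tb_max` seeking balance
#' at baseline evaporation. (3) If still unbalanced at `Tb_max`, raise
#' evaporative heat loss up to `max_ewl_W` to close the budget.
#' (4) Beyond that ceiling the state is returned saturated with a nonzero
#' flux residual (lethal-exceedance regime).
#'
#' @param env one microclimate step (see [solve_operative_temperature()]).
#' @param sp a [species_params].
#' @param tb_tol body-temperature bisection tolerance (degC).
#' @param compute_te also solve the bird-shaped operative temperature
#'   (default `TRUE`).
#' @return List of class `thermo_state`: `Tb_C`, `Te_C`, `met_W`,
#'   `evap_W`, `balance_residual_W`, `saturated`, `surface_C`.
#' @export
solve_endotherm <- function(env, sp, tb_tol = 0.005, compute_te = TRUE) {
  if (!inherits(sp, "species_params")) stop("`sp` must be species_params")
  geo <- .bird_geometry(sp)
  tair <- .env_field(env, "Tair_canopy_C")
  wind <- .env_field(env, "wind_canopy_ms")
  h <- convective_coefficient(geo$d_conv, wind, tair)
  q_abs <- .q_absorbed(env, geo, sp$shortwave_absorptance, sp$emissivity)

  ts_at <- function(tb) .surface_temperature(tb, tair, h, geo, sp$emissivity, q_abs)
  # net core-to-environment flux through the plumage at a given Tb;
  # the balance then reads M - E = q_net(Tb)
  q_net <- function(tb) geo$conductance_WK * (tb - ts_at(tb))

  target <- sp$basal_met_W - sp$baseline_ewl_W
  state <- function(tb, met, evap, residual = 0, saturated = FALSE) {
    te <- if (compute_te) {
      f <- function(te) {
        q_abs - sp$emissivity * .sigma_sb * geo$a_out * c_to_k(te)^4 -
          h * geo$a_out * (te - tair)
      }
      stats::uniroot(f, c(tair - 80, tair + 120), tol = 1e-7)$root
    } else {
      NA_real_
    }
    structure(list(Tb_C = tb, Te_C = te, met_W = met, evap_W = evap,
                   balance_residual_W = residual, saturated = saturated,
                   surface_C = ts_at(tb)),
              class = "thermo_state")
  }

  q1 <- q_net(sp$Tb_norm_C)
  if (q1 >= target) {
    # cold side / thermoneutral: metabolic rate adjusts, Tb defended
    return(state(sp$Tb_norm_C, met = q1 + sp$baseline_ewl_W,
                 evap = sp$baseline_ewl_W))
  }
  q_hi <- q_net(sp$Tb_max_C)
  if (q_hi >= target) {
    lo <- sp$Tb_norm_C; hi <- sp$Tb_max_C
    while (hi - lo > tb_tol) {
      mid <- (lo + hi) / 2
      if (q_net(mid) >= target) hi <- mid else lo <- mid
    }
    tb <- hi  # guarantees q_net(tb) >= target, residual <= G * tb_tol
    return(state(tb, met = sp$basal_met_W,
                 evap = sp$basal_met_W - q_net(tb)))
  }
  evap_req <- sp$basal_met_W - q_hi
  if (evap_req <= sp$max_ewl_W) {
    return(state(sp$Tb_max_C, met = sp$basal_met_W, evap = evap_req))
  }
  state(sp$Tb_max_C, met = sp$basal_met_W, evap = sp$max_ewl_W,
        residual = sp$basal_met_W - sp$max_ewl_W - q_hi, saturated = TRUE)
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("<thermo_state> Tb %.2f degC, Te %s degC, M %.3f W, E %.3f W%s\n",
              x$Tb_C,
              if (is.na(x$Te_C)) "NA" else sprintf("%.2f", x$Te_C),
              x$met_W, x$evap_W,
              if (x$saturated) sprintf(" [saturated, residual %.3f W]",
                                       x$balance_residual_W) else ""))
  invisible(x)
}

#' Time to lethal dehydration
#'
#' Hours until cumulative evaporative water loss reaches `fraction` of
#' body mass (default 15%, the lethal dehydration limit). With a constant
#' rate this is `fraction * mass / rate`; with an operative-temperature
#' series and a rate function of Te, the loss is integrated step by step
#' (linear within the crossing step).
#'
#' @param mass_g body mass (g).
#' @param ewl_rate_g_per_h water-loss rate: a single number (g h-1), or a
#'   function of operative temperature when `Te_C` is supplied.
#' @param Te_C optional operative temperature: a single value, or a vector
#'   sampled at `step_h` intervals for the time-varying form.
#' @param fraction lethal mass-loss fraction (default 0.15).
#' @param step_h time step of a `Te_C` series (h).
#' @return Hours to the dehydration limit (`Inf` if a finite series ends
#'   before the limit is reached).
#' @export
time_to_dehydration <- function(mass_g, ewl_rate_g_per_h, Te_C = NULL,
                                fraction = 0.15, step_h = 1) {
  stopifnot_scalar_number(mass_g, "mass_g", lo = 1e-6)
  stopifnot_scalar_number(fraction, "fraction", 0, 1)
  budget <- fraction * mass_g
  if (budget == 0) return(0)
  rate_fun <- if (is.function(ewl_rate_g_per_h)) {
    ewl_rate_g_per_h
  } else {
    function(te) ewl_rate_g_per_h
  }
  if (is.null(Te_C) || length(Te_C) == 1L) {
    rate <- rate_fun(if (is.null(Te_C)) NA_real_ else Te_C)
    if (!is.finite(rate) || rate <= 0) {
      stop("water-loss rate must be positive; no dehydration horizon")
    }
    return(budget / rate)
  }
  rates <- vapply(Te_C, rate_fun, numeric(1))
  if (any(rates <= 0)) stop("water-loss rate must be positive; no dehydration horizon")
  cum <- cumsum(rates * step_h)
  k <- which(cum >= budget)[1]
  if (is.na(k)) return(Inf)
  prev <- if (k == 1L) 0 else cum[k - 1L]
  (k - 1L) * step_h + (budget - prev) / rates[k] * 1
}

#' Convert evaporative heat loss to a water-loss rate
#'
#' Uses the latent heat of vaporization of water at body temperature
#' (2.406 kJ g-1): 1 W of evaporative cooling costs about 1.5 g of water
#' per hour.
#'
#' @param ewl_W evaporative heat loss (W).
#' @return Water loss in g h-1.
#' @export
ewl_watts_to_g_per_h <- function(ewl_W) ewl_W * 3600 / 2406
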