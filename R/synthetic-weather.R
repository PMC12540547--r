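#' Diurnal-cycle parameters for synthetic weather forcing
#'
#' Climatological defaults emulate a mesic lowveld savanna site: mean daily
#' maximum air temperature peaks at 32.6 degC in mid-January and bottoms at
#' 25.9 degC in mid-winter; daily minima range 20.6 degC (January) to
#' 5.6 degC (June). Day-to-day anomalies on the daily minima/maxima follow
#' an AR(1) process (coefficient 0.5) so hot spells persist over several
#' days, which matters for exposure-day statistics. Solar radiation follows
#' a half-sine daylight curve with seasonally varying day length; relative
#' humidity is in anti-phase with air temperature.
#'
#' @param tmax_annual_mean,tmax_annual_amp annual mean and amplitude of the
#'   daily-maximum temperature climatology (degC). With the defaults the
#'   mid-January climatological daily maximum is 32.6 degC.
#' @param tmin_annual_mean,tmin_annual_amp same for the daily minimum.
#' @param noise_sd_max,noise_sd_min innovation SD of the AR(1) anomalies on
#'   daily maxima / minima (degC).
#' @param ar1 AR(1) coefficient of the day-to-day anomalies.
#' @param solar_max_mean,solar_max_amp annual mean and amplitude of the
#'   clear-sky solar noon peak (W m-2).
#' @param daylength_mean_h,daylength_amp_h mean and seasonal amplitude of
#'   day length (h).
#' @param rh_mean,rh_amp mean relative humidity (%) and its diurnal
#'   amplitude (anti-phase with air temperature).
#' @param wind_mean,wind_amp mean wind speed (m s-1) and diurnal amplitude.
#' @param peak_doy day-of-year of the summer climatological peak
#'   (mid-January in the southern hemisphere).
#' @return A list of class `weather_params`.
#' @export
weather_params <- function(tmax_annual_mean = 29.25, tmax_annual_amp = 3.35,
                           tmin_annual_mean = 13.1, tmin_annual_amp = 7.5,
                           noise_sd_max = 1.5, noise_sd_min = 1.2, ar1 = 0.5,
                           solar_max_mean = 825, solar_max_amp = 175,
                           daylength_mean_h = 12, daylength_amp_h = 1.4,
                           rh_mean = 60, rh_amp = 25,
                           wind_mean = 2, wind_amp = 1,
                           peak_doy = 15) {
  structure(as.list(environment()), class = "weather_params")
}

# Seasonal phase: +1 at the summer peak day-of-year, -1 half a year later.
seasonal_phase <- function(doy, peak_doy) cos(2 * pi * (doy - peak_doy) / 365.25)

#' Generate an hourly above-canopy weather series
#'
#' Produces hourly air temperature, relative humidity, wind speed and
#' incoming shortwave for `n_days` starting on the first day of
#' `month_start`. Within each day air temperature is a sinusoid between the
#' day's minimum (03:00) and maximum (15:00); daily extremes are the
#' seasonal climatology plus AR(1) anomalies. Solar radiation is zero at
#' night and a half-sine between sunrise and sunset. Deterministic for a
#' fixed seed.
#'
#' @param n_days number of days (>= 1).
#' @param month_start starting calendar month (1-12); the series starts on
#'   the first day of that month.
#' @param params a [weather_params].
#' @param seed integer RNG seed.
#' @param start_year calendar year of the first day.
#' @return A data.frame of class `weather_series` with columns
#'   `timestamp` (POSIXct, UTC, hourly), `Tair_C`, `RH_pct`, `wind_ms`,
#'   `solar_Wm2`.
#' @export
generate_weather <- function(n_days, month_start = 10, params = weather_params(),
                             seed = 1L, start_year = 2021) {
  if (!is.numeric(n_days) || length(n_days) != 1L || n_days < 1) {
    stop("`n_days` must be a positive number of days")
  }
  n_days <- as.integer(n_days)
  stopifnot_scalar_number(month_start, "month_start", 1, 12)
  with_seed(seed, {
    t0 <- as.POSIXct(sprintf("%d-%02d-01 00:00:00", start_year, month_start),
                     tz = "UTC")
    days <- seq(as.Date(t0), by = "day", length.out = n_days)
    doy <- as.integer(strftime(days, "%j"))
    ph <- seasonal_phase(doy, params$peak_doy)
    tmax_clim <- params$tmax_annual_mean + params$tmax_annual_amp * ph
    tmin_clim <- params$tmin_annual_mean + params$tmin_annual_amp * ph

    ar_series <- function(n, sd, rho) {
      if (sd <= 0) return(numeric(n))
      e <- stats::rnorm(n, 0, sd)
      x <- numeric(n)
      x[1] <- e[1] / sqrt(1 - rho^2)  # stationary start
      for (i in seq_len(n)[-1]) x[i] <- rho * x[i - 1] + e[i]
      x
    }
    tmax_d <- tmax_clim + ar_series(n_days, params$noise_sd_max, params$ar1)
    tmin_d <- tmin_clim + ar_series(n_days, params$noise_sd_min, params$ar1)
    tmin_d <- pmin(tmin_d, tmax_d - 0.5)  # keep the diurnal cycle well posed

    hours <- 0:23
    day_idx <- rep(seq_len(n_days), each = 24L)
    hh <- rep(hours, n_days)
    mid <- (tmax_d[day_idx] + tmin_d[day_idx]) / 2
    amp <- (tmax_d[day_idx] - tmin_d[day_idx]) / 2
    # minimum at 03:00, maximum at 15:00
    tair <- mid + amp * sin(2 * pi * (hh - 9) / 24)

    daylen <- params$daylength_mean_h + params$daylength_amp_h * ph[day_idx]
    smax <- params$solar_max_mean + params$solar_max_amp * ph[day_idx]
    sunrise <- 12 - daylen / 2
    up <- hh > sunrise & hh < sunrise + daylen
    solar <- ifelse(up, smax * sin(pi * (hh - sunrise) / daylen), 0)
    solar <- pmax(solar, 0)

    rh <- clamp(params$rh_mean - params$rh_amp * sin(2 * pi * (hh - 9) / 24), 0, 100)
    wind <- pmax(0, params$wind_mean +
                   params$wind_amp * 0.5 * sin(2 * pi * (hh - 13) / 24))

    ts <- t0 + 3600 * (seq_along(hh) - 1L)
    w <- data.frame(timestamp = ts, Tair_C = tair, RH_pct = rh,
                    wind_ms = wind, solar_Wm2 = solar)
    class(w) <- c("weather_series", "data.frame")
    w
  })
}

#' @export
print.weather_series <- function(x, ...) {
  cat(sprintf("<weather_series> %d hourly steps, %s to %s\n", nrow(x),
              format(min(x$timestamp)), format(max(x$timestamp))))
  cat(sprintf("  Tair %.1f-%.1f degC, solar peak %.0f W m-2\n",
              min(x$Tair_C), max(x$Tair_C), max(x$solar_Wm2)))
  invisible(x)
}

#' @export
plot.weather_series <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$timestamp, x$Tair_C, type = "l", ylab = "Tair (degC)", xlab = "")
  graphics::plot(x$timestamp, x$solar_Wm2, type = "l",
                 ylab = "solar (W m-2)", xlab = "")
  invisible(x)
}

#' Climate-scenario perturbation
#'
#' Represents an end-century projection as twelve additive monthly air
#' temperature offsets plus a multiplicative humidity scaling (RH is
#' clamped to `[0, 100]` after scaling). [default_endcentury_scenario()]
#' ships a high-emissions end-of-century perturbation of +4.3 degC in all
#' months with unchanged humidity.
#'
#' @param monthly_dTair_C twelve monthly temperature deltas (degC), or a
#'   single value recycled to all months.
#' @param rh_scale multiplicative factor applied to relative humidity (> 0).
#' @param label scenario name.
#' @return A list of class `climate_scenario`.
#' @export
climate_scenario <- function(monthly_dTair_C, rh_scale = 1, label = "scenario") {
  if (length(monthly_dTair_C) == 1L) monthly_dTair_C <- rep(monthly_dTair_C, 12L)
  if (length(monthly_dTair_C) != 12L || any(!is.finite(monthly_dTair_C))) {
    stop("`monthly_dTair_C` must be 12 finite monthly offsets (or one, recycled)")
  }
  stopifnot_scalar_number(rh_scale, "rh_scale", lo = 1e-9)
  structure(list(monthly_dTair_C = as.numeric(monthly_dTair_C),
                 rh_scale = rh_scale, label = label),
            class = "climate_scenario")
}

#' @rdname climate_scenario
#' @export
default_endcentury_scenario <- function() {
  climate_scenario(4.3, rh_scale = 1, label = "end-century high emissions")
}

#' Apply a climate scenario to a weather series
#'
#' Shifts air temperature by the relevant month's delta and scales
#' (then clamps) relative humidity; solar radiation and wind are unchanged.
#'
#' @param w a [generate_weather()] series.
#' @param s a [climate_scenario].
#' @return A `weather_series` of the same length.
#' @export
apply_scenario <- function(w, s) {
  if (!inherits(s, "climate_scenario")) stop("`s` must be a climate_scenario")
  month <- as.integer(strftime(w$timestamp, "%m", tz = "UTC"))
  out <- w
  out$Tair_C <- w$Tair_C + s$monthly_dTair_C[month]
  out$RH_pct <- clamp(w$RH_pct * s$rh_scale, 0, 100)
  attr(out, "scenario") <- s$label
  out
}

#' Simulate black-bulb logger observations from a true series
#'
#' Resamples a true operative-temperature series to the logger interval by
#' linear interpolation and adds Gaussian sensor noise, producing
#' pseudo-observations for the validation harness.
#'
#' @param true_series data.frame with columns `timestamp` and a temperature
#'   column (the first non-timestamp column is used).
#' @param noise_sd Gaussian noise SD (degC, >= 0).
#' @param logger_interval_min logging interval in minutes.
#' @param seed integer RNG seed.
#' @return data.frame with `timestamp` and `Te_C` at the logger interval.
#' @export
generate_bulb_observations <- function(true_series, noise_sd = 0.5,
                                       logger_interval_min = 20, seed = 1L) {
  stopifnot_scalar_number(noise_sd, "noise_sd", lo = 0)
  tcol <- setdiff(names(true_series), "timestamp")[1]
  tt <- as.numeric(true_series$timestamp)
  out_t <- seq(tt[1], tt[length(tt)], by = logger_interval_min * 60)
  with_seed(seed, {
    z <- stats::approx(tt, true_series[[tcol]], xout = out_t)$y
    z <- z + stats::rnorm(length(z), 0, noise_sd)
    data.frame(timestamp = as.POSIXct(out_t, origin = "1970-01-01", tz = "UTC"),
               Te_C = z)
  })
}

#' Write / read a weather series as CSV with ISO-8601 timestamps
#'
#' @param w a `weather_series`.
#' @param path CSV file path.
#' @export
write_weather_csv <- function(w, path) {
  out <- w
  out$timestamp <- strftime(w$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  w$timestamp <- as.POSIXct(w$timestamp, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  class(w) <- c("weather_series", "data.frame")
  w
}
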