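#' Austral-summer season specification
#'
#' The exposure accounting window: 1 October through 31 March. Days are
#' labelled by the "summer" they belong to, named after the calendar year
#' of its October (e.g. days from 2021-10-01 to 2022-03-31 belong to
#' summer 2021).
#'
#' @param months months included in the season (default October-March).
#' @return List of class `season_spec`.
#' @export
season_spec <- function(months = c(10:12, 1:3)) {
  structure(list(months = as.integer(months)), class = "season_spec")
}

# Summer label per timestamp: year of the season's October.
summer_label <- function(timestamp) {
  m <- as.integer(strftime(timestamp, "%m", tz = "UTC"))
  y <- as.integer(strftime(timestamp, "%Y", tz = "UTC"))
  ifelse(m >= 7L, y, y - 1L)
}

# Check an hourly series is gap-free; error listing the missing hours.
check_hourly <- function(w) {
  d <- diff(as.numeric(w$timestamp))
  if (any(d != 3600)) {
    gaps <- which(d != 3600)
    miss <- unlist(lapply(gaps[seq_len(min(5L, length(gaps)))], function(i) {
      format(w$timestamp[i] + 3600 * seq_len(min(3, d[i] / 3600 - 1)),
             "%Y-%m-%d %H:00")
    }))
    stop("weather series has gaps; missing hours include: ",
         paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

#' Daily maximum body temperature for one canopy category
#'
#' Runs the microclimate surrogate and the endotherm solver over every
#' hour of a weather series for a single canopy height x density class and
#' reduces to daily maxima. This is the per-category engine: exposure for
#' each tree in the category is this series, broadcast (the 100-category
#' economy - identical by construction to solving per tree).
#'
#' @param cls a [canopy_class].
#' @param sp a [species_params].
#' @param w an hourly `weather_series` (gaps raise an error).
#' @param params a [microclimate_params].
#' @return data.frame: `date`, `summer`, `max_Tb_C`.
#' @export
run_category_season <- function(cls, sp, w, params = microclimate_params()) {
  check_hourly(w)
  mc <- within_canopy_air(w, cls, params)
  # plain-list hourly environments: much cheaper than data.frame row slices
  tb <- vapply(seq_len(nrow(mc)), function(i) {
    env <- list(Tair_canopy_C = mc$Tair_canopy_C[i],
                solar_canopy_Wm2 = mc$solar_canopy_Wm2[i],
                RH_pct = mc$RH_pct[i],
                wind_canopy_ms = mc$wind_canopy_ms[i],
                T_sky_C = mc$T_sky_C[i], T_ground_C = mc$T_ground_C[i],
                perch_height_m = mc$perch_height_m[i])
    solve_endotherm(env, sp, compute_te = FALSE)$Tb_C
  }, numeric(1))
  date <- as.Date(w$timestamp, tz = "UTC")
  mx <- tapply(tb, date, max)
  dts <- as.Date(names(mx))
  data.frame(date = dts,
             summer = summer_label(as.POSIXct(paste(dts, "12:00"), tz = "UTC")),
             max_Tb_C = as.numeric(mx))
}

#' Count hyperthermia-exposure days
#'
#' Days on which the daily maximum body temperature *strictly* exceeds the
#' threshold (default 42 degC, ~2 degC above normothermic resting Tb).
#'
#' @param daily_max numeric vector of daily maximum Tb (degC), or a
#'   [run_category_season()] data.frame.
#' @param threshold_C hyperthermia threshold (degC).
#' @return Integer day count.
#' @export
exposure_days <- function(daily_max, threshold_C = 42) {
  if (is.data.frame(daily_max)) daily_max <- daily_max$max_Tb_C
  sum(daily_max > threshold_C)
}

#' Per-tree hyperthermia exposure across a landscape
#'
#' Drives the microclimate + endotherm models once per occupied canopy
#' height x density category over the austral-summer days of the forcing
#' series, then broadcasts the category result to its member trees. Each
#' category is represented by its bin-midpoint height and density.
#' Exposure-day counts are averaged over the summers covered by the
#' forcing (units: days per summer).
#'
#' @param crowns a measured `crown_set` (see [segment_trees()]); trees
#'   without a category (outside the height range) are skipped.
#' @param w hourly `weather_series` covering at least one summer season.
#' @param sp a [species_params].
#' @param scenario optional [climate_scenario] applied to the forcing.
#' @param season a [season_spec].
#' @param params a [microclimate_params].
#' @param threshold_C hyperthermia threshold (degC).
#' @param pai_max,perch_fraction passed to [canopy_class()].
#' @return data.frame of class `exposure_records`: one row per tree with
#'   `tree_id`, bins, `n_days_above_threshold` (d per summer), `max_Tb_C`,
#'   `season_label`, `species`, `scenario`.
#' @export
thermal_exposure <- function(crowns, w, sp, scenario = NULL,
                             season = season_spec(),
                             params = microclimate_params(),
                             threshold_C = 42, pai_max = 4,
                             perch_fraction = 0.5) {
  if (!is.null(scenario)) w <- apply_scenario(w, scenario)
  m <- as.integer(strftime(w$timestamp, "%m", tz = "UTC"))
  ws <- w[m %in% season$months, , drop = FALSE]
  if (nrow(ws) == 0L) stop("forcing series does not cover the season")

  keep <- !is.na(crowns$height_bin) & !is.na(crowns$density_bin)
  trees <- as.data.frame(crowns)[keep, , drop = FALSE]
  if (nrow(trees) == 0L) stop("no categorised trees to expose")
  grid <- category_grid()
  hb <- grid$height_breaks_m; db <- grid$density_breaks
  cat_key <- paste(trees$height_bin, trees$density_bin, sep = ":")
  occupied <- unique(data.frame(height_bin = trees$height_bin,
                                density_bin = trees$density_bin))
  if (nrow(occupied) > grid$n_categories) {
    stop("more occupied categories than the grid allows")  # cannot happen
  }

  res <- vector("list", nrow(occupied))
  for (i in seq_len(nrow(occupied))) {
    hbin <- occupied$height_bin[i]; dbin <- occupied$density_bin[i]
    height_mid <- (hb[hbin] + hb[hbin + 1L]) / 2
    dens_mid <- (db[dbin] + db[dbin + 1L]) / 2
    cls <- canopy_class(height_mid, dens_mid, pai_max = pai_max,
                        perch_fraction = perch_fraction)
    # gap-check per contiguous summer block, not across the winter gap
    blocks <- split(seq_len(nrow(ws)),
                    cumsum(c(1, diff(as.numeric(ws$timestamp)) != 3600)))
    daily <- do.call(rbind, lapply(blocks, function(ix) {
      run_category_season(cls, sp, ws[ix, , drop = FALSE], params)
    }))
    per_summer <- tapply(daily$max_Tb_C, daily$summer,
                         function(x) sum(x > threshold_C))
    res[[i]] <- data.frame(
      height_bin = hbin, density_bin = dbin,
      n_days_above_threshold = mean(per_summer),
      max_Tb_C = max(daily$max_Tb_C),
      season_label = paste(sort(unique(daily$summer)), collapse = "+")
    )
  }
  percat <- do.call(rbind, res)
  idx <- match(cat_key, paste(percat$height_bin, percat$density_bin, sep = ":"))
  out <- data.frame(
    tree_id = trees$tree_id,
    height_bin = trees$height_bin, density_bin = trees$density_bin,
    height_label = trees$height_label, density_label = trees$density_label,
    n_days_above_threshold = percat$n_days_above_threshold[idx],
    max_Tb_C = percat$max_Tb_C[idx],
    season_label = percat$season_label[idx],
    species = sp$name,
    scenario = if (is.null(scenario)) "current" else scenario$label
  )
  structure(out, threshold_C = threshold_C,
            class = c("exposure_records", "data.frame"))
}

#' Summarize per-tree exposure over the landscape
#'
#' Reduces per-tree exposure records to (a) the fraction of trees in the
#' exposure classes `<= 10`, `11-70` and `> 70` days per summer, (b) a
#' histogram of seasonal maximum body temperature in 0.5-degC bins
#' (number of trees per bin), and, when a scenario run is supplied,
#' (c) tree-matched current-vs-scenario deltas.
#'
#' @param records current-climate `exposure_records`.
#' @param scenario_records optional scenario `exposure_records` for the
#'   same trees.
#' @param class_breaks upper edges of the exposure classes (days).
#' @param tb_bin_C width of the maximum-Tb histogram bins (degC).
#' @return List of class `landscape_summary` with elements `per_tree`,
#'   `exposure_classes`, `tb_histogram`, and `deltas` (or `NULL`).
#' @export
summarize_landscape <- function(records, scenario_records = NULL,
                                class_breaks = c(10, 70), tb_bin_C = 0.5) {
  class_of <- function(n) {
    cut(n, breaks = c(-Inf, class_breaks, Inf),
        labels = c(sprintf("<=%g d", class_breaks[1]),
                   sprintf("%g-%g d", class_breaks[1] + 1, class_breaks[2]),
                   sprintf(">%g d", class_breaks[2])))
  }
  tab <- function(rec) {
    cl <- class_of(rec$n_days_above_threshold)
    data.frame(class = levels(cl), n_trees = as.integer(table(cl)),
               fraction = as.numeric(table(cl)) / nrow(rec))
  }
  hist_tb <- function(rec) {
    lo <- floor(rec$max_Tb_C / tb_bin_C) * tb_bin_C
    t <- table(lo)
    data.frame(bin_lo_C = as.numeric(names(t)),
               bin_hi_C = as.numeric(names(t)) + tb_bin_C,
               n_trees = as.integer(t))
  }
  out <- list(
    per_tree = as.data.frame(records),
    exposure_classes = tab(records),
    tb_histogram = hist_tb(records),
    deltas = NULL,
    threshold_C = attr(records, "threshold_C")
  )
  if (!is.null(scenario_records)) {
    idx <- match(records$tree_id, scenario_records$tree_id)
    if (anyNA(idx)) stop("scenario records missing for some trees")
    out$deltas <- data.frame(
      tree_id = records$tree_id,
      d_days = scenario_records$n_days_above_threshold[idx] -
        records$n_days_above_threshold,
      d_max_Tb_C = scenario_records$max_Tb_C[idx] - records$max_Tb_C
    )
    out$scenario_exposure_classes <- tab(scenario_records)
    out$scenario_tb_histogram <- hist_tb(scenario_records)
  }
  structure(out, class = "landscape_summary")
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat(sprintf("<landscape_summary> %d trees, Tb threshold %g degC\n",
              nrow(x$per_tree), x$threshold_C %||% 42))
  cat("exposure classes (current):\n")
  print(x$exposure_classes, row.names = FALSE)
  if (!is.null(x$deltas)) {
    cat(sprintf("scenario: mean +%.1f exposure days, mean +%.2f degC max Tb\n",
                mean(x$deltas$d_days), mean(x$deltas$d_max_Tb_C)))
  }
  invisible(x)
}

#' Render per-tree exposure values onto the crown-label grid
#'
#' Paints every crown cell with its tree's exposure statistic (exposure
#' days by default, or seasonal maximum Tb), producing a map raster
#' aligned with the CHM; background cells are `NA`. Deterministic given
#' identical inputs.
#'
#' @param crowns the `crown_set` whose label grid to paint.
#' @param records `exposure_records` keyed by `tree_id`.
#' @param value `"n_days_above_threshold"` or `"max_Tb_C"`.
#' @return A [canopy_raster].
#' @export
render_exposure_map <- function(crowns, records,
                                value = c("n_days_above_threshold", "max_Tb_C")) {
  value <- match.arg(value)
  lab <- attr(crowns, "labels")
  geom <- attr(crowns, "geometry")
  labelled <- sort(unique(lab[lab > 0L]))
  vals <- records[[value]][match(labelled, records$tree_id)]
  missing_rec <- labelled[is.na(match(labelled, records$tree_id))]
  # trees outside the categorised range carry no record: that is an error
  # only if they are labelled in the grid we are asked to paint
  if (length(missing_rec)) {
    stop("no exposure record for labelled tree(s): ",
         paste(utils::head(missing_rec, 5), collapse = ", "))
  }
  lut <- rep(NA_real_, max(labelled))
  lut[labelled] <- vals
  v <- matrix(NA_real_, nrow(lab), ncol(lab))
  nz <- lab > 0L
  v[nz] <- lut[lab[nz]]
  canopy_raster(v, geom$resolution, geom$origin, layer = paste0("exposure_", value))
}
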