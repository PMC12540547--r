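#' Two-sample Kolmogorov-Smirnov comparison
#'
#' The validation statistic for comparing distributions of predicted and
#' observed daily maxima: `D` is the supremum distance between the two
#' empirical CDFs, evaluated at every pooled data value; the p-value uses
#' the asymptotic two-sample Kolmogorov distribution with the standard
#' effective-sample-size refinement, appropriate for season-length samples
#' (~180 days). Ties are handled by evaluating both ECDFs at the pooled
#' support (no continuity correction).
#'
#' @param a,b numeric samples (non-empty).
#' @return List of class `ks_result`: `D`, `p_value`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  support <- sort(unique(c(a, b)))
  fa <- vapply(support, function(x) mean(a <= x), numeric(1))
  fb <- vapply(support, function(x) mean(b <= x), numeric(1))
  d <- max(abs(fa - fb))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * d
  p <- if (d == 0) 1 else {
    k <- 1:100
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
  }
  structure(list(D = d, p_value = p, n_a = length(a), n_b = length(b)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.3f, p = %.3f (n = %d, %d)\n",
              x$D, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Day counts per temperature interval and their prediction errors
#'
#' Bins the daily maxima of a predicted and an observed series into
#' fixed-width temperature intervals (2 degC by default, edges anchored at
#' even Celsius values) and reports, per interval, the predicted minus
#' observed day count, together with the mean and SD of the per-interval
#' errors.
#'
#' @param pred_daily_max,obs_daily_max daily-maximum series covering the
#'   same season (equal lengths required).
#' @param bin_width_C interval width (degC).
#' @return List of class `binned_day_error`: `bin_errors` (data.frame
#'   with `bin_lo_C`, `bin_hi_C`, `n_pred`, `n_obs`, `error_d`),
#'   `mean_error_d`, `sd_error_d`.
#' @export
binned_day_error <- function(pred_daily_max, obs_daily_max, bin_width_C = 2) {
  if (length(pred_daily_max) != length(obs_daily_max)) {
    stop("predicted and observed series must cover the same days")
  }
  stopifnot_scalar_number(bin_width_C, "bin_width_C", lo = 1e-9)
  lo_all <- floor(c(pred_daily_max, obs_daily_max) / bin_width_C)
  bins <- seq(min(lo_all), max(lo_all))
  count <- function(x) {
    tabulate(match(floor(x / bin_width_C), bins), nbins = length(bins))
  }
  n_pred <- count(pred_daily_max)
  n_obs <- count(obs_daily_max)
  err <- n_pred - n_obs
  structure(list(
    bin_errors = data.frame(bin_lo_C = bins * bin_width_C,
                            bin_hi_C = (bins + 1) * bin_width_C,
                            n_pred = n_pred, n_obs = n_obs, error_d = err),
    mean_error_d = mean(err),
    sd_error_d = stats::sd(err)
  ), class = "binned_day_error")
}

#' @export
print.binned_day_error <- function(x, ...) {
  cat(sprintf("Per-interval day-count error: %.1f +/- %.1f d over %d bins\n",
              x$mean_error_d, x$sd_error_d, nrow(x$bin_errors)))
  invisible(x)
}

#' Validate predicted against observed daily-maximum series
#'
#' The combined validation harness: KS comparison of the two distributions
#' of daily maxima plus the per-2-degC day-count error summary.
#'
#' @inheritParams binned_day_error
#' @param alpha significance level for the KS decision.
#' @return List of class `validation_result` with the KS result, the
#'   binned errors, and `distributions_differ` (logical at `alpha`).
#' @export
validate_predictions <- function(pred_daily_max, obs_daily_max,
                                 bin_width_C = 2, alpha = 0.05) {
  ks <- ks_two_sample(pred_daily_max, obs_daily_max)
  be <- binned_day_error(pred_daily_max, obs_daily_max, bin_width_C)
  structure(list(ks = ks, bin_errors = be,
                 distributions_differ = ks$p_value < alpha),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  print(x$ks)
  print(x$bin_errors)
  cat(if (x$distributions_differ) {
    "distributions differ at the chosen alpha\n"
  } else {
    "no significant distributional difference\n"
  })
  invisible(x)
}

# Daily maxima of a (timestamp, value) series, by calendar date.
daily_maxima <- function(series, value_col = NULL) {
  if (is.null(value_col)) value_col <- setdiff(names(series), "timestamp")[1]
  mx <- tapply(series[[value_col]], as.Date(series$timestamp, tz = "UTC"), max)
  data.frame(date = as.Date(names(mx)), max_C = as.numeric(mx))
}
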