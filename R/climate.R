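#' Yearly climate driver series
#'
#' A `climate_series` holds one scenario's (or site's) yearly drivers: the
#' mean summer temperature and, optionally, soil moisture (constant by
#' default: projections force temperature, not moisture).
#'
#' @param id scenario or site identifier.
#' @param years strictly increasing, consecutive integer years.
#' @param T_summer mean summer temperature per year (degrees C).
#' @param moisture soil moisture per year (unit scale); recycled if scalar.
#' @return An object of class `climate_series` (a data frame with columns
#'   `year`, `T_summer_C`, `moisture` and attribute `scenario_id`).
#' @export
climate_series <- function(id, years, T_summer, moisture = 0.5) {
  years <- as.integer(years)
  if (length(years) < 1 || any(diff(years) != 1L))
    stop_input("years must be consecutive integers")
  check_finite(T_summer, "T_summer")
  if (length(T_summer) != length(years))
    stop_input("T_summer must match years in length")
  moisture <- rep_len(moisture, length(years))
  check_finite(moisture, "moisture")
  structure(data.frame(year = years, T_summer_C = as.numeric(T_summer),
                       moisture = moisture),
            scenario_id = as.character(id),
            class = c("climate_series", "data.frame"))
}

#' Constant-climate series
#'
#' Used for burn-in quasi-equilibration (for example at the 2017-2020 mean
#' summer temperature of the home site).
#'
#' @param T_ref constant mean summer temperature (degrees C).
#' @param n_years series length, >= 1.
#' @param year0 first year.
#' @param moisture constant soil moisture.
#' @param id scenario identifier.
#' @return A [climate_series()].
#' @export
constant_scenario <- function(T_ref, n_years, year0 = 2017L,
                              moisture = 0.5, id = "constant") {
  if (n_years < 1) stop_input("n_years must be >= 1")
  climate_series(id, seq(year0, length.out = n_years),
                 rep(T_ref, n_years), moisture)
}

#' Gradual warming scenario
#'
#' Builds a smooth mean warming trajectory from `T0` to `T0 + delta_end`
#' plus seeded Gaussian interannual noise. Three qualitative shapes mirror
#' the RCP families: `"plateau"` warms linearly until `plateau_year` and
#' then stabilises (RCP 2.6-like), `"linear"` warms steadily through the
#' century (RCP 4.5-like), and `"accelerating"` warms quadratically, slowly
#' at first and then rapidly (RCP 8.5-like).
#'
#' @param T0 starting mean summer temperature (degrees C).
#' @param delta_end total warming by `year_end` (K).
#' @param year0,year_end first and last year, `year_end > year0`.
#' @param shape one of `"linear"`, `"plateau"`, `"accelerating"`.
#' @param interannual_sd SD of the yearly Gaussian noise (K), >= 0.
#' @param seed RNG seed for the noise (NULL: use the current stream).
#' @param plateau_year year after which the `"plateau"` shape stays flat.
#' @param moisture constant soil moisture.
#' @param id scenario identifier.
#' @return A [climate_series()].
#' @export
gradual_scenario <- function(T0, delta_end, year0 = 2017L, year_end = 2098L,
                             shape = c("linear", "plateau", "accelerating"),
                             interannual_sd = 0, seed = NULL,
                             plateau_year = 2040L, moisture = 0.5,
                             id = NULL) {
  shape <- match.arg(shape)
  if (year_end <= year0) stop_input("year_end must be > year0")
  if (interannual_sd < 0) stop_input("interannual_sd must be >= 0")
  years <- seq(as.integer(year0), as.integer(year_end))
  frac <- (years - year0) / (year_end - year0)
  ramp <- switch(shape,
    linear = frac,
    accelerating = frac^2,
    plateau = {
      pe <- min(max(plateau_year, year0 + 1L), year_end)
      pmin((years - year0) / (pe - year0), 1)
    })
  mu <- T0 + delta_end * ramp
  noise <- with_seed(seed, stats::rnorm(length(years), 0, interannual_sd))
  climate_series(id %||% paste0("gradual_", shape, "_", delta_end, "K"),
                 years, mu + noise, moisture)
}

#' Stepwise (abrupt-change) scenario
#'
#' Emulates the stepwise climate manipulation of transplant and warming
#' experiments: from the first simulated year onwards, yearly temperatures
#' are i.i.d. Gaussian draws with the sample mean and variance of a window
#' of a source scenario (for example the 2088-2098 window of a gradual
#' run).
#'
#' @param source a [climate_series()].
#' @param window_start,window_end inclusive year window within `source`.
#' @param n_years length of the generated series.
#' @param seed RNG seed (NULL: use the current stream).
#' @param year0 first year of the output (default: first source year).
#' @param id scenario identifier.
#' @return A [climate_series()].
#' @export
stepwise_scenario <- function(source, window_start, window_end, n_years,
                              seed = NULL, year0 = NULL, id = "stepwise") {
  stopifnot(inherits(source, "climate_series"))
  sel <- source$year >= window_start & source$year <= window_end
  if (!any(sel)) stop_input("empty source window")
  x <- source$T_summer_C[sel]
  m <- mean(x)
  s <- if (length(x) > 1) stats::sd(x) else 0
  draws <- with_seed(seed, stats::rnorm(n_years, m, s))
  climate_series(id, seq(as.integer(year0 %||% source$year[1]),
                         length.out = n_years),
                 draws, source$moisture[1])
}

#' Site-versus-station climate calibration
#'
#' Ordinary least squares regression of a site's observed drivers on a
#' reference weather station's, one model per variable; used to predict
#' site conditions from the station record.
#'
#' @param site_T,station_T paired site / station temperature observations
#'   (>= 3 pairs).
#' @param site_M,station_M optional paired moisture observations.
#' @return An object of class `site_calibration` with per-variable
#'   `intercept`, `slope` and `resid_sd`.
#' @export
fit_site_calibration <- function(site_T, station_T,
                                 site_M = NULL, station_M = NULL) {
  one <- function(y, x, what) {
    if (length(y) != length(x) || length(y) < 3)
      stop_input("need >= 3 paired ", what, " observations")
    fit <- stats::lm(y ~ x)
    # noise-free pairs (identity checks) trigger a harmless perfect-fit
    # warning from summary.lm
    se <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))))
    list(intercept = unname(stats::coef(fit)[1]),
         slope = unname(stats::coef(fit)[2]),
         resid_sd = stats::sigma(fit),
         se = se)
  }
  out <- list(temperature = one(site_T, station_T, "temperature"))
  if (!is.null(site_M)) out$moisture <- one(site_M, station_M, "moisture")
  structure(out, class = "site_calibration")
}

#' Predict site conditions from a station series
#'
#' @param calibration a [fit_site_calibration()].
#' @param station a [climate_series()] observed at the station.
#' @param id identifier of the predicted series.
#' @return A [climate_series()] at the site.
#' @export
predict_site <- function(calibration, station, id = "site") {
  stopifnot(inherits(calibration, "site_calibration"),
            inherits(station, "climate_series"))
  ct <- calibration$temperature
  T_site <- ct$intercept + ct$slope * station$T_summer_C
  M <- station$moisture
  if (!is.null(calibration$moisture)) {
    cm <- calibration$moisture
    M <- cm$intercept + cm$slope * station$moisture
  }
  climate_series(id, station$year, T_site, M)
}

#' Read or write climate series CSV
#'
#' Columns: `scenario_id`, `year`, `T_summer_C`, `moisture`.
#'
#' @param path CSV path.
#' @param series a single [climate_series()] or a list of them.
#' @return `read_climate()` returns a named list of [climate_series()].
#' @export
read_climate <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(d, d$scenario_id), function(ds) {
    ds <- ds[order(ds$year), ]
    climate_series(ds$scenario_id[1], ds$year, ds$T_summer_C, ds$moisture)
  })
  out
}

#' @rdname read_climate
#' @export
write_climate <- function(series, path) {
  if (inherits(series, "climate_series")) series <- list(series)
  d <- do.call(rbind, lapply(series, function(s)
    data.frame(scenario_id = attr(s, "scenario_id"), year = s$year,
               T_summer_C = s$T_summer_C, moisture = s$moisture)))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
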