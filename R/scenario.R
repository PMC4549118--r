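## weight column names shared across modules
.wd_cols <- paste0("wd_", c("mon", "tue", "wed", "thu", "fri", "sat", "sun"))
.mw_cols <- paste0("mw_", tolower(month.abb))

#' Define a synthetic multi-site surveillance scenario
#'
#' A scenario fixes everything needed to simulate method-specific death
#' counts for several sites: per-site populations, baseline annualized
#' rates, weekday and month seasonality, a smooth secular trend on the log
#' rate, and a step intervention effect applied on and after a given date.
#' Counts are generated daily and, optionally, aggregated to weeks from a
#' cut-over date onwards (mirroring registries that release only weekly
#' aggregates in later years).
#'
#' Weekday and month multipliers are normalized at construction so their
#' log-mean is zero (geometric mean one); this keeps `base_annual_rate`
#' interpretable as the seasonally averaged rate and makes the implied
#' regression coefficients returned by [scenario_truth()] well defined.
#' The secular trend is centered so that its mean over the pre-intervention
#' days is zero, so baseline rates remain calibrated to the pre period.
#'
#' @param sites character vector of site labels.
#' @param populations population at risk per site: a named list/vector, one
#'   entry per site; each entry either a single number (constant population)
#'   or a vector named by calendar year. Populations are held constant
#'   within each calendar year.
#' @param methods character vector of method category labels.
#' @param base_annual_rate baseline events per 100,000 person-years, a
#'   `length(sites) x length(methods)` matrix (rows = sites), or a vector
#'   recycled across methods.
#' @param weekday_multipliers 7 positive reals (Monday first).
#' @param month_multipliers 12 positive reals (January first).
#' @param trend secular trend of the log rate: `NULL` (flat),
#'   `list(slope_per_year = s)` for a linear trend, or
#'   `list(n_knots = k, coef = b)` for a cubic B-spline with `k` evenly
#'   spaced interior knots (`length(b) = k + 4`). May also be a named list
#'   with one such specification per method.
#' @param intervention_date `Date` (or coercible); the step effect applies
#'   to all days on or after this date.
#' @param intervention_multiplier positive step multiplier(s): a scalar, a
#'   vector named by site, or a `sites x methods` matrix.
#' @param date_range length-2 `Date` vector, first and last day simulated.
#' @param weekly_aggregation_from `Date` or `NULL`; days on or after this
#'   date are emitted as 7-day (final block possibly shorter) aggregate
#'   records instead of daily records.
#' @param seed default integer seed used by [generate_observations()].
#'
#' @return An object of class `scenario_config`.
#' @seealso [generate_observations()], [scenario_truth()], [scenario_taiwan()]
#' @export
scenario_config <- function(sites, populations, methods, base_annual_rate,
                            weekday_multipliers = rep(1, 7),
                            month_multipliers = rep(1, 12),
                            trend = NULL,
                            intervention_date,
                            intervention_multiplier = 1,
                            date_range,
                            weekly_aggregation_from = NULL,
                            seed = NULL) {
  sites <- as.character(sites)
  methods <- as.character(methods)
  stopifnot(length(sites) >= 1, length(methods) >= 1,
            !anyDuplicated(sites), !anyDuplicated(methods))

  pops <- as.list(populations)
  if (is.null(names(pops)) && length(pops) == length(sites)) names(pops) <- sites
  if (!all(sites %in% names(pops)))
    stop("`populations` must provide an entry for every site")
  pops <- pops[sites]
  for (p in pops) {
    if (!is.numeric(p) || any(p <= 0)) stop("populations must be positive")
  }

  rate <- base_annual_rate
  if (!is.matrix(rate)) rate <- matrix(rate, nrow = length(sites), ncol = length(methods))
  if (!identical(dim(rate), c(length(sites), length(methods))))
    stop("`base_annual_rate` must be a sites x methods matrix")
  dimnames(rate) <- list(sites, methods)
  if (any(rate < 0)) stop("base rates must be nonnegative")

  if (length(weekday_multipliers) != 7 || any(weekday_multipliers <= 0))
    stop("`weekday_multipliers` must be 7 positive values (Monday first)")
  if (length(month_multipliers) != 12 || any(month_multipliers <= 0))
    stop("`month_multipliers` must be 12 positive values (January first)")
  # normalize to geometric mean one so that base rates stay interpretable
  wd <- weekday_multipliers / exp(mean(log(weekday_multipliers)))
  mw <- month_multipliers / exp(mean(log(month_multipliers)))

  imult <- intervention_multiplier
  if (!is.matrix(imult)) {
    if (length(imult) == 1L) {
      imult <- matrix(imult, length(sites), length(methods))
    } else {
      if (is.null(names(imult)) && length(imult) == length(sites)) names(imult) <- sites
      if (!all(sites %in% names(imult)))
        stop("per-site `intervention_multiplier` must be named by site")
      imult <- matrix(imult[sites], length(sites), length(methods))
    }
  }
  dimnames(imult) <- list(sites, methods)
  if (any(imult <= 0)) stop("intervention multipliers must be positive")

  date_range <- as.Date(date_range)
  if (length(date_range) != 2 || date_range[2] < date_range[1])
    stop("`date_range` must be two dates, start <= end")
  intervention_date <- as.Date(intervention_date)
  if (!is.null(weekly_aggregation_from))
    weekly_aggregation_from <- as.Date(weekly_aggregation_from)

  if (!is.null(trend) && !is.null(names(trend)) &&
      all(names(trend) %in% methods) && length(trend) && is.list(trend[[1]])) {
    trend_by_method <- lapply(methods, function(m) trend[[m]])
    names(trend_by_method) <- methods
  } else {
    trend_by_method <- stats::setNames(rep(list(trend), length(methods)), methods)
  }

  structure(list(
    sites = sites, populations = pops, methods = methods,
    base_annual_rate = rate,
    weekday_multipliers = wd, month_multipliers = mw,
    trend = trend_by_method,
    intervention_date = intervention_date,
    intervention_multiplier = imult,
    date_range = date_range,
    weekly_aggregation_from = weekly_aggregation_from,
    seed = seed
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario:", length(x$sites), "site(s) x", length(x$methods),
      "method(s), ", format(x$date_range[1]), "..", format(x$date_range[2]), "\n")
  cat("  intervention on", format(x$intervention_date), "; multipliers:\n")
  print(round(x$intervention_multiplier, 3))
  invisible(x)
}

# daily calendar covariates for a scenario
.scenario_days <- function(config) {
  dates <- seq(config$date_range[1], config$date_range[2], by = "day")
  lt <- as.POSIXlt(dates)
  data.frame(
    date = dates,
    t = as.numeric(dates - config$date_range[1]) + 0.5,  # day midpoints
    wd = ((lt$wday + 6L) %% 7L) + 1L,                    # Monday = 1
    mon = lt$mon + 1L,
    year = lt$year + 1900L,
    post = as.integer(dates >= config$intervention_date)
  )
}

# secular-trend function (log scale), centered over pre-intervention days
.trend_fun <- function(config, method) {
  spec <- config$trend[[method]]
  days <- .scenario_days(config)
  pre_t <- days$t[days$post == 0L]
  if (!length(pre_t)) pre_t <- days$t
  if (is.null(spec)) return(function(t) rep(0, length(t)))
  if (!is.null(spec$slope_per_year)) {
    s <- spec$slope_per_year / 365.25
    t0 <- mean(pre_t)
    return(function(t) s * (t - t0))
  }
  if (!is.null(spec$coef)) {
    k <- if (is.null(spec$n_knots)) 0L else as.integer(spec$n_knots)
    if (length(spec$coef) != k + 4)
      stop("B-spline trend needs n_knots + 4 coefficients")
    tmax <- max(days$t) + 0.5
    knots <- if (k > 0) seq(0, tmax, length.out = k + 2)[-c(1, k + 2)] else NULL
    base_val <- function(t) {
      B <- splines::bs(t, knots = knots, degree = 3, intercept = TRUE,
                       Boundary.knots = c(0, tmax))
      drop(B %*% spec$coef)
    }
    center <- mean(base_val(pre_t))
    return(function(t) base_val(t) - center)
  }
  stop("unrecognized trend specification")
}

# per-calendar-year population lookup, vectorized over years
.pop_for_years <- function(pop_entry, years) {
  if (length(pop_entry) == 1L && is.null(names(pop_entry)))
    return(rep(as.numeric(pop_entry), length(years)))
  nm <- as.character(years)
  if (!all(nm %in% names(pop_entry)))
    stop("population missing for year(s): ",
         paste(setdiff(unique(nm), names(pop_entry)), collapse = ", "))
  as.numeric(pop_entry[nm])
}

# expected daily event count for one site x method
.daily_means <- function(config, site, method, days = .scenario_days(config)) {
  pop <- .pop_for_years(config$populations[[site]], days$year)
  trf <- .trend_fun(config, method)
  mu <- pop / 1e5 * config$base_annual_rate[site, method] / 365.25 *
    config$weekday_multipliers[days$wd] *
    config$month_multipliers[days$mon] *
    exp(trf(days$t)) *
    ifelse(days$post == 1L, config$intervention_multiplier[site, method], 1)
  if (any(!is.finite(mu)) || any(mu < 0)) stop("invalid (negative or non-finite) mean")
  mu
}

#' Simulate an observation table from a scenario
#'
#' Draws independent Poisson daily counts for every site x method x day with
#' the scenario's mean structure, then aggregates days on/after
#' `weekly_aggregation_from` into 7-day records. Aggregation boundaries are
#' also cut at the intervention date, so no record ever straddles it.
#' Weekly records carry fractional weekday and month weights (the fraction
#' of the record's days falling on each weekday / in each month) and a
#' person-day-weighted population.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed; defaults to the one stored in `config`.
#' @return An `obs_table` data frame (see [as_obs_table()] for the schema),
#'   with the scenario's study start and intervention date attached as
#'   attributes.
#' @export
generate_observations <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  days <- .scenario_days(config)
  out <- vector("list", length(config$sites) * length(config$methods))
  k <- 0L
  for (site in config$sites) {
    pop <- .pop_for_years(config$populations[[site]], days$year)
    for (method in config$methods) {
      mu <- .daily_means(config, site, method, days)
      y <- stats::rpois(length(mu), mu)
      k <- k + 1L
      out[[k]] <- .aggregate_days(config, site, method, days, y, pop)
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  as_obs_table(df, study_start = config$date_range[1],
               intervention_date = config$intervention_date)
}

# collapse daily draws into records (daily, or weekly after the cut-over)
.aggregate_days <- function(config, site, method, days, y, pop) {
  cut <- config$weekly_aggregation_from
  if (is.null(cut)) {
    pid <- seq_len(nrow(days))
  } else {
    weekly <- days$date >= cut
    block <- as.numeric(days$date - cut) %/% 7
    pid <- ifelse(weekly, 1e9 + block, seq_len(nrow(days)))
  }
  # never let a record straddle the intervention date
  pid <- paste0(pid, "_", days$post)
  pid <- factor(pid, levels = unique(pid))

  n_days <- as.vector(table(pid))
  count <- as.vector(rowsum(y, pid))
  start <- as.Date(tapply(as.numeric(days$date), pid, min), origin = "1970-01-01")
  popm <- as.vector(rowsum(pop, pid)) / n_days
  wdW <- rowsum(outer(days$wd, 1:7, `==`) + 0, pid) / n_days
  mwW <- rowsum(outer(days$mon, 1:12, `==`) + 0, pid) / n_days
  post <- as.vector(tapply(days$post, pid, max))

  df <- data.frame(site = site, method = method, period_start = start,
                   period_length_days = n_days, count = count,
                   population = popm, post_intervention = post,
                   midpoint_time = as.numeric(start - config$date_range[1]) + n_days / 2,
                   stringsAsFactors = FALSE)
  colnames(wdW) <- .wd_cols
  colnames(mwW) <- .mw_cols
  cbind(df, wdW, mwW)
}

#' Ground-truth regression coefficients implied by a scenario
#'
#' Maps a scenario's multiplicative structure onto the parameterization of
#' the seasonal count regression fitted by [fit_poisson()]: log rate ratios
#' of non-reference sites against the reference site, log weekday
#' multipliers relative to Monday, log month multipliers relative to
#' January, the reference site's log step effect (`post`), and each
#' non-reference site's extra log step effect (`post_<site>`). The
#' intercept entry is the log baseline rate of the reference site per
#' person-day on a Monday in January; it is exact under a flat trend.
#'
#' @param config a [scenario_config()].
#' @param method which method category's coefficients to return.
#' @param reference_site reference level; defaults to the last site.
#' @return Named numeric vector of true coefficients.
#' @export
scenario_truth <- function(config, method = config$methods[1],
                           reference_site = config$sites[length(config$sites)]) {
  stopifnot(inherits(config, "scenario_config"),
            method %in% config$methods, reference_site %in% config$sites)
  other <- setdiff(config$sites, reference_site)
  rate <- config$base_annual_rate
  im <- config$intervention_multiplier
  wd <- config$weekday_multipliers
  mw <- config$month_multipliers
  out <- c(
    log(rate[reference_site, method] / 1e5 / 365.25) + log(wd[1]) + log(mw[1]),
    log(rate[other, method] / rate[reference_site, method]),
    log(wd[2:7] / wd[1]),
    log(mw[2:12] / mw[1]),
    log(im[reference_site, method]),
    log(im[other, method] / im[reference_site, method])
  )
  names(out) <- c("(Intercept)", paste0("site_", other, recycle0 = TRUE),
                  .wd_cols[-1], .mw_cols[-1],
                  "post", paste0("post_", other, recycle0 = TRUE))
  out
}

#' Taiwan-calibrated three-city charcoal-restriction scenario
#'
#' Default scenario emulating the published evaluation setting: three
#' metropolitan cities (New Taipei City, intervention site, 3.9 M
#' residents; Taipei City and Kaohsiung City, controls, 2.7 M each), two
#' method categories (charcoal-burning vs non-charcoal suicide), daily
#' counts from 2009-01-01, a step intervention in effect from 2012-05-01,
#' and weekly-only aggregation of 2013 records.
#'
#' Baseline rates are the observed pre-intervention annualized rates
#' (charcoal 6.2 / 3.5 / 5.3 and non-charcoal 12.3 / 10.8 / 14.9 per
#' 100,000 person-years). Step multipliers are the trend-adjusted
#' regression effects (charcoal: exp(-0.31) in New Taipei City,
#' exp(-0.18) in Taipei City, exp(0.05) in Kaohsiung City), so the true
#' New-Taipei-vs-Kaohsiung contrast is -0.36 on the log scale. A linear
#' secular log-trend per method (charcoal -0.0585/yr, non-charcoal
#' +0.0908/yr) is calibrated so that these step effects jointly reproduce
#' the observed pre/post count totals of all three cities in expectation.
#' Mild weekday (Monday excess) and month (spring peak) seasonality is
#' included.
#'
#' @param seed default seed stored in the config.
#' @param weekly_2013 aggregate 2013 to weekly records (the registry
#'   release format); set `FALSE` for daily records throughout.
#' @param null_effect if `TRUE`, all intervention multipliers are 1 (a
#'   null scenario for calibration studies).
#' @param end_date last simulated day.
#' @return A [scenario_config()].
#' @export
scenario_taiwan <- function(seed = NULL, weekly_2013 = TRUE,
                            null_effect = FALSE, end_date = "2013-12-31") {
  sites <- c("New Taipei City", "Taipei City", "Kaohsiung City")
  methods <- c("charcoal", "other")
  rates <- cbind(charcoal = c(6.2, 3.5, 5.3), other = c(12.3, 10.8, 14.9))
  imult <- cbind(charcoal = exp(c(-0.31, -0.18, 0.05)),
                 other    = exp(c(-0.24, -0.22, -0.21)))
  if (null_effect) imult[] <- 1
  scenario_config(
    sites = sites,
    populations = list(`New Taipei City` = 3.9e6, `Taipei City` = 2.7e6,
                       `Kaohsiung City` = 2.7e6),
    methods = methods,
    base_annual_rate = rates,
    weekday_multipliers = c(1.08, 1.02, 1.00, 0.98, 0.97, 0.96, 0.99),
    month_multipliers = exp(0.08 * cos(2 * pi * (1:12 - 5) / 12)),
    trend = list(charcoal = list(slope_per_year = -0.0585),
                 other = list(slope_per_year = 0.0908)),
    intervention_date = "2012-05-01",
    intervention_multiplier = imult,
    date_range = c(as.Date("2009-01-01"), as.Date(end_date)),
    weekly_aggregation_from = if (weekly_2013) as.Date("2013-01-01") else NULL,
    seed = seed
  )
}

#' Read a scenario from a flat YAML configuration file
#'
#' The file holds the fields of [scenario_config()] under the same names;
#' `populations` and (optionally matrix-valued) `base_annual_rate` /
#' `intervention_multiplier` are given as named maps keyed by site.
#'
#' @param path YAML file path.
#' @return A [scenario_config()].
#' @export
scenario_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("sites", "populations", "methods", "base_annual_rate",
            "intervention_date", "date_range")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("config is missing fields: ", paste(miss, collapse = ", "))
  rate <- y$base_annual_rate
  if (is.list(rate)) rate <- do.call(rbind, lapply(y$sites, function(s) unlist(rate[[s]])))
  imult <- y$intervention_multiplier %||% 1
  if (is.list(imult)) imult <- do.call(rbind, lapply(y$sites, function(s) unlist(imult[[s]])))
  scenario_config(
    sites = y$sites, populations = y$populations, methods = y$methods,
    base_annual_rate = rate,
    weekday_multipliers = y$weekday_multipliers %||% rep(1, 7),
    month_multipliers = y$month_multipliers %||% rep(1, 12),
    trend = y$trend,
    intervention_date = y$intervention_date,
    intervention_multiplier = imult,
    date_range = as.Date(unlist(y$date_range)),
    weekly_aggregation_from = y$weekly_aggregation_from,
    seed = y$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
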