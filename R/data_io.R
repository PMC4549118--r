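#' Construct and validate an observation table
#'
#' The observation table is the package's central container: one row per
#' site x method x interval, with
#' \describe{
#'   \item{site, method}{labels}
#'   \item{period_start}{`Date`, first day of the interval}
#'   \item{period_length_days}{interval length \eqn{T_i} in days}
#'   \item{count}{nonnegative event count \eqn{y_i}}
#'   \item{population}{population at risk \eqn{Pop_i} (person-day weighted
#'     mean if the interval spans calendar years)}
#'   \item{post_intervention}{0/1 indicator; intervals never straddle the
#'     intervention date}
#'   \item{midpoint_time}{days since study start at the interval center
#'     \eqn{t_i}}
#'   \item{wd_mon..wd_sun, mw_jan..mw_dec}{weekday and month weights, each
#'     set summing to 1. Daily records are one-hot; weekly records carry
#'     weekday weights 1/7 and month weights proportional to the days of
#'     the week falling in each month.}
#' }
#' Missing derived columns (`post_intervention`, `midpoint_time`, weights)
#' are filled from the calendar. Validation fails with a message listing
#' the offending rows.
#'
#' @param df data frame holding at least site, method, period_start,
#'   period_length_days, count, population.
#' @param study_start `Date`; origin of `midpoint_time`. Defaults to the
#'   earliest `period_start`.
#' @param intervention_date `Date` used to derive/validate
#'   `post_intervention` and check for straddling intervals.
#' @return A validated data frame of class `obs_table` with attributes
#'   `study_start` and `intervention_date`.
#' @export
as_obs_table <- function(df, study_start = NULL, intervention_date = NULL) {
  need <- c("site", "method", "period_start", "period_length_days",
            "count", "population")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df$period_start <- as.Date(df$period_start)
  if (is.null(study_start)) study_start <- min(df$period_start)
  study_start <- as.Date(study_start)
  if (!is.null(intervention_date)) intervention_date <- as.Date(intervention_date)

  bad <- which(!is.finite(df$count) | df$count < 0 | df$count != round(df$count))
  if (length(bad)) stop("invalid counts in rows: ", paste(bad, collapse = ", "))
  bad <- which(!is.finite(df$period_length_days) | df$period_length_days <= 0)
  if (length(bad)) stop("nonpositive period lengths in rows: ", paste(bad, collapse = ", "))
  bad <- which(!is.finite(df$population) | df$population <= 0)
  if (length(bad)) stop("nonpositive populations in rows: ", paste(bad, collapse = ", "))

  if (!is.null(intervention_date)) {
    straddle <- which(df$period_start < intervention_date &
                      df$period_start + df$period_length_days - 1 >= intervention_date)
    if (length(straddle))
      stop("interval(s) straddling the intervention date in rows: ",
           paste(straddle, collapse = ", "))
    df$post_intervention <- as.integer(df$period_start >= intervention_date)
  } else if (is.null(df$post_intervention)) {
    stop("`intervention_date` needed to derive post_intervention")
  }
  df$midpoint_time <- as.numeric(df$period_start - study_start) + df$period_length_days / 2

  if (!all(.wd_cols %in% names(df)) || !all(.mw_cols %in% names(df))) {
    W <- .calendar_weights(df$period_start, df$period_length_days)
    df[.wd_cols] <- W$wd
    df[.mw_cols] <- W$mw
  }
  wsum <- rowSums(df[.wd_cols])
  msum <- rowSums(df[.mw_cols])
  bad <- which(abs(wsum - 1) > 1e-9 | abs(msum - 1) > 1e-9 |
               apply(df[c(.wd_cols, .mw_cols)], 1, function(r) any(r < 0)))
  if (length(bad)) stop("weights must be nonnegative and sum to 1; rows: ",
                        paste(bad, collapse = ", "))

  df <- df[order(df$site, df$method, df$period_start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, study_start = study_start,
            intervention_date = intervention_date,
            class = c("obs_table", "data.frame"))
}

# one-hot (daily) or fractional (multi-day) weekday/month weights
.calendar_weights <- function(start, len) {
  n <- length(start)
  wd <- matrix(0, n, 7)
  mw <- matrix(0, n, 12)
  for (i in seq_len(n)) {
    d <- start[i] + seq_len(len[i]) - 1
    lt <- as.POSIXlt(d)
    wdi <- ((lt$wday + 6L) %% 7L) + 1L
    wd[i, ] <- tabulate(wdi, 7) / len[i]
    mw[i, ] <- tabulate(lt$mon + 1L, 12) / len[i]
  }
  list(wd = wd, mw = mw)
}

#' Classify an ICD-10 external-cause code into a method category
#'
#' Charcoal-burning deaths are identified by X67 (intentional
#' self-poisoning by and exposure to other gases and vapours) together
#' with the corresponding undetermined-intent code Y17. All other codes in
#' X60--X84 (intentional self-harm) or Y10--Y34 (undetermined intent) form
#' the non-charcoal category. Codes outside both ranges are out of scope
#' and returned as `NA`.
#'
#' @param code character vector of ICD-10 codes (e.g. `"X67"`, `"Y20.1"`).
#' @return Character vector: `"charcoal"`, `"other"`, or `NA` for codes
#'   outside the study's scope. Malformed codes raise an error.
#' @examples
#' classify_method(c("X67", "Y17", "X70", "Y20", "X59"))
#' @export
classify_method <- function(code) {
  code <- toupper(trimws(as.character(code)))
  ok <- grepl("^[A-Z][0-9]{2}(\\.[0-9]+)?$", code)
  if (any(!ok)) stop("malformed ICD-10 code(s): ",
                     paste(unique(code[!ok]), collapse = ", "))
  letter <- substr(code, 1, 1)
  num <- as.integer(substr(code, 2, 3))
  charcoal <- (letter == "X" & num == 67) | (letter == "Y" & num == 17)
  other <- ((letter == "X" & num >= 60 & num <= 84) |
            (letter == "Y" & num >= 10 & num <= 34)) & !charcoal
  out <- rep(NA_character_, length(code))
  out[charcoal] <- "charcoal"
  out[other] <- "other"
  out
}

#' Annualized event rate per 100,000 person-years
#'
#' `rate = count * 365.25 / (period_length_days * population / 100000)`.
#' Returned unrounded; descriptive tables display one decimal place.
#'
#' @param count event count(s).
#' @param population population at risk.
#' @param period_length_days length of the observation period in days.
#' @return Rate(s) per 100,000 person-years.
#' @examples
#' round(annualized_rate(808, 3.9e6, 1216), 1)  # 6.2
#' @export
annualized_rate <- function(count, population, period_length_days) {
  if (any(population <= 0) || any(period_length_days <= 0))
    stop("population and period length must be positive")
  count * 365.25 / (period_length_days * population / 1e5)
}

#' Percent change between two rates
#'
#' `100 * (1 - rate_post / rate_pre)`; positive values are reductions.
#'
#' @param rate_pre pre-period rate (> 0).
#' @param rate_post post-period rate.
#' @return Unrounded percent change; display convention is the nearest
#'   integer.
#' @export
percent_change <- function(rate_pre, rate_post) {
  if (any(rate_pre <= 0)) stop("`rate_pre` must be positive")
  100 * (1 - rate_post / rate_pre)
}

#' Descriptive pre/post rate table
#'
#' Sums counts per site x method x period (pre / post intervention), adds
#' an "all" row aggregating the method categories, and annualizes with
#' person-time computed from each site's distinct observation intervals
#' (so per-calendar-year populations are respected).
#'
#' @param obs an `obs_table`.
#' @param intervention_date defaults to the table's attribute.
#' @return Data frame with columns site, method, period, count,
#'   person_days, rate (unrounded), rate_display (1 d.p.).
#' @export
rate_table <- function(obs, intervention_date = attr(obs, "intervention_date")) {
  stopifnot(inherits(obs, "obs_table"))
  if (is.null(intervention_date)) stop("`intervention_date` required")
  post <- obs$period_start >= as.Date(intervention_date)
  if (all(post) || !any(post)) stop("observations must cover both periods")
  period <- ifelse(post, "post", "pre")

  rows <- list()
  for (s in unique(obs$site)) {
    sel_s <- obs$site == s
    # person-time from the site's distinct intervals (not per method)
    first_m <- obs$method[sel_s][1]
    for (p in c("pre", "post")) {
      base <- sel_s & period == p & obs$method == first_m
      pdays <- sum(obs$period_length_days[base] * obs$population[base])
      for (m in c(unique(obs$method), "all")) {
        sel <- sel_s & period == p & (if (m == "all") TRUE else obs$method == m)
        cnt <- sum(obs$count[sel])
        rate <- cnt * 365.25 / (pdays / 1e5)
        rows[[length(rows) + 1]] <- data.frame(
          site = s, method = m, period = p, count = cnt,
          person_days = pdays, rate = rate,
          rate_display = round(rate, 1), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$period <- factor(out$period, levels = c("pre", "post"))
  out[order(out$site, out$method, out$period), , drop = FALSE]
}

#' Read an observation table from CSV
#'
#' Canonical schema: `site, method, period_start (ISO-8601),
#' period_length_days, count, population`, plus optional precomputed
#' weight columns `wd_mon..wd_sun` / `mw_jan..mw_dec` and
#' `post_intervention`. Column names can be remapped through `schema_map`.
#' Missing weights are derived from the calendar (one-hot for daily rows,
#' uniform-weekday / day-proportional-month for multi-day rows).
#'
#' @param path CSV file.
#' @param intervention_date `Date`; used to derive `post_intervention` and
#'   to reject intervals straddling it.
#' @param schema_map optional named character vector mapping canonical
#'   names to the file's column names, e.g. `c(count = "deaths")`.
#' @param study_start optional `Date` origin for `midpoint_time`.
#' @return An `obs_table`.
#' @export
load_observations <- function(path, intervention_date, schema_map = NULL,
                              study_start = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema_map)) {
    for (canon in names(schema_map)) {
      src <- schema_map[[canon]]
      if (!src %in% names(df)) stop("schema_map column not found: ", src)
      names(df)[names(df) == src] <- canon
    }
  }
  as_obs_table(df, study_start = study_start,
               intervention_date = intervention_date)
}

#' Write an observation table to CSV in the canonical schema
#'
#' @param obs an `obs_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  stopifnot(inherits(obs, "obs_table"))
  cols <- c("site", "method", "period_start", "period_length_days",
            "count", "population", "post_intervention", .wd_cols, .mw_cols)
  utils::write.csv(as.data.frame(obs)[cols], path, row.names = FALSE)
  invisible(path)
}

#' Subset an observation table, preserving its metadata
#'
#' @param obs an `obs_table`.
#' @param site,method optional labels to keep.
#' @param segment optional `"pre"` or `"post"`.
#' @return An `obs_table` with the same `study_start` and
#'   `intervention_date` attributes.
#' @export
obs_subset <- function(obs, site = NULL, method = NULL, segment = NULL) {
  stopifnot(inherits(obs, "obs_table"))
  keep <- rep(TRUE, nrow(obs))
  if (!is.null(site)) keep <- keep & obs$site %in% site
  if (!is.null(method)) keep <- keep & obs$method %in% method
  if (!is.null(segment)) {
    segment <- match.arg(segment, c("pre", "post"))
    keep <- keep & (obs$post_intervention == as.integer(segment == "post"))
  }
  out <- obs[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, study_start = attr(obs, "study_start"),
            intervention_date = attr(obs, "intervention_date"),
            class = class(obs))
}
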