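#' Specify the seasonal spline count regression
#'
#' The model for record \eqn{i} is
#' \deqn{E[y_i] = Pop_i T_i \exp\{ \beta_0 + B(t_i)\beta^{tr} +
#'   \sum_s site_{si}\beta^c_s + \sum_d wd_{di}\beta^w_d +
#'   \sum_m mo_{mi}\beta^m_m + post_i\beta^{intv}_1 +
#'   \sum_s site_{si} post_i \beta^{intv}_{s} \},}
#' with \eqn{B(t_i)} an order-4 (cubic) B-spline basis in days since study
#' start with evenly spaced interior knots, weekday and month terms taking
#' the record's (possibly fractional) calendar weights relative to Monday
#' and January, site dummies relative to a reference site, and a step
#' intervention term plus per-non-reference-site interactions. The spline
#' order is fixed at 4; the number of interior knots is either given or
#' selected by AIC ([select_knots()]).
#'
#' @param n_interior_knots nonnegative integer, or `"AIC"` to select.
#' @param reference_site reference site label; defaults at design-build
#'   time to the last site present in the data.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(n_interior_knots = "AIC", reference_site = NULL) {
  if (!identical(n_interior_knots, "AIC")) {
    n_interior_knots <- as.integer(n_interior_knots)
    stopifnot(n_interior_knots >= 0)
  }
  structure(list(spline_order = 4L, n_interior_knots = n_interior_knots,
                 reference_site = reference_site),
            class = "model_spec")
}

#' Build the regression design matrix and exposure offset
#'
#' Columns: intercept; cubic B-spline basis of the interval midpoint with
#' the first basis column dropped (a full basis sums to one and is
#' collinear with the intercept); dummies for each non-reference site;
#' weekday weights Tuesday..Sunday; month weights February..December; the
#' post-intervention indicator; and its interactions with the
#' non-reference sites. The offset is \eqn{\log(Pop_i T_i)} (person-days),
#' so coefficients act on log rates per person-day.
#'
#' @param obs an `obs_table` (typically one method category, all sites).
#' @param spec a [model_spec()] with a resolved (numeric) knot count.
#' @param time_range spline boundary, days since study start; defaults to
#'   the observed span. Fix it across fits that must share a basis.
#' @return List of class `design_matrix`: `X`, `offset`, `y`, `obs`,
#'   `spec`, `sites`, `reference_site`, `time_range`.
#' @export
build_design <- function(obs, spec = model_spec(0), time_range = NULL) {
  stopifnot(inherits(obs, "obs_table"), inherits(spec, "model_spec"))
  k <- spec$n_interior_knots
  if (identical(k, "AIC"))
    stop("resolve the knot count first (see select_knots())")
  sites <- unique(obs$site)
  ref <- spec$reference_site %||% sites[length(sites)]
  if (!ref %in% sites) stop("reference site not present in data: ", ref)
  other <- setdiff(sites, ref)

  t_i <- obs$midpoint_time
  if (is.null(time_range))
    time_range <- c(min(t_i - obs$period_length_days / 2),
                    max(t_i + obs$period_length_days / 2))
  knots <- if (k > 0) seq(time_range[1], time_range[2], length.out = k + 2)[-c(1, k + 2)] else NULL
  B <- splines::bs(t_i, knots = knots, degree = 3, intercept = TRUE,
                   Boundary.knots = time_range)[, -1, drop = FALSE]
  colnames(B) <- paste0("trend", seq_len(ncol(B)))

  site_d <- sapply(other, function(s) as.numeric(obs$site == s))
  if (length(other)) {
    site_d <- matrix(site_d, nrow = nrow(obs),
                     dimnames = list(NULL, paste0("site_", other)))
  } else site_d <- NULL
  post <- obs$post_intervention
  int_d <- if (length(other)) {
    m <- site_d * post
    colnames(m) <- paste0("post_", other)
    m
  } else NULL

  X <- cbind(`(Intercept)` = 1, B,
             site_d,
             as.matrix(obs[.wd_cols[-1]]),
             as.matrix(obs[.mw_cols[-1]]),
             post = post, int_d)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_cols <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  structure(list(X = X, offset = log(obs$population * obs$period_length_days),
                 y = obs$count, obs = obs, spec = spec, sites = sites,
                 reference_site = ref, time_range = time_range),
            class = "design_matrix")
}

#' Fit the Poisson count regression
#'
#' Maximum-likelihood Poisson fit with log link and exposure offset; the
#' coefficient covariance is the inverse observed Fisher information.
#'
#' @param design a [build_design()] result.
#' @return Object of class `mr_fit`: `family`, `coefficients`, `vcov`,
#'   `loglik`, `aic`, `fitted` (means \eqn{\hat\mu_i}), `nb_dispersion`
#'   (`NULL` for Poisson), `design`.
#' @export
fit_poisson <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  fit <- stats::glm.fit(design$X, design$y, offset = design$offset,
                        family = stats::poisson())
  if (!fit$converged) stop("Poisson IRLS did not converge")
  if (any(abs(fit$coefficients) > 20))
    warning("extreme coefficient(s); possible separation")
  mu <- fit$fitted.values
  ll <- sum(stats::dpois(design$y, mu, log = TRUE))
  k <- length(fit$coefficients)
  W <- mu
  V <- solve(crossprod(design$X, W * design$X))
  dimnames(V) <- list(colnames(design$X), colnames(design$X))
  structure(list(family = "poisson", coefficients = fit$coefficients,
                 vcov = V, loglik = ll, aic = 2 * k - 2 * ll,
                 fitted = mu, nb_dispersion = NULL, design = design),
            class = "mr_fit")
}

#' Fit the negative-binomial (NB2) count regression
#'
#' ML fit of the NB2 model (variance \eqn{\mu + \mu^2/\theta}) with log
#' link and exposure offset, dispersion estimated jointly via
#' [MASS::glm.nb()]. If the dispersion collapses to the Poisson boundary
#' (\eqn{\theta \to \infty}) the Poisson fit is returned with a warning.
#'
#' @param design a [build_design()] result.
#' @return An `mr_fit` with `family = "negbin"` and `nb_dispersion`
#'   \eqn{= \theta}.
#' @export
fit_negbin <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X; y <- design$y; off <- design$offset
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ 0 + X + offset(off))),
    error = function(e) NULL)
  if (is.null(fit) || fit$theta > 1e6) {
    warning("NB dispersion at the Poisson boundary; returning the Poisson fit")
    return(fit_poisson(design))
  }
  beta <- stats::coef(fit)
  names(beta) <- sub("^X", "", names(beta))
  V <- stats::vcov(fit)
  dimnames(V) <- list(names(beta), names(beta))
  mu <- fit$fitted.values
  ll <- fit$twologlik / 2
  k <- length(beta) + 1  # + dispersion
  structure(list(family = "negbin", coefficients = beta, vcov = V,
                 loglik = ll, aic = 2 * k - 2 * ll, fitted = mu,
                 nb_dispersion = fit$theta, nb_dispersion_se = fit$SE.theta,
                 design = design),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d coefficients, logLik %.2f, AIC %.2f\n",
              x$family, length(x$coefficients), x$loglik, x$aic))
  if (!is.null(x$nb_dispersion))
    cat(sprintf("  NB dispersion theta = %.3f\n", x$nb_dispersion))
  invisible(x)
}

#' Coefficient table (estimate, SE, Wald z, p)
#'
#' @param fit an `mr_fit`.
#' @return Data frame with one row per coefficient.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "mr_fit"))
  est <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p_value = unname(2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}

#' Select the number of interior spline knots by AIC
#'
#' Fits the Poisson model for each candidate interior-knot count and
#' returns the spec with the AIC-minimizing count; ties go to fewer knots.
#'
#' @param obs an `obs_table`.
#' @param spec a [model_spec()] (its `reference_site` is kept).
#' @param grid candidate interior-knot counts (default `0:10`).
#' @param time_range optional fixed spline boundary (see [build_design()]).
#' @return The resolved `model_spec`, with the candidate AIC table
#'   attached as attribute `"aic_table"`.
#' @export
select_knots <- function(obs, spec = model_spec(), grid = 0:10,
                         time_range = NULL) {
  grid <- sort(unique(as.integer(grid)))
  aics <- rep(NA_real_, length(grid))
  for (j in seq_along(grid)) {
    sp <- model_spec(grid[j], spec$reference_site)
    aics[j] <- tryCatch(
      fit_poisson(build_design(obs, sp, time_range = time_range))$aic,
      error = function(e) NA_real_)
  }
  if (all(is.na(aics))) stop("all candidate fits failed")
  best <- grid[which.min(aics)]  # first minimum: ties resolve to fewer knots
  out <- model_spec(best, spec$reference_site)
  attr(out, "aic_table") <- data.frame(n_interior_knots = grid, aic = aics)
  out
}

#' Overdispersion test for a Poisson fit
#'
#' Auxiliary-regression test of \eqn{H_0: Var = \mu} against
#' \eqn{Var = \mu + c\,\mu} (alternative linear in the mean): the
#' statistics \eqn{z_i = ((y_i-\hat\mu_i)^2 - y_i)/\hat\mu_i} are averaged
#' and a one-sided z-test of \eqn{c > 0} is applied. Because the squared
#' residuals are computed around *fitted* means, their null expectation is
#' deflated by roughly one per estimated mean parameter
#' (\eqn{E[\sum_i z_i] \approx -k}); the statistic is therefore centered
#' as \eqn{stat = \sqrt{n}\,(\bar z + k/n)/sd(z)}, which restores the
#' nominal one-sided size.
#'
#' @param fit a Poisson `mr_fit`.
#' @param alpha significance level for the `overdispersed` flag.
#' @return List `statistic`, `p_value`, `overdispersed`.
#' @export
dispersion_test <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "mr_fit"))
  if (fit$family != "poisson") stop("dispersion test applies to a Poisson fit")
  mu <- fit$fitted
  if (any(mu <= 0)) stop("fitted means must be positive")
  y <- fit$design$y
  z <- ((y - mu)^2 - y) / mu
  k <- length(fit$coefficients)
  n <- length(z)
  s <- stats::sd(z)
  stat <- if (s == 0) sign(mean(z) + k / n) * Inf else sqrt(n) * (mean(z) + k / n) / s
  p <- stats::pnorm(stat, lower.tail = FALSE)
  list(statistic = stat, p_value = p, overdispersed = isTRUE(p < alpha))
}

#' Non-randomized PIT residual diagnostics for count fits
#'
#' For each observation the probability-integral-transform mass is spread
#' uniformly over \eqn{[F_i(y_i-1), F_i(y_i)]} (the non-randomized PIT for
#' discrete outcomes); the masses are aggregated into equal-width bins and
#' a chi-squared uniformity statistic with `bins - 1` degrees of freedom
#' is computed. Under a correctly specified model the histogram is
#' approximately uniform.
#'
#' @param fit an `mr_fit` (Poisson or negative binomial).
#' @param bins number of histogram bins (default 10, minimum 2).
#' @return List `histogram` (data frame: `bin_low`, `bin_high`, `mass`,
#'   `relative`), `chisq_stat`, `p_value`, `bins`.
#' @export
pit_residuals <- function(fit, bins = 10) {
  stopifnot(inherits(fit, "mr_fit"))
  bins <- as.integer(bins)
  if (bins < 2) stop("`bins` must be at least 2")
  y <- fit$design$y
  mu <- fit$fitted
  if (fit$family == "poisson") {
    F1 <- stats::ppois(y - 1, mu)
    F2 <- stats::ppois(y, mu)
  } else {
    F1 <- stats::pnbinom(y - 1, mu = mu, size = fit$nb_dispersion)
    F2 <- stats::pnbinom(y, mu = mu, size = fit$nb_dispersion)
  }
  edges <- seq(0, 1, length.out = bins + 1)
  lo <- edges[-(bins + 1)]; hi <- edges[-1]
  width <- pmax(F2 - F1, .Machine$double.eps)
  O <- vapply(seq_len(bins), function(j) {
    sum(pmax(0, pmin(F2, hi[j]) - pmax(F1, lo[j])) / width)
  }, numeric(1))
  n <- length(y)
  expected <- n / bins
  stat <- sum((O - expected)^2 / expected)
  list(histogram = data.frame(bin_low = lo, bin_high = hi, mass = O,
                              relative = O / expected),
       chisq_stat = stat,
       p_value = stats::pchisq(stat, df = bins - 1, lower.tail = FALSE),
       bins = bins)
}

#' Intervention effect as a percent rate change
#'
#' `scope = "contrast"` uses the site's interaction coefficient (its extra
#' step effect relative to the reference site; for the reference site this
#' is the common `post` term). `scope = "total"` uses the site's total log
#' step effect `post + post_<site>` with covariance-propagated SE. The
#' percent reduction is \eqn{100(1 - e^{\beta})} with Wald 95% interval
#' \eqn{100(1 - e^{\beta \pm 1.96\,se})}.
#'
#' @param fit an `mr_fit` containing intervention terms.
#' @param site site label.
#' @param scope `"contrast"` (default, the reported per-site estimate) or
#'   `"total"`.
#' @return Object of class `intervention_effect`: `site`, `scope`,
#'   `log_effect`, `se`, `pct_reduction`, `pct_ci`, `p_value`.
#' @export
effect_estimate <- function(fit, site, scope = c("contrast", "total")) {
  stopifnot(inherits(fit, "mr_fit"))
  scope <- match.arg(scope)
  cf <- fit$coefficients
  V <- fit$vcov
  if (!"post" %in% names(cf)) stop("fit has no intervention terms")
  ref <- fit$design$reference_site
  if (!site %in% fit$design$sites) stop("unknown site: ", site)
  key <- paste0("post_", site)
  if (site == ref) {
    beta <- cf[["post"]]; v <- V["post", "post"]
  } else if (scope == "contrast") {
    beta <- cf[[key]]; v <- V[key, key]
  } else {
    beta <- cf[["post"]] + cf[[key]]
    v <- V["post", "post"] + V[key, key] + 2 * V["post", key]
  }
  se <- sqrt(v)
  z <- beta / se
  structure(list(site = site, scope = scope, log_effect = beta, se = se,
                 pct_reduction = 100 * (1 - exp(beta)),
                 pct_ci = c(100 * (1 - exp(beta + 1.96 * se)),
                            100 * (1 - exp(beta - 1.96 * se))),
                 p_value = 2 * stats::pnorm(-abs(z))),
            class = "intervention_effect")
}

#' @export
print.intervention_effect <- function(x, ...) {
  cat(sprintf("%s (%s): %+.0f%% change (log effect %.2f, SE %.2f), 95%% CI [%.0f%%, %.0f%%], p = %.3g\n",
              x$site, x$scope, -x$pct_reduction, x$log_effect, x$se,
              x$pct_ci[1], x$pct_ci[2], x$p_value))
  invisible(x)
}
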