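# Shared fixtures and independent oracles for the test suite.

# one-site, one-method scenario with optional step effect and trend
flat_scenario <- function(rate = 6.2, pop = 3.9e6, mult = 1,
                          start = "2009-01-01", end = "2010-12-31",
                          int_date = "2010-01-01", slope = NULL,
                          weekly_from = NULL, seed = NULL) {
  scenario_config(
    sites = "A", populations = c(A = pop), methods = "m",
    base_annual_rate = rate,
    intervention_date = int_date,
    intervention_multiplier = mult,
    trend = if (is.null(slope)) NULL else list(slope_per_year = slope),
    date_range = c(as.Date(start), as.Date(end)),
    weekly_aggregation_from = weekly_from,
    seed = seed
  )
}

# the published-evaluation calendar restricted to the restricted method,
# daily throughout (used for parameter-recovery and power studies)
charcoal_scenario <- function(null_effect = FALSE) {
  cfg <- scenario_taiwan(weekly_2013 = FALSE, null_effect = null_effect)
  scenario_config(
    sites = cfg$sites, populations = cfg$populations, methods = "charcoal",
    base_annual_rate = cfg$base_annual_rate[, "charcoal", drop = FALSE],
    weekday_multipliers = cfg$weekday_multipliers,
    month_multipliers = cfg$month_multipliers,
    trend = list(charcoal = cfg$trend$charcoal),
    intervention_date = cfg$intervention_date,
    intervention_multiplier = cfg$intervention_multiplier[, "charcoal", drop = FALSE],
    date_range = cfg$date_range
  )
}

# small hand-built regression design (tiny enough for brute-force oracles)
tiny_design <- function(n = 20, seed = 7, theta = NULL) {
  set.seed(seed)
  x1 <- scale(seq_len(n))[, 1]
  x2 <- rep_len(c(0, 1), n)
  post <- as.numeric(seq_len(n) > n / 2)
  X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2, post = post)
  off <- log(runif(n, 5e5, 2e6) * 1)
  beta <- c(-12.5, 0.3, -0.2, -0.4)
  mu <- exp(drop(X %*% beta) + off)
  y <- if (is.null(theta)) rpois(n, mu) else rnbinom(n, mu = mu, size = theta)
  obs <- data.frame(site = "A", method = "m",
                    period_start = as.Date("2009-01-01") + seq_len(n) - 1,
                    period_length_days = 1, count = y,
                    population = exp(off), post_intervention = post,
                    midpoint_time = seq_len(n) - 0.5)
  structure(list(X = X, offset = off, y = y, obs = obs,
                 spec = model_spec(0), sites = "A", reference_site = "A",
                 time_range = c(0, n)),
            class = "design_matrix")
}

# brute-force ML oracles (generic optimizer, independent of glm/glm.nb)
brute_loglik_poisson <- function(design) {
  X <- design$X; y <- design$y; off <- design$offset
  nll <- function(b) {
    eta <- drop(X %*% b) + off
    sum(exp(eta)) - sum(y * eta)
  }
  gr <- function(b) drop(crossprod(X, exp(drop(X %*% b) + off) - y))
  b0 <- c(log(sum(y) / sum(exp(off))), rep(0, ncol(X) - 1))
  o <- optim(b0, nll, gr, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-15))
  eta <- drop(X %*% o$par) + off
  sum(dpois(y, exp(eta), log = TRUE))
}

brute_loglik_negbin <- function(design) {
  X <- design$X; y <- design$y; off <- design$offset
  nll <- function(p) {
    b <- p[-length(p)]
    th <- exp(p[length(p)])
    mu <- exp(drop(X %*% b) + off)
    -sum(dnbinom(y, mu = mu, size = th, log = TRUE))
  }
  b0 <- c(log(sum(y) / sum(exp(off))), rep(0, ncol(X) - 1), 0)
  o <- optim(b0, nll, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-15))
  o <- optim(o$par, nll, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-15))
  -o$value
}

# map scenario ground truth onto a design's columns (zeros for trend terms)
truth_for_design <- function(config, design, method = config$methods[1]) {
  tr <- scenario_truth(config, method, reference_site = design$reference_site)
  beta <- setNames(numeric(ncol(design$X)), colnames(design$X))
  common <- intersect(names(tr), names(beta))
  beta[common] <- tr[common]
  beta
}
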