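test_that("the design matrix encodes the calendar, sites and intervention", {
  cfg <- scenario_taiwan(seed = 51)
  obs <- obs_subset(generate_observations(cfg), method = "charcoal")
  spec <- model_spec(2, reference_site = "Kaohsiung City")
  d <- build_design(obs, spec)

  # column-count invariant: 1 + (k + 3) + sites-1 + 6 + 11 + (1 + sites-1)
  expect_equal(ncol(d$X), 1 + (2 + 3) + 2 + 6 + 11 + 3)
  expect_true(qr(d$X)$rank == ncol(d$X))

  # a daily Tuesday-in-February Kaohsiung pre-period record is one-hot
  i <- which(obs$site == "Kaohsiung City" &
             obs$period_start == as.Date("2009-02-03"))
  row <- d$X[i, ]
  expect_equal(unname(row["wd_tue"]), 1)
  expect_equal(sum(row[grep("^wd_", names(row))]), 1)
  expect_equal(unname(row["mw_feb"]), 1)
  expect_equal(unname(row[c("site_New Taipei City", "site_Taipei City",
                            "post", "post_New Taipei City", "post_Taipei City")]),
               rep(0, 5))

  # a weekly 2013 New Taipei record has averaged weekday dummies and
  # active intervention terms; its offset is log(Pop * T)
  j <- which(obs$site == "New Taipei City" &
             obs$period_start == as.Date("2013-03-05"))
  expect_equal(obs$period_length_days[j], 7)
  expect_true(all(abs(d$X[j, grep("^wd_", colnames(d$X))] - 1/7) < 1e-12))
  expect_equal(unname(d$X[j, c("post", "post_New Taipei City")]), c(1, 1))
  expect_equal(d$offset[j], log(3.9e6 * 7))

  expect_error(build_design(obs, model_spec("AIC")), "resolve")
})

test_that("Poisson ML reproduces the closed form and a brute-force optimum", {
  # intercept-only fit equals log(total count / total exposure)
  set.seed(5)
  n <- 50
  obs <- data.frame(count = rpois(n, 3))
  d0 <- structure(list(X = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
                       offset = rep(log(1e5), n), y = obs$count, obs = obs,
                       spec = model_spec(0), sites = "A", reference_site = "A"),
                  class = "design_matrix")
  f0 <- fit_poisson(d0)
  expect_equal(unname(f0$coefficients), log(sum(obs$count) / (n * 1e5)),
               tolerance = 1e-9)

  # likelihood at the optimum matches generic numerical maximization
  d <- tiny_design(20, seed = 7)
  fit <- fit_poisson(d)
  expect_equal(fit$loglik, brute_loglik_poisson(d), tolerance = 1e-6)
  expect_equal(fit$aic, 2 * ncol(d$X) - 2 * fit$loglik)
})

test_that("negative-binomial ML matches brute force and nests the Poisson fit", {
  d <- tiny_design(30, seed = 19, theta = 1.5)
  fit <- fit_negbin(d)
  expect_equal(fit$family, "negbin")
  expect_equal(fit$loglik, brute_loglik_negbin(d), tolerance = 1e-5)

  # on equidispersed data the NB likelihood can only improve on Poisson
  # (up to the dispersion-estimation stopping tolerance)
  dp <- tiny_design(30, seed = 23)
  fp <- fit_poisson(dp)
  fn <- suppressWarnings(fit_negbin(dp))
  expect_gte(fn$loglik, fp$loglik - 0.01)
})

test_that("NB dispersion is recovered from overdispersed data", {
  # daily year then weekly years, theta = 2 (variance = mu + mu^2/2);
  # the daily rows keep the weekday columns identifiable
  cfg <- flat_scenario(rate = 30, pop = 3e6, end = "2012-12-31",
                       int_date = "2011-01-01", mult = 0.8,
                       weekly_from = "2010-01-01")
  obs <- generate_observations(cfg, seed = 29)
  mu_true <- 3e6 / 1e5 * 30 / 365.25 * obs$period_length_days *
    ifelse(obs$post_intervention == 1, 0.8, 1)
  set.seed(30)
  obs$count <- rnbinom(nrow(obs), mu = mu_true, size = 2)
  obs <- as_obs_table(as.data.frame(obs), intervention_date = "2011-01-01")
  d <- build_design(obs, model_spec(0))
  fit <- fit_negbin(d)
  expect_lt(abs(fit$nb_dispersion - 2), 2.5 * fit$nb_dispersion_se)
})

test_that("AIC knot selection favours parsimony and reacts to curvature", {
  spec <- model_spec("AIC")
  # linear generating trend: parsimonious counts dominate across replicates
  picks <- vapply(61:70, function(s) {
    flat <- obs_subset(generate_observations(scenario_taiwan(weekly_2013 = FALSE),
                                             seed = s),
                       method = "charcoal")
    select_knots(flat, model_spec("AIC", "Kaohsiung City"),
                 grid = 0:5)$n_interior_knots
  }, numeric(1))
  expect_gte(sum(picks <= 1), 6)

  flat <- obs_subset(generate_observations(scenario_taiwan(weekly_2013 = FALSE),
                                           seed = 61),
                     method = "charcoal")
  chosen <- select_knots(flat, model_spec("AIC", "Kaohsiung City"), grid = 0:5)
  expect_s3_class(attr(chosen, "aic_table"), "data.frame")

  # strongly curved trend: one full oscillation on the log rate
  curved <- scenario_config(
    sites = c("A", "B"), populations = c(A = 4e6, B = 4e6), methods = "m",
    base_annual_rate = 20,
    trend = list(n_knots = 4, coef = c(0, 2, -2, 2, -2, 2, 0, 0)),
    intervention_date = "2011-01-01",
    intervention_multiplier = c(A = 0.8, B = 1),
    date_range = c(as.Date("2009-01-01"), as.Date("2012-12-31")))
  obs_c <- generate_observations(curved, seed = 62)
  chosen_c <- select_knots(obs_c, model_spec("AIC", "B"), grid = 0:6)
  expect_gt(chosen_c$n_interior_knots, 0)

  # a single-candidate grid is returned as-is
  one <- select_knots(flat, model_spec("AIC", "Kaohsiung City"), grid = 3)
  expect_equal(one$n_interior_knots, 3)
})

test_that("the dispersion test has the right direction and degenerate behaviour", {
  # under-dispersed limit: y identically equal to the fitted mean
  mu <- rep(4, 100)
  fake <- structure(list(family = "poisson", fitted = mu,
                         design = list(y = mu)), class = "mr_fit")
  dt <- dispersion_test(fake)
  expect_lt(dt$statistic, 0)
  expect_false(dt$overdispersed)

  # strongly overdispersed data are flagged
  cfg <- flat_scenario(rate = 40, pop = 3e6, end = "2011-12-31",
                       int_date = "2010-07-01", mult = 0.8)
  obs <- generate_observations(cfg, seed = 71)
  mu_true <- 3e6 / 1e5 * 40 / 365.25 * obs$period_length_days *
    ifelse(obs$post_intervention == 1, 0.8, 1)
  set.seed(72)
  obs$count <- rnbinom(nrow(obs), mu = mu_true, size = 0.8)
  obs <- as_obs_table(as.data.frame(obs), intervention_date = "2010-07-01")
  fit <- fit_poisson(build_design(obs, model_spec(0)))
  expect_true(dispersion_test(fit)$overdispersed)

  expect_error(dispersion_test(structure(list(family = "negbin"),
                                         class = "mr_fit")),
               "Poisson")
})

test_that("PIT residuals flag a wrong distribution but not a correct model", {
  cfg <- flat_scenario(rate = 20, pop = 3.9e6, mult = exp(-0.6),
                       end = "2011-12-31", int_date = "2010-07-01")
  obs <- generate_observations(cfg, seed = 81)
  d_full <- build_design(obs, model_spec(0))
  fit_full <- fit_poisson(d_full)
  p_full <- pit_residuals(fit_full)
  expect_gt(p_full$p_value, 0.05)
  expect_equal(sum(p_full$histogram$mass), nrow(obs), tolerance = 1e-8)

  # overdispersed counts fitted as Poisson: U-shaped histogram, rejection
  mu_true <- 3.9e6 / 1e5 * 20 / 365.25 *
    ifelse(obs$post_intervention == 1, exp(-0.6), 1)
  set.seed(82)
  obs$count <- rnbinom(nrow(obs), mu = mu_true, size = 1)
  obs <- as_obs_table(as.data.frame(obs), intervention_date = "2010-07-01")
  d_bad <- build_design(obs, model_spec(0))
  fit_bad <- fit_poisson(d_bad)
  expect_lt(pit_residuals(fit_bad)$p_value, 1e-4)
  # ... and the matching NB fit repairs the calibration
  fit_nb <- fit_negbin(d_bad)
  expect_gt(pit_residuals(fit_nb)$p_value, 0.05)

  expect_error(pit_residuals(fit_full, bins = 1), "at least 2")
})

test_that("effect estimates apply the 1 - exp(beta) transform with Wald intervals", {
  # constructed fit with the published coefficient values
  V <- diag(c(0.27, 0.11, 0.14)^2)
  dimnames(V) <- list(c("post", "post_NTP", "post_TP"),
                      c("post", "post_NTP", "post_TP"))
  fake <- structure(list(
    family = "poisson",
    coefficients = c(post = 0.05, post_NTP = -0.36, post_TP = -0.23),
    vcov = V,
    design = list(sites = c("NTP", "TP", "KHH"), reference_site = "KHH")),
    class = "mr_fit")
  e <- effect_estimate(fake, "NTP", scope = "contrast")
  expect_equal(round(e$pct_reduction), 30)
  expect_equal(e$log_effect, -0.36)
  e2 <- effect_estimate(fake, "NTP", scope = "total")
  expect_equal(e2$log_effect, 0.05 - 0.36)
  expect_equal(e2$se, sqrt(0.27^2 + 0.11^2), tolerance = 1e-12)
  expect_equal(round(100 * (1 - exp(-0.13))), 12)

  # zero effect maps to 0% with a log-symmetric interval
  fake$coefficients["post_NTP"] <- 0
  e0 <- effect_estimate(fake, "NTP", scope = "contrast")
  expect_equal(e0$pct_reduction, 0)
  expect_equal(log(1 - e0$pct_ci[1] / 100), -log(1 - e0$pct_ci[2] / 100),
               tolerance = 1e-12)

  # monotone: a more negative coefficient means a larger reduction
  betas <- seq(0, -1, by = -0.1)
  expect_true(all(diff(100 * (1 - exp(betas))) > 0))

  expect_error(effect_estimate(fake, "nowhere"), "unknown site")
})
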