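test_that("ICD-10 codes partition into the two method categories", {
  expect_identical(classify_method(c("X67", "Y17")), c("charcoal", "charcoal"))
  expect_identical(classify_method(c("X70", "Y20", "X60", "X84", "Y10", "Y34")),
                   rep("other", 6))
  expect_true(is.na(classify_method("X59")))
  expect_true(is.na(classify_method("A41")))
  expect_error(classify_method("67X"), "malformed")

  # the in-scope ranges split into exactly two disjoint, nonempty groups
  codes <- c(sprintf("X%02d", 60:84), sprintf("Y%02d", 10:34))
  cls <- classify_method(codes)
  expect_false(anyNA(cls))
  expect_setequal(unique(cls), c("charcoal", "other"))
  expect_identical(codes[cls == "charcoal"], c("X67", "Y17"))
})

test_that("annualized rates and percent changes reproduce the published arithmetic", {
  # pre 2009-01-01..2012-04-30 and post 2012-05-01..2013-12-31 calendars
  pre_days <- as.numeric(as.Date("2012-04-30") - as.Date("2009-01-01")) + 1
  post_days <- as.numeric(as.Date("2013-12-31") - as.Date("2012-05-01")) + 1
  expect_equal(pre_days, 1216)   # includes 2012-02-29
  expect_equal(post_days, 610)

  r_pre <- annualized_rate(808, 3.9e6, pre_days)
  r_post <- annualized_rate(256, 3.9e6, post_days)
  expect_equal(round(r_pre, 1), 6.2)
  expect_equal(round(r_post, 1), 3.9)
  expect_equal(round(percent_change(r_pre, r_post)), 37)
  expect_equal(round(percent_change(12.3, 11.9)), 3)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(annualized_rate(0, 1e6, 100), 0)
  expect_error(annualized_rate(10, 0, 10), "positive")
  expect_error(percent_change(0, 1), "positive")

  # linear in count, inversely proportional to population
  expect_equal(annualized_rate(20, 1e6, 50), 2 * annualized_rate(10, 1e6, 50))
  expect_equal(annualized_rate(10, 2e6, 50), annualized_rate(10, 1e6, 50) / 2)
})

test_that("rate_table aggregates counts and the method categories add up", {
  obs <- generate_observations(scenario_taiwan(), seed = 21)
  rt <- rate_table(obs)
  for (s in unique(rt$site)) for (p in c("pre", "post")) {
    sel <- rt$site == s & rt$period == p
    expect_equal(rt$count[sel & rt$method == "all"],
                 sum(rt$count[sel & rt$method != "all"]))
  }
  # person-time is counted once per site, not once per method
  ntp <- rt[rt$site == "New Taipei City" & rt$period == "pre", ]
  expect_equal(unique(ntp$person_days), 3.9e6 * 1216)

  # a single-record table reports its own count and rate
  one <- as_obs_table(data.frame(site = "A", method = "m",
                                 period_start = c("2009-01-01", "2010-01-01"),
                                 period_length_days = c(365, 365),
                                 count = c(73, 10), population = 1e6),
                      intervention_date = "2010-01-01")
  rt1 <- rate_table(one)
  expect_equal(rt1$count[rt1$period == "pre" & rt1$method == "m"], 73)
  expect_equal(rt1$rate[rt1$period == "pre" & rt1$method == "m"],
               annualized_rate(73, 1e6, 365))
})

test_that("observation tables validate and round-trip through CSV", {
  cfg <- scenario_taiwan(seed = 31)
  obs <- generate_observations(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- load_observations(path, intervention_date = "2012-05-01")
  expect_equal(nrow(back), nrow(obs))
  expect_equal(sum(back$count), sum(obs$count))
  expect_equal(back$midpoint_time, obs$midpoint_time)
  expect_equal(as.matrix(back[paste0("wd_", c("mon","sun"))]),
               as.matrix(obs[paste0("wd_", c("mon","sun"))]))

  # schema remapping
  df <- utils::read.csv(path)
  names(df)[names(df) == "count"] <- "deaths"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  back2 <- load_observations(path2, intervention_date = "2012-05-01",
                             schema_map = c(count = "deaths"))
  expect_equal(sum(back2$count), sum(obs$count))

  # validation failures name the offending rows
  bad <- data.frame(site = "A", method = "m", period_start = "2009-01-01",
                    period_length_days = 1, count = -1, population = 1e6)
  expect_error(as_obs_table(bad, intervention_date = "2010-01-01"),
               "invalid counts.*1")
  straddle <- data.frame(site = "A", method = "m",
                         period_start = c("2009-12-20", "2009-12-29"),
                         period_length_days = 7, count = 1, population = 1e6)
  expect_error(as_obs_table(straddle, intervention_date = "2010-01-01"),
               "straddling.*2")
})

test_that("derived calendar weights follow the daily and weekly rules", {
  # a daily record is one-hot; 2009-02-03 is a Tuesday in February
  day <- as_obs_table(data.frame(site = "A", method = "m",
                                 period_start = c("2009-02-03", "2010-06-01"),
                                 period_length_days = 1, count = 0,
                                 population = 1e6),
                      intervention_date = "2010-01-01")
  r <- day[day$period_start == as.Date("2009-02-03"), ]
  expect_equal(r$wd_tue, 1)
  expect_equal(sum(as.matrix(r[grep("^wd_", names(day), value = TRUE)])), 1)
  expect_equal(r$mw_feb, 1)

  # a 7-day record has uniform weekday weights and day-proportional months
  wk <- as_obs_table(data.frame(site = "A", method = "m",
                                period_start = c("2009-01-29", "2010-06-01"),
                                period_length_days = c(7, 1), count = 0,
                                population = 1e6),
                     intervention_date = "2010-01-01")
  r <- wk[wk$period_length_days == 7, ]
  expect_true(all(abs(as.matrix(r[grep("^wd_", names(wk), value = TRUE)]) - 1/7) < 1e-12))
  expect_equal(r$mw_jan, 3 / 7)  # Jan 29-31, then Feb 1-4
  expect_equal(r$mw_feb, 4 / 7)
})

test_that("obs_subset filters while preserving study metadata", {
  obs <- generate_observations(scenario_taiwan(), seed = 41)
  sub <- obs_subset(obs, site = "Taipei City", method = "charcoal", segment = "post")
  expect_s3_class(sub, "obs_table")
  expect_true(all(sub$site == "Taipei City" & sub$post_intervention == 1))
  expect_identical(attr(sub, "study_start"), attr(obs, "study_start"))
  expect_identical(attr(sub, "intervention_date"), attr(obs, "intervention_date"))
})
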