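# Scenario engine: calibration, counterfactual runs, PAF arithmetic,
# sensitivity propagation and the latency hook.

test_that("baseline calibration divides out the population mean RR", {
  expect_equal(calibrate_baseline(11.7, 1.17), 10, tolerance = 1e-12)
  expect_identical(calibrate_baseline(25, 1), 25)
  # round trip over a random grid
  set.seed(5)
  for (i in 1:25) {
    r <- runif(1, 1, 100); m <- runif(1, 1, 2)
    expect_equal(calibrate_baseline(r, m) * m, r, tolerance = 1e-12)
  }
  expect_error(calibrate_baseline(10, 0), class = "pafsim_domain_error")
  expect_error(calibrate_baseline(-1, 1.1), class = "pafsim_domain_error")
})

test_that("PAF arithmetic reproduces the published count-based table", {
  # reference / intervention counts and the integer percents printed with them
  cases <- list(
    list(ref = 2480, int = 2149, paf4 = 0.1335, pct = 13),  # red meat, men
    list(ref = 2878, int = 2581, paf4 = 0.1032, pct = 10),  # red meat, women
    list(ref = 2878, int = 2490, paf4 = 0.1348, pct = 13)   # processed, women
  )
  for (cs in cases) {
    paf <- paf_from_counts(cs$ref, cs$int)
    expect_equal(round_half_up(paf, 4), cs$paf4)
    expect_identical(round_half_up(100 * paf), cs$pct)
  }
  expect_identical(paf_from_counts(500, 500), 0)
  expect_error(paf_from_counts(0, 0), class = "pafsim_domain_error")
  expect_error(paf_from_counts(100, 150), class = "pafsim_domain_error")
})

test_that("identity scenario changes nothing", {
  w <- single_stratum_world()
  rf <- fit_loglinear(red_spec())
  res <- run_scenario(w$exposure, rf, w$rates, w$pop,
                      scenario("ref", "identity"), standard = w$standard)
  expect_identical(res$by_sex$paf, 0)
  expect_identical(res$by_sex$avoided_cases, 0)
  expect_identical(res$by_sex$reference_asr, res$by_sex$intervention_asr)
  expect_identical(res$by_stratum$intervention_rate,
                   res$by_stratum$rate_per_100k)
})

test_that("single-stratum engine PAF equals the closed form 1 - 1/E[RR]", {
  rf <- fit_loglinear(red_spec())
  for (pars in list(c(62.4, 55), c(50, 50), c(70.4, 55.2))) {
    w <- single_stratum_world(mean = pars[1], sd = pars[2])
    res <- run_scenario(w$exposure, rf, w$rates, w$pop,
                        scenario("elim", "zero"), standard = w$standard)
    d <- exposure_distribution("male", 0, Inf, pars[1], pars[2])
    erp <- mean_rr(discretize(d, step = rf$step), rf)
    expect_equal(res$by_sex$paf, 1 - 1 / erp, tolerance = 1e-12)
  }
})

test_that("reference scenario reproduces the input incidence exactly", {
  syn <- small_synth()
  rf <- fit_loglinear(syn$rr)
  res <- run_scenario(syn$exposure, rf, syn$incidence, syn$population,
                      scenario("elim", "zero"))
  # reference side equals expected cases straight from the inputs
  ec <- expected_cases(syn$incidence, syn$population)
  expect_identical(res$by_stratum$reference_cases, ec$cases)
  expect_equal(unname(case_totals(ec)),
               res$by_sex$reference_cases, tolerance = 1e-12)
  # calibration consistency: r0 * E[RR] gives back the observed rates
  expect_equal(res$by_stratum$baseline_rate * res$by_stratum$mean_rr_reference,
               res$by_stratum$rate_per_100k, tolerance = 1e-12)
})

test_that("PAF is monotone in the relative risk and in mean consumption", {
  syn <- small_synth()
  scn <- scenario("elim", "zero")
  pafs_by_rr <- vapply(c(1.05, 1.17, 1.31), function(rr) {
    rf <- fit_loglinear(rr_spec("red_meat", rr, reference_dose = 100))
    res <- run_scenario(syn$exposure, rf, syn$incidence, syn$population, scn)
    sum(res$by_sex$avoided_cases) / sum(res$by_sex$reference_cases)
  }, numeric(1))
  expect_true(all(diff(pafs_by_rr) > 0))

  rf <- fit_loglinear(syn$rr)
  pafs_by_mean <- vapply(c(0.6, 1, 1.4), function(f) {
    exp2 <- syn$exposure
    exp2$mean_g_day <- exp2$mean_g_day * f
    exp2$sd_g_day <- exp2$sd_g_day * f  # fixed sd/mean ratio
    res <- run_scenario(exp2, rf, syn$incidence, syn$population, scn)
    sum(res$by_sex$avoided_cases) / sum(res$by_sex$reference_cases)
  }, numeric(1))
  expect_true(all(diff(pafs_by_mean) > 0))
})

test_that("null associations and zero exposure both give PAF 0", {
  syn <- small_synth()
  scn <- scenario("elim", "zero")
  rf_null <- fit_loglinear(rr_spec("null", 1.0, reference_dose = 100))
  res_null <- run_scenario(syn$exposure, rf_null, syn$incidence,
                           syn$population, scn)
  expect_equal(res_null$by_sex$paf, c(0, 0), tolerance = 1e-12)

  zero_exp <- syn$exposure
  zero_exp$mean_g_day <- 0
  zero_exp$sd_g_day <- 0
  zero_exp$family <- "point_mass"
  rf <- fit_loglinear(syn$rr)
  res_zero <- run_scenario(zero_exp, rf, syn$incidence, syn$population, scn)
  expect_equal(res_zero$by_sex$paf, c(0, 0), tolerance = 1e-12)
})

test_that("sex totals conserve the per-stratum avoided cases", {
  syn <- small_synth()
  res <- run_scenario(syn$exposure, fit_loglinear(syn$rr), syn$incidence,
                      syn$population, scenario("elim", "zero"))
  for (s in c("female", "male")) {
    strat <- res$by_stratum[res$by_stratum$sex == s, ]
    expect_equal(
      sum(strat$reference_cases - strat$intervention_cases),
      res$by_sex$avoided_cases[res$by_sex$sex == s],
      tolerance = 1e-10)
  }
})

test_that("partial-reduction scenarios interpolate between identity and zero", {
  w <- single_stratum_world()
  rf <- fit_loglinear(red_spec())
  pafs <- vapply(list(scenario("id", "identity"),
                      scenario("half", "scale", scale_factor = 0.5),
                      scenario("zero", "zero")), function(scn) {
    run_scenario(w$exposure, rf, w$rates, w$pop, scn,
                 standard = w$standard)$by_sex$paf
  }, numeric(1))
  expect_true(all(diff(pafs) > 0))
  expect_error(scenario("bad", "scale", scale_factor = 1.5),
               class = "pafsim_config_error")
})

test_that("sensitivity runs propagate the RR interval monotonically", {
  syn <- small_synth()
  scn <- scenario("elim", "zero")
  sens <- sensitivity_run(syn$exposure, syn$rr, syn$incidence,
                          syn$population, scn)
  expect_true(all(sens$by_sex$paf_lower <= sens$by_sex$paf))
  expect_true(all(sens$by_sex$paf <= sens$by_sex$paf_upper))
  # fewer intervention cases pair with the larger PAF
  expect_true(all(sens$by_sex$intervention_cases_lower <=
                    sens$by_sex$intervention_cases_upper))
  expect_equal(sens$by_sex$intervention_cases_lower,
               sens$upper$by_sex$intervention_cases)

  # degenerate interval collapses all three runs
  degen <- rr_spec("red_meat", 1.17, 1.17, 1.17, reference_dose = 100)
  sd_res <- sensitivity_run(syn$exposure, degen, syn$incidence,
                            syn$population, scn)
  expect_identical(sd_res$by_sex$paf_lower, sd_res$by_sex$paf)
  expect_identical(sd_res$by_sex$paf_upper, sd_res$by_sex$paf)

  # widening the interval can only widen the PAF interval
  wide <- rr_spec("red_meat", 1.17, 1.02, 1.40, reference_dose = 100)
  sw <- sensitivity_run(syn$exposure, wide, syn$incidence, syn$population,
                        scn)
  expect_true(all(sw$by_sex$paf_lower <= sens$by_sex$paf_lower))
  expect_true(all(sw$by_sex$paf_upper >= sens$by_sex$paf_upper))
})

test_that("latency delays intervention effects in multi-year streams", {
  stream <- data.frame(year = 2010:2019, reference_cases = 100,
                       intervention_cases = 80)
  expect_identical(apply_latency(stream, 0), stream)
  lag5 <- apply_latency(stream, 5)
  expect_identical(lag5$intervention_cases,
                   c(rep(100, 5), rep(80, 5)))
  all_lag <- apply_latency(stream, 15)
  expect_identical(all_lag$intervention_cases, all_lag$reference_cases)
  expect_error(apply_latency(stream, -1), class = "pafsim_domain_error")
})
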