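# Synthetic recall samples, stratum summaries, and demography generation.

test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(seed = 99, n_subjects = 200)
  expect_identical(generate_recall_sample(cfg), generate_recall_sample(cfg))
  expect_identical(generate_demography(cfg), generate_demography(cfg))
  cfg2 <- synthetic_config(seed = 100, n_subjects = 200)
  expect_false(identical(generate_recall_sample(cfg)$g_day,
                         generate_recall_sample(cfg2)$g_day))
})

test_that("point-mass consumption yields constant records", {
  cons <- colombia_like_consumption("red_meat")
  cons$sd_g_day <- 0
  cons$mean_g_day <- 50
  cons$family <- "point_mass"
  cfg <- synthetic_config(seed = 3, n_subjects = 50, consumption = cons)
  rec <- generate_recall_sample(cfg)
  expect_true(all(rec$g_day == 50))
  expect_identical(nrow(rec), 50L * nrow(cons))
})

test_that("large-sample stratum means sit within 3 SE of configured truth", {
  cfg <- synthetic_config(seed = 12, n_subjects = 10000)
  rec <- generate_recall_sample(cfg)
  est <- estimate_stratum_distribution(rec)
  truth <- cfg$consumption
  merged <- merge(est, truth, by = c("sex", "age_low"),
                  suffixes = c("_est", "_true"))
  se <- merged$sd_g_day_true / sqrt(merged$n)
  expect_true(all(abs(merged$mean_g_day_est - merged$mean_g_day_true) <
                    3 * se))
  # the CI of the mean has the printed survey shape: tight around the mean
  expect_true(all(merged$ci_lower < merged$mean_g_day_est))
  expect_true(all(merged$ci_upper > merged$mean_g_day_est))
})

test_that("stratum summaries match hand calculations", {
  rec <- data.frame(sex = "male", age = c(30, 40), g_day = c(40, 60))
  adults <- data.frame(age_low = 15, age_high = 44)
  row <- estimate_stratum_distribution(rec, age_groups = adults)
  expect_equal(row$mean_g_day, 50)
  expect_equal(row$sd_g_day, 14.142, tolerance = 1e-4)
  # constant records: sd 0, degenerate CI
  rec2 <- data.frame(sex = "male", age = c(50, 51, 52), g_day = 70)
  row2 <- estimate_stratum_distribution(
    rec2, age_groups = data.frame(age_low = 45, age_high = 54))
  expect_identical(c(row2$mean_g_day, row2$sd_g_day), c(70, 0))
  expect_identical(c(row2$ci_lower, row2$ci_upper), c(70, 70))
  expect_error(estimate_stratum_distribution(
    data.frame(sex = "male", age = 30, g_day = 50)),
    class = "pafsim_domain_error")
})

test_that("generated demography has the configured structure", {
  cfg <- synthetic_config(seed = 21, rate_noise_sd = 0)
  dem <- generate_demography(cfg)
  expect_identical(sort(unique(dem$incidence$sex)), c("female", "male"))
  male <- dem$incidence[dem$incidence$sex == "male", ]
  male <- male[order(male$age_low), ]
  # log-linear rise with the configured anchor and slope
  expect_equal(male$rate_per_100k[male$age_low == 40], 5, tolerance = 1e-12)
  expect_equal(diff(log(male$rate_per_100k)), rep(0.40, 16),
               tolerance = 1e-12)
  # flat curve: ASR equals the common rate
  flat <- synthetic_config(seed = 21, rate_slope = 0, rate_noise_sd = 0)
  dem_flat <- generate_demography(flat)
  expect_equal(unname(age_standardize(dem_flat$incidence, segi_standard())),
               rep(5, 2), tolerance = 1e-12)
})

test_that("doubling the population doubles cases but leaves the PAF alone", {
  syn <- small_synth(seed = 31, n_subjects = 800)
  rf <- fit_loglinear(syn$rr)
  scn <- scenario("elim", "zero")
  res <- run_scenario(syn$exposure, rf, syn$incidence, syn$population, scn)
  pop2 <- syn$population
  pop2$count <- 2 * pop2$count
  res2 <- run_scenario(syn$exposure, rf, syn$incidence, pop2, scn)
  expect_equal(res2$by_sex$reference_cases, 2 * res$by_sex$reference_cases,
               tolerance = 1e-12)
  expect_equal(res2$by_sex$paf, res$by_sex$paf, tolerance = 1e-12)
})

test_that("engine PAF equals a brute-force stratum-by-stratum computation", {
  syn <- small_synth(seed = 77, n_subjects = 1000)
  rf <- fit_loglinear(syn$rr)
  res <- run_scenario(syn$exposure, rf, syn$incidence, syn$population,
                      scenario("elim", "zero"))
  # brute force: loop strata, divide rate by its stratum E[RR], sum cases
  for (s in c("female", "male")) {
    ref_sum <- 0; int_sum <- 0
    for (i in which(syn$incidence$sex == s)) {
      age <- syn$incidence$age_low[i]
      exp_rows <- syn$exposure[syn$exposure$sex == s, ]
      j <- which(age >= exp_rows$age_low & age <= exp_rows$age_high)
      if (!length(j)) j <- which.max(exp_rows$age_high)
      d <- exposure_distribution(s, exp_rows$age_low[j],
                                 exp_rows$age_high[j],
                                 exp_rows$mean_g_day[j],
                                 exp_rows$sd_g_day[j])
      er <- mean_rr(discretize(d, step = rf$step), rf)
      cnt <- syn$population$count[syn$population$sex == s &
                                    syn$population$age_low == age]
      ref_sum <- ref_sum + syn$incidence$rate_per_100k[i] * cnt / 1e5
      int_sum <- int_sum + syn$incidence$rate_per_100k[i] / er * cnt / 1e5
    }
    brute_paf <- 1 - int_sum / ref_sum
    expect_equal(res$by_sex$paf[res$by_sex$sex == s], brute_paf,
                 tolerance = 1e-10)
  }
})
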