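# Shared fixtures built in code.

red_spec <- function() rr_spec("red_meat", 1.17, 1.05, 1.31,
                               reference_dose = 100)
processed_spec <- function() rr_spec("processed_meat", 1.35, 1.27, 1.45,
                                     reference_dose = 100)

# A full 0-4 .. 80+ rate table for one or both sexes.
make_rate_table <- function(rates, sexes = "male") {
  lows <- seq(0, 80, by = 5)
  do.call(rbind, lapply(sexes, function(s) {
    data.frame(sex = s, age_low = lows,
               age_high = c(lows[-1] - 1, Inf),
               rate_per_100k = rates)
  }))
}

make_pop_table <- function(counts, sexes = "male") {
  lows <- seq(0, 80, by = 5)
  do.call(rbind, lapply(sexes, function(s) {
    data.frame(sex = s, age_low = lows,
               age_high = c(lows[-1] - 1, Inf),
               count = counts)
  }))
}

# Degenerate single-stratum world (one sex, one all-ages group) with a
# matching one-group standard; lets the engine be checked against the
# closed-form single-stratum PAF 1 - 1/E[RR].
single_stratum_world <- function(rate = 50, count = 1e6, mean = 62.4,
                                 sd = 55, family = "gamma") {
  list(
    rates = data.frame(sex = "male", age_low = 0, age_high = Inf,
                       rate_per_100k = rate),
    pop = data.frame(sex = "male", age_low = 0, age_high = Inf,
                     count = count),
    exposure = data.frame(sex = "male", age_low = 0, age_high = Inf,
                          mean_g_day = mean, sd_g_day = sd,
                          family = family),
    standard = data.frame(age_low = 0, age_high = Inf, weight = 1e5)
  )
}

# Small but national-shaped synthetic inputs for engine tests.
small_synth <- function(seed = 42, n_subjects = 1500, ...) {
  synthetic_inputs(synthetic_config(seed = seed, n_subjects = n_subjects,
                                    ...))
}
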