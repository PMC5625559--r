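# Seeded synthetic inputs with the statistical structure the pipeline
# assumes: per-subject 24-h-recall consumption, stratified exposure summaries,
# age-specific incidence and national-scale population counts.
#
# The default "colombia-like" fixture targets the published sex-level
# consumption summaries for Colombia (red meat 62.4 g/day males / 55.0
# females; processed meat 58.3 / 50.7) with SDs of the same magnitude as the
# means, an age profile shaped by the printed anchors (highest red-meat
# intake in young adults, lowest in small children; processed-meat intake
# declining after middle age), colorectal-cancer-like incidence rising
# log-linearly with age, and a gently tapering population pyramid. It is
# illustrative: it reproduces the published inputs' shape, not their exact
# stratum values (which are not public).

# Broad survey age groups used for consumption estimation.
SURVEY_AGE_GROUPS <- data.frame(
  age_low = c(0, 15, 45, 55),
  age_high = c(14, 44, 54, 64)
)

#' Colombia-like consumption truth per stratum
#'
#' Default per-stratum gamma consumption parameters for the synthetic fixture.
#' Male means follow the age profile described above; female means and SDs are
#' the male values scaled by the published female/male ratio of the sex-level
#' means (0.881 for red meat, 0.870 for processed meat).
#'
#' @param risk_factor `"red_meat"` or `"processed_meat"`.
#' @return data.frame with columns `sex`, `age_low`, `age_high`, `mean_g_day`,
#'   `sd_g_day`, `family`.
#' @export
colombia_like_consumption <- function(risk_factor = c("red_meat",
                                                      "processed_meat")) {
  risk_factor <- match.arg(risk_factor)
  if (risk_factor == "red_meat") {
    male_mean <- c(48, 68, 64, 61)
    male_sd <- c(34, 56, 55, 52)
    f_ratio <- 55.0 / 62.4
  } else {
    male_mean <- c(52, 61, 52, 44)
    male_sd <- c(38, 55, 42, 31)
    f_ratio <- 50.7 / 58.3
  }
  male <- data.frame(sex = "male", SURVEY_AGE_GROUPS,
                     mean_g_day = male_mean, sd_g_day = male_sd,
                     family = "gamma")
  female <- male
  female$sex <- "female"
  female$mean_g_day <- male_mean * f_ratio
  female$sd_g_day <- male_sd * f_ratio
  rbind(male, female)
}

#' Configuration for the synthetic-data generator
#'
#' @param seed integer RNG seed; every generated artifact is reproducible
#'   given the seed.
#' @param n_subjects recall subjects per stratum (>= 2).
#' @param risk_factor which consumption truth to use when `consumption` is
#'   not supplied.
#' @param consumption per-stratum truth table in the
#'   [colombia_like_consumption()] layout.
#' @param rate_at_40 incidence rate per 100,000 at the 40-44 age group (the
#'   anchor of the log-linear age curve).
#' @param rate_slope log-linear incidence slope per 5-year age group.
#' @param rate_noise_sd SD of multiplicative log-normal noise on the age
#'   curve (0 for a perfectly log-linear table).
#' @param pop_base population count per sex in the 0-4 group.
#' @param pop_decay multiplicative decay of counts per successive age group
#'   (a crude pyramid).
#' @param rr risk-factor truth as an [rr_spec()]; defaults to the published
#'   meta-analytic RRs at 100 g/day (1.17, CI 1.05-1.31 for red meat; 1.35,
#'   CI 1.27-1.45 for processed meat).
#' @return an object of class `synthetic_config`.
#' @examples
#' synthetic_config(seed = 1, n_subjects = 1000)
#' @export
synthetic_config <- function(seed, n_subjects = 10000,
                             risk_factor = c("red_meat", "processed_meat"),
                             consumption = NULL,
                             rate_at_40 = 5, rate_slope = 0.40,
                             rate_noise_sd = 0.05,
                             pop_base = 2.1e6, pop_decay = 0.93,
                             rr = NULL) {
  risk_factor <- match.arg(risk_factor)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed)) {
    stop_config("a single integer seed is required")
  }
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    stop_config("n_subjects must be >= 2 per stratum")
  }
  if (is.null(consumption)) {
    consumption <- colombia_like_consumption(risk_factor)
  }
  consumption <- validate_strat_table(consumption, "mean_g_day", "consumption")
  if (!all(consumption$family %in% EXPOSURE_FAMILIES)) {
    stop_config("unknown consumption family: %s",
                paste(setdiff(consumption$family, EXPOSURE_FAMILIES),
                      collapse = ", "))
  }
  for (v in c(rate_at_40 = rate_at_40, pop_base = pop_base,
              pop_decay = pop_decay)) {
    if (!is.numeric(v) || v <= 0) stop_config("scale parameters must be > 0")
  }
  if (rate_noise_sd < 0) stop_config("rate_noise_sd must be >= 0")
  if (is.null(rr)) {
    rr <- if (risk_factor == "red_meat") {
      rr_spec("red_meat", 1.17, 1.05, 1.31, reference_dose = 100)
    } else {
      rr_spec("processed_meat", 1.35, 1.27, 1.45, reference_dose = 100)
    }
  }
  stopifnot(inherits(rr, "rr_spec"))
  structure(
    list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
         risk_factor = risk_factor, consumption = consumption,
         rate_at_40 = rate_at_40, rate_slope = rate_slope,
         rate_noise_sd = rate_noise_sd, pop_base = pop_base,
         pop_decay = pop_decay, rr = rr),
    class = "synthetic_config"
  )
}

# Draw n values from one stratum's consumption family.
draw_consumption <- function(n, mean, sd, family) {
  switch(family,
    gamma = stats::rgamma(n, shape = mean^2 / sd^2, scale = sd^2 / mean),
    truncated_normal = {
      # inverse-CDF sampling of the normal truncated at 0
      z0 <- stats::pnorm(0, mean, sd)
      stats::qnorm(z0 + stats::runif(n) * (1 - z0), mean, sd)
    },
    point_mass = rep(mean, n),
    stop_config("unknown consumption family '%s'", family)
  )
}

#' Generate a synthetic 24-h-recall sample
#'
#' Draws `n_subjects` per stratum from the configured consumption truth,
#' emulating the per-subject output of a national dietary recall survey.
#' Subject ages are uniform within each stratum (bounded below at 2 years,
#' the youngest age such surveys cover).
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns `subject_id`, `sex`, `age`, `g_day`;
#'   byte-identical across runs with the same config.
#' @examples
#' rec <- generate_recall_sample(synthetic_config(seed = 7, n_subjects = 100))
#' head(rec)
#' @export
generate_recall_sample <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cons <- config$consumption
  out <- vector("list", nrow(cons))
  for (i in seq_len(nrow(cons))) {
    n <- config$n_subjects
    ages <- sample(max(cons$age_low[i], 2):cons$age_high[i], n,
                   replace = TRUE)
    g <- draw_consumption(n, cons$mean_g_day[i], cons$sd_g_day[i],
                          cons$family[i])
    out[[i]] <- data.frame(sex = cons$sex[i], age = ages, g_day = g)
  }
  out <- do.call(rbind, out)
  out <- cbind(subject_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Estimate stratum consumption distributions from recall records
#'
#' Groups records into sex x age-group strata and computes the sample mean,
#' sample SD (n-1 denominator) and the normal-approximation 95% CI of the
#' mean, `mean +/- 1.96 sd / sqrt(n)` — the summary layer that feeds the
#' exposure model.
#'
#' @param records data.frame with columns `sex`, `age`, `g_day` (e.g. from
#'   [generate_recall_sample()]).
#' @param age_groups data.frame with `age_low`, `age_high` defining the
#'   estimation strata (default: the broad survey groups 0-14, 15-44, 45-54,
#'   55-64).
#' @return data.frame with columns `sex`, `age_low`, `age_high`, `n`,
#'   `mean_g_day`, `sd_g_day`, `ci_lower`, `ci_upper`, `family` (`"gamma"`),
#'   ready for [run_scenario()].
#' @examples
#' rec <- data.frame(sex = "male", age = c(30, 40), g_day = c(40, 60))
#' estimate_stratum_distribution(rec)
#' @export
estimate_stratum_distribution <- function(records,
                                          age_groups = SURVEY_AGE_GROUPS) {
  stopifnot(all(c("sex", "age", "g_day") %in% names(records)))
  out <- list()
  for (s in sort(unique(records$sex))) {
    for (i in seq_len(nrow(age_groups))) {
      lo <- age_groups$age_low[i]
      hi <- age_groups$age_high[i]
      g <- records$g_day[records$sex == s & records$age >= lo &
                           records$age <= hi]
      if (length(g) < 2) {
        stop_domain("stratum %s %s has fewer than 2 records",
                    s, age_label(lo, hi))
      }
      m <- mean(g)
      sdev <- stats::sd(g)
      half <- 1.96 * sdev / sqrt(length(g))
      out[[length(out) + 1L]] <- data.frame(
        sex = s, age_low = lo, age_high = hi, n = length(g),
        mean_g_day = m, sd_g_day = sdev,
        ci_lower = m - half, ci_upper = m + half, family = "gamma")
    }
  }
  do.call(rbind, out)
}

#' Generate synthetic incidence and population tables
#'
#' Incidence rates rise log-linearly with 5-year age group from the
#' configured anchor (`rate_at_40` at ages 40-44), with optional seeded
#' log-normal noise; population counts follow a geometric pyramid. Both
#' tables span 0-4 through 80+ for both sexes.
#'
#' @param config a [synthetic_config()].
#' @return list with `incidence` (`sex`, `age_low`, `age_high`,
#'   `rate_per_100k`) and `population` (`sex`, `age_low`, `age_high`,
#'   `count`), deterministic given the seed.
#' @examples
#' dem <- generate_demography(synthetic_config(seed = 7))
#' head(dem$incidence)
#' @export
generate_demography <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  lows <- seq(0, 80, by = 5)
  highs <- c(lows[-1] - 1, Inf)
  anchor_idx <- which(lows == 40)
  out_inc <- list()
  out_pop <- list()
  for (s in c("female", "male")) {
    curve <- config$rate_at_40 *
      exp(config$rate_slope * (seq_along(lows) - anchor_idx))
    if (config$rate_noise_sd > 0) {
      curve <- curve * exp(stats::rnorm(length(curve), 0,
                                        config$rate_noise_sd))
    }
    counts <- config$pop_base * config$pop_decay^(seq_along(lows) - 1)
    out_inc[[s]] <- data.frame(sex = s, age_low = lows, age_high = highs,
                               rate_per_100k = curve)
    out_pop[[s]] <- data.frame(sex = s, age_low = lows, age_high = highs,
                               count = round(counts))
  }
  list(incidence = do.call(rbind, c(out_inc, make.row.names = FALSE)),
       population = do.call(rbind, c(out_pop, make.row.names = FALSE)))
}

#' Generate a complete synthetic input set
#'
#' Convenience wrapper: draws the recall sample, estimates the stratum
#' exposure table from it, and generates the demography tables — everything
#' [run_scenario()] needs.
#'
#' @param config a [synthetic_config()].
#' @return list with `exposure`, `incidence`, `population`, `rr` (the truth
#'   spec) and `config`.
#' @examples
#' syn <- synthetic_inputs(synthetic_config(seed = 1, n_subjects = 500))
#' names(syn)
#' @export
synthetic_inputs <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  records <- generate_recall_sample(config)
  exposure <- estimate_stratum_distribution(records)
  dem <- generate_demography(config)
  list(exposure = exposure, incidence = dem$incidence,
       population = dem$population, rr = config$rr, config = config)
}
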