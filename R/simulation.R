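# Scenario engine: calibrate stratum baselines from observed incidence and
# current exposure, apply a counterfactual exposure transform, and aggregate
# cases, age-standardized rates and PAFs.
#
# The engine is a single-year PAF calculator: reference and intervention are
# evaluated on the same year's population and rates, and latency is a no-op
# hook (latency 0) unless a multi-year result stream is supplied to
# apply_latency(). Per stratum with observed rate r and population-average
# relative risk E[RR] under current exposure, the zero-exposure baseline is
# r0 = r / E[RR]; the intervention rate is r0 * E[RR | transformed exposure].
# PAFs are computed from summed expected case counts per sex; ASRs are
# reported separately.

#' Counterfactual exposure scenario
#'
#' @param name scenario label.
#' @param transform `"identity"` (reference scenario), `"zero"` (eliminate
#'   consumption) or `"scale"` (multiply consumption by `scale_factor`).
#' @param scale_factor required for `transform = "scale"`; in `[0, 1]`.
#' @param year calendar year label (bookkeeping only).
#' @param latency_years integer >= 0; 0 (the default) makes intervention
#'   effects immediate, reducing the model to a pure PAF calculation.
#' @return an object of class `paf_scenario`.
#' @examples
#' scenario("eliminate", "zero", year = 2010)
#' @export
scenario <- function(name = transform, transform = c("identity", "zero", "scale"),
                     scale_factor = NULL, year = 2010, latency_years = 0) {
  transform <- match.arg(transform)
  if (transform == "scale") {
    if (is.null(scale_factor) || !is.numeric(scale_factor) ||
        scale_factor < 0 || scale_factor > 1) {
      stop_config("scale transform requires scale_factor in [0, 1]")
    }
  }
  if (!is.numeric(latency_years) || latency_years < 0 ||
      latency_years != round(latency_years)) {
    stop_domain("latency_years must be a non-negative integer")
  }
  structure(
    list(name = name, transform = transform, scale_factor = scale_factor,
         year = year, latency_years = as.integer(latency_years)),
    class = "paf_scenario"
  )
}

#' Zero-exposure baseline rate from an observed rate
#'
#' Inverts the population-average relative risk: `r0 = observed / E[RR]`, the
#' rate the stratum would have at zero exposure. Re-applying the current
#' exposure's E[RR] to `r0` reproduces the observed rate exactly, which is the
#' engine's calibration-consistency guarantee.
#'
#' @param observed_rate observed incidence rate per 100,000 (>= 0).
#' @param pop_mean_rr population-average relative risk (> 0) from [mean_rr()].
#' @return baseline rate per 100,000.
#' @examples
#' calibrate_baseline(11.7, 1.17)  # 10
#' @export
calibrate_baseline <- function(observed_rate, pop_mean_rr) {
  if (!is.numeric(pop_mean_rr) || any(pop_mean_rr <= 0)) {
    stop_domain("population mean RR must be > 0")
  }
  if (!is.numeric(observed_rate) || any(observed_rate < 0)) {
    stop_domain("observed rate must be >= 0")
  }
  observed_rate / pop_mean_rr
}

#' PAF from reference and intervention case counts
#'
#' @param reference_cases expected cases under the reference scenario (> 0).
#' @param intervention_cases expected cases under the intervention, in
#'   `[0, reference_cases]`.
#' @return the attributable fraction `(reference - intervention) / reference`.
#'   Display as an integer percentage with `round_half_up(100 * paf)`.
#' @examples
#' paf_from_counts(2480, 2149)                   # 0.1335
#' round_half_up(100 * paf_from_counts(2480, 2149))  # 13
#' @export
paf_from_counts <- function(reference_cases, intervention_cases) {
  if (any(reference_cases <= 0)) {
    stop_domain("PAF undefined: reference cases must be > 0")
  }
  if (any(intervention_cases < 0) ||
      any(intervention_cases > reference_cases)) {
    stop_domain("intervention cases must lie in [0, reference cases]")
  }
  (reference_cases - intervention_cases) / reference_cases
}

# Coerce an exposure input (data.frame in the exposure CSV dialect, a single
# exposure_dist, or a list of them) to a list of exposure_dist objects.
as_exposure_list <- function(exposures) {
  if (inherits(exposures, "exposure_dist")) return(list(exposures))
  if (is.data.frame(exposures)) {
    fam <- if ("family" %in% names(exposures)) exposures$family else
      rep("gamma", nrow(exposures))
    return(lapply(seq_len(nrow(exposures)), function(i) {
      exposure_distribution(exposures$sex[i], exposures$age_low[i],
                            exposures$age_high[i],
                            mean = exposures$mean_g_day[i],
                            sd = exposures$sd_g_day[i], family = fam[i])
    }))
  }
  if (is.list(exposures) &&
      all(vapply(exposures, inherits, logical(1), "exposure_dist"))) {
    return(exposures)
  }
  stop_config("exposures must be a data.frame or exposure_distribution list")
}

# Assign each incidence/population stratum (5-year group) the exposure
# distribution of the broad survey age group containing its lower bound.
# Strata older than the oldest surveyed group inherit the oldest group's
# distribution (and younger ones the youngest's) when extend_ages = TRUE,
# reflecting surveys that measure consumption over a narrower age range than
# the registry covers.
match_exposure <- function(dists, sex, age_low, extend_ages = TRUE) {
  cand <- dists[vapply(dists, function(d) d$sex == sex, logical(1))]
  if (!length(cand)) {
    stop_alignment("no exposure distribution for sex %s", sex)
  }
  hit <- Filter(function(d) age_low >= d$age_low && age_low <= d$age_high,
                cand)
  if (length(hit)) return(hit[[1]])
  if (!extend_ages) {
    stop_alignment("no exposure distribution covers sex %s age %d",
                   sex, age_low)
  }
  lows <- vapply(cand, `[[`, numeric(1), "age_low")
  highs <- vapply(cand, `[[`, numeric(1), "age_high")
  if (age_low > max(highs)) cand[[which.max(highs)]]
  else cand[[which.min(lows)]]
}

#' Run a counterfactual exposure scenario
#'
#' For each sex/age stratum the engine discretizes the current exposure
#' distribution, computes its population-average relative risk, calibrates the
#' zero-exposure baseline rate from the observed incidence, applies the
#' scenario's exposure transform, and recomputes the incidence rate. Results
#' are aggregated to expected case counts and Segi age-standardized rates per
#' sex; the PAF is the avoided-case fraction.
#'
#' @param exposures exposure strata: a data.frame with columns `sex`,
#'   `age_low`, `age_high`, `mean_g_day`, `sd_g_day` (optional `family`), or a
#'   list of [exposure_distribution()] objects. Broad survey age groups are
#'   broadcast to the finer incidence strata by assignment.
#' @param risk_function a `loglinear_rr` from [fit_loglinear()].
#' @param rates incidence data.frame (`sex`, `age_low`, `age_high`,
#'   `rate_per_100k`).
#' @param pop population data.frame (`sex`, `age_low`, `age_high`, `count`).
#' @param scn a [scenario()].
#' @param standard standard population for ASRs (default [segi_standard()]).
#' @param upper_quantile grid extent passed to [discretize()].
#' @param extend_ages broadcast exposure beyond the surveyed age range
#'   (default `TRUE`).
#' @return an object of class `scenario_result`: list with `by_sex` (per-sex
#'   reference/intervention cases, avoided cases, `paf`, reference and
#'   intervention ASRs), `by_stratum` (per-stratum rates, mean RRs, baseline
#'   and intervention rates, cases), `calibration` (risk-function constants),
#'   `scenario`, `risk_function`.
#' @examples
#' syn <- synthetic_inputs(synthetic_config(seed = 1, n_subjects = 500))
#' rf <- fit_loglinear(rr_spec("red_meat", 1.17, reference_dose = 100))
#' res <- run_scenario(syn$exposure, rf, syn$incidence, syn$population,
#'                     scenario("eliminate", "zero"))
#' res$by_sex
#' @export
run_scenario <- function(exposures, risk_function, rates, pop, scn,
                         standard = segi_standard(),
                         upper_quantile = 0.999, extend_ages = TRUE) {
  stopifnot(inherits(risk_function, "loglinear_rr"),
            inherits(scn, "paf_scenario"))
  dists <- as_exposure_list(exposures)
  cases_ref <- expected_cases(rates, pop)  # validates + aligns

  step <- risk_function$step
  n <- nrow(cases_ref)
  mean_rr_ref <- numeric(n)
  mean_rr_int <- numeric(n)
  for (i in seq_len(n)) {
    d <- match_exposure(dists, cases_ref$sex[i], cases_ref$age_low[i],
                        extend_ages = extend_ages)
    cats <- discretize(d, step = step, upper_quantile = upper_quantile)
    mean_rr_ref[i] <- mean_rr(cats, risk_function)
    if (scn$transform == "identity") {
      mean_rr_int[i] <- mean_rr_ref[i]
    } else {
      d_int <- transform_exposure(d, scn$transform, scn$scale_factor)
      cats_int <- discretize(d_int, step = step,
                             upper_quantile = upper_quantile)
      mean_rr_int[i] <- mean_rr(cats_int, risk_function)
    }
  }

  by_stratum <- cases_ref
  attr(by_stratum, "totals") <- NULL
  by_stratum$mean_rr_reference <- mean_rr_ref
  by_stratum$mean_rr_intervention <- mean_rr_int
  by_stratum$baseline_rate <- calibrate_baseline(by_stratum$rate_per_100k,
                                                 mean_rr_ref)
  # identity is a true no-op: keep the observed rate bit-for-bit rather than
  # round-tripping it through (rate / E[RR]) * E[RR]
  by_stratum$intervention_rate <- if (scn$transform == "identity") {
    by_stratum$rate_per_100k
  } else {
    by_stratum$baseline_rate * mean_rr_int
  }
  by_stratum$reference_cases <- by_stratum$cases
  by_stratum$intervention_cases <-
    by_stratum$intervention_rate * by_stratum$count / 1e5
  by_stratum$cases <- NULL

  int_rates <- data.frame(sex = by_stratum$sex, age_low = by_stratum$age_low,
                          age_high = by_stratum$age_high,
                          rate_per_100k = by_stratum$intervention_rate)
  asr_ref <- age_standardize(rates, standard)
  asr_int <- age_standardize(int_rates, standard)

  sexes <- sort(unique(by_stratum$sex))
  ref_tot <- vapply(sexes, function(s)
    sum(by_stratum$reference_cases[by_stratum$sex == s]), numeric(1))
  int_tot <- vapply(sexes, function(s)
    sum(by_stratum$intervention_cases[by_stratum$sex == s]), numeric(1))
  by_sex <- data.frame(
    sex = sexes,
    reference_cases = ref_tot,
    intervention_cases = int_tot,
    avoided_cases = ref_tot - int_tot,
    paf = ifelse(ref_tot > 0, (ref_tot - int_tot) / ref_tot, 0),
    reference_asr = asr_ref[sexes],
    intervention_asr = asr_int[sexes],
    row.names = NULL
  )

  calibration <- data.frame(
    risk_factor = risk_function$risk_factor,
    which_rr = risk_function$which,
    beta_per_g_day = risk_function$beta,
    intercept = risk_function$intercept,
    reference_dose_g_day = risk_function$reference_dose,
    step_g_day = step
  )

  structure(
    list(by_sex = by_sex, by_stratum = by_stratum, calibration = calibration,
         scenario = scn, risk_function = risk_function),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s transform), %s: %s\n",
              x$scenario$name, x$scenario$transform, x$scenario$year,
              x$risk_function$risk_factor))
  df <- x$by_sex
  df$paf_pct <- round_half_up(100 * df$paf)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Sensitivity analysis across relative-risk confidence bounds
#'
#' Runs the scenario three times with risk functions calibrated to the lower,
#' central and upper relative risks of the spec, holding exposure, incidence
#' and population fixed. Because a larger RR removes more cases, the lower
#' intervention-case bound pairs with the upper PAF bound.
#'
#' @param exposures,rates,pop,scn,... as in [run_scenario()].
#' @param spec an [rr_spec()] carrying `rr_lower`, `rr_central`, `rr_upper`.
#' @param step dose grid width passed to [fit_loglinear()].
#' @return an object of class `sensitivity_result`: the central
#'   `scenario_result` plus `lower`/`upper` runs, and a `by_sex` table
#'   augmented with `paf_lower`, `paf_upper`, `intervention_cases_lower`
#'   (fewest cases, from the upper RR) and `intervention_cases_upper`.
#' @examples
#' syn <- synthetic_inputs(synthetic_config(seed = 1, n_subjects = 500))
#' spec <- rr_spec("red_meat", 1.17, 1.05, 1.31, reference_dose = 100)
#' sens <- sensitivity_run(syn$exposure, spec, syn$incidence,
#'                         syn$population, scenario("eliminate", "zero"))
#' sens$by_sex[, c("sex", "paf_lower", "paf", "paf_upper")]
#' @export
sensitivity_run <- function(exposures, spec, rates, pop, scn, step = 20, ...) {
  stopifnot(inherits(spec, "rr_spec"))
  runs <- lapply(c("lower", "central", "upper"), function(w) {
    run_scenario(exposures, fit_loglinear(spec, which = w, step = step),
                 rates, pop, scn, ...)
  })
  names(runs) <- c("lower", "central", "upper")
  by_sex <- runs$central$by_sex
  by_sex$paf_lower <- runs$lower$by_sex$paf
  by_sex$paf_upper <- runs$upper$by_sex$paf
  # fewer intervention cases <-> larger PAF
  by_sex$intervention_cases_lower <- runs$upper$by_sex$intervention_cases
  by_sex$intervention_cases_upper <- runs$lower$by_sex$intervention_cases
  structure(
    list(by_sex = by_sex, central = runs$central, lower = runs$lower,
         upper = runs$upper, spec = spec),
    class = "sensitivity_result"
  )
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sensitivity analysis: %s, RR %g (%g-%g) per %g g/day\n",
              x$spec$risk_factor, x$spec$rr_central, x$spec$rr_lower,
              x$spec$rr_upper, x$spec$reference_dose))
  df <- x$by_sex
  df$paf_pct <- sprintf("%d (%d-%d)", round_half_up(100 * df$paf),
                        round_half_up(100 * df$paf_lower),
                        round_half_up(100 * df$paf_upper))
  print(df[, c("sex", "reference_cases", "intervention_cases",
               "intervention_cases_lower", "intervention_cases_upper",
               "paf_pct")],
        row.names = FALSE, digits = 5)
  invisible(x)
}

#' Apply a latency delay to a multi-year result stream
#'
#' With latency L, the intervention's rate change is delayed by L years: for
#' the first L years of the stream every `intervention_*` column is replaced
#' by its `reference_*` counterpart. Latency 0 is the identity, which is the
#' configuration of a pure same-year PAF analysis.
#'
#' @param stream data.frame with a `year` column and paired
#'   `reference_*` / `intervention_*` columns.
#' @param latency_years integer >= 0.
#' @return the stream with delayed intervention columns.
#' @examples
#' s <- data.frame(year = 2010:2014, reference_cases = 100,
#'                 intervention_cases = 80)
#' apply_latency(s, 2)$intervention_cases  # 100 100 80 80 80
#' @export
apply_latency <- function(stream, latency_years) {
  if (!is.numeric(latency_years) || latency_years < 0 ||
      latency_years != round(latency_years)) {
    stop_domain("latency_years must be a non-negative integer")
  }
  if (latency_years == 0) return(stream)
  stopifnot(is.data.frame(stream), "year" %in% names(stream))
  int_cols <- grep("^intervention_", names(stream), value = TRUE)
  ref_cols <- sub("^intervention_", "reference_", int_cols)
  if (!all(ref_cols %in% names(stream))) {
    stop_config("stream lacks reference_* counterparts for: %s",
                paste(setdiff(ref_cols, names(stream)), collapse = ", "))
  }
  years <- sort(unique(stream$year))
  delayed <- stream$year %in% years[seq_len(min(latency_years, length(years)))]
  for (i in seq_along(int_cols)) {
    stream[[int_cols[i]]][delayed] <- stream[[ref_cols[i]]][delayed]
  }
  stream
}
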