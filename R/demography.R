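# Age/sex rate and population tables, expected case counts, and direct age
# standardization against the Segi world standard.
#
# Tables are plain data.frames with columns sex, age_low, age_high plus a
# value column (rate_per_100k or count); age groups are 5-year bands 0-4 ..
# 80+ (or 85+). Validators check the partition once so downstream arithmetic
# can stay simple.

# Canonical Segi world standard, per 100,000, ages 0-4 through 85+.
SEGI_WEIGHTS <- c(12000, 10000, 9000, 9000, 8000, 8000, 6000, 6000, 6000,
                  6000, 5000, 4000, 4000, 3000, 2000, 1000, 500, 500)

#' Segi world standard population
#'
#' The classical Segi world standard used for direct age standardization,
#' expressed per 100,000 of standard population across 5-year age groups.
#'
#' @param top_age lower bound of the open-ended top group: `85` for the full
#'   18-group standard (0-4 ... 85+), or `80` (default) to merge 85+ into 80+
#'   (final weight 1000) for rate tables that stop at 80+.
#' @return a data.frame with columns `age_low`, `age_high`, `weight`; weights
#'   sum to 100,000.
#' @examples
#' sum(segi_standard()$weight)  # 100000
#' @export
segi_standard <- function(top_age = 80) {
  if (!top_age %in% c(80, 85)) {
    stop_config("top_age must be 80 or 85")
  }
  lows <- seq(0, 85, by = 5)
  w <- SEGI_WEIGHTS
  if (top_age == 80) {
    w <- c(w[1:16], w[17] + w[18])
    lows <- lows[1:17]
  }
  data.frame(
    age_low = lows,
    age_high = c(lows[-1] - 1, Inf),
    weight = w
  )
}

# Validate a sex/age-stratified table: required columns, non-negative values,
# and a non-overlapping exhaustive age partition within each sex.
validate_strat_table <- function(df, value_col, what) {
  required <- c("sex", "age_low", "age_high", value_col)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_config("%s table is missing column(s): %s", what,
                paste(missing_cols, collapse = ", "))
  }
  if (any(df[[value_col]] < 0, na.rm = TRUE) || anyNA(df[[value_col]])) {
    stop_domain("%s table contains negative or missing values", what)
  }
  for (s in unique(df$sex)) {
    sub <- df[df$sex == s, ]
    sub <- sub[order(sub$age_low), ]
    if (anyDuplicated(sub$age_low)) {
      stop_config("%s table has duplicated age groups for sex %s", what, s)
    }
    finite_high <- sub$age_high[-nrow(sub)]
    if (nrow(sub) > 1 && any(finite_high + 1 != sub$age_low[-1])) {
      stop_config("%s table age groups do not partition ages for sex %s",
                  what, s)
    }
  }
  df
}

#' Expected case counts from rates and population
#'
#' Per-stratum expected annual cases, `rate x count / 100000`, with totals by
#' sex stored as an attribute (also retrievable with [case_totals()]).
#'
#' @param rates data.frame with columns `sex`, `age_low`, `age_high`,
#'   `rate_per_100k`.
#' @param pop data.frame with columns `sex`, `age_low`, `age_high`, `count`.
#'   Strata must match `rates` exactly; a mismatch raises an alignment error
#'   listing the missing strata.
#' @return the merged data.frame with an added `cases` column and a `totals`
#'   attribute (named numeric, one element per sex).
#' @examples
#' rates <- data.frame(sex = "male", age_low = 0, age_high = Inf,
#'                     rate_per_100k = 10)
#' pop <- data.frame(sex = "male", age_low = 0, age_high = Inf,
#'                   count = 1e6)
#' expected_cases(rates, pop)$cases  # 100
#' @export
expected_cases <- function(rates, pop) {
  rates <- validate_strat_table(rates, "rate_per_100k", "incidence")
  pop <- validate_strat_table(pop, "count", "population")
  rk <- stratum_key(rates$sex, rates$age_low)
  pk <- stratum_key(pop$sex, pop$age_low)
  missing_in_pop <- setdiff(rk, pk)
  missing_in_rates <- setdiff(pk, rk)
  if (length(missing_in_pop) || length(missing_in_rates)) {
    stop_alignment(
      "incidence/population strata mismatch; missing in population: [%s]; missing in incidence: [%s]",
      paste(missing_in_pop, collapse = ", "),
      paste(missing_in_rates, collapse = ", "))
  }
  out <- merge(rates, pop[, c("sex", "age_low", "count")],
               by = c("sex", "age_low"))
  out <- out[order(out$sex, out$age_low), ]
  rownames(out) <- NULL
  out$cases <- out$rate_per_100k * out$count / 1e5
  totals <- tapply(out$cases, out$sex, sum)
  attr(out, "totals") <- c(totals)
  out
}

#' Totals by sex from an expected-cases table
#'
#' @param cases result of [expected_cases()].
#' @return named numeric vector of total cases per sex.
#' @export
case_totals <- function(cases) {
  tot <- attr(cases, "totals")
  if (is.null(tot)) tot <- c(tapply(cases$cases, cases$sex, sum))
  tot
}

#' Directly age-standardized rate
#'
#' Computes the Segi-standardized rate `sum_a w_a r_a / sum_a w_a` per
#' 100,000 person-years, separately for each sex present in the table.
#'
#' @param rates data.frame with columns `sex`, `age_low`, `age_high`,
#'   `rate_per_100k`, covering every standard age group (matched on
#'   `age_low`).
#' @param std standard population data.frame from [segi_standard()] or a
#'   compatible `age_low`/`weight` table.
#' @param zero_fill if `TRUE`, standard age groups missing from the rate
#'   table count as rate 0 (with a message); if `FALSE` (default) they raise
#'   a coverage error.
#' @return named numeric vector of ASRs per 100,000, one element per sex.
#' @examples
#' rates <- do.call(rbind, lapply(seq(0, 80, 5), function(a)
#'   data.frame(sex = "male", age_low = a,
#'              age_high = if (a == 80) Inf else a + 4, rate_per_100k = 7)))
#' age_standardize(rates, segi_standard())  # 7: uniform rates pass through
#' @export
age_standardize <- function(rates, std = segi_standard(), zero_fill = FALSE) {
  rates <- validate_strat_table(rates, "rate_per_100k", "incidence")
  out <- vapply(sort(unique(rates$sex)), function(s) {
    sub <- rates[rates$sex == s, ]
    idx <- match(std$age_low, sub$age_low)
    if (anyNA(idx)) {
      missing_groups <- age_label(std$age_low[is.na(idx)],
                                  std$age_high[is.na(idx)])
      if (!zero_fill) {
        stop_alignment("rate table (sex %s) does not cover standard age group(s): %s",
                       s, paste(missing_groups, collapse = ", "))
      }
      message(sprintf("age_standardize: zero-filling %d uncovered group(s) for sex %s: %s",
                      sum(is.na(idx)), s,
                      paste(missing_groups, collapse = ", ")))
    }
    r <- ifelse(is.na(idx), 0, sub$rate_per_100k[idx])
    sum(std$weight * r) / sum(std$weight)
  }, numeric(1))
  out
}
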