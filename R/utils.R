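# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (so 0.1345 at 3 d.p. is
#' 0.135 and 14.5% rounds to 15%), matching the display convention of the
#' published risk-function and PAF tables. `base::round()` uses banker's
#' rounding and would disagree on exact ties.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(14.5)        # 15
#' round_half_up(-0.1575, 3)  # -0.158
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Structured condition constructors. Each command maps these classes to exit
# codes (config 2, alignment 3, io 4).
stop_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pafsim_domain_error", "pafsim_error")))
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pafsim_config_error", "pafsim_error")))
}

stop_alignment <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pafsim_alignment_error", "pafsim_error")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pafsim_io_error", "pafsim_error")))
}

# Format an age group as "low-high" or "low+" for open-ended groups.
age_label <- function(age_low, age_high) {
  ifelse(is.finite(age_high),
         paste0(age_low, "-", age_high),
         paste0(age_low, "+"))
}

# Stratum key used for alignment checks.
stratum_key <- function(sex, age_low) paste(sex, age_low, sep = ":")
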