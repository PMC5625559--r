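# Log-linear dose-response relative-risk functions.
#
# The dose-response model is ln RR(x) = beta * x with beta = ln(RR_ref) / d_ref,
# so that RR at the reference dose d_ref reproduces the meta-analytic relative
# risk and RR(0) = 1. The "intercept" reported alongside published risk
# functions is -ln(RR_ref): the log-risk change from the reference dose down to
# zero exposure (negative for harmful exposures).

#' Meta-analytic relative-risk specification
#'
#' Bundles a central relative risk with its 95% confidence bounds at a stated
#' reference dose. This is the calibration input for [fit_loglinear()]: the
#' central RR drives the main analysis and the bounds drive the sensitivity
#' runs.
#'
#' @param risk_factor character label, e.g. `"red_meat"` or `"processed_meat"`.
#' @param rr_central relative risk at `reference_dose` (dimensionless, > 0).
#' @param rr_lower,rr_upper 95% confidence bounds for `rr_central`. Default to
#'   `rr_central` (degenerate interval) so single-RR calibration works.
#' @param reference_dose dose at which the RRs apply, in g/day (> 0).
#' @param sex `"male"`, `"female"` or `"both"`.
#' @return an object of class `rr_spec`.
#' @examples
#' rr_spec("red_meat", 1.17, 1.05, 1.31, reference_dose = 100)
#' @seealso [fit_loglinear()], [rescale_rr_dose()]
#' @export
rr_spec <- function(risk_factor, rr_central, rr_lower = rr_central,
                    rr_upper = rr_central, reference_dose = 100,
                    sex = "both") {
  stopifnot(is.character(risk_factor), length(risk_factor) == 1L)
  for (v in c(rr_central = rr_central, rr_lower = rr_lower,
              rr_upper = rr_upper)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop_domain("relative risks for '%s' must be positive finite numbers",
                  risk_factor)
    }
  }
  if (rr_lower > rr_central || rr_central > rr_upper) {
    stop_domain("'%s': requires rr_lower <= rr_central <= rr_upper (got %g, %g, %g)",
                risk_factor, rr_lower, rr_central, rr_upper)
  }
  if (!is.numeric(reference_dose) || reference_dose <= 0) {
    stop_domain("'%s': reference_dose must be > 0 g/day", risk_factor)
  }
  sex <- match.arg(sex, c("male", "female", "both"))
  structure(
    list(risk_factor = risk_factor, rr_central = rr_central,
         rr_lower = rr_lower, rr_upper = rr_upper,
         reference_dose = reference_dose, sex = sex),
    class = "rr_spec"
  )
}

#' @export
print.rr_spec <- function(x, ...) {
  cat(sprintf("Relative-risk spec: %s (%s)\n", x$risk_factor, x$sex))
  cat(sprintf("  RR %.3g (95%% CI %.3g-%.3g) per %g g/day\n",
              x$rr_central, x$rr_lower, x$rr_upper, x$reference_dose))
  invisible(x)
}

#' Intercept of a log-linear risk function
#'
#' Returns `-ln(rr)`, the log relative risk change implied by moving from the
#' reference dose to zero exposure. Negative for harmful exposures (RR > 1),
#' zero for a null association. Full precision is retained; round only for
#' display (published tables print 3 decimal places).
#'
#' @param rr relative risk at the reference dose (> 0).
#' @param risk_factor optional label used in error messages.
#' @return the intercept, dimensionless.
#' @examples
#' intercept_from_rr(1.17)  # -0.157 to 3 d.p.
#' intercept_from_rr(1.35)  # -0.300
#' @export
intercept_from_rr <- function(rr, risk_factor = NULL) {
  if (!is.numeric(rr) || any(!is.finite(rr)) || any(rr <= 0)) {
    stop_domain("relative risk for '%s' must be > 0 (got %s)",
                if (is.null(risk_factor)) "exposure" else risk_factor,
                paste(format(rr), collapse = ", "))
  }
  -log(rr)
}

#' Rescale a relative risk to a different reference dose
#'
#' Under the log-linear model, an RR quoted per `dose_from` g/day corresponds
#' to `rr^(dose_to / dose_from)` per `dose_to` g/day. This is the exact
#' transformation; published tables sometimes print hand-transformed values
#' that differ slightly, and those can instead be supplied directly to
#' [rr_spec()].
#'
#' @param rr relative risk (> 0) at `dose_from`.
#' @param dose_from,dose_to doses in g/day (> 0).
#' @return the rescaled relative risk.
#' @examples
#' rescale_rr_dose(1.17, 50, 100)   # 1.3689
#' rescale_rr_dose(1.17, 100, 50)   # sqrt(1.17)
#' @export
rescale_rr_dose <- function(rr, dose_from, dose_to) {
  if (!is.numeric(rr) || any(rr <= 0)) stop_domain("rr must be > 0")
  if (!is.numeric(dose_from) || any(dose_from <= 0) ||
      !is.numeric(dose_to) || any(dose_to <= 0)) {
    stop_domain("doses must be > 0 g/day")
  }
  rr^(dose_to / dose_from)
}

#' Calibrate a log-linear risk function from a relative-risk spec
#'
#' Fits `ln RR(x) = beta * x` with `beta = ln(rr) / reference_dose`, where `rr`
#' is the chosen bound of the spec (central for the main analysis, lower/upper
#' for sensitivity runs). The intercept `-ln(rr)` is stored for reporting.
#'
#' @param spec an [rr_spec()].
#' @param which which RR to calibrate to: `"central"` (default), `"lower"` or
#'   `"upper"`.
#' @param step dose grid width in g/day used when discretizing exposures
#'   (default 20).
#' @return an object of class `loglinear_rr` with fields `beta` (per g/day),
#'   `intercept`, `reference_dose`, `step`, `risk_factor`, `which`.
#' @examples
#' rf <- fit_loglinear(rr_spec("red_meat", 1.17, reference_dose = 100))
#' rf$beta               # ln(1.17)/100
#' rr_at_dose(rf, 100)   # 1.17
#' @export
fit_loglinear <- function(spec, which = c("central", "lower", "upper"),
                          step = 20) {
  stopifnot(inherits(spec, "rr_spec"))
  which <- match.arg(which)
  rr <- switch(which, central = spec$rr_central, lower = spec$rr_lower,
               upper = spec$rr_upper)
  intercept <- intercept_from_rr(rr, spec$risk_factor)
  if (!is.numeric(step) || step <= 0) stop_domain("step must be > 0 g/day")
  structure(
    list(beta = log(rr) / spec$reference_dose, intercept = intercept,
         reference_dose = spec$reference_dose, step = step,
         risk_factor = spec$risk_factor, which = which),
    class = "loglinear_rr"
  )
}

#' Evaluate a log-linear risk function at a dose
#'
#' @param rf a `loglinear_rr` from [fit_loglinear()].
#' @param dose dose(s) in g/day, >= 0.
#' @return relative risk(s) `exp(beta * dose)`; exactly 1 at dose 0.
#' @examples
#' rf <- fit_loglinear(rr_spec("red_meat", 1.17, reference_dose = 100))
#' rr_at_dose(rf, c(0, 50, 100))
#' @export
rr_at_dose <- function(rf, dose) {
  stopifnot(inherits(rf, "loglinear_rr"))
  if (!is.numeric(dose) || any(dose < 0)) {
    stop_domain("dose must be >= 0 g/day")
  }
  exp(rf$beta * dose)
}

#' @export
print.loglinear_rr <- function(x, ...) {
  cat(sprintf("Log-linear risk function: %s (%s RR)\n", x$risk_factor, x$which))
  cat(sprintf("  beta      %.6g per g/day\n", x$beta))
  cat(sprintf("  intercept %.3f  (-ln RR at %g g/day)\n",
              round_half_up(x$intercept, 3), x$reference_dose))
  cat(sprintf("  step      %g g/day\n", x$step))
  invisible(x)
}
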