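# Stratified consumption distributions and their discretization into dose
# categories.
#
# Survey inputs give only a mean and SD of g/day consumption per sex x age
# group stratum. A parametric family turns each (mean, sd) pair into a full
# distribution; the default is gamma by method of moments (shape = mean^2/sd^2,
# scale = sd^2/mean), appropriate for non-negative, right-skewed 24-h-recall
# intake where SDs run near or above the means. The distribution is then cut
# into uniform dose bins (default 20 g/day) whose prevalences feed the
# population-average relative risk E[RR] = sum_i p_i exp(beta x_i).

EXPOSURE_FAMILIES <- c("gamma", "truncated_normal", "point_mass")

#' Stratified exposure distribution
#'
#' One stratum's consumption distribution, parameterized by its mean and SD in
#' g/day plus a distribution family.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_low,age_high integer age bounds in years (closed-closed);
#'   `age_high = Inf` for an open-ended group.
#' @param mean mean consumption in g/day (>= 0).
#' @param sd standard deviation in g/day (>= 0). `sd = 0` forces the
#'   `point_mass` family and vice versa.
#' @param family `"gamma"` (default), `"truncated_normal"` (normal truncated
#'   at 0 and renormalized) or `"point_mass"`.
#' @return an object of class `exposure_dist`.
#' @examples
#' exposure_distribution("male", 15, 44, mean = 62.4, sd = 55)
#' @export
exposure_distribution <- function(sex, age_low, age_high, mean, sd,
                                  family = "gamma") {
  sex <- match.arg(sex, c("male", "female"))
  family <- match.arg(family, EXPOSURE_FAMILIES)
  if (!is.numeric(mean) || mean < 0) stop_domain("mean must be >= 0 g/day")
  if (!is.numeric(sd) || sd < 0) stop_domain("sd must be >= 0 g/day")
  if (sd == 0) family <- "point_mass"
  if (family == "point_mass" && sd != 0) {
    stop_domain("point_mass family requires sd = 0")
  }
  if (family == "gamma" && mean == 0) {
    stop_domain("gamma family requires mean > 0 (stratum %s %s)",
                sex, age_label(age_low, age_high))
  }
  structure(
    list(sex = sex, age_low = age_low, age_high = age_high,
         mean = mean, sd = sd, family = family),
    class = "exposure_dist"
  )
}

# Distribution function of the family on [0, Inf).
exposure_cdf <- function(dist, q) {
  switch(dist$family,
    gamma = {
      shape <- dist$mean^2 / dist$sd^2
      scale <- dist$sd^2 / dist$mean
      stats::pgamma(q, shape = shape, scale = scale)
    },
    truncated_normal = {
      z0 <- stats::pnorm(0, dist$mean, dist$sd)
      (stats::pnorm(q, dist$mean, dist$sd) - z0) / (1 - z0)
    },
    point_mass = as.numeric(q >= dist$mean)
  )
}

exposure_quantile <- function(dist, p) {
  switch(dist$family,
    gamma = {
      shape <- dist$mean^2 / dist$sd^2
      scale <- dist$sd^2 / dist$mean
      stats::qgamma(p, shape = shape, scale = scale)
    },
    truncated_normal = {
      z0 <- stats::pnorm(0, dist$mean, dist$sd)
      stats::qnorm(z0 + p * (1 - z0), dist$mean, dist$sd)
    },
    point_mass = dist$mean
  )
}

# E[X | X > a] for the family; used as the midpoint of the open tail bin so
# that the exponentially growing RR is not evaluated at an arbitrary center.
tail_conditional_mean <- function(dist, a) {
  switch(dist$family,
    gamma = {
      shape <- dist$mean^2 / dist$sd^2
      scale <- dist$sd^2 / dist$mean
      upper <- stats::pgamma(a, shape = shape, scale = scale,
                             lower.tail = FALSE)
      # identity: E[X 1{X>a}] = mean * P(Gamma(shape+1, scale) > a)
      dist$mean *
        stats::pgamma(a, shape = shape + 1, scale = scale,
                      lower.tail = FALSE) / upper
    },
    truncated_normal = {
      # conditional on X > a >= 0 the truncation at 0 is irrelevant
      alpha <- (a - dist$mean) / dist$sd
      dist$mean + dist$sd * stats::dnorm(alpha) / stats::pnorm(alpha,
                                                              lower.tail = FALSE)
    },
    point_mass = dist$mean
  )
}

#' Discretize an exposure distribution into dose categories
#'
#' Cuts the distribution into uniform bins `[0, step), [step, 2 step), ...`
#' extending to the distribution's `upper_quantile` quantile; the final bin is
#' open-ended and absorbs the remaining tail mass. Prevalences are exact CDF
#' differences of the chosen family. Midpoints are bin centers except for the
#' tail bin, which uses the conditional tail mean, and for a point mass, whose
#' bin midpoint is the mass point itself (the conditional mean within the bin).
#'
#' @param dist an [exposure_distribution()].
#' @param step bin width in g/day (> 0, default 20).
#' @param upper_quantile grid extent as a quantile of the distribution, in
#'   `[0.99, 1)` (default 0.999).
#' @return an object of class `exposure_categories` with fields `bin_edges`
#'   (length m+1, last edge `Inf`), `midpoints` and `prevalences` (length m,
#'   summing to 1).
#' @examples
#' d <- exposure_distribution("male", 15, 44, mean = 50, sd = 50)
#' cats <- discretize(d, step = 20)
#' sum(cats$prevalences)
#' @export
discretize <- function(dist, step = 20, upper_quantile = 0.999) {
  stopifnot(inherits(dist, "exposure_dist"))
  if (!is.numeric(step) || step <= 0) stop_domain("step must be > 0 g/day")
  if (upper_quantile < 0.99 || upper_quantile >= 1) {
    stop_domain("upper_quantile must be in [0.99, 1)")
  }
  if (dist$family == "point_mass") {
    if (dist$mean < 0) stop_domain("point mass at a negative dose")
    # single occupied bin containing the mass point
    i <- floor(dist$mean / step)
    edges <- c(i * step, (i + 1) * step)
    cats <- list(bin_edges = edges, midpoints = dist$mean, prevalences = 1)
    class(cats) <- "exposure_categories"
    return(cats)
  }
  upper <- exposure_quantile(dist, upper_quantile)
  n_bins <- max(1L, ceiling(upper / step))
  inner_edges <- step * seq(0L, n_bins)
  edges <- c(inner_edges, Inf)
  cdf_vals <- exposure_cdf(dist, inner_edges)
  prev <- diff(c(cdf_vals, 1))
  midpoints <- inner_edges[-length(inner_edges)] + step / 2
  tail_mid <- if (prev[length(prev)] > 0) {
    tail_conditional_mean(dist, inner_edges[length(inner_edges)])
  } else {
    inner_edges[length(inner_edges)]
  }
  midpoints <- c(midpoints, tail_mid)
  prev <- pmax(prev, 0)
  prev <- prev / sum(prev)
  structure(
    list(bin_edges = edges, midpoints = midpoints, prevalences = prev),
    class = "exposure_categories"
  )
}

#' Population-average relative risk over exposure categories
#'
#' Computes `sum_i p_i exp(beta x_i)`, the population-average relative risk of
#' the stratum relative to zero exposure. This is the quantity that links the
#' observed stratum incidence rate to its counterfactual zero-exposure
#' baseline (PAF = 1 - 1/E[RR] in the single-stratum case).
#'
#' @param cats an `exposure_categories` from [discretize()].
#' @param rf a `loglinear_rr` from [fit_loglinear()].
#' @return the population mean RR, >= 1 when `beta >= 0`.
#' @examples
#' d <- exposure_distribution("male", 15, 44, mean = 62.4, sd = 55)
#' rf <- fit_loglinear(rr_spec("red_meat", 1.17, reference_dose = 100))
#' mean_rr(discretize(d), rf)
#' @export
mean_rr <- function(cats, rf) {
  stopifnot(inherits(cats, "exposure_categories"),
            inherits(rf, "loglinear_rr"))
  sum(cats$prevalences * exp(rf$beta * cats$midpoints))
}

# Apply a scenario exposure transform to a distribution.
#   identity -> unchanged; zero -> point mass at 0; scale s -> mean and sd
#   both scaled by s (for the gamma family this rescales theta, preserving
#   shape; s = 0 collapses to a point mass at 0).
transform_exposure <- function(dist, transform, scale_factor = NULL) {
  switch(transform,
    identity = dist,
    zero = exposure_distribution(dist$sex, dist$age_low, dist$age_high,
                                 mean = 0, sd = 0, family = "point_mass"),
    scale = {
      if (is.null(scale_factor) || !is.numeric(scale_factor) ||
          scale_factor < 0 || scale_factor > 1) {
        stop_config("scale transform requires a scale factor in [0, 1]")
      }
      if (scale_factor == 0) {
        transform_exposure(dist, "zero")
      } else {
        exposure_distribution(dist$sex, dist$age_low, dist$age_high,
                              mean = dist$mean * scale_factor,
                              sd = dist$sd * scale_factor,
                              family = dist$family)
      }
    },
    stop_config("unknown exposure transform '%s'", transform)
  )
}

#' @export
print.exposure_dist <- function(x, ...) {
  cat(sprintf("Exposure distribution: %s, ages %s\n",
              x$sex, age_label(x$age_low, x$age_high)))
  cat(sprintf("  %s, mean %.1f g/day, sd %.1f g/day\n",
              x$family, x$mean, x$sd))
  invisible(x)
}
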