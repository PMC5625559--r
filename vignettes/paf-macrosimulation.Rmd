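---
title: "Methods: PAF macro-simulation for continuous dietary exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PAF macro-simulation for continuous dietary exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pafsim)
```

## The model

`pafsim` estimates the fraction of disease incidence attributable to a
continuous exposure by comparing a *reference* scenario (observed
consumption) with a counterfactual *intervention* scenario (consumption
removed or reduced) on the same year's population and incidence — a
single-year potential-impact-fraction calculation in the tradition of
macro-simulation tools used for chronic-disease scenario modelling.

Three assumptions define the risk side:

1. **Log-linear dose response.** ln RR(x) = βx with β = ln(RR_ref)/d_ref,
   calibrated so the meta-analytic RR at the reference dose d_ref is
   reproduced exactly and RR(0) = 1. No threshold, no saturation: each
   additional gram per day multiplies risk by the same factor. The companion
   "intercept" −ln(RR_ref) is only a reporting convention for the log-risk
   decline from d_ref to zero.
2. **Parametric exposure distributions.** Surveys deliver only a mean and SD
   of g/day per sex × age-group stratum. A distribution family turns each
   pair into a full distribution (see *Design choices*).
3. **Multiplicative, immediately reversible risk.** The observed stratum rate
   r factors as r = r₀ · E[RR], where r₀ is the zero-exposure baseline and
   E[RR] = Σᵢ pᵢ exp(βxᵢ) is the population-average relative risk over
   discretized dose categories. Setting exposure to a counterfactual simply
   swaps E[RR]; no latency intervenes (the `apply_latency()` hook exists for
   multi-year streams but the default configuration is zero latency, which
   makes the engine a pure PAF calculator).

PAF per sex is computed from summed expected case counts,
(reference − intervention)/reference, because the published tables this
surface mirrors do their arithmetic on counts; age-standardized rates are
reported separately and their ratio differs slightly from the count-based
PAF whenever the population age structure differs from the standard.

## Tunable parameters

| parameter | unit | default | why |
|---|---|---|---|
| `reference_dose` | g/day | 100 | dose at which meta-analytic RRs are quoted |
| `step` | g/day | 20 | dose-category width of the risk-function grid |
| `upper_quantile` | — | 0.999 | grid extent; the open tail bin absorbs the rest |
| family | — | gamma | non-negative, right-skewed; admits an exact E[exp(βX)] |
| standard | — | Segi world | 18 five-year weights summing to 100,000; 85+ merged into 80+ by default when tables stop at 80+ |
| rounding | — | half away from zero | matches the printing convention of published PAF tables (`round_half_up()`); full precision is always retained internally |

## Design choices

**Gamma by method of moments.** Shape k = mean²/sd², scale θ = sd²/mean.
24-h-recall intake is non-negative with SDs near or above the means, which a
normal cannot represent without truncating a large mass at zero. The gamma
choice also provides the package's sharpest oracle: E[exp(βX)] =
(1 − βθ)^(−k) exactly, and the test suite requires the discretized E[RR] at
0.1 g/day bins to match this closed form within 0.1%. A truncated normal is
available for comparison; a point mass (sd = 0) is the degenerate case and
uses the mass point itself as its bin midpoint, so that all mass at the
reference dose reproduces the calibrating RR exactly.

**Tail handling.** Bins are [0, step), [step, 2·step), … out to the 0.999
quantile; the final open bin uses the conditional tail mean E[X | X > a] as
its midpoint rather than an arbitrary center, bounding discretization bias
where exp(βx) grows fastest.

**Dose rescaling.** `rescale_rr_dose()` implements the exact log-linear
transformation rr^(dose_to/dose_from). Published tables sometimes print
hand-transformed RRs that are not exact rescalings of the literature values
they cite; both entry paths are therefore supported — supply the printed RR
directly, or the literature (rr, dose) pair — and the package takes the
printed 100 g/day values as calibration inputs when reproducing published
constants, since those match every printed intercept at 3 decimal places.
The legacy "change per unit" bookkeeping column that accompanies such tables
is not used in any computation.

**Broadcasting exposure to incidence strata.** Consumption is surveyed on
broad age groups (0–14, 15–44, 45–54, 55–64) but incidence and population
come in 5-year groups up to 80+. Each 5-year stratum is assigned the broad
group containing its lower bound — assignment, not interpolation, matching
the granularity of the inputs. Strata older than the surveyed range inherit
the oldest surveyed distribution (and younger ones the youngest); this is
deliberate and configurable (`extend_ages`), since incidence peaks above the
age range most consumption surveys cover and dropping those strata would
discard most of the burden.

**Identity as a true no-op.** Under the identity transform the engine
returns the observed rates bit-for-bit instead of round-tripping them
through (r/E[RR])·E[RR], so the reference scenario reproduces its inputs
exactly rather than to floating tolerance.

**Sensitivity pairing.** Lower/central/upper RRs give pointwise-ordered risk
functions, hence ordered PAFs; the *lower* intervention-case bound pairs
with the *upper* PAF bound.

## The synthetic-data generator

The generator stands in for three restricted sources: a national 24-h-recall
survey, registry-based incidence estimates, and census population
projections. It emulates their *statistical structure*:

- per-subject consumption drawn from the configured family per stratum,
  with the default "colombia-like" truth anchored to published sex-level
  means (red meat 62.4/55.0 g/day for males/females; processed meat
  58.3/50.7) and an age profile shaped by the published anchors (highest
  red-meat intake in young adults, lowest in small children; processed-meat
  intake declining after middle age), SDs of the same magnitude as means;
- incidence rising log-linearly with 5-year age group from an anchor of
  5 per 100,000 at ages 40–44 with slope 0.40 per group (≈ rates doubling
  every 8–9 years of age, a colorectal-cancer-like gradient), with optional
  seeded log-normal noise (SD 0.05);
- a geometric population pyramid (2.1 million per sex at 0–4, decaying 7%
  per group, ≈ 23 million per sex overall).

It does **not** emulate: item-level foods or their classification into meat
categories, usual-intake deattenuation of single-day recalls, joint
distributions of multiple exposures (factors are modelled one at a time),
within-stratum age trends, or registry under-ascertainment. Passing tests
therefore demonstrate that the *pipeline arithmetic* is correct under its
distributional assumptions — not that any particular national estimate is
externally valid, and not that the published absolute counts can be
recovered (those depend on unpublished stratum-level inputs).

Determinism contract: one seed drives everything; identical seeds give
byte-identical fixtures, and the seed is recorded in the run metadata.

## Numerical choices

- Calibration round-trip is required to 1e−9 relative error; the
  single-stratum engine PAF must equal 1 − 1/E[RR] to 1e−12.
- Prevalences are exact CDF differences, clipped at zero and renormalized
  only to absorb floating residue (sums are within 1e−9 of 1 before
  renormalization).
- Degenerate inputs: RR = 1 gives β = 0 and PAF exactly 0; sd = 0 collapses
  to a point mass; an empty or single-record stratum is an estimation error,
  not a silent NA; reference cases of 0 make the PAF an explicit error
  rather than NaN.
- Problem sizes used by the test and acceptance runs: 5,000 recall subjects
  per stratum for fixture analyses (survey scale: the emulated survey had
  ≈ 39,000 respondents over 8 strata) and 10,000 per stratum × 50 seeds for
  the parameter-recovery study; both complete in seconds.

## Known limitations

- Single-factor PAFs only; summing PAFs across correlated exposures
  (red and processed meat overlap in diets) overstates the joint fraction.
- The log-linear form extrapolates beyond the dose range of the underlying
  meta-analysis; the 0.999-quantile grid cap limits, but does not remove,
  the influence of the far tail.
- Sensitivity propagates only the RR confidence interval — not consumption
  or incidence uncertainty, mirroring the published workflow this package
  re-implements.
- Direct standardization uses the classical Segi weights; ASR comparisons
  against tables standardized to other world standards will differ.
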