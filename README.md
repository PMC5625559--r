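# pafsim

Macro-simulation of **population attributable fractions (PAFs)** for disease
incidence and continuous dietary exposures, built around the comparative-risk
workflow used to estimate the share of colorectal cancer attributable to red
and processed meat consumption in a national population.

## The problem and who this is for

Cancer registries report incidence by sex and 5-year age group; dietary
surveys report consumption as a mean ± SD of g/day per sex and broad age
group; meta-analyses report a relative risk (RR) with a 95% CI at a reference
dose (e.g. RR 1.17 per 100 g/day of red meat). Epidemiologists who want a
national attributable-burden estimate must join these three sources: how many
incident cases would not occur if consumption were set to a counterfactual
level (typically zero)?

`pafsim` implements that join as a tested, reusable pipeline for
epidemiologists and burden-of-disease modellers.

## The model

A log-linear dose–response links intake x (g/day) to relative risk:

    ln RR(x) = beta * x,      beta = ln(RR_ref) / d_ref

so RR(0) = 1 and RR(d_ref) reproduces the meta-analytic RR. The "intercept"
reported with such risk functions is −ln(RR_ref), the log-risk decline from
the reference dose down to zero exposure (−0.157 for RR 1.17).

Each stratum's consumption distribution (gamma by default, fitted by method
of moments to the surveyed mean/SD) is discretized into 20 g/day dose
categories with prevalences p_i and midpoints x_i, giving the
population-average relative risk

    E[RR] = sum_i p_i * exp(beta * x_i).

The observed stratum rate r is calibrated to its zero-exposure baseline
r0 = r / E[RR]; an intervention scenario replaces the exposure distribution
(zero, or scaled) and recomputes rates as r0 · E[RR | counterfactual].
Expected cases (rate × population / 100,000) are summed per sex and

    PAF = (reference cases − intervention cases) / reference cases,

with age-standardized rates (Segi world standard) reported alongside.
Sensitivity runs repeat everything at the lower and upper RR confidence
bounds. A seeded synthetic-data generator produces survey-, registry- and
census-shaped inputs so the whole pipeline is testable without restricted
data.

## Worked example

```r
library(pafsim)

syn <- synthetic_inputs(synthetic_config(seed = 42, n_subjects = 5000))
sens <- sensitivity_run(syn$exposure, syn$rr, syn$incidence, syn$population,
                        scenario("eliminate", "zero", year = 2010))
print(sens)
```

```
Sensitivity analysis: red_meat, RR 1.17 (1.05-1.31) per 100 g/day
    sex reference_cases intervention_cases intervention_cases_lower
 female          3020.7             2762.9                   2581.3
   male          2962.3             2681.8                   2484.6
 intervention_cases_upper  paf_pct
                   2939.9 9 (3-15)
                   2874.3 9 (3-16)
```

Reading the output: on this synthetic population roughly 3,000 annual cases
per sex are expected under observed consumption; eliminating red meat
(RR 1.17 per 100 g/day, mean intake ≈ 55–62 g/day) would avoid about 9% of
them, and propagating the RR confidence interval widens that to 3–16%. The
calibrated risk function itself prints the published-style constants:

```
Log-linear risk function: red_meat (central RR)
  beta      0.00157004 per g/day
  intercept -0.157  (-ln RR at 100 g/day)
  step      20 g/day
```

A file-based workflow is available through the command entry points
(`cmd_synth`, `cmd_simulate`, `cmd_sensitivity`), which exchange CSV tables
plus a YAML run configuration and write `paf_table.csv`, `asr_table.csv` and
a `run_log.yaml` with every calibration constant. A thin CLI wrapper lives in
`inst/cli/pafsim.R`:

```sh
Rscript inst/cli/pafsim.R synth --config synth.yaml --out rundir
Rscript inst/cli/pafsim.R sensitivity --config rundir/run.yaml
```

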