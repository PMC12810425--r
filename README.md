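# oxshedsim

Monte Carlo simulation of oxidative-stress-linked hair shedding cohorts.

## The problem

Telogen effluvium — diffuse shedding from follicles prematurely pushed out of
the anagen growth phase — has oxidative stress among its plausible triggers,
and smoked cannabis is a substantial reactive-oxygen-species source. A real
longitudinal trichoscopy cohort in cannabis-using young adults is close to
infeasible, so the question is studied *in silico*: if cannabis raised
follicular oxidative burden through modest linear effects, would a simulated
24-week observational study look like early telogen effluvium?

`oxshedsim` is for simulation methodologists and dermatoepidemiology
researchers who want that thought experiment as a reproducible, calibrated,
testable machine rather than a one-off script.

## The model

Each of n = 140 agents gets demographics (age, sex, ordinal diet quality),
baseline vertex follicular density `D_0 ~ N(185, 28)` hairs/cm² truncated to
[150, 220], daily cannabis exposure `X` from a zero-inflated gamma (mean
1.07 g/day, SD 0.84, capped at 5), and baseline severity from a 3-domain ×
3-item five-point Likert instrument (SAHL) built on an equicorrelated latent
model. A latent oxidative load

    L = α_x·X + α_sex·sex + α_diet·(2 − diet) + ε,   ε ~ N(0, σ_ε)

drives the Week-24 endpoints

    D_24 = D_0 − β_D·L + η
    latent_24 = latent_0 + β_S·L + υ   (SAHL items regenerated at item level)

The free coefficients are never published; they are fitted by Nelder–Mead
with common random numbers against the published summary statistics
(correlations, reliability indices, adjusted R², exposure moments), and the
converged fit ships as the `"paper_default"` preset. A full account of the
model, the calibration objective, and which published targets are mutually
unreachable under this structure is in
`vignettes/oxshedsim-methods.Rmd`.

## Worked example

```r
library(oxshedsim)

cfg <- sim_config()          # calibrated "paper_default" preset
cohort <- simulate_cohort(cfg, seed = 7)
report <- analyze_cohort(cohort)
report
#> <analysis_report> schema 1.0 - n = 140
#>   r(exposure, SAHL wk24)    = +0.134 (p = 0.115)
#>   r(exposure, density wk24) = -0.378 (p = 4.12e-06)
#>   Cronbach alpha: 0.492 (baseline), 0.679 (week 24); ICC(2,1) = 0.380

round(report$ancova$adjusted_means, 1)
#>      non    light moderate    heavy
#>    172.4    171.9    151.8    123.8
```

Read: in this single 140-agent draw, exposure correlates −0.38 with Week-24
follicular density (the dose–response also shows up as monotonically falling
covariate-adjusted density across the non/light/moderate/heavy strata,
ANCOVA F(3, 133) = 10.26), while the exposure–severity correlation (+0.13
here) fluctuates replicate to replicate around its population value of about
0.26 — at n = 140 a correlation carries a sampling SD of roughly 0.08.

The same pipeline is scriptable from a shell:

```sh
oxshedsim simulate --seed 7 --out cohort.csv        # + cohort.csv.meta.json
oxshedsim analyze --cohort cohort.csv --out report.json
oxshedsim calibrate --budget 2000 --n-eval 20000
oxshedsim reproduce-paper                           # target-vs-achieved table
```

Identical seed and config give byte-identical CSV and JSON outputs; every
random step draws from its own named substream, so baseline data are
invariant to the outcome coefficients.

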