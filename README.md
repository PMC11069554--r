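# rfdosim

Whole-body RF-EMF dosimetry and calibrated synthetic-cohort simulation
for rodent exposure experiments.

## The problem

Chronic-exposure studies that place caged, unrestrained rodents in front
of a radiofrequency antenna need two quantitative pieces before any
biology can be interpreted: (1) a defensible estimate of the dose — the
incident power density across the cage and the whole-body averaged
specific absorption rate (SAR), checked against the ICNIRP limits — and
(2) a statistical pipeline that turns per-animal longitudinal records
(weights, temperatures, organ masses, water-maze trials) into
exposed-versus-control comparison tables. `rfdosim` provides both,
together with a seeded generator of synthetic cohorts calibrated to the
published group statistics of a five-week 2.4 GHz study on male Wistar
rats of three ages, so the entire analysis is reproducible without the
original raw data. It is aimed at bioelectromagnetics researchers
planning or auditing such experiments, and at anyone who wants a tested
exact Mann-Whitney implementation with an honest two-sided convention.

## The model

Far-field incident power density follows the inverse-square law,

    S_inc(r) = P_A · 10^(G/10) / (4 π r²)        [W/m²]

and the cage-averaged density is the exact line average of that profile
over the occupiable depth `[r0, r0 + Δ]`. Whole-body SAR uses the closed
form

    SAR_wb = (k / f_GHz) · ⟨S_inc⟩ · ⟨L⟩ / ⟨m⟩   [W/kg]

with `k = 5.954e-2` by default (overridable), `⟨L⟩` the mean animal
length and `⟨m⟩` the mean body mass. Group comparisons use a
from-scratch Mann-Whitney U test whose exact two-sided p-value is
obtained by enumerating the null distribution of U
(`p = min(1, 2·min(P(U≤u), P(U≥u)))`), with a tie-corrected normal
approximation beyond n = 12 per arm. The methods vignette
(`vignettes/rf-dosimetry-and-cohort-simulation.Rmd`) documents every
modelling choice, including how censored maze latencies are generated
from moment-matched truncated normals.

## Worked example

```r
library(rfdosim)

ant  <- antenna_spec(power_input_w = 0.0891, gain_db = 7, frequency_ghz = 2.4)
scen <- exposure_scenario(r_near = 0.12, cage_extent = 0.375,
                          mean_mass_kg = 0.49155, mean_length_m = 0.25,
                          label = "presenile cages")
summ <- sar_range(ant, scen)
print(summ)
#> Exposure summary [presenile cages]
#>   S_inc (W/m^2): min 0.15  avg 0.60  max 2.47
#>   SAR_wb (W/kg): min 0.0018  avg 0.0075  max 0.031
#>   mean mass 0.4915 kg (length 0.25 m assumed, flagged as assumption)
print(icnirp_check(summ))
#> ICNIRP compliance: COMPLIANT
#>   whole-body SAR margin (limit/avg): 10.6
#>   power-density margin (reference/max): 4.05
```

Reading: animals at the cage near edge (0.12 m) see ~2.5 W/m², about
4-fold below the 10 W/m² ICNIRP reference; the cage-averaged whole-body
SAR of ~0.0075 W/kg sits an order of magnitude below the 0.08 W/kg
whole-body limit, so the exposure is compliant with margin.

Simulating and analysing a cohort:

```r
coh <- generate_cohort(default_calibration("juvenile", "control"), seed = 1)
mwm_daily_summary(coh$trials)[1, c("day", "mean_successful_latency_s",
                                   "percent_successful")]
#>   day mean_successful_latency_s percent_successful
#> 1   1                  32.09478               72.5
```

The full workflow — dosimetry for both exposure scenarios, all six
cohorts, endpoint tables and the comparison table — is one call,
`run_experiment(default_run_config(seed = 20240504))`, or step by step
through the narrative drivers `analysis/01_dosimetry.R` …
`analysis/04_compare.R`.

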