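---
title: "Far-field RF-EMF dosimetry and calibrated cohort simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Far-field RF-EMF dosimetry and calibrated cohort simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfdosim)
```

# What this package models

`rfdosim` rebuilds, as a reusable and tested pipeline, the quantitative
skeleton of a five-week whole-body radiofrequency exposure experiment on
male Wistar rats of three ages (juvenile, adult, presenile): a 2.4 GHz
transmitter irradiating cages of unrestrained animals around the clock,
with weekly body weights, rectal and skin temperatures, terminal organ
weights and a Morris water maze (MWM) test in the final week, analysed by
exposed-versus-control Mann-Whitney comparisons.

Two components carry the science:

1. a **closed-form far-field dosimetry model** — incident power density,
   cage-averaged whole-body specific absorption rate (SAR), and checking
   against the ICNIRP whole-body limits; and
2. a **seeded synthetic-cohort generator** calibrated to the published
   group statistics, standing in for the study's raw per-animal data,
   with endpoint computation and a from-scratch exact Mann-Whitney U
   test on top.

# The dosimetry model

## Incident power density

In the far field of the antenna the power flux through unit area follows
the inverse-square law

$$ S_{inc}(r) \;=\; \frac{P_A \, 10^{G/10}}{4 \pi r^2}, $$

with $P_A$ the power at the antenna input (W), $G$ the antenna gain (dB,
linearised as $10^{G/10}$) and $r$ the distance (m). The default antenna
is the study's: $P_A = 0.0891$ W, $G = 7$ dB, $f = 2.4$ GHz. For a
combined electric/magnetic dipole the far field forms at roughly one
free-space wavelength, $c/f \approx 12.5$ cm at 2.4 GHz;
`exposure_scenario()` flags cages closer than that with an **advisory**
warning rather than an error, because the experimental geometry operates
exactly at about one wavelength. Reflections and multiple scattering are
deliberately ignored, mirroring the modelling assumption of the original
setup.

## Cage averaging

Animals are unrestrained, so a cage spans distances
$[r_0, r_0 + \Delta]$ along the beam axis. The exposure summary uses the
one-dimensional line average of the inverse-square profile,

$$ \langle S_{inc} \rangle \;=\; \frac{1}{\Delta} \int_{r_0}^{r_0+\Delta}
   S_{inc}(r)\, dr \;=\; \frac{P_A\,10^{G/10}}{4\pi}\,\frac{1}{r_0\,(r_0+\Delta)}, $$

which is exact, bracketed by the endpoint densities, and verified in the
test suite against adaptive quadrature to a relative error below
$10^{-9}$. The default cage depth is $\Delta = 0.375$ m, one of the
printed cage dimensions; with the two documented placements
($r_0 = 0.12$ m and $r_0 = 0.20$ m) the line averages land within 2% of
the published scenario averages (0.605 and 0.31 W/m²). The extent is
configurable per scenario.

## Whole-body SAR

The whole-body averaged SAR of a rodent in a plane wave is estimated by
the closed form

$$ SAR_{wb} \;=\; \frac{k}{f_{GHz}}\,
   \frac{\langle S_{inc}\rangle\,\langle L \rangle}{\langle m \rangle}, $$

with $\langle L \rangle$ the averaged animal length (m),
$\langle m \rangle$ the averaged body mass (kg) and $k$ a dimensionless
coefficient held in `dosimetry_constants()`. The adopted default is
$k = 5.954\times 10^{-2}$: taken at face value with SI inputs, a
coefficient of 5.954 would produce SAR values two orders of magnitude
above the published scenario summaries, whereas $5.954\times10^{-2}$
reproduces both (0.0076 and 0.0059 W/kg) from the printed densities and
plausible rat masses and lengths; we read the discrepancy as a lost
exponent in typesetting and keep the constant overridable.

Mean lengths are not published. The defaults — 0.25 m for presenile
animals and 0.19 m for the pooled juvenile/adult exposure — are package
assumptions, recorded in the configuration and flagged as assumptions in
printed reports. Mean masses default to the baseline body-weight means
(0.49155 kg presenile; 0.2484 kg juvenile/adult pooled).

`icnirp_check()` compares the cage-averaged SAR with the 0.08 W/kg
whole-body limit and the averaged density with the 10 W/m² reference
level (boundary equality counts as compliant), and reports
limit/observed margins — the density margin against the cage **maximum**,
the worst-case position.

Three published numbers are deliberately excluded from validation: the
0.91 W/m² maximum of the second exposure (the model gives 0.89; the
gain may not be exactly 7 dB), the 0.13 W/m² minimum (implies a distance
matching no stated geometry) and the 0.0322 W/kg maximum SAR (mutually
inconsistent with the 0.0076 average under any single length/mass pair
to within ~2%). They are documented here and not asserted anywhere.

# The synthetic-cohort generator

## What it emulates

`default_calibration(age_group, arm)` returns the published cells for
each of the six cohorts (n = 10 each): six weekly weight means, five
rectal and five skin temperature means, five organ weight coefficients,
and per-day MWM latency and success cells. `generate_cohort(spec, seed)`
then draws:

* **Weights** as autocorrelated trajectories: the baseline from a
  positive-truncated normal, then weekly increments whose means are the
  consecutive differences of the calibrated means. Increment dispersion
  is $\sqrt{\max(sd_t^2 - sd_{t-1}^2,\ (0.25\,sd_t)^2)}$ — printed
  dispersions sometimes shrink week-to-week, which independent
  increments cannot reproduce exactly, so a floor keeps trajectories
  stochastic; group *means* are matched exactly at every timepoint
  regardless, and zero-dispersion specs remain fully deterministic.
  Increments may be negative (presenile weights decline late in the
  study).
* **Temperatures** from normals truncated to the physiological range
  30–42 °C.
* **Organ masses** as coefficient draws (percent of body weight,
  positive-truncated) times the terminal weight, so regenerating the
  coefficient from the stored mass returns the draw exactly.
* **MWM trials**, four per animal on training days 1, 2, 3, 4 and 7
  (the habituation day generates no records, and day 7 is treated like
  the other training days). Per-trial success is Bernoulli with the
  published day percentage divided by 100; successful latencies come
  from a truncated normal on (0, 60) s **moment-matched** so that the
  post-truncation mean and SD equal the published cell
  (`match_truncated_normal_moments()`, verified against quadrature to
  $10^{-6}$); failures are censored at exactly 60 s.
* **Passive swimming**: each animal receives a propensity drawn from a
  Beta distribution with mean 0.35, and a *failed* trial is flagged
  passive with probability propensity × day-decay
  (1, 0.5, 0.25, 0.12, 0.06 across the five days). This emulates the
  observed pattern — most passive episodes on day 1, fading afterwards,
  with recurrent individuals — without reverse-engineering the published
  per-animal lists. Passive flags are by construction a subset of
  failures.

Animal tags follow the housing scheme, `"<cage>-<individual>"`, with
presenile cohorts split 5 + 5 over two cages.

## Interpretation choices worth stating

* The published tables label dispersion "standard error", but magnitudes
  such as 28.9 ± 15.4 at n = 10 are only plausible as per-animal
  standard deviations; the generator treats all printed dispersions as
  SDs. If they really were standard errors, the synthetic cohorts are
  substantially over-dispersed.
* The published success percentages (55.5, 63.6, 97.7, …) are not
  multiples of 1/40 and therefore cannot arise from 10 animals × 4
  trials; their denominators are not reverse-engineered. The generator
  applies the percentage as an i.i.d. per-trial probability.
* Failed trials are stored at exactly 60 s (censoring convention);
  latency summaries average **successful swims only**, matching the
  published metric. An all-trials average is available but off by
  default.

## What passing tests do and do not show

The generator is validated by seed determinism, logical invariants
(censoring, passive ⊂ failure, organ-coefficient closure), exact
reproduction of all published weight/organ/temperature cells under
zero dispersion, and parameter recovery (cell means recovered within
three Monte-Carlo standard errors over replicate cohorts). It does *not*
model mechanistic physiology (feed intake, circadian temperature
structure, energy balance), swim paths, or any exposure effect: exposed
and control arms differ only through their calibration cells. Results on
synthetic cohorts therefore say nothing about real biological exposure
responses; they validate the pipeline's arithmetic and statistical
behaviour.

A consequence worth flagging: where the published exposed and control
cells differ by an appreciable fraction of their SD, that difference is
*real* in the synthetic population, so the comparison stage flags it at
a rate above the nominal level. That is faithful behaviour, not a false
positive — under a shared calibration (a true null) the test suite
verifies the flagged fraction stays at or below the nominal 5%.

# The Mann-Whitney U test

`mann_whitney_u()` is implemented from first principles. U is computed
from mid-ranks; the exact two-sided p-value enumerates the null
distribution of U through the partition-counting recurrence (Gaussian
binomial coefficients) and uses the convention
$p = \min(1,\ 2\min(P(U \le u),\ P(U \ge u)))$ — stated explicitly
because two-sided conventions differ. With `method = "auto"` the exact
path is taken for tie-free samples up to n = 12 per arm; otherwise the
normal approximation with tie-corrected variance and (by default) a 0.5
continuity correction applies. Exact conditional tie handling is not
implemented; with ties the exact request falls back to the
approximation and records that. Which continuity convention the original
analysis software used is unknowable, so it is a flag.

No multiple-testing correction is applied by default (the original
analysis reported raw per-contrast p-values); a Holm option exists.
The published p-values themselves depend on unavailable raw data and
are not reproduced or asserted.

# Orchestration and determinism

`run_experiment()` executes dosimetry planning, simulation of the six
cohorts, endpoint tables and the comparison table, writing everything
under one output directory with a manifest (configuration hash, master
seed, FNV-1a checksum per file) and a structured log. Per-cohort seeds
derive from the master seed by one step of a Lehmer congruential map,
so adding a cohort never perturbs the others, and all derived seeds stay
below $2^{31}$. CSVs are written with 17 significant digits so doubles
round-trip exactly: an analyze-only rerun from the stored CSVs
reproduces byte-identical tables. The numbered scripts under `analysis/`
are thin narrative drivers over these functions.

# Numerical choices and problem sizes

* Moment matching solves a two-parameter system by Nelder-Mead on
  (location, log scale) from three starts, accepts only residuals below
  $10^{-6}$, caches solutions per cell, and rejects infeasible targets
  (a variable bounded on an interval of width $w$ cannot have
  $sd \ge w/2$; the truncated-normal family is further bounded by its
  uniform limit).
* The exact U null distribution is cached per $(n_1, n_2)$; counts stay
  exact in doubles far beyond the sizes used here.
* Parameter-recovery checks use 200 replicate cohorts; the day-1 latency
  calibration check in the acceptance script uses 500 cohorts; the
  null-rate simulation for the exact test uses 10,000 draws at n = 10
  per arm. These sizes give Monte-Carlo standard errors comfortably
  below the tolerances being checked while keeping the default test run
  fast.
* Zero-dispersion ("degenerate noise") specs are the exactness fixture:
  every animal equals its group means, so endpoint tables must
  reproduce the published cells to floating tolerance.

# Known limitations

* The inverse-square model ignores near-field structure, reflections
  and scattering; at one wavelength from the antenna it is an
  approximation by design, and the advisory flag says so.
* Mean animal lengths are assumptions, not data.
* The generator matches first and second moments per cell; it does not
  attempt higher moments, between-endpoint correlations (beyond the
  weight trajectory and the organ-terminal link), or the exact
  published passive-swimmer identities.
* Latency cells are matched conditionally on success; the joint
  distribution of success and latency within a day is otherwise
  independent, which real learning dynamics need not be.
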