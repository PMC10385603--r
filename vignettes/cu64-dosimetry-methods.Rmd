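---
title: "Models and methods: Cu-64 antibody dosimetry and efficacy analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: Cu-64 antibody dosimetry and efficacy analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cudosim)
```

`cudosim` implements the quantitative chain used in preclinical copper-64
radioimmunotherapy studies of mouse tumour models: ex vivo biodistribution
expressed as percent injected dose per gram (%ID/g), time--activity curve
(TAC) fitting and integration, MIRD mean absorbed doses from sphere
self-dose S-values, binding-assay arithmetic, and tumour-growth/survival
efficacy analytics. A seeded synthetic-cohort generator reproduces the
statistical structure of such a study so that every stage is testable
end to end without any animal data. This vignette records the models, the
conventions and the design decisions, including the places where the
design was genuinely open.

## Nuclear data

All dosimetry is traceable to one bundled copper-64 record
(`cu64()`, shipped as a JSON resource): half-life 12.7004 h, branching
fractions beta+ 17.4%, beta- 39.0%, electron capture 44%, mean beta
energies 0.2782 and 0.1902 MeV, an Auger/conversion-electron term of
0.004 MeV per decay, and a photon component of 0.1842 MeV per decay
(annihilation plus the 1.346 MeV gamma). Two deliberate conventions:

* the branching fractions are stored exactly as printed in standard decay
  compilations even though they sum to 1.004; no renormalisation is
  applied, so energy bookkeeping inherits the published rounding;
* the non-penetrating energy per decay is the branch-weighted beta energy
  (0.1226 MeV) plus the Auger/conversion term, 0.1266 MeV in total.

Decay bookkeeping is exact: `decay_factor(t)` is `2^(-t/T_half)` and
`decay_correct()` inverts it, round-tripping to machine precision.

## Biodistribution conventions

`percent_id_per_gram()` converts per-mouse organ counts to %ID/g using
the study conventions: counts/min are divided by the counter efficiency,
converted to MBq, decay-corrected back to injection time over the
sacrifice delay, and normalised by the tail-corrected injected activity
(injected minus the activity remaining at the tail injection site) and
the organ mass:

$$\%ID/g = 100\cdot\frac{A_{organ}/2^{-t_{sac}/T_{1/2}}}{(A_{inj}-A_{tail})\, m_{organ}}.$$

%ID/g is therefore *stored decay-corrected*; this matters for dosimetry
(below). The sampling grid is configuration-driven; the default is
{5 min, 2 h, 24 h, 48 h, 72 h}. Group statistics use the sample SD
(n−1); the two-sample comparison is an unpaired t test, Welch's
unequal-variance form by default with the pooled-variance variant behind
a flag, since unequal group spreads are the norm in such data.

## Time--activity curves and cumulated activity

Organ kinetics are fitted on the decay-corrected %ID/g means with one of
three forms: a single exponential, a sum of two exponentials, or the
rising-to-plateau uptake model $P(1-e^{-\lambda_u t})$ (the
two-exponential form with one negative amplitude, reparameterised for
organs such as tumours that accumulate and hold activity). Fitting is
Levenberg--Marquardt least squares with a deterministic multi-start over
rate constants in {0.01, 0.1, 1}/h; noiseless data are recovered to at
least 1e-6. Model choice, where not forced by the user, is by
small-sample corrected AIC with ties broken towards fewer parameters;
with five timepoints the four-parameter biexponential is automatically
unsupportable (infinite AICc), which matches practice.

The single most consequential unstated convention in this chain is the
ordering of decay correction and integration: because the stored curves
are biological (decay-corrected), physical decay is re-applied *inside*
the integral. The cumulated activity per injected MBq is then analytic,

$$\tilde A = \int_0^\infty A(t)\,e^{-\lambda_{phys}t}\,dt
  = \sum_i \frac{a_i}{\lambda_i + \lambda_{phys}},$$

with %ID/g converted to MBq/g per injected MBq (/100) and hours to
seconds (x3600). The analytic value is verified against adaptive
quadrature to 1e-6 relative in the tests. Beyond the last observed
timepoint the fitted biological model is extrapolated as-is by default; a
conservative `physical_only` tail mode freezes the biology at the last
timepoint and lets only physical decay act thereafter.

## MIRD dosimetry

Mean absorbed doses follow the MIRD scheme, $D = \tilde A \cdot S$, with
self-dose only. Organs are modelled as unit-density spheres of their
dissected mass, the tumour by default as the 0.306 g sphere implied by
the 306 mm^3 average tumour volume of the biodistribution cohort.

Two S-value methods are implemented:

* **local_np** (default): all non-penetrating energy absorbed where
  emitted, $S = \Delta_{np}/m$ -- appropriate at mouse-organ scale for
  the short-range Cu-64 betas;
* **monte_carlo**: a desk-scale electron transport model -- uniform
  emission points, isotropic directions, straight-path travel over the
  CSDA range with uniform energy deposition along the path, using a
  bundled water range table. Each beta branch is scaled by the resulting
  absorbed fraction; Auger/conversion electrons stay fully absorbed and
  photon self-absorption is neglected (the photon absorbed fraction of a
  gram-scale sphere is essentially zero), so the MC S-value is always
  below the local one. For this transport the absorbed fraction has the
  closed form $1 - \tfrac{3}{8}\rho + \tfrac{1}{64}\rho^3$
  ($\rho$ = range/radius), which the test suite uses as an independent
  oracle. This model is a QA device for the local approximation, not a
  claim of radiological accuracy: it omits scattering, straggling and
  the beta spectrum.

Blood is treated by local deposition: dose equals the cumulated activity
concentration times the mean energy per decay. The study convention
counts *all* emitted energy (including photons) in blood; because the
physics convention would count only non-penetrating energy, both modes
are exposed (`energy_mode`), with `"all"` the default.

Cross-organ photon dose is deliberately omitted; reproducing voxel-
phantom cross-fire S-values is out of scope at desk scale. Every report
carries a "self-dose only" provenance flag. For Cu-64 the photon
component is ~0.18 MeV per decay spread over the whole body; the
resulting cross-dose to any one organ is small relative to the
non-penetrating self-dose that dominates the reported values, but
reported doses should be read as slight underestimates for distant-organ
contributions.

The published-style dose table (`assemble_dose_table()`) computes the
per-administration column from *unrounded* per-MBq doses, then rounds
both columns half-away-from-zero to one decimal, matching the
publication convention. (The reverse order -- multiplying the rounded
per-MBq column -- does not reproduce published tables of this kind.)

## Binding assays

The immunoreactive fraction is the bead share of total counts; the
one-site specific binding fit $B(c) = B_{max}c/(K_d+c)$ is pure specific
binding by default, with an optional linear nonspecific term behind a
flag. Concentrations are stored in nM; a mass/molar bridge at the IgG
molecular weight of 150 kDa is provided for assays whose axes are in
ug/mL. Cellular uptake is normalised to percent of deposited activity
per million cells, and the blocking fraction is the relative uptake
reduction under antigen excess.

## Tumour growth and survival

Calliper volumes use $(L \times W \times h)\times 3.14/6$ with the
constant 3.14 exactly, as in the field's convention. Doubling time is
$\ln 2$ over the slope of a log-linear fit of volume on day, within a
window that defaults to [first injection, second injection); zero or
negative slopes report `NA`. The maximum volume reduction is computed
per mouse relative to the volume on the second-injection day and then
averaged -- group-mean-relative alternatives exist, but the per-mouse
reading matches how individual trajectories are reported.

Sacrifice rules fire on the first day any humane endpoint is met
(paralysis, 2000 mm^3 volume, 20% weight loss, checked in that order);
survivors are censored at the 100-day study horizon. The Kaplan--Meier
estimate comes from `survival::survfit()`, with the median defined as
the smallest event time at which survival reaches 0.5 or below (and
`NA` when never reached). The log-rank test is the standard
one-degree-of-freedom Mantel--Cox chi-square via
`survival::survdiff()`. Both are cross-checked in the tests against
brute-force oracles (direct product-limit enumeration over all event/
censoring patterns up to n = 6; per-event-time hypergeometric moments).
One calibration caveat is documented in the test suite: with complete
(uncensored) samples as small as 10 + 10 the log-rank chi-square is
intrinsically anticonservative (true type-I level ~0.065 at nominal
0.05, approaching the nominal level only slowly with n); this is a
property of the statistic itself, reproduced by the independent oracle.

## The synthetic-cohort generator

The generators define the study conditions; they are parameterised once
in `default_config()` and are pure functions of (config, seed) -- same
seed, bit-identical output, with sub-stream seeds (`derive_seed()`) so
stages can be regenerated independently.

* **Biodistribution** (`gen_biodistribution()`): per-mouse %ID/g drawn
  truncated-normal (at zero) from an organ x timepoint mean/SD table.
  Cells printed in the source study are entered verbatim (e.g. healthy
  blood 26.6 +/- 7.8 at 5 min, tumour 9.2/45.6/62.5 %ID/g at
  5 min/2 h/48 h); unprinted cells are log-linear interpolations between
  printed anchors and are flagged `interpolated` in the table. Organ
  masses are nominal 20 g-mouse values (blood 1.2 g, liver 1.0 g, ...);
  muscle and bone are sampled aliquots. Whole-body conservation is
  enforced by proportionally rescaling any mouse whose organ-mass-
  weighted %ID sum exceeds 100% (rare under the defaults, so configured
  means are preserved). Records are emitted as raw counts so the
  analysis path (efficiency, decay, tail correction) is exercised.
* **Growth** (`gen_tumour_growth()`): exponential volume
  $V_0 2^{(t-t_1)/dT}$ from a common 30 mm^3 volume at first treatment
  (day 6; a just-palpable tumour consistent with the saline group
  reaching the 2000 mm^3 endpoint in ~2 weeks at its 1.9 d doubling
  time), mouse-level doubling times lognormal (treated 4.51 +/- 2.17 d,
  saline 1.9 +/- 0.5 d -- the saline SD is a chosen value, the printed
  one being corrupt in the source), post-second-dose regression by a
  truncated-normal fraction (70.7 +/- 21.3%) over two weeks followed by
  regrowth, and multiplicative lognormal measurement noise (CV 0.1).
  Calliper dimensions are back-solved (equal axes) so the volume formula
  round-trips exactly. The printed day-18 group-mean volumes are not
  separately calibrated; with a common V0 and the printed doubling
  times they are not simultaneously attainable, and doubling time is
  the quantity the generator is required to reproduce.
* **Survival** (`gen_survival()`): event times log-logistic (shape 8, a
  steep but heavy-tailed choice consistent with the tight published
  curves), scaled so that the *whole-group* median -- including the
  cured fraction censored at 100 days -- equals the configured group
  median (e.g. 45 days with a 2/6 cure fraction for the repeated-35-MBq
  group). An alternative mode derives events mechanistically from the
  growth generator through the sacrifice rules.
* **Assays**: bead counts binomial at the true immunoreactive fraction
  (0.794 of 1e6 counts); saturation signals one-site at Kd 0.626 nM with
  5% multiplicative noise on an 8-point grid spanning 0.05--10x Kd.

What the generators deliberately do not emulate: inter-organ
correlations within a mouse (organ values are independent draws before
the conservation rescale), calibration drift of the counter, cohort
effects, competing-risk structure between toxicity and disease, and any
mechanistic radiobiology (no dose-response link between the dosimetry
and the efficacy modules). Passing recovery tests therefore shows the
estimators are unbiased under the study's marginal statistical
structure, not that the biology is mechanistically reproduced.

## Problem sizes and numerical choices

Recovery checks use 200 cohorts for biodistribution (n = 4 each), 200
bead-assay replicates, and 500 replicates for the Kd fit, the growth
doubling time and the survival medians -- enough for Monte-Carlo error
well below the tolerances being checked while keeping the whole suite
fast. Monte-Carlo sphere runs use 2e4--1e5 histories with reported
standard errors; nonlinear fits run to ftol/ptol 1e-14 with
deterministic multi-starts; ties in model selection go to the simpler
model; degenerate inputs (zero injected activity, flat growth, all-
censored groups, zero-variance tests) return flagged values (`NA`,
warnings) rather than errors where a downstream summary can still
proceed.

## Known limitations

Self-dose-only dosimetry (above); sphere geometry for all organs; the
straight-path CSDA transport is a first-order oracle only; the KM median
on six animals is a noisy order statistic whose cohort-mean sits a few
percent below the population median (visible in the recovery checks);
and the %ID/g module assumes a single scalar counter efficiency per run.
Real-data users should also note that whether organ masses were weighed
wet or blotted is not modelled -- it cancels nowhere in %ID/g.
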