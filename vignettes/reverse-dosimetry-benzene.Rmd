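---
title: "Reverse dosimetry for benzene: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse dosimetry for benzene: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benzrisk)
```

`benzrisk` reconstructs a child's inhaled benzene exposure from a single
urinary trans,trans-muconic acid (tt-MA) measurement and converts the
reconstructed air concentration into non-cancer and cancer risk estimates.
This vignette is the package's own account of the science: the model and
its assumptions, the parameters that matter, the numerical machinery, what
the synthetic data do and do not emulate, and the design choices made where
the problem left the design open.

## The forward model

The model is a steady-state, four-compartment PBPK description of
inhalation-only benzene exposure. Its assumptions, stated up front because
everything else follows from them:

(a) the subject is exposed only by inhalation, to a constant air
    concentration;
(b) blood reaches its steady-state concentration instantaneously relative
    to the time scales of interest;
(c) arterial blood delivers benzene homogeneously to all compartments;
(d) metabolism is exclusively hepatic, and the urinary metabolite
    accumulates in the bladder between voids;
(e) the bladder is emptied every three hours (micturition interval
    180 min).

**Tissue uptake.** Each compartment *i* (richly perfused, fat, poorly
perfused, liver) with blood flow $Q_i$ (L/min), volume $V_i$ (L) and
tissue:blood partition coefficient $P_i$ follows

$$C_i(t) = \frac{Q_i P_i C_{art} t}{V_i P_i + Q_i t},$$

which is 0 at $t = 0$, strictly increasing, and saturates at the
equilibrium value $P_i C_{art}$ once flow-delivered benzene ($Q_i t$)
dominates the tissue's storage capacity ($V_i P_i$). A note on units: this
expression is dimensionally a concentration (mg/L) and the package treats
it as one throughout, even though compartment outputs are sometimes loosely
labelled as rates in the applied literature.

**Arterial concentration.** How air concentration maps to arterial blood
is genuinely open in the steady-state formulation, so the package makes the
choice explicit and testable via `arterial_mode`:

* `"equilibrium"` (default): instantaneous blood:air equilibrium,
  $C_{art} = P_{b:a} \cdot C_{inh}/1000$ (the factor 1000 converts mg/m³
  to mg/L). This is the direct reading of assumption (b).
* `"mass_balance"`: the standard steady-state inhalation balance
  $C_{art} = (Q_{alv} C_{inh}/1000 + Q_{card} C_{ven}) /
  (Q_{card} + Q_{alv}/P_{b:a})$. The mixed venous return $C_{ven}$ needs a
  closure that the steady-state model does not supply; the package takes it
  as a caller argument with default 0 (complete peripheral extraction),
  which makes this mode a conservative lower bound on $C_{art}$.

Both modes are linear in $C_{inh}$, which the inversion relies on only
weakly (monotonicity is what matters).

**Metabolism and urine.** Liver venous blood, $C_{vl} = C_{liver}/P_{liver}$,
feeds Michaelis–Menten metabolism $v = V_{max} C_{vl} / (K_m + C_{vl})$
(mg/min), bounded by $V_{max}$ and concave. Over one micturition interval
the bladder collects $f_{ttMA} \cdot v \cdot 180 \cdot (142.11 / 78.11)$ mg
of tt-MA (the ratio converts benzene mass to tt-MA mass; benzene 78.11
g/mol, tt-MA 142.11 g/mol), diluted in the void volume to give mg/L of
urine. Because assumption (b) makes the rate constant at steady state, the
default is the product rate × interval; `integrate = TRUE` replaces it with
quadrature of the time-varying rate over the voiding window
(`stats::integrate`, relative tolerance 1e-10), which matters only for
voids collected before the liver has equilibrated.

The chain implies a hard ceiling on explainable observations:
$\max(\text{tt-MA}) = f_{ttMA} V_{max} \cdot 180 \cdot (142.11/78.11) /
V_{void}$ (`ttma_saturation_bound()`). Observations at or above it raise a
classed saturation error rather than returning a huge extrapolation.

## Parameters

| parameter | units | default | why |
|---|---|---|---|
| $Q_i$, $V_i$, $P_i$ | L/min, L, — | see `default_pbpk_parameters()` | order-of-magnitude values for a 32 kg child: flows split a 3 L/min cardiac output, volumes are weight fractions, partitions in the range reported for benzene (fat ≫ lean tissue) |
| $V_{max}$, $K_m$ | mg/min, mg/L | 0.35, 0.35 | saturable hepatic clearance with half-saturation well above ambient-exposure blood levels |
| $f_{ttMA}$ | — | 0.02 | within the single-digit-percent range reported for the urinary tt-MA yield of absorbed benzene; this is the dominant scaling uncertainty of the inversion |
| $P_{b:a}$ | — | 8.2 | typical human blood:air partition coefficient for benzene |
| void volume, interval | L, min | 0.2, 180 | school-age child void; three-hour interval is assumption (e) |
| RfC | mg/m³ | 0.03 | reference concentration, critical effect decreased lymphocyte count |
| IUR | (µg/m³)⁻¹ | 2.2e-6–7.8e-6 | leukemia inhalation unit risk interval; values quoted per mg/m³ are normalized via `iur_unit` |

The compartment and metabolism defaults are **illustrative**: each carries
a provenance string saying so, the YAML config
(`inst/extdata/pbpk_defaults.yaml`) lets every value be replaced with a
literature-sourced one (with a `<key>_source` sibling), and the pipeline
copies provenance into `run.log` so defaults are never silently mistaken
for measured values. No test asserts an absolute urine concentration from
these defaults — correctness is established by round-trip and limit
properties, which hold for any admissible parameter set.

Per-child physiology is scaled from the 32 kg reference by
`child_physiology()`: ventilation and cardiac output allometrically
(exponent 0.75), void volume linearly, with a measured urinary creatinine
replacing the reference when available.

## The inversion

Below saturation the forward map is continuous and strictly increasing, so
the inverse is unique. `invert_air_concentration()` doubles an upper
bracket from 1 mg/m³ until it straddles the observation (at most 200
doublings), refines with `stats::uniroot`, and then *verifies* the root by
evaluating the forward model there, requiring a relative mismatch below
1e-9. Zero observation returns zero exactly.

Cohort estimation inverts **per child** with that child's physiology and
then averages. The alternative — inverting the cohort-mean tt-MA once — is
kept as `mode = "pooled"` for comparison; with a skewed tt-MA distribution
the two differ, and per-child inversion is the one whose spread is
interpretable (an SD larger than the mean simply reflects the skew).

## Exposure and risk arithmetic

Chronic exposure is $CE = (C \cdot ET \cdot EF \cdot ED)/(1440 \cdot AT)$
with $AT = ED \times 365$ days, under which $ED$ cancels algebraically —
a property the tests assert on random scenarios. Three standard scenarios
ship with the package: 4 h/day and 8 h/day for 6 years (children), and an
8 h/day lifetime projection to age 70. Because $ED$ cancels, the computed
lifetime CE equals the 8 h/day value; published lifetime projections often
embed age-dependent exposure-calculator adjustments this package does not
model, so `risk_table()` accepts a `scenario_c_ce_override` that lets such
an externally supplied CE flow through the risk arithmetic unchanged, while
the computed value stays visible in `CE_raw`.

Two presentation conventions, both applied only at the reporting surface
with raw values retained alongside:

* **HQ** divides the CE *rounded to 2 d.p.* by the RfC (so 1.60/0.03 →
  53.3; the unrounded ratio is 53.4) and is reported at 1 d.p.
* **Cancer risk** is reported at 1 significant figure per 1000 exposed.
  Note one consequence: a raw risk of 12.48 × 10⁻³ presents as 10 per
  1000. The package reports this rounding faithfully but its tests pin
  only values that are unambiguous under the convention.

`population_burden()` multiplies exposure units by children per unit
(234 workshops × 2 children = 468), expresses that as a rounded percentage
of a reference population, and takes nearest-integer expected cases from
the *rounded* per-capita risk interval — matching how such burdens are
quoted in practice (1–3 cases at 2–6 per 1000; 2–5 at 4–10 per 1000).

## Synthetic data: what it emulates, what it does not

`generate_cohort()` emulates the *structure* of a 41-child biomonitoring
sample: Bernoulli censoring below the LOQ (expected 23/41), abnormal
albumin/creatinine flags among the quantifiable (expected 3/18),
retained tt-MA drawn from a lognormal whose $(\mu, \sigma)$ are
moment-matched in closed form ($\mu = \ln(m^2/\sqrt{m^2+s^2})$,
$\sigma^2 = \ln(1+s^2/m^2)$) to mean 0.81 and SD 0.83 mg/L, ages uniform
on 6–12, and anthropometry from a linear growth reference with Gaussian
scatter. Censored values are uniform on (0, LOQ) — inconsequential, since
they are discarded. Everything is deterministic given the integer seed.

`fixture_cohort_41()` freezes one such cohort exactly: 23/3/15 by
construction, with the 15 retained tt-MA values affine-adjusted once so
their sample mean and SD (n−1 denominator) are 0.81 and 0.83 at 2 d.p.
It also ships as `inst/extdata/cohort_fixture_synthetic.csv`.

What passing tests on these data show: the exclusion logic, the inversion
numerics, the estimator's moments and the end-to-end plumbing are correct.
What they do not show: that any particular parameter set reproduces a real
cohort's air concentrations — real data have correlated
age/weight/creatinine structure, assay error that is not lognormal,
within-child temporal variability from single spot samples, and
between-child differences in $f_{ttMA}$ and metabolic capacity, none of
which the generator models.

A note on the LOQ: the package takes the LOQ in the same unit as the tt-MA
column (default 0.06 mg/L). Assay documentation sometimes quotes tt-MA
LOQs in µg/L; at 0.06 µg/L essentially no field sample would be censored,
which is inconsistent with half a cohort falling below it, so the mg/L
reading is the coherent one and the value is a config parameter either way.

## Numerical choices, edge cases, tie-breaks

* Effective steady state: the liver curve's relative shortfall from its
  asymptote is $(V P)/(V P + Q t)$, so the default evaluation time solves
  that for 1e-6 in closed form (`steady_state_time()`).
* Degenerate cohorts: one retained child reports SD 0 (flagged rather than
  NA so downstream arithmetic survives); zero retained children raise a
  classed empty-cohort error *after* the exclusion report is written.
* A record failing both exclusion rules counts as below-LOQ: censoring is
  applied first, so the two exclusion counts partition the cohort
  deterministically.
* Observations exactly at the saturation bound are rejected (the bound is
  an open supremum, reached only in the limit).
* All validation failures are classed conditions
  (`benzrisk_domain_error`, `benzrisk_validation_error`,
  `benzrisk_saturation_error`, `benzrisk_empty_cohort_error`, ...) so
  callers and the CLI can map them to exit codes.

## Problem sizes

The test suite exercises 100-draw parameter-randomization loops for the
round-trip and limit properties, a 200-child noisy cohort (geometric SD
1.5) for median parameter recovery within 5%, and 10⁴ Monte Carlo draws
for the lognormal moment check; the full suite runs in a few seconds on a
single CPU. These sizes were chosen as the smallest at which the
stochastic checks are comfortably stable across seeds.

## Known limitations

* Steady-state only: no transient multi-day ODE simulation, no dermal or
  oral routes, and a single lumped tt-MA fraction rather than full
  metabolite speciation.
* The benzene half-life parameter is carried in `metabolism_params()` for
  completeness but unused by the steady-state chain.
* $f_{ttMA}$ scales the inversion linearly end to end; its uncertainty
  dominates any absolute air-concentration estimate made with default
  parameters.
* Risk arithmetic is deterministic; no Monte Carlo uncertainty
  propagation, and no age-dependent adjustment factors for early-life
  carcinogen exposure.
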