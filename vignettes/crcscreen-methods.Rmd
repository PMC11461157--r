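---
title: "Methods: the crcscreen microsimulation and cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the crcscreen microsimulation and cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`crcscreen` estimates the comparative and cost-effectiveness of colorectal
cancer (CRC) screening strategies — annual fecal immunochemical testing
(FIT), decennial colonoscopy, and blood tests of configurable accuracy,
interval and price — for a US average-risk cohort entering at age 45. This
vignette documents the model, its assumptions, the tunable parameters, the
reproducibility scheme, and the limits of what a green test establishes.

## The natural-history model

Established CRC policy models (the CISNET colon models) are individually
calibrated, proprietary microsimulations. `crcscreen` replaces them with
**one configurable stand-in** that reproduces the *structure* those models
share and is calibrated to a single published summary statistic, not to
their full output:

1. **Adenoma onset.** Each person carries a lognormal frailty
   $f_i = \exp(\sigma Z_i - \sigma^2/2)$ (mean 1, log-SD $\sigma$ =
   `adenoma_risk_dispersion`, default 1.1), concentrating adenomas in a
   minority of the cohort as colonoscopy prevalence studies suggest.
   Adenomas arise as a non-homogeneous Poisson process on ages
   [20, `max_age`]: onset ages have density proportional to
   $((a-20)/(\text{max\_age}-20))^g$ with $g$ = `onset_age_shape`
   (default 1.2), and a frailty-1 person expects `baseline_onset_rate`
   onsets by `max_age` (default 3.16, set by calibration — see below).
   Lesion slots are capped at `max_lesions` = 12 per person so the
   per-person random-number layout is parameter-independent.
2. **Progression.** Each adenoma independently (no interaction between
   lesions) waits a Weibull time (shape 1.1, scale 45 y) to become
   *advanced* (≥ 10 mm, the category whose removal prevents cancer). An
   advanced adenoma progresses to *preclinical cancer* with probability
   0.40 after a Weibull dwell (shape 1.3, scale 12 y), otherwise never.
   Preclinical cancer surfaces clinically after a Weibull **sojourn time**
   (shape 2, scale 4 y, mean ≈ 3.5 y) during which it is screen-detectable
   but asymptomatic.
3. **Stage and survival.** Cancers are staged early/late at detection:
   symptom-detected cancers are early with probability 0.55,
   screen-detected cancers with probability 0.85 — this **stage shift is
   the sole survival benefit of detecting an existing cancer**, while
   polypectomy of advanced adenomas is the prevention mechanism. Survival
   after diagnosis is a stage-specific cure fraction (early 0.82, late
   0.30) plus a Weibull time to CRC death for the non-cured (shape 1.2,
   scale 6 y early / 2.5 y late).
4. **Competing mortality.** Other-cause death ages are drawn from an annual
   life table; the default renders a Gompertz–Makeham hazard
   ($A = 8\times10^{-4}$, $B = 2.75\times10^{-5}$, $\theta = 0.092$) whose
   remaining life expectancy at 45 is ≈ 37 years, matching a modern US
   cohort without requiring a data download. A cohort life table can be
   supplied as a CSV (`age,q`).

**Calibration.** The published quantity the stand-in is anchored to is the
unscreened burden: the three established models project 32–36 lifetime CRC
deaths per 1000 unscreened 45-year-olds. `calibrate_defaults()` bisects
`baseline_onset_rate` (falling back to a coarse grid over the progression
probability) against that envelope under common random numbers; the shipped
default (3.09375) was fixed with n = 200 000 at seed 1 and lands near the
midpoint (≈ 33.5–34.7 across seeds). Secondary behaviour is realistic
rather than fitted: ≈ 90 clinical cancers per 1000 unscreened (mean
diagnosis age ≈ 73), ≈ 35 % adenoma and ≈ 9 % advanced-adenoma prevalence
at 60.

**Entry condition.** The cohort is average-risk and cancer-free at entry:
lesions that would have surfaced clinically before age 45 are excluded at
simulation. Prevalent adenomas and preclinical cancers at 45 are retained —
they are exactly what the first screen can find.

## The screening engine

Each strategy is a state machine applied to the fixed natural history:

- Routine screens run every `interval` years from 45 while the exam age is
  ≤ 75. Noninvasive tests are **person-level**: the positivity probability
  depends on the most advanced lesion present (`sens_crc` for preclinical
  cancer, `sens_adv_adenoma` for advanced adenoma, `1 − specificity` for a
  non-advanced-only or clear colon). A positive in a person with any lesion
  is a true positive; a false positive requires a colon in which the
  follow-up colonoscopy finds nothing.
- Any positive noninvasive test triggers an immediate follow-up
  colonoscopy with **lesion-level** sensitivity (0.91 per adenoma and per
  preclinical cancer, independently). Detected adenomas are removed and
  their future progression cancelled; the procedure costs $1312.36 with
  removal, $963.95 without.
- Adenoma findings put the person under colonoscopy surveillance until age
  85: 3-year interval after high-risk findings (any advanced adenoma or
  ≥ 3 adenomas), 7 years after 1–2 non-advanced adenomas, 10 years after a
  clean surveillance exam. The published analyses cite guidelines without
  printing intervals, so these are package defaults, documented here, not
  source values. A clean follow-up colonoscopy after a false-positive
  screen resumes the routine regimen 10 years later.
- Symptomatic (clinical) diagnosis preempts any same-age screen; it incurs
  a diagnostic colonoscopy cost. A screen-detected cancer ends the
  screening regimen (single-primary convention: later cancers in other
  lesions are ignored, a simplification that is negligible at cohort
  scale).
- Each colonoscopy carries an independent complication risk (default
  0.25 %, $7000, 14 quality-adjusted days).

**Lead time is not credited.** For a screen-detected cancer the survival
clock starts at the age the lesion *would have surfaced clinically*, not at
detection. Combined with the coupling below this guarantees that earlier
detection can only improve an individual's cancer outcome, removing
lead-time bias from the projected benefit.

**FIT defaults.** Person-level sensitivities 23.8 % (advanced adenoma) and
73.8 % (CRC) and $23.42 per test are published inputs; the specificity
(96.4 %) and the zero per-test disutility are package placeholders for
values the published analyses keep in supplementary material. Blood tests
are assumed
to carry no differential disutility relative to FIT.

## Reproducibility and common random numbers

A single master seed fans out into named 31-bit substreams keyed by
`(seed, person, purpose)` (`substream_seed()`, `stream_id()`):

- Person *i*'s natural history depends only on the seed and *i*, so a
  cohort of *n* is a prefix of any larger cohort, and results are invariant
  to person ordering.
- Raw uniforms are drawn once per person in a fixed layout and transformed
  into event times afterwards, so *parameter sets* also share randomness —
  calibration bisects a smooth monotone objective.
- All strategies reuse the same natural histories; only test, complication
  and procedure draws come from a strategy-specific stream keyed by the
  regimen's **clinical signature, excluding price**. Scenarios differing
  only in unit cost therefore share identical event histories (their QALYs
  are bit-identical, and costs are repriced analytically via the
  discounted test count), and a test with zero sensitivity and perfect
  specificity reproduces the no-screening life course exactly.
- Stage-at-detection, cure and survival-time draws are *coupled* through
  shared per-lesion uniforms with the screen-detected early-stage fraction
  at least the clinical fraction, so screening cannot harm a cancer
  outcome through randomness alone.

## Economics

All costs (2021 USD) and benefits are discounted to age 45 at 3 %/year;
amounts exactly at 45 are undiscounted (half-open convention). Life-years
are integrated with the same kernel in closed form. QALYs subtract
per-event disutilities (days per test/colonoscopy/complication) and a
per-diagnosis cancer-care decrement (0.25/0.60 QALYs early/late). Treatment
costs are lumped: a stage cost at diagnosis ($70k early / $140k late) plus
a terminal-care cost ($80k) at CRC death — a stand-in for phase-based
costing whose magnitudes were chosen once so that unscreened CRC care costs
≈ $5.5k per person, inside the published $5268–5845 range, and that
preserves the cost-offset mechanism that makes FIT cost-saving. ICERs are
computed between consecutive efficient strategies after strict and
extended dominance; the least effective nondominated strategy carries no
ICER. Exact QALY/cost ties are kept-first by input order and flagged.

## Threshold analysis and scenario discovery

The default factorial design is 3 CRC sensitivities × 5 advanced-adenoma
sensitivities × 3 intervals × 20 costs = 900 scenarios at fixed 90 %
specificity, evaluated on a shared desk-scale cohort (default 2×10⁴ persons
versus the original 10⁷ per model — common random numbers keep
between-strategy contrasts stable at this size, which is why the package's
checks compare strategies rather than absolute levels). A scenario is
*cost-effective* if it is neither strictly nor extended dominated by no
screening, FIT or colonoscopy and its ICER is below $150 000/QALY (a
cost-saving efficient scenario qualifies). `models = k` runs k perturbed
natural-history parameter sets (±6 % onset rate) to mimic cross-model
ranges; this mimics, but does not reproduce, the published three-model
spread.

Discovery proceeds in the published two steps. First a random-forest
classifier (500 trees, `mtry = floor(sqrt(p))`, one-hot-encoded interval
and model, seeded) is trained on the binary cost-effectiveness label, and
variables are ranked by **mean decrease in Gini impurity**. The forest is
implemented in-package (no R random-forest implementation ships in the
supported environment); it is deliberately minimal and is validated against
constructed separable and null cases. One documented caveat: Gini
importance is biased toward predictors with many distinct values — under a
label independent of all predictors the 20-level cost variable still
attracts ≈ 2× the mean importance. This bias is shared by the standard
implementations; the package's null-stability test therefore uses
equal-cardinality predictors.

Second, a locally weighted regression (tricube weights, degree 1, span 0.5
— the published analyses name the method but not its span or degree, so
these are package choices) smooths NMB over (cost, advanced-adenoma sensitivity)
separately within each interval panel, conditioned on 92 % CRC sensitivity
and averaged across model replicates. The "evenly spaced 3-dimensional grid
of 10 000 points" is realized as ≈ 10 000/3 points per interval panel
(58 × 58 each, with a warning when the requested total is not an integer
lattice). Contours are extracted by marching squares per panel; the
colonoscopy NMB level partitions each panel into regions where a blood
test would or would not match colonoscopy's value.

## What a green test does and does not establish

The test-suite verifies *structure and mechanism*: the calibration envelope,
determinism and prefix properties, the state machine's scheduling rules,
exact inert-test equivalence, monotonicity of gains in sensitivity and
against interval, frontier agreement with a brute-force dominance oracle,
the NMB identity, and the discovery stack on constructed inputs. It does
**not** establish that absolute QALY, cost or ICER levels match the
published three-model ranges: those arise from independently calibrated
models that this package deliberately replaces with one stand-in anchored
to a single mortality statistic. Qualitative orderings (the $500
CMS-minimum triennial blood test being dominated by FIT and colonoscopy;
FIT being cost-saving) do reproduce and are asserted, with the
calibration-dependent FIT check reported as a soft warning.

## Known limitations

- Perfect adherence to screening, follow-up and surveillance; differential
  adherence across modalities is out of scope by design.
- Two-stage (early/late) cancer model; four-stage machinery, within-colon
  lesion location, and birth-cohort incidence trends are not modeled.
- Sequential test results are independent Bernoulli draws given the current
  state; there is no persistent per-person test-failure correlation.
- No probabilistic sensitivity analysis; parameter uncertainty is explored
  only through the factorial design and the `models = k` perturbations.
- Treatment costs and disutilities are lumped stand-ins for phase-based
  schedules; absolute cost levels should be read as calibrated
  placeholders.
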