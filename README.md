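# crcscreen

Microsimulation and cost-effectiveness analysis of colorectal cancer (CRC)
screening, built to answer one policy question: **under what combination of
accuracy, screening interval and price is a blood-based CRC screening test as
effective and as cost-effective as annual fecal immunochemical testing (FIT)
or decennial colonoscopy?**

The package is aimed at health-economic modelers and test developers. It
provides:

- **`nathist`** — a calibrated stand-in natural-history model of the
  adenoma–carcinoma sequence: person-level lognormal frailty on adenoma risk,
  age-increasing adenoma onset, Weibull dwell times from non-advanced to
  advanced (≥ 10 mm) adenoma and on to preclinical cancer, a preclinical
  sojourn, early/late stage at detection, stage-specific survival, and
  competing other-cause mortality from a Gompertz–Makeham life table. The
  shipped defaults are calibrated so that an unscreened cohort of
  45-year-olds suffers ≈ 34 lifetime CRC deaths per 1000, inside the 32–36
  envelope spanned by the three established CISNET colon models.
- **`screening`** — a strategy engine applying FIT, colonoscopy or a
  configurable blood test to each life history: person-level sensitivity to
  the most advanced lesion for noninvasive tests, lesion-level sensitivity
  for colonoscopy, follow-up colonoscopy after any positive noninvasive
  test, polypectomy, surveillance until 85, resumption of routine screening
  10 years after a clean follow-up, and procedure complications. Strategies
  are compared under common random numbers.
- **`cea`** — discounted (3 %/year) life-years, QALYs and costs per 1000
  versus no screening; incremental cost-effectiveness ratios (ICERs) with
  strict and extended dominance; net monetary benefit
  `NMB = WTP × QALYG − net cost` at a willingness to pay of $100 000/QALY.
- **`threshold`** — a 900-scenario full factorial over blood-test CRC
  sensitivity (74/83/92 %), advanced-adenoma sensitivity (10–50 %),
  interval (1–3 y) and cost ($25–$500 by $25) at fixed 90 % specificity.
- **`discovery`** — scenario discovery: a seeded random-forest classifier
  ranks the design variables by mean decrease in Gini impurity, and a
  locally weighted regression builds a smoothed NMB surface over the top
  three characteristics (conditioned on 92 % CRC sensitivity) with iso-NMB
  contour lines, including the colonoscopy reference level.

## Worked example

```r
library(crcscreen)

cohort <- simulate_cohort(nathist_params(), n = 20000, seed = 1)
econ   <- econ_params()
o_ns   <- run_strategy(cohort, strategy_no_screening(), econ = econ)
sums   <- lapply(list(o_ns,
                      run_strategy(cohort, strategy_fit(),         econ = econ),
                      run_strategy(cohort, strategy_colonoscopy(), econ = econ),
                      run_strategy(cohort, strategy_blood(),       econ = econ)),
                 summarize_outcomes, no_screen_outcome = o_ns, econ = econ)
compute_frontier(sums, econ)
```

```
                            strategy qalyg_per_1000 net_cost_per_person
1                       No screening          0.000                 0.0
2                           FIT, 1 y        124.902             -2492.1
3                  Colonoscopy, 10 y        149.891             -1900.0
4 Blood (CRC 74%, AA 10%, $500), 3 y         85.505              1149.4
     status  icer     nmb
1 dominated    NA     0.0
2 efficient    NA 14982.3
3 efficient 23694 16889.1
4 dominated    NA  7401.2
```

Reading the table: relative to no screening, annual FIT adds 124.9
discounted QALYs per 1000 persons while *saving* $2492 per person (screening
averts expensive cancer care), so no screening is dominated. Colonoscopy
adds more QALYs at a higher (but still negative) net cost; its ICER versus
FIT is $23 694 per QALY gained. A $500 triennial blood test that only meets
the CMS minimum (74 % CRC sensitivity, 10 % advanced-adenoma sensitivity)
delivers fewer QALYs than either comparator at a higher cost — it is
dominated, and its net monetary benefit ($7401/person) is less than half of
colonoscopy's ($16 889).

The threshold and discovery layers scale this comparison across the
factorial design:

```r
cfg <- run_config(cohort_n = 20000, seed = 1, output_dir = "out")
tab <- run_threshold(cfg)       # writes out/scenarios.csv (900 rows)
run_discovery(cfg, tab)         # importance.csv, nmb_surface.csv, contours.json
```

## Acceptance script

`scripts/acceptance.R` regenerates the headline calibration quantity from
scratch: it simulates 200 000 unscreened persons from age 45 with the
shipped default natural-history parameters and reports lifetime CRC deaths
per 1000, which is compared against both edges of the published three-model
envelope. Run it from the repository root against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
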