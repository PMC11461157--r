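lt <- gompertz_makeham_life_table()

test_that("person-level test positivity follows the state-specific rates", {
  blood <- blood_test_profile()   # 74% CRC, 10% AA, 90% specificity
  draws <- function(state, profile, n = 10000) {
    ph <- switch(state,
      preclinical_crc = mk_person(50, adv = 52, preclin = 54, clinical = 70),
      advanced_adenoma = mk_person(50, adv = 52),
      nonadvanced_adenoma = mk_person(50),
      none = mk_person(numeric()))
    snap <- lesion_state_at(ph, 60)
    stopifnot(snap$state == state)
    set.seed(99)
    mean(vapply(seq_len(n),
                function(i) screening_test_outcome(snap, profile)$positive,
                logical(1)))
  }
  # binomial 99.9% CI half-width at n = 10000 is ~0.016 at p = 0.74
  expect_lt(abs(draws("preclinical_crc", blood) - 0.74), 0.016)
  expect_lt(abs(draws("none", blood) - 0.10), 0.012)
  expect_lt(abs(draws("advanced_adenoma", blood) - 0.10), 0.012)
  # nonadvanced-only persons are positive only through lack of specificity
  expect_lt(abs(draws("nonadvanced_adenoma", blood) - 0.10), 0.012)
  perfect <- test_profile("perfect-spec", "blood", sens_crc = 0.74,
                          specificity = 1)
  expect_equal(draws("nonadvanced_adenoma", perfect, n = 500), 0)
})

test_that("positive results in persons with lesions are not false positives", {
  ph <- mk_person(50, adv = 52)
  snap <- lesion_state_at(ph, 60)
  always <- test_profile("always-pos", "blood", sens_crc = 1,
                         sens_adv_adenoma = 1, specificity = 0)
  set.seed(1)
  out <- screening_test_outcome(snap, always)
  expect_true(out$positive)
  expect_equal(out$classification, "true_pos_adenoma")
  clear <- lesion_state_at(mk_person(numeric()), 60)
  out2 <- screening_test_outcome(clear, always)
  expect_equal(out2$classification, "false_pos")
})

test_that("screening a clinically symptomatic person is a logic error", {
  ph <- mk_person(50, adv = 52, preclin = 54, clinical = 58)
  snap <- lesion_state_at(ph, 60)
  expect_error(screening_test_outcome(snap, blood_test_profile()),
               "symptomatically")
})

test_that("colonoscopy detects per lesion and prices removal", {
  ph <- mk_person(onset = c(48, 50), adv = Inf)  # two nonadvanced adenomas
  perfect <- colonoscopy_profile(lesion_sens_adenoma = 1, lesion_sens_crc = 1,
                                 complication_prob = 0)
  set.seed(2)
  res <- perform_colonoscopy(ph, 60, integer(), perfect)
  expect_setequal(res$detected_ids, c(1L, 2L))
  expect_true(res$any_removal)
  expect_equal(res$cost, 1312.36)

  clean <- mk_person(numeric())
  res2 <- perform_colonoscopy(clean, 60, integer(), perfect)
  expect_length(res2$detected_ids, 0)
  expect_equal(res2$cost, 963.95)

  blind <- colonoscopy_profile(lesion_sens_adenoma = 0, lesion_sens_crc = 0,
                               complication_prob = 0)
  res3 <- perform_colonoscopy(ph, 60, integer(), blind)
  expect_length(res3$detected_ids, 0)
  expect_equal(res3$cost, 963.95)
})

test_that("next_due implements the resumption and surveillance state machine", {
  st <- strategy_blood(interval = 3)
  # clean follow-up colonoscopy at 52 -> routine screen resumes at 62
  expect_equal(next_due(52, "followup_negative", st),
               list(age = 62, mode = "routine"))
  # advanced adenoma removed at 60 -> high-risk surveillance at 63
  expect_equal(next_due(60, "adenoma_high_risk", st),
               list(age = 63, mode = "surveillance"))
  expect_equal(next_due(60, "adenoma_low_risk", st),
               list(age = 67, mode = "surveillance"))
  # surveillance ends after 85
  expect_null(next_due(83, "adenoma_high_risk", st))
  expect_null(next_due(85, "surveillance_negative", st))
  # routine screens are not scheduled past 75
  expect_equal(next_due(72, "negative_screen", st)$age, 75)
  expect_null(next_due(73, "negative_screen", st))
})

test_that("an inert test reproduces no screening exactly; costs differ by tests", {
  coh <- simulate_cohort(nathist_params(), lt, n = 3000, seed = 8)
  o_ns <- run_strategy(coh, strategy_no_screening())
  inert <- strategy("Inert",
                    test_profile("Inert", "blood", sens_crc = 0,
                                 sens_adv_adenoma = 0, specificity = 1,
                                 unit_cost = 50),
                    interval = 1)
  o_in <- run_strategy(coh, inert)
  expect_identical(o_in$per_person$ly_disc, o_ns$per_person$ly_disc)
  expect_identical(o_in$per_person$crc_death, o_ns$per_person$crc_death)
  expect_identical(o_in$per_person$crc_case, o_ns$per_person$crc_case)
  extra <- o_in$per_person$cost_disc - o_ns$per_person$cost_disc
  expect_equal(extra, 50 * o_in$per_person$test_count_disc)
  # no-screening CRC deaths equal the natural-history count identically
  expect_equal(mean(o_ns$per_person$crc_death) * 1000,
               unscreened_crc_deaths_per_1000(coh))
})

test_that("screening with positive sensitivity cannot increase CRC deaths (CRN)", {
  coh <- simulate_cohort(nathist_params(), lt, n = 5000, seed = 21)
  o_ns <- run_strategy(coh, strategy_no_screening())
  for (st in list(strategy_fit(), strategy_colonoscopy(), strategy_blood())) {
    o <- run_strategy(coh, st)
    expect_lte(sum(o$per_person$crc_death), sum(o_ns$per_person$crc_death))
  }
})

test_that("event logs are conserved and respect the age rules", {
  coh <- simulate_cohort(nathist_params(), lt, n = 800, seed = 23)
  o <- run_strategy(coh, strategy_fit(), keep_events = TRUE)
  ev <- o$events
  expect_true(all(c("person_id", "age", "event", "detail") %in% names(ev)))
  # events are age-ordered within person
  expect_true(all(unlist(tapply(ev$age, ev$person_id, function(a) diff(a) >= 0))))
  # every positive noninvasive screen has exactly one follow-up colonoscopy
  pos <- ev[ev$event == "screen_test" & grepl(":positive$", ev$detail), ]
  fol <- ev[ev$event == "followup_colonoscopy", ]
  expect_equal(nrow(pos), nrow(fol))
  expect_equal(paste(pos$person_id, pos$age), paste(fol$person_id, fol$age))
  # no routine screens after the stop age, no surveillance after 85
  expect_true(all(ev$age[ev$event == "screen_test"] <= 75))
  expect_true(all(ev$age[ev$event == "surveillance_colonoscopy"] <= 85))
  # no screening events after death
  deaths <- ev[ev$event %in% c("crc_death", "other_death"), ]
  dage <- tapply(deaths$age, deaths$person_id, min)
  screens <- ev[ev$event %in% c("screen_test", "followup_colonoscopy",
                                "surveillance_colonoscopy"), ]
  expect_true(all(screens$age <= dage[as.character(screens$person_id)] |
                  is.na(dage[as.character(screens$person_id)])))
})

test_that("annual perfect colonoscopy intercepts lesions arising in the screening window", {
  # stage durations concentrated near 4 years (Weibull shape 40) so every
  # progression step takes >2 years with near certainty; annual exams with
  # perfect lesion sensitivity must then remove every adenoma with onset in
  # [45, 75] before it can become cancer
  p <- nathist_params(baseline_onset_rate = 5,
                      dwell_nonadv_to_adv = list(shape = 40, scale = 4),
                      dwell_adv_to_preclinical = list(prob = 1, shape = 40, scale = 4),
                      sojourn_time = list(shape = 40, scale = 4))
  coh <- simulate_cohort(p, lt, n = 1500, seed = 29)
  st <- strategy("Annual colonoscopy",
                 test_profile("Colonoscopy", "colonoscopy"), interval = 1)
  perfect <- colonoscopy_profile(lesion_sens_adenoma = 1, lesion_sens_crc = 1,
                                 complication_prob = 0)
  o <- run_strategy(coh, st, colo = perfect, keep_events = TRUE)
  diag <- o$events[o$events$event == "crc_diagnosis_clinical", ]
  # oracle: walk each diagnosed person's lesions; the culprit lesion (its
  # clinical age equals the diagnosis age) must have arisen outside [45, 75]
  for (k in seq_len(nrow(diag))) {
    ph <- crcscreen:::cohort_person_history(coh, diag$person_id[k])
    culprit <- ph$lesions[abs(ph$lesions$clinical_age - diag$age[k]) < 1e-9, ]
    expect_equal(nrow(culprit), 1L)
    expect_true(culprit$onset_age < 45 || culprit$onset_age > 75)
  }
})

test_that("shorter intervals weakly increase QALYs and strictly increase screening cost", {
  coh <- acc_cohort(8000L, 37L)
  o_ns <- run_strategy(coh, strategy_no_screening())
  outs <- lapply(c(3, 2, 1), function(iv)
    run_strategy(coh, strategy_blood(interval = iv, sens_adv_adenoma = 0.3)))
  q <- vapply(outs, function(o)
    summarize_outcomes(o, o_ns)$qalyg_per_1000, numeric(1))
  expect_true(all(diff(q) >= 0))
  # screening-cost component: discounted test count strictly increases
  tc <- vapply(outs, function(o) sum(o$per_person$test_count_disc), numeric(1))
  expect_true(all(diff(tc) > 0))
})
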