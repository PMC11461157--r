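# Screening overlay: scheduled tests applied to natural histories, with
# person-level sensitivity for noninvasive tests, lesion-level sensitivity
# for colonoscopy, follow-up colonoscopy after a positive noninvasive test,
# polypectomy (which cancels a lesion's future progression), surveillance
# until 85, the resume-at-10-years rule after a clean follow-up, and
# procedure complications. Natural histories are shared across strategies
# (common random numbers); only test/complication/stage draws come from a
# strategy-specific substream.

#' Screening test profile
#'
#' Accuracy, cost and disutility of one screening test. Noninvasive tests
#' (stool, blood) use person-level sensitivity: the positivity probability is
#' determined by the person's most advanced lesion. Colonoscopy uses
#' lesion-level sensitivity (see [colonoscopy_profile()]).
#'
#' @param name display name.
#' @param modality one of `"stool"`, `"blood"`, `"colonoscopy"`, `"none"`.
#' @param sens_crc person-level sensitivity to preclinical CRC.
#' @param sens_adv_adenoma person-level sensitivity to advanced adenoma.
#' @param sens_nonadv_adenoma person-level sensitivity when the most advanced
#'   lesion is a non-advanced adenoma; `NULL` (the default for noninvasive
#'   tests) means such persons test positive only through lack of
#'   specificity, i.e. with probability `1 - specificity`.
#' @param specificity probability of a negative test given no lesion.
#' @param unit_cost USD per administration.
#' @param disutility_days quality-adjusted days lost per administration.
#' @return a list of class `test_profile`.
#' @export
test_profile <- function(name, modality = c("blood", "stool", "colonoscopy", "none"),
                         sens_crc = 0, sens_adv_adenoma = 0,
                         sens_nonadv_adenoma = NULL, specificity = 1,
                         unit_cost = 0, disutility_days = 0) {
  modality <- match.arg(modality)
  probs <- c(sens_crc, sens_adv_adenoma, specificity, sens_nonadv_adenoma)
  if (any(probs < 0 | probs > 1))
    stop("test_profile: probabilities must lie in [0, 1]")
  stopifnot(unit_cost >= 0, disutility_days >= 0)
  structure(list(name = name, modality = modality,
                 sensitivity_level = if (modality == "colonoscopy") "lesion" else "person",
                 sens_crc = sens_crc, sens_adv_adenoma = sens_adv_adenoma,
                 sens_nonadv_adenoma = sens_nonadv_adenoma,
                 specificity = specificity, unit_cost = unit_cost,
                 disutility_days = disutility_days),
            class = "test_profile")
}

#' Annual fecal immunochemical test (FIT) profile
#'
#' Person-level sensitivities 23.8% (advanced adenoma) and 73.8% (CRC) with
#' a unit cost of $23.42. The specificity (96.4%) and the zero per-test
#' disutility are documented package defaults, not headline inputs.
#' @param unit_cost USD per test.
#' @export
fit_test_profile <- function(unit_cost = 23.42)
  test_profile("FIT", "stool", sens_crc = 0.738, sens_adv_adenoma = 0.238,
               specificity = 0.964, unit_cost = unit_cost)

#' Blood-test profile
#'
#' Defaults follow the CMS coverage minimum: 74% CRC sensitivity, 90%
#' specificity, 10% advanced-adenoma sensitivity (advanced adenomas found
#' only through lack of specificity), $500 per test, no differential
#' disutility relative to FIT.
#' @param sens_crc,sens_adv_adenoma,specificity accuracy parameters.
#' @param unit_cost USD per test.
#' @export
blood_test_profile <- function(sens_crc = 0.74, sens_adv_adenoma = 0.10,
                               specificity = 0.90, unit_cost = 500)
  test_profile(sprintf("Blood (CRC %g%%, AA %g%%, $%g)", 100 * sens_crc,
                       100 * sens_adv_adenoma, unit_cost),
               "blood", sens_crc = sens_crc,
               sens_adv_adenoma = sens_adv_adenoma,
               specificity = specificity, unit_cost = unit_cost)

#' Colonoscopy operating profile
#'
#' Lesion-level sensitivity of 91% for both adenomas and CRC; each lesion is
#' detected independently and detected adenomas are removed (their future
#' progression is cancelled). The cost depends on whether any lesion was
#' removed. Complication risk, cost and disutility are per procedure.
#'
#' @param lesion_sens_adenoma,lesion_sens_crc per-lesion detection
#'   probabilities.
#' @param specificity probability of no spurious finding in a clean colon
#'   (the model books no cost or action for colonoscopy false positives, so
#'   values below 1 have no effect; retained for completeness).
#' @param cost_without_removal,cost_with_removal USD per procedure.
#' @param complication_prob per-procedure complication probability.
#' @param complication_cost USD per complication.
#' @param complication_disutility_days quality-adjusted days lost per
#'   complication.
#' @param disutility_days quality-adjusted days lost per procedure.
#' @return a list of class `colonoscopy_profile`.
#' @export
colonoscopy_profile <- function(lesion_sens_adenoma = 0.91,
                                lesion_sens_crc = 0.91,
                                specificity = 1.0,
                                cost_without_removal = 963.95,
                                cost_with_removal = 1312.36,
                                complication_prob = 0.0025,
                                complication_cost = 7000,
                                complication_disutility_days = 14,
                                disutility_days = 1) {
  probs <- c(lesion_sens_adenoma, lesion_sens_crc, specificity, complication_prob)
  if (any(probs < 0 | probs > 1))
    stop("colonoscopy_profile: probabilities must lie in [0, 1]")
  if (cost_with_removal < cost_without_removal)
    stop("colonoscopy_profile: cost_with_removal must be >= cost_without_removal")
  structure(list(lesion_sens_adenoma = lesion_sens_adenoma,
                 lesion_sens_crc = lesion_sens_crc, specificity = specificity,
                 cost_without_removal = cost_without_removal,
                 cost_with_removal = cost_with_removal,
                 complication_prob = complication_prob,
                 complication_cost = complication_cost,
                 complication_disutility_days = complication_disutility_days,
                 disutility_days = disutility_days),
            class = "colonoscopy_profile")
}

#' Surveillance policy after adenoma detection
#'
#' After adenomas are found and removed at any colonoscopy, the person
#' follows colonoscopy surveillance until `stop_age`: high-risk findings
#' (any advanced adenoma, or three or more adenomas) return at the high-risk
#' interval, one or two non-advanced adenomas at the low-risk interval, and a
#' clean surveillance exam at the `clear` interval. The interval values are
#' package defaults approximating US guidelines.
#'
#' @param high_risk,low_risk,clear intervals in years.
#' @param stop_age last age at which a surveillance exam may occur.
#' @return a list of class `surveillance_policy`.
#' @export
surveillance_policy <- function(high_risk = 3, low_risk = 7, clear = 10,
                                stop_age = 85) {
  stopifnot(high_risk >= 1, low_risk >= 1, clear >= 1, stop_age >= 75)
  structure(list(high_risk = high_risk, low_risk = low_risk, clear = clear,
                 stop_age = stop_age), class = "surveillance_policy")
}

#' Screening strategy
#'
#' A primary test embedded in a regimen: routine screening every `interval`
#' years from `start_age` while the exam age does not exceed `stop_age`,
#' follow-up colonoscopy after any positive noninvasive test, surveillance
#' per `surveillance` after polypectomy, and resumption of the routine
#' regimen `resume_after_negative_followup` years after a clean follow-up
#' colonoscopy.
#'
#' @param name display name.
#' @param primary_test a [test_profile()].
#' @param interval routine interval in years (`Inf` for no screening).
#' @param start_age,stop_age routine screening window (default 45-75).
#' @param surveillance a [surveillance_policy()].
#' @param resume_after_negative_followup years until the next routine screen
#'   after a negative follow-up colonoscopy (default 10).
#' @return a list of class `screening_strategy`.
#' @export
strategy <- function(name, primary_test, interval, start_age = 45,
                     stop_age = 75, surveillance = surveillance_policy(),
                     resume_after_negative_followup = 10) {
  if (!inherits(primary_test, "test_profile"))
    stop("strategy: 'primary_test' must be a test_profile")
  if (start_age >= stop_age) stop("strategy: start_age must precede stop_age")
  if (interval < 1) stop("strategy: interval must be >= 1 year")
  if (surveillance$stop_age < stop_age)
    stop("strategy: surveillance stop_age must be >= strategy stop_age")
  structure(list(name = name, primary_test = primary_test,
                 interval = interval, start_age = start_age,
                 stop_age = stop_age, surveillance = surveillance,
                 resume_after_negative_followup = resume_after_negative_followup),
            class = "screening_strategy")
}

#' @rdname strategy
#' @export
strategy_no_screening <- function()
  strategy("No screening", test_profile("None", "none"), interval = Inf)

#' @rdname strategy
#' @export
strategy_fit <- function(interval = 1)
  strategy("FIT, 1 y", fit_test_profile(), interval = interval)

#' @rdname strategy
#' @export
strategy_colonoscopy <- function(interval = 10)
  strategy("Colonoscopy, 10 y",
           test_profile("Colonoscopy", "colonoscopy"), interval = interval)

#' @rdname strategy
#' @param ... passed to [blood_test_profile()].
#' @export
strategy_blood <- function(interval = 3, ...) {
  tp <- blood_test_profile(...)
  strategy(sprintf("%s, %g y", tp$name, interval), tp, interval = interval)
}

# stream label: the clinical signature of a regimen. Costs and disutilities
# are deliberately excluded so that regimens differing only in price share
# identical screening randomness.
regimen_stream_label <- function(strategy) {
  tp <- strategy$primary_test
  paste("screen", tp$modality, tp$sens_crc, tp$sens_adv_adenoma,
        if (is.null(tp$sens_nonadv_adenoma)) "spec" else tp$sens_nonadv_adenoma,
        tp$specificity, strategy$interval, strategy$start_age,
        strategy$stop_age, sep = "|")
}

#' Outcome of one noninvasive screening test
#'
#' Person-level positivity rule: the probability of a positive result is
#' `sens_crc` if the most advanced lesion is preclinical CRC,
#' `sens_adv_adenoma` for an advanced adenoma, and `1 - specificity` when the
#' most advanced lesion is a non-advanced adenoma (unless
#' `sens_nonadv_adenoma` is set) or the colon is clear. A positive result in
#' a person with any lesion is a true positive; only a positive in a clear
#' colon is a false positive. Draws one uniform from the current RNG stream.
#'
#' @param snapshot a `lesion_snapshot` from [lesion_state_at()].
#' @param profile a person-level [test_profile()].
#' @return list with `positive` (logical) and `classification` (one of
#'   `"true_pos_crc"`, `"true_pos_adenoma"`, `"false_pos"`, `"true_neg"`,
#'   `"false_neg"`).
#' @export
screening_test_outcome <- function(snapshot, profile) {
  if (profile$sensitivity_level != "person")
    stop("screening_test_outcome: profile must use person-level sensitivity")
  if (snapshot$state == "clinical_crc")
    stop("screening_test_outcome: clinical CRC must be diagnosed symptomatically, not screened")
  p <- positivity_prob(snapshot$state, profile)
  positive <- stats::runif(1L) < p
  classification <-
    if (positive) switch(snapshot$state,
                         preclinical_crc = "true_pos_crc",
                         advanced_adenoma = ,
                         nonadvanced_adenoma = "true_pos_adenoma",
                         none = "false_pos")
    else if (snapshot$state == "none") "true_neg" else "false_neg"
  list(positive = positive, classification = classification)
}

positivity_prob <- function(state, profile) {
  switch(state,
         preclinical_crc = profile$sens_crc,
         advanced_adenoma = profile$sens_adv_adenoma,
         nonadvanced_adenoma =
           if (is.null(profile$sens_nonadv_adenoma)) 1 - profile$specificity
           else profile$sens_nonadv_adenoma,
         none = 1 - profile$specificity,
         stop("positivity_prob: unexpected state ", state))
}

#' Perform a colonoscopy on one person
#'
#' Each present, non-removed lesion is detected independently: adenomas with
#' probability `lesion_sens_adenoma`, preclinical cancers with
#' `lesion_sens_crc`. Detected adenomas are removed. The procedure cost is
#' `cost_with_removal` if at least one lesion was removed, otherwise
#' `cost_without_removal`; a complication is drawn independently. Draws from
#' the current RNG stream.
#'
#' @param person a `person_history`.
#' @param age exam age; the person must be alive.
#' @param removed_ids lesions excised at earlier exams.
#' @param profile a [colonoscopy_profile()].
#' @return list with `detected_ids`, `removed_ids` (updated), `crc_found_ids`
#'   (detected preclinical cancers), `any_removal`, `complication`, `cost`.
#' @export
perform_colonoscopy <- function(person, age, removed_ids = integer(),
                                profile = colonoscopy_profile()) {
  if (age >= person$other_cause_death_age)
    stop("perform_colonoscopy: person is not alive at this age")
  les <- person$lesions
  keep <- !(les$lesion_id %in% removed_ids)
  states <- lesion_states_vec(les[keep, , drop = FALSE], age)
  ids <- les$lesion_id[keep]
  present <- states %in% c("nonadvanced_adenoma", "advanced_adenoma", "preclinical_crc")
  ids <- ids[present]; states <- states[present]
  p_det <- ifelse(states == "preclinical_crc", profile$lesion_sens_crc,
                  profile$lesion_sens_adenoma)
  detected <- if (length(ids)) stats::runif(length(ids)) < p_det else logical()
  det_ids <- ids[detected]
  det_states <- states[detected]
  crc_found <- det_ids[det_states == "preclinical_crc"]
  removed_new <- det_ids[det_states != "preclinical_crc"]
  any_removal <- length(removed_new) > 0L
  complication <- stats::runif(1L) < profile$complication_prob
  list(detected_ids = det_ids,
       removed_ids = c(removed_ids, removed_new),
       crc_found_ids = crc_found,
       any_removal = any_removal,
       complication = complication,
       cost = if (any_removal) profile$cost_with_removal else profile$cost_without_removal)
}

#' Age of the next scheduled exam
#'
#' Pure state-machine mapping used by the simulator: given the exam age, its
#' outcome class and the current mode, returns the next exam (age and mode)
#' or `NULL` when no further exams are scheduled. Routine exams are only
#' scheduled up to the strategy `stop_age`; surveillance exams up to the
#' surveillance `stop_age` (85), after which screening stops.
#'
#' @param age age of the exam just performed.
#' @param outcome one of `"negative_screen"` (routine noninvasive negative),
#'   `"followup_negative"` (clean colonoscopy after a positive noninvasive
#'   test), `"routine_colonoscopy_negative"`, `"adenoma_low_risk"`,
#'   `"adenoma_high_risk"`, `"surveillance_negative"`.
#' @param strategy a [strategy()].
#' @return `NULL`, or a list with `age` and `mode` (`"routine"` or
#'   `"surveillance"`).
#' @export
next_due <- function(age, outcome, strategy) {
  sv <- strategy$surveillance
  nxt <- switch(outcome,
    negative_screen = list(age = age + strategy$interval, mode = "routine"),
    routine_colonoscopy_negative = list(age = age + strategy$interval, mode = "routine"),
    followup_negative = list(age = age + strategy$resume_after_negative_followup,
                             mode = "routine"),
    adenoma_low_risk = list(age = age + sv$low_risk, mode = "surveillance"),
    adenoma_high_risk = list(age = age + sv$high_risk, mode = "surveillance"),
    surveillance_negative = list(age = age + sv$clear, mode = "surveillance"),
    stop("next_due: unknown outcome class ", outcome))
  cap <- if (nxt$mode == "routine") strategy$stop_age else sv$stop_age
  if (nxt$age > cap) NULL else nxt
}
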