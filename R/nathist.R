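# Natural-history model: each person carries a lognormal frailty that scales
# an age-increasing adenoma onset intensity; every adenoma may dwell to
# advanced (>= 10 mm) status, may then progress to preclinical cancer, and
# after a sojourn time surfaces clinically. Stage at detection and stage-
# specific survival couple screen-detected and clinically detected outcomes
# through shared per-lesion uniforms, so that earlier detection can only
# improve a person's cancer outcome (common random numbers).

STREAM_NATHIST <- 1L

#' Natural-history parameters for the adenoma-carcinoma model
#'
#' Defines one configurable stand-in natural history: adenoma onset is a
#' non-homogeneous Poisson process with person-level lognormal frailty and a
#' polynomial age effect on `[20, max_age]`; dwell times (non-advanced to
#' advanced, advanced to preclinical cancer) and the preclinical sojourn time
#' are Weibull; cancers are staged early/late with separate stage
#' distributions for screen-detected and symptom-detected disease; survival
#' after diagnosis is a stage-specific cure fraction plus a Weibull time to
#' cancer death for the non-cured.
#'
#' The default values ship calibrated so that an unscreened cohort entering
#' at age 45 experiences approximately 34 lifetime CRC deaths per 1000
#' persons, the midpoint of the 32-36 envelope spanned by the established
#' CISNET colon models for this cohort (see the package vignette).
#'
#' @param adenoma_risk_dispersion person-level log-risk standard deviation of
#'   the lognormal frailty (mean 1).
#' @param baseline_onset_rate expected number of adenoma onsets by `max_age`
#'   for a frailty-1 person.
#' @param onset_age_shape exponent `g >= 0` of the onset age effect: onset
#'   ages have density proportional to `((a - 20)/(max_age - 20))^g`.
#' @param dwell_nonadv_to_adv list `(shape, scale)` of the Weibull years from
#'   adenoma onset to advanced (>= 10 mm) status.
#' @param dwell_adv_to_preclinical list `(prob, shape, scale)`: probability an
#'   advanced adenoma ever progresses to preclinical cancer, and the Weibull
#'   dwell time if it does.
#' @param sojourn_time list `(shape, scale)` of the Weibull preclinical
#'   (screen-detectable, asymptomatic) sojourn before clinical surfacing.
#' @param stage_fractions_clinical,stage_fractions_screen named probability
#'   vectors over `c("early", "late")` summing to 1; the screen-detected
#'   early fraction must be at least the clinical early fraction (stage
#'   shift is the mechanism by which screening improves survival).
#' @param crc_survival list with `cure` (named per-stage cure probabilities),
#'   `shape`, and `scale` (named per-stage Weibull scale, years) of survival
#'   after diagnosis for non-cured cases.
#' @param max_age closing age of the simulation (years).
#' @param max_lesions per-person cap on simulated adenomas; a fixed cap keeps
#'   the per-person random-number layout independent of the parameters, which
#'   preserves common random numbers across parameter sets.
#' @return a validated list of class `nathist_params`.
#' @export
nathist_params <- function(adenoma_risk_dispersion = 1.1,
                           baseline_onset_rate = 3.1640625,
                           onset_age_shape = 1.2,
                           dwell_nonadv_to_adv = list(shape = 1.1, scale = 45),
                           dwell_adv_to_preclinical = list(prob = 0.40, shape = 1.3, scale = 12),
                           sojourn_time = list(shape = 2, scale = 4),
                           stage_fractions_clinical = c(early = 0.55, late = 0.45),
                           stage_fractions_screen = c(early = 0.85, late = 0.15),
                           crc_survival = list(cure = c(early = 0.82, late = 0.30),
                                               shape = 1.2,
                                               scale = c(early = 6, late = 2.5)),
                           max_age = 100,
                           max_lesions = 12L) {
  p <- list(adenoma_risk_dispersion = adenoma_risk_dispersion,
            baseline_onset_rate = baseline_onset_rate,
            onset_age_shape = onset_age_shape,
            dwell_nonadv_to_adv = dwell_nonadv_to_adv,
            dwell_adv_to_preclinical = dwell_adv_to_preclinical,
            sojourn_time = sojourn_time,
            stage_fractions_clinical = stage_fractions_clinical,
            stage_fractions_screen = stage_fractions_screen,
            crc_survival = crc_survival,
            max_age = max_age,
            max_lesions = as.integer(max_lesions))
  validate_nathist_params(p)
  class(p) <- "nathist_params"
  p
}

validate_nathist_params <- function(p) {
  chk_pos <- function(x, field, allow_zero = FALSE) {
    if (!is.numeric(x) || any(!is.finite(x)) ||
        any(if (allow_zero) x < 0 else x <= 0))
      stop(sprintf("nathist_params: invalid '%s' (must be %s)", field,
                   if (allow_zero) "nonnegative" else "positive"), call. = FALSE)
  }
  chk_pos(p$adenoma_risk_dispersion, "adenoma_risk_dispersion", allow_zero = TRUE)
  chk_pos(p$baseline_onset_rate, "baseline_onset_rate", allow_zero = TRUE)
  chk_pos(p$onset_age_shape, "onset_age_shape", allow_zero = TRUE)
  chk_pos(p$dwell_nonadv_to_adv$shape, "dwell_nonadv_to_adv$shape")
  chk_pos(p$dwell_nonadv_to_adv$scale, "dwell_nonadv_to_adv$scale")
  pr <- p$dwell_adv_to_preclinical$prob
  if (!is.numeric(pr) || pr < 0 || pr > 1)
    stop("nathist_params: invalid 'dwell_adv_to_preclinical$prob' (probability)", call. = FALSE)
  chk_pos(p$dwell_adv_to_preclinical$shape, "dwell_adv_to_preclinical$shape")
  chk_pos(p$dwell_adv_to_preclinical$scale, "dwell_adv_to_preclinical$scale")
  chk_pos(p$sojourn_time$shape, "sojourn_time$shape")
  chk_pos(p$sojourn_time$scale, "sojourn_time$scale", allow_zero = TRUE)
  for (nm in c("stage_fractions_clinical", "stage_fractions_screen")) {
    sf <- p[[nm]]
    if (!all(c("early", "late") %in% names(sf)) || any(sf < 0) ||
        abs(sum(sf) - 1) > 1e-9)
      stop(sprintf("nathist_params: '%s' must be probabilities over early/late summing to 1", nm),
           call. = FALSE)
  }
  if (p$stage_fractions_screen[["early"]] < p$stage_fractions_clinical[["early"]])
    stop("nathist_params: screen-detected early-stage fraction must be >= clinical early-stage fraction",
         call. = FALSE)
  cs <- p$crc_survival
  if (any(cs$cure < 0 | cs$cure > 1) || !all(c("early", "late") %in% names(cs$cure)))
    stop("nathist_params: 'crc_survival$cure' must be per-stage probabilities", call. = FALSE)
  chk_pos(cs$shape, "crc_survival$shape")
  chk_pos(cs$scale, "crc_survival$scale")
  if (p$max_age <= 45) stop("nathist_params: 'max_age' must exceed 45", call. = FALSE)
  if (p$max_lesions < 1L) stop("nathist_params: 'max_lesions' must be >= 1", call. = FALSE)
  invisible(p)
}

# fixed per-person random layout: 1 normal + (3 + 8 * max_lesions) uniforms
N_LESION_DRAWS <- 8L

raw_person_draws <- function(seed, ids, max_lesions) {
  ncol <- 3L + N_LESION_DRAWS * max_lesions
  raw <- matrix(NA_real_, length(ids), ncol)
  z <- numeric(length(ids))
  for (k in seq_along(ids)) {
    set.seed(substream_seed(seed, ids[k], STREAM_NATHIST))
    z[k] <- stats::rnorm(1L)
    raw[k, ] <- stats::runif(ncol)
  }
  list(z = z, u = raw)
}

#' Simulate a screening-free cohort of life histories
#'
#' Generates `n` independent persons entering at age 45: other-cause death
#' age from the life table, adenoma onsets and progression, the first
#' clinically surfacing cancer (single-primary convention), its stage and the
#' resulting CRC death age in the absence of screening. Person `i`'s history
#' depends only on `(params, life_table, seed, i)`, so a cohort of `n` is a
#' prefix of any larger cohort with the same seed.
#'
#' @param params a [nathist_params()] object.
#' @param life_table a [life_table()]; defaults to
#'   [gompertz_makeham_life_table()].
#' @param n number of persons.
#' @param seed master integer seed.
#' @return an object of class `crc_cohort`: a list with elements `persons`
#'   (one row per person), `lesions` (one row per adenoma, with event ages
#'   `onset_age`, `adv_age`, `preclin_age`, `clinical_age`, `Inf` meaning the
#'   transition never occurs, plus the coupling uniforms used for stage, cure
#'   and survival-time draws), an index into `lesions` by person, and the
#'   generating `params`, `life_table`, `seed`.
#' @export
simulate_cohort <- function(params, life_table = gompertz_makeham_life_table(),
                            n, seed = 1L) {
  stopifnot(inherits(params, "nathist_params"), n >= 1)
  n <- as.integer(n)
  M <- params$max_lesions
  rp <- raw_person_draws(seed, seq_len(n), M)
  u <- rp$u

  sg <- params$adenoma_risk_dispersion
  frailty <- exp(sg * rp$z - sg^2 / 2)
  lambda <- frailty * params$baseline_onset_rate
  n_les <- pmin(stats::qpois(u[, 1L], lambda), M)
  death_oc <- sample_death_age(life_table, u[, 2L])

  # flatten lesion slots
  pid <- rep.int(seq_len(n), n_les)
  slot <- sequence(n_les)
  les <- transform_lesions(params, u, pid, slot)
  # average-risk cohort is cancer-free at entry: lesions that would have
  # surfaced clinically before 45 are excluded (prevalent preclinical
  # cancers and adenomas at 45 are retained)
  les <- les[!(les$clinical_age < 45), , drop = FALSE]
  rownames(les) <- NULL

  persons <- data.frame(person_id = seq_len(n),
                        frailty = frailty,
                        n_lesions = tabulate(les$person_id, nbins = n),
                        other_cause_death_age = death_oc)

  # first clinically surfacing lesion per person (single primary)
  fc <- first_clinical_summary(params, les, death_oc, n)
  persons$first_clinical_crc_age <- fc$age
  persons$stage_at_clinical <- fc$stage
  persons$crc_death_age_unscreened <- fc$crc_death_age
  persons$death_age_unscreened <- pmin(death_oc, fc$crc_death_age, na.rm = TRUE)

  idx <- lesion_index(les$person_id, n)
  structure(list(persons = persons, lesions = les, lesion_start = idx$start,
                 lesion_end = idx$end, params = params,
                 life_table = life_table, seed = as.integer(seed), n = n),
            class = "crc_cohort")
}

transform_lesions <- function(params, u, pid, slot) {
  base <- 3L + (slot - 1L) * N_LESION_DRAWS
  gcol <- function(j) u[cbind(pid, base + j)]
  g <- params$onset_age_shape
  span <- params$max_age - 20
  onset <- 20 + span * gcol(1L)^(1 / (g + 1))
  d1 <- params$dwell_nonadv_to_adv
  adv <- onset + stats::qweibull(gcol(2L), d1$shape, d1$scale)
  d2 <- params$dwell_adv_to_preclinical
  progresses <- gcol(3L) < d2$prob
  preclin <- ifelse(progresses,
                    adv + stats::qweibull(gcol(4L), d2$shape, d2$scale), Inf)
  so <- params$sojourn_time
  clinical <- preclin + if (so$scale == 0) 0 else
    stats::qweibull(gcol(5L), so$shape, so$scale)
  clinical[!is.finite(preclin)] <- Inf
  data.frame(person_id = pid, lesion_id = slot,
             onset_age = onset, adv_age = adv, preclin_age = preclin,
             clinical_age = clinical,
             u_stage = gcol(6L), u_cure = gcol(7L), u_surv = gcol(8L))
}

# Stage / cure / survival for the lesion with the earliest clinical age.
first_clinical_summary <- function(params, les, death_oc, n) {
  age <- rep(NA_real_, n)
  stage <- rep(NA_character_, n)
  crc_death <- rep(NA_real_, n)
  if (nrow(les)) {
    o <- order(les$person_id, les$clinical_age)
    first <- o[!duplicated(les$person_id[o])]
    fp <- les$person_id[first]
    clin <- les$clinical_age[first]
    eligible <- is.finite(clin) & clin < death_oc[fp]
    first <- first[eligible]; fp <- fp[eligible]; clin <- clin[eligible]
    if (length(first)) {
      out <- lesion_cancer_outcome(params, les[first, , drop = FALSE],
                                   detection_mode = "clinical",
                                   reference_age = clin)
      age[fp] <- clin
      stage[fp] <- out$stage
      cd <- out$death_age
      cd[cd >= death_oc[fp]] <- NA_real_   # censored by other-cause death
      crc_death[fp] <- cd
    }
  }
  list(age = age, stage = stage, crc_death_age = crc_death)
}

# Shared stage/cure/survival transformation. `reference_age` is the age the
# survival clock starts: the lesion's clinical age when it has one (so lead
# time from earlier detection is not itself credited as survival), otherwise
# the detection age.
lesion_cancer_outcome <- function(params, les, detection_mode, reference_age) {
  frac_early <- if (detection_mode == "screen")
    params$stage_fractions_screen[["early"]] else
    params$stage_fractions_clinical[["early"]]
  stage <- ifelse(les$u_stage < frac_early, "early", "late")
  cure <- params$crc_survival$cure[stage]
  cured <- les$u_cure < cure
  st <- stats::qweibull(les$u_surv, params$crc_survival$shape,
                        params$crc_survival$scale[stage])
  death_age <- ifelse(cured, Inf, reference_age + st)
  list(stage = stage, cured = cured, death_age = death_age)
}

lesion_index <- function(pid, n) {
  cnt <- tabulate(pid, nbins = n)
  end <- cumsum(cnt)
  start <- end - cnt + 1L
  start[cnt == 0L] <- 0L
  end[cnt == 0L] <- -1L
  list(start = start, end = end)
}

#' Simulate a single screening-free life history
#'
#' Convenience wrapper around the cohort machinery returning the complete
#' history of one person as a `person_history` list.
#'
#' @inheritParams simulate_cohort
#' @param person_id index of the person within the seed's cohort; the history
#'   is identical to row `person_id` of [simulate_cohort()] with the same
#'   seed.
#' @return a list of class `person_history` with the person row fields plus a
#'   `lesions` data frame.
#' @export
sample_person <- function(params, life_table = gompertz_makeham_life_table(),
                          seed = 1L, person_id = 1L) {
  coh <- simulate_person_subset(params, life_table, person_id, seed)
  cohort_person_history(coh, 1L)
}

# simulate specific person ids (used by sample_person; histories match the
# full cohort because substreams are keyed by person id)
simulate_person_subset <- function(params, life_table, ids, seed) {
  M <- params$max_lesions
  rp <- raw_person_draws(seed, ids, M)
  u <- rp$u
  sg <- params$adenoma_risk_dispersion
  frailty <- exp(sg * rp$z - sg^2 / 2)
  n_les <- pmin(stats::qpois(u[, 1L], frailty * params$baseline_onset_rate), M)
  death_oc <- sample_death_age(life_table, u[, 2L])
  pid <- rep.int(seq_along(ids), n_les)
  les <- transform_lesions(params, u, pid, sequence(n_les))
  les <- les[!(les$clinical_age < 45), , drop = FALSE]
  rownames(les) <- NULL
  fc <- first_clinical_summary(params, les, death_oc, length(ids))
  persons <- data.frame(person_id = ids, frailty = frailty,
                        n_lesions = tabulate(match(les$person_id, seq_along(ids)),
                                             nbins = length(ids)),
                        other_cause_death_age = death_oc,
                        first_clinical_crc_age = fc$age,
                        stage_at_clinical = fc$stage,
                        crc_death_age_unscreened = fc$crc_death_age,
                        death_age_unscreened = pmin(death_oc, fc$crc_death_age, na.rm = TRUE))
  les$person_id <- ids[les$person_id]
  idx <- lesion_index(match(les$person_id, ids), length(ids))
  structure(list(persons = persons, lesions = les, lesion_start = idx$start,
                 lesion_end = idx$end, params = params, life_table = life_table,
                 seed = as.integer(seed), n = length(ids)),
            class = "crc_cohort")
}

cohort_person_history <- function(cohort, i) {
  p <- cohort$persons[i, ]
  s <- cohort$lesion_start[i]
  les <- if (s > 0L)
    cohort$lesions[s:cohort$lesion_end[i], , drop = FALSE]
  else cohort$lesions[0L, , drop = FALSE]
  structure(list(person_id = p$person_id,
                 other_cause_death_age = p$other_cause_death_age,
                 lesions = les,
                 first_clinical_crc_age = p$first_clinical_crc_age,
                 stage_at_clinical = p$stage_at_clinical,
                 crc_death_age_unscreened = p$crc_death_age_unscreened),
            class = "person_history")
}

LESION_STATES <- c("none", "nonadvanced_adenoma", "advanced_adenoma",
                   "preclinical_crc", "clinical_crc")

#' Most advanced lesion state of a person at a given age
#'
#' Classifies each non-removed lesion by its event ages and returns the most
#' advanced category present together with per-state counts. Noninvasive
#' tests act on this person-level snapshot (sensitivity to the most advanced
#' lesion), colonoscopy acts on the individual lesions.
#'
#' @param person a `person_history` (see [sample_person()]).
#' @param age query age in years.
#' @param removed_ids integer ids of lesions already excised by polypectomy.
#' @return a list of class `lesion_snapshot` with `age`, `state`, and named
#'   integer `counts` per state.
#' @export
lesion_state_at <- function(person, age, removed_ids = integer()) {
  les <- person$lesions
  keep <- !(les$lesion_id %in% removed_ids)
  states <- lesion_states_vec(les[keep, , drop = FALSE], age)
  counts <- table(factor(states, levels = LESION_STATES))
  counts <- counts[setdiff(LESION_STATES, "none")]
  top <- if (length(states) && any(states != "none"))
    LESION_STATES[max(match(states, LESION_STATES))] else "none"
  structure(list(age = age, state = top,
                 counts = stats::setNames(as.integer(counts), names(counts))),
            class = "lesion_snapshot")
}

lesion_states_vec <- function(les, age) {
  if (!nrow(les)) return(character())
  ifelse(les$onset_age > age, "none",
  ifelse(les$adv_age > age, "nonadvanced_adenoma",
  ifelse(les$preclin_age > age, "advanced_adenoma",
  ifelse(les$clinical_age > age, "preclinical_crc", "clinical_crc"))))
}

#' Lifetime CRC deaths per 1000 unscreened persons
#'
#' @param cohort a `crc_cohort`.
#' @return deaths per 1000 cohort members.
#' @export
unscreened_crc_deaths_per_1000 <- function(cohort) {
  mean(!is.na(cohort$persons$crc_death_age_unscreened)) * 1000
}

#' Calibrate the onset rate to a target unscreened CRC mortality
#'
#' Tunes `baseline_onset_rate` (and, if needed, the advanced-adenoma
#' progression probability) by deterministic bisection so that the simulated
#' unscreened lifetime CRC deaths per 1000 at the given `(n, seed)` fall in
#' the target interval. Because all parameter sets reuse identical underlying
#' uniforms (common random numbers), the objective is a smooth monotone
#' function of the onset rate and bisection converges cleanly.
#'
#' @param target numeric length-2 interval of acceptable deaths per 1000.
#' @param params0 starting [nathist_params()].
#' @param n cohort size used for each evaluation.
#' @param seed master seed used for each evaluation.
#' @param rate_bounds search bounds for `baseline_onset_rate`.
#' @param prog_grid fallback grid of progression probabilities tried in order
#'   if no onset rate within `rate_bounds` reaches the target.
#' @param max_iter bisection iteration cap per progression level.
#' @return calibrated `nathist_params` (returns `params0` unchanged if it
#'   already meets the target).
#' @export
calibrate_defaults <- function(target, params0 = nathist_params(), n = 20000,
                               seed = 1L, rate_bounds = c(0, 12),
                               prog_grid = NULL, max_iter = 40L) {
  stopifnot(length(target) == 2L, target[1] <= target[2])
  lt <- gompertz_makeham_life_table()
  eval_deaths <- function(p)
    unscreened_crc_deaths_per_1000(simulate_cohort(p, lt, n = n, seed = seed))
  d0 <- eval_deaths(params0)
  if (d0 >= target[1] && d0 <= target[2]) return(params0)

  if (is.null(prog_grid)) prog_grid <- params0$dwell_adv_to_preclinical$prob
  best <- list(dist = Inf, params = params0, deaths = d0)
  mid <- mean(target)
  for (pr in prog_grid) {
    p <- params0
    p$dwell_adv_to_preclinical$prob <- pr
    lo <- rate_bounds[1]; hi <- rate_bounds[2]
    with_rate <- function(r) { q <- p; q$baseline_onset_rate <- r; q }
    d_lo <- eval_deaths(with_rate(lo)); d_hi <- eval_deaths(with_rate(hi))
    for (d in c(d_lo, d_hi)) {
      if (abs(d - mid) < best$dist)
        best <- list(dist = abs(d - mid),
                     params = with_rate(if (d == d_lo) lo else hi), deaths = d)
    }
    if (d_lo > target[2] || d_hi < target[1]) next  # unbracketed at this level
    for (it in seq_len(max_iter)) {
      r <- (lo + hi) / 2
      d <- eval_deaths(with_rate(r))
      if (abs(d - mid) < best$dist)
        best <- list(dist = abs(d - mid), params = with_rate(r), deaths = d)
      if (d >= target[1] && d <= target[2]) return(with_rate(r))
      if (d < mid) lo <- r else hi <- r
    }
  }
  stop(sprintf(paste0("calibrate_defaults: search failed; best deaths per 1000 = %.2f ",
                      "(target [%g, %g]) at baseline_onset_rate = %.4f"),
               best$deaths, target[1], target[2],
               best$params$baseline_onset_rate), call. = FALSE)
}
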