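# The strategy engine. One pass over the cohort applies the regimen's state
# machine to each person's (fixed) natural history. All monetary and
# quality-of-life quantities are accumulated already discounted to the
# reference age, so a strategy run needs no second pass.

#' Apply a screening strategy to a cohort
#'
#' Simulates, person by person and in age order: routine screens, follow-up
#' colonoscopy after a positive noninvasive test, polypectomy (cancelling the
#' removed lesion's progression), surveillance, the 10-year resume rule,
#' complications, screen-detected and symptom-detected cancer with
#' stage-specific survival, and competing other-cause death. The natural
#' history comes unchanged from the cohort; only test, complication and
#' procedure draws use a strategy-specific substream, keyed by the regimen's
#' clinical signature, so strategies are compared under common random
#' numbers. Outcomes for symptomatic cancers reuse the stage and survival
#' already drawn in the cohort, hence a strategy that never intervenes
#' reproduces the unscreened life course exactly.
#'
#' @param cohort a `crc_cohort` from [simulate_cohort()].
#' @param strategy a [strategy()].
#' @param colo a [colonoscopy_profile()].
#' @param econ an [econ_params()].
#' @param seed overlay master seed; defaults to the cohort seed.
#' @param keep_events if `TRUE`, also return an event log data frame
#'   (columns `person_id`, `age`, `event`, `detail`); intended for small
#'   cohorts.
#' @return a list of class `strategy_outcome`: `strategy_name`, `n`,
#'   `cohort_seed`, `per_person` (data frame with discounted life-years
#'   `ly_disc`, undiscounted `ly_undisc`, `qaly_disc`, total discounted cost
#'   `cost_disc`, the discounted count of primary tests `test_count_disc`,
#'   flags `crc_case`/`crc_death`, `stage`, `detection_mode`, counts of
#'   colonoscopies and tests), the `unit_cost` of the primary test, and
#'   optionally `events`.
#' @export
run_strategy <- function(cohort, strategy, colo = colonoscopy_profile(),
                         econ = econ_params(), seed = NULL,
                         keep_events = FALSE) {
  stopifnot(inherits(cohort, "crc_cohort"),
            inherits(strategy, "screening_strategy"),
            inherits(colo, "colonoscopy_profile"))
  if (is.null(seed)) seed <- cohort$seed
  tp <- strategy$primary_test
  if (is.null(tp$modality)) stop("run_strategy: strategy references an undefined test profile")
  n <- cohort$n
  params <- cohort$params
  pers <- cohort$persons
  les <- cohort$lesions
  ls <- cohort$lesion_start; le <- cohort$lesion_end
  r <- econ$discount_rate; ref <- econ$reference_age
  disc <- function(age) (1 + r)^(-(age - ref))
  test_dis <- tp$disutility_days / 365.25
  colo_dis <- colo$disutility_days / 365.25
  compl_dis <- colo$complication_disutility_days / 365.25
  treat_cost <- econ$treatment_cost_by_stage
  crc_dis <- econ$disutility_crc_care
  sid <- stream_id(regimen_stream_label(strategy))
  screening_active <- is.finite(strategy$interval) && tp$modality != "none"
  colo_primary <- tp$modality == "colonoscopy"
  frac_early_screen <- params$stage_fractions_screen[["early"]]
  frac_early_clin <- params$stage_fractions_clinical[["early"]]
  cure_p <- params$crc_survival$cure
  surv_shape <- params$crc_survival$shape
  surv_scale <- params$crc_survival$scale

  ly_disc <- ly_undisc <- qaly <- cost <- test_cnt_d <- numeric(n)
  crc_case <- crc_death <- integer(n)
  stage_out <- det_mode <- rep(NA_character_, n)
  n_colos <- n_tests <- integer(n)
  events <- if (keep_events) vector("list", 4096L) else NULL
  n_ev <- 0L
  log_ev <- function(pid, age, event, detail) {
    n_ev <<- n_ev + 1L
    if (n_ev > length(events)) length(events) <<- 2L * n_ev
    events[[n_ev]] <<- list(person_id = pid, age = age, event = event,
                            detail = detail)
  }

  for (i in seq_len(n)) {
    death_oc <- pers$other_cause_death_age[i]
    s0 <- ls[i]
    has_les <- s0 > 0L
    if (has_les) {
      rows <- s0:le[i]
      on <- les$onset_age[rows]; ad <- les$adv_age[rows]
      pc <- les$preclin_age[rows]; cl <- les$clinical_age[rows]
      ustg <- les$u_stage[rows]; ucur <- les$u_cure[rows]; usrv <- les$u_surv[rows]
      removed <- rep(FALSE, length(rows))
    } else removed <- logical()

    set.seed(substream_seed(seed, i, sid))
    mode <- "routine"
    next_exam <- if (screening_active) strategy$start_age else Inf
    d_cost <- 0; d_dis <- 0; tc_d <- 0; ntst <- 0L; ncol <- 0L
    death <- death_oc; case <- 0L; dth <- 0L
    stg <- NA_character_; dmode <- NA_character_

    repeat {
      t_clin <- if (has_les && any(!removed)) suppressWarnings(min(cl[!removed])) else Inf
      if (t_clin < death_oc && t_clin <= next_exam) {
        # symptomatic diagnosis preempts screening
        j <- which(!removed)[which.min(cl[!removed])]
        stg <- if (ustg[j] < frac_early_clin) "early" else "late"
        cured <- ucur[j] < cure_p[[stg]]
        dj <- disc(t_clin)
        d_cost <- d_cost + dj * (econ$diagnostic_colonoscopy_cost + treat_cost[[stg]])
        d_dis <- d_dis + dj * crc_dis[[stg]]
        case <- 1L; dmode <- "clinical"
        if (keep_events) log_ev(i, t_clin, "crc_diagnosis_clinical", stg)
        if (!cured) {
          t_d <- t_clin + stats::qweibull(usrv[j], surv_shape, surv_scale[[stg]])
          if (t_d < death_oc) {
            death <- t_d; dth <- 1L
            d_cost <- d_cost + disc(t_d) * econ$terminal_care_cost
            if (keep_events) log_ev(i, t_d, "crc_death", stg)
          }
        }
        break
      }
      if (death_oc <= next_exam) break
      # ---- exam at next_exam ----
      age <- next_exam
      if (has_les) {
        active <- !removed & on <= age
        st_pre <- active & pc <= age          # preclinical CRC present
        st_adv <- active & ad <= age & pc > age
        st_non <- active & ad > age
      } else st_pre <- st_adv <- st_non <- logical()
      do_colo <- FALSE
      outcome <- NULL
      if (!colo_primary && mode == "routine") {
        # noninvasive screen
        state <- if (any(st_pre)) "preclinical_crc" else
                 if (any(st_adv)) "advanced_adenoma" else
                 if (any(st_non)) "nonadvanced_adenoma" else "none"
        p_pos <- positivity_prob(state, tp)
        pos <- stats::runif(1L) < p_pos
        da <- disc(age)
        d_cost <- d_cost + da * tp$unit_cost
        d_dis <- d_dis + da * test_dis
        tc_d <- tc_d + da
        ntst <- ntst + 1L
        if (keep_events) log_ev(i, age, "screen_test",
                                paste0(tp$name, ":", if (pos) "positive" else "negative"))
        if (!pos) outcome <- "negative_screen" else do_colo <- TRUE
        followup <- TRUE
      } else {
        do_colo <- TRUE            # routine colonoscopy or surveillance exam
        followup <- FALSE
      }
      if (do_colo) {
        ncol <- ncol + 1L
        idx <- which(st_pre | st_adv | st_non)
        det <- if (length(idx)) {
          p_det <- ifelse(st_pre[idx], colo$lesion_sens_crc, colo$lesion_sens_adenoma)
          idx[stats::runif(length(idx)) < p_det]
        } else integer()
        da <- disc(age)
        crc_det <- det[st_pre[det]]
        aden_det <- det[!st_pre[det]]
        any_rem <- length(aden_det) > 0L
        d_cost <- d_cost + da * (if (any_rem) colo$cost_with_removal else colo$cost_without_removal)
        d_dis <- d_dis + da * colo_dis
        if (stats::runif(1L) < colo$complication_prob) {
          d_cost <- d_cost + da * colo$complication_cost
          d_dis <- d_dis + da * compl_dis
          if (keep_events) log_ev(i, age, "complication", "colonoscopy")
        }
        if (keep_events)
          log_ev(i, age,
                 if (followup) "followup_colonoscopy"
                 else if (mode == "surveillance") "surveillance_colonoscopy"
                 else "screen_test",
                 sprintf("detected=%d removed=%d", length(det), length(aden_det)))
        if (length(crc_det)) {
          # screen-detected cancer: the lesion that would surface first
          j <- crc_det[which.min(cl[crc_det])]
          stg <- if (ustg[j] < frac_early_screen) "early" else "late"
          cured <- ucur[j] < cure_p[[stg]]
          d_cost <- d_cost + da * treat_cost[[stg]]
          d_dis <- d_dis + da * crc_dis[[stg]]
          case <- 1L; dmode <- "screen"
          if (keep_events) log_ev(i, age, "crc_diagnosis_screen", stg)
          if (!cured) {
            # survival clock starts at the age the cancer would have
            # surfaced clinically: lead time is not credited
            t_d <- cl[j] + stats::qweibull(usrv[j], surv_shape, surv_scale[[stg]])
            if (t_d < death_oc) {
              death <- t_d; dth <- 1L
              d_cost <- d_cost + disc(t_d) * econ$terminal_care_cost
              if (keep_events) log_ev(i, t_d, "crc_death", stg)
            }
          }
          break
        }
        if (any_rem) {
          removed[aden_det] <- TRUE
          if (keep_events) log_ev(i, age, "polypectomy", length(aden_det))
          high <- any(st_adv[aden_det]) || length(aden_det) >= 3L
          outcome <- if (high) "adenoma_high_risk" else "adenoma_low_risk"
        } else {
          outcome <- if (followup) "followup_negative"
                     else if (mode == "surveillance") "surveillance_negative"
                     else "routine_colonoscopy_negative"
        }
      }
      nxt <- next_due(age, outcome, strategy)
      if (is.null(nxt)) { next_exam <- Inf } else {
        next_exam <- nxt$age; mode <- nxt$mode
      }
    }
    if (keep_events && death == death_oc && dth == 0L)
      log_ev(i, death_oc, "other_death", "")
    ly_undisc[i] <- death - ref
    ld <- discounted_years(death, econ)
    ly_disc[i] <- ld
    qaly[i] <- ld - d_dis
    cost[i] <- d_cost
    test_cnt_d[i] <- tc_d
    crc_case[i] <- case; crc_death[i] <- dth
    stage_out[i] <- stg; det_mode[i] <- dmode
    n_colos[i] <- ncol; n_tests[i] <- ntst
  }

  per_person <- data.frame(person_id = seq_len(n), ly_disc = ly_disc,
                           ly_undisc = ly_undisc, qaly_disc = qaly,
                           cost_disc = cost, test_count_disc = test_cnt_d,
                           crc_case = crc_case, crc_death = crc_death,
                           stage = stage_out, detection_mode = det_mode,
                           n_colonoscopies = n_colos, n_tests = n_tests)
  out <- list(strategy_name = strategy$name, n = n,
              cohort_seed = cohort$seed, unit_cost = tp$unit_cost,
              per_person = per_person)
  if (keep_events) {
    evl <- events[seq_len(n_ev)]
    out$events <- data.frame(
      person_id = vapply(evl, `[[`, numeric(1), "person_id"),
      age = vapply(evl, `[[`, numeric(1), "age"),
      event = vapply(evl, `[[`, character(1), "event"),
      detail = vapply(evl, function(e) as.character(e$detail), character(1)))
    out$events <- out$events[order(out$events$person_id, out$events$age), ]
    rownames(out$events) <- NULL
  }
  class(out) <- "strategy_outcome"
  out
}

#' Reprice a strategy outcome at a different primary-test unit cost
#'
#' Under full adherence the unit cost of the primary test affects only the
#' cost accumulator (via the discounted count of administered tests), so
#' outcomes for test-cost scenario grids can be recomputed without
#' re-simulating.
#'
#' @param outcome a `strategy_outcome`.
#' @param new_unit_cost replacement USD cost per primary test.
#' @return the outcome with adjusted per-person costs and `unit_cost`.
#' @export
reprice_outcome <- function(outcome, new_unit_cost) {
  stopifnot(inherits(outcome, "strategy_outcome"), new_unit_cost >= 0)
  dd <- new_unit_cost - outcome$unit_cost
  outcome$per_person$cost_disc <- outcome$per_person$cost_disc +
    dd * outcome$per_person$test_count_disc
  outcome$unit_cost <- new_unit_cost
  outcome
}
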