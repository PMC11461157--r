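# Cost-effectiveness layer: discounting to the cohort entry age, per-strategy
# outcome summaries versus no screening, net monetary benefit, and the
# efficiency frontier with strict and extended dominance.

#' Economic parameters
#'
#' Costs are in 2021 US dollars; all costs and benefits are discounted to the
#' cohort entry age (45) at `discount_rate` per year. Events occurring
#' exactly at the reference age are undiscounted (half-open convention).
#'
#' @param discount_rate annual discount rate (default 3%).
#' @param reference_age cohort entry age; discounting reference.
#' @param wtp willingness to pay per QALY gained (USD).
#' @param treatment_cost_by_stage named USD cost of initial cancer care
#'   incurred at diagnosis, per stage.
#' @param terminal_care_cost USD cost incurred at death from CRC.
#' @param diagnostic_colonoscopy_cost USD cost of the diagnostic colonoscopy
#'   incurred at symptom-detected diagnosis (screen-detected cancers are
#'   found by an already-costed colonoscopy).
#' @param disutility_crc_care named per-stage quality-adjusted life-year
#'   decrement applied at diagnosis (years).
#' @param currency_year calendar year of the cost basis.
#' @return a list of class `econ_params`.
#' @export
econ_params <- function(discount_rate = 0.03,
                        reference_age = 45,
                        wtp = 1e5,
                        treatment_cost_by_stage = c(early = 70000, late = 140000),
                        terminal_care_cost = 80000,
                        diagnostic_colonoscopy_cost = 1312.36,
                        disutility_crc_care = c(early = 0.25, late = 0.60),
                        currency_year = 2021) {
  stopifnot(discount_rate >= 0, wtp > 0,
            all(treatment_cost_by_stage >= 0), terminal_care_cost >= 0,
            diagnostic_colonoscopy_cost >= 0, all(disutility_crc_care >= 0),
            all(c("early", "late") %in% names(treatment_cost_by_stage)),
            all(c("early", "late") %in% names(disutility_crc_care)))
  structure(list(discount_rate = discount_rate, reference_age = reference_age,
                 wtp = wtp, treatment_cost_by_stage = treatment_cost_by_stage,
                 terminal_care_cost = terminal_care_cost,
                 diagnostic_colonoscopy_cost = diagnostic_colonoscopy_cost,
                 disutility_crc_care = disutility_crc_care,
                 currency_year = currency_year),
            class = "econ_params")
}

#' Discount a point amount to the reference age
#'
#' `amount / (1 + r)^(event_age - reference_age)`. Continuous flows
#' (life-years) are integrated with the same kernel by [discounted_years()].
#'
#' @param amount value at `event_age`.
#' @param event_age age at which the amount accrues; must be at least the
#'   reference age.
#' @param econ an [econ_params()].
#' @return discounted value.
#' @examples
#' discounted_value(100, 55, econ_params())  # 100 / 1.03^10
#' @export
discounted_value <- function(amount, event_age, econ = econ_params()) {
  if (any(event_age < econ$reference_age))
    stop("discounted_value: event_age precedes the reference age")
  amount / (1 + econ$discount_rate)^(event_age - econ$reference_age)
}

#' Discounted person-years lived from the reference age to death
#'
#' Integral of `(1+r)^-(t - ref)` from the reference age to `death_age`:
#' `(1 - (1+r)^-(D - ref)) / log(1+r)`, or `D - ref` at `r = 0`.
#'
#' @param death_age age at death (vectorized).
#' @param econ an [econ_params()].
#' @return discounted years lived.
#' @export
discounted_years <- function(death_age, econ = econ_params()) {
  tt <- pmax(death_age - econ$reference_age, 0)
  r <- econ$discount_rate
  if (r == 0) tt else (1 - (1 + r)^(-tt)) / log(1 + r)
}

#' Summarize a strategy's outcomes relative to no screening
#'
#' Aggregates the per-person records of two [run_strategy()] results run on
#' the same cohort (common random numbers) into discounted life-years gained,
#' QALYs gained and CRC outcomes per 1000 persons, plus per-person costs.
#'
#' @param strategy_outcome a `strategy_outcome` from [run_strategy()].
#' @param no_screen_outcome the no-screening `strategy_outcome` from the same
#'   cohort and seed.
#' @param econ an [econ_params()].
#' @return a list of class `outcome_summary` with fields `strategy`,
#'   `crc_cases_per_1000`, `crc_deaths_per_1000`, `lyg_per_1000`,
#'   `qalyg_per_1000` (all relative quantities vs no screening, discounted),
#'   `cost_per_person`, `net_cost_per_person`, `nmb_per_person`, and `n`.
#' @export
summarize_outcomes <- function(strategy_outcome, no_screen_outcome,
                               econ = econ_params()) {
  a <- strategy_outcome; b <- no_screen_outcome
  if (a$n != b$n || a$cohort_seed != b$cohort_seed)
    stop("summarize_outcomes: outcomes come from different cohorts")
  pa <- a$per_person; pb <- b$per_person
  out <- list(strategy = a$strategy_name,
              crc_cases_per_1000 = mean(pa$crc_case) * 1000,
              crc_deaths_per_1000 = mean(pa$crc_death) * 1000,
              lyg_per_1000 = (mean(pa$ly_disc) - mean(pb$ly_disc)) * 1000,
              qalyg_per_1000 = (mean(pa$qaly_disc) - mean(pb$qaly_disc)) * 1000,
              cost_per_person = mean(pa$cost_disc),
              net_cost_per_person = mean(pa$cost_disc) - mean(pb$cost_disc),
              n = a$n)
  out$nmb_per_person <- net_monetary_benefit_values(
    out$qalyg_per_1000 / 1000, out$net_cost_per_person, econ$wtp)
  class(out) <- "outcome_summary"
  out
}

net_monetary_benefit_values <- function(qalyg_pp, net_cost_pp, wtp)
  wtp * qalyg_pp - net_cost_pp

#' Net monetary benefit of a strategy
#'
#' `wtp * QALY gained per person - net cost per person`, both relative to no
#' screening; the single-scale value measure used to rank all strategies
#' including dominated ones.
#'
#' @param summary an `outcome_summary` from [summarize_outcomes()].
#' @param econ an [econ_params()]; `econ$wtp` is the willingness to pay.
#' @return net monetary benefit in USD per person.
#' @export
net_monetary_benefit <- function(summary, econ = econ_params()) {
  net_monetary_benefit_values(summary$qalyg_per_1000 / 1000,
                              summary$net_cost_per_person, econ$wtp)
}

#' Efficiency frontier with strict and extended dominance
#'
#' Orders strategies by QALYs gained, marks strictly dominated strategies
#' (another strategy has at least the benefit at no more cost, one strictly),
#' then iteratively removes extended-dominated strategies (whose incremental
#' cost-effectiveness ratio exceeds that of the next more effective efficient
#' strategy) and recomputes ICERs between consecutive efficient strategies.
#' The least effective nondominated strategy carries no ICER.
#'
#' @param summaries a list of `outcome_summary` objects (or any list of lists
#'   with fields `strategy`, `qalyg_per_1000`, `net_cost_per_person`),
#'   normally including the no-screening reference.
#' @param econ an [econ_params()] used for the net-monetary-benefit column.
#' @return a `data.frame` of class `frontier_result`, one row per strategy in
#'   input order: `strategy`, `qalyg_per_1000`, `net_cost_per_person`,
#'   `status` (`"efficient"`, `"dominated"`, `"extended_dominated"`), `icer`
#'   (vs the previous efficient strategy; `NA` otherwise), `nmb`.
#' @export
compute_frontier <- function(summaries, econ = econ_params()) {
  if (length(summaries) < 2L)
    stop("compute_frontier: need at least two strategies")
  nm <- vapply(summaries, function(s) s$strategy, character(1))
  q <- vapply(summaries, function(s) s$qalyg_per_1000, numeric(1)) / 1000
  cc <- vapply(summaries, function(s) s$net_cost_per_person, numeric(1))
  n <- length(q)
  tie <- duplicated(round(cbind(q, cc), 12))
  if (any(tie))
    warning("compute_frontier: strategies tied in both QALYs and cost; keeping first by input order")

  status <- rep("efficient", n)
  status[tie] <- "dominated"   # exact duplicate of an earlier strategy
  # strict dominance (pairwise)
  for (i in seq_len(n)) {
    dom <- (q >= q[i]) & (cc <= cc[i]) & (q > q[i] | cc < cc[i])
    dom[i] <- FALSE
    if (any(dom)) status[i] <- "dominated"
  }
  # extended dominance among the remainder, in QALY order
  repeat {
    cand <- which(status == "efficient")
    cand <- cand[order(q[cand], cc[cand])]
    if (length(cand) < 3L) break
    icers <- diff(cc[cand]) / diff(q[cand])
    bad <- which(diff(icers) < 0)   # ICER exceeds that of the next strategy
    if (!length(bad)) break
    status[cand[bad[1L] + 1L]] <- "extended_dominated"
  }
  eff <- which(status == "efficient")
  eff <- eff[order(q[eff], cc[eff])]
  icer <- rep(NA_real_, n)
  if (length(eff) >= 2L)
    icer[eff[-1L]] <- diff(cc[eff]) / diff(q[eff])
  out <- data.frame(strategy = nm, qalyg_per_1000 = q * 1000,
                    net_cost_per_person = cc, status = status, icer = icer,
                    nmb = net_monetary_benefit_values(q, cc, econ$wtp),
                    stringsAsFactors = FALSE)
  class(out) <- c("frontier_result", "data.frame")
  out
}

#' Write an outcome-summary table as CSV
#'
#' One row per strategy in the column order of the headline results table:
#' CRC deaths, QALYs gained, costs, net monetary benefit, ICER and dominance
#' status. Money is written to the cent, per-1000 outcomes to one decimal.
#'
#' @param summaries list of `outcome_summary` objects.
#' @param frontier the matching [compute_frontier()] result.
#' @param path output CSV path.
#' @return the written data frame, invisibly.
#' @export
write_summary_csv <- function(summaries, frontier, path) {
  df <- data.frame(
    strategy = vapply(summaries, `[[`, character(1), "strategy"),
    crc_cases_per_1000 = round(vapply(summaries, `[[`, numeric(1), "crc_cases_per_1000"), 1),
    crc_deaths_per_1000 = round(vapply(summaries, `[[`, numeric(1), "crc_deaths_per_1000"), 1),
    lyg_per_1000 = round(vapply(summaries, `[[`, numeric(1), "lyg_per_1000"), 1),
    qalyg_per_1000 = round(vapply(summaries, `[[`, numeric(1), "qalyg_per_1000"), 1),
    cost_per_person = round(vapply(summaries, `[[`, numeric(1), "cost_per_person"), 2),
    net_cost_per_person = round(vapply(summaries, `[[`, numeric(1), "net_cost_per_person"), 2),
    nmb_per_person = round(vapply(summaries, `[[`, numeric(1), "nmb_per_person"), 2),
    icer = round(frontier$icer[match(vapply(summaries, `[[`, character(1), "strategy"),
                                     frontier$strategy)], 2),
    status = frontier$status[match(vapply(summaries, `[[`, character(1), "strategy"),
                                   frontier$strategy)])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
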