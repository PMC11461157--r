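# Full-factorial threshold analysis over blood-test characteristics.
# Scenarios share a single cohort under common random numbers; scenarios
# differing only in unit cost also share the simulated screening overlay and
# are repriced analytically, so the default 900-scenario grid costs 45
# simulation runs (3 CRC sensitivities x 5 advanced-adenoma sensitivities x
# 3 intervals), not 900.

#' Factorial design specification for blood-test scenarios
#'
#' Defaults reproduce the 900-scenario design: CRC sensitivity 74/83/92%,
#' advanced-adenoma sensitivity 10-50% in steps of 10, screening interval
#' 1-3 years, and unit cost $25-$500 in $25 increments, with specificity
#' fixed at 90% throughout.
#'
#' @param crc_sens_levels,aa_sens_levels,intervals,costs factor levels,
#'   each sorted ascending and unique.
#' @param specificity fixed blood-test specificity.
#' @return a list of class `scenario_spec`.
#' @export
scenario_spec <- function(crc_sens_levels = c(0.74, 0.83, 0.92),
                          aa_sens_levels = c(0.10, 0.20, 0.30, 0.40, 0.50),
                          intervals = c(1, 2, 3),
                          costs = seq(25, 500, by = 25),
                          specificity = 0.90) {
  for (nm in c("crc_sens_levels", "aa_sens_levels", "intervals", "costs")) {
    v <- get(nm)
    if (!length(v)) stop("scenario_spec: empty level list '", nm, "'")
    if (anyDuplicated(v)) stop("scenario_spec: duplicate levels in '", nm, "'")
    if (is.unsorted(v)) stop("scenario_spec: levels of '", nm, "' must be ascending")
  }
  stopifnot(specificity >= 0, specificity <= 1)
  structure(list(crc_sens_levels = crc_sens_levels,
                 aa_sens_levels = aa_sens_levels, intervals = intervals,
                 costs = costs, specificity = specificity),
            class = "scenario_spec")
}

#' Build the factorial scenario grid
#'
#' Cartesian product of the specification's levels in deterministic order:
#' cost varies fastest, then advanced-adenoma sensitivity, then interval,
#' then CRC sensitivity. Scenario ids are stable row numbers in that order.
#'
#' @param spec a [scenario_spec()].
#' @return a data frame with columns `scenario_id`, `crc_sens`, `aa_sens`,
#'   `interval`, `cost`, `specificity`.
#' @export
build_scenario_grid <- function(spec = scenario_spec()) {
  g <- expand.grid(cost = spec$costs, aa_sens = spec$aa_sens_levels,
                   interval = spec$intervals, crc_sens = spec$crc_sens_levels,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(scenario_id = seq_len(nrow(g)), crc_sens = g$crc_sens,
             aa_sens = g$aa_sens, interval = g$interval, cost = g$cost,
             specificity = spec$specificity)
}

#' Evaluate every scenario of a blood-test grid on one cohort
#'
#' Runs each distinct regimen (CRC sensitivity, AA sensitivity, interval)
#' once with [run_strategy()] and reprices across cost levels, then computes
#' the outcome summary, the cost-effectiveness frontier against the
#' comparators, the scenario's classification and noninferiority flags.
#'
#' @param grid a grid from [build_scenario_grid()].
#' @param cohort the shared `crc_cohort`.
#' @param comparators named list with elements `no_screen`, `fit`, `col`:
#'   `strategy_outcome`s evaluated on the same cohort. Built automatically
#'   when `NULL`.
#' @param econ an [econ_params()].
#' @param colo a [colonoscopy_profile()].
#' @param seed overlay seed (defaults to the cohort's).
#' @param wtp_cap ICER threshold (USD/QALY) below which an efficient
#'   scenario counts as cost-effective.
#' @param model label recorded in the result (used when pooling runs across
#'   natural-history parameter sets).
#' @param progress if `TRUE`, print one line per simulated regimen.
#' @return a data frame, one row per scenario: the factor levels, per-1000
#'   outcomes, per-person costs, `nmb`, `effect_noninf_fit`,
#'   `effect_noninf_col`, `nmb_noninf_col`, `ce_status` and the binary
#'   `cost_effective` label used downstream.
#' @export
evaluate_scenarios <- function(grid, cohort, comparators = NULL,
                               econ = econ_params(),
                               colo = colonoscopy_profile(), seed = NULL,
                               wtp_cap = 150000, model = "default",
                               progress = FALSE) {
  if (is.null(seed)) seed <- cohort$seed
  if (is.null(comparators)) {
    comparators <- list(
      no_screen = run_strategy(cohort, strategy_no_screening(), colo, econ, seed),
      fit = run_strategy(cohort, strategy_fit(), colo, econ, seed),
      col = run_strategy(cohort, strategy_colonoscopy(), colo, econ, seed))
  }
  o_ns <- comparators$no_screen
  s_fit <- summarize_outcomes(comparators$fit, o_ns, econ)
  s_col <- summarize_outcomes(comparators$col, o_ns, econ)

  reg <- unique(grid[c("crc_sens", "aa_sens", "interval", "specificity")])
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(reg))) {
    st <- strategy_blood(interval = reg$interval[k],
                         sens_crc = reg$crc_sens[k],
                         sens_adv_adenoma = reg$aa_sens[k],
                         specificity = reg$specificity[k],
                         unit_cost = grid$cost[1L])
    if (progress)
      message(sprintf("regimen %d/%d: crc=%.2f aa=%.2f interval=%g",
                      k, nrow(reg), reg$crc_sens[k], reg$aa_sens[k],
                      reg$interval[k]))
    ob <- run_strategy(cohort, st, colo, econ, seed)
    sel <- which(grid$crc_sens == reg$crc_sens[k] &
                 grid$aa_sens == reg$aa_sens[k] &
                 grid$interval == reg$interval[k])
    for (i in sel) {
      oc <- reprice_outcome(ob, grid$cost[i])
      oc$strategy_name <- sprintf("scenario_%d", grid$scenario_id[i])
      sm <- summarize_outcomes(oc, o_ns, econ)
      cls <- classify_scenario(sm, s_fit, s_col, econ, wtp_cap)
      rows[[i]] <- data.frame(
        scenario_id = grid$scenario_id[i], model = model,
        crc_sens = grid$crc_sens[i], aa_sens = grid$aa_sens[i],
        interval = grid$interval[i], cost = grid$cost[i],
        crc_deaths_per_1000 = sm$crc_deaths_per_1000,
        crc_cases_per_1000 = sm$crc_cases_per_1000,
        lyg_per_1000 = sm$lyg_per_1000, qalyg_per_1000 = sm$qalyg_per_1000,
        cost_per_person = sm$cost_per_person,
        net_cost_per_person = sm$net_cost_per_person,
        nmb = sm$nmb_per_person,
        effect_noninf_fit = cls$effect_noninf_fit,
        effect_noninf_col = cls$effect_noninf_col,
        nmb_noninf_col = cls$nmb_noninf_col,
        ce_status = cls$ce_status,
        cost_effective = cls$cost_effective)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify one blood-test scenario against the comparators
#'
#' Builds the frontier over no screening, FIT, colonoscopy and the scenario,
#' and labels the scenario `"dominated"`, `"extended_dominated"`,
#' `"cost_effective_under_150k"` (efficient with an ICER below `wtp_cap`, or
#' efficient and cost-saving) or `"efficient_above_150k"`. Also reports
#' effectiveness noninferiority (at least the comparator's QALYs gained,
#' same cohort and seed) and net-monetary-benefit noninferiority vs
#' colonoscopy.
#'
#' @param summary the scenario's `outcome_summary`.
#' @param s_fit,s_col comparator summaries on the same cohort.
#' @param econ an [econ_params()].
#' @param wtp_cap ICER cost-effectiveness threshold (default $150,000/QALY).
#' @return a list with `ce_status`, `cost_effective`, `effect_noninf_fit`,
#'   `effect_noninf_col`, `nmb_noninf_col`.
#' @export
classify_scenario <- function(summary, s_fit, s_col, econ = econ_params(),
                              wtp_cap = 150000) {
  s_ns <- list(strategy = "No screening", qalyg_per_1000 = 0,
               net_cost_per_person = 0)
  fr <- compute_frontier(list(s_ns, s_fit, s_col, summary), econ)
  row <- fr[fr$strategy == summary$strategy, ]
  ce_status <- if (row$status != "efficient") row$status
    else if (is.na(row$icer) || row$icer < wtp_cap) "cost_effective_under_150k"
    else "efficient_above_150k"
  nmb_of <- function(s) net_monetary_benefit_values(
    s$qalyg_per_1000 / 1000, s$net_cost_per_person, econ$wtp)
  list(ce_status = ce_status,
       cost_effective = ce_status == "cost_effective_under_150k",
       effect_noninf_fit = summary$qalyg_per_1000 >= s_fit$qalyg_per_1000,
       effect_noninf_col = summary$qalyg_per_1000 >= s_col$qalyg_per_1000,
       nmb_noninf_col = nmb_of(summary) >= nmb_of(s_col))
}
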