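# Shared fixtures and independent oracles. Expensive cohorts are built once
# per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the shared desk-scale cohort used by the heavier checks
acc_cohort <- function(n = 20000L, seed = 42L) {
  cached(sprintf("cohort_%d_%d", n, seed),
         simulate_cohort(nathist_params(), gompertz_makeham_life_table(),
                         n = n, seed = seed))
}

acc_no_screen <- function(n = 20000L, seed = 42L) {
  cached(sprintf("noscreen_%d_%d", n, seed),
         run_strategy(acc_cohort(n, seed), strategy_no_screening()))
}

# minimal summary stub for frontier tests
mk_summary <- function(name, qalyg_pp, netcost_pp)
  list(strategy = name, qalyg_per_1000 = qalyg_pp * 1000,
       net_cost_per_person = netcost_pp)

# Brute-force dominance oracle, independent of compute_frontier: a strategy
# is efficient iff no single strategy nor convex combination of two others
# weakly dominates it with one strict inequality.
frontier_oracle_status <- function(q, cc) {
  n <- length(q)
  vapply(seq_len(n), function(i) {
    for (j in seq_len(n)) {
      if (j == i) next
      if (q[j] >= q[i] && cc[j] <= cc[i] && (q[j] > q[i] || cc[j] < cc[i]))
        return("dominated")
    }
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j == i || k == i || j >= k) next
      # feasible lambda interval where the blend's QALYs >= q[i]
      if (q[j] == q[k]) {
        if (q[k] < q[i]) next
        lam <- c(0, 1)
      } else {
        t <- (q[i] - q[k]) / (q[j] - q[k])
        lam <- if (q[j] > q[k]) c(max(0, t), 1) else c(0, min(1, t))
        if (lam[1] > lam[2]) next
      }
      cm <- lam * cc[j] + (1 - lam) * cc[k]
      qm <- lam * q[j] + (1 - lam) * q[k]
      strict <- (qm > q[i] + 1e-12) | (cm < cc[i] - 1e-12)
      if (any(cm <= cc[i] + 1e-12 & strict))
        return("extended_dominated")
    }
    "efficient"
  }, character(1))
}

# hand-constructed person history for screening unit tests
mk_person <- function(onset, adv = Inf, preclin = Inf, clinical = Inf,
                      death_oc = 95, u_stage = 0.5, u_cure = 0.5,
                      u_surv = 0.5) {
  k <- length(onset)
  structure(list(
    person_id = 1L,
    other_cause_death_age = death_oc,
    lesions = data.frame(person_id = rep(1L, k), lesion_id = seq_len(k),
                         onset_age = onset,
                         adv_age = rep_len(adv, k),
                         preclin_age = rep_len(preclin, k),
                         clinical_age = rep_len(clinical, k),
                         u_stage = rep_len(u_stage, k),
                         u_cure = rep_len(u_cure, k),
                         u_surv = rep_len(u_surv, k)),
    first_clinical_crc_age = NA_real_,
    stage_at_clinical = NA_character_,
    crc_death_age_unscreened = NA_real_), class = "person_history")
}
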