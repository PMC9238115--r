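# Deterministic cohort engine. Occupancy is propagated as a row vector
# through the weekly matrix; costs and utilities are credited to the state
# occupied during each cycle (start-of-cycle occupancy), transitions take
# effect at cycle end, and no half-cycle correction is applied: over 52
# weekly cycles the correction is far below the reporting precision.

#' Apply a strategy's relative risk to the transition matrix
#'
#' Multiplies every off-diagonal transition into the exacerbation state
#' (W->A, S->A) by `rr_exacerbation`; with `rr_scope = "A_and_S_entry"` the
#' W->S entry is scaled as well. The probability removed from a transition is
#' credited to the source state's stay probability: an averted exacerbation
#' leaves the patient where they were. The result is row-stochastic by
#' construction.
#'
#' @param base 3x3 row-stochastic weekly transition matrix.
#' @param strat A [strategy()].
#' @return Adjusted 3x3 transition matrix.
#' @examples
#' P <- base_inputs()$transition
#' adjust_transitions(P, strategy("EO", 0.57))["W", "A"]  # 0.004 * 0.57
#' @export
adjust_transitions <- function(base, strat) {
  validate_transition_matrix(base)
  rr <- strat$rr_exacerbation
  if (rr == 1) return(base)
  P <- base
  scale_entry <- function(from, to) {
    p <- P[from, to] * rr
    if (p > 1)
      stop(sprintf("rr x p > 1 for %s->%s (rr = %g, p = %g)", from, to, rr,
                   P[from, to]), call. = FALSE)
    P[from, from] <<- P[from, from] + P[from, to] - p
    P[from, to] <<- p
  }
  scale_entry("W", "A")
  scale_entry("S", "A")
  if (strat$rr_scope == "A_and_S_entry") scale_entry("W", "S")
  validate_transition_matrix(P)
  P
}

#' Run the deterministic cohort model for one strategy arm
#'
#' Starting with the whole cohort in the configured initial state, occupancy
#' is propagated for `horizon_cycles` weekly cycles. Each cycle accrues
#' `utility[state] / 52` QALYs and `state_costs[state] +
#' test_cost * tests_per_year / 52` USD per unit of occupancy, undiscounted.
#'
#' @param transitions Weekly transition matrix for this arm (already
#'   RR-adjusted; see [adjust_transitions()]).
#' @param utilities Named utility vector (annual weights).
#' @param state_costs Named per-cycle state-cost vector (USD).
#' @param strat The arm's [strategy()] (supplies the testing cost stream).
#' @param config A [model_config()].
#' @return An object of class `"cua_arm"`: list with `strategy`,
#'   `expected_cost` (USD/patient/year), `expected_qaly` (QALY/patient/year)
#'   and `trace` (data frame: cycle, occupancy per state, cycle_cost,
#'   cycle_qaly; cycle 0 is the initial distribution and accrues nothing).
#' @export
run_cohort <- function(transitions, utilities, state_costs, strat,
                       config = model_config()) {
  st <- health_states()
  n <- config$horizon_cycles
  occ <- matrix(0, n + 1L, 3L, dimnames = list(NULL, st))
  occ[1L, config$initial_state] <- 1
  for (t in seq_len(n))
    occ[t + 1L, ] <- occ[t, , drop = FALSE] %*% transitions
  u <- utilities[st]; cs <- state_costs[st]
  cpy <- 52 / config$cycle_length_weeks  # cycles per year
  test_per_cycle <- strat$test_cost_per_administration * strat$tests_per_year / cpy
  # credit for the state occupied during cycle t = occupancy at its start
  during <- occ[seq_len(n), , drop = FALSE]
  cycle_qaly <- as.vector(during %*% u) / cpy
  cycle_cost <- as.vector(during %*% cs) + test_per_cycle
  trace <- data.frame(cycle = 0:n, occ,
                      cycle_cost = c(0, cycle_cost),
                      cycle_qaly = c(0, cycle_qaly))
  structure(list(strategy = strat$name,
                 expected_cost = sum(cycle_cost),
                 expected_qaly = sum(cycle_qaly),
                 trace = trace),
            class = "cua_arm")
}

#' @export
print.cua_arm <- function(x, ...) {
  cat(sprintf("<cua_arm> %s: cost %.2f USD/yr, %.4f QALY/yr\n", x$strategy,
              x$expected_cost, x$expected_qaly))
  invisible(x)
}

#' Evaluate every strategy arm on one parameter set
#'
#' @param params A [parameter_set()] (needs >= 2 strategies for comparisons).
#' @param config A [model_config()].
#' @return Named list of [run_cohort()] results, one per strategy.
#' @export
evaluate_arms <- function(params, config = model_config()) {
  lapply(params$strategies, function(s)
    run_cohort(adjust_transitions(params$transition, s), params$utilities,
               params$state_costs, s, config))
}

#' Export a cohort trace as long-format CSV
#'
#' @param arm A `"cua_arm"` from [run_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(arm, path) {
  tr <- arm$trace
  long <- do.call(rbind, lapply(health_states(), function(s)
    data.frame(cycle = tr$cycle, state = s, occupancy = tr[[s]],
               cycle_cost = tr$cycle_cost, cycle_qaly = tr$cycle_qaly)))
  long <- long[order(long$cycle, match(long$state, health_states())), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
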