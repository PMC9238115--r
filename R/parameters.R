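#' @keywords internal
"_PACKAGE"

# The three health states, in fixed order. W = well-controlled,
# S = sub-optimal control (no exacerbation), A = asthma exacerbation.
#' Health-state labels of the asthma model
#' @return Character vector `c("W", "S", "A")`.
#' @export
health_states <- function() c("W", "S", "A")

#' Build a weekly transition matrix from its off-diagonal probabilities
#'
#' Only transitions between distinct states are configured; each stay
#' probability is derived as the row complement, so rows are row-stochastic
#' by construction.
#'
#' @param off A named list of named lists, e.g.
#'   `list(W = list(S = 0.097, A = 0.004), ...)`; missing entries are 0.
#' @return A 3x3 row-stochastic matrix with dimnames `W,S,A`.
#' @examples
#' transition_matrix(list(W = list(S = 0.097, A = 0.004),
#'                        S = list(W = 0.817, A = 0.007),
#'                        A = list(W = 0.271, S = 0.052)))
#' @export
transition_matrix <- function(off) {
  st <- health_states()
  P <- matrix(0, 3, 3, dimnames = list(st, st))
  for (from in names(off)) {
    if (!from %in% st) stop("unknown state '", from, "'", call. = FALSE)
    for (to in names(off[[from]])) {
      if (!to %in% st) stop("unknown state '", to, "'", call. = FALSE)
      if (to == from)
        stop("stay probability ", from, "->", from,
             " is derived, not configured", call. = FALSE)
      P[from, to] <- off[[from]][[to]]
    }
  }
  diag(P) <- 0
  over <- rowSums(P) > 1 + 1e-12
  if (any(over))
    stop(paste(sprintf("row '%s': off-diagonal probability mass sums to %.12g (> 1)",
                       rownames(P)[over], rowSums(P)[over]), collapse = "\n"),
         call. = FALSE)
  diag(P) <- 1 - rowSums(P)
  validate_transition_matrix(P)
  P
}

validate_transition_matrix <- function(P, label = "transition matrix") {
  errs <- character()
  if (!is.matrix(P) || any(dim(P) != 3L))
    return(stop(label, ": must be a 3x3 matrix", call. = FALSE))
  if (any(P < -1e-12 | P > 1 + 1e-12))
    errs <- c(errs, sprintf("%s: entries outside [0,1]", label))
  bad <- abs(rowSums(P) - 1) > 1e-12
  if (any(bad))
    errs <- c(errs, sprintf("%s: row '%s' sums to %.12g, not 1", label,
                            rownames(P)[bad], rowSums(P)[bad]))
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)
  invisible(P)
}

#' Define one management strategy (comparator arm)
#'
#' @param name Arm identifier (e.g. `"EO"`, `"FeNO"`, `"standard"`).
#' @param rr_exacerbation Relative risk applied to transitions into the
#'   exacerbation state (and optionally into sub-optimal control, see
#'   `rr_scope`); 1 for standard care.
#' @param rr_scope `"A_entry_only"` multiplies the W->A and S->A entries;
#'   `"A_and_S_entry"` additionally multiplies W->S. Probability removed from
#'   a transition is credited to the source state's stay probability.
#' @param rr_sd SD of the lognormal PSA prior on `rr_exacerbation` (0 = fixed).
#' @param test_cost_per_administration USD per biomarker test.
#' @param test_cost_sd SD of the gamma PSA prior on the test cost.
#' @param tests_per_year Number of test administrations per patient-year.
#' @return An object of class `"cua_strategy"`.
#' @export
strategy <- function(name, rr_exacerbation = 1,
                     rr_scope = c("A_entry_only", "A_and_S_entry"),
                     rr_sd = 0,
                     test_cost_per_administration = 0, test_cost_sd = 0,
                     tests_per_year = 0) {
  rr_scope <- match.arg(rr_scope)
  errs <- character()
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    errs <- c(errs, "strategy name must be a non-empty string")
  if (!is.numeric(rr_exacerbation) || rr_exacerbation <= 0)
    errs <- c(errs, sprintf("strategy '%s': rr_exacerbation must be > 0", name))
  if (test_cost_per_administration < 0 || tests_per_year < 0)
    errs <- c(errs, sprintf("strategy '%s': negative test cost/frequency", name))
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)
  structure(list(name = name, rr_exacerbation = rr_exacerbation,
                 rr_scope = rr_scope, rr_sd = rr_sd,
                 test_cost_per_administration = test_cost_per_administration,
                 test_cost_sd = test_cost_sd,
                 tests_per_year = tests_per_year),
            class = "cua_strategy")
}

#' Model run configuration
#'
#' The model is fixed at weekly cycles over a 12-month horizon with no
#' discounting; those values are validated, not silently changed, so a
#' configuration that contradicts the analytic frame fails loudly.
#'
#' @param horizon_cycles Number of weekly cycles (default 52 = 12 months).
#' @param cycle_length_weeks Cycle length in weeks (must be 1).
#' @param wtp Willingness-to-pay threshold in USD/QALY (default 5180).
#' @param discount_rate Annual discount rate; must be 0 for the one-year frame.
#' @param initial_state State holding the whole cohort at cycle 0.
#' @param psa_replicates Default number of PSA replicates.
#' @return An object of class `"cua_config"`.
#' @export
model_config <- function(horizon_cycles = 52L, cycle_length_weeks = 1,
                         wtp = 5180, discount_rate = 0, initial_state = "W",
                         psa_replicates = 1000L) {
  errs <- character()
  if (cycle_length_weeks != 1)
    errs <- c(errs, "cycle_length_weeks must be 1")
  if (discount_rate != 0)
    errs <- c(errs, "discount_rate must be 0 over the 12-month horizon")
  if (!initial_state %in% health_states())
    errs <- c(errs, "initial_state must be one of W, S, A")
  if (horizon_cycles < 1) errs <- c(errs, "horizon_cycles must be >= 1")
  if (wtp < 0) errs <- c(errs, "wtp must be >= 0")
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)
  structure(list(horizon_cycles = as.integer(horizon_cycles),
                 cycle_length_weeks = cycle_length_weeks, wtp = wtp,
                 discount_rate = discount_rate, initial_state = initial_state,
                 psa_replicates = as.integer(psa_replicates)),
            class = "cua_config")
}

#' Assemble the full parameter set of the model
#'
#' @param transition 3x3 row-stochastic weekly transition matrix
#'   (see [transition_matrix()]).
#' @param utilities Named numeric vector of utility weights in `[0,1]`,
#'   one per state (`W`, `S`, `A`), in QALYs per year spent in the state.
#' @param state_costs Named numeric vector of USD per state per weekly cycle.
#' @param strategies List of [strategy()] objects with unique names.
#' @param transition_sds 3x3 matrix of PSA standard deviations for the
#'   off-diagonal transition probabilities (`NA` on the diagonal; 0 = fixed).
#' @param utility_sds Named numeric vector of beta-prior SDs for utilities.
#' @param state_cost_cv Coefficient of variation of the gamma PSA priors on
#'   the per-cycle state costs (a single CV shared by the three states).
#' @param sa_ranges Optional data frame `parameter_id, low, high` of one-way
#'   sensitivity ranges; see [default_sa_ranges()].
#' @return An object of class `"cua_params"`.
#' @export
parameter_set <- function(transition, utilities, state_costs, strategies,
                          transition_sds = NULL, utility_sds = NULL,
                          state_cost_cv = 0, sa_ranges = NULL) {
  st <- health_states()
  errs <- character()
  v <- tryCatch({validate_transition_matrix(transition); NULL},
                error = function(e) conditionMessage(e))
  if (!is.null(v)) errs <- c(errs, v)
  utilities <- utilities[st]; state_costs <- state_costs[st]
  if (anyNA(utilities) || any(utilities < 0 | utilities > 1))
    errs <- c(errs, "utilities: one value per state W,S,A required, each in [0,1]")
  if (anyNA(state_costs) || any(state_costs < 0))
    errs <- c(errs, "state_costs: one non-negative value per state required")
  if (!length(strategies))
    errs <- c(errs, "at least one strategy required")
  if (!all(vapply(strategies, inherits, TRUE, "cua_strategy")))
    errs <- c(errs, "strategies must be built with strategy()")
  nm <- vapply(strategies, function(s) s$name, "")
  if (anyDuplicated(nm))
    errs <- c(errs, sprintf("duplicate strategy names: %s",
                            paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (is.null(transition_sds)) {
    transition_sds <- matrix(0, 3, 3, dimnames = list(st, st))
    diag(transition_sds) <- NA
  }
  if (is.null(utility_sds)) utility_sds <- stats::setNames(rep(0, 3), st)
  if (state_cost_cv < 0) errs <- c(errs, "state_cost_cv must be >= 0")
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)
  names(strategies) <- nm
  structure(list(transition = transition, transition_sds = transition_sds,
                 utilities = utilities, utility_sds = utility_sds[st],
                 state_costs = state_costs, state_cost_cv = state_cost_cv,
                 strategies = strategies, sa_ranges = sa_ranges),
            class = "cua_params")
}

#' @export
print.cua_params <- function(x, ...) {
  cat("<cua_params> 3-state weekly Markov inputs\n")
  cat("Transition matrix:\n"); print(round(x$transition, 4))
  cat("Utilities:", paste(sprintf("%s=%g", names(x$utilities), x$utilities),
                          collapse = "  "), "\n")
  cat("State costs (USD/cycle):",
      paste(sprintf("%s=%.2f", names(x$state_costs), x$state_costs),
            collapse = "  "), "\n")
  for (s in x$strategies)
    cat(sprintf("Strategy %-10s RR=%.3g (%s)  test %.2f USD x %.3g/yr\n",
                s$name, s$rr_exacerbation, s$rr_scope,
                s$test_cost_per_administration, s$tests_per_year))
  invisible(x)
}

#' Base-case inputs of the published Colombian pediatric asthma analysis
#'
#' Transition probabilities, utilities, relative risks and test costs as
#' reported for the source cost-utility study (weekly cycles; EO = sputum
#' eosinophil guidance, FeNO = exhaled nitric oxide guidance). Per-cycle
#' state costs and the testing schedule are not reported anywhere and default
#' to zero here; [calibrate_cua()] fits them to the published arm-level
#' results, and [replication_params()] loads the frozen calibrated set.
#'
#' @param rr_scope RR scope applied to the biomarker arms.
#' @return A [parameter_set()].
#' @export
base_inputs <- function(rr_scope = "A_entry_only") {
  st <- health_states()
  P <- transition_matrix(list(W = list(S = 0.097, A = 0.004),
                              S = list(W = 0.817, A = 0.007),
                              A = list(W = 0.271, S = 0.052)))
  Psd <- matrix(0, 3, 3, dimnames = list(st, st)); diag(Psd) <- NA
  Psd["W", "S"] <- 0.029; Psd["W", "A"] <- 0.002
  Psd["S", "W"] <- 0.038; Psd["S", "A"] <- 0.003
  Psd["A", "W"] <- 0.044; Psd["A", "S"] <- 0.046
  parameter_set(
    transition = P, transition_sds = Psd,
    utilities = c(W = 0.99, S = 0.70, A = 0.31),
    utility_sds = c(W = 0.016, S = 0.072, A = 0.070),
    state_costs = c(W = 0, S = 0, A = 0),
    strategies = list(
      strategy("EO", rr_exacerbation = 0.57, rr_scope = rr_scope,
               rr_sd = 0.20, test_cost_per_administration = 9.14,
               test_cost_sd = 4.09, tests_per_year = 0),
      strategy("FeNO", rr_exacerbation = 0.76, rr_scope = rr_scope,
               rr_sd = 0.274, test_cost_per_administration = 2.20,
               test_cost_sd = 1.08, tests_per_year = 0),
      strategy("standard", rr_exacerbation = 1)))
}

#' Default one-way sensitivity ranges
#'
#' Test costs use their reported one-way ranges (FeNO 1.20-4.20,
#' EO 5.15-13.20 USD); transition probabilities, utilities, relative risks
#' and state costs use +/-25% of the base-case value (probabilities and
#' utilities capped at 1). Inverted printed ranges are normalised to
#' `(min, max)` with a warning.
#'
#' @param params A [parameter_set()].
#' @return Data frame with columns `parameter_id`, `low`, `high`.
#' @export
default_sa_ranges <- function(params) {
  rows <- list()
  add <- function(id, base, low = NULL, high = NULL, cap = Inf) {
    if (is.null(low)) low <- base * 0.75
    if (is.null(high)) high <- base * 1.25
    if (low > high) {
      warning(sprintf("SA range for %s printed inverted; normalising", id))
      tmp <- low; low <- high; high <- tmp
    }
    high <- min(high, cap)
    rows[[length(rows) + 1L]] <<- data.frame(parameter_id = id, low = low,
                                             high = high)
  }
  st <- health_states()
  # a transition can grow only by what the row's stay probability can absorb
  for (from in st) for (to in st) if (from != to &&
                                      params$transition[from, to] > 0)
    add(sprintf("transition.%s.%s", from, to), params$transition[from, to],
        cap = params$transition[from, to] + params$transition[from, from])
  for (s in st) add(sprintf("utility.%s", s), params$utilities[[s]], cap = 1)
  for (s in st) if (params$state_costs[[s]] > 0)
    add(sprintf("state_cost.%s", s), params$state_costs[[s]])
  for (k in params$strategies) {
    if (k$rr_exacerbation != 1)
      add(sprintf("rr.%s", k$name), k$rr_exacerbation)
    if (k$test_cost_per_administration > 0) {
      tr <- switch(k$name, EO = c(5.15, 13.20), FeNO = c(1.20, 4.20), NULL)
      if (is.null(tr))
        add(sprintf("test_cost.%s", k$name), k$test_cost_per_administration)
      else add(sprintf("test_cost.%s", k$name),
               k$test_cost_per_administration, tr[1], tr[2])
    }
  }
  do.call(rbind, rows)
}
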