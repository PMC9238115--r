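# First-order (individual-level) microsimulator and random model generator.
# The microsimulation uses the same cycle convention as the cohort engine
# (credit for the start-of-cycle state, transition at cycle end), so its
# per-patient mean cost/QALY is an unbiased estimate of the cohort totals.

#' Simulate individual patient trajectories through the Markov model
#'
#' @param transitions Weekly transition matrix (RR-adjusted if needed).
#' @param utilities Named annual utility vector.
#' @param state_costs Named per-cycle state costs (USD).
#' @param n Number of patients.
#' @param config A [model_config()].
#' @param seed Optional integer seed (uses the global RNG when `NULL`).
#' @return Object of class `"cua_microsim"`: `states` (n x cycles+1 integer
#'   matrix of state indices into [health_states()]), per-patient `cost` and
#'   `qaly` vectors, and `occupancy` (empirical per-cycle state shares).
#' @export
simulate_patients <- function(transitions, utilities, state_costs, n,
                              config = model_config(), seed = NULL) {
  stopifnot(n >= 1L)
  validate_transition_matrix(transitions)
  if (!is.null(seed)) set.seed(seed)
  st <- health_states()
  ncyc <- config$horizon_cycles
  states <- matrix(0L, n, ncyc + 1L)
  states[, 1L] <- match(config$initial_state, st)
  # vectorised: per cycle, patients in the same state draw from one row
  for (t in seq_len(ncyc)) {
    cur <- states[, t]
    nxt <- integer(n)
    for (s in 1:3) {
      idx <- which(cur == s)
      if (length(idx))
        nxt[idx] <- sample.int(3L, length(idx), replace = TRUE,
                               prob = transitions[s, ])
    }
    states[, t + 1L] <- nxt
  }
  during <- states[, seq_len(ncyc), drop = FALSE]
  u <- utilities[st]; cs <- state_costs[st]
  qaly <- rowSums(matrix(u[during], n)) / (52 / config$cycle_length_weeks)
  cost <- rowSums(matrix(cs[during], n))
  occupancy <- t(apply(during, 2, tabulate, nbins = 3L)) / n
  colnames(occupancy) <- st
  structure(list(states = states, cost = cost, qaly = qaly,
                 occupancy = occupancy, n = n), class = "cua_microsim")
}

#' @export
print.cua_microsim <- function(x, ...) {
  cat(sprintf(
    "<cua_microsim> %d patients: mean cost %.2f (SE %.2f), mean QALY %.4f (SE %.5f)\n",
    x$n, mean(x$cost), stats::sd(x$cost) / sqrt(x$n),
    mean(x$qaly), stats::sd(x$qaly) / sqrt(x$n)))
  invisible(x)
}

#' Export microsimulated trajectories as long-format CSV
#'
#' @param sim A `"cua_microsim"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(sim, path) {
  st <- health_states()
  ncol_s <- ncol(sim$states)
  long <- data.frame(
    patient_id = rep(seq_len(sim$n), each = ncol_s),
    cycle = rep(0:(ncol_s - 1L), sim$n),
    state = st[as.vector(t(sim$states))])
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Generate a random valid parameter set for property-based tests
#'
#' Draws a random row-stochastic transition matrix (Dirichlet rows), random
#' utilities in `[0,1]`, positive state costs, and a set of strategies with
#' spread-out relative risks and distinct test prices. With
#' `symmetric = TRUE` the chain is doubly stochastic and symmetric, so its
#' stationary distribution is uniform by construction.
#'
#' @param n_strategies Number of strategies (first one is standard care,
#'   RR = 1).
#' @param symmetric Build a symmetric chain with known uniform stationary
#'   distribution.
#' @param zero_variance Set every prior SD to zero (PSA degenerates to the
#'   base case).
#' @param seed Optional integer seed.
#' @return A [parameter_set()].
#' @export
make_toy_model <- function(n_strategies = 3L, symmetric = FALSE,
                           zero_variance = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- health_states()
  if (symmetric) {
    # symmetric doubly stochastic: uniform stationary distribution
    a <- stats::runif(1, 0.05, 0.3); b <- stats::runif(1, 0.05, 0.3)
    P <- matrix(c(1 - a - b, a, b,
                  a, 1 - a - b, b,
                  b, b, 1 - 2 * b), 3, 3, byrow = TRUE,
                dimnames = list(st, st))
  } else {
    P <- t(vapply(1:3, function(i) {
      g <- stats::rgamma(3, shape = c(5, 2, 1))
      g / sum(g)
    }, numeric(3)))
    dimnames(P) <- list(st, st)
  }
  u <- sort(stats::runif(3, 0.2, 1), decreasing = TRUE)
  names(u) <- st
  cs <- stats::setNames(sort(stats::rgamma(3, 2, rate = 0.05)), st)
  rrs <- c(1, stats::runif(n_strategies - 1L, 0.2, 1.4))
  scopes <- c("A_entry_only", "A_and_S_entry")
  pick_scope <- function(k) scopes[1L + (k %% 2L)]
  # cap each RR so the scaled entries never exhaust a row's stay probability
  max_rr <- function(P, scope) {
    lim <- function(from, entries) {
      e <- sum(P[from, entries])
      if (e == 0) Inf else 1 + P[from, from] / e
    }
    min(lim("W", if (scope == "A_and_S_entry") c("S", "A") else "A"),
        lim("S", "A"))
  }
  rrs <- vapply(seq_len(n_strategies), function(k)
    min(rrs[k], 0.95 * max_rr(P, pick_scope(k))), 0)
  strategies <- lapply(seq_len(n_strategies), function(k)
    strategy(if (k == 1L) "standard" else paste0("arm", k),
             rr_exacerbation = rrs[k],
             rr_scope = pick_scope(k),
             rr_sd = if (zero_variance || k == 1L) 0 else 0.1 * rrs[k],
             test_cost_per_administration = if (k == 1L) 0 else
               stats::runif(1, 1, 20),
             test_cost_sd = if (zero_variance || k == 1L) 0 else
               stats::runif(1, 0.5, 2),
             tests_per_year = if (k == 1L) 0 else stats::runif(1, 2, 20)))
  Psd <- matrix(0, 3, 3, dimnames = list(st, st)); diag(Psd) <- NA
  if (!zero_variance)
    for (i in st) for (j in st) if (i != j && P[i, j] > 0)
      Psd[i, j] <- 0.2 * sqrt(P[i, j] * (1 - P[i, j]) / 50)
  usd <- if (zero_variance) c(W = 0, S = 0, A = 0) else
    stats::setNames(0.3 * sqrt(u * (1 - u) / 50), st)
  usd[u >= 1 - 1e-9] <- 0
  parameter_set(transition = P, transition_sds = Psd, utilities = u,
                utility_sds = usd, state_costs = cs,
                state_cost_cv = if (zero_variance) 0 else 0.1,
                strategies = strategies)
}
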