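# Second-order Monte Carlo machinery. Each PSA replicate draws ONE shared
# parameter set (utilities ~ beta, state and test costs ~ gamma, relative
# risks ~ lognormal, transition rows ~ Dirichlet, all moment-matched) and
# evaluates every arm on it: uncertainty is parametric and common across
# arms; arms differ only through their RR and testing stream.

#' Draw one random parameter set from the configured priors
#'
#' @param params Base [parameter_set()]; printed SDs define the priors
#'   (zero SD keeps an input fixed at its base value).
#' @return A [parameter_set()] realisation. Uses R's global RNG; seed it
#'   (or use [run_psa()]) for reproducibility.
#' @export
draw_parameter_set <- function(params) {
  st <- health_states()
  P <- params$transition
  for (from in st) {
    sds <- params$transition_sds[from, ]
    sds[from] <- NA
    if (all(is.na(sds) | sds == 0)) next
    dp <- dirichlet_row_params(P[from, ], ifelse(is.na(sds), 0, sds),
                               label = from)
    P[from, ] <- draw_dirichlet_row(dp, 1L)[1L, ]
  }
  u <- params$utilities
  for (s in st) if (params$utility_sds[[s]] > 0)
    u[s] <- draw_prior(prior_spec("beta", params$utilities[[s]],
                                  params$utility_sds[[s]]),
                       label = paste0("utility.", s))
  cs <- params$state_costs
  if (params$state_cost_cv > 0)
    for (s in st) if (cs[[s]] > 0)
      cs[s] <- draw_prior(prior_spec("gamma", params$state_costs[[s]],
                                     params$state_cost_cv *
                                       params$state_costs[[s]]),
                          label = paste0("state_cost.", s))
  strategies <- lapply(params$strategies, function(k) {
    if (k$rr_sd > 0)
      k$rr_exacerbation <- draw_prior(
        prior_spec("lognormal", k$rr_exacerbation, k$rr_sd),
        label = paste0("rr.", k$name))
    if (k$test_cost_sd > 0 && k$test_cost_per_administration > 0)
      k$test_cost_per_administration <- draw_prior(
        prior_spec("gamma", k$test_cost_per_administration, k$test_cost_sd),
        label = paste0("test_cost.", k$name))
    k
  })
  out <- params
  out$transition <- P; out$utilities <- u; out$state_costs <- cs
  out$strategies <- strategies
  out
}

#' Probabilistic sensitivity analysis
#'
#' Runs `replicates` second-order Monte Carlo replicates: each draws a shared
#' parameter set via [draw_parameter_set()] and evaluates every arm
#' deterministically on it.
#'
#' @param params Base [parameter_set()].
#' @param config A [model_config()].
#' @param replicates Number of replicates (default from `config`).
#' @param seed Integer seed; the whole PSA is reproducible from it.
#' @return Object of class `"cua_psa"`: matrices `cost` and `qaly`
#'   (replicates x strategies), `seed`, `n_replicates`, `wtp`.
#' @export
run_psa <- function(params, config = model_config(),
                    replicates = config$psa_replicates, seed = 1L) {
  stopifnot(replicates >= 1L)
  set.seed(seed)
  nm <- names(params$strategies)
  cost <- qaly <- matrix(NA_real_, replicates, length(nm),
                         dimnames = list(NULL, nm))
  for (r in seq_len(replicates)) {
    pr <- draw_parameter_set(params)
    arms <- evaluate_arms(pr, config)
    cost[r, ] <- vapply(arms, function(a) a$expected_cost, 0)
    qaly[r, ] <- vapply(arms, function(a) a$expected_qaly, 0)
  }
  structure(list(cost = cost, qaly = qaly, seed = seed,
                 n_replicates = replicates, wtp = config$wtp,
                 strategies = nm),
            class = "cua_psa")
}

#' Simulate method: PSA replicates of a fitted cost-utility analysis
#'
#' @param object A [cua()] object.
#' @param nsim Number of PSA replicates.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A `"cua_psa"` object (see [run_psa()]).
#' @export
simulate.cua <- function(object, nsim = object$config$psa_replicates,
                         seed = 1L, ...) {
  run_psa(object$params, object$config, replicates = nsim, seed = seed)
}

#' @export
print.cua_psa <- function(x, ...) {
  cat(sprintf("<cua_psa> %d replicates (seed %d), WTP %.0f USD/QALY\n",
              x$n_replicates, x$seed, x$wtp))
  s <- rbind(mean_cost = colMeans(x$cost), sd_cost = apply(x$cost, 2, stats::sd),
             mean_qaly = colMeans(x$qaly), sd_qaly = apply(x$qaly, 2, stats::sd))
  print(round(t(s), 4))
  invisible(x)
}

#' Incremental PSA cloud for a pair of strategies
#'
#' @param psa A `"cua_psa"`.
#' @param pair Length-2 character vector `c(reference, comparator)`.
#' @return Data frame with `delta_qaly`, `delta_cost`, `inmb` per replicate.
#' @export
psa_increments <- function(psa, pair = c("EO", "FeNO")) {
  stopifnot(all(pair %in% psa$strategies))
  dq <- psa$qaly[, pair[1]] - psa$qaly[, pair[2]]
  dc <- psa$cost[, pair[1]] - psa$cost[, pair[2]]
  data.frame(delta_qaly = dq, delta_cost = dc, inmb = dq * psa$wtp - dc)
}

#' Quadrant shares of the cost-effectiveness plane
#'
#' Quadrants follow the mathematical (counter-clockwise) convention on the
#' (x = incremental QALY, y = incremental cost) plane:
#' Q1 `(+,+)`, Q2 `(-,+)`, Q3 `(-,-)`, Q4 `(+,-)`. Boundary points
#' (an increment exactly 0) count as positive. Shares always sum to 1.
#'
#' @param psa A `"cua_psa"`.
#' @param pair Reference/comparator pair, as in [psa_increments()].
#' @return Named numeric vector `Q1..Q4` with attribute `"signs"` giving the
#'   `(dQALY, dCost)` sign labels so any numbering convention can be read off.
#' @export
quadrant_shares <- function(psa, pair = c("EO", "FeNO")) {
  inc <- psa_increments(psa, pair)
  qpos <- inc$delta_qaly >= 0; cpos <- inc$delta_cost >= 0
  sh <- c(Q1 = mean(qpos & cpos), Q2 = mean(!qpos & cpos),
          Q3 = mean(!qpos & !cpos), Q4 = mean(qpos & !cpos))
  attr(sh, "signs") <- c(Q1 = "(+dQALY,+dCost)", Q2 = "(-dQALY,+dCost)",
                         Q3 = "(-dQALY,-dCost)", Q4 = "(+dQALY,-dCost)")
  sh
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability a strategy is
#' cost-effective is the fraction of replicates in which it attains the
#' highest net monetary benefit; exact ties share the replicate equally, so
#' probabilities across strategies sum to 1 at every threshold.
#'
#' @param psa A `"cua_psa"`.
#' @param wtp_grid Non-negative thresholds; the default spans 0-15,000
#'   USD/QALY in 101 steps and includes 5180 exactly.
#' @return Object of class `"cua_ceac"`: data frame `wtp`, one probability
#'   column per strategy, and `frontier` (the most probable strategy).
#' @export
ceac <- function(psa, wtp_grid = sort(unique(c(seq(0, 15000, length.out = 101),
                                               5180)))) {
  stopifnot(length(wtp_grid) >= 1L, all(wtp_grid >= 0))
  k <- length(psa$strategies)
  prob <- matrix(0, length(wtp_grid), k,
                 dimnames = list(NULL, psa$strategies))
  for (i in seq_along(wtp_grid)) {
    b <- psa$qaly * wtp_grid[i] - psa$cost
    mx <- b == apply(b, 1, max)
    prob[i, ] <- colMeans(mx / rowSums(mx))
  }
  out <- data.frame(wtp = wtp_grid, prob,
                    frontier = psa$strategies[max.col(prob, "first")])
  class(out) <- c("cua_ceac", "data.frame")
  out
}

#' Scatter the PSA cloud on the incremental cost-effectiveness plane
#'
#' @param x A `"cua_psa"`.
#' @param pair Reference/comparator pair.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cua_psa <- function(x, pair = c("EO", "FeNO"), ...) {
  inc <- psa_increments(x, pair)
  graphics::plot(inc$delta_qaly, inc$delta_cost, pch = ".",
                 xlab = sprintf("Incremental QALYs (%s - %s)", pair[1], pair[2]),
                 ylab = "Incremental cost (USD)", ...)
  graphics::abline(h = 0, v = 0, col = "grey")
  graphics::abline(0, x$wtp, lty = 2)
  invisible(x)
}

#' Export PSA cloud / CEAC tables as CSV
#'
#' @param psa A `"cua_psa"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_psa_csv <- function(psa, path) {
  long <- do.call(rbind, lapply(psa$strategies, function(s)
    data.frame(replicate = seq_len(psa$n_replicates), strategy = s,
               cost = psa$cost[, s], qaly = psa$qaly[, s])))
  utils::write.csv(long[order(long$replicate, long$strategy), ], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_psa_csv
#' @param ceac_table A `"cua_ceac"` from [ceac()].
#' @export
write_ceac_csv <- function(ceac_table, path) {
  utils::write.csv(as.data.frame(ceac_table), path, row.names = FALSE)
  invisible(path)
}

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the deterministic model with each listed parameter set to
#' the low then the high end of its range, everything else held at base
#' case, and records the resulting ICER of the reference pair and the
#' highest-NMB strategy at each end.
#'
#' @param params Base [parameter_set()].
#' @param config A [model_config()].
#' @param ranges Data frame `parameter_id, low, high`
#'   (default [default_sa_ranges()]).
#' @param pair Reference/comparator pair for the recorded ICER.
#' @return Data frame: `parameter_id, end, value, icer, flag, best_nmb`,
#'   plus the base-case ICER as attribute `"base_icer"`.
#' @export
owsa <- function(params, config = model_config(),
                 ranges = default_sa_ranges(params), pair = c("EO", "FeNO")) {
  base_arms <- evaluate_arms(params, config)
  base_ic <- icer(base_arms[[pair[1]]], base_arms[[pair[2]]])
  rows <- list()
  for (i in seq_len(nrow(ranges))) {
    id <- ranges$parameter_id[i]
    for (end in c("low", "high")) {
      val <- ranges[[end]][i]
      p2 <- set_parameter(params, id, val)
      arms <- evaluate_arms(p2, config)
      ic <- icer(arms[[pair[1]]], arms[[pair[2]]])
      b <- vapply(arms, function(a)
        nmb(a$expected_qaly, a$expected_cost, config$wtp), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter_id = id, end = end, value = val, icer = ic$value,
        flag = ic$flag, best_nmb = names(b)[which.max(b)])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "base_icer") <- base_ic$value
  out
}

# Resolve a dotted parameter_id ("transition.W.S", "utility.S",
# "state_cost.A", "rr.EO", "test_cost.FeNO", "tests_per_year.EO") and return
# a modified copy of the parameter set. Transition edits rebalance the
# source-state stay probability so the row stays stochastic.
set_parameter <- function(params, id, value) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  p <- params
  kind <- parts[1]
  if (kind == "transition" && length(parts) == 3L) {
    from <- parts[2]; to <- parts[3]
    P <- p$transition
    P[from, from] <- P[from, from] + P[from, to] - value
    P[from, to] <- value
    if (P[from, from] < 0)
      stop(sprintf("parameter %s = %g makes row '%s' leave the simplex",
                   id, value, from), call. = FALSE)
    p$transition <- P
  } else if (kind == "utility" && length(parts) == 2L) {
    p$utilities[parts[2]] <- value
  } else if (kind == "state_cost" && length(parts) == 2L) {
    p$state_costs[parts[2]] <- value
  } else if (kind %in% c("rr", "test_cost", "tests_per_year") &&
             length(parts) == 2L) {
    k <- parts[2]
    if (!k %in% names(p$strategies))
      stop("unknown strategy in parameter id: ", id, call. = FALSE)
    field <- switch(kind, rr = "rr_exacerbation",
                    test_cost = "test_cost_per_administration",
                    tests_per_year = "tests_per_year")
    p$strategies[[k]][[field]] <- value
  } else stop("unknown parameter id: ", id, call. = FALSE)
  p
}
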