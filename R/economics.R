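# Incremental cost-effectiveness analytics. ICERs are never compared on
# rounded values; rounding happens only at print time.

#' Incremental cost-effectiveness ratio between two arms
#'
#' `(C_ref - C_comp) / (Q_ref - Q_comp)`, with dominance expressed as flags
#' rather than errors: `"dominant"` when the reference saves money and gains
#' QALYs, `"dominated"` when it costs more and loses QALYs,
#' `"dominated-by-cost"` when QALYs are equal and it costs more,
#' `"undefined"` when both deltas vanish.
#'
#' @param reference,comparator `"cua_arm"` objects (or lists with
#'   `expected_cost` and `expected_qaly`), evaluated on the same inputs.
#' @return List with `delta_cost`, `delta_qaly`, `value` (USD/QALY, `NA`
#'   when flagged) and `flag` (`"ok"` or a dominance flag).
#' @examples
#' a <- list(expected_cost = 1376, expected_qaly = 0.95)
#' b <- list(expected_cost = 1334, expected_qaly = 0.94)
#' icer(a, b)$value  # 4200
#' @export
icer <- function(reference, comparator) {
  dc <- reference$expected_cost - comparator$expected_cost
  dq <- reference$expected_qaly - comparator$expected_qaly
  flag <- "ok"; val <- NA_real_
  if (dq > 0 && dc < 0) flag <- "dominant"
  else if (dq < 0 && dc > 0) flag <- "dominated"
  else if (dq == 0) flag <- if (dc > 0) "dominated-by-cost"
                            else if (dc < 0) "dominant-by-cost" else "undefined"
  else val <- dc / dq
  list(delta_cost = dc, delta_qaly = dq, value = val, flag = flag)
}

#' Net monetary benefit
#'
#' `NMB = QALY x WTP - cost`; vectorised over its arguments.
#'
#' @param qaly QALYs per patient.
#' @param cost Cost per patient (USD).
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return NMB in USD.
#' @export
nmb <- function(qaly, cost, wtp) qaly * wtp - cost

#' Incremental net monetary benefit of arm `a` over arm `b`
#'
#' `(Q_a - Q_b) x WTP - (C_a - C_b)`, identically `nmb(a) - nmb(b)`.
#'
#' @param a,b Arm results with `expected_cost`, `expected_qaly`.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return INMB in USD; positive means `a` is cost-effective versus `b`.
#' @export
inmb <- function(a, b, wtp) {
  (a$expected_qaly - b$expected_qaly) * wtp -
    (a$expected_cost - b$expected_cost)
}

#' Cost-effectiveness frontier over a set of arms
#'
#' Arms are ordered by cost; strictly dominated arms (costlier and no more
#' effective than another) are removed first, then extended dominance is
#' applied iteratively: an arm is removed when the ICER of reaching it
#' exceeds the ICER of the next more effective frontier arm. The surviving
#' arms have strictly increasing ICERs. Exact cost/QALY ties keep the
#' first-listed arm, with a message.
#'
#' @param arms List of `"cua_arm"` objects.
#' @return List with `order` (arm names by increasing cost), `frontier`
#'   (names of non-dominated arms), `status` (named: `"frontier"`,
#'   `"dominated"` or `"ext_dominated"`), and `icers` (ICER of each frontier
#'   arm versus the previous frontier arm).
#' @export
ce_frontier <- function(arms) {
  stopifnot(length(arms) >= 1L)
  nm <- vapply(arms, function(a) a$strategy, "")
  cost <- vapply(arms, function(a) a$expected_cost, 0)
  qaly <- vapply(arms, function(a) a$expected_qaly, 0)
  dup <- duplicated(round(cbind(cost, qaly), 12))
  if (any(dup))
    message("tied arms (equal cost and QALY): keeping first-listed on frontier")
  ord <- order(cost, -qaly, seq_along(arms))
  status <- stats::setNames(rep("frontier", length(arms)), nm)
  # strict dominance (including ties resolved to the first-listed arm)
  for (i in seq_along(arms)) for (j in seq_along(arms)) {
    if (i == j) next
    better <- (cost[j] < cost[i] && qaly[j] >= qaly[i]) ||
              (cost[j] <= cost[i] && qaly[j] > qaly[i]) ||
              (cost[j] == cost[i] && qaly[j] == qaly[i] && j < i)
    if (better && status[nm[j]] != "dominated") status[nm[i]] <- "dominated"
  }
  repeat {
    live <- ord[status[nm[ord]] == "frontier" |
                  status[nm[ord]] == "ext_dominated"]
    live <- live[status[nm[live]] == "frontier"]
    if (length(live) < 3L) break
    ic <- diff(cost[live]) / diff(qaly[live])
    drop <- which(diff(ic) < 0)  # ICER decreases => middle arm ext. dominated
    if (!length(drop)) break
    status[nm[live[drop[1L] + 1L]]] <- "ext_dominated"
  }
  live <- ord[status[nm[ord]] == "frontier"]
  icers <- if (length(live) > 1L)
    stats::setNames(diff(cost[live]) / diff(qaly[live]), nm[live][-1L])
  else stats::setNames(numeric(0), character(0))
  list(order = nm[ord], frontier = nm[live], status = status, icers = icers)
}

#' Base-case cost-utility analysis
#'
#' The central evaluator: runs the deterministic cohort model for every
#' strategy, derives pairwise incremental comparisons, net monetary benefit
#' at the configured willingness-to-pay, dominance status and the efficiency
#' frontier. Returned objects have `print`, `summary`, `coef`, `plot` and
#' `simulate` methods; `simulate()` runs the probabilistic sensitivity
#' analysis (see [simulate.cua()]).
#'
#' @param params A [parameter_set()] with at least two strategies.
#' @param config A [model_config()].
#' @return An object of class `"cua"`.
#' @examples
#' rp <- replication_params()
#' fit <- cua(rp$params, rp$config)
#' fit
#' coef(fit)
#' @export
cua <- function(params, config = model_config()) {
  stopifnot(inherits(params, "cua_params"), length(params$strategies) >= 2L)
  arms <- evaluate_arms(params, config)
  fr <- ce_frontier(arms)
  tab <- ce_table_internal(arms, fr, config$wtp)
  structure(list(params = params, config = config, arms = arms,
                 frontier = fr, table = tab),
            class = "cua")
}

ce_table_internal <- function(arms, fr, wtp) {
  ord <- fr$order
  cost <- vapply(arms[ord], function(a) a$expected_cost, 0)
  qaly <- vapply(arms[ord], function(a) a$expected_qaly, 0)
  d_cost <- c(NA, diff(cost)); d_qaly <- c(NA, diff(qaly))
  icer_col <- rep(NA_real_, length(ord)); flag <- fr$status[ord]
  for (i in seq_along(ord)[-1L]) {
    ic <- icer(arms[[ord[i]]], arms[[ord[i - 1L]]])
    icer_col[i] <- ic$value
  }
  data.frame(strategy = ord, cost = cost, marginal_cost = d_cost,
             qaly = qaly, marginal_qaly = d_qaly, ce_ratio = cost / qaly,
             nmb = nmb(qaly, cost, wtp), icer = icer_col,
             status = unname(flag), row.names = NULL)
}

#' Tabulate base-case results
#'
#' @param x A `"cua"` object.
#' @param path Optional CSV output path.
#' @return The cost-effectiveness table (strategy, cost, marginal cost,
#'   QALYs, marginal QALYs, cost/effectiveness ratio, NMB, pairwise ICER,
#'   dominance status), ordered by increasing cost.
#' @export
ce_table <- function(x, path = NULL) {
  stopifnot(inherits(x, "cua"))
  if (!is.null(path)) utils::write.csv(x$table, path, row.names = FALSE)
  x$table
}

#' @export
print.cua <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Cost-utility analysis: %d strategies, %d weekly cycles, WTP %0.f USD/QALY\n\n",
    length(x$arms), x$config$horizon_cycles, x$config$wtp))
  tab <- x$table
  shown <- data.frame(strategy = tab$strategy,
                      cost = sprintf("%.0f", tab$cost),
                      qaly = sprintf("%.3f", tab$qaly),
                      NMB = sprintf("%.0f", tab$nmb),
                      ICER = ifelse(is.na(tab$icer),
                                    ifelse(tab$status == "frontier", "(ref)",
                                           tab$status),
                                    sprintf("%.0f", tab$icer)),
                      status = tab$status)
  print(shown, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cua <- function(object, ...) {
  structure(list(table = object$table, frontier = object$frontier,
                 wtp = object$config$wtp), class = "summary.cua")
}

#' @export
print.summary.cua <- function(x, ...) {
  cat("Efficiency frontier:", paste(x$frontier$frontier, collapse = " -> "),
      "\n")
  if (length(x$frontier$icers))
    cat("Frontier ICERs (USD/QALY):",
        paste(sprintf("%s = %.0f", names(x$frontier$icers), x$frontier$icers),
              collapse = ", "), "\n")
  best <- x$table$strategy[which.max(x$table$nmb)]
  cat(sprintf("Highest NMB at WTP %.0f: %s\n", x$wtp, best))
  print(x$table, digits = 6)
  invisible(x)
}

#' @export
coef.cua <- function(object, ...) {
  m <- cbind(cost = vapply(object$arms, function(a) a$expected_cost, 0),
             qaly = vapply(object$arms, function(a) a$expected_qaly, 0))
  rownames(m) <- names(object$arms)
  m
}

#' Plot the deterministic cost-effectiveness plane
#'
#' Arms as points on the (QALY, cost) plane with the efficiency frontier
#' drawn through the non-dominated arms.
#'
#' @param x A `"cua"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cua <- function(x, ...) {
  cf <- coef(x)
  graphics::plot(cf[, "qaly"], cf[, "cost"], pch = 19,
                 xlab = "QALYs per patient-year",
                 ylab = "Cost per patient-year (USD)", ...)
  graphics::text(cf[, "qaly"], cf[, "cost"], rownames(cf), pos = 3)
  fr <- x$frontier$frontier
  graphics::lines(cf[fr, "qaly"], cf[fr, "cost"], lty = 2)
  invisible(x)
}
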