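test_that("zero-variance priors make every PSA replicate the base case", {
  toy <- make_toy_model(zero_variance = TRUE, seed = 8)
  cfg <- model_config(psa_replicates = 3L)
  det <- cua(toy, cfg)
  psa <- run_psa(toy, cfg, replicates = 3, seed = 99)
  for (r in 1:3) {
    expect_equal(unname(psa$cost[r, ]), unname(coef(det)[, "cost"]),
                 tolerance = 1e-12)
    expect_equal(unname(psa$qaly[r, ]), unname(coef(det)[, "qaly"]),
                 tolerance = 1e-12)
  }
  # deterministic signs => the whole cloud collapses into one quadrant
  qs <- quadrant_shares(psa, pair = c("arm2", "standard"))
  expect_equal(sum(qs == 1), 1L)
  expect_equal(sum(qs), 1)
})

test_that("identical seeds give bit-identical PSA results; seeds matter", {
  rp <- replication_cfg()
  a <- run_psa(rp$params, rp$config, replicates = 25, seed = 123)
  b <- run_psa(rp$params, rp$config, replicates = 25, seed = 123)
  expect_identical(a$cost, b$cost)
  expect_identical(a$qaly, b$qaly)
  c2 <- run_psa(rp$params, rp$config, replicates = 25, seed = 124)
  expect_false(identical(a$cost, c2$cost))
})

test_that("draws are shared across arms within a replicate", {
  rp <- replication_cfg()
  # remove arm-specific uncertainty: only shared draws remain
  p <- rp$params
  p$strategies <- lapply(p$strategies, function(s) {
    s$rr_sd <- 0; s$test_cost_sd <- 0; s })
  psa <- run_psa(p, rp$config, replicates = 40, seed = 2)
  # with shared parameter draws, standard-arm cost moves with EO-arm cost
  expect_gt(cor(psa$cost[, "EO"], psa$cost[, "standard"]), 0.99)
})

test_that("quadrant shares sum to one and respect the sign convention", {
  rp <- replication_cfg()
  psa <- run_psa(rp$params, rp$config, replicates = 60, seed = 5)
  qs <- quadrant_shares(psa)
  expect_equal(sum(qs), 1)
  inc <- psa_increments(psa)
  expect_equal(unname(qs["Q1"]),
               mean(inc$delta_qaly >= 0 & inc$delta_cost >= 0))
  expect_identical(attr(qs, "signs")[["Q2"]], "(-dQALY,+dCost)")
})

test_that("CEAC probabilities are coherent across the WTP grid", {
  rp <- replication_cfg()
  psa <- run_psa(rp$params, rp$config, replicates = 80, seed = 31)
  cc <- ceac(psa)
  probs <- as.matrix(cc[, psa$strategies])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(cc)))
  expect_true(5180 %in% cc$wtp)
  # at WTP 0 a strategy wins iff it is cheapest
  cheapest <- psa$strategies[max.col(-psa$cost, "first")]
  at0 <- cc[cc$wtp == 0, psa$strategies]
  expect_equal(unname(unlist(at0)),
               as.vector(table(factor(cheapest, levels = psa$strategies)) /
                           psa$n_replicates),
               tolerance = 1e-12)
})

test_that("tied strategies split the acceptability probability evenly", {
  toy <- make_toy_model(zero_variance = TRUE, seed = 4)
  twin <- toy$strategies$arm2
  twin$name <- "arm2twin"
  toy2 <- parameter_set(toy$transition, toy$utilities, toy$state_costs,
                        c(toy$strategies, list(arm2twin = twin)),
                        transition_sds = toy$transition_sds,
                        utility_sds = toy$utility_sds,
                        state_cost_cv = 0)
  psa <- run_psa(toy2, model_config(), replicates = 10, seed = 1)
  cc <- ceac(psa, wtp_grid = c(0, 5180))
  expect_equal(cc$arm2, cc$arm2twin)
})

test_that("pairwise acceptability crosses one half near the median PSA ICER", {
  rp <- replication_cfg()
  psa <- run_psa(rp$params, rp$config, replicates = 400, seed = 17)
  # EO vs standard: incremental QALYs are positive in almost every replicate,
  # so the acceptability curve should cross 0.5 near the cloud's median ICER
  inc <- psa_increments(psa, pair = c("EO", "standard"))
  pce <- function(wtp) mean(inc$delta_qaly * wtp - inc$delta_cost > 0)
  med <- median(inc$delta_cost / inc$delta_qaly)
  expect_lt(abs(pce(max(med, 0)) - 0.5), 0.15)
})

test_that("PSA summaries shrink like one over root n", {
  rp <- replication_cfg()
  psa <- run_psa(rp$params, rp$config, replicates = 400, seed = 9)
  half <- psa$qaly[1:200, "EO"]
  full <- psa$qaly[, "EO"]
  se_half <- sd(half) / sqrt(200); se_full <- sd(full) / sqrt(400)
  expect_equal(se_half / se_full, sqrt(2), tolerance = 0.35)
})

test_that("one-way sensitivity analysis records both range ends per parameter", {
  rp <- replication_cfg()
  tab <- owsa(rp$params, rp$config)
  base_ic <- attr(tab, "base_icer")
  expect_equal(nrow(tab), 2 * nrow(rp$params$sa_ranges))
  # degenerate range reproduces the base-case ICER
  deg <- owsa(rp$params, rp$config,
              ranges = data.frame(parameter_id = "utility.S",
                                  low = rp$params$utilities[["S"]],
                                  high = rp$params$utilities[["S"]]))
  expect_equal(deg$icer, rep(base_ic, 2))
  # FeNO test-cost excursions recorded at the printed range ends
  fe <- tab[tab$parameter_id == "test_cost.FeNO", ]
  expect_equal(sort(fe$value), c(1.20, 4.20))
  expect_length(unique(fe$icer), 2L)  # both ends re-evaluated and recorded
  expect_error(owsa(rp$params, rp$config,
                    ranges = data.frame(parameter_id = "nope.X",
                                        low = 1, high = 2)),
               "unknown parameter")
})
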