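test_that("relative-risk adjustment scales exacerbation entries and rebalances stays", {
  P <- base_inputs()$transition
  eo <- strategy("EO", 0.57)
  Q <- adjust_transitions(P, eo)
  expect_equal(Q["W", "A"], 0.004 * 0.57)
  expect_equal(Q["S", "A"], 0.007 * 0.57)
  expect_equal(Q["W", "W"], P["W", "W"] + 0.004 * (1 - 0.57))
  expect_equal(Q["W", "S"], P["W", "S"])  # untouched under A-entry scope
  expect_equal(rowSums(Q), rowSums(P), tolerance = 1e-15)

  feno <- strategy("FeNO", 0.76)
  expect_equal(adjust_transitions(P, feno)["S", "A"], 0.00532)

  wide <- strategy("x", 0.5, rr_scope = "A_and_S_entry")
  Qw <- adjust_transitions(P, wide)
  expect_equal(Qw["W", "S"], P["W", "S"] * 0.5)
  expect_equal(rowSums(Qw), c(W = 1, S = 1, A = 1), tolerance = 1e-15)

  expect_identical(adjust_transitions(P, strategy("std", 1)), P)
  expect_error(adjust_transitions(P, strategy("bad", 300)), "rr x p > 1")
})

test_that("cohort traces conserve mass and start in the initial state", {
  set.seed(11)
  cfg <- model_config()
  for (i in 1:300) {
    P <- random_stochastic_matrix()
    arm <- run_cohort(P, c(W = 1, S = 0.5, A = 0), c(W = 0, S = 1, A = 2),
                      strategy("s"), cfg)
    occ <- as.matrix(arm$trace[, health_states()])
    expect_true(all(abs(rowSums(occ) - 1) < 1e-10))
    expect_true(all(occ >= 0))
    expect_equal(unname(occ[1, ]), c(1, 0, 0))
  }
})

test_that("degenerate chains give closed-form accruals", {
  cfg <- model_config()
  st <- health_states()
  I3 <- diag(3); dimnames(I3) <- list(st, st)
  arm <- run_cohort(I3, c(W = 0.99, S = 0.7, A = 0.31),
                    c(W = 2, S = 0, A = 0), strategy("s"), cfg)
  expect_equal(arm$expected_qaly, 0.99)
  expect_equal(arm$expected_cost, 2 * 52)

  # deterministic two-state alternation: W <-> S every cycle
  P <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE,
              dimnames = list(st, st))
  arm2 <- run_cohort(P, c(W = 1, S = 0, A = 0), c(W = 0, S = 0, A = 0),
                     strategy("s"), model_config(horizon_cycles = 2))
  occ <- as.matrix(arm2$trace[, st])
  expect_equal(unname(occ), rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0)))
  # 2 cycles at mean occupancy utility 0.5: 2/52 * 0.5
  expect_equal(arm2$expected_qaly, 2 / 52 * 0.5)
})

test_that("cohort engine matches explicit path enumeration on 3-cycle models", {
  set.seed(3)
  u <- c(W = 0.95, S = 0.6, A = 0.2)
  cs <- c(W = 5, S = 20, A = 300)
  for (i in 1:10) {
    P <- random_stochastic_matrix()
    oracle <- path_enumeration_oracle(P, u, cs, k = 3)
    arm <- run_cohort(P, u, cs, strategy("s"),
                      model_config(horizon_cycles = 3))
    expect_equal(arm$expected_qaly, oracle$qaly, tolerance = 1e-9)
    expect_equal(arm$expected_cost, oracle$cost, tolerance = 1e-9)
  }
})

test_that("long-run occupancy converges to the stationary distribution", {
  P <- base_inputs()$transition
  pi_oracle <- stationary_oracle(P)
  arm <- run_cohort(P, c(W = 1, S = 1, A = 1), c(W = 0, S = 0, A = 0),
                    strategy("s"), model_config(horizon_cycles = 1000))
  final <- unlist(arm$trace[nrow(arm$trace), health_states()])
  expect_equal(unname(final), pi_oracle, tolerance = 1e-8)
  expect_equal(pi_oracle, c(0.882, 0.105, 0.013), tolerance = 0.01)
})

test_that("stronger exacerbation reduction never hurts QALYs or raises A-occupancy", {
  rp <- replication_cfg()
  rrs <- seq(0.3, 1, by = 0.1)
  res <- t(vapply(rrs, function(rr) {
    s <- strategy("x", rr)
    arm <- run_cohort(adjust_transitions(rp$params$transition, s),
                      rp$params$utilities, rp$params$state_costs, s,
                      rp$config)
    c(q = arm$expected_qaly, a = sum(arm$trace$A))
  }, numeric(2)))
  expect_true(all(diff(res[, "q"]) <= 1e-12))        # QALY non-increasing in RR
  expect_true(all(diff(res[, "a"]) >= -1e-12))       # A-occupancy non-decreasing
})

test_that("evaluate_arms returns one result per strategy from shared inputs", {
  rp <- replication_cfg()
  arms <- evaluate_arms(rp$params, rp$config)
  expect_named(arms, c("EO", "FeNO", "standard"))
  # EO never occupies the exacerbation state more than standard care
  expect_true(all(arms$EO$trace$A <= arms$standard$trace$A + 1e-15))
  zero <- rp$params
  zero$state_costs[] <- 0
  zero$strategies <- lapply(zero$strategies, function(s) {
    s$test_cost_per_administration <- 0; s })
  expect_equal(unname(vapply(evaluate_arms(zero, rp$config),
                             function(a) a$expected_cost, 0)),
               c(0, 0, 0))
})

test_that("trace CSV export is long-format and re-readable", {
  rp <- replication_cfg()
  arm <- evaluate_arms(rp$params, rp$config)$EO
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(arm, tmp)
  back <- read.csv(tmp)
  expect_named(back, c("cycle", "state", "occupancy", "cycle_cost",
                       "cycle_qaly"))
  expect_equal(nrow(back), 3 * 53)
  expect_equal(sum(back$occupancy), 53, tolerance = 1e-9)
})
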