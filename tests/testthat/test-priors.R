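test_that("method-of-moments beta and gamma parameters reproduce their moments", {
  cases <- list(
    list(fam = "beta", m = 0.70, s = 0.072, check = c(shape1 = 27.66, shape2 = 11.85)),
    list(fam = "beta", m = 0.99, s = 0.016, check = NULL),
    list(fam = "beta", m = 0.31, s = 0.070, check = NULL),
    list(fam = "gamma", m = 95.05, s = 8.53, check = c(shape = 124.15, scale = 0.7655)),
    list(fam = "gamma", m = 9.14, s = 4.09, check = NULL),
    list(fam = "lognormal", m = 0.57, s = 0.20, check = NULL),
    list(fam = "lognormal", m = 0.76, s = 0.274, check = NULL))
  for (cs in cases) {
    mm <- moment_match(prior_spec(cs$fam, cs$m, cs$s))
    # frozen hand-evaluated shape values
    if (!is.null(cs$check))
      for (nm in names(cs$check))
        expect_equal(mm[[nm]], cs$check[[nm]], tolerance = 1e-3)
    # moments recovered exactly under the family's closed forms
    rec <- switch(cs$fam,
      beta = {
        m <- mm$shape1 / (mm$shape1 + mm$shape2)
        c(m, sqrt(m * (1 - m) / (mm$shape1 + mm$shape2 + 1)))
      },
      gamma = c(mm$shape * mm$scale, sqrt(mm$shape) * mm$scale),
      lognormal = {
        m <- exp(mm$meanlog + mm$sdlog^2 / 2)
        c(m, m * sqrt(exp(mm$sdlog^2) - 1))
      })
    expect_equal(rec, c(cs$m, cs$s), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("zero-variance priors degenerate to a point mass", {
  for (fam in c("beta", "gamma", "lognormal")) {
    mm <- moment_match(prior_spec(fam, 0.5, 0))
    expect_true(mm$degenerate)
    expect_identical(draw_prior(prior_spec(fam, 0.5, 0), 5), rep(0.5, 5))
  }
})

test_that("infeasible beta priors fail naming the parameter", {
  expect_error(moment_match(prior_spec("beta", 0.5, 0.6), label = "u_S"),
               "u_S.*infeasible")
})

test_that("Dirichlet row concentration is anchored to the largest-SD component", {
  dp <- dirichlet_row_params(c(0.899, 0.097, 0.004), c(NA, 0.029, 0.002))
  expect_equal(dp$n_eff, 0.097 * 0.903 / 0.029^2 - 1, tolerance = 1e-12)
  expect_equal(dp$alpha, c(0.899, 0.097, 0.004) * dp$n_eff, tolerance = 1e-12)
  expect_true(all(dp$alpha > 0))
  # sampled rows live on the simplex and reproduce the anchored marginal SD
  set.seed(42)
  draws <- draw_dirichlet_row(dp, 1e5)
  expect_equal(rowSums(draws), rep(1, 1e5), tolerance = 1e-12)
  expect_equal(sd(draws[, 2]), 0.029, tolerance = 0.02)
  expect_equal(colMeans(draws), c(0.899, 0.097, 0.004), tolerance = 0.005)
})

test_that("degenerate Dirichlet rows return a point mass, and bad rows error", {
  expect_warning(dp <- dirichlet_row_params(c(1, 0, 0), c(NA, 0.1, 0)),
                 "degenerate")
  expect_identical(draw_dirichlet_row(dp, 3),
                   matrix(rep(c(1, 0, 0), each = 3), nrow = 3))
  expect_error(dirichlet_row_params(c(0.5, 0.6, 0.1), c(0.1, 0.1, 0.1)),
               "sum")
})

test_that("Monte Carlo draws reproduce every replication prior's moments", {
  rp <- replication_cfg()$params
  set.seed(7)
  n <- 1e5
  check_moments <- function(x, m, s, what) {
    # mean within 3 standard errors, SD within 5%
    expect_lt(abs(mean(x) - m), 3 * s / sqrt(n) + 1e-12)
    expect_equal(sd(x), s, tolerance = 0.05)
  }
  for (s in health_states()) {
    su <- rp$utility_sds[[s]]
    check_moments(draw_prior(prior_spec("beta", rp$utilities[[s]], su), n),
                  rp$utilities[[s]], su)
    sc <- rp$state_cost_cv * rp$state_costs[[s]]
    check_moments(draw_prior(prior_spec("gamma", rp$state_costs[[s]], sc), n),
                  rp$state_costs[[s]], sc)
  }
  for (k in rp$strategies) {
    if (k$rr_sd > 0)
      check_moments(draw_prior(prior_spec("lognormal", k$rr_exacerbation,
                                          k$rr_sd), n),
                    k$rr_exacerbation, k$rr_sd)
    if (k$test_cost_sd > 0)
      check_moments(draw_prior(prior_spec("gamma",
                                          k$test_cost_per_administration,
                                          k$test_cost_sd), n),
                    k$test_cost_per_administration, k$test_cost_sd)
  }
  for (from in health_states()) {
    sds <- rp$transition_sds[from, ]; sds[from] <- 0
    dp <- dirichlet_row_params(rp$transition[from, ], sds, label = from)
    draws <- draw_dirichlet_row(dp, n)
    k <- which.max(sds)
    expect_equal(sd(draws[, k]), sds[[k]], tolerance = 0.05)
    expect_equal(colMeans(draws), unname(rp$transition[from, ]),
                 tolerance = 0.01)
  }
})
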