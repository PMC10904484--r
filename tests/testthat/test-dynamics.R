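test_that("the stock recursion depreciates and adds realised gambling", {
  expect_equal(stock_update(10, 3, 0.2), 11)
  expect_equal(stock_update(2, 1, 0.5), 2)   # fixed point S = A / d
  # abstinence: geometric decay toward zero, never negative
  S <- 5
  for (k in 1:30) {
    S_next <- stock_update(S, 0, 0.4)
    expect_lt(S_next, S)
    expect_gte(S_next, 0)
    S <- S_next
  }
  expect_equal(S, 5 * 0.6^30)
  expect_error(stock_update(-1, 0, 0.5), "non-negative")
  expect_error(stock_update(1, 1, 1), "d")
})

test_that("the myopic optimum matches its closed form with a corner at zero", {
  ag <- unbiased_agent(1.5, -0.5, -0.5, -0.5, alpha_C = 1, d = 0.5)
  expect_equal(myopic_optimal_amount(0, ag), 1)  # -b/c = 1
  expect_equal(myopic_optimal_amount(1, ag), 2)  # -(1+1)/(-1)
  # b^S < 0 forces the corner solution
  ag2 <- unbiased_agent(0.5, -1, -1, -1, alpha_C = 1, d = 0.5)
  expect_equal(myopic_optimal_amount(0, ag2), 0)
})

test_that("grid search over decision utility recovers the closed-form optimum", {
  ag <- unbiased_agent(1.5, -0.5, -0.5, -0.5, alpha_C = 1, d = 0.5)
  expect_equal(brute_force_optimum(0, ag, grid_step = 1e-4), 1,
               tolerance = 2e-4)
  ag2 <- unbiased_agent(0.5, -1, -1, -1, alpha_C = 1, d = 0.5)
  expect_equal(brute_force_optimum(0, ag2, grid_step = 1e-4), 0)
  set.seed(61)
  for (k in 1:30) {
    ag <- rand_agent(participating = sample(c(TRUE, FALSE), 1),
                     biased = sample(c(TRUE, FALSE), 1))
    S <- runif(1, 0, 4)
    step <- 1e-3
    expect_lte(abs(brute_force_optimum(S, ag, step) -
                     myopic_optimal_amount(S, ag)), step)
  }
})

test_that("trajectories follow the stock recursion and converge to the equilibrium", {
  ag <- unbiased_agent(1.5, -1, -0.5, -1, alpha_C = 0.5, d = 0.5)
  tr <- simulate_trajectory(ag, T_horizon = 200)
  p <- tr$periods
  # recursion holds between consecutive records
  expect_equal(p$S[-1], (1 - ag$d) * p$S[-nrow(p)] + p$A[-nrow(p)])
  # unconstrained: realised amount equals the optimum, cravings satisfied
  expect_equal(p$A, p$A_star)
  expect_true(all(p$craving_loss == 0))
  expect_true(tr$converged)
  expect_false(tr$divergent)
  expect_equal(p$A[200], equilibrium_amount(ag), tolerance = 1e-9)
  expect_equal(p$S[200], equilibrium_stock(ag), tolerance = 1e-9)
})

test_that("a vanishing craving propensity gives a constant amount gambled", {
  ag <- agent_parameters(
    subjective = coefficient_set(1.5, -1, -0.5, -1, "subjective"),
    objective = coefficient_set(1.5, -1, -0.5, -1, "objective"),
    alpha_C = 1e-12, d = 0.5)
  tr <- simulate_trajectory(ag, T_horizon = 50)
  expect_equal(tr$periods$A, rep(0.5, 50), tolerance = 1e-8)  # -b/c
})

test_that("zero income means no gambling, zero utilities, non-gambler status", {
  ag <- unbiased_agent(1.5, -1, -0.5, -1, alpha_C = 0.5, d = 0.5,
                       income = 0)
  tr <- simulate_trajectory(ag, T_horizon = 20)
  expect_true(all(tr$periods$A == 0))
  expect_true(all(tr$periods$status == "non_gambler"))
  expect_equal(tr$lifetime_decision_utility, 0)
  expect_equal(tr$lifetime_experienced_utility, 0)
})

test_that("income-constrained gamblers gamble their budget and carry unsatisfied cravings", {
  ag_free <- unbiased_agent(1.5, -1, -0.5, -1, alpha_C = 0.6, d = 0.5)
  ag_tight <- unbiased_agent(1.5, -1, -0.5, -1, alpha_C = 0.6, d = 0.5,
                             income = 0.6)  # below the equilibrium 1.25
  tr_free <- simulate_trajectory(ag_free, T_horizon = 100)
  tr <- simulate_trajectory(ag_tight, T_horizon = 100)
  p <- tr$periods
  constrained <- p$A < p$A_star
  expect_true(any(constrained))
  expect_equal(p$A[constrained], rep(0.6, sum(constrained)))
  # whenever the realised amount falls short with stock present, cravings bite
  expect_true(all(p$craving_loss[constrained & p$S > 0] > 0))
  # stock grows more slowly than unconstrained
  expect_true(all(p$S <= tr_free$periods$S + 1e-12))
})

test_that("gambler status transitions through current and ex-gambler as amounts start and stop", {
  ag <- unbiased_agent(1.5, -1, -0.5, -1, alpha_C = 0.5, d = 0.5)
  # exogenous abstinence from period 5 onward via a zero cap
  cap <- c(rep(Inf, 5), rep(0, 15))
  tr <- simulate_trajectory(ag, T_horizon = 20, cap = cap)
  st <- tr$periods$status
  expect_equal(st[1], "current_gambler")
  expect_true(all(st[1:5] == "current_gambler"))
  expect_true(all(st[6:20] == "ex_gambler"))
  # relapse: cap lifted again
  cap2 <- c(rep(Inf, 5), rep(0, 5), rep(Inf, 10))
  tr2 <- simulate_trajectory(ag, T_horizon = 20, cap = cap2)
  expect_equal(tr2$periods$status[11], "current_gambler")
})

test_that("the convergence condition separates contracting from drifting recursions", {
  expect_true(reaches_equilibrium(
    unbiased_agent(1.5, -1, -0.5, -1, alpha_C = 0.5, d = 0.5)))  # 2 > 1
  expect_false(reaches_equilibrium(
    unbiased_agent(1.5, -0.5, -0.5, -0.5, alpha_C = 1, d = 0.5)))  # 1 < 2
  # knife edge |c^S| = alpha_C / d: the exact affine recurrence has slope
  # one and drifts upward without bound, so it must count as divergent
  ag <- unbiased_agent(1.5, -1, -0.5, -1, alpha_C = 1, d = 0.5)
  expect_false(reaches_equilibrium(ag))
  S <- 0; A_seq <- numeric(50)
  for (t in 1:50) {
    A <- myopic_optimal_amount(S, ag)
    A_seq[t] <- A
    S <- stock_update(S, A, ag$d)
  }
  expect_true(all(diff(A_seq) > 0))
  # constant additive drift each period: linear growth
  expect_equal(diff(A_seq), rep(diff(A_seq)[1], 49), tolerance = 1e-9)
})

test_that("equilibrium amount and stock match the fixed point of the recursion", {
  expect_equal(equilibrium_amount(boundary_agent(0.5)), 1)
  expect_equal(equilibrium_amount(boundary_agent(0.6)), 1.25)
  expect_equal(equilibrium_stock(boundary_agent(0.6)), 2.5)
  tr <- simulate_trajectory(boundary_agent(0.6), T_horizon = 500)
  expect_equal(tr$periods$A[500], 1.25, tolerance = 1e-6)
  # errors on divergent and non-participating agents
  expect_error(equilibrium_amount(
    unbiased_agent(1.5, -0.5, -0.5, -0.5, alpha_C = 1, d = 0.5)),
    "equilibrium")
  expect_error(equilibrium_amount(
    unbiased_agent(0.5, -1, -1, -1, alpha_C = 0.1, d = 0.5)),
    "participate")
})

test_that("the long-run harm verdict matches the sign of objective utility at equilibrium", {
  # boundary: equilibrium amount 1, long-run utility exactly 0 -> benign
  expect_false(develops_negative_utility(boundary_agent(0.5)))
  expect_equal(classify_agent(boundary_agent(0.5))$long_run_experienced_utility, 0)
  # perturbed craving propensity: utility -0.3125 -> harmful
  expect_true(develops_negative_utility(boundary_agent(0.6)))
  expect_equal(classify_agent(boundary_agent(0.6))$long_run_experienced_utility,
               -0.3125)
  # divergent agents are always harmful
  expect_true(develops_negative_utility(
    unbiased_agent(1.5, -0.5, -0.5, -0.5, alpha_C = 1, d = 0.5)))
  expect_error(develops_negative_utility(
    unbiased_agent(0.5, -1, -1, -1, alpha_C = 0.1, d = 0.5)),
    "participate")
})

test_that("the direct harm verdict agrees with the threshold-form inequality", {
  set.seed(71)
  for (k in 1:60) {
    ag <- rand_agent(participating = TRUE, convergent = TRUE,
                     biased = sample(c(TRUE, FALSE), 1))
    if (net_slope(ag$objective) <= 0) next
    expect_identical(develops_negative_utility(ag),
                     harm_condition_inequality(ag))
    expect_silent(develops_negative_utility(ag, cross_check = TRUE))
  }
})

test_that("harm thresholds bracket the sign change of experienced utility", {
  ag <- boundary_agent(0.6)  # unbiased b = 1, c = -2
  expect_equal(harm_threshold_amount(ag), 1)  # 2 b^O / |c^O|
  expect_equal(baseline_gamble_utility(harm_threshold_amount(ag),
                                       ag$objective), 0)
  expect_equal(harm_threshold_stock(ag), 5 / 3)  # (2 * 1 - 1) / 0.6
  expect_equal(indirect_experienced_utility(5 / 3, ag), 0)
  # below the threshold stock the curve is positive, beyond it negative
  expect_gt(indirect_experienced_utility(5 / 3 - 0.1, ag), 0)
  expect_lt(indirect_experienced_utility(5 / 3 + 0.1, ag), 0)
  # b^O <= 0: harmful at any positive amount
  agX <- agent_parameters(
    subjective = coefficient_set(1.2, -1, -0.5, -1, "subjective"),
    objective = coefficient_set(0.4, -1, -0.5, -1, "objective"),
    alpha_C = 0.3, d = 0.5)
  expect_equal(as.numeric(harm_threshold_amount(agX)), 0)
  expect_true(attr(harm_threshold_amount(agX), "harmful_at_any_amount"))
  expect_equal(as.numeric(harm_threshold_stock(agX)), 0)
})

test_that("bisection on the indirect utility curve recovers the threshold stock", {
  set.seed(81)
  found <- 0
  for (k in 1:40) {
    ag <- rand_agent(participating = TRUE, biased = sample(c(TRUE, FALSE), 1))
    if (net_slope(ag$objective) <= 0) next
    S_star <- as.numeric(harm_threshold_stock(ag))
    if (S_star <= 0) next
    root <- uniroot(function(S) indirect_experienced_utility(S, ag),
                    lower = S_star / 2, upper = S_star * 2,
                    tol = 1e-12)$root
    expect_equal(root, S_star, tolerance = 1e-9)
    found <- found + 1
  }
  expect_gte(found, 10)
})

test_that("regime classification composes participation, convergence and harm", {
  # b^S < 0: non-participant
  cls <- classify_agent(unbiased_agent(0.5, -1, -1, -1, alpha_C = 0.1,
                                       d = 0.5))
  expect_equal(cls$regime, "non_participant")
  expect_false(cls$participates)
  # zero income: non-participant even with attractive beliefs
  cls0 <- classify_agent(unbiased_agent(1.5, -1, -0.5, -1, alpha_C = 0.1,
                                        d = 0.5, income = 0))
  expect_equal(cls0$regime, "non_participant")
  # boundary long-run utility counts as benign
  expect_equal(classify_agent(boundary_agent(0.5))$regime,
               "benign_equilibrium")
  expect_equal(classify_agent(boundary_agent(0.6))$regime,
               "harmful_equilibrium")
  clsd <- classify_agent(
    unbiased_agent(1.5, -0.5, -0.5, -0.5, alpha_C = 1, d = 0.5))
  expect_equal(clsd$regime, "divergent_harmful")
  expect_true(clsd$develops_negative_utility)
  expect_identical(clsd$long_run_experienced_utility, -Inf)
})

test_that("simulated amounts contract toward equilibrium at the predicted geometric ratio", {
  set.seed(91)
  for (k in 1:15) {
    ag <- rand_agent(participating = TRUE, convergent = TRUE,
                     u_range = c(0.1, 0.7))
    ratio <- 1 - ag$d + ag$alpha_C / abs(net_curvature(ag$subjective))
    expect_lt(ratio, 1)
    tr <- simulate_trajectory(ag, T_horizon = 300)
    gap <- abs(tr$periods$A - equilibrium_amount(ag))
    # once past the first few periods the gap shrinks by `ratio` each step
    idx <- which(gap[50:250] > 1e-8) + 49L
    if (length(idx) > 5) {
      observed <- gap[idx + 1L] / gap[idx]
      expect_equal(observed, rep(ratio, length(idx)), tolerance = 1e-3)
    }
    expect_equal(tr$periods$A[300], equilibrium_amount(ag),
                 tolerance = 1e-8)
  }
})
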