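test_that("gamble lists satisfy the structural constraints deterministically", {
  set.seed(1)
  g <- generate_gamble_list(48)
  expect_equal(nrow(g), 48)
  expect_true(all(g$xL > g$yL) && all(g$xR > g$yR))
  expect_true(all(g$pL > 0 & g$pL < 1) && all(g$pR > 0 & g$pR < 1))
  expect_false(any(g$xL == g$xR & g$yL == g$yR & g$pL == g$pR))
  for (v in c("dEV", "dSD", "AR")) {
    expect_true(any(g[[v]] > 0) && any(g[[v]] < 0))
  }
  expect_lt(abs(cor(g$dEV, g$AR)), 0.95)
  set.seed(1)
  expect_identical(generate_gamble_list(48), g)
  expect_error(generate_gamble_list(10, alphabet = 100), "2 distinct")
})

test_that("simulated choices follow the logistic rule and its symmetries", {
  pair <- regret_only_pair()
  dv <- decision_variables(pair)
  expect_equal(dv$dEV, 0)
  expect_equal(dv$dSD, 0)
  expect_gt(dv$AR, 0)

  # all-zero coefficients: coin flip
  set.seed(5)
  flips <- replicate(4000, simulate_choice(pair, c(0, 0, 0, 0)))
  expect_lt(abs(mean(flips) - 0.5), 3 * sqrt(0.25 / 4000))

  # a regret-averse agent prefers the option with the smaller maximum
  # regret (here: left) on a pure-AR trial
  set.seed(6)
  prefs <- replicate(4000, simulate_choice(pair, c(0, 0, 0, 0.01)))
  p_expected <- plogis(0.01 * dv$AR)
  expect_gt(mean(prefs), 0.5)
  expect_lt(abs(mean(prefs) - p_expected), 3 * sqrt(p_expected * (1 - p_expected) / 4000))

  # swapping sides maps P(left) to 1 - P(left) when the intercept is zero
  swapped <- trial_pair(pair$right, pair$left)
  dv_s <- decision_variables(swapped)
  expect_equal(plogis(0.01 * dv_s$AR), 1 - p_expected)
})

test_that("simulated ratings follow the linear rule with rounding and clamping", {
  expect_equal(simulate_rating(0, 0, c(0, 0, 0)), 0)
  # baseline-condition coefficients on the worked extreme trial saturate
  expect_equal(simulate_rating(400, 250, c(0, -0.25, -0.59)), -50)
  set.seed(7)
  r <- simulate_rating(runif(500, -400, 400), runif(500, -250, 250),
                       c(0, -0.25, -0.59), sigma = 20)
  expect_true(all(r >= -50 & r <= 50))
  expect_true(all(r == round(r)))
  # without rounding/clamping the rule is exactly linear
  expect_equal(simulate_rating(100, 50, c(1, -0.25, -0.59),
                               round = FALSE, clamp = FALSE),
               1 - 25 - 29.5)
})

test_that("simulate_dataset is reproducible and has the full 2x2 bookkeeping", {
  cfg <- tiny_config(seed = 21)
  d <- simulate_dataset(cfg)
  expect_equal(nrow(d), 6 * 4 * 12)
  counts <- table(d$subject_id, d$beneficiary, d$audience)
  expect_true(all(counts == 12))
  # obtained/counterfactual lie on the correct wheels
  expect_true(all(ifelse(d$choice == 1,
                         d$obtained == d$xL | d$obtained == d$yL,
                         d$obtained == d$xR | d$obtained == d$yR)))
  expect_true(all(ifelse(d$choice == 1,
                         d$counterfactual == d$xR | d$counterfactual == d$yR,
                         d$counterfactual == d$xL | d$counterfactual == d$yL)))
  expect_equal(d$regret, d$counterfactual - d$obtained)
  expect_identical(simulate_dataset(cfg), d)
})

test_that("zero between-subject spread makes all subjects share the population coefficients", {
  cfg <- tiny_config(seed = 31, population = population_spec(tau_scale = 0))
  d <- simulate_dataset(cfg)
  tc <- attr(d, "true_coefficients")
  cell <- tc[tc$beneficiary == "self" & tc$audience == "absent", ]
  expect_equal(var(cell$b_r), 0)
  expect_equal(unique(cell$b_e), 0.010)
  expect_equal(unique(cell$b_r), 0.010)
})

test_that("between-subject spread of true coefficients matches tau", {
  cfg <- simulation_config(n_subjects = 400, n_trials_per_condition = 4,
                           seed = 41)
  d <- simulate_dataset(cfg)
  tc <- attr(d, "true_coefficients")
  cell <- tc[tc$beneficiary == "self" & tc$audience == "absent", ]
  pop <- cfg$population
  tau_r <- pop$tau_r[pop$beneficiary == "self" & pop$audience == "absent"]
  # Monte-Carlo tolerance for an SD from 400 draws: ~ tau/sqrt(2*399)
  expect_lt(abs(sd(cell$b_r) - tau_r), 4 * tau_r / sqrt(2 * 399))
  b_r_pop <- pop$b_r[pop$beneficiary == "self" & pop$audience == "absent"]
  expect_lt(abs(mean(cell$b_r) - b_r_pop), 4 * tau_r / sqrt(400))
})

test_that("subject-constant random effects reuse the same draws in every cell", {
  cfg <- tiny_config(seed = 51, population = null_population_spec(),
                     subject_constant_effects = TRUE)
  d <- simulate_dataset(cfg)
  tc <- attr(d, "true_coefficients")
  per_subject <- split(tc$b_r, tc$subject_id)
  for (v in per_subject) expect_equal(var(v), 0)
})
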