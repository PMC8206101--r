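test_that("expected value and SD follow the probability-weighted formulas", {
  expect_equal(expected_value(lottery(200, -200, 0.5)), 0)
  expect_equal(expected_value(lottery(50, -50, 0.8)), 30)
  expect_equal(expected_value(lottery(200, 50, 0.75)), 162.5)
  expect_equal(lottery_sd(lottery(200, -200, 0.5)), 200)
  expect_equal(lottery_sd(lottery(50, -50, 0.8)), 40)

  # brute-force enumeration oracle over the p = k/20 grid
  for (k in 1:19) {
    p <- k / 20
    l <- lottery(200, -50, p)
    ev_enum <- sum(c(p, 1 - p) * c(200, -50))
    sd_enum <- sqrt(sum(c(p, 1 - p) * (c(200, -50) - ev_enum)^2))
    expect_equal(expected_value(l), ev_enum, tolerance = 1e-12)
    expect_equal(lottery_sd(l), sd_enum, tolerance = 1e-12)
    expect_true(ev_enum > -50 && ev_enum < 200)
    expect_gt(lottery_sd(l), 0)
  }
})

test_that("invalid lotteries are rejected with the violated invariant named", {
  expect_error(lottery(50, 50, 0.5), "x > y")
  expect_error(lottery(-50, 50, 0.5), "x > y")
  expect_error(lottery(50, -50, 0), "p must lie strictly")
  expect_error(lottery(50, -50, 1.2), "p must lie strictly")
})

test_that("decision variables match the printed orientation and identities", {
  p_id <- trial_pair(c(200, -200, 0.5), c(200, -200, 0.5))
  dv <- decision_variables(p_id)
  expect_equal(unlist(dv[c("dEV", "dSD", "AR")]), c(dEV = 0, dSD = 0, AR = 0))

  dv <- decision_variables(trial_pair(c(200, -200, 0.5), c(50, -50, 0.8)))
  expect_equal(dv$dEV, -30)
  expect_equal(dv$dSD, -160)
  expect_equal(dv$AR, 0)

  dv <- decision_variables(trial_pair(c(200, 50, 0.5), c(50, -50, 0.5)))
  expect_equal(dv$dEV, 125)
  expect_equal(dv$dSD, -25)
  expect_equal(dv$AR, 250)
})

test_that("swapping left and right negates all three decision variables", {
  set.seed(11)
  g <- generate_gamble_list(30)
  for (i in seq_len(nrow(g))) {
    fwd <- decision_variables(trial_pair(c(g$xL[i], g$yL[i], g$pL[i]),
                                         c(g$xR[i], g$yR[i], g$pR[i])))
    rev <- decision_variables(trial_pair(c(g$xR[i], g$yR[i], g$pR[i]),
                                         c(g$xL[i], g$yL[i], g$pL[i])))
    expect_identical(fwd$dEV, -rev$dEV)
    expect_identical(fwd$dSD, -rev$dSD)
    expect_identical(fwd$AR, -rev$AR)
  }
})

test_that("spin draws from the two outcomes at the stated probability", {
  l <- lottery(100, -100, 0.5)
  set.seed(99)
  draws <- spin(l, 10000)
  expect_true(all(draws %in% c(100, -100)))
  freq_x <- mean(draws == 100)
  expect_lt(abs(freq_x - 0.5), 3 * sqrt(0.25 / 10000))
  set.seed(99)
  expect_identical(spin(l, 10000), draws)
})

test_that("experienced regret is counterfactual minus obtained", {
  expect_equal(experienced_regret(-200, 200), 400)
  expect_equal(experienced_regret(50, 50), 0)
  expect_equal(experienced_regret(200, -200), -400)
})

test_that("experienced disappointment contrasts the chosen lottery's branches", {
  ch <- lottery(50, -200, 0.3)
  expect_equal(experienced_disappointment(ch, -200), 250)
  expect_equal(experienced_disappointment(ch, 50), -250)
  expect_equal(experienced_disappointment(ch, 50),
               -experienced_disappointment(ch, -200))
  expect_error(experienced_disappointment(ch, 100), "not an outcome")
})

test_that("points-to-GBP conversion is exact at anchors, interpolated and monotone", {
  expect_identical(points_to_gbp(c(200, 50, -50, -200)), c(2.5, 1.5, 1.0, 0))
  expect_equal(points_to_gbp(0), 1.25)
  expect_equal(points_to_gbp(125), 2.0) # midway between (50,1.5) and (200,2.5)
  grid <- points_to_gbp(seq(-200, 200, by = 1))
  expect_true(all(diff(grid) >= 0))
  expect_error(points_to_gbp(250), "out of range")
  expect_error(points_to_gbp(-201), "out of range")
})
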