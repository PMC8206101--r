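test_that("every 2x2 within-subject F equals the squared paired t", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    tab <- coef_table_2x2(12, means = c(self.absent = 0, partner.absent = 0.3,
                                        self.present = 0.1, partner.present = 0.5))
    an <- rm_anova_2x2(tab)
    wide <- reshape(tab, idvar = c("subject_id", "beneficiary"),
                    timevar = "audience", direction = "wide")
    # audience contrast: per-subject mean(present) - mean(absent)
    diffs <- tapply(tab$value[tab$audience == "present"],
                    tab$subject_id[tab$audience == "present"], mean) -
      tapply(tab$value[tab$audience == "absent"],
             tab$subject_id[tab$audience == "absent"], mean)
    tt <- t.test(diffs)
    expect_equal(an$F[an$effect == "audience"], unname(tt$statistic)^2,
                 tolerance = 1e-10)
    expect_equal(an$p[an$effect == "audience"], tt$p.value, tolerance = 1e-10)
    # interaction contrast: (sp - sa) - (pp - pa) per subject, halved
    g <- function(b, a) tab$value[tab$beneficiary == b & tab$audience == a][
      order(tab$subject_id[tab$beneficiary == b & tab$audience == a])]
    inter <- (g("self", "present") - g("self", "absent") -
                g("partner", "present") + g("partner", "absent")) / 2
    tt_i <- t.test(inter)
    expect_equal(an$F[an$effect == "beneficiary:audience"],
                 unname(tt_i$statistic)^2, tolerance = 1e-10)
    # structural identities
    expect_true(all(an$SSn >= 0) && all(an$SSd >= 0))
    expect_equal(an$F, (an$SSn / an$DFn) / (an$SSd / an$DFd), tolerance = 1e-12)
    expect_equal(an$pes, an$SSn / (an$SSn + an$SSd), tolerance = 1e-12)
    expect_true(all(an$pes >= 0 & an$pes < 1))
    expect_true(all(an$pes_lo <= an$pes_hi))
  }
})

test_that("identical cell values per subject give zero effect sums of squares", {
  set.seed(4)
  base <- rnorm(8)
  tab <- expand.grid(subject_id = 1:8, beneficiary = c("self", "partner"),
                     audience = c("absent", "present"))
  tab$value <- base[tab$subject_id]
  an <- rm_anova_2x2(tab)
  eff <- an[an$effect != "(Intercept)", ]
  expect_identical(eff$SSn, rep(0, 3))
  expect_identical(eff$F, rep(0, 3))
})

test_that("incomplete designs are rejected with the offending cell named", {
  set.seed(5)
  tab <- coef_table_2x2(6)
  expect_error(rm_anova_2x2(tab[-1, ]), "incomplete 2x2")
})

test_that("eta-squared confidence intervals behave at the boundaries and shrink with df", {
  expect_equal(eta_sq_ci(0, 1, 30)[1], 0)
  ci_narrow <- eta_sq_ci(5, 1, 200)
  ci_wide <- eta_sq_ci(5, 1, 20)
  expect_lt(diff(ci_narrow), diff(ci_wide))
  expect_error(eta_sq_ci(-1, 1, 10), "F must be")
  expect_error(eta_sq_ci(5, 0, 10), "degrees of freedom")
  ci <- eta_sq_ci(8.61, 1, 49)
  expect_true(all(ci >= 0 & ci < 1) && ci[1] < ci[2])
})

test_that("post-hoc contrasts reduce to paired t tests and ignore subject order", {
  set.seed(6)
  tab <- coef_table_2x2(10, means = c(self.absent = 0.4, partner.absent = 0,
                                      self.present = 0, partner.present = 0))
  ph <- posthoc_contrast(tab, factor = "beneficiary", fixed_level = "absent")
  sub <- tab[tab$audience == "absent", ]
  tt <- t.test(sub$value[sub$beneficiary == "partner"][order(sub$subject_id[sub$beneficiary == "partner"])],
               sub$value[sub$beneficiary == "self"][order(sub$subject_id[sub$beneficiary == "self"])],
               paired = TRUE)
  expect_equal(ph$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(ph$DFd, 9)
  shuffled <- tab[sample(nrow(tab)), ]
  ph2 <- posthoc_contrast(shuffled, factor = "beneficiary", fixed_level = "absent")
  expect_equal(ph2$F, ph$F, tolerance = 1e-12)
  # identical pairs: F = 0
  tab0 <- tab
  tab0$value <- rep(1:10, 4)
  expect_equal(posthoc_contrast(tab0, factor = "beneficiary",
                                fixed_level = "absent")$F, 0)
  expect_error(posthoc_contrast(tab, factor = "beneficiary",
                                fixed_level = "nowhere"), "not found")
})

test_that("paired contrasts at a known shift match the noncentral-F expectation", {
  delta <- 0.5; sigma <- 1; n <- 20
  lambda <- n * delta^2 / sigma^2
  df2 <- n - 1
  expected_F <- df2 * (1 + lambda) / (df2 - 2)
  set.seed(7)
  Fs <- replicate(400, {
    diffs <- rnorm(n, delta, sigma)
    tt <- t.test(diffs)
    unname(tt$statistic)^2
  })
  expect_lt(abs(mean(Fs) - expected_F) / expected_F, 0.15)
})

test_that("the calibration harnesses are deterministic and monotone in alpha", {
  cfg <- simulation_config(n_subjects = 8, n_trials_per_condition = 8,
                           population = null_population_spec(), seed = 900)
  t1 <- type1_simulation(cfg, n_replicates = 12, alpha = 0.05)
  t1b <- type1_simulation(cfg, n_replicates = 12, alpha = 0.05)
  expect_identical(t1$p_values, t1b$p_values)
  expect_equal(t1$n_effective + t1$n_failed, 12)
  strict <- colMeans(t1$p_values < 0.01, na.rm = TRUE)
  loose <- colMeans(t1$p_values < 0.05, na.rm = TRUE)
  expect_true(all(strict <= loose))
  expect_error(type1_simulation(tiny_config(seed = 1), n_replicates = 2),
               "identical choice coefficients")
})
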