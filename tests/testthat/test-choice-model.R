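test_that("the mixed fit reduces to the pooled logistic MLE at zero variance", {
  cfg <- simulation_config(n_subjects = 20, n_trials_per_condition = 24,
                           population = population_spec(tau_scale = 0),
                           seed = 61)
  d <- simulate_dataset(cfg)
  plain <- choice_model_spec(random = character(0), random_intercept = FALSE)
  fit <- fit_choice_condition(d, "self", "absent", spec = plain)
  sub <- d[d$beneficiary == "self" & d$audience == "absent", ]
  X <- cbind(`(Intercept)` = 1, dEV = sub$dEV, dSD = sub$dSD, AR = sub$AR)
  oracle <- logistic_mle(X, sub$choice)
  expect_equal(unname(fit$beta_hat), unname(oracle$coefficients),
               tolerance = 1e-6)
  # Laplace objective at the optimum beats the null point (beta = 0, theta = 0)
  mixed <- fit_choice_condition(d, "self", "absent")
  expect_gte(mixed$logLik, mixed$n_obs * log(0.5))
})

test_that("per-subject composite coefficients have the documented shape and degeneracies", {
  cfg <- simulation_config(n_subjects = 10, n_trials_per_condition = 16,
                           population = population_spec(tau_scale = 0),
                           seed = 71)
  d <- simulate_dataset(cfg)
  fit <- fit_choice_condition(d, "self", "absent", method = "pirls")
  co <- extract_subject_coefficients(fit)
  expect_equal(nrow(co), 10)
  expect_named(co, c("subject_id", "e", "sd", "r"))
  # tau = 0 in truth: BLUPs shrink essentially to the fixed effects
  expect_lt(max(abs(co$r - fit$beta_hat[["AR"]])), 0.3 * abs(fit$beta_hat[["AR"]]) + 1e-3)
})

test_that("unconverged models refuse coefficient extraction", {
  fake <- structure(list(converged = FALSE, messages = "nope"),
                    class = "fitted_choice_model")
  expect_error(extract_subject_coefficients(fake), "converge")
})

test_that("left/right swap with recoded choice leaves the preferences side-free", {
  # swapping sides negates every gamble statistic AND the coded response,
  # so the preference weights are invariant while the side-bias intercept
  # flips sign
  cfg <- tiny_config(seed = 81, n_subjects = 10, n_trials = 16)
  d <- simulate_dataset(cfg)
  fit <- fit_choice_condition(d, "self", "absent", method = "pirls")
  m <- d
  m[, c("xL", "yL", "pL", "xR", "yR", "pR")] <-
    m[, c("xR", "yR", "pR", "xL", "yL", "pL")]
  m$choice <- 1L - m$choice
  m <- add_decision_variables(m)
  expect_equal(m$dEV, -d$dEV)
  expect_equal(m$AR, -d$AR)
  fit_m <- fit_choice_condition(m, "self", "absent", method = "pirls")
  for (term in c("dEV", "dSD", "AR")) {
    expect_equal(fit_m$beta_hat[[term]], fit$beta_hat[[term]],
                 tolerance = 1e-4)
  }
  expect_equal(fit_m$beta_hat[["(Intercept)"]], -fit$beta_hat[["(Intercept)"]],
               tolerance = 1e-4)
})

test_that("BIC comparison penalises a useless disappointment regressor and rewards a real one", {
  set.seed(91)
  d_null <- manual_choice_data(20, 32, c(b0 = 0, b_e = 0.01, b_sd = -0.002, b_r = 0.01))
  cmp <- compare_models_bic(d_null, method = "pirls")
  expect_gt(cmp$delta_bic, 0)

  set.seed(92)
  d_dis <- manual_choice_data(25, 48, c(b0 = 0, b_e = 0.01, b_sd = 0, b_r = 0,
                                        b_ad = 0.03))
  cmp2 <- compare_models_bic(d_dis, method = "pirls")
  expect_lt(cmp2$delta_bic, 0)

  expect_error(
    compare_models_bic(d_null,
                       base = choice_model_spec(fixed = c("dEV", "dSD", "AR")),
                       augmented = choice_model_spec(fixed = c("dEV", "dSD"))),
    "nest")
})

test_that("the combined dummy-interaction model reports all condition terms", {
  cfg <- tiny_config(seed = 101, n_subjects = 8, n_trials = 12,
                     population = null_population_spec())
  d <- simulate_dataset(cfg)
  fit <- fit_choice_combined(d, method = "pirls")
  expect_s3_class(fit, "fitted_choice_model")
  if (fit$converged) {
    terms <- names(fit$beta_hat)
    expect_true(all(c("dEV:beneficiarypartner", "dEV:audiencepresent",
                      "dSD:beneficiarypartner", "AR:audiencepresent") %in% terms))
    expect_true(all(is.finite(fit$wald_p)))
  } else {
    expect_gt(length(fit$messages), 0)
  }
  # missing cells are a precondition error, not a crash downstream
  expect_error(fit_choice_combined(d[d$audience == "absent", ]), "four design cells")
})

test_that("separation triggers the flagged ridge-stabilised fallback", {
  set.seed(111)
  g <- generate_gamble_list(24)
  d <- do.call(rbind, lapply(1:6, function(s) {
    data.frame(subject_id = s, beneficiary = "self", audience = "absent",
               g, choice = as.integer(g$dEV + 0.1 * g$AR > 0))
  }))
  plain <- choice_model_spec(random = character(0), random_intercept = FALSE)
  expect_warning(fit <- fit_choice_condition(d, spec = plain), "separation")
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$beta_hat)))
})

test_that("thin conditions fail the fitting precondition", {
  cfg <- tiny_config(seed = 121)
  d <- simulate_dataset(cfg)
  few <- d[d$subject_id == 1 & d$beneficiary == "self" & d$audience == "absent", ]
  expect_error(fit_choice_condition(few), ">= 2 subjects")
})
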