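# Shared fixtures: small configurations and hand-built trial tables.

tiny_config <- function(seed, n_subjects = 6L, n_trials = 12L, ...) {
  simulation_config(n_subjects = n_subjects, n_trials_per_condition = n_trials,
                    seed = seed, ...)
}

# A pair with equal EV and SD on both sides but unequal maximum regret:
# left (150, -50, 0.5) and right (100, -150, 0.8) both have EV 50 and
# SD 100, while AR = |{-150} - 150| - |{-50} - 100| = 150 > 0 (the right
# lottery carries the larger possible regret).
regret_only_pair <- function() {
  trial_pair(c(150, -50, 0.5), c(100, -150, 0.8))
}

# Balanced 2x2 within-subject coefficient table from per-cell means plus
# i.i.d. subject noise.
coef_table_2x2 <- function(n, means = c(self.absent = 0, partner.absent = 0,
                                        self.present = 0, partner.present = 0),
                           sd_subject = 1, sd_noise = 1) {
  cells <- expand.grid(beneficiary = c("self", "partner"),
                       audience = c("absent", "present"),
                       stringsAsFactors = FALSE)
  subj_eff <- rnorm(n, 0, sd_subject)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    key <- paste(cells$beneficiary[i], cells$audience[i], sep = ".")
    data.frame(subject_id = seq_len(n),
               beneficiary = cells$beneficiary[i],
               audience = cells$audience[i],
               value = means[[key]] + subj_eff + rnorm(n, 0, sd_noise))
  }))
}

# Manually built choice dataset with known generating coefficients; the
# linear predictor may include the anticipated-disappointment factor dAD.
manual_choice_data <- function(n_subjects, n_trials, beta,
                               beneficiary = "self", audience = "absent") {
  g <- generate_gamble_list(n_trials)
  do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    eta <- beta[["b0"]] + beta[["b_e"]] * g$dEV + beta[["b_sd"]] * g$dSD +
      beta[["b_r"]] * g$AR +
      (if ("b_ad" %in% names(beta)) beta[["b_ad"]] * g$dAD else 0)
    data.frame(subject_id = s, beneficiary = beneficiary, audience = audience,
               g, choice = rbinom(nrow(g), 1L, plogis(eta)))
  }))
}
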