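#' Run the two-stage pipeline once and return the ANOVA for one coefficient
#'
#' Internal worker shared by the calibration harnesses: simulate a
#' dataset, fit the four per-condition choice models, extract per-subject
#' coefficients and run the 2x2 repeated-measures ANOVA on the chosen
#' coefficient.
#' @noRd
.pipeline_anova_once <- function(config, coefficient, method) {
  data <- simulate_dataset(config)
  cells <- expand.grid(beneficiary = c("self", "partner"),
                       audience = c("absent", "present"),
                       stringsAsFactors = FALSE)
  tabs <- lapply(seq_len(nrow(cells)), function(i) {
    fit <- fit_choice_condition(data, cells$beneficiary[i], cells$audience[i],
                                method = method)
    co <- extract_subject_coefficients(fit)
    data.frame(subject_id = co$subject_id,
               beneficiary = cells$beneficiary[i],
               audience = cells$audience[i],
               value = co[[coefficient]])
  })
  rm_anova_2x2(do.call(rbind, tabs))
}

#' Type-I error of the two-stage analysis under a null population
#'
#' Simulates the full pipeline (generate data with identical population
#' coefficients in all four cells, fit the per-condition mixed models,
#' run the stage-2 ANOVA) `n_replicates` times and reports the empirical
#' rejection rate of each ANOVA effect at level `alpha`, with an exact
#' binomial confidence interval. Under the null, per-subject coefficients
#' are exchangeable across cells, so the rate should sit at `alpha`.
#'
#' Replicates whose stage-1 fits fail are excluded and counted.
#'
#' @param config A [simulation_config()] whose population has identical
#'   cells (see [null_population_spec()]); its seed anchors the whole
#'   replicate stream.
#' @param n_replicates Number of simulated experiments.
#' @param alpha Nominal level of the stage-2 tests.
#' @param coefficient Which stage-1 coefficient to analyse
#'   (`"e"`, `"sd"` or `"r"`).
#' @param method Stage-1 estimation method; the default `"pirls"`
#'   (`nAGQ = 0`) keeps large replicate counts tractable.
#' @return List with `rates` (named vector: beneficiary, audience,
#'   interaction), `ci` (binomial 95% CIs per effect), `n_effective`,
#'   `n_failed`, `alpha`, `p_values` (matrix of per-replicate p-values).
#' @export
type1_simulation <- function(config, n_replicates = 500L, alpha = 0.05,
                             coefficient = "r",
                             method = c("pirls", "laplace")) {
  method <- match.arg(method)
  pop <- config$population
  for (col in c("b0", "b_e", "b_sd", "b_r")) {
    if (length(unique(pop[[col]])) != 1L) {
      stop("type1_simulation requires identical choice coefficients in all ",
           "four cells; use null_population_spec()", call. = FALSE)
    }
  }
  effects <- c("beneficiary", "audience", "beneficiary:audience")
  pvals <- matrix(NA_real_, n_replicates, length(effects),
                  dimnames = list(NULL, effects))
  failed <- 0L
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- (config$seed + r) %% .Machine$integer.max
    an <- tryCatch(.pipeline_anova_once(cfg, coefficient, method),
                   error = function(e) NULL)
    if (is.null(an)) { failed <- failed + 1L; next }
    pvals[r, ] <- an$p[match(effects, an$effect)]
  }
  ok <- complete.cases(pvals)
  rates <- colMeans(pvals[ok, , drop = FALSE] < alpha)
  ci <- t(vapply(colnames(pvals), function(e) {
    x <- sum(pvals[ok, e] < alpha)
    as.numeric(stats::binom.test(x, sum(ok))$conf.int)
  }, numeric(2)))
  colnames(ci) <- c("lower", "upper")
  list(rates = rates, ci = ci, n_effective = sum(ok), n_failed = failed,
       alpha = alpha, p_values = pvals)
}

#' Power of the two-stage analysis over a grid of sample sizes
#'
#' Like [type1_simulation()] but with a population encoding a true
#' condition effect (by default the audience offset on the
#' anticipated-regret coefficient of the default [population_spec()]),
#' reporting the empirical rejection rate of the targeted effect for each
#' sample size.
#'
#' @param config A [simulation_config()]; its population must encode a
#'   nonzero effect for `effect` on `coefficient`.
#' @param effect ANOVA effect whose rejection counts as success
#'   (`"audience"`, `"beneficiary"` or `"beneficiary:audience"`).
#' @param n_subjects Integer vector of sample sizes to scan.
#' @param n_replicates Replicates per sample size.
#' @inheritParams type1_simulation
#' @return Data frame with columns `n_subjects`, `power`, `lower`,
#'   `upper` (binomial 95% CI), `n_effective`, `n_failed`.
#' @export
power_simulation <- function(config, effect = "audience", coefficient = "r",
                             n_subjects = c(10L, 25L, 50L),
                             n_replicates = 100L, alpha = 0.05,
                             method = c("pirls", "laplace")) {
  method <- match.arg(method)
  effect <- match.arg(effect, c("beneficiary", "audience", "beneficiary:audience"))
  rows <- lapply(seq_along(n_subjects), function(i) {
    n <- n_subjects[i]
    hits <- logical(0)
    failed <- 0L
    for (r in seq_len(n_replicates)) {
      cfg <- config
      cfg$n_subjects <- as.integer(n)
      cfg$seed <- (config$seed + 10000L * i + r) %% .Machine$integer.max
      an <- tryCatch(.pipeline_anova_once(cfg, coefficient, method),
                     error = function(e) NULL)
      if (is.null(an)) { failed <- failed + 1L; next }
      hits <- c(hits, an$p[an$effect == effect] < alpha)
    }
    ci <- as.numeric(stats::binom.test(sum(hits), length(hits))$conf.int)
    data.frame(n_subjects = n, power = mean(hits),
               lower = ci[1], upper = ci[2],
               n_effective = length(hits), n_failed = failed)
  })
  do.call(rbind, rows)
}
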