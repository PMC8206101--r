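#' Population specification for the generative agent model
#'
#' Defines, for each of the four cells of the 2x2 design (beneficiary x
#' audience), the population-level choice coefficients, the between-subject
#' spread of those coefficients, and the rating-generation model.
#'
#' Choice: a subject's probability of choosing the left lottery is
#' `plogis(b0 + b_e*dEV + b_sd*dSD + b_r*AR)` with subject-level composite
#' coefficients drawn as `beta + N(0, diag(tau^2))` (diagonal covariance:
#' independent random effects, redrawn per condition cell).
#'
#' Rating: `rating = a + b_reg*regret + b_dis*disappointment + N(0, sigma^2)`,
#' with per-subject slopes again drawn around the cell values with spread
#' `rating_tau`, then rounded to integers and clamped to `[-50, 50]`.
#'
#' Defaults place the control cell (self / absent) at
#' `beta = (0, 0.010, -0.002, 0.010)` logit per point, with modest additive
#' condition offsets reproducing the qualitative pattern of the study:
#' an audience raises regret aversion (`b_r`) and damps the expected-value
#' and risk-seeking weights, while choosing for the partner lowers regret
#' aversion and increases risk seeking. Rating coefficients default to the
#' baseline-condition estimates `b_reg = -0.25`, `b_dis = -0.59` rating
#' units per point. Between-subject spreads default to half the magnitude
#' of each population coefficient.
#'
#' @param control Named numeric vector of control-cell (self/absent) choice
#'   coefficients `c(b0, b_e, b_sd, b_r)` in logit units per point.
#' @param audience_offset Additive offset applied to `control` when the
#'   audience is present.
#' @param beneficiary_offset Additive offset applied when choosing for the
#'   partner.
#' @param interaction_offset Extra additive offset in the partner/present
#'   cell only (default zero: purely additive effects).
#' @param rating_control Control-cell rating coefficients
#'   `c(a, b_reg, b_dis)` in rating units (per point for the slopes).
#' @param rating_audience_offset,rating_beneficiary_offset,rating_interaction_offset
#'   Additive offsets for the rating coefficients, analogous to the choice
#'   offsets.
#' @param tau_scale Between-subject SD of each coefficient as a fraction of
#'   its cell-level magnitude (default 0.5).
#' @param rating_sigma Residual SD of the rating noise, rating units.
#' @return An object of class `"population_spec"`: a data frame with one
#'   row per design cell and columns `beneficiary`, `audience`, `b0`,
#'   `b_e`, `b_sd`, `b_r`, `tau0`, `tau_e`, `tau_sd`, `tau_r`, `a`,
#'   `b_reg`, `b_dis`, `tau_a`, `tau_reg`, `tau_dis`, `sigma`.
#' @seealso [null_population_spec()] for a spec with identical cells,
#'   used by [type1_simulation()].
#' @export
population_spec <- function(control = c(b0 = 0, b_e = 0.010, b_sd = -0.002, b_r = 0.010),
                            audience_offset = c(b0 = 0, b_e = -0.003, b_sd = 0.001, b_r = 0.005),
                            beneficiary_offset = c(b0 = 0, b_e = 0.002, b_sd = -0.001, b_r = -0.004),
                            interaction_offset = c(b0 = 0, b_e = 0, b_sd = 0, b_r = 0),
                            rating_control = c(a = 0, b_reg = -0.25, b_dis = -0.59),
                            rating_audience_offset = c(a = 0, b_reg = -0.08, b_dis = 0.10),
                            rating_beneficiary_offset = c(a = 0, b_reg = 0, b_dis = 0.08),
                            rating_interaction_offset = c(a = 0, b_reg = 0, b_dis = -0.08),
                            tau_scale = 0.5,
                            rating_sigma = 12) {
  stopifnot(length(control) == 4L, length(audience_offset) == 4L,
            length(beneficiary_offset) == 4L, length(interaction_offset) == 4L,
            length(rating_control) == 3L, tau_scale >= 0, rating_sigma > 0)
  cells <- expand.grid(beneficiary = c("self", "partner"),
                       audience = c("absent", "present"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    part <- cells$beneficiary[i] == "partner"
    pres <- cells$audience[i] == "present"
    beta <- control +
      (if (pres) audience_offset else 0) +
      (if (part) beneficiary_offset else 0) +
      (if (part && pres) interaction_offset else 0)
    rat <- rating_control +
      (if (pres) rating_audience_offset else 0) +
      (if (part) rating_beneficiary_offset else 0) +
      (if (part && pres) rating_interaction_offset else 0)
    data.frame(beneficiary = cells$beneficiary[i], audience = cells$audience[i],
               b0 = beta[[1]], b_e = beta[[2]], b_sd = beta[[3]], b_r = beta[[4]],
               tau0 = tau_scale * abs(beta[[1]]), tau_e = tau_scale * abs(beta[[2]]),
               tau_sd = tau_scale * abs(beta[[3]]), tau_r = tau_scale * abs(beta[[4]]),
               a = rat[[1]], b_reg = rat[[2]], b_dis = rat[[3]],
               tau_a = tau_scale * abs(rat[[1]]), tau_reg = tau_scale * abs(rat[[2]]),
               tau_dis = tau_scale * abs(rat[[3]]), sigma = rating_sigma)
  })
  spec <- do.call(rbind, rows)
  class(spec) <- c("population_spec", class(spec))
  spec
}

#' Null population: identical coefficients in all four design cells
#'
#' Convenience constructor for type-I-error studies: all condition offsets
#' are zero, so any cross-condition difference in fitted coefficients is
#' pure noise.
#'
#' @inheritParams population_spec
#' @return A [population_spec()] whose four cells are identical.
#' @export
null_population_spec <- function(control = c(b0 = 0, b_e = 0.010, b_sd = -0.002, b_r = 0.010),
                                 rating_control = c(a = 0, b_reg = -0.25, b_dis = -0.59),
                                 tau_scale = 0.5, rating_sigma = 12) {
  zero4 <- c(b0 = 0, b_e = 0, b_sd = 0, b_r = 0)
  zero3 <- c(a = 0, b_reg = 0, b_dis = 0)
  population_spec(control = control, audience_offset = zero4,
                  beneficiary_offset = zero4, interaction_offset = zero4,
                  rating_control = rating_control,
                  rating_audience_offset = zero3,
                  rating_beneficiary_offset = zero3,
                  rating_interaction_offset = zero3,
                  tau_scale = tau_scale, rating_sigma = rating_sigma)
}

.pop_cell <- function(population, beneficiary, audience) {
  row <- population[population$beneficiary == beneficiary &
                      population$audience == audience, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("population_spec has no unique cell for (", beneficiary, ", ",
         audience, ")", call. = FALSE)
  }
  row
}

#' Configuration of a simulated experiment
#'
#' Bundles everything [simulate_dataset()] needs: design size, population
#' parameters, gamble-generation settings and the seed (mandatory, so every
#' dataset is reproducible).
#'
#' @param n_subjects Number of simulated subjects (default 50, the study's
#'   sample size).
#' @param n_trials_per_condition Trials per design cell (default 48, the
#'   study's stimulus-list length).
#' @param population A [population_spec()].
#' @param alphabet Point values lotteries draw outcomes from (default the
#'   task's outcome set).
#' @param probability_grid Allowed win probabilities (default multiples of
#'   0.05 in `[0.2, 0.8]`, giving visibly distinct wheel segments).
#' @param seed Integer RNG seed. Required.
#' @param subject_constant_effects If `TRUE`, a subject's standard-normal
#'   random-effect draws are shared across the four cells (each cell still
#'   scales them by its own `tau`); by default effects are redrawn per cell,
#'   matching the per-condition independent fits of the analysis.
#' @param rating_round,rating_clamp Whether simulated ratings are rounded
#'   to integers and clamped to `[-50, 50]` (both `TRUE` for realism;
#'   switch off for exact-recovery diagnostics).
#' @return An object of class `"simulation_config"` (a named list).
#' @export
simulation_config <- function(n_subjects = 50L, n_trials_per_condition = 48L,
                              population = population_spec(),
                              alphabet = c(-200, -50, 50, 200),
                              probability_grid = seq(0.2, 0.8, by = 0.05),
                              seed,
                              subject_constant_effects = FALSE,
                              rating_round = TRUE, rating_clamp = TRUE) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("simulation_config: an integer seed is required", call. = FALSE)
  }
  if (n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  if (n_trials_per_condition < 4L) stop("n_trials_per_condition must be >= 4", call. = FALSE)
  if (length(unique(alphabet)) < 2L) {
    stop("alphabet must contain at least 2 distinct point values", call. = FALSE)
  }
  if (!all(probability_grid > 0 & probability_grid < 1)) {
    stop("probability_grid must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials_per_condition = as.integer(n_trials_per_condition),
                 population = population,
                 alphabet = sort(unique(alphabet)),
                 probability_grid = probability_grid,
                 seed = as.integer(seed),
                 subject_constant_effects = isTRUE(subject_constant_effects),
                 rating_round = isTRUE(rating_round),
                 rating_clamp = isTRUE(rating_clamp)),
            class = "simulation_config")
}
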