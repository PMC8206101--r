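#' Generate a stimulus list of lottery pairs
#'
#' Draws `n_trials` trial pairs with outcomes from `alphabet` and win
#' probabilities from `probability_grid`, enforcing `x > y` within each
#' lottery and rejecting trials whose two lotteries are identical. The
#' whole list is resampled until the decision variables dEV, dSD and AR
#' each span positive and negative values and no pair of the three
#' regressors is nearly collinear (|r| < 0.95), so downstream regressions
#' are identifiable.
#'
#' Uses R's global RNG stream; call [set.seed()] first for reproducibility.
#'
#' @param n_trials Number of trial pairs.
#' @param alphabet Candidate outcome values, points.
#' @param probability_grid Candidate win probabilities in (0, 1).
#' @param max_attempts Resampling budget before giving up.
#' @return A data frame with columns `trial_index`, `xL`, `yL`, `pL`,
#'   `xR`, `yR`, `pR`, `dEV`, `dSD`, `AR`, `dAD`.
#' @export
generate_gamble_list <- function(n_trials,
                                 alphabet = c(-200, -50, 50, 200),
                                 probability_grid = seq(0.2, 0.8, by = 0.05),
                                 max_attempts = 100L) {
  alphabet <- sort(unique(alphabet))
  if (length(alphabet) < 2L) {
    stop("gamble generation infeasible: need >= 2 distinct outcome values",
         call. = FALSE)
  }
  if (!all(probability_grid > 0 & probability_grid < 1)) {
    stop("probability_grid must lie strictly in (0, 1)", call. = FALSE)
  }
  draw_side <- function(n) {
    # choose two distinct outcomes per lottery; larger one is x
    i <- sample.int(length(alphabet), n, replace = TRUE)
    j <- sample.int(length(alphabet) - 1L, n, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    a <- alphabet[i]; b <- alphabet[j]
    data.frame(x = pmax(a, b), y = pmin(a, b),
               p = sample(probability_grid, n, replace = TRUE))
  }
  for (attempt in seq_len(max_attempts)) {
    L <- draw_side(n_trials)
    R <- draw_side(n_trials)
    same <- L$x == R$x & L$y == R$y & L$p == R$p
    while (any(same)) {
      R[same, ] <- draw_side(sum(same))
      same <- L$x == R$x & L$y == R$y & L$p == R$p
    }
    g <- data.frame(trial_index = seq_len(n_trials),
                    xL = L$x, yL = L$y, pL = L$p,
                    xR = R$x, yR = R$y, pR = R$p)
    g <- add_decision_variables(g)
    spans <- function(v) any(v > 0) && any(v < 0)
    dv <- g[, c("dEV", "dSD", "AR")]
    cors <- suppressWarnings(cor(dv))
    cors[!is.finite(cors)] <- 1  # zero-variance column: treat as degenerate
    if (spans(g$dEV) && spans(g$dSD) && spans(g$AR) &&
        max(abs(cors[upper.tri(cors)])) < 0.95) {
      return(g)
    }
  }
  stop("gamble generation failed: could not satisfy span/collinearity ",
       "constraints in ", max_attempts, " attempts", call. = FALSE)
}

#' Add the decision-variable columns to a trial table
#'
#' Vectorised computation of `dEV`, `dSD`, `AR` and `dAD` (see
#' [decision_variables()]) from the six lottery columns
#' `xL, yL, pL, xR, yR, pR`.
#'
#' @param data Data frame with the six lottery columns.
#' @return `data` with columns `dEV`, `dSD`, `AR`, `dAD` (re)computed.
#' @export
add_decision_variables <- function(data) {
  need <- c("xL", "yL", "pL", "xR", "yR", "pR")
  if (!all(need %in% names(data))) {
    stop("missing lottery columns: ", paste(setdiff(need, names(data)), collapse = ", "),
         call. = FALSE)
  }
  evL <- data$pL * data$xL + (1 - data$pL) * data$yL
  evR <- data$pR * data$xR + (1 - data$pR) * data$yR
  sdL <- sqrt(data$pL * (data$xL - evL)^2 + (1 - data$pL) * (data$yL - evL)^2)
  sdR <- sqrt(data$pR * (data$xR - evR)^2 + (1 - data$pR) * (data$yR - evR)^2)
  data$dEV <- evL - evR
  data$dSD <- sdR - sdL
  data$AR  <- abs(data$yR - data$xL) - abs(data$yL - data$xR)
  data$dAD <- (data$xL - data$yL) - (data$xR - data$yR)
  data
}

#' Simulate one choice from subject-level coefficients
#'
#' Bernoulli draw with `P(left) = plogis(b0 + b_e*dEV + b_sd*dSD + b_r*AR)`
#' where the coefficients are the subject's composite (population +
#' deviation) values. Uses the global RNG stream.
#'
#' @param pair A [trial_pair()] (or list with `left`/`right` lotteries).
#' @param coefs Named numeric vector `c(b0, b_e, b_sd, b_r)`.
#' @return 1 (left) or 0 (right).
#' @export
simulate_choice <- function(pair, coefs) {
  stopifnot(length(coefs) == 4L)
  dv <- decision_variables(pair)
  eta <- coefs[[1]] + coefs[[2]] * dv$dEV + coefs[[3]] * dv$dSD + coefs[[4]] * dv$AR
  rbinom(1L, 1L, plogis(eta))
}

#' Simulate an emotional rating from experienced-emotion factors
#'
#' `rating = a + b_reg*regret + b_dis*disappointment + N(0, sigma^2)`,
#' optionally rounded to the integer cursor positions of the rating axis
#' and clamped to `[-50, 50]`.
#'
#' @param regret,disappointment Experienced-emotion factors, points.
#' @param coefs Named numeric vector `c(a, b_reg, b_dis)`.
#' @param sigma Residual noise SD, rating units.
#' @param round,clamp Apply integer rounding / `[-50, 50]` clamping.
#' @return Numeric vector of ratings. Vectorised over the factors.
#' @export
simulate_rating <- function(regret, disappointment, coefs, sigma = 0,
                            round = TRUE, clamp = TRUE) {
  stopifnot(length(coefs) == 3L, sigma >= 0)
  r <- coefs[[1]] + coefs[[2]] * regret + coefs[[3]] * disappointment
  if (sigma > 0) r <- r + rnorm(length(r), 0, sigma)
  if (round) r <- base::round(r)
  if (clamp) r <- pmin(50, pmax(-50, r))
  r
}

#' Simulate the full 2x2 Wheel-of-Fortune experiment
#'
#' Generates one stimulus list (shared by all subjects and conditions, as
#' in the study), then for every subject and design cell draws subject
#' composite coefficients around the cell's population values, simulates
#' choices, spins both wheels (the task reveals the counterfactual
#' outcome too), computes experienced regret and disappointment, and
#' generates ratings. Fully reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A data frame of class `"wof_dataset"`, one row per trial, with
#'   columns `subject_id`, `beneficiary`, `audience`, `trial_index`, the
#'   six lottery columns, `dEV`, `dSD`, `AR`, `dAD`, `choice` (1 = left),
#'   `obtained`, `counterfactual`, `regret`, `disappointment`, `rating`.
#'   Attributes: `config` (the generating configuration) and
#'   `true_coefficients` (per subject x cell composite truths, for
#'   recovery studies).
#' @examples
#' d <- simulate_dataset(simulation_config(n_subjects = 4,
#'                                         n_trials_per_condition = 8,
#'                                         seed = 1))
#' nrow(d) # 4 subjects x 4 cells x 8 trials
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  gambles <- generate_gamble_list(config$n_trials_per_condition,
                                  alphabet = config$alphabet,
                                  probability_grid = config$probability_grid)
  cells <- expand.grid(beneficiary = c("self", "partner"),
                       audience = c("absent", "present"),
                       stringsAsFactors = FALSE)
  nt <- config$n_trials_per_condition
  out <- vector("list", config$n_subjects * nrow(cells))
  truth <- vector("list", config$n_subjects * nrow(cells))
  k <- 0L
  for (s in seq_len(config$n_subjects)) {
    # shared standard-normal draws when effects are subject-constant
    z_choice_shared <- rnorm(4L)
    z_rating_shared <- rnorm(3L)
    for (ci in seq_len(nrow(cells))) {
      cell <- .pop_cell(config$population, cells$beneficiary[ci], cells$audience[ci])
      z_c <- if (config$subject_constant_effects) z_choice_shared else rnorm(4L)
      z_r <- if (config$subject_constant_effects) z_rating_shared else rnorm(3L)
      coefs <- c(b0 = cell$b0 + z_c[1] * cell$tau0,
                 b_e = cell$b_e + z_c[2] * cell$tau_e,
                 b_sd = cell$b_sd + z_c[3] * cell$tau_sd,
                 b_r = cell$b_r + z_c[4] * cell$tau_r)
      rcoefs <- c(a = cell$a + z_r[1] * cell$tau_a,
                  b_reg = cell$b_reg + z_r[2] * cell$tau_reg,
                  b_dis = cell$b_dis + z_r[3] * cell$tau_dis)
      eta <- coefs[["b0"]] + coefs[["b_e"]] * gambles$dEV +
        coefs[["b_sd"]] * gambles$dSD + coefs[["b_r"]] * gambles$AR
      choice <- rbinom(nt, 1L, plogis(eta))
      outL <- ifelse(runif(nt) < gambles$pL, gambles$xL, gambles$yL)
      outR <- ifelse(runif(nt) < gambles$pR, gambles$xR, gambles$yR)
      obtained <- ifelse(choice == 1L, outL, outR)
      counterfactual <- ifelse(choice == 1L, outR, outL)
      other <- ifelse(choice == 1L,
                      ifelse(obtained == gambles$xL, gambles$yL, gambles$xL),
                      ifelse(obtained == gambles$xR, gambles$yR, gambles$xR))
      regret <- counterfactual - obtained
      disappointment <- other - obtained
      rating <- simulate_rating(regret, disappointment, rcoefs,
                                sigma = cell$sigma,
                                round = config$rating_round,
                                clamp = config$rating_clamp)
      k <- k + 1L
      out[[k]] <- data.frame(subject_id = s,
                             beneficiary = cells$beneficiary[ci],
                             audience = cells$audience[ci],
                             gambles,
                             choice = choice, obtained = obtained,
                             counterfactual = counterfactual,
                             regret = regret, disappointment = disappointment,
                             rating = rating)
      truth[[k]] <- data.frame(subject_id = s,
                               beneficiary = cells$beneficiary[ci],
                               audience = cells$audience[ci],
                               t(coefs), t(rcoefs))
    }
  }
  data <- do.call(rbind, out)
  rownames(data) <- NULL
  attr(data, "config") <- config
  tc <- do.call(rbind, truth)
  rownames(tc) <- NULL
  attr(data, "true_coefficients") <- tc
  class(data) <- c("wof_dataset", class(data))
  data
}
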