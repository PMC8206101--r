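#' Specification of the choice model
#'
#' Fixed regressors default to the three gamble statistics (`dEV`, `dSD`,
#' `AR`) plus an intercept; random regressors default to the same set,
#' with a diagonal (independent) random-effect covariance, mirroring the
#' analysis the study reports. No interactions among the gamble statistics
#' are used. The anticipated-disappointment regressor `dAD` can be added
#' for BIC model comparison.
#'
#' @param fixed Character vector of fixed-effect regressor columns.
#' @param random Character vector of random-slope columns (must be a
#'   subset of `fixed`); `character(0)` fits a plain pooled logistic
#'   regression (zero random-effect variance).
#' @param intercept,random_intercept Include fixed / random intercepts.
#' @return An object of class `"choice_model_spec"`.
#' @export
choice_model_spec <- function(fixed = c("dEV", "dSD", "AR"),
                              random = fixed,
                              intercept = TRUE,
                              random_intercept = intercept) {
  if (!all(random %in% fixed)) {
    stop("random regressors must be a subset of the fixed regressors",
         call. = FALSE)
  }
  if (length(fixed) < 1L) stop("need at least one fixed regressor", call. = FALSE)
  structure(list(fixed = fixed, random = random,
                 intercept = isTRUE(intercept),
                 random_intercept = isTRUE(random_intercept)),
            class = "choice_model_spec")
}

.choice_formula <- function(spec) {
  fixed_part <- paste(c(if (spec$intercept) "1" else "0", spec$fixed),
                      collapse = " + ")
  has_rand <- length(spec$random) > 0L || spec$random_intercept
  if (!has_rand) {
    return(list(formula = as.formula(paste("choice ~", fixed_part)),
                mixed = FALSE))
  }
  rand_part <- paste(c(if (spec$random_intercept) "1" else "0", spec$random),
                     collapse = " + ")
  f <- paste0("choice ~ ", fixed_part, " + (", rand_part, " || subject_id)")
  list(formula = as.formula(f), mixed = TRUE)
}

.subset_condition <- function(data, beneficiary, audience) {
  if (!is.null(beneficiary)) data <- data[data$beneficiary == beneficiary, , drop = FALSE]
  if (!is.null(audience)) data <- data[data$audience == audience, , drop = FALSE]
  data
}

# Drop rows unusable for choice fitting, recording per-reason counts.
.clean_choice_rows <- function(data) {
  dropped <- c(missing_choice = sum(is.na(data$choice)))
  data <- data[!is.na(data$choice), , drop = FALSE]
  if (dropped[["missing_choice"]] > 0) {
    message("dropped ", dropped[["missing_choice"]], " rows with missing choice")
  }
  attr(data, "dropped") <- dropped
  data
}

#' Fit the mixed-effects logistic choice model for one condition
#'
#' Stage 1 of the two-stage analysis: a logistic regression of choice
#' (1 = left) on the gamble statistics with per-subject random slopes
#' (diagonal covariance), fitted by Laplace-approximated maximum
#' likelihood via `lme4::glmer` with the nloptwrap optimizer. Fixed
#' effects are the population-level estimates (BLUE); the per-subject
#' deviations are the posterior modes (BLUP).
#'
#' On a convergence failure the fit is retried from zero variance
#' components with a tightened tolerance; if separation is detected (some
#' fitted logits beyond +-25) the fixed effects are re-estimated with a
#' small ridge penalty and the fit is flagged.
#'
#' @param data A dataset from [simulate_dataset()] or [read_dataset()]
#'   (decision-variable columns are recomputed if absent).
#' @param beneficiary,audience Condition selectors; pass `NULL` to keep
#'   all levels (e.g. when `data` is already one condition).
#' @param spec A [choice_model_spec()].
#' @param method `"laplace"` (default) or `"pirls"`, the fast
#'   `nAGQ = 0` approximation used by the simulation harnesses.
#' @return An object of class `"fitted_choice_model"`: list with
#'   `beta_hat`, `se`, `wald_z`, `wald_p`, `b_hat` (subjects x terms
#'   deviation matrix), `theta_hat` (random-effect SDs), `logLik`, `BIC`,
#'   `n_obs`, `n_subjects`, `converged`, `singular`, `separation`,
#'   `messages`, `spec`, `condition`, and `fit` (the underlying model
#'   object, when a mixed model was fitted).
#' @export
fit_choice_condition <- function(data, beneficiary = NULL, audience = NULL,
                                 spec = choice_model_spec(),
                                 method = c("laplace", "pirls")) {
  method <- match.arg(method)
  d <- .subset_condition(as.data.frame(data), beneficiary, audience)
  if (!all(spec$fixed %in% names(d))) d <- add_decision_variables(d)
  d <- .clean_choice_rows(d)
  if (nrow(d) == 0L) stop("no usable rows in the requested condition", call. = FALSE)
  n_per <- table(d$subject_id)
  if (length(n_per) < 2L || min(n_per) < 8L) {
    stop("need >= 2 subjects with >= 8 trials each in the condition; got ",
         length(n_per), " subject(s), min ", if (length(n_per)) min(n_per) else 0,
         " trials", call. = FALSE)
  }
  d$subject_id <- factor(d$subject_id)
  fm <- .choice_formula(spec)
  msgs <- character()

  if (!fm$mixed) {
    fit <- stats::glm(fm$formula, data = d, family = stats::binomial())
    beta <- coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    separation <- max(abs(stats::predict(fit, type = "link"))) > 25
    if (separation) {
      warning("separation suspected; fixed effects ridge-stabilised",
              call. = FALSE)
      X <- stats::model.matrix(fit)
      ridge <- logistic_mle(X, d$choice, penalty = 1e-3)
      beta[] <- ridge$coefficients
      se[] <- ridge$se
    }
    ll <- as.numeric(logLik(fit))
    k <- length(beta)
    res <- .new_choice_fit(beta, se, b_hat = NULL, theta = numeric(0),
                           ll = ll, k = k, n_obs = nrow(d),
                           n_subjects = nlevels(d$subject_id),
                           converged = fit$converged, singular = FALSE,
                           msgs = msgs, spec = spec,
                           condition = c(beneficiary = beneficiary %||% "all",
                                         audience = audience %||% "all"),
                           fit = fit, dropped = attr(d, "dropped"),
                           separation = separation)
    return(res)
  }

  ctrl <- lme4::glmerControl(optimizer = "nloptwrap", calc.derivs = FALSE)
  nagq <- if (method == "pirls") 0L else 1L
  run <- .collect_fit(lme4::glmer(fm$formula, data = d, family = stats::binomial(),
                                  control = ctrl, nAGQ = nagq))
  if (!is.null(run$error) || !.glmer_ok(run)) {
    msgs <- c(msgs, run$messages,
              "restarting from zero variance components with tightened tolerance")
    m <- length(spec$random) + as.integer(spec$random_intercept)
    ctrl2 <- lme4::glmerControl(optimizer = "nloptwrap", calc.derivs = FALSE,
                                optCtrl = list(xtol_abs = 1e-10, ftol_abs = 1e-10))
    run2 <- .collect_fit(lme4::glmer(fm$formula, data = d,
                                     family = stats::binomial(),
                                     control = ctrl2, nAGQ = nagq,
                                     start = list(theta = rep(0, m))))
    if (is.null(run2$error)) run <- run2 else msgs <- c(msgs, run2$messages)
  }
  if (!is.null(run$error)) {
    stop(structure(class = c("regretwheel_convergence_error", "error", "condition"),
                   list(message = paste0("choice model failed to converge: ",
                                         conditionMessage(run$error), "\n",
                                         paste(msgs, collapse = "\n")),
                        call = sys.call(-1), diagnostics = msgs)))
  }
  fit <- run$fit
  msgs <- c(msgs, run$messages)
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  theta <- lme4::getME(fit, "theta")
  b <- as.matrix(lme4::ranef(fit)$subject_id)
  # separation concerns the fixed effects: ignore subject-level saturation
  eta_fixed <- drop(lme4::getME(fit, "X") %*% beta)
  separation <- max(abs(eta_fixed)) > 25
  if (separation) {
    msgs <- c(msgs, "separation suspected: fixed effects ridge-stabilised")
    warning("separation suspected in condition (",
            paste(c(beneficiary, audience), collapse = ", "),
            "); fixed effects ridge-stabilised", call. = FALSE)
    X <- cbind(`(Intercept)` = if (spec$intercept) rep(1, nrow(d)) else NULL,
               as.matrix(d[, spec$fixed, drop = FALSE]))
    ridge <- logistic_mle(X, d$choice, penalty = 1e-3)
    beta[] <- ridge$coefficients
    se[] <- ridge$se
  }
  ll <- as.numeric(logLik(fit))
  k <- length(beta) + length(theta)
  .new_choice_fit(beta, se, b_hat = b, theta = theta, ll = ll, k = k,
                  n_obs = nrow(d), n_subjects = nlevels(d$subject_id),
                  converged = .glmer_ok(run), singular = lme4::isSingular(fit),
                  msgs = msgs, spec = spec,
                  condition = c(beneficiary = beneficiary %||% "all",
                                audience = audience %||% "all"),
                  fit = fit, dropped = attr(d, "dropped"),
                  separation = separation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run a fitting call capturing warnings/messages without losing the fit.
.collect_fit <- function(expr) {
  msgs <- character()
  err <- NULL
  fit <- withCallingHandlers(
    tryCatch(expr, error = function(e) { err <<- e; NULL }),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  list(fit = fit, messages = msgs, error = err)
}

.glmer_ok <- function(run) {
  if (is.null(run$fit)) return(FALSE)
  conv <- grepl("failed to converge|convergence code", run$messages,
                ignore.case = TRUE)
  length(run$fit@optinfo$conv$lme4) == 0 && !any(conv)
}

.new_choice_fit <- function(beta, se, b_hat, theta, ll, k, n_obs, n_subjects,
                            converged, singular, msgs, spec, condition, fit,
                            dropped, separation = FALSE) {
  z <- beta / se
  structure(list(beta_hat = beta, se = se, wald_z = z,
                 wald_p = 2 * pnorm(-abs(z)),
                 b_hat = b_hat, theta_hat = theta,
                 logLik = ll, BIC = -2 * ll + k * log(n_obs),
                 n_params = k, n_obs = n_obs, n_subjects = n_subjects,
                 converged = converged, singular = singular,
                 separation = separation,
                 messages = msgs, dropped_rows = dropped,
                 spec = spec, condition = condition, fit = fit),
            class = "fitted_choice_model")
}

#' @export
print.fitted_choice_model <- function(x, ...) {
  cat("Mixed-effects logistic choice model (",
      paste(x$condition, collapse = " / "), ")\n", sep = "")
  cat(sprintf("  %d obs, %d subjects; BIC %.1f; converged: %s%s\n",
              x$n_obs, x$n_subjects, x$BIC, x$converged,
              if (x$singular) " (singular)" else ""))
  tab <- data.frame(estimate = x$beta_hat, se = x$se,
                    z = x$wald_z, p = signif(x$wald_p, 3))
  print(tab, digits = 4)
  invisible(x)
}

#' Per-subject composite choice coefficients (fixed effect + BLUP)
#'
#' Returns each subject's estimated preference weights for the three
#' gamble statistics: the fixed effect plus the subject's random-effect
#' deviation (shrunken toward the population value).
#'
#' @param model A converged [fit_choice_condition()] result.
#' @return Data frame with columns `subject_id`, `e` (dEV weight),
#'   `sd` (dSD weight), `r` (AR weight).
#' @export
extract_subject_coefficients <- function(model) {
  stopifnot(inherits(model, "fitted_choice_model"))
  if (!model$converged) {
    stop("model did not converge; see $messages for diagnostics", call. = FALSE)
  }
  terms <- c(e = "dEV", sd = "dSD", r = "AR")
  terms <- terms[terms %in% names(model$beta_hat)]
  if (is.null(model$b_hat)) {
    subj <- seq_len(model$n_subjects)
    out <- data.frame(subject_id = subj)
    for (nm in names(terms)) out[[nm]] <- model$beta_hat[[terms[[nm]]]]
    return(out)
  }
  out <- data.frame(subject_id = rownames(model$b_hat))
  for (nm in names(terms)) {
    dev <- if (terms[[nm]] %in% colnames(model$b_hat)) {
      model$b_hat[, terms[[nm]]]
    } else 0
    out[[nm]] <- model$beta_hat[[terms[[nm]]]] + dev
  }
  rownames(out) <- NULL
  out
}

#' Compare nested choice models by BIC
#'
#' Fits a base and an augmented model (the augmented regressors must nest
#' the base ones) and returns `BIC(augmented) - BIC(base)`. A positive
#' value means the augmentation (e.g. adding the anticipated-disappointment
#' factor `dAD`) is not supported by the data.
#'
#' @inheritParams fit_choice_condition
#' @param base,augmented [choice_model_spec()]s; `augmented` must contain
#'   every fixed regressor of `base`.
#' @return List with `delta_bic`, `bic_base`, `bic_augmented`, and both
#'   fitted models.
#' @export
compare_models_bic <- function(data, beneficiary = NULL, audience = NULL,
                               base = choice_model_spec(),
                               augmented = choice_model_spec(fixed = c("dEV", "dSD", "AR", "dAD")),
                               method = c("laplace", "pirls")) {
  if (!all(base$fixed %in% augmented$fixed)) {
    stop("augmented model must nest the base model", call. = FALSE)
  }
  f_base <- fit_choice_condition(data, beneficiary, audience, base, method)
  f_aug <- fit_choice_condition(data, beneficiary, audience, augmented, method)
  if (!f_base$converged || !f_aug$converged) {
    stop("BIC comparison requires both fits to converge", call. = FALSE)
  }
  list(delta_bic = f_aug$BIC - f_base$BIC,
       bic_base = f_base$BIC, bic_augmented = f_aug$BIC,
       base_fit = f_base, augmented_fit = f_aug)
}

#' Combined choice model with condition-dummy interactions
#'
#' Single model over all four design cells in which condition dummies
#' (beneficiary, audience and their interaction) interact with each gamble
#' statistic. Non-convergence is an expected outcome at this model size
#' and is reported cleanly in the returned object rather than raised.
#'
#' @inheritParams fit_choice_condition
#' @return A `"fitted_choice_model"` whose `converged` flag and `messages`
#'   field report the optimizer outcome; Wald tests cover every
#'   dummy-by-statistic term.
#' @export
fit_choice_combined <- function(data, spec = choice_model_spec(),
                                method = c("laplace", "pirls")) {
  method <- match.arg(method)
  d <- as.data.frame(data)
  cells <- unique(d[, c("beneficiary", "audience")])
  if (nrow(cells) < 4L) {
    stop("combined model needs all four design cells; found ",
         nrow(cells), call. = FALSE)
  }
  if (!all(spec$fixed %in% names(d))) d <- add_decision_variables(d)
  d <- .clean_choice_rows(d)
  d$subject_id <- factor(d$subject_id)
  d$beneficiary <- factor(d$beneficiary, levels = c("self", "partner"))
  d$audience <- factor(d$audience, levels = c("absent", "present"))
  fixed_part <- paste0("(", paste(spec$fixed, collapse = " + "),
                       ") * beneficiary * audience")
  rand_part <- paste(c(if (spec$random_intercept) "1" else "0", spec$random),
                     collapse = " + ")
  f <- as.formula(paste0("choice ~ ", fixed_part,
                         " + (", rand_part, " || subject_id)"))
  ctrl <- lme4::glmerControl(optimizer = "nloptwrap", calc.derivs = FALSE)
  run <- .collect_fit(lme4::glmer(f, data = d, family = stats::binomial(),
                                  control = ctrl,
                                  nAGQ = if (method == "pirls") 0L else 1L))
  if (is.null(run$fit)) {
    return(structure(list(beta_hat = NULL, converged = FALSE,
                          messages = c(run$messages,
                                       conditionMessage(run$error)),
                          spec = spec, condition = c(beneficiary = "all",
                                                     audience = "all")),
                     class = "fitted_choice_model"))
  }
  fit <- run$fit
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  theta <- lme4::getME(fit, "theta")
  ll <- as.numeric(logLik(fit))
  .new_choice_fit(beta, se, b_hat = as.matrix(lme4::ranef(fit)$subject_id),
                  theta = theta, ll = ll, k = length(beta) + length(theta),
                  n_obs = nrow(d), n_subjects = nlevels(d$subject_id),
                  converged = .glmer_ok(run), singular = lme4::isSingular(fit),
                  msgs = run$messages, spec = spec,
                  condition = c(beneficiary = "all", audience = "all"),
                  fit = fit, dropped = attr(d, "dropped"))
}
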