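#' Fit the linear mixed model of emotional ratings for one condition
#'
#' Stage 1 for ratings: trial-wise emotional ratings are regressed on the
#' experienced regret and experienced disappointment factors with
#' per-subject random intercepts and slopes (diagonal covariance,
#' mirroring the choice model), by REML via `lmerTest::lmer`.
#' Degrees of freedom and p-values for the fixed effects use the
#' Satterthwaite approximation, hence the fractional df.
#'
#' Because the two experienced-emotion factors are strongly correlated by
#' construction of the task, the fit also reports their sample
#' correlation in the condition (`factor_correlation`) as a collinearity
#' surface for interpretation.
#'
#' If the full model fails, the fit falls back to a random-intercept-only
#' model, and finally to a pooled linear regression, flagging the
#' fallback. A constant-rating condition is returned as a degenerate fit
#' (zero slopes, zero residual SD) with `degenerate = TRUE`.
#'
#' @param data Dataset with columns `rating`, `regret`, `disappointment`
#'   (recomputed from outcomes if absent), `subject_id`.
#' @param beneficiary,audience Condition selectors (`NULL` = keep all).
#' @param min_rating_fraction Minimum fraction of non-missing ratings
#'   required (default 0.8).
#' @return Object of class `"fitted_rating_model"`: list with `beta_hat`
#'   (`(Intercept)`, `regret`, `disappointment`), `se`, `df`, `p`,
#'   `b_hat`, `theta_hat` (random-effect SDs), `residual_sd`,
#'   `factor_correlation`, `converged`, `degenerate`, `fallback`,
#'   `messages`, `n_obs`, `n_subjects`, `fit`.
#' @export
fit_rating_condition <- function(data, beneficiary = NULL, audience = NULL,
                                 min_rating_fraction = 0.8) {
  d <- .subset_condition(as.data.frame(data), beneficiary, audience)
  if (!"regret" %in% names(d)) {
    if (!all(c("counterfactual", "obtained") %in% names(d))) {
      stop("cannot compute the experienced-regret factor: need counterfactual and obtained columns",
           call. = FALSE)
    }
    d$regret <- d$counterfactual - d$obtained
  }
  if (!"disappointment" %in% names(d)) {
    need <- c("choice", "obtained", "xL", "yL", "xR", "yR")
    if (!all(need %in% names(d))) {
      stop("cannot compute the experienced-disappointment factor: need choice and lottery columns",
           call. = FALSE)
    }
    other <- ifelse(d$choice == 1L,
                    ifelse(d$obtained == d$xL, d$yL, d$xL),
                    ifelse(d$obtained == d$xR, d$yR, d$xR))
    d$disappointment <- other - d$obtained
  }
  n_all <- nrow(d)
  d <- d[!is.na(d$rating), , drop = FALSE]
  if (n_all == 0L || nrow(d) / n_all < min_rating_fraction) {
    stop("fewer than ", round(100 * min_rating_fraction),
         "% of trials in the condition carry a rating", call. = FALSE)
  }
  d$subject_id <- factor(d$subject_id)
  condition <- c(beneficiary = beneficiary %||% "all",
                 audience = audience %||% "all")
  fc <- suppressWarnings(cor(d$regret, d$disappointment))

  if (var(d$rating) == 0) {
    beta <- c(`(Intercept)` = d$rating[1], regret = 0, disappointment = 0)
    return(structure(list(beta_hat = beta,
                          se = setNames(rep(0, 3), names(beta)),
                          df = setNames(rep(NA_real_, 3), names(beta)),
                          p = setNames(rep(NA_real_, 3), names(beta)),
                          b_hat = NULL, theta_hat = numeric(0),
                          residual_sd = 0, factor_correlation = fc,
                          converged = TRUE, degenerate = TRUE,
                          fallback = "constant-response",
                          messages = "constant ratings: degenerate fit",
                          n_obs = nrow(d), n_subjects = nlevels(d$subject_id),
                          condition = condition, fit = NULL),
                     class = "fitted_rating_model"))
  }

  forms <- list(
    full = rating ~ regret + disappointment + (regret + disappointment || subject_id),
    intercept_only = rating ~ regret + disappointment + (1 | subject_id))
  fallback <- NA_character_
  msgs <- character()
  fit <- NULL
  for (nm in names(forms)) {
    run <- .collect_fit(lmerTest::lmer(forms[[nm]], data = d, REML = TRUE))
    msgs <- c(msgs, run$messages)
    if (!is.null(run$fit)) {
      fit <- run$fit
      fallback <- if (nm == "full") NA_character_ else "random-intercept-only"
      if (nm != "full") {
        warning("rating model fell back to random-intercept-only", call. = FALSE)
      }
      break
    }
  }
  if (is.null(fit)) {
    # pooled OLS: unbiased for the fixed effects, no subject deviations
    ols <- stats::lm(rating ~ regret + disappointment, data = d)
    sm <- summary(ols)
    beta <- coef(ols)
    return(structure(list(beta_hat = beta, se = sm$coefficients[, 2],
                          df = setNames(rep(ols$df.residual, 3), names(beta)),
                          p = sm$coefficients[, 4],
                          b_hat = NULL, theta_hat = numeric(0),
                          residual_sd = sm$sigma, factor_correlation = fc,
                          converged = TRUE, degenerate = FALSE,
                          fallback = "pooled-ols", messages = msgs,
                          n_obs = nrow(d), n_subjects = nlevels(d$subject_id),
                          condition = condition, fit = ols),
                     class = "fitted_rating_model"))
  }
  sm <- suppressWarnings(summary(fit))$coefficients
  beta <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  theta <- vc$sdcor[is.na(vc$var2) & vc$grp != "Residual"]
  names(theta) <- vc$var1[is.na(vc$var2) & vc$grp != "Residual"]
  b <- as.matrix(lme4::ranef(fit)$subject_id)
  structure(list(beta_hat = beta, se = sm[, "Std. Error"],
                 df = sm[, "df"], p = sm[, "Pr(>|t|)"],
                 b_hat = b, theta_hat = theta,
                 residual_sd = stats::sigma(fit), factor_correlation = fc,
                 converged = TRUE, degenerate = FALSE, fallback = fallback,
                 messages = msgs, n_obs = nrow(d),
                 n_subjects = nlevels(d$subject_id),
                 condition = condition, fit = fit),
            class = "fitted_rating_model")
}

#' @export
print.fitted_rating_model <- function(x, ...) {
  cat("Linear mixed rating model (", paste(x$condition, collapse = " / "),
      ")\n", sep = "")
  cat(sprintf("  %d obs, %d subjects; residual SD %.2f; corr(regret, disappointment) = %.2f\n",
              x$n_obs, x$n_subjects, x$residual_sd, x$factor_correlation))
  if (!is.na(x$fallback %||% NA)) cat("  fallback:", x$fallback, "\n")
  print(data.frame(estimate = x$beta_hat, se = x$se, df = round(x$df, 1),
                   p = signif(x$p, 3)), digits = 4)
  invisible(x)
}

#' Per-subject composite rating coefficients
#'
#' One row per subject with the composite (fixed + BLUP) sensitivities of
#' the emotional rating to experienced regret and disappointment; the
#' stage-2 input for the rating-side ANOVAs.
#'
#' @param model A converged [fit_rating_condition()] result.
#' @return Data frame with columns `subject_id`, `b_reg`, `b_dis`.
#' @export
extract_rating_coefficients <- function(model) {
  stopifnot(inherits(model, "fitted_rating_model"))
  if (!isTRUE(model$converged)) {
    stop("rating model did not converge; see $messages", call. = FALSE)
  }
  if (is.null(model$b_hat)) {
    subj <- seq_len(model$n_subjects)
    return(data.frame(subject_id = subj,
                      b_reg = model$beta_hat[["regret"]],
                      b_dis = model$beta_hat[["disappointment"]]))
  }
  dev_reg <- if ("regret" %in% colnames(model$b_hat)) model$b_hat[, "regret"] else 0
  dev_dis <- if ("disappointment" %in% colnames(model$b_hat)) {
    model$b_hat[, "disappointment"]
  } else 0
  out <- data.frame(subject_id = rownames(model$b_hat),
                    b_reg = model$beta_hat[["regret"]] + dev_reg,
                    b_dis = model$beta_hat[["disappointment"]] + dev_dis)
  rownames(out) <- NULL
  out
}
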