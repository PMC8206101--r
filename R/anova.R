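#' Two-way repeated-measures ANOVA on a 2x2 within-subject design
#'
#' Stage 2 of the two-stage analysis: each subject contributes one value
#' per design cell (a stage-1 coefficient), and the beneficiary and
#' audience effects are tested with the classical within-subject
#' decomposition. With two levels per factor every F statistic equals the
#' squared paired t of the corresponding within-subject contrast, and no
#' sphericity correction is needed. Effect size is partial eta-squared,
#' `SSn / (SSn + SSd)`, with a confidence interval from noncentral-F
#' inversion ([eta_sq_ci()]).
#'
#' The `(Intercept)` row tests the grand mean against zero (its error term
#' is the between-subject variation of subject means).
#'
#' @param table Data frame with columns `subject_id`, `beneficiary`,
#'   `audience` and the value column; every subject must appear exactly
#'   once in each of the four cells.
#' @param value Name of the value column (default `"value"`).
#' @param ci_level Confidence level for the eta-squared intervals.
#' @return Object of class `"rm_anova"`: a data frame with rows
#'   `(Intercept)`, `beneficiary`, `audience`, `beneficiary:audience` and
#'   columns `effect`, `DFn`, `DFd`, `SSn`, `SSd`, `F`, `p`, `pes`
#'   (partial eta-squared), `pes_lo`, `pes_hi`.
#' @examples
#' tab <- expand.grid(subject_id = 1:8, beneficiary = c("self", "partner"),
#'                    audience = c("absent", "present"))
#' tab$value <- rnorm(nrow(tab))
#' rm_anova_2x2(tab)
#' @export
rm_anova_2x2 <- function(table, value = "value", ci_level = 0.95) {
  d <- as.data.frame(table)
  need <- c("subject_id", "beneficiary", "audience", value)
  if (!all(need %in% names(d))) {
    stop("table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  d$subject_id <- factor(d$subject_id)
  d$beneficiary <- factor(d$beneficiary)
  d$audience <- factor(d$audience)
  counts <- base::table(d$subject_id, d$beneficiary, d$audience)
  if (nlevels(d$beneficiary) != 2L || nlevels(d$audience) != 2L) {
    stop("both factors must have exactly two levels", call. = FALSE)
  }
  if (any(counts != 1L)) {
    miss <- which(counts != 1L, arr.ind = TRUE)
    stop("incomplete 2x2 within design; first offending (subject, beneficiary, audience): ",
         paste(dimnames(counts)[[1]][miss[1, 1]], dimnames(counts)[[2]][miss[1, 2]],
               dimnames(counts)[[3]][miss[1, 3]], collapse = ", "), call. = FALSE)
  }
  n <- nlevels(d$subject_id)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  d$.value <- d[[value]]

  fit <- aov(.value ~ beneficiary * audience +
               Error(subject_id / (beneficiary * audience)), data = d)
  sm <- summary(fit)
  pick <- function(effect) {
    stratum <- sm[[paste0("Error: subject_id:", effect)]][[1]]
    i <- match(sub(":", ":", effect), trimws(rownames(stratum)))
    c(SSn = stratum[i, "Sum Sq"], SSd = stratum[nrow(stratum), "Sum Sq"],
      DFn = stratum[i, "Df"], DFd = stratum[nrow(stratum), "Df"])
  }
  eff <- list(beneficiary = pick("beneficiary"),
              audience = pick("audience"),
              `beneficiary:audience` = pick("beneficiary:audience"))

  # grand-mean (intercept) test against the between-subject stratum
  m_i <- tapply(d$.value, d$subject_id, mean)
  gm <- mean(d$.value)
  eff <- c(list(`(Intercept)` = c(SSn = 4 * n * gm^2,
                                  SSd = 4 * sum((m_i - gm)^2),
                                  DFn = 1, DFd = n - 1)), eff)

  # snap floating-point residue to exact zero so degenerate inputs
  # (identical cell values) give F = 0 rather than a ratio of noise
  tol <- 1e-12 * (sum(d$.value^2) + .Machine$double.xmin)
  rows <- lapply(names(eff), function(nm) {
    e <- eff[[nm]]
    if (e[["SSn"]] < tol) e[["SSn"]] <- 0
    if (e[["SSd"]] < tol) e[["SSd"]] <- 0
    Fv <- if (e[["SSn"]] == 0) 0 else
      (e[["SSn"]] / e[["DFn"]]) / (e[["SSd"]] / e[["DFd"]])
    p <- if (is.finite(Fv)) pf(Fv, e[["DFn"]], e[["DFd"]], lower.tail = FALSE)
      else 0
    pes <- if (e[["SSn"]] + e[["SSd"]] == 0) 0 else
      e[["SSn"]] / (e[["SSn"]] + e[["SSd"]])
    ci <- if (is.finite(Fv)) eta_sq_ci(Fv, e[["DFn"]], e[["DFd"]], level = ci_level)
      else c(NA_real_, NA_real_)
    data.frame(effect = nm, DFn = e[["DFn"]], DFd = e[["DFd"]],
               SSn = e[["SSn"]], SSd = e[["SSd"]], F = Fv, p = p,
               pes = pes, pes_lo = ci[1], pes_hi = ci[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rm_anova", class(out))
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (2x2 within-subject)\n")
  y <- as.data.frame(x)
  y$`eta^2 [95% CI]` <- sprintf("%.3f [%.3f, %.3f]", y$pes, y$pes_lo, y$pes_hi)
  print(y[, c("effect", "DFn", "DFd", "SSn", "SSd", "F", "p", "eta^2 [95% CI]")],
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' Confidence interval for partial eta-squared by noncentral-F inversion
#'
#' Inverts the noncentral-F distribution at the observed F: the interval
#' bounds are the noncentrality parameters whose distributions place the
#' observed F at the upper / lower tail quantile, mapped to the partial
#' eta-squared scale via `lambda / (lambda + DFn + DFd + 1)`. The lower
#' bound is floored at 0.
#'
#' @param F Observed F statistic (>= 0).
#' @param DFn,DFd Numerator and denominator degrees of freedom.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Numeric vector `c(lower, upper)` on the partial eta-squared
#'   scale.
#' @examples
#' eta_sq_ci(8.61, 1, 49) # about [0.015, 0.326]
#' @export
eta_sq_ci <- function(F, DFn, DFd, level = 0.95) {
  if (!(is.finite(F) && F >= 0)) stop("F must be finite and >= 0", call. = FALSE)
  if (!(DFn >= 1 && DFd >= 1)) stop("invalid degrees of freedom", call. = FALSE)
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)", call. = FALSE)
  a <- (1 - level) / 2
  # pf() warns about reduced precision at extreme noncentralities; the
  # residual error there is far below the interval's resolution
  pnc <- function(q, ncp) suppressWarnings(pf(q, DFn, DFd, ncp = ncp))
  ncp_for <- function(prob) {
    # smallest lambda with pf(F, DFn, DFd, lambda) = prob
    if (pnc(F, 0) <= prob) return(0)
    hi <- 1
    while (pnc(F, hi) > prob) hi <- hi * 2
    uniroot(function(l) pnc(F, l) - prob, c(0, hi), tol = 1e-9)$root
  }
  lo <- ncp_for(1 - a)
  hi <- ncp_for(a)
  scale <- function(l) l / (l + DFn + DFd + 1)
  c(scale(lo), scale(hi))
}

#' Post-hoc paired contrast within one level of the other factor
#'
#' Paired comparison of the two levels of `factor` restricted to trials
#' where the other factor sits at `fixed_level`; reported as
#' `F = t^2` with `DFn = 1`, `DFd = n - 1`, and partial eta-squared
#' `t^2 / (t^2 + df)`.
#'
#' @param table As in [rm_anova_2x2()].
#' @param factor `"beneficiary"` or `"audience"`: the factor to contrast.
#' @param fixed_level Level at which the *other* factor is held.
#' @param value Name of the value column.
#' @return List with `F`, `DFn`, `DFd`, `p`, `pes`, `pes_ci`,
#'   `mean_difference`.
#' @export
posthoc_contrast <- function(table, factor = c("beneficiary", "audience"),
                             fixed_level, value = "value") {
  factor <- match.arg(factor)
  other <- setdiff(c("beneficiary", "audience"), factor)
  d <- as.data.frame(table)
  if (!fixed_level %in% d[[other]]) {
    stop("level '", fixed_level, "' not found in factor '", other, "'",
         call. = FALSE)
  }
  d <- d[d[[other]] == fixed_level, , drop = FALSE]
  levels_f <- sort(unique(d[[factor]]))
  if (length(levels_f) != 2L) stop("contrast factor must have two levels", call. = FALSE)
  wide <- merge(d[d[[factor]] == levels_f[1], c("subject_id", value)],
                d[d[[factor]] == levels_f[2], c("subject_id", value)],
                by = "subject_id", suffixes = c(".1", ".2"))
  diff <- wide[[paste0(value, ".1")]] - wide[[paste0(value, ".2")]]
  n <- length(diff)
  if (n < 3L) stop("need at least 3 paired subjects", call. = FALSE)
  if (sd(diff) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- t.test(diff)
  }
  Fv <- unname(tt$statistic)^2
  list(F = Fv, DFn = 1L, DFd = n - 1L, p = tt$p.value,
       pes = Fv / (Fv + (n - 1)),
       pes_ci = eta_sq_ci(Fv, 1, n - 1),
       mean_difference = mean(diff))
}
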