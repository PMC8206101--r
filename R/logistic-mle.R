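#' Plain pooled logistic regression by Newton-Raphson
#'
#' A small, self-contained maximum-likelihood logistic fitter used as an
#' independent reference for the mixed-model fits: in the limit of zero
#' random-effect variance the mixed-effects fixed effects must coincide
#' with this pooled MLE. An optional ridge penalty (`penalty/2 * ||beta||^2`
#' on the log-likelihood scale) stabilises separable data.
#'
#' @param X Numeric design matrix (include the intercept column yourself).
#' @param y 0/1 response vector.
#' @param penalty Non-negative ridge penalty (0 = plain MLE).
#' @param tol Convergence tolerance on the step's infinity norm.
#' @param max_iter Iteration budget.
#' @return List with `coefficients`, `se` (from the observed information),
#'   `logLik`, `converged`, `iterations`.
#' @export
logistic_mle <- function(X, y, penalty = 0, tol = 1e-10, max_iter = 100L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)), penalty >= 0)
  beta <- rep(0, ncol(X))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- p * (1 - p)
    grad <- drop(crossprod(X, y - p)) - penalty * beta
    hess <- crossprod(X * w, X) + diag(penalty, ncol(X))
    step <- solve(hess, grad)
    # halve overshooting steps so separation cannot blow the iteration up
    while (max(abs(step)) > 10) step <- step / 2
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - log1p(exp(eta)))
  w <- plogis(eta) * (1 - plogis(eta))
  se <- sqrt(diag(solve(crossprod(X * w, X) + diag(penalty, ncol(X)))))
  list(coefficients = setNames(drop(beta), colnames(X)),
       se = setNames(se, colnames(X)),
       logLik = ll, converged = converged, iterations = it)
}
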