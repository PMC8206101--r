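#' Construct a lottery (one wheel of the Wheel-of-Fortune task)
#'
#' A lottery has two point outcomes, a better one `x` and a worse one `y`
#' (`x > y`), and a probability `p` of landing on `x`. Both outcomes may be
#' gains or losses.
#'
#' @param x Better outcome, in points.
#' @param y Worse outcome, in points. Must satisfy `x > y`.
#' @param p Probability of obtaining `x`, strictly inside (0, 1).
#' @return An object of class `"lottery"`: a named list with elements
#'   `x`, `y`, `p`.
#' @examples
#' lottery(200, -50, 0.25)
#' @export
lottery <- function(x, y, p) {
  if (!is.numeric(x) || !is.numeric(y) || !is.numeric(p) ||
      length(x) != 1L || length(y) != 1L || length(p) != 1L ||
      !is.finite(x) || !is.finite(y) || !is.finite(p)) {
    stop("lottery: x, y and p must be finite scalars", call. = FALSE)
  }
  if (!(x > y)) {
    stop("invalid lottery: the better outcome must exceed the worse one (x > y), got x = ",
         x, ", y = ", y, call. = FALSE)
  }
  if (!(p > 0 && p < 1)) {
    stop("invalid lottery: p must lie strictly in (0, 1), got p = ", p,
         call. = FALSE)
  }
  structure(list(x = x, y = y, p = p), class = "lottery")
}

#' @export
print.lottery <- function(x, ...) {
  cat(sprintf("<lottery> %g points with p = %g, else %g points\n",
              x$x, x$p, x$y))
  invisible(x)
}

as_lottery <- function(l) {
  if (inherits(l, "lottery")) return(l)
  if (is.numeric(l) && length(l) == 3L) return(lottery(l[[1]], l[[2]], l[[3]]))
  if (is.list(l) && all(c("x", "y", "p") %in% names(l))) {
    return(lottery(l$x, l$y, l$p))
  }
  stop("cannot interpret input as a lottery", call. = FALSE)
}

#' Expected value of a lottery
#'
#' `EV = p*x + (1 - p)*y`, in points. Always strictly between the two
#' outcomes for a valid lottery.
#'
#' @param l A [lottery()], or a numeric vector `c(x, y, p)`.
#' @return Expected value in points.
#' @examples
#' expected_value(lottery(50, -50, 0.8)) # 30
#' @export
expected_value <- function(l) {
  l <- as_lottery(l)
  l$p * l$x + (1 - l$p) * l$y
}

#' Probability-weighted standard deviation (risk) of a lottery
#'
#' `SD = sqrt(p*(x - EV)^2 + (1 - p)*(y - EV)^2)`, in points; strictly
#' positive for any valid lottery since `x > y` and `0 < p < 1`.
#'
#' @inheritParams expected_value
#' @return Standard deviation in points.
#' @examples
#' lottery_sd(lottery(200, -200, 0.5)) # 200
#' @export
lottery_sd <- function(l) {
  l <- as_lottery(l)
  ev <- expected_value(l)
  sqrt(l$p * (l$x - ev)^2 + (1 - l$p) * (l$y - ev)^2)
}

#' Construct a trial: two lotteries under a social condition
#'
#' @param left,right [lottery()] objects (or `c(x, y, p)` vectors).
#' @param beneficiary `"self"` or `"partner"`: who the outcome accrues to.
#' @param audience `"absent"` or `"present"`: whether the partner watches.
#' @param trial_index Positive integer position in the stimulus list.
#' @return An object of class `"trial_pair"`.
#' @export
trial_pair <- function(left, right, beneficiary = "self", audience = "absent",
                       trial_index = 1L) {
  beneficiary <- match.arg(beneficiary, c("self", "partner"))
  audience <- match.arg(audience, c("absent", "present"))
  if (!(is.numeric(trial_index) && length(trial_index) == 1L && trial_index >= 1)) {
    stop("trial_index must be a positive integer", call. = FALSE)
  }
  structure(list(left = as_lottery(left), right = as_lottery(right),
                 beneficiary = beneficiary, audience = audience,
                 trial_index = as.integer(trial_index)),
            class = "trial_pair")
}

#' Decision variables of a trial: dEV, dSD and anticipated regret
#'
#' The three gamble statistics that drive choice:
#' * `dEV = EV_L - EV_R`, the expected-value advantage of the left lottery;
#' * `dSD = SD_R - SD_L`, the risk difference (note the reversed
#'   orientation relative to `dEV`);
#' * `AR  = |y_R - x_L| - |y_L - x_R|`, the anticipated-regret factor:
#'   the difference in maximum possible experienced regret between the
#'   two options.
#'
#' Also returned is `dAD = (x_L - y_L) - (x_R - y_R)`, the difference in
#' maximum within-lottery disappointment, used only for model comparison.
#'
#' @param pair A [trial_pair()], or a list with elements `left`, `right`.
#' @return A named list with elements `dEV`, `dSD`, `AR`, `dAD`.
#' @examples
#' decision_variables(trial_pair(c(200, 50, 0.5), c(50, -50, 0.5)))
#' @export
decision_variables <- function(pair) {
  L <- as_lottery(pair$left)
  R <- as_lottery(pair$right)
  list(
    dEV = expected_value(L) - expected_value(R),
    dSD = lottery_sd(R) - lottery_sd(L),
    AR  = abs(R$y - L$x) - abs(L$y - R$x),
    dAD = (L$x - L$y) - (R$x - R$y)
  )
}

#' Spin a lottery wheel
#'
#' Draws outcomes from a lottery using R's global random number stream;
#' seed with [set.seed()] for reproducibility.
#'
#' @inheritParams expected_value
#' @param n Number of independent spins.
#' @return Vector of `n` outcomes, each `x` (with probability `p`) or `y`.
#' @export
spin <- function(l, n = 1L) {
  l <- as_lottery(l)
  ifelse(runif(n) < l$p, l$x, l$y)
}

#' Experienced regret factor
#'
#' Post-outcome regret: the realised outcome of the unchosen lottery minus
#' the realised outcome of the chosen one. Positive values are regret
#' ("the other wheel did better"), negative values rejoicing.
#'
#' @param obtained Realised outcome of the chosen lottery, points.
#' @param counterfactual Realised outcome of the unchosen lottery, points.
#' @return `counterfactual - obtained`, in points. Vectorised.
#' @examples
#' experienced_regret(-200, 200) # 400
#' @export
experienced_regret <- function(obtained, counterfactual) {
  stopifnot(is.numeric(obtained), is.numeric(counterfactual),
            all(is.finite(obtained)), all(is.finite(counterfactual)))
  counterfactual - obtained
}

#' Experienced disappointment factor
#'
#' Within-lottery letdown: the unobtained outcome of the chosen lottery
#' minus the obtained one. Positive when the wheel landed on the worse
#' branch.
#'
#' @param chosen The chosen [lottery()].
#' @param obtained The realised outcome; must be one of the chosen
#'   lottery's two outcomes.
#' @return `(other outcome) - obtained`, in points.
#' @examples
#' experienced_disappointment(lottery(50, -200, 0.5), -200) # 250
#' @export
experienced_disappointment <- function(chosen, obtained) {
  chosen <- as_lottery(chosen)
  if (!(length(obtained) == 1L && obtained %in% c(chosen$x, chosen$y))) {
    stop("obtained (", obtained, ") is not an outcome of the chosen lottery {",
         chosen$x, ", ", chosen$y, "}", call. = FALSE)
  }
  if (obtained == chosen$x) chosen$y - obtained else chosen$x - obtained
}

# Anchor points of the points -> GBP bonus conversion.
.gbp_anchors <- list(points = c(-200, -50, 50, 200),
                     gbp    = c(0, 1.0, 1.5, 2.5))

#' Convert task points to bonus payment (GBP)
#'
#' The task pays a bonus by converting trial outcomes to money through
#' four anchor points: 200, 50, -50 and -200 points map to 2.5, 1.5, 1.0
#' and 0 GBP. The four anchors are not collinear, so between anchors the
#' conversion is piecewise-linear: exact at every anchor and monotone
#' non-decreasing throughout.
#'
#' @param points Numeric vector of point values in `[-200, 200]`.
#' @return Bonus in GBP, same length as `points`.
#' @examples
#' points_to_gbp(c(-200, -50, 50, 200)) # 0.0 1.0 1.5 2.5
#' @export
points_to_gbp <- function(points) {
  stopifnot(is.numeric(points), all(is.finite(points)))
  if (any(points < -200 | points > 200)) {
    stop("points out of range: the conversion is defined on [-200, 200]",
         call. = FALSE)
  }
  stats::approx(.gbp_anchors$points, .gbp_anchors$gbp, xout = points,
                method = "linear", ties = "ordered")$y
}
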