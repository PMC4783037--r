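#' Certainty-equivalent points
#'
#' Risk attitude is elicited at the root objective with 50-50 lotteries:
#' the certainty equivalent x_p is the sure overall value the expert judges
#' equivalent to a lottery whose expected value is p. The bisection variant
#' asks for x_0.5 first (lottery between worst and best state), then x_0.25
#' and x_0.75. A risk-neutral expert answers x_p = p; x_p < p signals risk
#' aversion at that state, x_p > p risk proneness.
#'
#' @param x25,x50,x75 Certainty equivalents in (0, 1), strictly increasing.
#' @param expert Optional expert id.
#' @return A `riv_ce_points`.
#' @export
ce_points <- function(x25, x50, x75, expert = NA_character_) {
  for (x in c(x25, x50, x75)) {
    if (!is_number(x) || x <= 0 || x >= 1) {
      stop_riverval("certainty equivalents must lie strictly inside (0, 1)")
    }
  }
  if (!(x25 < x50 && x50 < x75)) {
    stop_riverval("inconsistent elicitation: CE points must be strictly increasing")
  }
  structure(list(x25 = x25, x50 = x50, x75 = x75, expert = expert),
            class = "riv_ce_points")
}

#' Utility function from certainty equivalents
#'
#' Interpolates monotonically (piecewise linearly) through the five anchors
#' (0, 0), (x_0.25, 0.25), (x_0.5, 0.5), (x_0.75, 0.75), (1, 1), so that
#' u(x_p) = p exactly for each elicited p. Extra elicited pairs (consistency
#' probes) may be supplied and are checked for monotonicity.
#'
#' @param ce A [ce_points()] object.
#' @param extra_points Optional data frame `value`, `utility` of additional
#'   anchors from consistency checks.
#' @return A `riv_utility_function` with a `points` data frame
#'   (`value`, `utility`).
#' @examples
#' u <- utility_from_ce(ce_points(0.15, 0.40, 0.65))
#' evaluate_utility(u, 0.5)  # 0.6
#' @export
utility_from_ce <- function(ce, extra_points = NULL) {
  stopifnot(inherits(ce, "riv_ce_points"))
  pts <- data.frame(value = c(0, ce$x25, ce$x50, ce$x75, 1),
                    utility = c(0, 0.25, 0.5, 0.75, 1))
  if (!is.null(extra_points)) {
    extra_points <- as.data.frame(extra_points)
    stopifnot(all(c("value", "utility") %in% names(extra_points)))
    pts <- rbind(pts, extra_points[c("value", "utility")])
  }
  pts <- pts[order(pts$value), , drop = FALSE]
  if (anyDuplicated(pts$value) || any(diff(pts$utility) < 0)) {
    stop_riverval("inconsistent elicitation: utility anchors are not monotone")
  }
  structure(list(points = pts, expert = ce$expert), class = "riv_utility_function")
}

#' @export
print.riv_utility_function <- function(x, ...) {
  cat("<utility function> ", nrow(x$points), " anchors",
      if (!is.na(x$expert %||% NA)) paste0(", expert ", x$expert), "\n", sep = "")
  invisible(x)
}

#' Evaluate a utility function
#'
#' @param u A `riv_utility_function`.
#' @param value Overall value(s) in \[0, 1\].
#' @return Utility in \[0, 1\] (piecewise-linear interpolation through the
#'   anchors).
#' @export
evaluate_utility <- function(u, value) {
  stopifnot(inherits(u, "riv_utility_function"))
  if (any(value < 0 | value > 1)) stop_riverval("value must lie in [0, 1]")
  stats::approx(u$points$value, u$points$utility, xout = value,
                ties = "ordered")$y
}

#' Invert a utility function
#'
#' Returns the value whose utility is `utility` — for u(x_p) = p this
#' recovers the certainty equivalent x_p, supporting consistency checks and
#' parameter-recovery tests.
#'
#' @param u A `riv_utility_function`.
#' @param utility Utility level(s) in \[0, 1\].
#' @return Value(s) in \[0, 1\].
#' @export
invert_utility <- function(u, utility) {
  stopifnot(inherits(u, "riv_utility_function"))
  if (any(utility < 0 | utility > 1)) stop_riverval("utility must lie in [0, 1]")
  stats::approx(u$points$utility, u$points$value, xout = utility,
                ties = "ordered")$y
}

#' Classify risk attitude at a probe value
#'
#' A utility curve above the diagonal at `at` (u(at) > at) means the sure
#' state is valued more than the corresponding lottery — risk aversion; below
#' the diagonal, risk proneness. Equivalently, the certainty equivalent lies
#' below/above the lottery's expected value. Attitudes within `tol` of the
#' diagonal are classified neutral; published attitudes are reported as
#' "slightly" averse or prone without a numeric threshold, so the default
#' tolerance is a small 0.02 on the value scale.
#'
#' @param u A `riv_utility_function`.
#' @param at Probe value in (0, 1).
#' @param tol Neutrality tolerance on the value scale.
#' @return `"averse"`, `"neutral"` or `"prone"`.
#' @export
classify_risk <- function(u, at = 0.5, tol = 0.02) {
  stopifnot(inherits(u, "riv_utility_function"))
  if (any(at <= 0 | at >= 1)) stop_riverval("probe value must lie in (0, 1)")
  ux <- evaluate_utility(u, at)
  ifelse(ux > at + tol, "averse", ifelse(ux < at - tol, "prone", "neutral"))
}

#' Apply risk attitude to a root value
#'
#' Transforms the overall (root) value to a utility. With `u = NULL` the
#' identity is used — the risk-neutral simplification.
#'
#' @param root_value Overall value in \[0, 1\].
#' @param u A `riv_utility_function`, or `NULL` for risk neutrality.
#' @return The root utility.
#' @export
apply_risk <- function(root_value, u = NULL) {
  if (!is.numeric(root_value) || any(root_value < 0 | root_value > 1)) {
    stop_riverval("root value must lie in [0, 1]")
  }
  if (is.null(u)) return(root_value)
  evaluate_utility(u, root_value)
}

#' Exponential-utility diagnostic fit
#'
#' Fits the one-parameter exponential utility
#' u(x) = (1 - exp(-r x)) / (1 - exp(-r)) to the elicited anchors by least
#' squares. Provided as a diagnostic only; the assessment itself always uses
#' the piecewise-linear interpolant, which honours the anchors exactly.
#'
#' @param u A `riv_utility_function`.
#' @return List with `r` (risk-aversion coefficient, positive = averse),
#'   `fitted` closure, and `rmse` at the anchors.
#' @export
fit_exponential_utility <- function(u) {
  stopifnot(inherits(u, "riv_utility_function"))
  pts <- u$points
  f <- function(r, x) if (abs(r) < 1e-8) x else (1 - exp(-r * x)) / (1 - exp(-r))
  obj <- function(r) sum((f(r, pts$value) - pts$utility)^2)
  opt <- stats::optimize(obj, c(-50, 50))
  list(r = opt$minimum,
       fitted = function(x) f(opt$minimum, x),
       rmse = sqrt(opt$objective / nrow(pts)))
}
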