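#' Single-attribute value functions
#'
#' A value function maps an attribute's natural scale (individuals, degrees
#' Celsius, m3/year, ...) to a preference value in \[0, 1\], where 0 is the
#' worst-possible and 1 the best-possible state of the reference reach.
#' Functions are piecewise linear through the elicited anchor points;
#' orientation may be increasing, decreasing (best state at the numerically
#' smaller level, e.g. maximum summer temperature), or unimodal (an optimum
#' level flanked by two monotone limbs, e.g. in-stream respiration).
#'
#' @param points Data frame with columns `x` (attribute level), `v` (value in
#'   \[0, 1\]) and optionally `limb` (1/2, unimodal functions only).
#' @param attribute Attribute number (as in the attribute table) or `NA`.
#' @param source Expert id or `"literature"`.
#' @param kind `"continuous"` or `"discrete"`.
#' @param orientation `"increasing"`, `"decreasing"` or `"unimodal"`.
#' @return A `riv_value_function`.
#' @export
value_function <- function(points, attribute = NA_integer_, source = "expert",
                           kind = c("continuous", "discrete"),
                           orientation = c("increasing", "decreasing", "unimodal")) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  points <- as.data.frame(points, stringsAsFactors = FALSE)
  stopifnot(all(c("x", "v") %in% names(points)))
  if (is.null(points$limb)) points$limb <- 1L
  if (anyNA(points$x) || anyNA(points$v)) stop_riverval("value-function points contain NA")
  if (any(points$v < 0 | points$v > 1)) stop_riverval("values must lie in [0, 1]")
  if (orientation != "unimodal" && any(points$limb != 1L)) {
    stop_riverval("only unimodal functions have two limbs")
  }
  vf <- structure(
    list(points = points, attribute = attribute, source = source,
         kind = kind, orientation = orientation),
    class = "riv_value_function"
  )
  if (kind == "continuous") check_vf_monotone(vf)
  if (kind == "discrete" && anyDuplicated(points$x)) {
    stop_riverval("discrete value function maps a level twice")
  }
  vf
}

# each limb: x strictly ordered, v monotone from 0 to 1 (or 1 to 0);
# worst end(s) at value 0, best end / peak at value 1
check_vf_monotone <- function(vf) {
  for (l in unique(vf$points$limb)) {
    p <- vf$points[vf$points$limb == l, , drop = FALSE]
    p <- p[order(p$x), , drop = FALSE]
    if (nrow(p) < 2L) stop_riverval("each limb needs at least two points")
    if (any(diff(p$x) <= 0)) stop_riverval("x coordinates must be strictly ordered")
    dv <- diff(p$v)
    if (any(dv > 0) && any(dv < 0)) {
      stop_riverval("values are not monotone along limb ", l)
    }
    ends <- range(p$v)
    if (abs(ends[1]) > 1e-12 || abs(ends[2] - 1) > 1e-12) {
      stop_riverval("limb ", l, " must span values 0 to 1 (got ",
                    format(ends[1]), " to ", format(ends[2]), ")")
    }
  }
  invisible(vf)
}

#' @export
print.riv_value_function <- function(x, ...) {
  cat("<value function> attribute ", x$attribute, ", ", x$kind, ", ",
      x$orientation, ", ", nrow(x$points), " points, source ", x$source,
      "\n", sep = "")
  invisible(x)
}

#' Construct a value function from bisection answers
#'
#' The bisection method fixes interior anchor points of a value function:
#' the mid-value level `x_0.5` splits the worst-to-best improvement into two
#' equally valued halves, then `x_0.25` and `x_0.75` (optionally `x_0.1`,
#' `x_0.9`) refine each half. The result is the piecewise-linear function
#' through all supplied (level, value) pairs plus the endpoints
#' (`x_worst`, 0) and (`x_best`, 1).
#'
#' @param x_worst,x_best Attribute levels of the worst- and best-possible
#'   state. `x_worst > x_best` declares a decreasing orientation.
#' @param mid_levels Named numeric vector of elicited levels, names are the
#'   target values (e.g. `c("0.5" = 300, "0.25" = 80)`). May be empty, in
#'   which case the function is the straight line between the endpoints.
#' @param ... Passed to [value_function()] (`attribute`, `source`).
#' @return A `riv_value_function`.
#' @examples
#' # adult nase: 0 to 2000 individuals, mid-value point at 300
#' nase <- construct_from_bisection(0, 2000, c("0.5" = 300))
#' evaluate_vf(nase, 300)   # 0.5
#' evaluate_vf(nase, 1150)  # 0.75
#' @export
construct_from_bisection <- function(x_worst, x_best, mid_levels = numeric(), ...) {
  stopifnot(is_number(x_worst), is_number(x_best))
  if (x_worst == x_best) stop_riverval("worst and best level coincide")
  if (length(mid_levels)) {
    vals <- as.numeric(names(mid_levels))
    if (anyNA(vals) || any(vals <= 0 | vals >= 1)) {
      stop_riverval("mid levels must be named by values strictly inside (0, 1)")
    }
    lo <- min(x_worst, x_best); hi <- max(x_worst, x_best)
    if (any(mid_levels <= lo | mid_levels >= hi)) {
      stop_riverval("inconsistent bisection answers: level outside (worst, best)")
    }
  } else {
    vals <- numeric()
  }
  pts <- data.frame(x = c(x_worst, mid_levels, x_best), v = c(0, vals, 1))
  pts <- pts[order(pts$v), , drop = FALSE]
  increasing <- x_best > x_worst
  if (any(diff(pts$x) * (if (increasing) 1 else -1) <= 0)) {
    stop_riverval("inconsistent bisection answers: levels not monotone in value")
  }
  pts <- pts[order(pts$x), , drop = FALSE]
  value_function(pts, orientation = if (increasing) "increasing" else "decreasing",
                 ...)
}

#' Build a unimodal value function from a two-limb range
#'
#' Attributes with an ecological optimum (e.g. in-stream respiration) are
#' specified as two worst-to-best ranges sharing the peak level, written
#' `"0-7 // 14-7"`: value 0 at levels 0 and 14, value 1 at the shared peak 7.
#'
#' @param range_spec Either a string `"a-b // c-b"` (en dash or hyphen), or
#'   `NULL` if `worst`, `peak`, `worst2` are given directly.
#' @param worst,peak,worst2 Numeric alternative to the string form.
#' @param mid_levels Optional list of two named vectors of interior bisection
#'   levels, one per limb (as in [construct_from_bisection()]).
#' @param ... Passed to [value_function()].
#' @return A unimodal `riv_value_function`.
#' @examples
#' vf <- build_unimodal("0-7 // 14-7")
#' evaluate_vf(vf, 7)   # 1
#' evaluate_vf(vf, 14)  # 0
#' @export
build_unimodal <- function(range_spec = NULL, worst = NULL, peak = NULL,
                           worst2 = NULL, mid_levels = NULL, ...) {
  if (!is.null(range_spec)) {
    limbs <- parse_range(range_spec)
    if (is.na(limbs$worst2)) stop_riverval("not a two-limb range: ", range_spec)
    worst <- limbs$worst; worst2 <- limbs$worst2
    if (limbs$best != limbs$best2) {
      stop_riverval("limbs peak at unequal levels (", limbs$best, " vs ",
                    limbs$best2, ")")
    }
    peak <- limbs$best
  }
  stopifnot(is_number(worst), is_number(peak), is_number(worst2))
  mk_limb <- function(w, l, mids) {
    vf <- construct_from_bisection(w, peak, mids %||% numeric())
    p <- vf$points; p$limb <- l; p
  }
  p1 <- mk_limb(worst, 1L, if (length(mid_levels) >= 1) mid_levels[[1]] else NULL)
  p2 <- mk_limb(worst2, 2L, if (length(mid_levels) >= 2) mid_levels[[2]] else NULL)
  value_function(rbind(p1, p2), orientation = "unimodal", ...)
}

# "a-b" or "a-b // c-d" with hyphen, en dash or minus as the range separator;
# thousands commas allowed. Levels are non-negative in this notation (the
# separator would be ambiguous otherwise); negative levels take the numeric
# interface.
parse_range <- function(txt) {
  txt <- gsub(",", "", txt)
  txt <- gsub("–|−", "-", txt)
  parts <- strsplit(txt, "//", fixed = TRUE)[[1]]
  parse_pair <- function(s) {
    m <- regmatches(s, gregexpr("[0-9.]+(e-?[0-9]+)?", s))[[1]]
    if (length(m) < 2) return(c(NA_real_, NA_real_))
    nums <- suppressWarnings(as.numeric(m))
    if (length(nums) > 2) nums <- nums[1:2]
    nums
  }
  p1 <- parse_pair(parts[1])
  p2 <- if (length(parts) > 1) parse_pair(parts[2]) else c(NA_real_, NA_real_)
  list(worst = p1[1], best = p1[2], worst2 = p2[1], best2 = p2[2])
}

#' Evaluate a value function
#'
#' Linear interpolation between the bracketing anchor points; endpoint levels
#' return exactly 0 or 1. Unimodal functions are evaluated on the limb whose
#' level interval contains `x`. Discrete functions accept only their
#' admissible levels.
#'
#' @param vf A `riv_value_function`.
#' @param x Attribute level(s); vectorized.
#' @return Value(s) in \[0, 1\].
#' @export
evaluate_vf <- function(vf, x) {
  stopifnot(inherits(vf, "riv_value_function"), is.numeric(x))
  if (vf$kind == "discrete") {
    i <- match(x, vf$points$x)
    if (anyNA(i)) {
      stop_riverval("non-admissible discrete level: ",
                    paste(x[is.na(i)], collapse = ", "))
    }
    return(vf$points$v[i])
  }
  vapply(x, function(xi) {
    for (l in unique(vf$points$limb)) {
      p <- vf$points[vf$points$limb == l, , drop = FALSE]
      p <- p[order(p$x), , drop = FALSE]
      if (xi >= min(p$x) - 1e-12 && xi <= max(p$x) + 1e-12) {
        xi <- min(max(xi, min(p$x)), max(p$x))
        return(stats::approx(p$x, p$v, xout = xi, ties = "ordered")$y)
      }
    }
    stop_riverval("level ", xi, " outside the declared attribute range")
  }, numeric(1))
}

#' Invert a monotone value function
#'
#' Returns the attribute level at which the function attains value `v`.
#' Only defined for continuous single-limb (monotone) functions, or for a
#' named limb of a unimodal function.
#'
#' @param vf A `riv_value_function`.
#' @param v Value(s) in \[0, 1\].
#' @param limb Limb to invert for unimodal functions (1 or 2).
#' @return Attribute level(s); `evaluate_vf(vf, invert_vf(vf, v)) == v`
#'   within 1e-9.
#' @export
invert_vf <- function(vf, v, limb = NULL) {
  stopifnot(inherits(vf, "riv_value_function"))
  if (vf$kind != "continuous") stop_riverval("can only invert continuous functions")
  if (any(v < 0 | v > 1)) stop_riverval("values must lie in [0, 1]")
  limbs <- unique(vf$points$limb)
  if (length(limbs) > 1L && is.null(limb)) {
    stop_riverval("unimodal function: name the limb to invert")
  }
  p <- vf$points[vf$points$limb == (limb %||% limbs), , drop = FALSE]
  p <- p[order(p$v), , drop = FALSE]
  stats::approx(p$v, p$x, xout = v, ties = "ordered")$y
}

#' Classify a value function as linear or non-linear
#'
#' A continuous function counts as linear when every interior anchor point
#' deviates vertically from the endpoint chord by at most `tol` (per limb
#' for unimodal functions). The default tolerance of 0.02 on the value scale
#' is below visually distinguishable curvature in published preference
#' curves.
#'
#' @param vf A continuous `riv_value_function`.
#' @param tol Value-scale tolerance.
#' @return `"linear"` or `"nonlinear"`.
#' @examples
#' classify_shape(construct_from_bisection(0, 2000, c("0.5" = 300)))  # nonlinear
#' @export
classify_shape <- function(vf, tol = 0.02) {
  stopifnot(inherits(vf, "riv_value_function"))
  if (vf$kind != "continuous") stop_riverval("shape is defined for continuous functions only")
  for (l in unique(vf$points$limb)) {
    p <- vf$points[vf$points$limb == l, , drop = FALSE]
    p <- p[order(p$x), , drop = FALSE]
    n <- nrow(p)
    if (n <= 2L) next
    chord <- p$v[1] + (p$x - p$x[1]) / (p$x[n] - p$x[1]) * (p$v[n] - p$v[1])
    if (max(abs(p$v - chord)[-c(1, n)]) > tol) return("nonlinear")
  }
  "linear"
}

#' Translate a quality class to a value
#'
#' Class-based assessment protocols (e.g. five classes from "bad" to "very
#' good") are mapped onto the \[0, 1\] value scale by equal-width bands; a
#' class is represented by the midpoint of its band.
#'
#' @param class_index Class position, 1-based.
#' @param n_classes Number of classes (>= 2).
#' @param order `"best_first"` (class 1 is the best class) or
#'   `"worst_first"`.
#' @return The band-midpoint value.
#' @examples
#' from_class_scheme(1, 5)                 # best of five: 0.9
#' from_class_scheme(5, 5)                 # worst of five: 0.1
#' from_class_scheme(1, 2)                 # 0.75
#' @export
from_class_scheme <- function(class_index, n_classes = 5,
                              order = c("best_first", "worst_first")) {
  order <- match.arg(order)
  if (!is_number(n_classes) || n_classes < 2) stop_riverval("need at least 2 classes")
  if (any(class_index < 1 | class_index > n_classes)) {
    stop_riverval("class index out of range 1..", n_classes)
  }
  rank_from_worst <- if (order == "best_first") n_classes - class_index else class_index - 1
  (rank_from_worst + 0.5) / n_classes
}

# chord-only copy of a continuous function (per limb), used by the
# "linearize" simplification
linearize_vf <- function(vf) {
  if (vf$kind != "continuous") return(vf)
  pts <- do.call(rbind, lapply(unique(vf$points$limb), function(l) {
    p <- vf$points[vf$points$limb == l, , drop = FALSE]
    p <- p[order(p$x), , drop = FALSE]
    p[c(1, nrow(p)), , drop = FALSE]
  }))
  value_function(pts, attribute = vf$attribute, source = vf$source,
                 kind = vf$kind, orientation = vf$orientation)
}
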