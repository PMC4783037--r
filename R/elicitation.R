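#' Weight elicitation: swing, reversed swing, direct rating
#'
#' In the swing method all objectives start at their worst level; swinging
#' each in turn to its best level yields a ranking, then scores between 0 and
#' 100 points, where the best-ranked swing receives exactly 100. The
#' reversed-swing variant starts from the all-best state and scores the value
#' loss of swinging each objective to its worst level; the framing differs
#' but the scoring arithmetic is identical. Direct rating assigns importance
#' ratings straight away. In all three cases weights are the scores
#' normalized to sum 1, so they are scale-invariant and preserve rank order.
#'
#' @param scores Swing scores, 0-100, weakly decreasing in rank, best = 100.
#' @param ratings Positive importance ratings (direct rating).
#' @return Numeric weights summing to 1 (names preserved).
#' @examples
#' swing_weights(c(100, 50, 50))      # 0.50 0.25 0.25
#' swing_weights(c(100, 70, 50))      # 0.4545 0.3182 0.2273
#' direct_rating_weights(c(3, 1))     # 0.75 0.25
#' @name weight_elicitation
NULL

#' @rdname weight_elicitation
#' @export
swing_weights <- function(scores) {
  if (!is.numeric(scores) || !length(scores) || anyNA(scores)) {
    stop_riverval("scores must be numeric without NA")
  }
  if (any(scores < 0)) stop_riverval("swing scores must be non-negative")
  if (max(scores) != 100) {
    stop_riverval("the best-ranked swing must receive exactly 100 points")
  }
  scores / sum(scores)
}

#' @rdname weight_elicitation
#' @export
reversed_swing_weights <- function(scores) {
  swing_weights(scores)
}

#' @rdname weight_elicitation
#' @export
direct_rating_weights <- function(ratings) {
  if (!is.numeric(ratings) || !length(ratings) || anyNA(ratings)) {
    stop_riverval("ratings must be numeric without NA")
  }
  if (any(ratings < 0)) stop_riverval("ratings must be non-negative")
  if (sum(ratings) <= 0) stop_riverval("at least one rating must be positive")
  ratings / sum(ratings)
}

#' Group median over contributing experts
#'
#' When several experts supply a weight or synergy factor for the same
#' objective, the group value is the median over the contributing experts.
#' Explicit zero weights are deliberate exclusions and do contribute; entries
#' marked not-applicable (the empty "no aggregation required" cells, passed
#' as `NA`) do not. Even counts take the midpoint of the two central values.
#'
#' @param entries Per-expert numeric values; `NA` = not applicable.
#' @return The median of the contributing entries.
#' @examples
#' group_median(c(0.32, 0, 0.31, 0.26, 0.28))  # 0.28
#' group_median(c(1, NA, 0.25, 0.5, 1))        # 0.75
#' @export
group_median <- function(entries) {
  if (!is.numeric(entries)) stop_riverval("entries must be numeric")
  x <- entries[!is.na(entries)]
  if (!length(x)) stop_riverval("no contributing entries (all not-applicable)")
  stats::median(x)
}

#' Between-expert variation diagnostics
#'
#' The spread diagnostic used for elicited weights and synergy factors:
#' the min-max range over contributing experts, with a range of at least 0.4
#' flagged as large variation.
#'
#' @param entries Per-expert numeric values; `NA` = not applicable.
#' @param large_threshold Inclusive range threshold for the `large` flag.
#' @return List with `range` (max - min) and `large` (logical).
#' @examples
#' variation_stats(c(0.45, 1, 0.39, 0.53, 0.28))  # range 0.72, large
#' @export
variation_stats <- function(entries, large_threshold = 0.4) {
  if (!is.numeric(entries)) stop_riverval("entries must be numeric")
  x <- entries[!is.na(entries)]
  if (length(x) < 2L) stop_riverval("need at least 2 contributing entries")
  r <- max(x) - min(x)
  list(range = r, large = r >= large_threshold)
}

#' Consistency check for bisection responses
#'
#' Bisection answers are consistent when the elicited levels are monotone in
#' the target values, in the direction of the declared orientation. Returns
#' the violations rather than failing, to support interactive re-elicitation.
#'
#' @param responses Data frame with columns `value` and `level` (at least 3
#'   rows, e.g. the endpoints plus x_0.5).
#' @param orientation `"increasing"` or `"decreasing"`.
#' @return List with `pass` (logical) and `violations` (character vector,
#'   one line per offending pair of points).
#' @export
bisection_consistency <- function(responses,
                                  orientation = c("increasing", "decreasing")) {
  orientation <- match.arg(orientation)
  responses <- as.data.frame(responses)
  stopifnot(all(c("value", "level") %in% names(responses)))
  if (nrow(responses) < 3L) stop_riverval("need at least 3 response pairs")
  r <- responses[order(responses$value), , drop = FALSE]
  s <- if (orientation == "increasing") 1 else -1
  bad <- which(diff(r$level) * s <= 0)
  violations <- vapply(bad, function(i) {
    paste0("level for value ", r$value[i + 1], " (", r$level[i + 1],
           ") not beyond level for value ", r$value[i], " (", r$level[i], ")")
  }, character(1))
  list(pass = length(violations) == 0L, violations = violations)
}

#' Global leaf weights
#'
#' Weights are local to sibling groups; the global weight of a leaf is the
#' product of the local weights along its path from the root. Reported as a
#' diagnostic (e.g. for the few-objectives simplification), not used in the
#' roll-up itself.
#'
#' @param h A `riv_hierarchy`.
#' @param model An [assessment_model()] (for per-node weights; nodes without
#'   a spec use equal weights).
#' @return Named numeric vector of global weights over leaves, summing to 1.
#' @export
global_leaf_weights <- function(h, model) {
  stopifnot(inherits(h, "riv_hierarchy"))
  acc <- c()
  walk <- function(id, g) {
    kids <- node_children(h, id)
    if (!length(kids)) {
      acc[id] <<- g
      return(invisible())
    }
    spec <- model$aggregation[[id]]
    w <- if (!is.null(spec) && !is.null(spec$weights)) {
      spec$weights[kids] / sum(spec$weights[kids])
    } else {
      stats::setNames(rep(1 / length(kids), length(kids)), kids)
    }
    for (k in kids) walk(k, g * w[[k]])
  }
  walk(root_id(h), 1)
  acc
}
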