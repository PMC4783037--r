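#' Census of value-function shapes
#'
#' Summarizes a set of value-function records: totals, expert vs literature
#' sourcing, continuous vs discrete measurement scales, and — where curve
#' shapes are available — the linear/non-linear split at the
#' [classify_shape()] tolerance. Percentages are rounded half-up to whole
#' percent. Continuous/discrete counts refer to expert-sourced records, the
#' subset whose shapes reflect elicited preferences.
#'
#' @param x Either a list of `riv_value_function`s or an attribute-catalogue
#'   data frame as from [load_attribute_table()] (which records sources and
#'   scales but no curve shapes; shape counts are then `NA`).
#' @param tol Shape-classification tolerance.
#' @return List with `n_total`, `n_expert`, `n_literature`, `n_continuous`,
#'   `n_discrete`, `n_linear`, `n_nonlinear`, `pct_nonlinear`.
#' @examples
#' summarize_shapes(load_attribute_table())[c("n_expert", "n_continuous")]
#' @export
summarize_shapes <- function(x, tol = 0.02) {
  if (is.data.frame(x)) {
    expert <- x$source != "literature"
    return(list(
      n_total = nrow(x),
      n_expert = sum(expert),
      n_literature = sum(!expert),
      n_continuous = sum(expert & !x$discrete),
      n_discrete = sum(expert & x$discrete),
      n_linear = NA_integer_, n_nonlinear = NA_integer_,
      pct_nonlinear = NA_real_
    ))
  }
  stopifnot(is.list(x),
            all(vapply(x, inherits, logical(1), "riv_value_function")))
  src <- vapply(x, `[[`, character(1), "source")
  kind <- vapply(x, `[[`, character(1), "kind")
  expert <- src != "literature"
  cont <- x[kind == "continuous"]
  shapes <- vapply(cont, classify_shape, character(1), tol = tol)
  n_lin <- sum(shapes == "linear")
  n_non <- sum(shapes == "nonlinear")
  list(
    n_total = length(x),
    n_expert = sum(expert),
    n_literature = sum(!expert),
    n_continuous = sum(expert & kind == "continuous"),
    n_discrete = sum(expert & kind == "discrete"),
    n_linear = n_lin,
    n_nonlinear = n_non,
    pct_nonlinear = if (length(shapes)) round_half_up(100 * n_non / length(shapes))
                    else NA_real_
  )
}

#' Census of aggregation-method choices
#'
#' Counts aggregation decisions by method and reports the multiplicative
#' share, rounded half-up to whole percent.
#'
#' @param specs A data frame with a `method` column (e.g. from
#'   [load_aggregation_choices()]; `"add"`/`"mult"` and the long method
#'   names are both accepted), or a list of [aggregation_spec()]s.
#' @return List with `n_total`, `counts` (named, by method),
#'   `pct_multiplicative`.
#' @examples
#' summarize_aggregations(load_aggregation_choices())  # 12 additive, 76%
#' @export
summarize_aggregations <- function(specs) {
  methods <- if (is.data.frame(specs)) {
    stopifnot("method" %in% names(specs))
    specs$method
  } else {
    vapply(specs, function(s) s$method, character(1))
  }
  canon <- c(add = "additive", mult = "multiplicative", min = "minimum",
             additive = "additive", multiplicative = "multiplicative",
             minimum = "minimum", mixed = "mixed")
  if (any(!methods %in% names(canon))) {
    stop_riverval("unknown aggregation method: ",
                  paste(unique(methods[!methods %in% names(canon)]), collapse = ", "))
  }
  methods <- unname(canon[methods])
  counts <- table(methods)
  n <- length(methods)
  list(n_total = n,
       counts = stats::setNames(as.integer(counts), names(counts)),
       pct_multiplicative = round_half_up(100 * sum(methods == "multiplicative") / n))
}

#' Census of between-expert weight variation
#'
#' Applies [variation_stats()] to every objective (row) with at least two
#' contributing experts and reports how many show large variation
#' (min-max range >= 0.4).
#'
#' @param weight_table Numeric matrix or data frame, objectives x experts;
#'   `NA` = not elicited.
#' @param large_threshold Passed to [variation_stats()].
#' @return List with `n_objectives` (rows with >= 2 entries), `n_large`,
#'   `fraction_large`, and per-objective `ranges`.
#' @export
summarize_weight_variation <- function(weight_table, large_threshold = 0.4) {
  m <- as.matrix(weight_table)
  eligible <- rowSums(!is.na(m)) >= 2L
  ranges <- apply(m[eligible, , drop = FALSE], 1, function(r) {
    variation_stats(r, large_threshold)$range
  })
  list(n_objectives = sum(eligible),
       n_large = sum(ranges >= large_threshold),
       fraction_large = if (any(eligible)) sum(ranges >= large_threshold) / sum(eligible)
                        else NA_real_,
       ranges = ranges)
}

#' Simplification flags
#'
#' The four simplifications commonly applied in practice: restricting to few
#' objectives, linear value functions, additive aggregation, and risk
#' neutrality. Each flag is independently toggleable.
#'
#' @param linearize_value_functions Replace every continuous value function
#'   by the chord between its endpoints (per limb); discrete functions are
#'   left untouched.
#' @param force_additive Replace every aggregation method by additive
#'   (keeping weights; methods without weights get equal weights).
#' @param force_risk_neutral Drop the root utility function.
#' @param restrict_to_top_objectives Keep only the `n` leaves with the
#'   highest global weight (`NA` = keep all); weights are renormalized.
#' @return An `riv_simplification_config`.
#' @export
simplification_config <- function(linearize_value_functions = FALSE,
                                  force_additive = FALSE,
                                  force_risk_neutral = FALSE,
                                  restrict_to_top_objectives = NA) {
  structure(list(linearize_value_functions = isTRUE(linearize_value_functions),
                 force_additive = isTRUE(force_additive),
                 force_risk_neutral = isTRUE(force_risk_neutral),
                 restrict_to_top_objectives = restrict_to_top_objectives),
            class = "riv_simplification_config")
}

# apply the config to (hierarchy, model); returns list(hierarchy, model)
simplify_fixture <- function(h, model, config) {
  stopifnot(inherits(config, "riv_simplification_config"))
  vfs <- model$value_functions
  agg <- model$aggregation
  util <- model$utility
  if (config$linearize_value_functions) vfs <- lapply(vfs, linearize_vf)
  if (config$force_additive) {
    agg <- lapply(agg, function(s) aggregation_spec("additive", weights = s$weights))
  }
  if (config$force_risk_neutral) util <- NULL
  if (!is.na(config$restrict_to_top_objectives)) {
    n <- config$restrict_to_top_objectives
    gw <- global_leaf_weights(h, model)
    keep_leaves <- names(sort(gw, decreasing = TRUE))[seq_len(min(n, length(gw)))]
    keep <- unique(unlist(lapply(keep_leaves, function(id) {
      path <- id
      while (!is.na(p <- h$nodes$parent[match(path[length(path)], h$nodes$id)])) {
        path <- c(path, p)
      }
      path
    })))
    nd <- h$nodes[h$nodes$id %in% keep, , drop = FALSE]
    h <- hierarchy(nd,
                   h$node_attributes[h$node_attributes$node_id %in% keep_leaves, ,
                                     drop = FALSE],
                   h$catalogue,
                   h$labels[h$labels$node_id %in% keep, , drop = FALSE])
  }
  list(hierarchy = h, model = assessment_model(vfs, agg, util))
}

#' Compare full and simplified assessment models
#'
#' Scores each river state under the full preference model and under a
#' simplified variant, and compares the induced rankings: a pairwise
#' concordance coefficient (concordant minus discordant pairs over all
#' pairs; ties counted separately) and the list of rank-reversed state
#' pairs. With all flags off, the simplified model is the full model and the
#' outputs are identical.
#'
#' @param h A `riv_hierarchy`.
#' @param model An [assessment_model()].
#' @param config A [simplification_config()].
#' @param states A list of state data frames (see [rollup()]), or a single
#'   long data frame with a `state` id column.
#' @return List with `scores` (data frame: state, full, simplified),
#'   `concordance`, `n_tied_pairs`, and `reversals` (data frame of state
#'   pairs whose order flips).
#' @export
compare_models <- function(h, model, config, states) {
  if (is.data.frame(states)) {
    stopifnot("state" %in% names(states))
    states <- split(states[setdiff(names(states), "state")], states$state)
  }
  simp <- simplify_fixture(h, model, config)
  score <- function(hh, mm, st) rollup(hh, st, mm)$root_utility
  full <- vapply(states, function(st) score(h, model, st), numeric(1))
  simplified <- vapply(states, function(st) score(simp$hierarchy, simp$model, st),
                       numeric(1))
  ids <- names(states) %||% as.character(seq_along(states))
  conc <- 0L; disc <- 0L; tied <- 0L
  reversals <- list()
  np <- length(full)
  for (i in seq_len(max(np - 1, 0))) {
    for (j in seq((i + 1), np)) {
      a <- sign(full[i] - full[j]); b <- sign(simplified[i] - simplified[j])
      if (a == 0 || b == 0) {
        tied <- tied + 1L
      } else if (a == b) {
        conc <- conc + 1L
      } else {
        disc <- disc + 1L
        reversals[[length(reversals) + 1L]] <-
          data.frame(state_a = ids[i], state_b = ids[j], stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- np * (np - 1) / 2
  list(
    scores = data.frame(state = ids, full = unname(full),
                        simplified = unname(simplified), stringsAsFactors = FALSE),
    concordance = if (pairs > 0) (conc - disc) / pairs else NA_real_,
    n_tied_pairs = tied,
    reversals = if (length(reversals)) do.call(rbind, reversals) else
      data.frame(state_a = character(), state_b = character(),
                 stringsAsFactors = FALSE)
  )
}

#' Synergy demonstration curves
#'
#' The illustration used to discuss the synergy factor with experts:
#' `joint(t)` raises all n sub-objectives together from 0 to t, while
#' `lone(t)` raises one sub-objective at a time to t (the others staying at
#' 0) and sums the resulting aggregate values. For k = 1 the two curves
#' coincide; for k < 1 the joint improvement is worth more
#' (`lone(1) < joint(1) = 1`). The raw (unnormalized) curves of the
#' synergy-score product are also returned.
#'
#' @param weights Normalized weights (length n >= 2).
#' @param k Synergy factor in (0, 1].
#' @param n_grid Number of grid points on \[0, 1\].
#' @return Data frame with columns `t`, `joint`, `lone`, `joint_raw`,
#'   `lone_raw`.
#' @examples
#' d <- synergy_demo(rep(0.25, 4), k = 0.25)
#' d$lone[nrow(d)] < 1  # TRUE: joint improvement beats one-at-a-time
#' @export
synergy_demo <- function(weights, k, n_grid = 101) {
  check_weights(weights)
  n <- length(weights)
  if (n < 2) stop_riverval("need at least 2 objectives")
  raw <- function(v) (prod(k * weights * v + 1) - 1) / k
  rmax <- raw(rep(1, n))
  tt <- seq(0, 1, length.out = n_grid)
  joint_raw <- vapply(tt, function(t) raw(rep(t, n)), numeric(1))
  lone_raw <- vapply(tt, function(t) {
    sum(vapply(seq_len(n), function(i) {
      v <- rep(0, n); v[i] <- t; raw(v)
    }, numeric(1)))
  }, numeric(1))
  joint <- vapply(tt, function(t) {
    aggregate_multiplicative(rep(t, n), weights, k)
  }, numeric(1))
  lone <- vapply(tt, function(t) {
    sum(vapply(seq_len(n), function(i) {
      v <- rep(0, n); v[i] <- t
      aggregate_multiplicative(v, weights, k)
    }, numeric(1)))
  }, numeric(1))
  data.frame(t = tt, joint = joint, lone = lone,
             joint_raw = joint_raw, lone_raw = lone_raw)
}
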