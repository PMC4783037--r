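#' Aggregation of sub-objective values
#'
#' Values of sub-objectives are combined level by level up the objectives
#' hierarchy. Four aggregation models are supported:
#' \describe{
#'   \item{additive}{the weighted arithmetic mean \eqn{\sum_i w_i v_i};
#'     full compensation between sub-objectives.}
#'   \item{minimum}{one-out-all-out: the parent equals the worst child; no
#'     compensation at all.}
#'   \item{multiplicative}{a synergy-factor model that rewards jointly good
#'     sub-objectives. The raw score \eqn{r(v) = (\prod_i (k w_i v_i + 1) - 1)/k}
#'     is normalized by its all-ones value so the result is 0 when all
#'     children are 0 and 1 when all are 1. The synergy factor k takes values
#'     in (0, 1]: 0.25 large, 0.5 medium, 0.75 small synergy; k = 1 means no
#'     synergy and dispatches exactly to the additive model.}
#'   \item{mixed}{the convex combination
#'     \eqn{\alpha f_{add} + (1-\alpha) f_{min}}, a compromise retaining some
#'     sensitivity to the worst child.}
#' }
#' For every input, \eqn{f_{mult}(k<1) \le f_{add}} with equality only at the
#' all-zero and all-one extremes, and all aggregators are monotone in each
#' child value. Note that the synergy model is not idempotent: on constant
#' inputs \eqn{f_{mult}(v,\dots,v) < v} for \eqn{v \in (0,1)}, so it can fall
#' below the minimum aggregator there — divergent child values are penalized
#' relative to the additive model, uniformly mediocre ones are not rescued.
#'
#' @param values Child values in \[0, 1\].
#' @param weights Non-negative weights summing to 1 (not used by `minimum`).
#' @param k Synergy factor in (0, 1].
#' @param alpha Mix coefficient in \[0, 1\] (1 = purely additive).
#' @return The aggregated value in \[0, 1\].
#' @examples
#' aggregate_additive(c(0.8, 0.6, 0.9), c(0.32, 0.23, 0.45))  # 0.799
#' aggregate_minimum(c(0.2, 0.9, 0.7))                        # 0.2
#' aggregate_multiplicative(c(1, 0), c(0.5, 0.5), k = 0.5)    # 0.4444...
#' aggregate_mixed(c(1, 0), c(0.5, 0.5), alpha = 0.5)         # 0.25
#' @name aggregation
NULL

#' @rdname aggregation
#' @export
aggregate_additive <- function(values, weights) {
  values <- check_values(values)
  check_weights(weights, n = length(values))
  sum(weights * values)
}

#' @rdname aggregation
#' @export
aggregate_minimum <- function(values) {
  values <- check_values(values)
  min(values)
}

#' @rdname aggregation
#' @export
aggregate_multiplicative <- function(values, weights, k) {
  values <- check_values(values)
  check_weights(weights, n = length(values))
  if (!is_number(k) || k <= 0 || k > 1) {
    stop_riverval("synergy factor k must lie in (0, 1]")
  }
  if (k == 1) return(aggregate_additive(values, weights))
  raw <- function(v) (prod(k * weights * v + 1) - 1) / k
  raw(values) / raw(rep(1, length(values)))
}

#' @rdname aggregation
#' @export
aggregate_mixed <- function(values, weights, alpha) {
  values <- check_values(values)
  check_weights(weights, n = length(values))
  if (!is_number(alpha) || alpha < 0 || alpha > 1) {
    stop_riverval("alpha must lie in [0, 1]")
  }
  alpha * aggregate_additive(values, weights) + (1 - alpha) * aggregate_minimum(values)
}

#' Per-node aggregation specification
#'
#' @param method One of `"additive"`, `"minimum"`, `"multiplicative"`,
#'   `"mixed"`.
#' @param weights Named numeric vector of child weights (names = child node
#'   ids); `NULL` means equal weights. Ignored by `minimum`.
#' @param k Synergy factor, required iff `method = "multiplicative"`.
#' @param alpha Mix coefficient, required iff `method = "mixed"`.
#' @return An `riv_aggregation_spec`.
#' @export
aggregation_spec <- function(method = c("additive", "minimum", "multiplicative", "mixed"),
                             weights = NULL, k = NULL, alpha = NULL) {
  method <- match.arg(method)
  if (method == "multiplicative" && is.null(k)) stop_riverval("multiplicative needs k")
  if (method != "multiplicative" && !is.null(k)) stop_riverval("k only applies to multiplicative")
  if (method == "mixed" && is.null(alpha)) stop_riverval("mixed needs alpha")
  if (method != "mixed" && !is.null(alpha)) stop_riverval("alpha only applies to mixed")
  structure(list(method = method, weights = weights, k = k, alpha = alpha),
            class = "riv_aggregation_spec")
}

apply_aggregation <- function(spec, values, weights) {
  switch(spec$method,
    additive = aggregate_additive(values, weights),
    minimum = aggregate_minimum(values),
    multiplicative = aggregate_multiplicative(values, weights, spec$k),
    mixed = aggregate_mixed(values, weights, spec$alpha)
  )
}

#' Assessment model: value functions plus per-node aggregation
#'
#' @param value_functions List of [value_function()] objects; each must carry
#'   its `attribute` number. Several functions (different sources) may share
#'   one attribute; their evaluations are pooled by the median, mirroring the
#'   group-median rule used for weights.
#' @param aggregation Named list of [aggregation_spec()]s, keyed by node id.
#'   Nodes without an entry default to equal-weight additive aggregation.
#' @param utility Optional [utility_from_ce()] output applied to the root
#'   value (risk attitude); `NULL` assumes risk neutrality.
#' @return An `riv_assessment_model`.
#' @export
assessment_model <- function(value_functions, aggregation = list(), utility = NULL) {
  stopifnot(is.list(value_functions),
            all(vapply(value_functions, inherits, logical(1), "riv_value_function")))
  if (length(aggregation) && is.null(names(aggregation))) {
    stop_riverval("`aggregation` must be a named list keyed by node id")
  }
  structure(list(value_functions = value_functions, aggregation = aggregation,
                 utility = utility),
            class = "riv_assessment_model")
}

#' Hierarchical roll-up of attribute measurements
#'
#' Evaluates a measured river state against an objectives hierarchy: leaf
#' objectives are valued through their attributes' value functions (several
#' sources for one attribute are pooled by the median, as are several
#' attributes of one leaf), then values are aggregated level by level to the
#' root. Attributes without a measurement are dropped and the weights of the
#' surviving siblings renormalized; every such event is logged in the
#' provenance. A node all of whose children are missing is itself missing.
#'
#' @param h A `riv_hierarchy`.
#' @param state Data frame with columns `attribute` (number) and `level`
#'   (measured level; `NA` = not measured).
#' @param model An [assessment_model()].
#' @return An `riv_assessment_result`: list with `node_values` (named,
#'   `NA` = missing), `root_value`, `root_utility` (equal to `root_value`
#'   under risk neutrality) and `provenance` (data frame of renormalization /
#'   missing-data events).
#' @export
rollup <- function(h, state, model) {
  stopifnot(inherits(h, "riv_hierarchy"), inherits(model, "riv_assessment_model"))
  state <- as.data.frame(state, stringsAsFactors = FALSE)
  stopifnot(all(c("attribute", "level") %in% names(state)))
  prov <- list()
  note <- function(node, event, detail) {
    prov[[length(prov) + 1L]] <<- data.frame(node = node, event = event,
                                             detail = detail,
                                             stringsAsFactors = FALSE)
  }
  vf_by_attr <- split(model$value_functions,
                      vapply(model$value_functions, function(f) as.integer(f$attribute),
                             integer(1)))

  leaf_value <- function(id) {
    nums <- h$node_attributes$number[h$node_attributes$node_id == id]
    per_attr <- vapply(nums, function(nn) {
      lev <- state$level[state$attribute == nn]
      lev <- lev[!is.na(lev)]
      fs <- vf_by_attr[[as.character(nn)]]
      if (!length(lev) || is.null(fs)) {
        note(id, "missing_attribute",
             paste0("attribute ", nn,
                    if (!length(lev)) " has no measurement" else " has no value function"))
        return(NA_real_)
      }
      stats::median(vapply(fs, function(f) evaluate_vf(f, lev[1]), numeric(1)))
    }, numeric(1))
    ok <- per_attr[!is.na(per_attr)]
    if (!length(ok)) return(NA_real_)
    stats::median(ok)
  }

  node_values <- c()
  eval_node <- function(id) {
    kids <- node_children(h, id)
    if (!length(kids)) {
      val <- if (id %in% h$node_attributes$node_id) leaf_value(id) else NA_real_
      if (is.na(val) && !id %in% h$node_attributes$node_id) {
        note(id, "non_assessable", "no children and no attributes")
      }
      node_values[id] <<- val
      return(val)
    }
    vals <- vapply(kids, eval_node, numeric(1))
    spec <- model$aggregation[[id]] %||%
      aggregation_spec("additive")
    w <- spec$weights
    if (is.null(w)) {
      w <- stats::setNames(rep(1 / length(kids), length(kids)), kids)
    } else {
      if (!all(kids %in% names(w))) {
        stop_riverval("aggregation weights for node ", id, " do not cover children ",
                      paste(setdiff(kids, names(w)), collapse = ", "))
      }
      w <- w[kids] / sum(w[kids])
    }
    avail <- !is.na(vals)
    if (!any(avail)) {
      note(id, "all_children_missing", paste(kids, collapse = ", "))
      node_values[id] <<- NA_real_
      return(NA_real_)
    }
    if (!all(avail)) {
      if (sum(w[avail]) <= 0) {
        note(id, "all_weight_missing", paste(kids[!avail], collapse = ", "))
        node_values[id] <<- NA_real_
        return(NA_real_)
      }
      note(id, "renormalized",
           paste0("dropped ", paste(kids[!avail], collapse = ", "),
                  "; weights rescaled by 1/", format(sum(w[avail]))))
      w <- renormalize_weights(w, avail)
      vals <- vals[avail]
    }
    val <- apply_aggregation(spec, vals, w)
    node_values[id] <<- val
    val
  }

  root <- root_id(h)
  root_value <- eval_node(root)
  if (is.na(root_value)) {
    stop_riverval("root objective is missing: no assessable leaf under ", root)
  }
  root_utility <- if (!is.null(model$utility)) {
    apply_risk(root_value, model$utility)
  } else {
    root_value
  }
  structure(
    list(node_values = node_values, root_value = root_value,
         root_utility = root_utility,
         provenance = if (length(prov)) do.call(rbind, prov) else
           data.frame(node = character(), event = character(),
                      detail = character(), stringsAsFactors = FALSE)),
    class = "riv_assessment_result"
  )
}

#' @export
print.riv_assessment_result <- function(x, ...) {
  cat("<assessment> root value ", format(round(x$root_value, 4)),
      if (!is.null(x$root_utility) && x$root_utility != x$root_value)
        paste0(", root utility ", format(round(x$root_utility, 4))),
      "; ", sum(!is.na(x$node_values)), "/", length(x$node_values),
      " nodes valued, ", nrow(x$provenance), " provenance event(s)\n", sep = "")
  invisible(x)
}

#' Export an assessment result
#'
#' @param x An `riv_assessment_result`.
#' @param h The hierarchy it was computed on (for levels).
#' @param csv_path,json_path Output files (either may be `NULL`).
#' @return The per-node data frame (`node`, `level`, `value`), invisibly.
#' @export
write_assessment <- function(x, h, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "riv_assessment_result"), inherits(h, "riv_hierarchy"))
  df <- data.frame(node = names(x$node_values),
                   level = h$nodes$level[match(names(x$node_values), h$nodes$id)],
                   value = unname(x$node_values), stringsAsFactors = FALSE)
  df <- df[order(df$level, df$node), , drop = FALSE]
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(root_value = x$root_value, root_utility = x$root_utility,
           node_values = as.list(x$node_values),
           provenance = x$provenance),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(df)
}
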