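# Independent straight-line recursive evaluator used as the oracle for
# rollup(): its aggregation arithmetic is written out inline, separate from
# the package's aggregator functions.
oracle_eval <- function(h, state, model, id = h$nodes$id[is.na(h$nodes$parent)]) {
  kids <- h$nodes$id[!is.na(h$nodes$parent) & h$nodes$parent == id]
  if (!length(kids)) {
    nums <- h$node_attributes$number[h$node_attributes$node_id == id]
    vals <- c()
    for (nn in nums) {
      lev <- state$level[state$attribute == nn]
      lev <- lev[!is.na(lev)]
      fs <- Filter(function(f) isTRUE(as.integer(f$attribute) == as.integer(nn)),
                   model$value_functions)
      if (!length(lev) || !length(fs)) next
      vals <- c(vals, stats::median(vapply(fs, function(f) evaluate_vf(f, lev[1]),
                                           numeric(1))))
    }
    if (!length(vals)) return(NA_real_)
    return(stats::median(vals))
  }
  vv <- vapply(kids, function(k) oracle_eval(h, state, model, k), numeric(1))
  spec <- model$aggregation[[id]]
  w <- if (is.null(spec) || is.null(spec$weights)) {
    stats::setNames(rep(1 / length(kids), length(kids)), kids)
  } else {
    spec$weights[kids] / sum(spec$weights[kids])
  }
  ok <- !is.na(vv)
  if (!any(ok)) return(NA_real_)
  w <- w[ok] / sum(w[ok])
  vv <- vv[ok]
  method <- if (is.null(spec)) "additive" else spec$method
  if (method == "additive") {
    sum(w * vv)
  } else if (method == "minimum") {
    min(vv)
  } else if (method == "multiplicative") {
    k <- spec$k
    if (k == 1) sum(w * vv)
    else (prod(k * w * vv + 1) - 1) / (prod(k * w + 1) - 1)
  } else {
    spec$alpha * sum(w * vv) + (1 - spec$alpha) * min(vv)
  }
}

# Small hand-built hierarchy: root -> (nodeA -> leaf1, leaf2; nodeB -> leaf3)
toy_hierarchy <- function() {
  nodes <- data.frame(
    id = c("root", "nodeA", "nodeB", "leaf1", "leaf2", "leaf3"),
    name = c("overall", "A", "B", "a1", "a2", "b1"),
    level = c(0L, 1L, 1L, 2L, 2L, 2L),
    parent = c(NA, "root", "root", "nodeA", "nodeA", "nodeB"),
    stringsAsFactors = FALSE
  )
  cat_df <- data.frame(
    number = 1:3, abbreviation = paste0("a", 1:3),
    measure = "synthetic indicator", unit = "unit", range = "0-1",
    worst = 0, best = 1, worst2 = NA_real_, best2 = NA_real_,
    discrete = FALSE, levels = "", source = "expert",
    has_value_function = TRUE, flag = "", stringsAsFactors = FALSE
  )
  hierarchy(nodes,
            data.frame(node_id = c("leaf1", "leaf2", "leaf3"), number = 1:3,
                       stringsAsFactors = FALSE),
            cat_df)
}

toy_model <- function(methodA = "multiplicative", kA = 0.5,
                      methodB = "additive", utility = NULL) {
  vfs <- lapply(1:3, function(i) {
    construct_from_bisection(0, 1, attribute = i)
  })
  agg <- list(
    root = aggregation_spec("additive",
                            weights = c(nodeA = 0.6, nodeB = 0.4)),
    nodeA = if (methodA == "multiplicative") {
      aggregation_spec("multiplicative", weights = c(leaf1 = 0.7, leaf2 = 0.3),
                       k = kA)
    } else {
      aggregation_spec(methodA, weights = c(leaf1 = 0.7, leaf2 = 0.3))
    },
    nodeB = aggregation_spec(methodB, weights = c(leaf3 = 1))
  )
  assessment_model(vfs, agg, utility)
}

toy_state <- function(levels = c(0.8, 0.4, 0.9)) {
  data.frame(attribute = 1:3, level = levels)
}
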