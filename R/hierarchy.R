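#' Objectives hierarchies
#'
#' An objectives hierarchy decomposes an overall goal (here "ecological
#' state" of a river reach) into sub-objectives over up to five levels, down
#' to lowest-level objectives that are quantified by measurable attributes.
#' The root sits at level 0 so that published level-1 weights attach to its
#' children; per-level objective counts exclude the root.
#'
#' A `riv_hierarchy` is a list of four data frames:
#' \describe{
#'   \item{nodes}{`id`, `name`, `level` (integer, 0 = root), `parent`
#'     (`NA` for the root), `non_assessable` (structural placeholder nodes
#'     that carry neither children nor attributes).}
#'   \item{node_attributes}{`node_id`, `number` — attribute numbers attached
#'     to leaves.}
#'   \item{catalogue}{the attribute catalogue, see [load_attribute_table()].}
#'   \item{labels}{`node_id`, `expert`, `category` — per-expert essentiality
#'     labels (`essential`, `very_valuable`, `desirable`).}
#' }
#'
#' @param nodes,node_attributes,catalogue,labels Data frames as described
#'   above; missing parts default to empty.
#' @param check Validate the assembled hierarchy and fail on violations.
#' @return A `riv_hierarchy` object.
#' @seealso [load_hierarchy()], [validate_hierarchy()], [count_by_level()]
#' @export
hierarchy <- function(nodes, node_attributes = NULL, catalogue = NULL,
                      labels = NULL, check = TRUE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  need <- c("id", "name", "level", "parent")
  if (!all(need %in% names(nodes))) {
    stop_riverval("`nodes` needs columns ", paste(need, collapse = ", "))
  }
  if (is.null(nodes$non_assessable)) nodes$non_assessable <- FALSE
  nodes$non_assessable[is.na(nodes$non_assessable)] <- FALSE
  nodes$level <- as.integer(nodes$level)
  empty_na <- data.frame(node_id = character(), number = integer(),
                         stringsAsFactors = FALSE)
  empty_lab <- data.frame(node_id = character(), expert = character(),
                          category = character(), stringsAsFactors = FALSE)
  h <- structure(
    list(
      nodes = nodes[c("id", "name", "level", "parent", "non_assessable")],
      node_attributes = as.data.frame(node_attributes %||% empty_na,
                                      stringsAsFactors = FALSE),
      catalogue = as.data.frame(catalogue %||% empty_catalogue(),
                                stringsAsFactors = FALSE),
      labels = as.data.frame(labels %||% empty_lab, stringsAsFactors = FALSE)
    ),
    class = "riv_hierarchy"
  )
  if (check) {
    bad <- validate_hierarchy(h)
    if (length(bad)) {
      stop_riverval("invalid hierarchy:\n", paste("-", bad, collapse = "\n"))
    }
  }
  h
}

empty_catalogue <- function() {
  data.frame(
    number = integer(), abbreviation = character(), measure = character(),
    unit = character(), worst = numeric(), best = numeric(),
    worst2 = numeric(), best2 = numeric(), discrete = logical(),
    levels = character(), source = character(),
    has_value_function = logical(), flag = character(),
    stringsAsFactors = FALSE
  )
}

#' @export
print.riv_hierarchy <- function(x, ...) {
  cl <- count_by_level(x)
  cat("<riv_hierarchy> ", cl$total, " objectives on ",
      length(cl$counts), " level(s) [",
      paste(cl$counts, collapse = "/"), "], ",
      nrow(x$catalogue), " attribute record(s)\n", sep = "")
  invisible(x)
}

#' Validate an objectives hierarchy
#'
#' Checks all structural invariants: unique ids, existing parents, levels
#' strictly increasing from parent to child, a single root, children
#' xor attributes at every node (placeholders flagged `non_assessable` are
#' the only leaves allowed to carry no attribute), attribute numbers known
#' to the catalogue, acyclicity and connectedness, and well-formed
#' essentiality labels.
#'
#' @param h A `riv_hierarchy`.
#' @return A character vector of violations, each naming the offending id;
#'   `character(0)` when the hierarchy is valid.
#' @export
validate_hierarchy <- function(h) {
  stopifnot(inherits(h, "riv_hierarchy"))
  nd <- h$nodes
  out <- character()
  dup <- unique(nd$id[duplicated(nd$id)])
  for (d in dup) out <- c(out, paste0("duplicate id: ", d))
  roots <- nd$id[is.na(nd$parent)]
  if (length(roots) != 1L) {
    out <- c(out, paste0("expected exactly one root, found ", length(roots),
                         if (length(roots)) paste0(" (", paste(roots, collapse = ", "), ")")))
  }
  known <- nd$id
  for (i in seq_len(nrow(nd))) {
    p <- nd$parent[i]
    if (is.na(p)) next
    if (!p %in% known) {
      out <- c(out, paste0("dangling parent: node ", nd$id[i],
                           " names unknown parent ", p))
    } else if (nd$level[match(p, nd$id)] >= nd$level[i]) {
      out <- c(out, paste0("level order: node ", nd$id[i],
                           " (level ", nd$level[i], ") under parent ", p,
                           " (level ", nd$level[match(p, nd$id)], ")"))
    }
  }
  # cycle / connectivity: walk each node up to the root
  idx <- stats::setNames(seq_len(nrow(nd)), nd$id)
  for (i in seq_len(nrow(nd))) {
    seen <- character()
    j <- i
    while (!is.na(nd$parent[j])) {
      if (nd$id[j] %in% seen) {
        out <- c(out, paste0("cycle involving node ", nd$id[j]))
        break
      }
      seen <- c(seen, nd$id[j])
      nxt <- idx[nd$parent[j]]
      if (is.na(nxt)) break
      j <- nxt
    }
  }
  has_child <- known %in% nd$parent
  has_attr <- known %in% h$node_attributes$node_id
  for (i in seq_len(nrow(nd))) {
    if (has_child[i] && has_attr[i]) {
      out <- c(out, paste0("node ", nd$id[i], " has both children and attributes"))
    }
    if (!has_child[i] && !has_attr[i] && !nd$non_assessable[i] && !is.na(nd$parent[i])) {
      out <- c(out, paste0("leaf without attributes: ", nd$id[i]))
    }
  }
  bad_na <- setdiff(h$node_attributes$node_id, known)
  for (b in unique(bad_na)) out <- c(out, paste0("attributes attached to unknown node: ", b))
  unknown_attr <- setdiff(h$node_attributes$number, h$catalogue$number)
  for (u in unknown_attr) {
    out <- c(out, paste0("unknown attribute number: ", u, " (node ",
                         paste(h$node_attributes$node_id[h$node_attributes$number == u],
                               collapse = ", "), ")"))
  }
  if (nrow(h$labels)) {
    badcat <- !h$labels$category %in% c("essential", "very_valuable", "desirable")
    for (i in which(badcat)) {
      out <- c(out, paste0("unknown essentiality category '", h$labels$category[i],
                           "' on node ", h$labels$node_id[i]))
    }
    key <- paste(h$labels$node_id, h$labels$expert)
    for (k in unique(key[duplicated(key)])) {
      out <- c(out, paste0("multiple labels for (node, expert) pair: ", k))
    }
    for (b in setdiff(h$labels$node_id, known)) {
      out <- c(out, paste0("label on unknown node: ", b))
    }
  }
  out
}

#' Read and write hierarchy documents
#'
#' Hierarchies are stored as JSON: a `nodes` array (id, name, level, parent,
#' attribute numbers, optional `non_assessable` flag and per-expert labels)
#' plus an `attribute_catalogue` array mirroring the attribute table columns.
#' Writing then reading reproduces an identical structure.
#'
#' @param path File path.
#' @return `load_hierarchy()` returns a validated `riv_hierarchy`;
#'   `write_hierarchy()` returns `path` invisibly.
#' @examples
#' h <- load_hierarchy(riverval_example("hierarchy_consolidated_synthetic.json"))
#' count_by_level(h)
#' @export
load_hierarchy <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(doc$nodes)) stop_riverval("hierarchy document has no `nodes` array")
  nodes <- do.call(rbind, lapply(doc$nodes, function(n) {
    data.frame(id = as.character(n$id), name = as.character(n$name %||% n$id),
               level = as.integer(n$level),
               parent = if (is.null(n$parent)) NA_character_ else as.character(n$parent),
               non_assessable = isTRUE(n$non_assessable),
               stringsAsFactors = FALSE)
  }))
  na <- do.call(rbind, lapply(doc$nodes, function(n) {
    if (is.null(n$attributes) || !length(n$attributes)) return(NULL)
    data.frame(node_id = as.character(n$id), number = as.integer(unlist(n$attributes)),
               stringsAsFactors = FALSE)
  }))
  labs <- do.call(rbind, lapply(doc$nodes, function(n) {
    if (is.null(n$labels) || !length(n$labels)) return(NULL)
    data.frame(node_id = as.character(n$id), expert = names(n$labels),
               category = as.character(unlist(n$labels)), stringsAsFactors = FALSE)
  }))
  cat_df <- NULL
  if (!is.null(doc$attribute_catalogue)) {
    cat_df <- do.call(rbind, lapply(doc$attribute_catalogue, function(a) {
      data.frame(
        number = as.integer(a$number), abbreviation = as.character(a$abbreviation),
        measure = as.character(a$measure %||% ""), unit = as.character(a$unit %||% ""),
        worst = as.numeric(a$worst %||% NA), best = as.numeric(a$best %||% NA),
        worst2 = as.numeric(a$worst2 %||% NA), best2 = as.numeric(a$best2 %||% NA),
        discrete = isTRUE(a$discrete), levels = as.character(a$levels %||% ""),
        source = as.character(a$source %||% "expert"),
        has_value_function = !isFALSE(a$has_value_function),
        flag = as.character(a$flag %||% ""), stringsAsFactors = FALSE)
    }))
  }
  hierarchy(nodes, na, cat_df, labs)
}

#' @rdname load_hierarchy
#' @param h A `riv_hierarchy`.
#' @export
write_hierarchy <- function(h, path) {
  stopifnot(inherits(h, "riv_hierarchy"))
  nodes <- lapply(seq_len(nrow(h$nodes)), function(i) {
    n <- h$nodes[i, ]
    rec <- list(id = n$id, name = n$name, level = n$level)
    if (!is.na(n$parent)) rec$parent <- n$parent
    attrs <- h$node_attributes$number[h$node_attributes$node_id == n$id]
    if (length(attrs)) rec$attributes <- as.integer(attrs)
    if (isTRUE(n$non_assessable)) rec$non_assessable <- TRUE
    labs <- h$labels[h$labels$node_id == n$id, , drop = FALSE]
    if (nrow(labs)) rec$labels <- as.list(stats::setNames(labs$category, labs$expert))
    rec
  })
  doc <- list(nodes = nodes)
  if (nrow(h$catalogue)) {
    doc$attribute_catalogue <- lapply(seq_len(nrow(h$catalogue)), function(i) {
      a <- as.list(h$catalogue[i, ])
      a[!vapply(a, function(x) is.na(x) || identical(x, ""), logical(1))]
    })
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Consolidate expert-labelled hierarchies
#'
#' Builds the consolidated hierarchy from per-expert essentiality labels:
#' a node (and its attached attributes) is retained exactly when at least one
#' expert labelled it "essential". Structure — parent links and levels — is
#' preserved; labels from all inputs are merged. The operation is idempotent.
#'
#' @param expert_hierarchies A list of `riv_hierarchy` objects sharing one
#'   attribute-catalogue namespace; labels may be spread across inputs.
#' @return The consolidated `riv_hierarchy`.
#' @details The root is always retained. If the essential set is not
#'   ancestor-closed the result would be disconnected; this is reported as an
#'   error naming the offending nodes. Conflicting parentage for one node id
#'   across experts is an error.
#' @export
consolidate <- function(expert_hierarchies) {
  if (inherits(expert_hierarchies, "riv_hierarchy")) {
    expert_hierarchies <- list(expert_hierarchies)
  }
  stopifnot(length(expert_hierarchies) >= 1L,
            all(vapply(expert_hierarchies, inherits, logical(1), "riv_hierarchy")))
  nodes <- do.call(rbind, lapply(expert_hierarchies, `[[`, "nodes"))
  # conflicting parentage check
  for (id in unique(nodes$id)) {
    p <- unique(nodes$parent[nodes$id == id])
    if (length(p) > 1L) {
      stop_riverval("conflicting parentage for node ", id, ": ",
                    paste(ifelse(is.na(p), "<root>", p), collapse = " vs "))
    }
  }
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  labels <- do.call(rbind, lapply(expert_hierarchies, `[[`, "labels"))
  labels <- labels[!duplicated(paste(labels$node_id, labels$expert)), , drop = FALSE]
  na <- do.call(rbind, lapply(expert_hierarchies, `[[`, "node_attributes"))
  na <- na[!duplicated(paste(na$node_id, na$number)), , drop = FALSE]
  cat_df <- do.call(rbind, lapply(expert_hierarchies, `[[`, "catalogue"))
  cat_df <- cat_df[!duplicated(cat_df$abbreviation), , drop = FALSE]

  essential <- unique(labels$node_id[labels$category == "essential"])
  root <- nodes$id[is.na(nodes$parent)]
  keep <- union(root, essential)
  kept <- nodes[nodes$id %in% keep, , drop = FALSE]
  orphan <- kept$id[!is.na(kept$parent) & !kept$parent %in% kept$id]
  if (length(orphan)) {
    stop_riverval("consolidation disconnects the tree at: ",
                  paste(orphan, collapse = ", "),
                  " (parent not essential for any expert)")
  }
  hierarchy(kept,
            na[na$node_id %in% kept$id, , drop = FALSE],
            cat_df,
            labels[labels$node_id %in% kept$id, , drop = FALSE])
}

#' Count objectives per hierarchy level
#'
#' @param h A `riv_hierarchy`.
#' @return A list with `counts` (named integer vector, one entry per occupied
#'   level, root excluded) and `total` (their sum).
#' @examples
#' h <- load_hierarchy(riverval_example("hierarchy_consolidated_synthetic.json"))
#' count_by_level(h)$total  # 102
#' @export
count_by_level <- function(h) {
  stopifnot(inherits(h, "riv_hierarchy"))
  lv <- h$nodes$level[!is.na(h$nodes$parent)]
  tab <- table(factor(lv, levels = sort(unique(lv))))
  counts <- stats::setNames(as.integer(tab), names(tab))
  list(counts = counts, total = sum(counts))
}

#' Renormalize sibling weights after dropping members
#'
#' When some sub-objectives of a sibling group are unavailable (missing data,
#' zero-weight exclusion), the weights of the remaining members are rescaled
#' to sum to one while preserving their proportions.
#'
#' @param sibling_weights Non-negative numeric weights of one sibling group.
#' @param available Logical vector flagging the members that remain;
#'   defaults to all.
#' @return Weights of the available members, summing to 1 within 1e-9; names
#'   are preserved.
#' @examples
#' renormalize_weights(c(0.5, 0.3, 0.2), c(TRUE, TRUE, FALSE))  # 0.625 0.375
#' @export
renormalize_weights <- function(sibling_weights,
                                available = rep(TRUE, length(sibling_weights))) {
  if (!is.numeric(sibling_weights) || anyNA(sibling_weights)) {
    stop_riverval("weights must be numeric without NA")
  }
  if (any(sibling_weights < 0)) stop_riverval("weights must be non-negative")
  if (length(available) != length(sibling_weights)) {
    stop_riverval("`available` must match the weights in length")
  }
  w <- sibling_weights[available]
  if (!length(w)) stop_riverval("no available sibling to renormalize")
  s <- sum(w)
  if (s <= 0) stop_riverval("available weights sum to 0; cannot renormalize")
  w / s
}

#' Prune zero-weight subtrees
#'
#' Experts may exclude objectives by assigning them a weight of zero; the
#' corresponding subtrees are removed and surviving sibling weights
#' renormalized.
#'
#' @param h A `riv_hierarchy`.
#' @param weights Named numeric vector: weight of each node within its
#'   sibling group, named by node id. Nodes without an entry keep weight
#'   `NA` and are never pruned.
#' @return A list with `hierarchy` (pruned) and `weights` (renormalized, for
#'   the surviving nodes that had weights).
#' @examples
#' # a level-1 pattern where only the biological branch is retained
#' @export
prune_zero_weight <- function(h, weights) {
  stopifnot(inherits(h, "riv_hierarchy"), is.numeric(weights),
            !is.null(names(weights)))
  nd <- h$nodes
  root <- nd$id[is.na(nd$parent)]
  if (!is.na(weights[root] %||% NA) && isTRUE(weights[root] == 0)) {
    stop_riverval("root weight is 0; nothing to assess")
  }
  zero <- names(weights)[!is.na(weights) & weights == 0]
  # whole sibling groups at zero are an error
  for (p in unique(nd$parent[nd$id %in% zero])) {
    sibs <- nd$id[!is.na(nd$parent) & nd$parent == p]
    sw <- weights[sibs]
    if (all(!is.na(sw) & sw == 0)) {
      stop_riverval("all siblings under ", p, " have weight 0")
    }
  }
  drop <- zero
  repeat {
    more <- nd$id[!is.na(nd$parent) & nd$parent %in% drop & !nd$id %in% drop]
    if (!length(more)) break
    drop <- c(drop, more)
  }
  kept <- nd[!nd$id %in% drop, , drop = FALSE]
  out_w <- weights[!names(weights) %in% drop]
  for (p in unique(kept$parent[!is.na(kept$parent)])) {
    sibs <- kept$id[!is.na(kept$parent) & kept$parent == p]
    sibs <- sibs[sibs %in% names(out_w) & !is.na(out_w[sibs])]
    if (length(sibs)) out_w[sibs] <- renormalize_weights(out_w[sibs])
  }
  list(
    hierarchy = hierarchy(kept,
                          h$node_attributes[h$node_attributes$node_id %in% kept$id, ,
                                            drop = FALSE],
                          h$catalogue,
                          h$labels[h$labels$node_id %in% kept$id, , drop = FALSE]),
    weights = out_w
  )
}

# children ids of `id`, in node-table order
node_children <- function(h, id) {
  h$nodes$id[!is.na(h$nodes$parent) & h$nodes$parent == id]
}

# ids of leaves (nodes with attached attributes)
leaf_ids <- function(h) {
  intersect(h$nodes$id, unique(h$node_attributes$node_id))
}

root_id <- function(h) h$nodes$id[is.na(h$nodes$parent)]
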