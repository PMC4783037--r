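test_that("packaged consolidated hierarchy is valid and round-trips", {
  h <- load_consolidated_hierarchy()
  expect_length(validate_hierarchy(h), 0)
  cl <- count_by_level(h)
  expect_identical(unname(cl$counts), c(3L, 7L, 18L, 51L, 23L))
  expect_identical(cl$total, 102L)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_hierarchy(h, tmp)
  h2 <- load_hierarchy(tmp)
  expect_equal(h2$nodes, h$nodes, ignore_attr = TRUE)
  expect_equal(h2$node_attributes, h$node_attributes, ignore_attr = TRUE)
  expect_equal(h2$catalogue$abbreviation, h$catalogue$abbreviation)
  expect_equal(h2$catalogue$worst, h$catalogue$worst)
})

test_that("a single root with one attributed leaf is a valid hierarchy", {
  nodes <- data.frame(id = c("r", "l"), name = c("root", "leaf"),
                      level = 0:1, parent = c(NA, "r"))
  cat_df <- data.frame(number = 1L, abbreviation = "a1", measure = "m",
                       unit = "u", range = "0-1", worst = 0, best = 1,
                       worst2 = NA_real_, best2 = NA_real_, discrete = FALSE,
                       levels = "", source = "expert",
                       has_value_function = TRUE, flag = "")
  h <- hierarchy(nodes, data.frame(node_id = "l", number = 1L), cat_df)
  cl <- count_by_level(h)
  expect_identical(unname(cl$counts), 1L)
  expect_identical(cl$total, 1L)
})

test_that("structural violations are reported with the offending id", {
  nodes <- data.frame(id = c("r", "x"), name = c("r", "x"), level = 0:1,
                      parent = c(NA, "ghost"))
  expect_error(hierarchy(nodes), "dangling parent.*ghost")

  nodes2 <- data.frame(id = c("r", "x", "x"), name = "n", level = c(0, 1, 1),
                       parent = c(NA, "r", "r"))
  expect_error(hierarchy(nodes2), "duplicate id: x")

  # leaf without attributes (and not flagged non-assessable)
  nodes3 <- data.frame(id = c("r", "x"), name = "n", level = 0:1,
                       parent = c(NA, "r"))
  expect_error(hierarchy(nodes3), "leaf without attributes: x")

  # unknown attribute number
  nodes4 <- data.frame(id = c("r", "x"), name = "n", level = 0:1,
                       parent = c(NA, "r"))
  expect_error(hierarchy(nodes4, data.frame(node_id = "x", number = 99L)),
               "unknown attribute number: 99")
})

test_that("consolidation keeps exactly the nodes essential for >= 1 expert", {
  mk <- function(labels) {
    nodes <- data.frame(
      id = c("r", "a", "b", "c"), name = c("r", "a", "b", "c"),
      level = c(0L, 1L, 1L, 1L), parent = c(NA, "r", "r", "r"))
    cat_df <- data.frame(number = 1:3, abbreviation = paste0("x", 1:3),
                         measure = "m", unit = "u", range = "0-1",
                         worst = 0, best = 1, worst2 = NA_real_,
                         best2 = NA_real_, discrete = FALSE, levels = "",
                         source = "expert", has_value_function = TRUE,
                         flag = "")
    hierarchy(nodes, data.frame(node_id = c("a", "b", "c"), number = 1:3),
              cat_df, labels)
  }
  # a: essential for one expert only; b: never essential; c: unlabelled
  h1 <- mk(data.frame(node_id = c("a", "b"), expert = "e1",
                      category = c("essential", "desirable")))
  h2 <- mk(data.frame(node_id = c("a", "b"), expert = "e2",
                      category = c("very_valuable", "very_valuable")))
  cons <- consolidate(list(h1, h2))
  expect_setequal(cons$nodes$id, c("r", "a"))
  expect_setequal(cons$node_attributes$number, 1L)
  # idempotent
  cons2 <- consolidate(cons)
  expect_equal(cons2$nodes, cons$nodes, ignore_attr = TRUE)
  # conflicting parentage across experts is an error
  h3 <- h2
  h3$nodes$parent[h3$nodes$id == "b"] <- "a"
  h3$nodes$level[h3$nodes$id == "b"] <- 2L
  expect_error(consolidate(list(h1, h3)), "conflicting parentage for node b")
})

test_that("weight renormalization preserves proportions and scale invariance", {
  expect_equal(renormalize_weights(c(0.5, 0.3, 0.2), c(TRUE, TRUE, FALSE)),
               c(0.625, 0.375))
  expect_equal(renormalize_weights(c(0.5, 0.3, 0.2)), c(0.5, 0.3, 0.2))
  expect_equal(renormalize_weights(c(0.0, 1.0), c(FALSE, TRUE)), 1.0)
  expect_error(renormalize_weights(c(0.3, 0.7), c(FALSE, FALSE)),
               "no available sibling")
  expect_error(renormalize_weights(c(0, 0.5), c(TRUE, FALSE)), "sum to 0")
  set.seed(42)
  for (i in 1:20) {
    w <- runif(sample(2:6, 1))
    avail <- runif(length(w)) > 0.3
    if (!any(avail) || sum(w[avail]) == 0) next
    r <- renormalize_weights(w, avail)
    expect_equal(sum(r), 1, tolerance = 1e-9)
    expect_equal(r, renormalize_weights(w * 7.3, avail), tolerance = 1e-12)
  }
})

test_that("zero-weight subtrees are pruned and survivors renormalized", {
  h <- toy_hierarchy()
  # the published level-1 pattern: all weight on one branch
  res <- prune_zero_weight(h, c(nodeA = 0, nodeB = 1))
  expect_setequal(res$hierarchy$nodes$id, c("root", "nodeB", "leaf3"))
  expect_equal(unname(res$weights["nodeB"]), 1)
  # all weights positive: identity
  res2 <- prune_zero_weight(h, c(nodeA = 0.6, nodeB = 0.4))
  expect_setequal(res2$hierarchy$nodes$id, h$nodes$id)
  expect_error(prune_zero_weight(h, c(nodeA = 0, nodeB = 0)),
               "all siblings under root")
  expect_error(prune_zero_weight(h, c(root = 0)), "root weight is 0")
})

test_that("count_by_level totals equal node count minus root on generated trees", {
  for (seed in 1:5) {
    spec <- generator_spec(level_counts = c(2, 4, 7), seed = seed)
    h <- generate_hierarchy(spec)
    cl <- count_by_level(h)
    expect_identical(unname(cl$counts), c(2L, 4L, 7L))
    expect_identical(cl$total, nrow(h$nodes) - 1L)
  }
})
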