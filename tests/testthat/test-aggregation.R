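test_that("additive aggregation is the weighted mean", {
  expect_equal(aggregate_additive(c(0.5, 0.5, 0.5), c(0.2, 0.3, 0.5)), 0.5)
  # published level-1 weights of the fish expert
  expect_equal(aggregate_additive(c(0.8, 0.6, 0.9), c(0.32, 0.23, 0.45)), 0.799)
  v <- c(0.1, 0.9, 0.4)
  expect_equal(aggregate_additive(v, rep(1 / 3, 3)), mean(v))
  expect_error(aggregate_additive(c(0.5, 0.5), c(0.5, 0.4)), "sum to 1")
  expect_error(aggregate_additive(c(0.5), c(0.5, 0.5)), "length mismatch")
})

test_that("minimum aggregation reflects only the worst sub-objective", {
  expect_equal(aggregate_minimum(c(0.2, 0.9, 0.7)), 0.2)
  expect_equal(aggregate_minimum(rep(0.4, 5)), 0.4)
  # improving a non-minimal input changes nothing
  expect_equal(aggregate_minimum(c(0.2, 0.95, 0.7)), 0.2)
  expect_error(aggregate_minimum(numeric()), "non-empty")
})

test_that("multiplicative aggregation matches the synergy-score formula", {
  w <- c(0.5, 0.5)
  # raw score 0.5 normalized by the all-ones raw score 1.125
  expect_equal(aggregate_multiplicative(c(1, 0), w, k = 0.5), 0.5 / 1.125)
  expect_equal(aggregate_multiplicative(c(0, 0), w, k = 0.25), 0)
  expect_equal(aggregate_multiplicative(c(1, 1), w, k = 0.25), 1)
  # k = 1 means no synergy: dispatches to the additive model exactly
  set.seed(3)
  for (i in 1:10) {
    n <- sample(2:5, 1)
    v <- runif(n)
    ww <- runif(n); ww <- ww / sum(ww)
    expect_identical(aggregate_multiplicative(v, ww, k = 1),
                     aggregate_additive(v, ww))
  }
  expect_error(aggregate_multiplicative(c(0.5, 0.5), w, k = 0), "in \\(0, 1\\]")
  expect_error(aggregate_multiplicative(c(0.5, 0.5), w, k = 1.5), "in \\(0, 1\\]")
})

test_that("mixed additive-minimum aggregation interpolates its limits", {
  w <- c(0.5, 0.5)
  expect_equal(aggregate_mixed(c(1, 0), w, alpha = 1), 0.5)
  expect_equal(aggregate_mixed(c(1, 0), w, alpha = 0), 0)
  expect_equal(aggregate_mixed(c(1, 0), w, alpha = 0.5), 0.25)
  expect_error(aggregate_mixed(c(1, 0), w, alpha = 1.2), "\\[0, 1\\]")
})

test_that("aggregators are idempotent on constant inputs (mult k<1 dips)", {
  grid <- seq(0, 1, by = 0.05)
  w <- c(0.3, 0.3, 0.4)
  for (v in grid) {
    vv <- rep(v, 3)
    expect_equal(aggregate_additive(vv, w), v)
    expect_equal(aggregate_minimum(vv), v)
    expect_equal(aggregate_mixed(vv, w, alpha = 0.4), v)
    m <- aggregate_multiplicative(vv, w, k = 0.25)
    expect_lte(m, v + 1e-12)
    if (v > 0 && v < 1) expect_lt(m, v)
  }
})

test_that("all aggregators are monotone in every input", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(2:5, 1)
    v <- runif(n)
    w <- runif(n); w <- w / sum(w)
    k <- sample(c(0.25, 0.5, 0.75, 1), 1)
    alpha <- runif(1)
    j <- sample(n, 1)
    v2 <- v
    v2[j] <- min(1, v[j] + runif(1, 0, 1 - v[j]))
    expect_gte(aggregate_additive(v2, w), aggregate_additive(v, w) - 1e-12)
    expect_gte(aggregate_minimum(v2), aggregate_minimum(v) - 1e-12)
    expect_gte(aggregate_multiplicative(v2, w, k),
               aggregate_multiplicative(v, w, k) - 1e-12)
    expect_gte(aggregate_mixed(v2, w, alpha), aggregate_mixed(v, w, alpha) - 1e-12)
  }
})

test_that("multiplicative (k<1) is bounded above by additive on a grid", {
  w <- c(0.4, 0.6)
  g <- seq(0, 1, by = 0.05)
  for (k in c(0.25, 0.5, 0.75)) {
    for (v1 in g) for (v2 in g) {
      v <- c(v1, v2)
      m <- aggregate_multiplicative(v, w, k)
      expect_lte(m, aggregate_additive(v, w) + 1e-12)
      # with a zero child the synergy score still dominates the minimum
      if (min(v) == 0) expect_gte(m, 0)
    }
  }
  # the synergy model is not bounded below by the minimum on near-constant
  # inputs: uniformly mediocre children are not rescued
  expect_lt(aggregate_multiplicative(c(0.5, 0.5), c(0.5, 0.5), 0.5), 0.5)
})

test_that("zero-weight children never influence the aggregate", {
  w <- c(0.5, 0.5, 0)
  for (k in c(0.25, 0.5, 1)) {
    expect_equal(aggregate_multiplicative(c(0.3, 0.8, 0.1), w, k),
                 aggregate_multiplicative(c(0.3, 0.8, 0.99), w, k))
  }
  expect_equal(aggregate_additive(c(0.3, 0.8, 0.1), w),
               aggregate_additive(c(0.3, 0.8, 0.99), w))
})

test_that("rollup equals hand-composed nested aggregation on the toy tree", {
  h <- toy_hierarchy()
  m <- toy_model()
  st <- toy_state(c(0.8, 0.4, 0.9))
  res <- rollup(h, st, m)
  vA <- aggregate_multiplicative(c(0.8, 0.4), c(0.7, 0.3), k = 0.5)
  vB <- 0.9
  expect_equal(unname(res$node_values["nodeA"]), vA)
  expect_equal(res$root_value, aggregate_additive(c(vA, vB), c(0.6, 0.4)))
  expect_equal(res$root_utility, res$root_value)  # risk-neutral default
})

test_that("all-best measurements give value 1 at every node", {
  h <- toy_hierarchy()
  m <- toy_model()
  res <- rollup(h, toy_state(c(1, 1, 1)), m)
  expect_true(all(abs(res$node_values - 1) < 1e-12))
})

test_that("missing leaves trigger weight renormalization with provenance", {
  h <- toy_hierarchy()
  m <- toy_model()
  st <- toy_state(c(0.8, NA, 0.9))
  res <- rollup(h, st, m)
  # leaf2 missing: nodeA keeps only leaf1 with weight renormalized to 1
  expect_equal(unname(res$node_values["nodeA"]),
               aggregate_multiplicative(0.8, 1, k = 0.5))
  expect_true(any(res$provenance$event == "renormalized"))
  expect_true(is.na(res$node_values["leaf2"]))
  # all leaves missing: root not assessable
  expect_error(rollup(h, toy_state(c(NA, NA, NA)), m), "root objective is missing")
})

test_that("rollup matches the independent recursive oracle on generated fixtures", {
  for (seed in 1:8) {
    spec <- generator_spec(level_counts = c(2, 4, 6), missingness = 0.15,
                           seed = seed)
    h <- generate_hierarchy(spec)
    pref <- generate_preferences(spec, h)
    st <- generate_states(h, 3, missingness = 0.15, seed = seed + 100)
    for (s in unique(st$state)) {
      sub <- st[st$state == s, ]
      got <- rollup(h, sub, pref$model)
      expect_equal(got$root_value, oracle_eval(h, sub, pref$model),
                   tolerance = 1e-12)
    }
  }
})
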