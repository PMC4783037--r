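test_that("identical spec and seed give identical artifacts", {
  spec <- generator_spec(level_counts = c(3, 5, 8), seed = 9)
  h1 <- generate_hierarchy(spec)
  h2 <- generate_hierarchy(spec)
  expect_identical(h1, h2)
  p1 <- generate_preferences(spec, h1)
  p2 <- generate_preferences(spec, h2)
  expect_identical(p1$true_shapes, p2$true_shapes)
  expect_identical(p1$methods, p2$methods)
  s1 <- generate_states(h1, 3, missingness = 0.2, seed = 4)
  s2 <- generate_states(h1, 3, missingness = 0.2, seed = 4)
  expect_identical(s1, s2)
  # written documents are byte-identical
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_hierarchy(h1, f1); write_hierarchy(h2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generated hierarchies have exact level counts and pass validation", {
  spec <- generator_spec(seed = 1)  # default emulated shape 3/7/18/51/23
  h <- generate_hierarchy(spec)
  cl <- count_by_level(h)
  expect_identical(unname(cl$counts), c(3L, 7L, 18L, 51L, 23L))
  expect_length(validate_hierarchy(h), 0)
  # single-branch tree
  h1 <- generate_hierarchy(generator_spec(level_counts = 1, seed = 3))
  expect_identical(count_by_level(h1)$total, 1L)
  # every leaf carries at least one attribute with a usable range
  expect_setequal(riverval:::leaf_ids(h), unique(h$node_attributes$node_id))
})

test_that("generation frequencies converge to the spec targets", {
  # 99% binomial CI: |phat - p| <= 2.576 sqrt(p(1-p)/n)
  ci <- function(p, n) 2.576 * sqrt(p * (1 - p) / n)

  spec <- generator_spec(level_counts = c(5, 500), pct_nonlinear = 0.8,
                         pct_multiplicative = 0.76, seed = 11)
  h <- generate_hierarchy(spec)
  pref <- generate_preferences(spec, h)
  shapes <- pref$true_shapes
  phat <- mean(shapes == "nonlinear")
  expect_lt(abs(phat - 0.8), ci(0.8, length(shapes)))

  mhat <- mean(pref$methods == "multiplicative")
  expect_lt(abs(mhat - 0.76), ci(0.76, length(pref$methods)))

  ks <- pref$synergies[!is.na(pref$synergies)]
  expect_true(all(ks %in% c(0.25, 0.5, 0.75, 1)))

  st <- generate_states(h, 5, missingness = 0.2, seed = 12)
  miss <- mean(is.na(st$level))
  expect_lt(abs(miss - 0.2), ci(0.2, nrow(st)))
})

test_that("zero targets are honoured by construction", {
  spec <- generator_spec(level_counts = c(3, 20), pct_nonlinear = 0,
                         pct_multiplicative = 0, seed = 8)
  h <- generate_hierarchy(spec)
  pref <- generate_preferences(spec, h)
  shapes <- vapply(pref$model$value_functions, classify_shape, character(1))
  expect_true(all(shapes == "linear"))
  expect_true(all(pref$methods == "additive"))
  st <- generate_states(h, 3, missingness = 0, seed = 2)
  expect_false(anyNA(st$level))
  res <- rollup(h, st[st$state == "state001", ], pref$model)
  expect_false(any(res$provenance$event == "renormalized"))
  expect_equal(generate_states(h, 0, seed = 1),
               data.frame(state = character(), attribute = integer(),
                          level = numeric(), stringsAsFactors = FALSE))
})

test_that("risk profiles classify as constructed at all probe states", {
  for (profile in c("averse", "prone")) {
    spec <- generator_spec(level_counts = c(2, 2), risk_profile = profile,
                           n_experts = 10, seed = 13)
    h <- generate_hierarchy(spec)
    pref <- generate_preferences(spec, h)
    for (ce in pref$ce_sets) {
      u <- utility_from_ce(ce)
      for (p in c(0.25, 0.5, 0.75)) {
        expect_identical(classify_risk(u, p), profile)
      }
    }
  }
  # mixed: averse at the poor and good state, prone at the moderate state
  spec <- generator_spec(level_counts = c(2, 2), risk_profile = "mixed",
                         n_experts = 10, seed = 14)
  h <- generate_hierarchy(spec)
  pref <- generate_preferences(spec, h)
  for (ce in pref$ce_sets) {
    u <- utility_from_ce(ce)
    expect_identical(classify_risk(u, 0.25), "averse")
    expect_identical(classify_risk(u, 0.5), "prone")
    expect_identical(classify_risk(u, 0.75), "averse")
  }
})

test_that("noiseless transcripts reconstruct the generating preferences", {
  # value function: anchors recovered exactly
  true_vf <- construct_from_bisection(0, 2000, c("0.25" = 80, "0.5" = 300,
                                                 "0.75" = 900))
  tr <- generate_bisection_responses(true_vf, noise_sd = 0, seed = 5)
  expect_equal(unname(tr$mid_levels["0.5"]), 300)
  rec <- construct_from_bisection(tr$x_worst, tr$x_best, tr$mid_levels)
  for (p in c(0.25, 0.5, 0.75)) {
    expect_equal(invert_vf(rec, p), invert_vf(true_vf, p))
  }
  xs <- seq(0, 2000, length.out = 50)
  expect_equal(evaluate_vf(rec, xs), evaluate_vf(true_vf, xs))
  # weights: swing scores proportional to true weights recover them
  w <- c(0.45, 0.23, 0.32)
  scores <- 100 * w / max(w)
  expect_equal(swing_weights(scores), w, tolerance = 1e-12)
  # CE anchors: reconstruction from the induced utility is exact
  ce <- ce_points(0.2, 0.45, 0.7)
  u <- utility_from_ce(ce)
  rec_ce <- ce_points(invert_utility(u, 0.25), invert_utility(u, 0.5),
                      invert_utility(u, 0.75))
  expect_equal(rec_ce$x25, 0.2)
  expect_equal(rec_ce$x50, 0.45)
  expect_equal(rec_ce$x75, 0.7)
})

test_that("recovery error is non-decreasing in elicitation noise", {
  true_vf <- construct_from_bisection(0, 100, c("0.5" = 20))
  err <- vapply(c(0, 2, 10), function(sd) {
    errs <- vapply(1:60, function(r) {
      tr <- generate_bisection_responses(true_vf, noise_sd = sd,
                                         seed = 1000 + r)
      rec <- construct_from_bisection(tr$x_worst, tr$x_best, tr$mid_levels)
      abs(invert_vf(rec, 0.5) - 20)
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(err) >= 0))
})
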