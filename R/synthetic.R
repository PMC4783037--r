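#' Generator specification for synthetic study fixtures
#'
#' Seeded generators produce hierarchies, expert preference sets and river
#' states with the statistical structure the analysis layer assumes, so that
#' every stage can be exercised without external data. The defaults emulate
#' the elicited study conditions: a five-level hierarchy with per-level node
#' counts 3/7/18/51/23, six experts, 81% non-linear value functions, 76%
#' multiplicative aggregation choices, synergy factors drawn from
#' \{0.25, 0.5, 0.75, 1\}, and risk attitudes that are averse or prone but
#' not neutral.
#'
#' @param level_counts Positive integers, nodes per level (root excluded).
#' @param n_experts Number of synthetic experts.
#' @param pct_nonlinear Probability that a generated continuous value
#'   function is non-linear (mid-value point displaced >= 0.1 from the
#'   chord, well above the 0.02 classification tolerance, so generated
#'   labels are unambiguous).
#' @param pct_multiplicative Probability that an aggregation choice is
#'   multiplicative.
#' @param synergy_probs Named probabilities over the assessed synergy levels.
#' @param risk_profile `"averse"`, `"prone"` or `"mixed"` (averse at the
#'   poor and good state, prone at the moderate state).
#' @param missingness Fraction of measurements missing in generated states.
#' @param seed Mandatory integer seed; identical spec + seed gives
#'   byte-identical output.
#' @return An `riv_generator_spec`.
#' @export
generator_spec <- function(level_counts = c(3L, 7L, 18L, 51L, 23L),
                           n_experts = 6L,
                           pct_nonlinear = 0.81,
                           pct_multiplicative = 0.76,
                           synergy_probs = c("0.25" = 0.25, "0.5" = 0.25,
                                             "0.75" = 0.25, "1" = 0.25),
                           risk_profile = c("mixed", "averse", "prone"),
                           missingness = 0.1,
                           seed) {
  risk_profile <- match.arg(risk_profile)
  if (missing(seed)) stop_riverval("`seed` is mandatory")
  if (!is.numeric(level_counts) || any(level_counts < 1)) {
    stop_riverval("level counts must be positive")
  }
  for (p in c(pct_nonlinear, pct_multiplicative, missingness)) {
    if (!is_number(p) || p < 0 || p > 1) stop_riverval("probabilities must lie in [0, 1]")
  }
  if (abs(sum(synergy_probs) - 1) > 1e-9 || any(synergy_probs < 0)) {
    stop_riverval("synergy_probs must be a probability distribution")
  }
  structure(list(level_counts = as.integer(level_counts),
                 n_experts = as.integer(n_experts),
                 pct_nonlinear = pct_nonlinear,
                 pct_multiplicative = pct_multiplicative,
                 synergy_probs = synergy_probs,
                 risk_profile = risk_profile,
                 missingness = missingness,
                 seed = as.integer(seed)),
            class = "riv_generator_spec")
}

#' Generate a synthetic objectives hierarchy
#'
#' Per-level node counts equal the spec exactly; each node of level l + 1
#' draws its parent uniformly from level l, so some nodes of intermediate
#' levels end up as leaves (as in the elicited hierarchy, where lowest-level
#' objectives sit on several levels). Every leaf receives one attribute with
#' a randomized range of increasing, decreasing or unimodal orientation.
#'
#' @param spec A [generator_spec()].
#' @return A validated `riv_hierarchy`.
#' @export
generate_hierarchy <- function(spec) {
  stopifnot(inherits(spec, "riv_generator_spec"))
  with_seed(spec$seed, {
    lc <- spec$level_counts
    nodes <- data.frame(id = "root", name = "overall objective", level = 0L,
                        parent = NA_character_, non_assessable = FALSE,
                        stringsAsFactors = FALSE)
    prev <- "root"
    for (l in seq_along(lc)) {
      ids <- sprintf("n%d_%d", l, seq_len(lc[l]))
      parents <- if (length(prev) == 1L) rep(prev, lc[l]) else
        sample(prev, lc[l], replace = TRUE)
      # every parent level must be reachable
      if (!length(prev)) stop_riverval("infeasible level counts: empty level ", l - 1)
      nodes <- rbind(nodes, data.frame(
        id = ids, name = paste("objective", ids), level = l, parent = parents,
        non_assessable = FALSE, stringsAsFactors = FALSE))
      prev <- ids
    }
    leaves <- nodes$id[!nodes$id %in% nodes$parent]
    orient <- sample(c("increasing", "decreasing", "unimodal"), length(leaves),
                     replace = TRUE, prob = c(0.55, 0.30, 0.15))
    lo <- round(stats::runif(length(leaves), 0, 50), 1)
    span <- round(stats::runif(length(leaves), 5, 100), 1)
    cat_rows <- lapply(seq_along(leaves), function(i) {
      w <- lo[i]; b <- lo[i] + span[i]
      row <- data.frame(number = i, abbreviation = paste0("attr", i),
                        measure = paste("synthetic indicator", i), unit = "unit",
                        range = "", worst = w, best = b,
                        worst2 = NA_real_, best2 = NA_real_,
                        discrete = FALSE, levels = "", source = "expert",
                        has_value_function = TRUE, flag = "",
                        stringsAsFactors = FALSE)
      if (orient[i] == "decreasing") {
        row$worst <- b; row$best <- w
        row$range <- paste0(b, "-", w)
      } else if (orient[i] == "unimodal") {
        row$worst2 <- b + span[i]; row$best2 <- b
        row$range <- paste0(w, "-", b, " // ", b + span[i], "-", b)
      } else {
        row$range <- paste0(w, "-", b)
      }
      row
    })
    hierarchy(nodes,
              data.frame(node_id = leaves, number = seq_along(leaves),
                         stringsAsFactors = FALSE),
              do.call(rbind, cat_rows))
  })
}

# draw one value function for a catalogue row; nonlinear mid-value point is
# displaced by 0.15-0.35 on the value scale (>= 0.1 from the chord)
draw_vf <- function(row, nonlinear, source = "expert") {
  mk <- function(w, b) {
    if (nonlinear) {
      d <- stats::runif(1, 0.15, 0.35) * sample(c(-1, 1), 1)
      p <- 0.5 + d
      mid <- w + p * (b - w)
      construct_from_bisection(w, b, c("0.5" = mid), source = source)
    } else {
      construct_from_bisection(w, b, source = source)
    }
  }
  if (!is.na(row$worst2)) {
    vf1 <- mk(row$worst, row$best)
    vf2 <- mk(row$worst2, row$best2)
    p1 <- vf1$points; p1$limb <- 1L
    p2 <- vf2$points; p2$limb <- 2L
    vf <- value_function(rbind(p1, p2), attribute = row$number, source = source,
                         orientation = "unimodal")
  } else {
    vf <- mk(row$worst, row$best)
    vf$attribute <- row$number
  }
  vf
}

#' Generate a synthetic expert preference set
#'
#' Draws, for a given hierarchy: one value function per attribute (shape
#' non-linear with probability `pct_nonlinear`), per-internal-node
#' aggregation choices (multiplicative with probability
#' `pct_multiplicative`, synergy factor from the spec's distribution,
#' otherwise additive), weights from a flat simplex (symmetric Dirichlet),
#' and per-expert certainty-equivalent points following the risk profile.
#'
#' @param spec A [generator_spec()].
#' @param h A `riv_hierarchy` (typically from [generate_hierarchy()]).
#' @return A list (`riv_preference_fixture`): `model`
#'   ([assessment_model()]), `true_shapes` (named, `"linear"`/`"nonlinear"`
#'   per attribute), `methods` (named, per internal node), `synergies`,
#'   `ce_sets` (list of [ce_points()]), `utility`.
#' @export
generate_preferences <- function(spec, h) {
  stopifnot(inherits(spec, "riv_generator_spec"), inherits(h, "riv_hierarchy"))
  with_seed(spec$seed + 1L, {
    cat_df <- h$catalogue
    nonlin <- stats::runif(nrow(cat_df)) < spec$pct_nonlinear
    vfs <- lapply(seq_len(nrow(cat_df)), function(i) {
      draw_vf(cat_df[i, ], nonlin[i])
    })
    true_shapes <- stats::setNames(ifelse(nonlin, "nonlinear", "linear"),
                                   cat_df$abbreviation)
    internal <- h$nodes$id[h$nodes$id %in% h$nodes$parent]
    mult <- stats::runif(length(internal)) < spec$pct_multiplicative
    synergies <- stats::setNames(rep(NA_real_, length(internal)), internal)
    agg <- stats::setNames(vector("list", length(internal)), internal)
    for (i in seq_along(internal)) {
      kids <- node_children(h, internal[i])
      w <- stats::rexp(length(kids))
      w <- stats::setNames(w / sum(w), kids)
      if (mult[i]) {
        k <- as.numeric(sample(names(spec$synergy_probs), 1,
                               prob = spec$synergy_probs))
        synergies[internal[i]] <- k
        agg[[internal[i]]] <- aggregation_spec("multiplicative", weights = w, k = k)
      } else {
        agg[[internal[i]]] <- aggregation_spec("additive", weights = w)
      }
    }
    draw_ce <- function(profile, expert) {
      d <- stats::runif(3, 0.05, 0.12)
      x <- switch(profile,
        averse = c(0.25, 0.5, 0.75) - d,
        prone = c(0.25, 0.5, 0.75) + d,
        mixed = c(0.25 - d[1], 0.5 + d[2] * 0.8, 0.75 - d[3] * 0.5)
      )
      x <- sort(pmin(pmax(x, 0.02), 0.98))
      ce_points(x[1], x[2], x[3], expert = expert)
    }
    ce_sets <- lapply(seq_len(spec$n_experts), function(e) {
      draw_ce(spec$risk_profile, paste0("expert", e))
    })
    utility <- utility_from_ce(ce_sets[[1]])
    list(model = assessment_model(vfs, agg, utility),
         true_shapes = true_shapes,
         methods = stats::setNames(ifelse(mult, "multiplicative", "additive"),
                                   internal),
         synergies = synergies,
         ce_sets = ce_sets,
         utility = utility)
  })
}

#' Generate synthetic river states
#'
#' Each measurement is drawn uniformly within its attribute's declared range
#' (over both limbs for unimodal attributes); a fraction of about
#' `missingness` of the measurements is marked missing. All states remain
#' evaluable by [rollup()] provided at least one leaf survives.
#'
#' @param h A `riv_hierarchy`.
#' @param n Number of states.
#' @param missingness Missing fraction in \[0, 1\].
#' @param seed Integer seed.
#' @return A long data frame: `state`, `attribute`, `level` (`NA` =
#'   missing).
#' @export
generate_states <- function(h, n, missingness = 0, seed) {
  stopifnot(inherits(h, "riv_hierarchy"))
  if (n == 0) {
    return(data.frame(state = character(), attribute = integer(),
                      level = numeric(), stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    cat_df <- h$catalogue
    out <- do.call(rbind, lapply(seq_len(n), function(s) {
      lev <- vapply(seq_len(nrow(cat_df)), function(i) {
        r <- cat_df[i, ]
        dom <- range(c(r$worst, r$best, r$worst2, r$best2), na.rm = TRUE)
        stats::runif(1, dom[1], dom[2])
      }, numeric(1))
      miss <- stats::runif(nrow(cat_df)) < missingness
      lev[miss] <- NA_real_
      data.frame(state = sprintf("state%03d", s), attribute = cat_df$number,
                 level = lev, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate a bisection elicitation transcript
#'
#' Simulates an expert answering bisection questions for a known monotone
#' value function: the answer for target value p is the true level
#' `invert_vf(true_vf, p)` plus Gaussian noise on the attribute scale,
#' clipped to the range and re-monotonized. With zero noise,
#' [construct_from_bisection()] applied to the transcript reproduces the
#' true function exactly at all elicited values.
#'
#' @param true_vf A monotone continuous `riv_value_function`.
#' @param noise_sd Noise standard deviation on the attribute scale.
#' @param seed Integer seed.
#' @param values Target values to elicit (interior grid points).
#' @return List with `x_worst`, `x_best`, `responses` (data frame `value`,
#'   `level`, endpoints included) and `mid_levels` (named vector ready for
#'   [construct_from_bisection()]).
#' @export
generate_bisection_responses <- function(true_vf, noise_sd = 0, seed,
                                         values = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(true_vf, "riv_value_function"))
  if (length(unique(true_vf$points$limb)) > 1L) {
    stop_riverval("transcripts are generated per monotone limb")
  }
  with_seed(seed, {
    p <- true_vf$points[order(true_vf$points$v), , drop = FALSE]
    x_worst <- p$x[1]; x_best <- p$x[nrow(p)]
    lo <- min(x_worst, x_best); hi <- max(x_worst, x_best)
    values <- sort(values)
    ans <- invert_vf(true_vf, values) + stats::rnorm(length(values), 0, noise_sd)
    eps <- (hi - lo) * 1e-6
    ans <- pmin(pmax(ans, lo + eps), hi - eps)
    ans <- sort(ans, decreasing = x_worst > x_best)
    # clipping can tie answers at the range ends; spread ties minimally so the
    # transcript stays strictly monotone, keeping every answer inside (lo, hi)
    n <- length(ans)
    s <- if (x_worst < x_best) 1 else -1
    for (i in seq_len(n)[-1]) {
      if (s * (ans[i] - ans[i - 1]) <= 0) ans[i] <- ans[i - 1] + s * eps
    }
    for (i in rev(seq_len(n))) {
      # keep the i-th answer strictly inside the range, leaving room for the
      # answers above it
      bound <- if (s > 0) hi - eps * (n - i + 1) else lo + eps * (n - i + 1)
      if (s * (ans[i] - bound) > 0) ans[i] <- bound
    }
    mid_levels <- stats::setNames(ans, values)
    list(x_worst = x_worst, x_best = x_best,
         responses = data.frame(value = c(0, values, 1),
                                level = c(x_worst, ans, x_best)),
         mid_levels = mid_levels)
  })
}
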