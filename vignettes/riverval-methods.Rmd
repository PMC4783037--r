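---
title: "Hierarchical multi-attribute value and utility assessment of river ecological state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical multi-attribute value and utility assessment of river ecological state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverval)
```

## The assessment model

`riverval` implements multi-attribute value/utility theory (MAVT/MAUT) for
assessing the ecological state of a river reach. The overall objective —
a good ecological state — is decomposed into an objectives hierarchy: three
level-1 branches (physical, chemical, biological state) subdivide over up to
five levels into lowest-level objectives, each quantified by one or more
measurable attributes (fish counts, water temperature, sediment transport,
...). Assessment proceeds bottom-up:

1. **Value functions** translate each attribute level $x$ to a value
   $v(x) \in [0,1]$, where 0 is the worst-possible and 1 the best-possible
   (reference) state of the reach. The reference is the best state achievable
   by an optimal rehabilitation measure under fixed constraints (towns,
   roads, agriculture), not a pristine state.
2. **Aggregation** combines child values into parent values, level by level,
   up to the root.
3. Optionally, a **utility function** transforms the root value to account
   for the assessor's risk attitude under uncertain outcomes.

### Value functions

Value functions are elicited by the bisection method: the mid-value level
$x_{0.5}$ splits the worst-to-best improvement into two equally valued
halves, then $x_{0.25}$ and $x_{0.75}$ (optionally $x_{0.1}$, $x_{0.9}$)
refine each half. The elicited grid $\{0, 0.1, 0.25, 0.5, 0.75, 0.9, 1\}$ is
the default in `construct_from_bisection()`.

Between anchors we interpolate **piecewise linearly**. The elicitation
protocol fixes anchor points, not a parametric family; piecewise-linear
interpolation reproduces every anchor exactly and is monotone by
construction. Experts describing "asymptotic" preferences may intend smooth
curves; with anchors at five or more values the difference to a smooth
interpolant is below the elicitation resolution, and we deliberately do not
guess a functional form.

Orientations: *increasing* (more is better), *decreasing* (the numerically
smaller level is best, e.g. maximum summer temperature with range 24–10 °C),
and *unimodal* (an ecological optimum flanked by two monotone limbs, written
`"0-7 // 14-7"`: value 0 at 0 and at 14, value 1 at the shared peak 7).
Orientation is inferred from the worst/best ordering of the range — the
tables encode direction implicitly by printing the worst level first.
Two-limb ranges whose printed limbs peak at unequal levels (three records in
the packaged catalogue, e.g. `1-3 // 20-5`) cannot be resolved into a single
peak from the printed information; the catalogue stores both limbs verbatim
and flags the records `unequal_peaks` for review, and `build_unimodal()`
refuses them.

Class-valued protocols (e.g. five quality classes from bad to very good) are
mapped to $[0,1]$ by `from_class_scheme()`: $n$ equal-width bands, a class
represented by its band midpoint, the best class in the top band (best of
five $\to$ 0.9).

**Shape classification.** A continuous function counts as *linear* when
every interior anchor deviates vertically from the endpoint chord by at most
`tol` (per limb for unimodal functions). The elicitation itself provides no
threshold — attitudes are reported qualitatively — so the default is
`tol = 0.02` on the value scale, below any visually distinguishable
curvature in published preference curves and well below the 0.1 displacement
the synthetic generator uses for functions it labels non-linear, so
generated labels are unambiguous.

### Aggregation

Four models are implemented (`aggregate_*()`), with weights $w_i \ge 0$,
$\sum_i w_i = 1$ local to each sibling group:

* **additive** — $f_{add} = \sum_i w_i v_i$: the weighted arithmetic mean;
  full compensation between sub-objectives.
* **minimum** — $f_{min} = \min_i v_i$ (one-out-all-out): no compensation;
  only the worst sub-objective matters.
* **multiplicative** — a synergy-factor model. The raw score is
  $r(v) = \big(\prod_i (k\,w_i v_i + 1) - 1\big)/k$ with synergy factor
  $k \in (0,1]$; the reported value is $r(v)/r(\mathbf{1})$, so the result
  is 0 at all-zero and 1 at all-one inputs. Elicited synergy levels are
  0.25 (large synergy), 0.5 (medium), 0.75 (small) and 1 (no synergy);
  the engine accepts any $k \in (0,1]$.
* **mixed** — $\alpha f_{add} + (1-\alpha) f_{min}$, a compromise that keeps
  some sensitivity to the worst child while rewarding improvements
  elsewhere.

Two numerical decisions deserve note. First, the printed synergy-product
formula does not algebraically reduce to the additive model at $k = 1$, yet
$k = 1$ is defined as "no synergy = additive"; we honour the stated
semantics by dispatching $k = 1$ to the additive model exactly and using the
normalized product only for $k < 1$. The product's typography is read as
$(\prod_i [\,\cdot\,] - 1)/k$; alternative readings fail the $[0,1]$
contract more badly and are not implemented. Second, the normalized synergy
model is *sub-idempotent*: $f_{mult}(v,\dots,v) < v$ on $(0,1)$ for
$k < 1$. A consequence is that the often-quoted ordering
$f_{min} \le f_{mult} \le f_{add}$ holds in its upper half everywhere but
fails against the minimum on near-constant inputs — the model penalizes
profiles that are not jointly good, it does not rescue uniformly mediocre
ones. The test suite asserts exactly the valid directions.

`synergy_demo()` reproduces the illustration used to discuss synergy with
assessors: raising all $n$ objectives together versus raising one at a time
and summing; for $k < 1$ the one-at-a-time curve ends strictly below 1.
Both normalized and raw curves are returned, since the illustration's
summed construction is most natural on the raw score.

### Missing data and the roll-up

Redundant attributes are a feature of ecological assessment: if an attribute
is unmeasured, the assessment still proceeds with the weights of the
remaining siblings renormalized to sum 1 (`renormalize_weights()`,
proportions preserved). `rollup()` applies this at every level, logs each
renormalization in a provenance table, marks nodes with no assessable
children missing, and fails only if the root itself is unassessable. When
several sources provide value functions for one attribute, and when a leaf
carries several measured attributes, the **median** pools them — the same
pooling rule used for weights across experts (the group median), kept
deliberately consistent. Even-sized groups take the midpoint of the two
central values; this is required to reproduce the level-1 synergy median
0.75 from the four contributing entries (1, 0.25, 0.5, 1).

### Weights

Swing, reversed-swing and direct rating all reduce to the same arithmetic —
scores normalized to sum 1 — and differ only in framing (worst-to-best
swings scored 0–100 with the top swing at exactly 100, best-to-worst value
losses, or direct importance ratings). The framing lives in metadata; the
package enforces the swing-specific invariants (best score 100, weakly
decreasing in rank) in `swing_weights()`. Weights are local to sibling
groups; `global_leaf_weights()` reports the product down the path as a
diagnostic only.

Group consolidation distinguishes **explicit zero weights** (deliberate
exclusions, which contribute to group medians — required to reproduce the
level-1 medians 0.28/0.23/0.45, where one expert assigned 0/0/1) from
**not-applicable entries** (`Ø` in the tables, e.g. the synergy cell of an
expert who needed no aggregation; these never contribute — required to
reproduce the synergy median 0.75). The packaged tables encode the
distinction per cell; loaders return `NA` for `Ø`. One expert's printed
level-1 weights sum to 1.01; sibling sums within 0.015 of 1 are treated as
printed rounding, not error.

The variation diagnostic is the min–max range over contributing experts,
flagged *large* at range $\ge 0.4$ (inclusive).

### Risk attitude

Risk is elicited at the root only — judging lotteries over whole-river
states requires breadth no single specialist has for sub-branches, and a
root-level attitude is the conservative choice. The variable
certainty-equivalent method presents 50–50 lotteries; the certainty
equivalent $x_p$ is the sure value judged equivalent to a lottery with
expected value $p$, elicited at $p = 0.5$, then 0.75 and 0.25.
`utility_from_ce()` interpolates piecewise linearly through
$(0,0), (x_{0.25},0.25), (x_{0.5},0.5), (x_{0.75},0.75), (1,1)$, so
$u(x_p) = p$ exactly. A one-parameter exponential fit is available as a
diagnostic (`fit_exponential_utility()`) but never used in assessment.

Classification follows the CE rule: $x_p < p$ (utility above the diagonal)
is risk-averse, $x_p > p$ risk-prone, within `tol = 0.02` of the diagonal
neutral — again a small default because published attitudes are described
only as "slightly" averse or prone. Note that a published phrase like
"slightly risk prone (utility = 0.6)" at the moderate state reads, under
this rule, as a certainty equivalent of 0.6 for the 50–50 lottery
(so $u(0.6) = 0.5$ and the curve is convex there); the packaged synthetic
CE sets encode that pattern — all three assessors averse at the poor (0.25)
and good (0.75) states, one slightly prone at the moderate state.

## Packaged fixtures

`inst/extdata/` transcribes the elicitation tables:

* `attribute_table.csv` — 80 attribute records with printed numbering
  preserved verbatim: 69 distinct numbers (number 24 was never printed,
  while the caption counts 70 attributes; the fixture records the printed
  facts without resolving them), several numbers carrying two or three
  expert-specific records. 76 records are expert-sourced and 4 from the
  literature; among the expert records two are discrete (binary
  measurements) and one ("mean suspended solids concentration at low flow")
  has no value function at all — it is nonetheless counted as a continuous
  expert record, the only reading under which the published census
  (76 = 74 continuous + 2 discrete) closes.
* `level1_weights.csv` — the level-1 weight/aggregation/synergy table for
  five experts, `Ø` cells empty.
* `aggregation_choices.csv` — the 49 aggregation decisions (37
  multiplicative, 12 additive). The per-branch totals named in the text fix
  the top level (4), the physical (14) and the biological branch (26); the
  chemical branch count (5) is inferred as the remainder and is consistent
  with the two additive chemical cases named. Decisions not attributed to a
  named expert are marked `unspecified`.
* `hierarchy_consolidated_synthetic.json` — the consolidated hierarchy:
  102 objectives on levels 1–5 (3/7/18/51/23) below a level-0 root, with the
  attribute catalogue at the leaves. The root sits at level 0 so the
  published level-1 weights attach to its children, and level counts exclude
  it. The root, the level-1 branches, the named level-2/3 objectives and all
  counts follow the published structure; the wiring below is a
  reconstruction (hence `_synthetic` in the name). The excluded
  "good water quality" branch is included as a structural level-2
  placeholder flagged `non_assessable`, the one exception to the rule that
  leaves carry attributes.
* `ce_sets_synthetic.json` — synthetic CE sets reproducing the qualitative
  risk pattern above (the elicited CE values were published only as curves).

Per-expert hierarchy variants are represented through essentiality labels
and zero weights rather than separate tree files; `consolidate()` retains
exactly the nodes labelled *essential* by at least one expert (structure
preserved, idempotent) and reports an error naming the offending nodes if
the essential set would disconnect the tree.

## The simplification analysis

`simplification_config()` toggles the four simplifications independently:

* **linearize** replaces each continuous value function by its endpoint
  chord, per limb; discrete functions are untouched (the linearity
  simplification is defined on continuous scales).
* **force_additive** replaces every method by additive, keeping weights;
  the minimum model carries no weights, so its nodes fall back to equal
  weights.
* **force_risk_neutral** drops the root utility.
* **restrict_to_top_objectives(n)** keeps the `n` leaves with the highest
  global weight (default 10, emulating the five-to-ten-objectives practice)
  and renormalizes; ancestors of surviving leaves are retained.

`compare_models()` scores states under the full and the simplified model and
compares rankings by pairwise concordant-minus-discordant counting over all
pairs, ties counted separately — no particular correlation statistic is
prescribed by the protocol, and the pairwise form makes the reversal list
exact. Census percentages round half-up to whole percent (37/49 → 76,
60/74 → 81), matching how the published fractions were rounded.

## The synthetic generator

`generator_spec()` defaults encode the study conditions: level counts
3/7/18/51/23, six experts, 81% non-linear value functions, 76%
multiplicative choices, synergy drawn uniformly from
$\{0.25, 0.5, 0.75, 1\}$ (the protocol fixes the support; no empirical
distribution over it was published, so the flat distribution is the neutral
choice), 10% missing measurements, and a mixed risk profile
(averse at 0.25/0.75, prone at 0.5). Weights are drawn from the flat simplex
(normalized exponentials); no attempt is made to mimic the empirical weight
spread beyond the variation diagnostics.

Hierarchies are grown level by level with parents drawn uniformly from the
level above, so per-level counts match the spec exactly and some
intermediate-level nodes end as leaves — as in the elicited hierarchy.
Non-linear functions displace the mid-value point by 0.15–0.35 on the value
scale (≥ 0.1 from the chord); generated labels are therefore unambiguous at
the 0.02 classification tolerance. Generated value functions are continuous
only — the two discrete expert records are fixture-level facts, and the
generator's shape targets concern the continuous census. Bisection
transcripts add Gaussian noise on the attribute scale, clip to the range and
re-monotonize with minimal strict spreading, so noiseless transcripts
reconstruct the generating function exactly at all elicited values.

All draws run under one explicit seed with the caller's RNG state restored
afterwards; identical spec and seed give byte-identical documents.

**What the generator does not emulate.** States are independent uniform
draws per attribute: there is no ecological covariance (temperature–fish
dependence and the like), no measurement error model, and no per-expert
disagreement structure beyond the drawn quantities. Passing tests therefore
demonstrate the correctness of the machinery under the stated statistical
structure, not predictive realism for any actual river.

## Verification strategy and problem sizes

The suite cross-checks `rollup()` against an independently written
recursive evaluator on 100 seeded random fixtures (~16 objectives each, 10%
missingness); checks aggregator idempotence, monotonicity and the valid
ordering bounds on a $10^4$-point grid; verifies exact parameter recovery of
value functions, weights and CE anchors from noiseless synthetic
transcripts; and verifies 100% shape-classifier agreement on ~500
generator-labelled functions under a fixed seed. Frequency targets
(non-linear share, multiplicative share, missingness) are tested at
$n \ge 500$ against 99% binomial confidence bounds. These sizes keep the
full suite under half a minute while leaving the binomial bounds tight
enough to catch implementation drift. Branch-level weight medians and the
"12 of 85" large-variation count from the original elicitation would
require the unpublished per-branch tables; the operations exist and are
exercised on synthetic tables instead.

## Known limitations

* The hierarchy wiring below level 3 is a reconstruction; analyses that
  depend on which leaf sits under which level-3 objective should treat the
  packaged tree as illustrative.
* Utilities apply at the root only; per-objective risk attitudes are out of
  scope.
* No Keeney–Raiffa master-constant solving: the synergy factor is assessed
  directly, never derived from $1 + K = \prod_i (1 + K w_i)$.
* Discrete value functions support exact admissible levels only; there is
  no fuzzy matching of class labels.
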