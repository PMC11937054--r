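---
title: "Cost-effectiveness modelling of sequential genetic testing strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-effectiveness modelling of sequential genetic testing strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gencea)
```

## The decision problem

Patients with suspected rare developmental disorders historically undergo a
"diagnostic odyssey": first-line chromosomal microarray (CMA) and Fragile X
testing, followed by iterative single-gene and gene-panel testing, often
without ever reaching a diagnosis. Trio exome sequencing (ES) and trio genome
sequencing (GS) — sequencing the affected child and both biological parents —
can replace parts of that pathway at different points: as a first-line test
(replacing everything), a second-line test (after CMA/Fragile X, replacing
panels), or a last-resort test (after all standard testing has failed).

Which configuration a health system should buy is an economic question:
each strategy has an expected cost per patient and an expected *diagnostic
yield* (the proportion of patients who receive a molecular diagnosis), and a
decision maker with a willingness to pay (WTP) of λ pounds per additional
diagnosis should prefer the strategy maximising net monetary benefit,
NMB = λ·DY − C.

`gencea` implements this comparison as a cohort decision tree, together with
the surrounding apparatus of a health-technology appraisal: incremental
cost-effectiveness analysis with dominance and an efficiency frontier,
one-way threshold analysis, and probabilistic sensitivity analysis (PSA)
with cost-effectiveness acceptability curves (CEACs).

## The tree model

A *strategy* is an ordered sequence of stages. Stage *i* carries a test, the
yield context under which it is delivered (a test's yield depends on where
in the pathway it sits — a last-resort test sees a pre-filtered population
and has lower yield than the same assay used first-line), a delivery year,
and two calibration slots: a `proceed_prob` (probability an undiagnosed
patient continues to this stage) and an `extra_cost` (e.g. associated clinic
visits). The engine walks the stages maintaining the probability `r` of
reaching each stage:

1. `r ← r × proceed_prob`;
2. cost accrues `r × (cost + extra_cost) × d(year)`;
3. yield accrues `r × yield × d(year)`;
4. diagnosed patients exit: `r ← r × (1 − yield)`.

Both costs and diagnoses are discounted with
`d(t) = (1 + rate)^−(t−1)`: year 1 is undiscounted, later years discounted
at 3.5% per annum by default, over a three-year horizon (stage *k* of a
sequential strategy is delivered in year *k*). Costs are treated as incurred
at the stage's delivery year with no half-cycle correction — this is an
annual decision tree, not a Markov model. All arithmetic is carried out in
full floating precision; rounding (costs to the pound, yields to 0.1
percentage points, incremental ratios truncated to the pound) happens only
at presentation.

The test suite verifies the engine against an independent oracle that
exhaustively enumerates every diagnosed/undiagnosed/dropped-out path through
the tree and probability-weights the outcomes — the two formulations agree
to floating tolerance on a thousand randomized strategies.

## The canonical configuration

`canonical_model()` loads the packaged Scottish NHS comparison of six
strategies built from four test definitions (2022 GBP, VAT inclusive):

| Test | Cost (95% CI) | Yields (95% CI) |
|---|---|---|
| CMA + Fragile X | £386 (358–414) | first-line 0.10 (0.09–0.12) |
| Single gene & panels | £2275 (1836–2948) | second-line 0.21 (0.14–0.29) |
| Trio GS | £5576 (5018–6133) | 1st-line 0.46 (0.36–0.57); 2nd-line 0.40 (0.33–0.47); last-resort 0.23 (0.14–0.32) |
| Trio ES | £1153 (1060–1245) | 2nd-line 0.37 (0.27–0.49); last-resort 0.21 (0.13–0.29) |

The `low_gs` scenario replaces the trio-GS cost by £3781 (3403–4159) per
trio, the outsourced-pipeline costing option.

```{r}
m <- canonical_model()
evaluate_model(m)
```

The single-stage first-line GS strategy reproduces its inputs exactly
(£5576, 46.0%). Two-stage strategies reconstruct the published
strategy-level values closely (2nd-line GS 44.8% vs 44.7% published;
2nd-line ES 42.2% vs 42.1%; standard testing 28.3% vs 28.2%, with costs
£40–60 below the published figures, which include clinic-visit costs).
Three-stage *last-resort* strategies under-estimate the published totals
(e.g. last-resort ES 42.2% vs 44.8%): the original evaluation's full tree
carries branch probabilities and per-stage costs from its supplementary
material that the simplified schematic does not determine. The fixture
exposes `proceed_prob` and `extra_cost` per stage precisely so those values
can be slotted in when available; we deliberately do not guess them, and the
packaged defaults are neutral (1 and 0). Analyses that depend on the
absolute last-resort totals — most visibly the PSA acceptability results
below — inherit this gap.

## Incremental analysis and the efficiency frontier

`dominance_table()` sorts strategies by ascending cost and applies, in
order: strict dominance (another strategy costs no more and diagnoses
strictly more, or strictly less with no fewer); then extended dominance —
iterative removal of strategies whose incremental cost per additional
diagnosis (ICAD) against the previous survivor exceeds the next survivor's,
until frontier ICADs strictly increase. Extended dominance is applied even
though the published base-case table only exhibits strict dominance: the
frontier definition ("successively more costly and more effective", with a
decision maker able to mix adjacent strategies) requires increasing ICADs,
and the low-GS scenario does exercise it (last-resort ES is excluded by
first-line GS on ICAD grounds despite costing less).

Each row's incremental cost and yield are taken against the most recent
cheaper frontier member — dominated rows keep their increments for report
parity with published tables. Ties in (cost, yield) are retained and
flagged; NMB ties report the lexicographically first strategy, so outputs
are deterministic.

```{r}
dominance_table(reference_results("base"))
```

On the published strategy-level values this reproduces the published
dominance calls and the footnote arithmetic (£65,407; £200,666; £536,000;
and £61,000 / £1,152,000 in the low-GS scenario). ICADs are *displayed*
truncated toward zero to the pound (`trunc_pound()`), which is the
convention the published table follows (200,666.67 prints as 200,666);
internal comparisons always use unrounded values.

## Threshold analysis

`solve_threshold()` varies one input and finds the value at which the
target strategy becomes NMB-optimal at a stated WTP. "Becomes cost
effective" is operationalised as *becomes the global NMB maximiser* (not
merely joining the frontier) — this reading reproduces the published
switching points most closely. The WTP itself is derived from revealed
historical policy: `implied_wtp(2429, 0.282)` ≈ £8613 per diagnosis, the
average standard-testing spend per diagnosis achieved.

The NMB gap between the target and the best alternative is piecewise linear
in any single cost or yield input, but not necessarily monotone (the best
alternative can change along the way). The solver therefore scans the
search interval (41 points by default), requires a *single* sign crossing —
zero crossings with a negative gap everywhere is reported as "never
optimal", more than one is an error asking for narrower bounds — and
refines the crossing by bisection (absolute tolerance £0.01 for costs,
1e-6 for yields; 200-iteration cap). A strict monotonicity requirement
would wrongly reject the legitimate "never" query for last-resort GS, whose
gap rises and falls while staying negative. Default bounds are (0.01×,
100×) the current value for costs and (0, 1) for yields. Where the input
enters NMB linearly the bisection agrees with the closed form
`c* = λ·DY_target − NMB_incumbent`, which the tests exploit as an oracle.

At the implied WTP of £8613 the base-case model yields: trio-GS cost must
fall to ≈ £1718 (published: £1753, computed from the full tree's unrounded
internals) or first-line GS yield rise to ≈ 90.8% (published: 89%) before
first-line GS becomes cost effective; last-resort GS is never cost
effective for any trio-GS cost.

## Probabilistic sensitivity analysis

Parameter uncertainty is propagated by Monte Carlo. Each input's
distribution is fitted from its published mean and 95% CI by moment
matching with `SE = (high − low)/3.92`: beta for yields
(α = m(m(1−m)/v − 1), β = α(1−m)/m), gamma for costs (shape m²/v, scale
v/m) — standard PSA practice; normal and lognormal are available and the
family can be overridden per parameter in the configuration. Fitted means
are exact by construction and fitted 2.5/97.5 percentiles land within 5% of
the published (slightly asymmetric) CIs for every canonical parameter. All
parameters are sampled independently — no joint structure is asserted, so
sampled context-specific yields of the same assay may occasionally invert
order; that is accepted rather than invented correlation. Draw matrices are
fully reproducible from the seed; the per-iteration tree evaluation is
vectorised, so 10,000 iterations of the six-strategy model take well under
a second.

`ceac()` computes, at each WTP on a £0–£100,000 grid (£500 steps by
default), the fraction of iterations in which each strategy attains maximal
NMB; ties are broken deterministically so curves sum to exactly 1. The
crossover WTP — where the most-likely strategy changes — is reported at
grid resolution.

In the base case the simplified tree gives 2nd-line ES a ≈ 99.9% chance of
being cost effective at £8613 and keeps it most likely up to ≈ £98,500
(£56,000–63,000 across seeds in the low-GS scenario; the most-likely curves
cross shallowly, so the crossover estimate is seed-sensitive even at 10,000
iterations). The published figures (93%, £83,000,
£48,000) are materially more uncertain about 2nd-line ES, because in the
full supplementary tree last-resort ES reaches 44.8% yield — a close,
frequently-winning competitor — whereas the uncalibrated reconstruction
puts last-resort ES at 42.2%, barely above 2nd-line ES at three times the
cost. This is the same calibration gap noted above, surfacing through the
PSA; it is a property of the missing supplementary inputs, not of the
sampling machinery, and the acceptability tests in the suite record the
discrepancy rather than masking it.

```{r, fig.width = 6, fig.height = 4}
psa <- run_psa(m, n_iter = 2000, seed = 1)
plot_ceac(ceac(psa))
```

## The synthetic generator

`generate_model()` produces random but structurally faithful
configurations — tests with uniform costs and yields in configurable
ranges, symmetric CIs of a stated relative width (clipped to the parameter
domain), strategies assembled as stages in years 1..k with full compliance
— so every analysis in the package can be property-tested without external
data. The generator emulates the *structure* of real model inputs, not
their joint realism: it does not correlate cost with complexity, does not
order context yields within a test, and uses a single unconditional yield
context per test. Passing tests on generated models therefore demonstrate
engine correctness (oracle equivalence, frontier geometry, CEAC
normalisation), not clinical plausibility. Defaults (4 tests, 6 strategies,
up to 3 stages, costs £300–£6000, yields 0.05–0.5, 20% relative CI width)
mirror the canonical model's scale.

## Numerical choices and limitations

* Problem sizes in the shipped tests: 1000 random strategies for engine
  equivalence, 100 random sets for frontier-oracle agreement, 10,000 PSA
  iterations for acceptability results, 50,000 draws for
  distribution-recovery checks.
* Strategy order from the configuration file is preserved everywhere;
  sorting happens only inside `dominance_table()`.
* The package deliberately excludes QALY/cost-utility modelling,
  Markov/state-transition structure, correlated PSA sampling and expected
  value of perfect information; the effectiveness measure is diagnostic
  yield only, which ignores downstream management change and broader
  patient value.
* Costs are context-bound (2022 GBP, VAT inclusive, Scottish NHS
  charges/micro-costing); re-use in another system requires re-costing,
  not just re-running.
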