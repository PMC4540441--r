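---
title: "Modelling coral decline risk with an expert-elicited Bayesian network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coral decline risk with an expert-elicited Bayesian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefbn)
```

## The model and its assumptions

`reefbn` treats a reef system as a small discrete Bayesian network. Every
node has a short, *ordered* state list in which later states mean more
stress: environmental input nodes use `below / average / above` (relative to
a long-term mean), event nodes use `decreased / unchanged / increased`
(frequency of the event over the coming decade), and the outcome node is
binary `no_decline / decline` — whether hard coral cover falls below its
present level within ten years. The joint distribution factorizes as usual,
P(X) = ∏ P(X_i | parents(X_i)), and every query the package answers is an
exact marginal of that factorization, computed by sum-product variable
elimination. The networks involved are tiny (about a dozen nodes, three
states each), so exact inference is cheap and no approximation is ever used;
a brute-force enumeration of the full joint is kept in the test suite as an
independent oracle, and the two agree to 1e-12 on randomized networks.

Three kinds of conditional distributions appear:

* **Composite nodes** (water quality; anthropogenic stress) are
  deterministic indices: the weighted mean of their parents' normalized
  state ordinals is cut at 1/3 and 2/3 into three states. Weights default
  to equal and are configurable per structure file; the half-open cut
  convention (`[0, 1/3)`, `[1/3, 2/3)`, `[2/3, 1]`) means an exactly
  intermediate index lands in the middle state.
* **Elicited nodes** (bleaching, disease, CoTS outbreaks, and the decline
  outcome) get full CPTs interpolated from two elicited endpoint rows (see
  below).
* **Input nodes** carry no distribution; they are always observed, their
  states supplied per reef from discretized environmental layers.

The shipped wiring — water quality ← nutrients/sediment/pollution;
anthropogenic stress ← fishing + water quality; bleaching ← temperature,
irradiance, water quality; disease ← temperature, water quality; CoTS ←
water quality; decline ← bleaching, disease, CoTS, cyclones, anthropogenic
stress — is a plausible reading of a schematic conceptual diagram, not a
structure learned from data. We flag it explicitly as an assumption:
cyclones are wired directly into the outcome because storm damage is
physical rather than mediated by the biological event nodes, and CoTS keeps
a water-quality parent (the nutrient-runoff outbreak hypothesis) while also
being observable from outbreak-history layers. Both choices are editable in
the YAML structure file, and conclusions about management efficacy can be
sensitive to such wiring — that caveat carries over to any reuse.

## From expert intervals to parameterizations

Each elicited quantity is one probability (one endpoint entry of one CPT).
Experts answer in the 4-point format: lowest possible value, best estimate,
highest possible value, and a confidence level for the stated interval.
Because experts state intervals at different confidence levels, intervals
are standardized to a common credible level (default 90) by scaling both
half-widths by `target / confidence` and clamping to [0, 1]; the best
estimate never moves. This linear rescaling is the standard first-order
treatment of 4-point data. Only the pooled best estimates parameterize the
model — the standardized intervals are kept for between-expert spread
diagnostics — so the rescaling choice cannot silently change headline
outputs.

Pooling uses equal expert weights and three statistics: the group mean, and
the 25th/75th percentiles with the linear-interpolation convention
(`stats::quantile` type 7). The percentile parameterizations are labelled by
*outcome*, not by percentile: "pessimistic" always means the higher
probability of the adverse event. An orientation map classifies each
quantity (probability of an `increased`-frequency or `decline` state =
adverse; the rest beneficial), and the pessimistic parameterization takes
p75 of adverse quantities and p25 of beneficial ones. A literal mode —
one percentile applied to every quantity regardless of orientation — is also
provided for sensitivity analysis, because percentile-labelled
parameterizations are ambiguous when quantities differ in orientation;
neither mode is claimed to be the only defensible reading, and the default
is the one that guarantees pessimistic ≥ optimistic decline probabilities,
which the test suite asserts over the entire input space of the default
model.

## Endpoint elicitation and CPT interpolation

Full CPT elicitation is infeasible: the outcome node alone has 3⁴ × 3 = 243
conditioning combinations. Instead only the two extreme rows are elicited —
the distribution when every parent is least adverse, and when every parent
is most adverse — and intermediate rows are linear interpolations. The
interpolation coordinate is the *ordinal adversity score*: the mean over
parents of (state index − 1)/(n states − 1), so s = 0 exactly at the benign
endpoint and s = 1 at the adverse endpoint, and each row is
(1 − s)·low + s·high. The coordinate choice is the simplest consistent
option and is isolated behind `interpolate_cpt()` so alternatives (weighted
or product coordinates) can be substituted. Two properties follow and are
tested: elicited endpoints are reproduced bit-for-bit at s ∈ {0, 1}, and if
the adverse endpoint stochastically dominates the benign one on the
adversity order, every CPT row is monotone in s — which in turn makes the
decline probability non-decreasing when any single input moves to a more
adverse state. Endpoint distributions are renormalized to sum to one at
model build (pooled per-state probabilities need not sum exactly).

## Layers, discretization, and zoning

Evidence is taken at reef centroids: one continuous value per layer per
reef, discretized into three categories. For generic layers the category
boundaries are mean ± 1 SD with the boundary values belonging to the extreme
categories ("1 SD *or more*"); for temperature anomalies a fixed ±1 °C rule
is used instead (a conservative mass-bleaching threshold), with the
boundaries belonging to `average` ("within 1 °C"). Layer statistics default
to being computed across the supplied (zoned) reef table; a stats file can
override them when climatological statistics exist. Several layers (plume
exposure, pollution load) have no agreed physical units and are treated as
unitless indices throughout.

Fishing effort reported on coarse blocks can be reapportioned onto fine
cells proportionally to fine-scale weights (`downscale_effort()`), which
conserves per-block totals exactly — the conventional downscaling assumption
that coarse and fine effort share a spatial pattern. Reefs inside no-take
zones are assigned zero effort before statistics and discretization.

## Scenarios

A scenario is a fixed what-if combination of stressor levels roughly a
decade out — not a forecast. Three mechanisms are exposed, because different
stressors are naturally shifted on different scales:

* a continuous temperature delta (default climate scenarios add +0.2 °C to
  anomalies *before* discretization, so reefs near the threshold can cross
  it);
* a relative multiplier on continuous cyclone exposure (default 1.3, i.e. a
  30% higher chance of being hit), applied before discretization; a
  categorical shift for cyclones is also available;
* ±1-category shifts (≈ ±1 SD) for everything else.

Shifts on the latent event nodes (disease, bleaching) cannot act on a layer,
so they are implemented as *evidence*: the node is clamped to the shift from
its neutral `unchanged` state. At baseline those nodes stay latent and the
network infers their distribution from the climate inputs. This is the one
place where a scenario changes what is observed rather than the observation
itself; the alternative (shifting the CPTs) would have required re-eliciting
under each scenario. CoTS outbreak frequency and irradiance are held
unchanged in all four shipped scenarios; CoTS evidence comes from the
outbreak-history layer by default and can be dropped (`observe_cots =
FALSE`) to let the network infer it from water quality.

The shipped scenario set: (1) baseline, all variables at present conditions;
(2) climate change without management (+0.2 °C, cyclones ×1.3, increased
disease and bleaching frequency); (3) climate change with local management
(as 2, plus one-category reductions in nutrients, sediment, pollution and
fishing); (4) management without further climate change (the reductions
alone). Headline outputs are per-reef decline probabilities, no-take vs open
zone means (arithmetic, with respect to the number of reefs), and
relative-change maps (p_b − p_a)/p_a with a reference of exactly zero
flagged undefined rather than divided.

## The synthetic-data generator

The generator exists so that every stage is testable end to end and so that
parameter-recovery experiments are possible; it emulates the *statistical
shape* of the study inputs, not actual Great Barrier Reef conditions. The
default fleet has 775 mid-shelf reefs scattered uniformly between 22.31°S
and 15.77°S with a third flagged no-take; layer families are normal for
temperature anomaly (mean 0, SD 0.5 °C) and irradiance, Poisson for decadal
cyclone and CoTS counts, and lognormal for effort and the load indices —
chosen once for qualitative realism (non-negativity, right skew for loads
and effort, counts for events) and fully configurable. The default expert
pool has 21 experts whose best estimates scatter around a configurable true
parameterization.

What the generator does *not* emulate: spatial autocorrelation between
neighbouring reefs, cyclone tracks, bathymetry, correlated layers, or
between-expert correlation. Passing tests therefore demonstrate correctness
of the machinery under the stated sampling assumptions, not predictive skill
on real reefs.

Expert noise is symmetric and additive on the probability scale by default,
clamped to [0, 1]. Clamping biases the mean for truths near the boundaries
(for a truth of 0.05 and noise SD 0.1 the expected clamped mean is ≈ 0.070),
which is a property of bounded elicitation scales, not an estimator defect.
For that reason the generator also offers symmetric noise on the log-odds
scale (`noise = "logit"`), which respects boundaries, and the
parameter-recovery experiment in the test suite uses it because the default
truth contains boundary-near entries (0.05, 0.95); the additive path is
separately verified to recover interior truths. The default true
parameterization itself encodes stochastically ordered endpoints (adverse
endpoint dominates benign) with a moderate decline probability even at the
benign endpoint, consistent with a system already in slow decline.

## Numerical choices and degenerate inputs

* Percentiles: type-7 linear interpolation; ties among expert bests need no
  extra handling.
* Elicited probabilities are floored at 0.001 (configurable) when a model is
  built: percentile pooling of boundary-clamped responses can return an
  exact zero, and a hard CPT zero would declare ordinary observed evidence
  (say, a decrease in outbreak frequency) logically impossible — an elicited
  zero means "very unlikely on a truncated response scale", not impossible.
* CPT rows must sum to 1 within 1e-9 (validation), and interpolated rows are
  renormalized defensively although convex combinations preserve the sum.
* Inference compares to the enumeration oracle at 1e-12; monotonicity
  assertions allow −1e-12 slack for floating-point noise.
* Variable elimination order is topological — optimal orderings are
  irrelevant at this scale.
* A parent declared with a single state contributes zero to ordinal scores,
  with a warning; a parentless elicited node takes its benign-endpoint
  distribution as its prior.
* Evidence with probability zero under the model aborts with an explicit
  message rather than returning 0/0.
* Reefs sharing an evidence combination share one inference call, so
  fleet-scale prediction costs scale with distinct evidence combinations
  (a few hundred) rather than reefs.
* CSV interchange is written with shortest-round-trip doubles and parsed
  with base R's correctly rounded converter, so all tabular formats
  round-trip bit-exactly (asserted in tests).

## Problem sizes used in the checks

The test suite runs the oracle comparison on 100 randomized small networks
(≤ 6 nodes, 3 states), exhausts the full 3⁷ input space of the default model
for the monotonicity and pessimistic-vs-optimistic assertions, uses a
10,000-expert pool for parameter recovery, and exercises the file pipeline
at 775 reefs in the acceptance checks with smaller fleets (30–120 reefs)
elsewhere; these sizes were chosen to make the properties sharp while
keeping a full run comfortable on a laptop.

## Known limitations

* The network wiring is an assumption; structure uncertainty is not
  propagated.
* No larval connectivity or between-reef dynamics: each reef is scored
  independently, so recruitment-subsidy benefits of reserve networks are
  invisible to the model.
* The ten-year horizon is semantic — it lives in what the experts were asked
  — and there is no temporal discretization in the engine.
* Uniform susceptibility across reefs: CPTs do not vary with community
  composition or reef type.
* The mean parameterization of pooled expert opinion is not guaranteed to
  lie between the pessimistic and optimistic ones quantity-by-quantity
  (means and percentiles can cross); only p25 ≤ p75 is guaranteed and
  asserted.
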