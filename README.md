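# reefbn

Expert-elicited spatial Bayesian networks for mapping the ten-year risk of
hard-coral-cover decline on individual reefs under combined climate-change and
local-management scenarios.

## The problem

Coral reefs face many stressors at once — thermal anomalies, cyclones, flood
plumes carrying nutrients, sediment and pollutants, crown-of-thorns starfish
(CoTS) outbreaks, disease, bleaching, and fishing — and managers can act on
only some of them. Field data rarely support fitting a joint multi-stressor
model, so a practical alternative is to encode the system as a discrete
Bayesian network (BN) whose conditional probability tables (CPTs) come from
structured expert elicitation, then drive that network with per-reef
environmental layers to produce a spatially explicit risk map under what-if
scenarios. `reefbn` implements that whole workflow for an audience of
ecological modellers and conservation planners: elicitation aggregation, CPT
construction, exact inference, layer discretization, scenario shifting, and
zone/change-map summaries, plus a fully seeded synthetic-data module so every
stage is testable without restricted data.

## The model

**Network.** A directed acyclic graph of discrete nodes, each with ordered
states encoding increasing adversity. The shipped structure has seven
evidence-bearing input nodes (temperature anomaly, cyclone exposure,
irradiance, nutrient/sediment/pollution loads, fishing effort), two
deterministic weighted composite indices (water quality; anthropogenic
stress), three elicited event nodes (bleaching, disease, CoTS outbreaks —
states *decreased / unchanged / increased* frequency), and a binary outcome
node: P(hard coral cover declines below present levels within 10 years).
Inference is exact (sum-product variable elimination); for per-reef
prediction, the marginal

P(decline | temperature, cyclones, irradiance, nutrients, sediment,
pollution, fishing, …)

is computed at each reef centroid's evidence.

**Elicitation.** Experts answer with the 4-point format (lowest, best,
highest, confidence). Intervals are standardized to a common credible level
by linearly rescaling half-widths by `target / confidence`; best estimates
are pooled per elicited quantity into three parameterizations — the group
**mean**, and **pessimistic**/**optimistic** percentile variants (type-7
linear-interpolation percentiles, with an orientation map so "pessimistic"
always means a higher probability of the adverse outcome).

**CPT interpolation.** Only the two extreme CPT rows are elicited per node —
the distribution when all parents are least adverse (`low`) and when all are
most adverse (`high`). Any other parent combination with ordinal adversity
score *s* (mean of normalized parent state indices) gets the row
`(1 − s)·low + s·high`, reproducing the elicited endpoints exactly at
*s* ∈ {0, 1}.

**Layers and scenarios.** Continuous layers are recoded into three states
(≥ 1 SD above average / within 1 SD / ≤ 1 SD below; temperature uses a fixed
±1 °C anomaly rule), coarse fishing-effort blocks can be reapportioned onto
fine cells proportionally to fine-scale weights, and no-take reefs carry zero
effort. Scenarios shift evidence categorically (±1 category ≈ ±1 SD), add a
temperature delta before discretization, and scale cyclone exposure by a
relative multiplier. Outputs are per-reef decline probabilities, zone
(no-take vs open) comparisons, and relative-change maps
`(p_b − p_a) / p_a` between scenario pairs.

## Worked example

```r
library(reefbn)

reefs <- apply_zoning(generate_reefs(n_reefs = 775, seed = 1))
stats <- compute_layer_stats(reefs)
pool  <- generate_expert_pool(n_experts = 21, seed = 2)
param <- build_parameterization(standardize_responses(pool), label = "mean")
model <- build_model(default_structure(), param)
scns  <- default_scenarios()

baseline <- predict_decline(model, reefs, scns$baseline, stats)
climate  <- predict_decline(model, reefs, scns$climate,  stats)
dplyr::bind_rows(glance(baseline), glance(climate))
#> # A tibble: 2 × 7
#>   scenario parameterization n_reefs mean_decline sd_decline min_decline
#> 1 baseline mean                 775        0.651     0.0662       0.486
#> 2 climate  mean                 775        0.760     0.0641       0.614

summarize_by_zone(baseline, reefs)
#>   scenario parameterization n_no_take n_open mean_overall mean_no_take mean_open
#> 1 baseline mean                   256    519        0.651        0.604     0.673

head(change_map(baseline, climate), 3)
#>   reef_id     p_a   p_b rel_change undefined
#> 1 reef_0001 0.684 0.800      0.169 FALSE
#> 2 reef_0002 0.622 0.738      0.185 FALSE
#> 3 reef_0003 0.695 0.800      0.151 FALSE
```

Reading the output: on this synthetic fleet the mean 10-year decline
probability rises from 0.651 at baseline to 0.760 under the climate-change
scenario; reefs open to fishing average a higher decline probability (0.673)
than no-take reefs (0.604); and the per-reef relative-change map shows
15–19% increases. `autoplot()` on a prediction set or change map draws the
corresponding centroid map, and `run_pipeline()` writes all 4 scenarios × 3
parameterizations (plus GeoJSON, zone summaries and change maps) in one
call. A thin command-line wrapper ships at `inst/scripts/reefbn`
(`simulate` / `run` / `report` subcommands).

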