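# Scenarios: categorical what-if shifts applied to per-reef evidence.
#
# A scenario is a fixed combination of stressor levels roughly ten years out,
# not a forecast. Shifts are +-1 category (about one standard deviation of
# the layer); temperature instead gets a continuous anomaly delta before
# discretization, and cyclone exposure a relative multiplier on the
# continuous exposure (the "+30% chance of being hit" mechanism), with the
# categorical shift also available for both.

SCENARIO_VARIABLES <- c(
  "temperature", "cyclones", "disease", "bleaching", "irradiance",
  "cots", "nutrients", "sediment", "pollution", "fishing"
)
EVENT_VARIABLES <- c("disease", "bleaching", "cots")

#' Define a stressor scenario
#'
#' @param name Scenario identifier.
#' @param shifts Named numeric vector of categorical shifts in `{-1, 0, +1}`
#'   over the scenario variables (temperature, cyclones, disease, bleaching,
#'   irradiance, cots, nutrients, sediment, pollution, fishing). Omitted
#'   variables are unchanged. Shifts on the latent event nodes `disease` and
#'   `bleaching` impose evidence on those nodes, moved from the neutral
#'   "unchanged" frequency state.
#' @param temp_delta Degrees C added to every reef's temperature anomaly
#'   before discretization.
#' @param cyclone_multiplier Multiplier applied to the continuous cyclone
#'   exposure before discretization (1.3 = 30% higher chance of being hit).
#'
#' @return A `reefbn_scenario` object.
#' @export
#' @examples
#' scenario("climate", shifts = c(disease = 1, bleaching = 1),
#'          temp_delta = 0.2, cyclone_multiplier = 1.3)
scenario <- function(name, shifts = numeric(), temp_delta = 0, cyclone_multiplier = 1) {
  shifts <- unlist(shifts)
  if (length(shifts) > 0) {
    unknown <- setdiff(names(shifts), SCENARIO_VARIABLES)
    if (length(unknown) > 0) {
      abort(sprintf(
        "unknown scenario variable%s: %s",
        if (length(unknown) > 1) "s" else "", paste(unknown, collapse = ", ")
      ))
    }
    if (!all(shifts %in% c(-1, 0, 1))) {
      abort("shifts must be -1, 0 or +1 categories")
    }
  }
  if (!is.finite(temp_delta)) abort("`temp_delta` must be finite")
  if (!is.finite(cyclone_multiplier) || cyclone_multiplier <= 0) {
    abort("`cyclone_multiplier` must be positive")
  }
  structure(
    list(
      name = name,
      shifts = shifts[shifts != 0],
      temp_delta = temp_delta,
      cyclone_multiplier = cyclone_multiplier
    ),
    class = "reefbn_scenario"
  )
}

#' @export
print.reefbn_scenario <- function(x, ...) {
  sh <- if (length(x$shifts) == 0) {
    "no categorical shifts"
  } else {
    paste(sprintf("%s%+d", names(x$shifts), x$shifts), collapse = ", ")
  }
  cat(sprintf(
    "<reefbn scenario '%s': %s; temp_delta=%+.1f C, cyclone x%.2f>\n",
    x$name, sh, x$temp_delta, x$cyclone_multiplier
  ))
  invisible(x)
}

#' The four shipped climate/management scenarios
#'
#' 1. `baseline`: all variables at present conditions.
#' 2. `climate`: +0.2 degrees C on temperature anomalies, 30% higher cyclone
#'    exposure, and increased disease-outbreak and mass-bleaching frequency;
#'    no management action.
#' 3. `climate_management`: as `climate`, plus roughly one-SD (~30%)
#'    reductions in nutrient, sediment and pollutant loads and fishing
#'    pressure.
#' 4. `management`: the best case — the management reductions of scenario 3
#'    with no further climate change.
#'
#' Irradiance and crown-of-thorns outbreak frequency are unchanged in every
#' scenario.
#'
#' @return Named list of four [scenario()] objects.
#' @export
default_scenarios <- function() {
  mgmt <- c(nutrients = -1, sediment = -1, pollution = -1, fishing = -1)
  list(
    baseline = scenario("baseline"),
    climate = scenario(
      "climate",
      shifts = c(disease = 1, bleaching = 1),
      temp_delta = 0.2, cyclone_multiplier = 1.3
    ),
    climate_management = scenario(
      "climate_management",
      shifts = c(c(disease = 1, bleaching = 1), mgmt),
      temp_delta = 0.2, cyclone_multiplier = 1.3
    ),
    management = scenario("management", shifts = mgmt)
  )
}

#' Shift an ordered three-category state
#'
#' Moves a state one category up or down its ordered vocabulary, clamping at
#' the ends: a "+1" on `average` gives `above`; a "+1" on `above` stays
#' `above`.
#'
#' @param state Character vector of states.
#' @param shift Scalar shift in `{-1, 0, +1}`.
#' @param states Ordered state vocabulary; default the layer categories
#'   `c("below", "average", "above")`.
#'
#' @return Shifted states.
#' @export
#' @examples
#' shift_state(c("below", "average", "above"), 1)
shift_state <- function(state, shift, states = LAYER_STATES) {
  idx <- match(state, states)
  if (any(is.na(idx))) {
    abort(sprintf(
      "illegal state '%s' for ordered vocabulary (%s)",
      state[which(is.na(idx))[1]], paste(states, collapse = ", ")
    ))
  }
  states[pmin(length(states), pmax(1, idx + shift))]
}

#' Apply a scenario to a reef table, producing per-reef evidence
#'
#' Builds the evidence table the network consumes under a scenario:
#' temperature is re-discretized after adding `temp_delta` to the anomaly;
#' cyclone exposure is multiplied by `cyclone_multiplier` before
#' discretization (then categorically shifted if the scenario also shifts
#' `cyclones`); every other shifted layer variable takes [shift_state()] of
#' its baseline category; shifted latent event variables (`disease`,
#' `bleaching`) become evidence at the shift from `unchanged`; everything
#' else keeps its baseline evidence.
#'
#' @inheritParams discretize_reefs
#' @param scn A [scenario()].
#'
#' @return A tibble: `reef_id` plus one state column per evidence node.
#' @export
apply_scenario <- function(reefs, scn, stats,
                           node_layers = DEFAULT_NODE_LAYERS,
                           observe_cots = TRUE) {
  if (!inherits(scn, "reefbn_scenario")) abort("`scn` must be a reefbn_scenario")
  reefs <- tibble::as_tibble(reefs)
  reefs_adj <- reefs
  reefs_adj[[node_layers[["temperature"]]]] <-
    reefs[[node_layers[["temperature"]]]] + scn$temp_delta
  reefs_adj[[node_layers[["cyclones"]]]] <-
    reefs[[node_layers[["cyclones"]]]] * scn$cyclone_multiplier

  ev <- discretize_reefs(reefs_adj, stats, node_layers, observe_cots)

  for (v in names(scn$shifts)) {
    sh <- scn$shifts[[v]]
    if (v %in% c("disease", "bleaching")) {
      ev[[v]] <- shift_state(rep("unchanged", nrow(ev)), sh, EVENT_STATES)
    } else if (v == "cots") {
      if (!is.null(ev[["cots"]])) {
        ev[["cots"]] <- shift_state(ev[["cots"]], sh, EVENT_STATES)
      } else {
        ev[["cots"]] <- shift_state(rep("unchanged", nrow(ev)), sh, EVENT_STATES)
      }
    } else if (v == "temperature") {
      ev[["temperature"]] <- shift_state(ev[["temperature"]], sh)
    } else {
      ev[[v]] <- shift_state(ev[[v]], sh)
    }
  }
  ev
}

#' Predict decline probability for every reef under a scenario
#'
#' Runs exact inference per reef on the scenario-shifted evidence. Reefs
#' sharing an evidence combination share one inference (the map from evidence
#' to probability is deterministic), so the cost scales with the number of
#' distinct combinations, not reefs.
#'
#' @inheritParams apply_scenario
#' @param model A `reefbn_model` from [build_model()].
#'
#' @return A `reefbn_predictions` tibble with columns `reef_id`, `p_decline`
#'   and attributes `scenario` and `parameterization`.
#' @export
predict_decline <- function(model, reefs, scn, stats,
                            node_layers = DEFAULT_NODE_LAYERS,
                            observe_cots = TRUE) {
  reefs <- tibble::as_tibble(reefs)
  if (nrow(reefs) == 0) abort("`reefs` must contain at least one reef")
  ev <- apply_scenario(reefs, scn, stats, node_layers, observe_cots)
  nodes <- setdiff(names(ev), "reef_id")
  combos <- dplyr::distinct(ev[nodes])
  combos$p_decline <- vapply(seq_len(nrow(combos)), function(i) {
    evidence <- unlist(combos[i, nodes])
    tryCatch(
      infer_decline(model, evidence),
      error = function(e) {
        rid <- ev$reef_id[
          which(Reduce(`&`, lapply(nodes, function(n) ev[[n]] == combos[[n]][i])))[1]
        ]
        abort(sprintf("inference failed for reef '%s': %s", rid, conditionMessage(e)))
      }
    )
  }, numeric(1))
  out <- ev |>
    dplyr::left_join(combos, by = nodes) |>
    dplyr::select("reef_id", "p_decline")
  new_predictions(out, scenario = scn$name, parameterization = model$label)
}

new_predictions <- function(tbl, scenario, parameterization) {
  structure(
    tibble::as_tibble(tbl),
    scenario = scenario,
    parameterization = parameterization,
    class = c("reefbn_predictions", class(tibble::tibble()))
  )
}

#' @export
print.reefbn_predictions <- function(x, ...) {
  cat(sprintf(
    "<reefbn predictions: scenario '%s', parameterization '%s', %d reefs>\n",
    attr(x, "scenario"), attr(x, "parameterization"), nrow(x)
  ))
  NextMethod()
}

#' Summarize prediction sets
#'
#' `glance()` on a prediction set gives its scenario, parameterization and
#' the mean/spread of per-reef decline probabilities.
#'
#' @param x A `reefbn_predictions` tibble.
#' @param ... Unused.
#'
#' @return A one-row tibble.
#' @export
glance.reefbn_predictions <- function(x, ...) {
  tibble::tibble(
    scenario = attr(x, "scenario"),
    parameterization = attr(x, "parameterization"),
    n_reefs = nrow(x),
    mean_decline = base::mean(x$p_decline),
    sd_decline = stats::sd(x$p_decline),
    min_decline = min(x$p_decline),
    max_decline = max(x$p_decline)
  )
}

#' Compare mean decline inside and outside no-take zones
#'
#' Arithmetic means of per-reef decline probability (with respect to the
#' number of reefs) overall, within no-take zones, and outside them;
#' `difference = mean_open - mean_no_take`. An empty zone yields `NA` for its
#' mean and sets the `undefined_zone` flag.
#'
#' @param pred A `reefbn_predictions` tibble (reef_id, p_decline).
#' @param reefs Reef table carrying `reef_id` and `no_take`.
#'
#' @return A one-row tibble: scenario, parameterization, n_no_take, n_open,
#'   mean_overall, mean_no_take, mean_open, difference, undefined_zone.
#' @export
summarize_by_zone <- function(pred, reefs) {
  reefs <- tibble::as_tibble(reefs)
  assert_cols(reefs, c("reef_id", "no_take"), "reef table")
  missing <- setdiff(reefs$reef_id, pred$reef_id)
  if (length(missing) > 0) {
    abort(sprintf(
      "predictions missing for reef%s: %s",
      if (length(missing) > 1) "s" else "",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  joined <- dplyr::inner_join(
    pred, reefs[c("reef_id", "no_take")],
    by = "reef_id"
  )
  zmean <- function(x) if (length(x) == 0) NA_real_ else base::mean(x)
  nt <- joined$p_decline[joined$no_take]
  op <- joined$p_decline[!joined$no_take]
  tibble::tibble(
    scenario = attr(pred, "scenario") %||% NA_character_,
    parameterization = attr(pred, "parameterization") %||% NA_character_,
    n_no_take = length(nt),
    n_open = length(op),
    mean_overall = base::mean(joined$p_decline),
    mean_no_take = zmean(nt),
    mean_open = zmean(op),
    difference = .data_diff(zmean(op), zmean(nt)),
    undefined_zone = length(nt) == 0 || length(op) == 0
  )
}

.data_diff <- function(a, b) {
  if (is.na(a) || is.na(b)) NA_real_ else a - b
}

#' Relative change in decline probability between two scenarios
#'
#' Per reef, `(b - a) / a`: the difference in predicted decline probability
#' between scenario `b` and reference scenario `a`, relative to the
#' reference. Reefs with a reference probability of exactly 0 are flagged
#' `undefined` and carry `NA` rather than a number.
#'
#' @param pred_a Reference predictions (the denominator scenario).
#' @param pred_b Comparison predictions over the same reef set.
#'
#' @return A `reefbn_change_map` tibble: `reef_id`, `p_a`, `p_b`,
#'   `rel_change`, `undefined`, with `scenario_a`/`scenario_b` attributes.
#' @export
#' @examples
#' a <- tibble::tibble(reef_id = "r1", p_decline = 0.59)
#' b <- tibble::tibble(reef_id = "r1", p_decline = 0.77)
#' change_map(a, b)$rel_change # ~ 0.305, an ~30% relative increase
change_map <- function(pred_a, pred_b) {
  only_a <- setdiff(pred_a$reef_id, pred_b$reef_id)
  only_b <- setdiff(pred_b$reef_id, pred_a$reef_id)
  if (length(only_a) > 0 || length(only_b) > 0) {
    abort(sprintf(
      "prediction sets cover different reefs (only in a: %s; only in b: %s)",
      paste(head(only_a, 5), collapse = ", "),
      paste(head(only_b, 5), collapse = ", ")
    ))
  }
  joined <- dplyr::inner_join(
    tibble::as_tibble(pred_a)[c("reef_id", "p_decline")],
    tibble::as_tibble(pred_b)[c("reef_id", "p_decline")],
    by = "reef_id", suffix = c("_a", "_b")
  )
  out <- joined |>
    dplyr::transmute(
      reef_id = .data$reef_id,
      p_a = .data$p_decline_a,
      p_b = .data$p_decline_b,
      undefined = .data$p_a == 0,
      rel_change = dplyr::if_else(.data$undefined, NA_real_, (.data$p_b - .data$p_a) / .data$p_a)
    ) |>
    dplyr::select("reef_id", "p_a", "p_b", "rel_change", "undefined")
  structure(
    out,
    scenario_a = attr(pred_a, "scenario"),
    scenario_b = attr(pred_b, "scenario"),
    class = c("reefbn_change_map", class(tibble::tibble()))
  )
}
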