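# Environmental layers: discretization, effort downscaling, zoning, evidence.
#
# Continuous per-reef layer values are re-coded into three categories to match
# the elicitation questions: 1 SD or more above average / within 1 SD /
# 1 SD or more below average (boundaries inclusive to the extreme states).
# Temperature anomalies use a fixed +-1 degree C rule instead (boundaries
# belong to "average"), the conventional conservative bleaching threshold.

# default mapping from network input nodes to reef-table layer columns
DEFAULT_NODE_LAYERS <- c(
  temperature = "temp_anomaly",
  cyclones = "cyclone_exposure",
  irradiance = "irradiance",
  nutrients = "nutrient_load",
  sediment = "sediment_load",
  pollution = "pollution_load",
  fishing = "fishing_effort",
  cots = "cots_outbreak"
)

REEF_LAYER_COLS <- unname(DEFAULT_NODE_LAYERS)
REEF_COLS <- c("reef_id", "lon", "lat", "shelf", "no_take", REEF_LAYER_COLS, "plume_exposure")

#' Discretize a continuous layer value into three categories
#'
#' `above` iff `value >= mean + sd`, `below` iff `value <= mean - sd`,
#' otherwise `average`: the +-1 SD boundaries belong to the extreme
#' categories ("1 standard deviation *or more*").
#'
#' @param value Numeric vector of layer values.
#' @param mean,sd Layer statistics; `sd` must be strictly positive.
#' @param context Optional string (reef/layer) used in error messages.
#'
#' @return Character vector over `c("below", "average", "above")`.
#' @export
#' @examples
#' discretize_layer(c(7.9, 10, 12), mean = 10, sd = 2)
discretize_layer <- function(value, mean, sd, context = NULL) {
  if (!is.finite(mean) || !is.finite(sd) || sd <= 0) {
    abort("layer statistics require finite mean and strictly positive sd")
  }
  if (any(!is.finite(value))) {
    abort(sprintf(
      "non-finite layer value%s",
      if (is.null(context)) "" else paste0(" (", context, ")")
    ))
  }
  dplyr::case_when(
    value >= mean + sd ~ "above",
    value <= mean - sd ~ "below",
    .default = "average"
  )
}

#' Discretize a temperature anomaly with the 1 degree C rule
#'
#' `above` iff the anomaly exceeds +1 degree C, `below` iff it is under
#' -1 degree C, otherwise `average`; the boundaries themselves are "within
#' 1 degree C" and belong to `average`. The +1 degree C threshold is a
#' conservative trigger for mass coral bleaching.
#'
#' @param anomaly Numeric vector of anomalies (degrees C relative to the
#'   climatological mean).
#' @inheritParams discretize_layer
#'
#' @return Character vector over `c("below", "average", "above")`.
#' @export
#' @examples
#' discretize_temperature(c(-1, 0, 1.2))
discretize_temperature <- function(anomaly, context = NULL) {
  if (any(!is.finite(anomaly))) {
    abort(sprintf(
      "non-finite temperature anomaly%s",
      if (is.null(context)) "" else paste0(" (", context, ")")
    ))
  }
  dplyr::case_when(
    anomaly > 1 ~ "above",
    anomaly < -1 ~ "below",
    .default = "average"
  )
}

#' Compute per-layer discretization statistics from a reef table
#'
#' Means and standard deviations are computed over the supplied table
#' (typically the mid-shelf fleet after [apply_zoning()]), one row per layer.
#' Supply a hand-made stats table instead when climatological statistics are
#' available.
#'
#' @param reefs Reef table (see [read_reefs()] for the column contract).
#' @param layers Character vector of layer column names; defaults to every
#'   layer the default network consumes except temperature (which has its own
#'   fixed rule).
#'
#' @return A tibble with columns `layer`, `mean`, `sd`.
#' @export
compute_layer_stats <- function(reefs, layers = setdiff(REEF_LAYER_COLS, "temp_anomaly")) {
  reefs <- tibble::as_tibble(reefs)
  assert_cols(reefs, layers, "reef table")
  purrr::map_dfr(layers, function(l) {
    x <- reefs[[l]]
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) {
      abort(sprintf("layer '%s' has non-positive or undefined sd; supply stats explicitly", l))
    }
    tibble::tibble(layer = l, mean = base::mean(x), sd = s)
  })
}

#' Downscale coarse fishing-effort blocks onto fine cells
#'
#' Reapportions each coarse block's total effort across its fine cells in
#' proportion to the fine-resolution weights, assuming the relative spatial
#' distribution at coarse resolution matches the fine-resolution pattern.
#' Per-block totals are conserved exactly; a block with total 0 yields all
#' zeros.
#'
#' @param coarse Tibble with columns `block_id`, `total` (effort per coarse
#'   block).
#' @param weights Tibble with columns `block_id`, `cell_id`, `weight`
#'   (non-negative fine-resolution weights).
#'
#' @return A tibble with columns `block_id`, `cell_id`, `effort`.
#' @export
#' @examples
#' downscale_effort(
#'   tibble::tibble(block_id = "b1", total = 90),
#'   tibble::tibble(block_id = "b1", cell_id = c("c1", "c2"), weight = c(1, 2))
#' )
downscale_effort <- function(coarse, weights) {
  coarse <- tibble::as_tibble(coarse)
  weights <- tibble::as_tibble(weights)
  assert_cols(coarse, c("block_id", "total"), "coarse effort table")
  assert_cols(weights, c("block_id", "cell_id", "weight"), "effort weights table")
  if (any(weights$weight < 0)) abort("effort weights must be non-negative")
  if (any(coarse$total < 0)) abort("block totals must be non-negative")
  orphan <- setdiff(coarse$block_id[coarse$total > 0], weights$block_id)
  if (length(orphan) > 0) {
    abort(sprintf(
      "block%s with positive total but no cells: %s",
      if (length(orphan) > 1) "s" else "", paste(orphan, collapse = ", ")
    ))
  }
  out <- weights |>
    dplyr::inner_join(coarse, by = "block_id") |>
    dplyr::group_by(.data$block_id) |>
    dplyr::mutate(wsum = sum(.data$weight)) |>
    dplyr::ungroup()
  dead <- out |>
    dplyr::filter(.data$total > 0, .data$wsum == 0) |>
    dplyr::distinct(.data$block_id)
  if (nrow(dead) > 0) {
    abort(sprintf(
      "block%s with positive total but all-zero weights: %s",
      if (nrow(dead) > 1) "s" else "", paste(dead$block_id, collapse = ", ")
    ))
  }
  out |>
    dplyr::mutate(
      effort = dplyr::if_else(.data$total == 0, 0, .data$total * .data$weight / .data$wsum)
    ) |>
    dplyr::select("block_id", "cell_id", "effort")
}

#' Zero fishing effort inside no-take zones
#'
#' Reefs flagged `no_take` are assumed to carry no fishing effort or catch;
#' every other field is untouched.
#'
#' @inheritParams compute_layer_stats
#' @param effort_col Name of the effort column; default `"fishing_effort"`.
#'
#' @return The reef table with effort overridden to 0 on no-take reefs.
#' @export
apply_zoning <- function(reefs, effort_col = "fishing_effort") {
  reefs <- tibble::as_tibble(reefs)
  assert_cols(reefs, c("no_take", effort_col), "reef table")
  if (!is.logical(reefs$no_take)) abort("`no_take` must be logical")
  reefs[[effort_col]] <- dplyr::if_else(reefs$no_take, 0, reefs[[effort_col]])
  reefs
}

layer_stat_lookup <- function(stats, layer) {
  row <- stats[stats$layer == layer, ]
  if (nrow(row) != 1) {
    abort(sprintf("layer statistics missing (or duplicated) for '%s'", layer))
  }
  row
}

# translate a below/average/above layer category onto a node's own ordered
# 3-state vocabulary (e.g. decreased/unchanged/increased for event nodes)
translate_state <- function(states_from, states_to, value) {
  states_to[match(value, states_from)]
}

#' Discretize a reef table into per-node baseline evidence
#'
#' Produces one evidence column per evidence-bearing node of the network:
#' temperature via the fixed 1 degree C anomaly rule, every other layer via
#' its +-1 SD statistics. The crown-of-thorns outbreak-history layer is
#' discretized the same way and translated onto the event node's
#' decreased/unchanged/increased vocabulary (it is observed evidence by
#' default, but can be dropped to let the network infer it).
#'
#' @inheritParams compute_layer_stats
#' @param stats Layer statistics tibble (`layer`, `mean`, `sd`), e.g. from
#'   [compute_layer_stats()].
#' @param node_layers Named character vector mapping node names to reef-table
#'   columns; default `DEFAULT_NODE_LAYERS` (internal constant mirroring the
#'   default structure).
#' @param observe_cots Include the `cots` evidence column? Default `TRUE`.
#'
#' @return A tibble: `reef_id` plus one state column per evidence node.
#' @export
discretize_reefs <- function(reefs, stats,
                             node_layers = DEFAULT_NODE_LAYERS,
                             observe_cots = TRUE) {
  reefs <- tibble::as_tibble(reefs)
  missing <- setdiff(unname(node_layers), names(reefs))
  if (length(missing) > 0) {
    abort(sprintf(
      "reef table is missing layer%s: %s",
      if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  out <- tibble::tibble(reef_id = reefs$reef_id)
  for (node in names(node_layers)) {
    if (node == "cots" && !observe_cots) next
    layer <- node_layers[[node]]
    if (node == "temperature") {
      st <- discretize_temperature(reefs[[layer]], context = layer)
    } else {
      ls <- layer_stat_lookup(stats, layer)
      st <- discretize_layer(reefs[[layer]], ls$mean, ls$sd, context = layer)
    }
    if (node == "cots") {
      st <- translate_state(LAYER_STATES, EVENT_STATES, st)
    }
    out[[node]] <- st
  }
  out
}

#' Evidence for a single reef
#'
#' Convenience wrapper around [discretize_reefs()] for one reef record,
#' returning the named state vector [infer_decline()] consumes.
#'
#' @param reef One-row reef table.
#' @inheritParams discretize_reefs
#'
#' @return Named character vector of node states.
#' @export
evidence_for_reef <- function(reef, stats,
                              node_layers = DEFAULT_NODE_LAYERS,
                              observe_cots = TRUE) {
  reef <- tibble::as_tibble(reef)
  if (nrow(reef) != 1) abort("`reef` must be a single reef record")
  ev <- discretize_reefs(reef, stats, node_layers, observe_cots)
  unlist(ev[1, setdiff(names(ev), "reef_id")])
}
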