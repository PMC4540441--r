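# The shipped network and model assembly.
#
# The default structure mirrors a central-GBR conceptual model: seven
# empirically-informed input nodes; two deterministic weighted composites
# (water quality, anthropogenic stress); three elicited event nodes
# (bleaching, disease, crown-of-thorns outbreaks); and a binary outcome node,
# the ten-year probability of hard-coral-cover decline. The exact wiring of a
# schematic conceptual diagram is an assumption, and the structure is fully
# editable (and round-trips through a YAML file, see read_structure()).

LAYER_STATES <- c("below", "average", "above")
EVENT_STATES <- c("decreased", "unchanged", "increased")
COMPOSITE_STATES <- c("low", "medium", "high")
OUTCOME_STATES <- c("no_decline", "decline")

#' The default reef-decline network structure
#'
#' Ten evidence-bearing variables (temperature anomaly, cyclone exposure,
#' irradiance, nutrient/sediment/pollution loads, fishing effort, plus the
#' crown-of-thorns outbreak-history state) feed three elicited event nodes and
#' two weighted composite indices, which in turn drive a binary
#' decline/no-decline outcome:
#'
#' * `water_quality` (composite) <- nutrients, sediment, pollution;
#' * `anthropogenic_stress` (composite) <- fishing, water_quality;
#' * `bleaching` (event) <- temperature, irradiance, water_quality;
#' * `disease` (event) <- temperature, water_quality;
#' * `cots` (event) <- water_quality;
#' * `decline` (outcome) <- bleaching, disease, cots, cyclones,
#'   anthropogenic_stress.
#'
#' Cyclones enter the outcome directly (physical damage is not mediated by the
#' biological event nodes). State orders encode increasing adversity. The
#' wiring is an explicit assumption of this package and is configurable.
#'
#' @param composite_weights Named list of per-parent weights for the two
#'   composite nodes; default equal weights.
#'
#' @return A `reefbn_structure`.
#' @export
#' @examples
#' default_structure()
default_structure <- function(composite_weights = NULL) {
  nodes <- list(
    bn_node("temperature", "input", LAYER_STATES),
    bn_node("cyclones", "input", LAYER_STATES),
    bn_node("irradiance", "input", LAYER_STATES),
    bn_node("nutrients", "input", LAYER_STATES),
    bn_node("sediment", "input", LAYER_STATES),
    bn_node("pollution", "input", LAYER_STATES),
    bn_node("fishing", "input", LAYER_STATES),
    bn_node("water_quality", "composite", COMPOSITE_STATES,
      parents = c("nutrients", "sediment", "pollution")
    ),
    bn_node("anthropogenic_stress", "composite", COMPOSITE_STATES,
      parents = c("fishing", "water_quality")
    ),
    bn_node("bleaching", "event", EVENT_STATES,
      parents = c("temperature", "irradiance", "water_quality")
    ),
    bn_node("disease", "event", EVENT_STATES,
      parents = c("temperature", "water_quality")
    ),
    bn_node("cots", "event", EVENT_STATES, parents = "water_quality"),
    bn_node("decline", "outcome", OUTCOME_STATES,
      parents = c("bleaching", "disease", "cots", "cyclones", "anthropogenic_stress")
    )
  )
  if (is.null(composite_weights)) {
    composite_weights <- list(
      water_quality = c(nutrients = 1, sediment = 1, pollution = 1),
      anthropogenic_stress = c(fishing = 1, water_quality = 1)
    )
  }
  bn_structure(nodes, composite_weights)
}

#' Elicited quantities required by a structure
#'
#' Every event and outcome node is parameterized by two elicited endpoint
#' distributions — the distribution over its states when all parents are least
#' adverse (`low`) and when all are most adverse (`high`). Each endpoint
#' probability is one elicited quantity with id `<node>.<endpoint>.<state>`.
#'
#' @param struct A `reefbn_structure`.
#'
#' @return A tibble with columns `quantity_id`, `node`, `endpoint`, `state`,
#'   `state_index`, in the order expected by [build_model()].
#' @export
elicited_quantities <- function(struct) {
  elicited <- c(nodes_of_kind(struct, "event"), nodes_of_kind(struct, "outcome"))
  purrr::map_dfr(elicited, function(n) {
    nd <- struct$nodes[[n]]
    tidyr::expand_grid(
      node = n, endpoint = c("low", "high"), state = nd$states
    ) |>
      dplyr::mutate(
        state_index = match(.data$state, nd$states),
        quantity_id = paste(.data$node, .data$endpoint, .data$state, sep = "."),
        .before = 1
      ) |>
      dplyr::select("quantity_id", "node", "endpoint", "state", "state_index")
  })
}

#' Adverse/beneficial orientation of elicited quantities
#'
#' Classifies each elicited quantity for percentile-based parameterizations:
#' a quantity is `"adverse"` when it is the probability of the node's most
#' adverse state (increased event frequency; coral decline) and
#' `"beneficial"` otherwise. Under the default orientation mode the
#' pessimistic parameterization takes the 75th percentile of adverse
#' quantities and the 25th of beneficial ones, so "pessimistic" always means
#' higher probabilities of adverse events.
#'
#' @inheritParams elicited_quantities
#'
#' @return Named character vector `quantity_id -> "adverse"/"beneficial"`.
#' @export
default_orientation <- function(struct = default_structure()) {
  q <- elicited_quantities(struct)
  n_states <- vapply(
    struct$nodes[q$node], function(nd) length(nd$states), numeric(1)
  )
  setNames(
    ifelse(q$state_index == n_states, "adverse", "beneficial"),
    q$quantity_id
  )
}

#' Build a runnable model from a structure and a parameterization
#'
#' Assembles one CPT per non-input node: composite nodes get their
#' deterministic weighted-index CPT ([composite_cpt()]); event and outcome
#' nodes get a CPT interpolated between the parameterization's two elicited
#' endpoint distributions ([interpolate_cpt()]). Endpoint distributions are
#' renormalized to sum to one (pooled per-state probabilities need not).
#'
#' Elicited probabilities are floored at `prob_floor` before normalization:
#' percentile pooling of boundary-clamped expert responses can yield an exact
#' zero, but an elicited zero reflects truncation of the response scale, not
#' logical impossibility, and a hard CPT zero would make otherwise ordinary
#' evidence (e.g. an observed decrease in outbreak frequency) impossible
#' under the model. Set `prob_floor = 0` to keep elicited zeros as-is.
#'
#' @param struct A `reefbn_structure`.
#' @param parameterization A `reefbn_parameterization` (or any tibble with
#'   `quantity_id` and `value`) covering every quantity in
#'   [elicited_quantities()].
#' @param thresholds Composite-index cut points, passed to [composite_cpt()].
#' @param prob_floor Minimum elicited probability per CPT-endpoint entry
#'   (default 0.001).
#'
#' @return A `reefbn_model`: list with `structure`, `cpts`, and the
#'   parameterization `label`.
#' @export
build_model <- function(struct, parameterization, thresholds = c(1 / 3, 2 / 3),
                        prob_floor = 1e-3) {
  need <- elicited_quantities(struct)
  values <- param_values(parameterization)
  absent <- setdiff(need$quantity_id, names(values))
  if (length(absent) > 0) {
    abort(sprintf(
      "parameterization is missing quantit%s: %s",
      if (length(absent) > 1) "ies" else "y", paste(absent, collapse = ", ")
    ))
  }

  cpts <- list()
  for (n in names(struct$nodes)) {
    nd <- struct$nodes[[n]]
    if (nd$kind == "input") next
    parent_nodes <- unname(struct$nodes[nd$parents])
    if (nd$kind == "composite") {
      w <- struct$composite_weights[[n]]
      if (is.null(w)) {
        w <- setNames(rep(1, length(nd$parents)), nd$parents)
      }
      cpts[[n]] <- composite_cpt(nd, parent_nodes, w, thresholds = thresholds)
    } else {
      ids_low <- paste(n, "low", nd$states, sep = ".")
      ids_high <- paste(n, "high", nd$states, sep = ".")
      cpts[[n]] <- interpolate_cpt(
        nd, parent_nodes,
        low_endpoint = pmax(unname(values[ids_low]), prob_floor),
        high_endpoint = pmax(unname(values[ids_high]), prob_floor)
      )
    }
  }
  model <- structure(
    list(
      structure = struct,
      cpts = cpts,
      label = attr(parameterization, "label") %||% "custom"
    ),
    class = "reefbn_model"
  )
  report <- validate_network(model)
  if (!all(report$ok)) {
    bad <- report[!report$ok, ]
    abort(sprintf(
      "built model failed validation: %s",
      paste(sprintf("%s[%s]: %s", bad$check, bad$node, bad$detail), collapse = "; ")
    ))
  }
  model
}

#' @export
print.reefbn_model <- function(x, ...) {
  cat(sprintf(
    "<reefbn model: %d nodes, %d CPTs, parameterization '%s'>\n",
    length(x$structure$nodes), length(x$cpts), x$label
  ))
  invisible(x)
}

#' @rdname tidy.reefbn_model
#' @export
glance.reefbn_model <- function(x, ...) {
  kinds <- vapply(x$structure$nodes, `[[`, character(1), "kind")
  tibble::tibble(
    parameterization = x$label,
    n_nodes = length(x$structure$nodes),
    n_input = sum(kinds == "input"),
    n_composite = sum(kinds == "composite"),
    n_event = sum(kinds == "event"),
    n_cpt_rows = sum(vapply(x$cpts, function(cpt) nrow(cpt$prob), numeric(1))),
    valid = network_is_valid(x)
  )
}

#' Tidy a reefbn model into one row per CPT entry
#'
#' `tidy()` flattens every conditional probability table into a long tibble:
#' one row per (parent-state combination, node state) with its probability.
#' `glance()` gives a one-row model summary.
#'
#' @param x A `reefbn_model`.
#' @param ... Unused.
#'
#' @return A tibble with columns `node`, `parent_combo`, `state`,
#'   `probability`.
#' @export
tidy.reefbn_model <- function(x, ...) {
  purrr::map_dfr(x$cpts, function(cpt) {
    grid <- parent_grid(x$structure, cpt$parents)
    combo <- if (length(cpt$parents) == 0) {
      "(prior)"
    } else {
      apply(grid, 1, function(r) paste(sprintf("%s=%s", cpt$parents, r), collapse = ", "))
    }
    tibble::tibble(
      node = cpt$node,
      parent_combo = rep(combo, times = length(cpt$states)),
      state = rep(cpt$states, each = nrow(cpt$prob)),
      probability = as.vector(cpt$prob)
    )
  })
}
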