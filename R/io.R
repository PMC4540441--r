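# File formats. All tabular interchange is plain CSV: written with readr
# (lossless shortest-round-trip doubles) and parsed with base R, whose
# decimal-to-double conversion is correctly rounded, so numeric tables
# round-trip bit-exactly. Network structures and scenarios are YAML; spatial
# output is GeoJSON (point features at reef centroids, predictions as
# properties).

read_csv_exact <- function(path, col_classes = NA) {
  tibble::as_tibble(utils::read.csv(path, colClasses = col_classes, check.names = FALSE))
}

#' Read and write elicitation record files
#'
#' CSV with header `expert_id,quantity_id,lowest,best,highest,confidence`,
#' one row per (expert, quantity). Reading validates the 4-point invariants.
#'
#' @param path File path.
#'
#' @return `read_elicitation()`: a validated elicitation tibble.
#' @export
read_elicitation <- function(path) {
  validate_responses(read_csv_exact(path, c(
    expert_id = "character", quantity_id = "character",
    lowest = "numeric", best = "numeric", highest = "numeric",
    confidence = "numeric"
  )))
}

#' @rdname read_elicitation
#' @param responses Elicitation tibble.
#' @export
write_elicitation <- function(responses, path) {
  readr::write_csv(validate_responses(responses), path)
  invisible(path)
}

#' Read and write parameterization files
#'
#' CSV with columns `label,quantity_id,value`; values round-trip bit-exactly.
#'
#' @param path File path.
#'
#' @return `read_parameterization()`: a `reefbn_parameterization`.
#' @export
read_parameterization <- function(path) {
  tbl <- read_csv_exact(path, c(
    label = "character", quantity_id = "character", value = "numeric"
  ))
  label <- unique(tbl$label)
  if (length(label) != 1) abort("parameterization file must carry a single label")
  new_parameterization(tbl[c("quantity_id", "value")], label)
}

#' @rdname read_parameterization
#' @param param A `reefbn_parameterization`.
#' @export
write_parameterization <- function(param, path) {
  readr::write_csv(
    tibble::tibble(
      label = attr(param, "label"),
      quantity_id = param$quantity_id,
      value = param$value
    ),
    path
  )
  invisible(path)
}

#' Read and write reef tables
#'
#' CSV, one row per reef, with identity columns (`reef_id`, `lon`, `lat`,
#' `shelf`, `no_take`) and one numeric column per environmental layer.
#' Reading validates coordinate ranges and non-negative effort/exposure.
#'
#' @param path File path.
#'
#' @return `read_reefs()`: a reef tibble.
#' @export
read_reefs <- function(path) {
  validate_reefs(read_csv_exact(path, c(
    reef_id = "character", shelf = "character", no_take = "logical"
  )))
}

#' @rdname read_reefs
#' @param reefs Reef tibble.
#' @export
write_reefs <- function(reefs, path) {
  readr::write_csv(validate_reefs(reefs), path)
  invisible(path)
}

#' Validate a reef table
#'
#' @param reefs Reef tibble.
#' @return The validated tibble.
#' @export
validate_reefs <- function(reefs) {
  reefs <- tibble::as_tibble(reefs)
  assert_cols(reefs, c("reef_id", "lon", "lat", "shelf", "no_take"), "reef table")
  if (any(abs(reefs$lat) > 90) || any(abs(reefs$lon) > 180)) {
    abort("reef centroids outside valid lon/lat ranges")
  }
  if (anyDuplicated(reefs$reef_id)) abort("duplicate reef_id in reef table")
  for (col in intersect(c("fishing_effort", "cyclone_exposure", "cots_outbreak"), names(reefs))) {
    if (any(reefs[[col]] < 0)) abort(sprintf("'%s' must be non-negative", col))
  }
  reefs
}

#' Read and write layer statistics files
#'
#' CSV `layer,mean,sd`.
#'
#' @param path File path.
#' @return `read_layer_stats()`: a stats tibble.
#' @export
read_layer_stats <- function(path) {
  stats <- read_csv_exact(path, c(
    layer = "character", mean = "numeric", sd = "numeric"
  ))
  if (any(stats$sd <= 0)) abort("layer sds must be strictly positive")
  stats
}

#' @rdname read_layer_stats
#' @param stats Stats tibble (`layer`, `mean`, `sd`).
#' @export
write_layer_stats <- function(stats, path) {
  readr::write_csv(tibble::as_tibble(stats), path)
  invisible(path)
}

#' Read and write effort grid files
#'
#' Coarse totals: CSV `block_id,total`. Fine weights: CSV
#' `block_id,cell_id,weight`.
#'
#' @param path File path.
#' @return The corresponding tibble.
#' @export
read_effort_coarse <- function(path) {
  read_csv_exact(path, c(block_id = "character", total = "numeric"))
}

#' @rdname read_effort_coarse
#' @export
read_effort_weights <- function(path) {
  read_csv_exact(path, c(
    block_id = "character", cell_id = "character", weight = "numeric"
  ))
}

#' Read and write network structure files
#'
#' YAML listing each node's kind, ordered states and parents, plus composite
#' weights, e.g.:
#'
#' ```yaml
#' nodes:
#'   temperature: {kind: input, states: [below, average, above]}
#'   decline:
#'     kind: outcome
#'     states: [no_decline, decline]
#'     parents: [bleaching, disease, cots, cyclones, anthropogenic_stress]
#' composite_weights:
#'   water_quality: {nutrients: 1, sediment: 1, pollution: 1}
#' ```
#'
#' @param path File path.
#' @return `read_structure()`: a `reefbn_structure`.
#' @export
read_structure <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$nodes)) abort("structure file has no `nodes` section")
  nodes <- purrr::imap(spec$nodes, function(nd, name) {
    bn_node(
      name = name,
      kind = nd$kind,
      states = as.character(nd$states),
      parents = as.character(nd$parents %||% character())
    )
  })
  weights <- purrr::map(spec$composite_weights %||% list(), function(w) {
    unlist(w)
  })
  bn_structure(unname(nodes), composite_weights = weights)
}

#' @rdname read_structure
#' @param struct A `reefbn_structure`.
#' @export
write_structure <- function(struct, path) {
  spec <- list(
    nodes = purrr::map(struct$nodes, function(nd) {
      out <- list(kind = nd$kind, states = as.list(nd$states))
      if (length(nd$parents) > 0) out$parents <- as.list(nd$parents)
      out
    }),
    composite_weights = purrr::map(struct$composite_weights, as.list)
  )
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' Read and write scenario files
#'
#' YAML with `name`, `temp_delta`, `cyclone_multiplier`, and a `shifts` map
#' whose values may be numeric (-1/0/1) or the conventional symbols
#' `"+"` / `"-"` / `"n.c."`.
#'
#' @param path File path.
#' @return `read_scenario()`: a [scenario()] object.
#' @export
read_scenario <- function(path) {
  spec <- yaml::read_yaml(path)
  shifts <- purrr::map_dbl(spec$shifts %||% list(), function(v) {
    if (is.character(v)) {
      switch(v,
        "+" = 1, "-" = -1, "n.c." = 0, "nc" = 0,
        abort(sprintf("unknown shift symbol '%s'", v))
      )
    } else {
      as.numeric(v)
    }
  })
  scenario(
    name = spec$name %||% abort("scenario file has no `name`"),
    shifts = shifts,
    temp_delta = spec$temp_delta %||% 0,
    cyclone_multiplier = spec$cyclone_multiplier %||% 1
  )
}

#' @rdname read_scenario
#' @param scn A [scenario()].
#' @export
write_scenario <- function(scn, path) {
  yaml::write_yaml(
    list(
      name = scn$name,
      temp_delta = scn$temp_delta,
      cyclone_multiplier = scn$cyclone_multiplier,
      shifts = as.list(scn$shifts)
    ),
    path
  )
  invisible(path)
}

#' Read and write CPT files
#'
#' Long CSV with columns `node`, one column per parent (its state in that
#' row's conditioning combination, `NA`-free; parentless nodes have none),
#' `state`, `probability`; bit-exact round-trip against the model's CPTs.
#'
#' @param model A `reefbn_model`.
#' @param path File path.
#' @export
write_cpts <- function(model, path) {
  long <- purrr::map_dfr(model$cpts, function(cpt) {
    grid <- parent_grid(model$structure, cpt$parents)
    grid_rep <- grid[rep(seq_len(nrow(grid)), times = length(cpt$states)), , drop = FALSE]
    dplyr::bind_cols(
      tibble::tibble(node = cpt$node),
      grid_rep,
      tibble::tibble(
        state = rep(cpt$states, each = nrow(grid)),
        probability = as.vector(cpt$prob)
      )
    )
  })
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_cpts
#' @param struct The `reefbn_structure` the CPTs belong to.
#' @return `read_cpts()`: a named list of CPT objects.
#' @export
read_cpts <- function(path, struct) {
  long <- read_csv_exact(path, c(
    node = "character", state = "character", probability = "numeric"
  ))
  cpts <- list()
  for (n in unique(long$node)) {
    nd <- struct$nodes[[n]]
    if (is.null(nd)) abort(sprintf("CPT file names unknown node '%s'", n))
    rows <- long[long$node == n, ]
    grid <- parent_grid(struct, nd$parents)
    prob <- matrix(NA_real_, nrow(grid), length(nd$states),
      dimnames = list(NULL, nd$states)
    )
    key <- function(df) {
      if (length(nd$parents) == 0) rep("", nrow(df)) else do.call(paste, c(df[nd$parents], sep = "\r"))
    }
    row_i <- match(key(rows), key(grid))
    col_i <- match(rows$state, nd$states)
    if (any(is.na(row_i)) || any(is.na(col_i))) {
      abort(sprintf("CPT file rows for '%s' do not match the structure", n))
    }
    prob[cbind(row_i, col_i)] <- rows$probability
    if (any(is.na(prob))) abort(sprintf("CPT file for '%s' is incomplete", n))
    cpts[[n]] <- new_cpt(n, nd$parents, nd$states, prob)
  }
  cpts
}

#' Write predictions as CSV
#'
#' CSV with columns `reef_id,scenario,parameterization,p_decline`.
#'
#' @param pred A `reefbn_predictions` tibble.
#' @param path File path.
#' @export
write_predictions <- function(pred, path) {
  readr::write_csv(
    tibble::tibble(
      reef_id = pred$reef_id,
      scenario = attr(pred, "scenario") %||% NA_character_,
      parameterization = attr(pred, "parameterization") %||% NA_character_,
      p_decline = pred$p_decline
    ),
    path
  )
  invisible(path)
}

#' @rdname write_predictions
#' @return `read_predictions()`: a `reefbn_predictions` tibble.
#' @export
read_predictions <- function(path) {
  tbl <- read_csv_exact(path, c(
    reef_id = "character", scenario = "character",
    parameterization = "character", p_decline = "numeric"
  ))
  new_predictions(
    tbl[c("reef_id", "p_decline")],
    scenario = unique(tbl$scenario),
    parameterization = unique(tbl$parameterization)
  )
}

#' Write a GeoJSON point layer of reef predictions
#'
#' One Point feature per reef at its centroid (WGS84 lon/lat), with the
#' requested columns attached as feature properties — ready for any GIS or
#' web map.
#'
#' @param reefs Reef tibble with `reef_id`, `lon`, `lat`.
#' @param path Output path.
#' @param properties Tibble keyed by `reef_id` whose remaining columns become
#'   feature properties (e.g. a predictions or change-map tibble); `NULL` for
#'   geometry-only output.
#' @export
write_geojson <- function(reefs, path, properties = NULL) {
  reefs <- tibble::as_tibble(reefs)
  assert_cols(reefs, c("reef_id", "lon", "lat"), "reef table")
  props <- tibble::tibble(reef_id = reefs$reef_id)
  if (!is.null(properties)) {
    props <- dplyr::left_join(
      props, tibble::as_tibble(properties),
      by = "reef_id"
    )
  }
  features <- purrr::map(seq_len(nrow(reefs)), function(i) {
    list(
      type = "Feature",
      geometry = list(
        type = "Point",
        coordinates = c(reefs$lon[i], reefs$lat[i])
      ),
      properties = as.list(props[i, ])
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path,
    auto_unbox = TRUE, digits = NA, pretty = FALSE
  )
  invisible(path)
}
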