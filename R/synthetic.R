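# Seeded synthetic data: reef fleets, expert pools, effort grids.
#
# These generators emulate the statistical shape of the study inputs — a
# mid-shelf reef fleet with roughly one-third of reefs in no-take zones, and
# a pool of ecologists whose 4-point answers scatter around a configurable
# "true" parameterization — so the full pipeline is testable without any
# external data, and so parameter-recovery experiments are possible. They are
# synthetic stand-ins with documented, configurable distribution families,
# not estimates of actual Great Barrier Reef conditions.

#' Generate a synthetic mid-shelf reef table
#'
#' Reef centroids are scattered uniformly in a latitude/longitude box
#' (defaults: the central-GBR mid-shelf band, 22.31-15.77 S), a configurable
#' fraction is flagged no-take, and layer values are drawn from
#' qualitatively realistic families: normal for temperature anomaly and
#' irradiance, Poisson counts for decadal cyclone exposure and
#' crown-of-thorns outbreaks, lognormal for fishing effort and the
#' plume/nutrient/sediment/pollution load indices (unitless skewed
#' non-negative indices).
#'
#' @param n_reefs Number of reefs (default 775, a central-GBR mid-shelf
#'   fleet).
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @param lat_range,lon_range Centroid bounding box, decimal degrees WGS84.
#' @param no_take_fraction Fraction of reefs flagged no-take (default 0.33).
#' @param layer_params Named list overriding per-layer distribution
#'   parameters; see the function body for the default families.
#'
#' @return A reef tibble with columns `reef_id`, `lon`, `lat`, `shelf`,
#'   `no_take`, `temp_anomaly`, `cyclone_exposure`, `plume_exposure`,
#'   `nutrient_load`, `sediment_load`, `pollution_load`, `irradiance`,
#'   `cots_outbreak`, `fishing_effort`.
#' @export
#' @examples
#' generate_reefs(n_reefs = 5, seed = 1)
generate_reefs <- function(n_reefs = 775,
                           seed = 1,
                           lat_range = c(-22.31, -15.77),
                           lon_range = c(145.5, 151.5),
                           no_take_fraction = 0.33,
                           layer_params = list()) {
  if (!is.numeric(n_reefs) || n_reefs < 1) abort("`n_reefs` must be >= 1")
  if (no_take_fraction < 0 || no_take_fraction > 1) {
    abort("`no_take_fraction` must be in [0, 1]")
  }
  defaults <- list(
    temp_anomaly = list(family = "normal", mean = 0, sd = 0.5),
    irradiance = list(family = "normal", mean = 40, sd = 5),
    cyclone_exposure = list(family = "poisson", lambda = 2),
    cots_outbreak = list(family = "poisson", lambda = 1),
    plume_exposure = list(family = "lognormal", meanlog = 0, sdlog = 0.6),
    nutrient_load = list(family = "lognormal", meanlog = 1, sdlog = 0.5),
    sediment_load = list(family = "lognormal", meanlog = 1.5, sdlog = 0.5),
    pollution_load = list(family = "lognormal", meanlog = 0.5, sdlog = 0.5),
    fishing_effort = list(family = "lognormal", meanlog = 3, sdlog = 0.5)
  )
  params <- utils::modifyList(defaults, layer_params)

  withr::local_seed(seed)
  n <- as.integer(n_reefs)
  draw <- function(p) {
    switch(p$family,
      normal = rnorm(n, p$mean, p$sd),
      poisson = as.numeric(rpois(n, p$lambda)),
      lognormal = rlnorm(n, p$meanlog, p$sdlog),
      abort(sprintf("unknown distribution family '%s'", p$family))
    )
  }
  n_no_take <- round(n * no_take_fraction)
  no_take <- sample(rep(c(TRUE, FALSE), c(n_no_take, n - n_no_take)))
  tibble::tibble(
    reef_id = sprintf("reef_%04d", seq_len(n)),
    lon = runif(n, lon_range[1], lon_range[2]),
    lat = runif(n, lat_range[1], lat_range[2]),
    shelf = "mid",
    no_take = no_take,
    temp_anomaly = draw(params$temp_anomaly),
    cyclone_exposure = draw(params$cyclone_exposure),
    plume_exposure = draw(params$plume_exposure),
    nutrient_load = draw(params$nutrient_load),
    sediment_load = draw(params$sediment_load),
    pollution_load = draw(params$pollution_load),
    irradiance = draw(params$irradiance),
    cots_outbreak = draw(params$cots_outbreak),
    fishing_effort = draw(params$fishing_effort)
  )
}

#' Default "true" elicited probabilities for the shipped network
#'
#' The truth the synthetic expert pool scatters around: one probability per
#' elicited quantity of [default_structure()]. Endpoint distributions are
#' chosen so that the all-adverse endpoint stochastically dominates the
#' all-benign endpoint on each node's adversity order (more stress means more
#' frequent adverse events and likelier decline), with a moderate decline
#' probability even at the benign endpoint — consistent with a system already
#' in slow decline.
#'
#' @return Named numeric vector `quantity_id -> probability`.
#' @export
default_truth <- function() {
  c(
    bleaching.low.decreased = 0.50, bleaching.low.unchanged = 0.40, bleaching.low.increased = 0.10,
    bleaching.high.decreased = 0.05, bleaching.high.unchanged = 0.15, bleaching.high.increased = 0.80,
    disease.low.decreased = 0.45, disease.low.unchanged = 0.45, disease.low.increased = 0.10,
    disease.high.decreased = 0.10, disease.high.unchanged = 0.20, disease.high.increased = 0.70,
    cots.low.decreased = 0.35, cots.low.unchanged = 0.45, cots.low.increased = 0.20,
    cots.high.decreased = 0.10, cots.high.unchanged = 0.30, cots.high.increased = 0.60,
    decline.low.no_decline = 0.70, decline.low.decline = 0.30,
    decline.high.no_decline = 0.05, decline.high.decline = 0.95
  )
}

#' Generate a synthetic 4-point expert pool
#'
#' Each expert's best estimate for each quantity is the true probability plus
#' symmetric noise, clamped to \[0, 1\] (additive on the probability scale by
#' default; `noise = "logit"` perturbs on the log-odds scale instead, which
#' respects boundaries for truths near 0 or 1). Lowest/highest are the best
#' estimate minus/plus `interval_width`, clamped; confidence is the stated
#' level for every response.
#'
#' @param truth Named vector of true probabilities per quantity (default
#'   [default_truth()]).
#' @param n_experts Number of experts (default 21).
#' @param noise_sd Spread of expert error (probability scale, or log-odds
#'   scale under `noise = "logit"`).
#' @param interval_width Half-spread of the stated (lowest, highest)
#'   interval around the best estimate.
#' @param confidence Stated confidence level for every interval.
#' @param noise `"additive"` (default) or `"logit"`.
#' @param seed Integer seed.
#'
#' @return An elicitation tibble with columns `expert_id`, `quantity_id`,
#'   `lowest`, `best`, `highest`, `confidence`, passing
#'   [validate_responses()].
#' @export
#' @examples
#' generate_expert_pool(n_experts = 3, seed = 1)
generate_expert_pool <- function(truth = default_truth(),
                                 n_experts = 21,
                                 noise_sd = 0.1,
                                 interval_width = 0.15,
                                 confidence = 80,
                                 noise = c("additive", "logit"),
                                 seed = 1) {
  noise <- match.arg(noise)
  if (!is.numeric(n_experts) || n_experts < 1) abort("`n_experts` must be >= 1")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  if (is.null(names(truth)) || any(truth < 0) || any(truth > 1)) {
    abort("`truth` must be a named vector of probabilities")
  }
  withr::local_seed(seed)
  n_e <- as.integer(n_experts)
  grid <- tidyr::expand_grid(
    expert_id = sprintf("expert_%05d", seq_len(n_e)),
    quantity_id = names(truth)
  )
  tv <- truth[grid$quantity_id]
  eps <- rnorm(nrow(grid), 0, noise_sd)
  best <- if (noise == "additive") {
    clamp01(tv + eps)
  } else {
    tvc <- pmin(1 - 1e-6, pmax(1e-6, tv))
    stats::plogis(stats::qlogis(tvc) + eps)
  }
  grid |>
    dplyr::mutate(
      lowest = clamp01(best - interval_width),
      best = unname(best),
      highest = clamp01(best + interval_width),
      confidence = confidence
    ) |>
    dplyr::select(
      "expert_id", "quantity_id", "lowest", "best", "highest", "confidence"
    )
}

#' Generate a coarse/fine effort-grid fixture
#'
#' Draws positive lognormal block totals and positive fine-cell weights, the
#' inputs [downscale_effort()] expects.
#'
#' @param n_blocks Number of coarse blocks.
#' @param cells_per_block Fine cells per block.
#' @param seed Integer seed.
#'
#' @return List with `coarse` (block_id, total) and `weights`
#'   (block_id, cell_id, weight) tibbles.
#' @export
generate_effort_grids <- function(n_blocks = 4, cells_per_block = 5, seed = 1) {
  if (n_blocks < 1 || cells_per_block < 1) {
    abort("`n_blocks` and `cells_per_block` must be >= 1")
  }
  withr::local_seed(seed)
  coarse <- tibble::tibble(
    block_id = sprintf("block_%02d", seq_len(n_blocks)),
    total = rlnorm(n_blocks, meanlog = 4, sdlog = 0.5)
  )
  weights <- tidyr::expand_grid(
    block_id = coarse$block_id,
    cell = seq_len(cells_per_block)
  ) |>
    dplyr::mutate(
      cell_id = sprintf("%s_cell_%02d", .data$block_id, .data$cell),
      weight = rlnorm(dplyr::n(), meanlog = 0, sdlog = 0.7)
    ) |>
    dplyr::select("block_id", "cell_id", "weight")
  list(coarse = coarse, weights = weights)
}
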