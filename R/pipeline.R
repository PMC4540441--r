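# End-to-end pipeline on files: simulate inputs, run all scenario x
# parameterization combinations, and report. These functions are the
# programmatic entry points; inst/scripts/reefbn is a thin command-line
# wrapper over them.

#' Write a complete set of synthetic pipeline inputs
#'
#' Generates a reef table, an expert elicitation table, effort-grid fixtures,
#' the default network structure and the four shipped scenarios, and writes
#' them under `dir` in the formats the pipeline reads. All randomness flows
#' from `seed`; the same seed yields byte-identical files.
#'
#' @param dir Output directory (created if absent).
#' @param seed Integer seed.
#' @param n_reefs,n_experts Sizes passed to the generators.
#' @param truth True parameterization for the expert pool.
#' @param quiet Suppress progress messages?
#' @param ... Further arguments to [generate_reefs()].
#'
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_inputs <- function(dir, seed = 1, n_reefs = 775, n_experts = 21,
                            truth = default_truth(), quiet = FALSE, ...) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    if (!quiet) inform(sprintf("created output directory %s", dir))
  }
  if (!quiet) {
    inform(sprintf(
      "simulate: n_reefs=%d, n_experts=%d, seed=%d", n_reefs, n_experts, seed
    ))
  }
  reefs <- generate_reefs(n_reefs = n_reefs, seed = seed, ...)
  experts <- generate_expert_pool(truth = truth, n_experts = n_experts, seed = seed + 1)
  grids <- generate_effort_grids(seed = seed + 2)

  paths <- list(
    reefs = file.path(dir, "reefs.csv"),
    elicitation = file.path(dir, "elicitation.csv"),
    effort_coarse = file.path(dir, "effort_coarse.csv"),
    effort_weights = file.path(dir, "effort_weights.csv"),
    structure = file.path(dir, "structure.yaml")
  )
  write_reefs(reefs, paths$reefs)
  write_elicitation(experts, paths$elicitation)
  readr::write_csv(grids$coarse, paths$effort_coarse)
  readr::write_csv(grids$weights, paths$effort_weights)
  write_structure(default_structure(), paths$structure)
  scn_dir <- file.path(dir, "scenarios")
  if (!dir.exists(scn_dir)) dir.create(scn_dir)
  for (scn in default_scenarios()) {
    p <- file.path(scn_dir, paste0(scn$name, ".yaml"))
    write_scenario(scn, p)
    paths[[paste0("scenario_", scn$name)]] <- p
  }
  invisible(paths)
}

# the three headline scenario comparisons (reference first)
CHANGE_MAP_PAIRS <- list(
  climate_management_vs_baseline = c("baseline", "climate_management"),
  climate_management_vs_climate = c("climate", "climate_management"),
  management_vs_baseline = c("baseline", "management")
)

#' Run the full scenario analysis
#'
#' Reads (or accepts) a reef table, elicitation records, a network structure
#' and scenarios; applies zoning; pools the elicitation into the requested
#' parameterizations; and for every scenario x parameterization writes
#' per-reef predictions (CSV + GeoJSON), a zone-comparison table, and the
#' three headline relative-change maps (climate+management vs baseline,
#' climate+management vs climate-only, management-only vs baseline) for each
#' parameterization.
#'
#' @param input_dir Directory laid out by [simulate_inputs()]; alternatively
#'   supply `reefs`, `elicitation`, `struct`, `scenarios` directly.
#' @param out_dir Output directory (created if absent).
#' @param labels Parameterization labels to run.
#' @param target_level Credible level for interval standardization.
#' @param reefs,elicitation,struct,scenarios Optional in-memory inputs
#'   overriding `input_dir`.
#' @param geojson Also write GeoJSON per prediction set? Default `TRUE`.
#' @param quiet Suppress progress messages?
#'
#' @return Invisibly, a list with `predictions` (named list of prediction
#'   tibbles), `zone_summary`, `change_maps`, and `means` (one row per
#'   scenario x parameterization).
#' @export
run_pipeline <- function(input_dir = NULL, out_dir,
                         labels = c("mean", "pessimistic", "optimistic"),
                         target_level = 90,
                         reefs = NULL, elicitation = NULL, struct = NULL,
                         scenarios = NULL, geojson = TRUE, quiet = FALSE) {
  if (is.null(reefs)) reefs <- read_reefs(file.path(input_dir, "reefs.csv"))
  if (is.null(elicitation)) {
    elicitation <- read_elicitation(file.path(input_dir, "elicitation.csv"))
  }
  if (is.null(struct)) struct <- read_structure(file.path(input_dir, "structure.yaml"))
  if (is.null(scenarios)) {
    files <- sort(list.files(
      file.path(input_dir, "scenarios"),
      pattern = "\\.yaml$", full.names = TRUE
    ))
    scenarios <- purrr::map(files, read_scenario)
    names(scenarios) <- purrr::map_chr(scenarios, "name")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!quiet) {
    inform(sprintf(
      "run: %d reefs, %d scenarios, parameterizations: %s",
      nrow(reefs), length(scenarios), paste(labels, collapse = ", ")
    ))
  }

  reefs <- apply_zoning(validate_reefs(reefs))
  stats <- compute_layer_stats(reefs)
  standardized <- standardize_responses(elicitation, target_level = target_level)
  orientation <- default_orientation(struct)
  required <- elicited_quantities(struct)$quantity_id

  models <- purrr::map(setNames(labels, labels), function(lab) {
    build_model(struct, build_parameterization(
      standardized,
      label = lab, orientation = orientation,
      required_quantities = required
    ))
  })

  predictions <- list()
  zone_rows <- list()
  for (lab in labels) {
    for (scn in scenarios) {
      key <- paste(scn$name, lab, sep = "_")
      pred <- predict_decline(models[[lab]], reefs, scn, stats)
      predictions[[key]] <- pred
      write_predictions(pred, file.path(out_dir, paste0("predictions_", key, ".csv")))
      if (geojson) {
        write_geojson(
          reefs, file.path(out_dir, paste0("predictions_", key, ".geojson")),
          properties = tibble::tibble(
            reef_id = pred$reef_id,
            scenario = scn$name, parameterization = lab,
            p_decline = pred$p_decline
          )
        )
      }
      zone_rows[[key]] <- summarize_by_zone(pred, reefs)
    }
  }
  zone_summary <- dplyr::bind_rows(zone_rows)
  readr::write_csv(zone_summary, file.path(out_dir, "zone_summary.csv"))

  change_maps <- list()
  for (lab in labels) {
    for (cmp in names(CHANGE_MAP_PAIRS)) {
      pair <- CHANGE_MAP_PAIRS[[cmp]]
      key_a <- paste(pair[1], lab, sep = "_")
      key_b <- paste(pair[2], lab, sep = "_")
      if (is.null(predictions[[key_a]]) || is.null(predictions[[key_b]])) next
      cm <- change_map(predictions[[key_a]], predictions[[key_b]])
      change_maps[[paste(cmp, lab, sep = "_")]] <- cm
      readr::write_csv(
        tibble::as_tibble(cm),
        file.path(out_dir, paste0("change_", cmp, "_", lab, ".csv"))
      )
    }
  }

  means <- purrr::map_dfr(predictions, glance)
  readr::write_csv(means, file.path(out_dir, "scenario_means.csv"))
  invisible(list(
    predictions = predictions,
    zone_summary = zone_summary,
    change_maps = change_maps,
    means = means
  ))
}

#' Summarize a finished pipeline run
#'
#' Reads the outputs written by [run_pipeline()] and returns the headline
#' tables: mean decline per scenario x parameterization, zone differences,
#' and the mean relative change of each headline scenario comparison.
#' Regenerating the report from the same directory is idempotent.
#'
#' @param out_dir Directory written by [run_pipeline()].
#'
#' @return A list of tibbles: `means`, `zone_summary`, `headline_changes`.
#' @export
pipeline_report <- function(out_dir) {
  means_path <- file.path(out_dir, "scenario_means.csv")
  zone_path <- file.path(out_dir, "zone_summary.csv")
  missing <- c(means_path, zone_path)[!file.exists(c(means_path, zone_path))]
  if (length(missing) > 0) {
    abort(sprintf(
      "pipeline outputs missing under '%s': %s",
      out_dir, paste(basename(missing), collapse = ", ")
    ))
  }
  means <- readr::read_csv(means_path, col_types = readr::cols())
  zone <- readr::read_csv(zone_path, col_types = readr::cols())
  change_files <- list.files(out_dir, pattern = "^change_.*\\.csv$", full.names = TRUE)
  headline <- purrr::map_dfr(change_files, function(f) {
    cm <- readr::read_csv(f, col_types = readr::cols())
    ok <- !cm$undefined
    tibble::tibble(
      comparison = sub("^change_(.*)\\.csv$", "\\1", basename(f)),
      n_reefs = nrow(cm),
      mean_rel_change = base::mean(cm$rel_change[ok]),
      mean_change_of_means = (base::mean(cm$p_b) - base::mean(cm$p_a)) / base::mean(cm$p_a)
    )
  })
  list(means = means, zone_summary = zone, headline_changes = headline)
}
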