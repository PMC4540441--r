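test_that("layer discretization puts the 1 SD boundaries in the extremes", {
  expect_equal(discretize_layer(10, mean = 10, sd = 2), "average")
  expect_equal(discretize_layer(12, mean = 10, sd = 2), "above") # boundary inclusive
  expect_equal(discretize_layer(8, mean = 10, sd = 2), "below")
  expect_equal(discretize_layer(7.9, mean = 10, sd = 2), "below")
  expect_equal(discretize_layer(11.9, mean = 10, sd = 2), "average")
  expect_error(discretize_layer(NaN, 10, 2, context = "reef_0001/nutrients"), "nutrients")
  expect_error(discretize_layer(1, 10, 0), "positive sd")
})

test_that("temperature discretization keeps the 1 degree boundaries in average", {
  expect_equal(discretize_temperature(c(0, 1.2, -1, 1, -1.01)),
    c("average", "above", "average", "average", "below")
  )
  expect_error(discretize_temperature(Inf), "non-finite")
})

test_that("discretization is monotone in the layer value", {
  set.seed(3)
  x <- sort(runif(200, 0, 20))
  states <- discretize_layer(x, mean = 10, sd = 2)
  idx <- match(states, c("below", "average", "above"))
  expect_true(all(diff(idx) >= 0))
  t_idx <- match(discretize_temperature(sort(runif(200, -3, 3))), c("below", "average", "above"))
  expect_true(all(diff(t_idx) >= 0))
})

test_that("effort downscaling reapportions totals proportionally", {
  even <- downscale_effort(
    tibble::tibble(block_id = "b", total = 100),
    tibble::tibble(block_id = "b", cell_id = paste0("c", 1:4), weight = 1)
  )
  expect_equal(even$effort, rep(25, 4))
  prop <- downscale_effort(
    tibble::tibble(block_id = "b", total = 90),
    tibble::tibble(block_id = "b", cell_id = c("c1", "c2"), weight = c(1, 2))
  )
  expect_equal(prop$effort, c(30, 60))
  zero <- downscale_effort(
    tibble::tibble(block_id = "b", total = 0),
    tibble::tibble(block_id = "b", cell_id = c("c1", "c2"), weight = c(0, 0))
  )
  expect_equal(zero$effort, c(0, 0))
  expect_error(
    downscale_effort(
      tibble::tibble(block_id = c("b1", "b2"), total = c(10, 5)),
      tibble::tibble(block_id = c("b1", "b1", "b2"), cell_id = c("c1", "c2", "c3"), weight = c(0, 0, 1))
    ),
    "all-zero weights: b1"
  )
  expect_error(
    downscale_effort(
      tibble::tibble(block_id = "lonely", total = 3),
      tibble::tibble(block_id = character(), cell_id = character(), weight = numeric())
    ),
    "no cells: lonely"
  )
})

test_that("downscaling conserves per-block mass on seeded fixtures", {
  grids <- generate_effort_grids(n_blocks = 6, cells_per_block = 8, seed = 5)
  fine <- downscale_effort(grids$coarse, grids$weights)
  sums <- fine |>
    dplyr::group_by(block_id) |>
    dplyr::summarise(total = sum(effort))
  merged <- dplyr::inner_join(sums, grids$coarse, by = "block_id", suffix = c("_fine", "_coarse"))
  expect_equal(nrow(merged), 6)
  expect_true(all(
    abs(merged$total_fine - merged$total_coarse) <= 1e-9 * merged$total_coarse
  ))
})

test_that("zoning zeroes effort only on no-take reefs", {
  reefs <- tibble::tibble(
    reef_id = c("r1", "r2", "r3"),
    no_take = c(TRUE, FALSE, TRUE),
    fishing_effort = c(12.3, 12.3, 4)
  )
  out <- apply_zoning(reefs)
  expect_equal(out$fishing_effort, c(0, 12.3, 0))
  expect_identical(out$reef_id, reefs$reef_id) # other fields untouched
  expect_error(apply_zoning(dplyr::mutate(reefs, no_take = "yes")), "logical")
})

test_that("reef evidence discretizes every node, with translated CoTS states", {
  stats <- tibble::tibble(
    layer = c(
      "cyclone_exposure", "irradiance", "nutrient_load", "sediment_load",
      "pollution_load", "fishing_effort", "cots_outbreak"
    ),
    mean = c(2, 40, 3, 4, 2, 10, 1),
    sd = c(1, 5, 1, 1, 1, 2, 0.5)
  )
  at_means <- tibble::tibble(
    reef_id = "r1", lon = 147, lat = -18, shelf = "mid", no_take = FALSE,
    temp_anomaly = 0, cyclone_exposure = 2, plume_exposure = 1,
    nutrient_load = 3, sediment_load = 4, pollution_load = 2,
    irradiance = 40, cots_outbreak = 1, fishing_effort = 10
  )
  ev <- evidence_for_reef(at_means, stats)
  expect_equal(ev[["cots"]], "unchanged")
  expect_true(all(ev[setdiff(names(ev), "cots")] == "average"))

  heavy <- dplyr::mutate(at_means, fishing_effort = 14) # mean + 2 sd
  ev2 <- evidence_for_reef(heavy, stats)
  expect_equal(ev2[["fishing"]], "above")
  expect_true(all(ev2[setdiff(names(ev2), c("fishing", "cots"))] == "average"))

  closed <- apply_zoning(dplyr::mutate(at_means, no_take = TRUE))
  expect_equal(evidence_for_reef(closed, stats)[["fishing"]], "below") # 0 <= 10 - 2

  expect_error(
    evidence_for_reef(dplyr::select(at_means, -nutrient_load), stats),
    "nutrient_load"
  )
  expect_error(evidence_for_reef(at_means[0, ], stats), "single reef")
  no_cots <- evidence_for_reef(at_means, stats, observe_cots = FALSE)
  expect_false("cots" %in% names(no_cots))
})

test_that("layer statistics come from the supplied table and reject degenerate layers", {
  fleet <- small_fleet()
  stats <- compute_layer_stats(fleet$reefs)
  expect_setequal(
    stats$layer,
    c(
      "cyclone_exposure", "irradiance", "nutrient_load", "sediment_load",
      "pollution_load", "fishing_effort", "cots_outbreak"
    )
  )
  expect_equal(
    stats$mean[stats$layer == "irradiance"],
    mean(fleet$reefs$irradiance)
  )
  flat <- dplyr::mutate(fleet$reefs, irradiance = 1)
  expect_error(compute_layer_stats(flat), "irradiance")
})

test_that("mid-shelf filtering is idempotent and keeps an all-mid fleet intact", {
  fleet <- small_fleet()
  once <- dplyr::filter(fleet$reefs, shelf == "mid")
  twice <- dplyr::filter(once, shelf == "mid")
  expect_identical(once, twice)
  expect_equal(nrow(once), nrow(fleet$reefs))
})
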