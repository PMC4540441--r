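test_that("state shifts move one category and clamp at the ends", {
  expect_equal(shift_state("above", 1), "above")
  expect_equal(shift_state("average", 1), "above")
  expect_equal(shift_state("below", -1), "below")
  expect_equal(shift_state("average", 0), "average")
  expect_equal(
    shift_state(c("decreased", "unchanged"), 1, c("decreased", "unchanged", "increased")),
    c("unchanged", "increased")
  )
  expect_error(shift_state("sideways", 1), "illegal state")
})

test_that("scenario construction validates variables and parameters", {
  expect_error(scenario("s", shifts = c(gravity = 1)), "unknown scenario variable")
  expect_error(scenario("s", shifts = c(fishing = 2)), "-1, 0 or \\+1")
  expect_error(scenario("s", cyclone_multiplier = 0), "positive")
  expect_error(scenario("s", temp_delta = NA_real_), "finite")
  scns <- default_scenarios()
  expect_named(scns, c("baseline", "climate", "climate_management", "management"))
  expect_equal(scns$climate$temp_delta, 0.2)
  expect_equal(scns$climate$cyclone_multiplier, 1.3)
  expect_equal(sort(names(scns$management$shifts)),
    c("fishing", "nutrients", "pollution", "sediment")
  )
})

test_that("the baseline scenario is the identity on evidence", {
  fleet <- small_fleet()
  base <- discretize_reefs(fleet$reefs, fleet$stats)
  via_scenario <- apply_scenario(fleet$reefs, default_scenarios()$baseline, fleet$stats)
  expect_identical(base, via_scenario)
})

test_that("scenario shifts act on categories, deltas and multipliers as declared", {
  stats <- tibble::tibble(
    layer = c(
      "cyclone_exposure", "irradiance", "nutrient_load", "sediment_load",
      "pollution_load", "fishing_effort", "cots_outbreak"
    ),
    mean = c(2, 40, 3, 4, 2, 10, 1),
    sd = c(1, 5, 1, 1, 1, 2, 0.5)
  )
  reef <- tibble::tibble(
    reef_id = "r1", lon = 147, lat = -18, shelf = "mid", no_take = FALSE,
    temp_anomaly = 0.9, cyclone_exposure = 2, plume_exposure = 1,
    nutrient_load = 3, sediment_load = 4, pollution_load = 2,
    irradiance = 40, cots_outbreak = 1, fishing_effort = 10
  )
  scns <- default_scenarios()

  ev3 <- apply_scenario(reef, scns$climate_management, stats)
  # management minus signs: average -> below for the four local stressors
  expect_equal(unlist(ev3[1, c("nutrients", "sediment", "pollution", "fishing")]),
    c(nutrients = "below", sediment = "below", pollution = "below", fishing = "below")
  )
  # +0.2 degrees pushes the 0.9 anomaly over the 1 degree threshold
  expect_equal(ev3$temperature, "above")
  # event-node shifts impose evidence moved from "unchanged"
  expect_equal(ev3$bleaching, "increased")
  expect_equal(ev3$disease, "increased")
  # CoTS held at its baseline observed state
  expect_equal(ev3$cots, "unchanged")

  ev4 <- apply_scenario(reef, scns$management, stats)
  expect_equal(ev4$temperature, "average") # no climate change in the best case
  # no event-node evidence is imposed without a climate shift
  expect_false(any(c("bleaching", "disease") %in% names(ev4)))

  # the cyclone multiplier acts on the continuous exposure before discretization
  windy <- dplyr::mutate(reef, cyclone_exposure = 2.5) # 2.5 * 1.3 = 3.25 >= mean + sd
  expect_equal(apply_scenario(windy, scns$climate, stats)$cyclones, "above")
  expect_equal(apply_scenario(windy, scns$baseline, stats)$cyclones, "average")
})

test_that("per-reef prediction is deterministic and respects constant leaves", {
  fleet <- small_fleet()
  const <- constant_leaf_model(p = 0.6)
  pred <- predict_decline(const, fleet$reefs, default_scenarios()$baseline, fleet$stats)
  expect_equal(pred$p_decline, rep(0.6, nrow(fleet$reefs)))
  expect_s3_class(pred, "reefbn_predictions")
  expect_identical(attr(pred, "scenario"), "baseline")

  # identical reefs get identical probabilities
  model <- build_model(default_structure(), truth_parameterization())
  twins <- fleet$reefs[c(1, 1), ]
  twins$reef_id <- c("t1", "t2")
  p2 <- predict_decline(model, twins, default_scenarios()$climate, fleet$stats)
  expect_equal(p2$p_decline[1], p2$p_decline[2])

  rerun <- predict_decline(model, fleet$reefs, default_scenarios()$climate, fleet$stats)
  rerun2 <- predict_decline(model, fleet$reefs, default_scenarios()$climate, fleet$stats)
  expect_identical(rerun, rerun2)
})

test_that("climate stress never lowers and management never raises per-reef decline", {
  fleet <- small_fleet()
  model <- build_model(default_structure(), truth_parameterization())
  scns <- default_scenarios()
  p1 <- predict_decline(model, fleet$reefs, scns$baseline, fleet$stats)
  p2 <- predict_decline(model, fleet$reefs, scns$climate, fleet$stats)
  p4 <- predict_decline(model, fleet$reefs, scns$management, fleet$stats)
  expect_true(all(p2$p_decline - p1$p_decline >= -1e-12))
  expect_true(all(p1$p_decline - p4$p_decline >= -1e-12))
})

test_that("zone summaries average with respect to the number of reefs", {
  reefs <- tibble::tibble(
    reef_id = c("r1", "r2", "r3"),
    no_take = c(FALSE, FALSE, TRUE)
  )
  pred <- tibble::tibble(reef_id = reefs$reef_id, p_decline = c(0.8, 0.6, 0.5))
  z <- summarize_by_zone(pred, reefs)
  expect_equal(z$mean_open, 0.7)
  expect_equal(z$mean_no_take, 0.5)
  expect_equal(z$difference, 0.2)
  expect_equal(z$mean_overall, mean(c(0.8, 0.6, 0.5)))
  expect_false(z$undefined_zone)

  flat <- tibble::tibble(reef_id = reefs$reef_id, p_decline = 0.5)
  zf <- summarize_by_zone(flat, reefs)
  expect_equal(zf$difference, 0)

  open_only <- dplyr::mutate(reefs, no_take = FALSE)
  zo <- summarize_by_zone(pred, open_only)
  expect_true(zo$undefined_zone)
  expect_true(is.na(zo$mean_no_take))
  expect_true(is.na(zo$difference))

  shuffled <- summarize_by_zone(pred[c(3, 1, 2), ], reefs[c(2, 3, 1), ])
  expect_equal(shuffled$mean_overall, z$mean_overall)
  expect_equal(shuffled$difference, z$difference)

  expect_error(summarize_by_zone(pred[-1, ], reefs), "r1")
})

test_that("change maps compute guarded relative changes", {
  a <- tibble::tibble(reef_id = c("r1", "r2"), p_decline = c(0.5, 0.25))
  expect_equal(change_map(a, a)$rel_change, c(0, 0))

  printed <- change_map(
    tibble::tibble(reef_id = "gbr", p_decline = 0.59),
    tibble::tibble(reef_id = "gbr", p_decline = 0.77)
  )
  expect_equal(printed$rel_change, (0.77 - 0.59) / 0.59)
  expect_equal(round(printed$rel_change, 2), 0.31) # "approximately 30%"

  zero <- change_map(
    tibble::tibble(reef_id = "r", p_decline = 0),
    tibble::tibble(reef_id = "r", p_decline = 0.3)
  )
  expect_true(zero$undefined)
  expect_true(is.na(zero$rel_change))

  b <- tibble::tibble(reef_id = c("r2", "r3"), p_decline = c(0.5, 0.5))
  err <- expect_error(change_map(a, b), "only in a: r1")
  expect_match(conditionMessage(err), "only in b: r3")
})
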