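three_state <- function(name) bn_node(name, "input", c("low", "mid", "high"))

test_that("ordinal score spans [0, 1] over the parent grid", {
  parents <- list(three_state("a"), three_state("b"))
  expect_equal(ordinal_score(c(a = "low", b = "low"), parents), 0)
  expect_equal(ordinal_score(c(a = "high", b = "high"), parents), 1)
  expect_equal(ordinal_score(c(a = "mid", b = "high"), parents), 0.75)
  expect_error(ordinal_score(c(a = "nope", b = "low"), parents), "illegal state")
  single <- list(bn_node("s", "input", "only"), three_state("b"))
  expect_warning(
    sc <- ordinal_score(c(s = "only", b = "high"), single),
    "single state"
  )
  expect_equal(sc, 0.5) # the degenerate parent contributes 0
})

test_that("interpolated CPTs reproduce elicited endpoints and the midpoint", {
  node <- bn_node("ev", "event", c("calm", "rough"), parents = c("a", "b"))
  parents <- list(three_state("a"), three_state("b"))
  cpt <- interpolate_cpt(node, parents, c(0.8, 0.2), c(0.2, 0.8))
  grid <- reefbn:::parent_grid(
    list(nodes = list(a = parents[[1]], b = parents[[2]])), c("a", "b")
  )
  s <- (match(grid$a, parents[[1]]$states) - 1) / 2 / 2 +
    (match(grid$b, parents[[2]]$states) - 1) / 2 / 2
  expect_identical(cpt$prob[s == 0, ], c(calm = 0.8, rough = 0.2))
  expect_identical(cpt$prob[s == 1, ], c(calm = 0.2, rough = 0.8))
  expect_equal(unname(cpt$prob[s == 0.5, ]), matrix(0.5, sum(s == 0.5), 2))
  expect_equal(rowSums(cpt$prob), rep(1, nrow(cpt$prob)))
})

test_that("stochastically ordered endpoints give rows monotone in adversity", {
  node <- bn_node("ev", "event", c("d", "u", "i"), parents = c("a", "b"))
  parents <- list(three_state("a"), three_state("b"))
  low <- c(0.6, 0.3, 0.1)
  high <- c(0.05, 0.2, 0.75) # dominates low on the adversity order
  cpt <- interpolate_cpt(node, parents, low, high)
  grid <- reefbn:::parent_grid(
    list(nodes = list(a = parents[[1]], b = parents[[2]])), c("a", "b")
  )
  s <- reefbn:::grid_scores(grid, parents)
  ord <- order(s)
  cdf1 <- cpt$prob[ord, 1]
  cdf2 <- cpt$prob[ord, 1] + cpt$prob[ord, 2]
  expect_true(all(diff(cdf1) <= 1e-12)) # CDF shrinks as stress grows
  expect_true(all(diff(cdf2) <= 1e-12))
})

test_that("endpoint distributions are renormalized and validated", {
  node <- bn_node("ev", "event", c("x", "y"), parents = "a")
  parents <- list(three_state("a"))
  cpt <- interpolate_cpt(node, parents, c(2, 2), c(1, 3))
  expect_equal(cpt$prob[1, ], c(x = 0.5, y = 0.5))
  expect_equal(cpt$prob[3, ], c(x = 0.25, y = 0.75))
  expect_error(interpolate_cpt(node, parents, c(0.5, 0.5), c(0.2, -0.1)), "non-negative")
  expect_error(interpolate_cpt(node, parents, c(0.5), c(0.2, 0.8)), "2 entries")
})

test_that("composite CPTs cut the weighted ordinal index at 1/3 and 2/3", {
  node <- bn_node("cx", "composite", c("low", "medium", "high"),
    parents = c("a", "b", "c")
  )
  parents <- list(three_state("a"), three_state("b"), three_state("c"))
  eq <- composite_cpt(node, parents, c(a = 1, b = 1, c = 1))
  grid <- reefbn:::parent_grid(
    list(nodes = setNames(parents, c("a", "b", "c"))), c("a", "b", "c")
  )
  all_high <- which(grid$a == "high" & grid$b == "high" & grid$c == "high")
  expect_equal(unname(eq$prob[all_high, ]), c(0, 0, 1))
  expect_true(all(rowSums(eq$prob) == 1))
  expect_true(all(eq$prob %in% c(0, 1))) # deterministic rows

  # degenerate weighting: the composite mirrors parent a exactly
  follow <- composite_cpt(node, parents, c(a = 1, b = 0, c = 0))
  expect_equal(
    colnames(follow$prob)[max.col(follow$prob)],
    c(low = "low", mid = "medium", high = "high")[grid$a],
    ignore_attr = TRUE
  )

  two <- bn_node("cx", "composite", c("low", "medium", "high"), parents = c("a", "b"))
  cpt2 <- composite_cpt(two, parents[1:2], c(a = 1, b = 1))
  grid2 <- reefbn:::parent_grid(
    list(nodes = setNames(parents[1:2], c("a", "b"))), c("a", "b")
  )
  mix <- which(grid2$a == "low" & grid2$b == "high") # index 0.5 -> middle state
  expect_equal(unname(cpt2$prob[mix, ]), c(0, 1, 0))
  expect_error(composite_cpt(two, parents[1:2], c(a = 0, b = 0)), "all-zero")
})

test_that("validation passes the default model and catches broken ones", {
  model <- build_model(default_structure(), truth_parameterization())
  report <- validate_network(model)
  expect_true(all(report$ok))
  expect_true(network_is_valid(model))

  # a missing CPT row is reported with node and combination context
  broken <- model
  broken$cpts$disease$prob <- broken$cpts$disease$prob[-1, ]
  rep1 <- validate_network(broken)
  bad <- rep1[!rep1$ok, ]
  expect_equal(bad$node, "disease")
  expect_match(bad$detail, "parent combinations")

  # a denormalized row names the offending combination
  broken2 <- model
  broken2$cpts$cots$prob[2, ] <- c(0.5, 0.5, 0.2)
  rep2 <- validate_network(broken2)
  expect_match(rep2$detail[!rep2$ok], "water_quality=medium")

  # a directed cycle (forced past the constructor) is detected
  cyclic <- model
  cyclic$structure$nodes$temperature$parents <- "decline"
  expect_false(validate_network(cyclic)$ok[1])
})

test_that("structures reject cycles, unknown parents and duplicate names", {
  a <- bn_node("a", "event", c("x", "y"), parents = "b")
  b <- bn_node("b", "event", c("x", "y"), parents = "a")
  expect_error(bn_structure(list(a, b)), "cycle")
  expect_error(
    bn_structure(list(bn_node("a", "event", "x", parents = "ghost"))),
    "unknown parent"
  )
  expect_error(
    bn_structure(list(bn_node("a", "input", "x"), bn_node("a", "input", "x"))),
    "duplicate"
  )
  expect_error(bn_node("a", "input", "x", parents = "b"), "cannot have parents")
})

test_that("model building requires a complete parameterization", {
  truth <- default_truth()
  short <- truth_parameterization(truth[-(1:2)])
  err <- expect_error(
    build_model(default_structure(), short),
    "bleaching.low.decreased"
  )
  expect_match(conditionMessage(err), "bleaching.low.unchanged")
})

test_that("elicited zeros are floored so observed evidence stays possible", {
  truth <- default_truth()
  truth[c("cots.low.decreased", "cots.high.decreased")] <- 0
  model <- build_model(default_structure(), truth_parameterization(truth))
  expect_true(all(model$cpts$cots$prob[, "decreased"] > 0))
  fleet <- small_fleet()
  ev <- unlist(discretize_reefs(fleet$reefs[1, ], fleet$stats)[1, -1])
  ev[["cots"]] <- "decreased"
  expect_gte(infer_decline(model, ev), 0)
  # opting out keeps the elicited zeros
  raw <- build_model(default_structure(), truth_parameterization(truth), prob_floor = 0)
  expect_true(all(raw$cpts$cots$prob[, "decreased"] == 0))
})
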