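# Tiny hand-built fixtures shared across test files.

# input -> event -> outcome chain with identity (deterministic) CPTs:
# the outcome copies the event, the event copies the input
chain_model <- function() {
  s3 <- c("a", "b", "c")
  nodes <- list(
    bn_node("x", "input", s3),
    bn_node("e", "event", s3, parents = "x"),
    bn_node("y", "outcome", s3, parents = "e")
  )
  struct <- bn_structure(nodes)
  identity_cpt <- function(name, parent) {
    prob <- diag(3)
    colnames(prob) <- s3
    reefbn:::new_cpt(name, parent, s3, prob)
  }
  structure(
    list(
      structure = struct,
      cpts = list(e = identity_cpt("e", "x"), y = identity_cpt("y", "e")),
      label = "chain"
    ),
    class = "reefbn_model"
  )
}

# default-structure model whose outcome CPT ignores its parents: every row is
# (1 - p, p), so the decline probability is p under any evidence
constant_leaf_model <- function(p = 0.6) {
  struct <- default_structure()
  model <- build_model(struct, truth_parameterization())
  out_cpt <- model$cpts$decline
  out_cpt$prob <- matrix(
    rep(c(1 - p, p), each = nrow(out_cpt$prob)),
    nrow(out_cpt$prob),
    dimnames = list(NULL, out_cpt$states)
  )
  model$cpts$decline <- out_cpt
  model
}

truth_parameterization <- function(truth = default_truth(), label = "mean") {
  reefbn:::new_parameterization(
    tibble::tibble(quantity_id = names(truth), value = unname(truth)),
    label
  )
}

# small synthetic fleet plus zoned stats, computed once per test run
small_fleet <- local({
  cache <- NULL
  function(n = 120, seed = 42) {
    if (is.null(cache)) {
      reefs <- apply_zoning(generate_reefs(n_reefs = n, seed = seed))
      cache <<- list(reefs = reefs, stats = compute_layer_stats(reefs))
    }
    cache
  }
})

# the three pooled parameterizations from a small simulated expert pool
pooled_parameterizations <- local({
  cache <- NULL
  function(seed = 99) {
    if (is.null(cache)) {
      std <- standardize_responses(generate_expert_pool(n_experts = 21, seed = seed))
      orient <- default_orientation()
      cache <<- list(
        mean = build_parameterization(std, "mean"),
        pessimistic = build_parameterization(std, "pessimistic", orient),
        optimistic = build_parameterization(std, "optimistic", orient)
      )
    }
    cache
  }
})
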