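# Independent brute-force oracle: enumerate the full joint distribution and
# condition by filtering rows. Shares no code with the package's variable
# elimination (row indices are computed by positional arithmetic over the
# canonical first-parent-fastest CPT layout).

oracle_marginal <- function(model, node, evidence = character()) {
  nodes <- model$structure$nodes
  grid <- expand.grid(
    lapply(nodes, `[[`, "states"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  names(grid) <- names(nodes)
  for (v in names(evidence)) {
    grid <- grid[grid[[v]] == evidence[[v]], , drop = FALSE]
  }
  p <- rep(1, nrow(grid))
  for (n in names(nodes)) {
    cpt <- model$cpts[[n]]
    if (is.null(cpt)) next # input node: fixed by evidence, no prior factor
    row <- rep(1L, nrow(grid))
    mult <- 1L
    for (pa in cpt$parents) {
      k <- match(grid[[pa]], nodes[[pa]]$states)
      row <- row + (k - 1L) * mult
      mult <- mult * length(nodes[[pa]]$states)
    }
    col <- match(grid[[n]], cpt$states)
    p <- p * cpt$prob[cbind(row, col)]
  }
  s <- vapply(
    nodes[[node]]$states,
    function(st) sum(p[grid[[node]] == st]),
    numeric(1)
  )
  s / sum(s)
}

oracle_decline <- function(model, evidence = character()) {
  out <- names(model$structure$nodes)[
    vapply(model$structure$nodes, `[[`, character(1), "kind") == "outcome"
  ]
  states <- model$structure$nodes[[out]]$states
  unname(oracle_marginal(model, out, evidence)[length(states)])
}

# seeded random network: chain-free random DAG of parentless-prior event
# nodes plus one outcome leaf, all with random CPTs
random_network <- function(seed, max_nodes = 6, n_states = 3) {
  set.seed(seed)
  n <- sample(3:max_nodes, 1)
  nms <- paste0("n", seq_len(n))
  nodes <- vector("list", n)
  for (i in seq_len(n)) {
    n_par <- if (i == 1) 0 else sample(0:min(i - 1, 2), 1)
    parents <- if (n_par > 0) sample(nms[seq_len(i - 1)], n_par) else character()
    nodes[[i]] <- bn_node(
      nms[i],
      kind = if (i == n) "outcome" else "event",
      states = paste0("s", seq_len(n_states)),
      parents = parents
    )
  }
  struct <- bn_structure(nodes)
  cpts <- lapply(struct$nodes, function(nd) {
    n_rows <- prod(vapply(
      struct$nodes[nd$parents], function(p) length(p$states), numeric(1)
    ))
    if (length(nd$parents) == 0) n_rows <- 1
    prob <- matrix(stats::rgamma(n_rows * length(nd$states), 1), n_rows)
    prob <- prob / rowSums(prob)
    colnames(prob) <- nd$states
    reefbn:::new_cpt(nd$name, nd$parents, nd$states, prob)
  })
  structure(
    list(structure = struct, cpts = cpts, label = "random"),
    class = "reefbn_model"
  )
}

random_evidence <- function(model, p_observe = 0.4) {
  nodes <- model$structure$nodes
  candidates <- setdiff(
    names(nodes),
    names(nodes)[vapply(nodes, `[[`, character(1), "kind") == "outcome"]
  )
  obs <- candidates[stats::runif(length(candidates)) < p_observe]
  vapply(
    nodes[obs],
    function(nd) sample(nd$states, 1),
    character(1)
  )
}
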