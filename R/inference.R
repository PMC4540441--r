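# Exact inference by sum-product variable elimination.
#
# Factors are plain lists: vars (character), levels (named list of state
# labels), val (numeric vector laid out in expand.grid order over `levels`,
# first variable fastest). The networks here are tiny (a dozen nodes, <= 3
# states), so clarity beats asymptotics; elimination order is topological.

model_factors <- function(model) {
  struct <- model$structure
  lapply(model$cpts, function(cpt) {
    vars <- c(cpt$parents, cpt$node)
    levels <- c(
      lapply(struct$nodes[cpt$parents], `[[`, "states"),
      setNames(list(cpt$states), cpt$node)
    )
    names(levels) <- vars
    # prob rows follow expand.grid over parents (first parent fastest);
    # as.vector over the matrix appends the node dimension last, matching
    # expand.grid over c(parents, node)
    list(vars = vars, levels = levels, val = as.vector(cpt$prob))
  })
}

factor_dims <- function(f) vapply(f$levels, length, integer(1))

# restrict a factor to var == state (dropping the variable)
factor_restrict <- function(f, var, state) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  k <- match(state, f$levels[[var]])
  if (is.na(k)) {
    abort(sprintf("illegal state '%s' for node '%s'", state, var))
  }
  dims <- factor_dims(f)
  arr <- array(f$val, dim = dims)
  idx <- rep(list(quote(expr = )), length(dims))
  idx[[i]] <- k
  sub <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  keep <- setdiff(seq_along(dims), i)
  # the restricted dimension has extent 1, so dropping it leaves the linear
  # layout over the remaining dimensions untouched
  list(vars = f$vars[keep], levels = f$levels[keep], val = as.vector(sub))
}

factor_product <- function(f1, f2) {
  all_vars <- union(f1$vars, f2$vars)
  all_levels <- c(f1$levels, f2$levels)[!duplicated(c(f1$vars, f2$vars))]
  names(all_levels) <- all_vars
  dims <- vapply(all_levels, length, integer(1))
  expand_to <- function(f) {
    if (length(f$vars) == 0) return(rep(f$val, prod(dims)))
    missing <- setdiff(all_vars, f$vars)
    ext_vars <- c(f$vars, missing)
    ext_dims <- c(factor_dims(f), vapply(all_levels[missing], length, integer(1)))
    arr <- array(f$val, dim = ext_dims) # recycles over appended dims
    perm <- match(all_vars, ext_vars)
    as.vector(aperm(arr, perm))
  }
  list(vars = all_vars, levels = all_levels, val = expand_to(f1) * expand_to(f2))
}

factor_marginalize <- function(f, var) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  dims <- factor_dims(f)
  keep <- setdiff(seq_along(dims), i)
  arr <- array(f$val, dim = dims)
  summed <- aperm(arr, c(keep, i))
  if (length(keep) == 0) {
    return(list(vars = character(), levels = list(), val = sum(f$val)))
  }
  m <- matrix(summed, nrow = prod(dims[keep]), ncol = dims[i])
  list(vars = f$vars[keep], levels = f$levels[keep], val = rowSums(m))
}

# marginal distribution of `node` given evidence (named character vector of
# node -> state); exact, by variable elimination in topological order
infer_marginal <- function(model, node, evidence = character()) {
  struct <- model$structure
  if (!node %in% names(struct$nodes)) {
    abort(sprintf("unknown query node '%s'", node))
  }
  unknown_ev <- setdiff(names(evidence), names(struct$nodes))
  if (length(unknown_ev) > 0) {
    abort(sprintf(
      "evidence on unknown node%s: %s",
      if (length(unknown_ev) > 1) "s" else "", paste(unknown_ev, collapse = ", ")
    ))
  }

  factors <- model_factors(model)
  # input nodes have no CPT; their evidence simply restricts child factors.
  for (v in names(evidence)) {
    factors <- lapply(factors, factor_restrict, var = v, state = evidence[[v]])
  }

  hidden <- setdiff(topological_order(struct), c(node, names(evidence)))
  for (v in hidden) {
    touches <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(touches)) next
    merged <- Reduce(factor_product, factors[touches])
    factors <- c(factors[!touches], list(factor_marginalize(merged, v)))
  }
  joint <- Reduce(factor_product, factors)
  if (!identical(joint$vars, node)) {
    joint <- Reduce(
      factor_marginalize,
      setdiff(joint$vars, node),
      init = joint
    )
  }
  z <- sum(joint$val)
  if (z <= 0) {
    abort(sprintf("evidence has probability zero; marginal for '%s' undefined", node))
  }
  setNames(joint$val / z, joint$levels[[node]])
}

#' Exact probability of coral decline given reef evidence
#'
#' Computes the exact marginal probability that the outcome node is in its
#' most adverse ("decline") state given observed states for the input nodes,
#' marginalizing over all unobserved intermediate nodes by variable
#' elimination. Evidence must cover every input node; evidence on event nodes
#' (e.g. an observed crown-of-thorns outbreak state, or a scenario-imposed
#' bleaching-frequency state) is optional and simply conditions the network
#' further.
#'
#' @param model A `reefbn_model` from [build_model()].
#' @param evidence Named character vector mapping node names to observed
#'   states, e.g. `c(temperature = "average", fishing = "above", ...)`.
#'
#' @return Probability of the decline state, in \[0, 1\].
#' @export
infer_decline <- function(model, evidence) {
  struct <- model$structure
  evidence <- unlist(evidence)
  inputs <- nodes_of_kind(struct, "input")
  missing <- setdiff(inputs, names(evidence))
  if (length(missing) > 0) {
    abort(sprintf(
      "evidence missing for input node%s: %s",
      if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  out <- outcome_node(struct)
  marg <- infer_marginal(model, out, evidence)
  decline_state <- struct$nodes[[out]]$states[length(struct$nodes[[out]]$states)]
  unname(marg[decline_state])
}
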