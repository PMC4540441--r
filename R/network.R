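# Network structure and CPT construction.
#
# A structure is a DAG of discrete nodes, each with an ordered state list
# (order = increasing stress/adversity). Input nodes carry evidence, composite
# nodes deterministically combine weighted parent ordinals into an index,
# event and outcome nodes carry elicited CPTs interpolated between the two
# elicited endpoint rows (all parents least adverse vs all most adverse).

NODE_KINDS <- c("input", "composite", "event", "outcome")

#' Declare one network node
#'
#' @param name Node name (identifier).
#' @param kind One of `"input"`, `"composite"`, `"event"`, `"outcome"`.
#' @param states Ordered character vector of state labels; the order encodes
#'   increasing stress/adversity.
#' @param parents Character vector of parent node names (empty for inputs).
#'
#' @return A `reefbn_node` list.
#' @export
#' @examples
#' bn_node("temperature", "input", c("below", "average", "above"))
bn_node <- function(name, kind, states, parents = character()) {
  kind <- match.arg(kind, NODE_KINDS)
  if (!is.character(states) || length(states) == 0 || anyDuplicated(states)) {
    abort(sprintf("node '%s': states must be a non-empty set of unique labels", name))
  }
  if (kind == "input" && length(parents) > 0) {
    abort(sprintf("input node '%s' cannot have parents", name))
  }
  structure(
    list(name = name, kind = kind, states = states, parents = as.character(parents)),
    class = "reefbn_node"
  )
}

#' Assemble a network structure
#'
#' @param nodes List of [bn_node()] objects.
#' @param composite_weights Named list: for each composite node, a named
#'   numeric vector of non-negative per-parent weights (need not sum to 1).
#'
#' @return A `reefbn_structure` object.
#' @export
bn_structure <- function(nodes, composite_weights = list()) {
  names(nodes) <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(names(nodes))) abort("duplicate node names in structure")
  struct <- structure(
    list(nodes = nodes, composite_weights = composite_weights),
    class = "reefbn_structure"
  )
  for (nd in nodes) {
    unknown <- setdiff(nd$parents, names(nodes))
    if (length(unknown) > 0) {
      abort(sprintf(
        "node '%s' has unknown parent%s: %s",
        nd$name, if (length(unknown) > 1) "s" else "", paste(unknown, collapse = ", ")
      ))
    }
  }
  ord <- topological_order(struct)
  if (is.null(ord)) abort("structure contains a directed cycle")
  struct
}

#' @export
print.reefbn_structure <- function(x, ...) {
  kinds <- vapply(x$nodes, `[[`, character(1), "kind")
  cat(sprintf(
    "<reefbn structure: %d nodes (%d input, %d composite, %d event, %d outcome)>\n",
    length(x$nodes), sum(kinds == "input"), sum(kinds == "composite"),
    sum(kinds == "event"), sum(kinds == "outcome")
  ))
  invisible(x)
}

# Kahn's algorithm; NULL if a cycle exists.
topological_order <- function(struct) {
  nodes <- struct$nodes
  remaining <- names(nodes)
  placed <- character()
  while (length(remaining) > 0) {
    ready <- remaining[vapply(
      remaining,
      function(n) all(nodes[[n]]$parents %in% placed),
      logical(1)
    )]
    if (length(ready) == 0) return(NULL)
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

nodes_of_kind <- function(struct, kind) {
  names(struct$nodes)[vapply(struct$nodes, `[[`, character(1), "kind") == kind]
}

outcome_node <- function(struct) {
  out <- nodes_of_kind(struct, "outcome")
  if (length(out) != 1) abort("structure must have exactly one outcome node")
  out
}

# parent-combination grid in declared parent order, first parent varying
# fastest; the canonical row order for every CPT in the package.
parent_grid <- function(struct, parents) {
  if (length(parents) == 0) {
    # a parentless CPT has a single (prior) row
    return(tibble::new_tibble(list(), nrow = 1L))
  }
  states <- lapply(struct$nodes[parents], `[[`, "states")
  grid <- expand.grid(states, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- parents
  tibble::as_tibble(grid)
}

new_cpt <- function(node, parents, states, prob) {
  # prob: matrix, one row per parent combination (canonical order), one
  # column per node state
  structure(
    list(node = node, parents = parents, states = states, prob = prob),
    class = "reefbn_cpt"
  )
}

#' @export
print.reefbn_cpt <- function(x, ...) {
  cat(sprintf(
    "<reefbn CPT for '%s' (%d states) | %s: %d rows>\n",
    x$node, length(x$states),
    if (length(x$parents) > 0) paste(x$parents, collapse = ", ") else "no parents",
    nrow(x$prob)
  ))
  invisible(x)
}

#' Ordinal adversity score of a parent-state combination
#'
#' Maps a combination of parent states to \[0, 1\]: each parent contributes its
#' state index scaled to \[0, 1\] (`(index - 1) / (n_states - 1)`), and the
#' score is the (optionally weighted) mean of contributions. The score is 0
#' exactly when every parent is in its least-adverse state and 1 exactly when
#' every parent is most adverse; it is the interpolation coordinate for
#' elicited CPTs. A single-state parent contributes 0 with a warning.
#'
#' @param combo Named character vector (or one-row data frame) assigning one
#'   state to every parent.
#' @param parents List of [bn_node()] objects, in declared parent order.
#' @param weights Optional named non-negative weights per parent; default
#'   equal.
#'
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' p <- list(
#'   bn_node("a", "input", c("low", "mid", "high")),
#'   bn_node("b", "input", c("low", "mid", "high"))
#' )
#' ordinal_score(c(a = "mid", b = "high"), p) # 0.75
ordinal_score <- function(combo, parents, weights = NULL) {
  combo <- unlist(combo)
  contrib <- vapply(parents, function(nd) {
    st <- combo[[nd$name]]
    idx <- match(st, nd$states)
    if (is.na(idx)) {
      abort(sprintf("illegal state '%s' for parent '%s'", st, nd$name))
    }
    if (length(nd$states) == 1) {
      warn(sprintf("parent '%s' has a single state; it contributes 0 to the ordinal score", nd$name))
      return(0)
    }
    (idx - 1) / (length(nd$states) - 1)
  }, numeric(1))
  if (is.null(weights)) {
    mean(contrib)
  } else {
    w <- weights[vapply(parents, `[[`, character(1), "name")]
    if (any(is.na(w)) || any(w < 0) || sum(w) == 0) {
      abort("weights must be named, non-negative, not all zero")
    }
    sum(w * contrib) / sum(w)
  }
}

# vectorized ordinal scores over a canonical parent grid
grid_scores <- function(grid, parent_nodes, weights = NULL) {
  # a parentless node sits at the least-adverse end of the interpolation axis
  if (nrow(grid) == 0 || length(parent_nodes) == 0) return(rep(0, nrow(grid)))
  contrib <- vapply(parent_nodes, function(nd) {
    idx <- match(grid[[nd$name]], nd$states)
    if (length(nd$states) == 1) rep(0, nrow(grid)) else (idx - 1) / (length(nd$states) - 1)
  }, numeric(nrow(grid)))
  contrib <- matrix(contrib, nrow = nrow(grid))
  if (is.null(weights)) {
    rowMeans(contrib)
  } else {
    w <- weights[vapply(parent_nodes, `[[`, character(1), "name")]
    if (any(is.na(w)) || any(w < 0) || sum(w) == 0) {
      abort("composite weights must be named, non-negative, not all zero")
    }
    as.numeric(contrib %*% w) / sum(w)
  }
}

#' Interpolate a full CPT from two elicited endpoint distributions
#'
#' Experts are asked only for the two extreme rows of a CPT: the distribution
#' over the node's states when all parents are least adverse
#' (`low_endpoint`) and when all are most adverse (`high_endpoint`). Every
#' other row is the convex combination `(1 - s) * low + s * high`, where `s`
#' is the combination's [ordinal_score()]. Rows at `s = 0` and `s = 1`
#' reproduce the elicited endpoints exactly.
#'
#' @param node A [bn_node()] (event or outcome kind).
#' @param parent_nodes List of the node's parent [bn_node()]s in declared
#'   order.
#' @param low_endpoint,high_endpoint Numeric distributions over `node$states`
#'   (same order); renormalized to sum to 1.
#'
#' @return A CPT object; rows sum to 1 within 1e-9.
#' @export
interpolate_cpt <- function(node, parent_nodes, low_endpoint, high_endpoint) {
  k <- length(node$states)
  if (length(low_endpoint) != k || length(high_endpoint) != k) {
    abort(sprintf(
      "endpoint distributions for '%s' must have %d entries", node$name, k
    ))
  }
  if (any(low_endpoint < 0) || any(high_endpoint < 0) ||
      sum(low_endpoint) <= 0 || sum(high_endpoint) <= 0) {
    abort(sprintf("endpoint distributions for '%s' must be non-negative with positive mass", node$name))
  }
  low <- low_endpoint / sum(low_endpoint)
  high <- high_endpoint / sum(high_endpoint)
  struct_like <- list(nodes = setNames(parent_nodes, vapply(parent_nodes, `[[`, character(1), "name")))
  grid <- parent_grid(struct_like, names(struct_like$nodes))
  s <- grid_scores(grid, parent_nodes)
  prob <- outer(1 - s, low) + outer(s, high)
  # convex combinations of distributions already sum to one; renormalize to
  # keep the row-sum invariant robust to accumulated rounding
  prob <- prob / rowSums(prob)
  # endpoint rows must be the elicited values bit for bit
  prob[s == 0, ] <- matrix(low, sum(s == 0), k, byrow = TRUE)
  prob[s == 1, ] <- matrix(high, sum(s == 1), k, byrow = TRUE)
  colnames(prob) <- node$states
  new_cpt(node$name, vapply(parent_nodes, `[[`, character(1), "name"), node$states, prob)
}

#' Deterministic CPT for a weighted composite index node
#'
#' The weighted mean of normalized parent state ordinals is cut at 1/3 and 2/3
#' into the composite node's three ordered states (index < 1/3 maps to the
#' lowest state, < 2/3 to the middle, otherwise the highest); each row puts
#' probability 1 on a single state.
#'
#' @inheritParams interpolate_cpt
#' @param weights Named non-negative per-parent weights, not all zero.
#' @param thresholds Two increasing cut points in (0, 1); default `c(1/3, 2/3)`.
#'
#' @return A deterministic CPT object.
#' @export
composite_cpt <- function(node, parent_nodes, weights, thresholds = c(1 / 3, 2 / 3)) {
  if (length(node$states) != length(thresholds) + 1) {
    abort(sprintf(
      "composite node '%s' needs %d states for %d thresholds",
      node$name, length(thresholds) + 1, length(thresholds)
    ))
  }
  if (all(weights == 0)) abort(sprintf("composite node '%s': all-zero weights", node$name))
  struct_like <- list(nodes = setNames(parent_nodes, vapply(parent_nodes, `[[`, character(1), "name")))
  grid <- parent_grid(struct_like, names(struct_like$nodes))
  idx <- grid_scores(grid, parent_nodes, weights = weights)
  state_i <- findInterval(idx, thresholds) + 1L # [0,t1) -> 1, [t1,t2) -> 2, [t2,..] -> 3
  prob <- matrix(0, nrow(grid), length(node$states), dimnames = list(NULL, node$states))
  prob[cbind(seq_len(nrow(grid)), state_i)] <- 1
  new_cpt(node$name, names(struct_like$nodes), node$states, prob)
}

#' Validate a network model
#'
#' Checks acyclicity, presence of a CPT for every non-input node, CPT
#' completeness (one row per parent-state combination, in canonical order),
#' row normalization within 1e-9, probability bounds, and state declarations.
#'
#' @param model A `reefbn_model` from [build_model()] (or a bare list with
#'   `structure` and `cpts`).
#'
#' @return A tibble with columns `check`, `node`, `ok`, `detail`; the model
#'   passes iff all `ok`. See [network_is_valid()].
#' @export
validate_network <- function(model) {
  struct <- model$structure
  cpts <- model$cpts
  res <- list()
  add <- function(check, node, ok, detail = "") {
    res[[length(res) + 1]] <<- tibble::tibble(
      check = check, node = node, ok = ok, detail = detail
    )
  }

  ord <- topological_order(struct)
  if (is.null(ord)) {
    add("acyclic", NA_character_, FALSE, "directed cycle among nodes")
  } else {
    add("acyclic", NA_character_, TRUE)
  }

  for (nd in struct$nodes) {
    add(
      "states_declared", nd$name,
      length(nd$states) >= 1 && !anyDuplicated(nd$states),
      if (length(nd$states) < 1) "no states" else ""
    )
    if (nd$kind == "input") next
    cpt <- cpts[[nd$name]]
    if (is.null(cpt)) {
      add("cpt_present", nd$name, FALSE, "missing CPT")
      next
    }
    add("cpt_present", nd$name, TRUE)
    n_expected <- prod(vapply(
      struct$nodes[nd$parents], function(p) length(p$states), numeric(1)
    ))
    if (length(nd$parents) == 0) n_expected <- 1
    if (nrow(cpt$prob) != n_expected) {
      add("cpt_complete", nd$name, FALSE, sprintf(
        "expected %d parent combinations, found %d", n_expected, nrow(cpt$prob)
      ))
    } else if (!identical(cpt$parents, nd$parents)) {
      add("cpt_complete", nd$name, FALSE, "CPT parents differ from structure")
    } else {
      add("cpt_complete", nd$name, TRUE)
    }
    sums <- rowSums(cpt$prob)
    bad <- which(abs(sums - 1) > 1e-9)
    if (length(bad) > 0) {
      combo <- describe_combo(struct, nd$parents, bad[1])
      add("rows_normalized", nd$name, FALSE, sprintf(
        "row %d (%s) sums to %.12f", bad[1], combo, sums[bad[1]]
      ))
    } else {
      add("rows_normalized", nd$name, TRUE)
    }
    add(
      "probabilities_bounded", nd$name,
      all(cpt$prob >= 0 & cpt$prob <= 1),
      ""
    )
  }
  dplyr::bind_rows(res)
}

describe_combo <- function(struct, parents, row) {
  if (length(parents) == 0) return("prior row")
  grid <- parent_grid(struct, parents)
  paste(sprintf("%s=%s", parents, unlist(grid[row, ])), collapse = ", ")
}

#' @rdname validate_network
#' @return `network_is_valid()`: a single logical.
#' @export
network_is_valid <- function(model) {
  all(validate_network(model)$ok)
}
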