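# Elicitation: 4-point expert responses -> pooled CPT parameterizations.
#
# Each expert supplies, for each elicited probability ("quantity"), a lowest
# possible value, best estimate, highest possible value, and a confidence
# level for the (lowest, highest) interval. Intervals are standardized to a
# common credible level, then best estimates are pooled across experts into
# three parameterizations: group mean, pessimistic and optimistic percentiles.

ELICITATION_COLS <- c(
  "expert_id", "quantity_id", "lowest", "best", "highest", "confidence"
)

#' Validate raw 4-point elicitation records
#'
#' Checks the invariants of 4-point responses: probabilities in \[0, 1\],
#' `lowest <= best <= highest`, and confidence in (0, 100\].
#'
#' @param responses Data frame with columns `expert_id`, `quantity_id`,
#'   `lowest`, `best`, `highest`, `confidence`. One row per (expert, quantity).
#'
#' @return The input as a tibble, invisibly usable in a pipe. Violations raise
#'   an error naming the offending expert and quantity.
#' @export
#' @examples
#' validate_responses(tibble::tibble(
#'   expert_id = "e1", quantity_id = "q1",
#'   lowest = 0.2, best = 0.5, highest = 0.8, confidence = 80
#' ))
validate_responses <- function(responses) {
  responses <- tibble::as_tibble(responses)
  assert_cols(responses, ELICITATION_COLS, "elicitation table")
  bad_row <- function(cond, msg) {
    i <- which(cond)
    if (length(i) > 0) {
      abort(sprintf(
        "%s for expert '%s', quantity '%s'",
        msg, responses$expert_id[i[1]], responses$quantity_id[i[1]]
      ))
    }
  }
  prob_cols <- c("lowest", "best", "highest")
  for (col in prob_cols) {
    x <- responses[[col]]
    bad_row(!is.finite(x), sprintf("non-finite '%s'", col))
    bad_row(x < 0 | x > 1, sprintf("'%s' outside [0, 1]", col))
  }
  bad_row(
    !is.finite(responses$confidence) | responses$confidence <= 0,
    "confidence must be strictly positive"
  )
  bad_row(responses$confidence > 100, "confidence above 100")
  bad_row(responses$lowest > responses$best, "lowest exceeds best")
  bad_row(responses$best > responses$highest, "best exceeds highest")
  dup <- duplicated(responses[c("expert_id", "quantity_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf(
      "duplicate response for expert '%s', quantity '%s'",
      responses$expert_id[i], responses$quantity_id[i]
    ))
  }
  responses
}

#' Standardize elicited intervals to a common credible level
#'
#' Rescales each response's interval half-widths, `best - lowest` and
#' `highest - best`, by `target_level / confidence`, leaving the best estimate
#' untouched, then clamps the interval ends to \[0, 1\]. A response stated at
#' the target level passes through unchanged. Only pooled best estimates feed
#' the parameterizations; the standardized intervals are retained for
#' between-expert spread diagnostics.
#'
#' @inheritParams validate_responses
#' @param target_level Credible level (in (0, 100\]) that all intervals are
#'   rescaled to. Default 90, a conventional reporting level for elicited
#'   intervals.
#'
#' @return A tibble with columns `quantity_id`, `expert_id`, `best`, `low_s`,
#'   `high_s`, `target_level`; `low_s <= best <= high_s` always holds.
#' @export
#' @examples
#' standardize_responses(
#'   tibble::tibble(
#'     expert_id = "e1", quantity_id = "q1",
#'     lowest = 0.4, best = 0.5, highest = 0.6, confidence = 50
#'   ),
#'   target_level = 100
#' )
standardize_responses <- function(responses, target_level = 90) {
  if (!is.numeric(target_level) || length(target_level) != 1 ||
      !is.finite(target_level) || target_level <= 0 || target_level > 100) {
    abort("`target_level` must be a single number in (0, 100]")
  }
  responses <- validate_responses(responses)
  responses |>
    dplyr::mutate(
      scale = target_level / .data$confidence,
      low_s = clamp01(.data$best - (.data$best - .data$lowest) * .data$scale),
      high_s = clamp01(.data$best + (.data$highest - .data$best) * .data$scale),
      target_level = target_level
    ) |>
    dplyr::select(
      "quantity_id", "expert_id", "best", "low_s", "high_s", "target_level"
    )
}

pool_stat <- function(best, stat) {
  switch(stat,
    mean = mean(best),
    p25 = unname(quantile(best, 0.25, type = 7)),
    p75 = unname(quantile(best, 0.75, type = 7)),
    abort(sprintf("unknown pooling statistic '%s'", stat))
  )
}

#' Pool expert best estimates per quantity
#'
#' Aggregates the experts' best estimates for each elicited quantity with one
#' of three statistics: the group `mean`, or the 25th/75th percentiles (`p25`,
#' `p75`). Percentiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7), so `p25` of bests {0.2, 0.5, 0.8} is 0.35.
#' All experts are weighted equally.
#'
#' @param standardized Tibble from [standardize_responses()] (or any table
#'   with `quantity_id` and `best` columns).
#' @param stat One of `"mean"`, `"p25"`, `"p75"`.
#'
#' @return A tibble with columns `quantity_id`, `n_experts`, `value`.
#' @export
#' @examples
#' resp <- tibble::tibble(
#'   expert_id = c("a", "b", "c"), quantity_id = "q",
#'   lowest = 0, best = c(0.2, 0.5, 0.8), highest = 1, confidence = 90
#' )
#' pool_experts(standardize_responses(resp), stat = "p25")
pool_experts <- function(standardized, stat = c("mean", "p25", "p75")) {
  stat <- match.arg(stat)
  standardized <- tibble::as_tibble(standardized)
  assert_cols(standardized, c("quantity_id", "best"), "standardized responses")
  if (nrow(standardized) == 0) {
    abort("no responses to pool: empty table (no quantity_id present)")
  }
  standardized |>
    dplyr::group_by(.data$quantity_id) |>
    dplyr::summarise(
      n_experts = dplyr::n(),
      value = pool_stat(.data$best, stat),
      .groups = "drop"
    )
}

#' Build a model parameterization from pooled elicitations
#'
#' Produces one probability per elicited quantity under one of three labels:
#'
#' * `"mean"`: the group mean of best estimates.
#' * `"pessimistic"` / `"optimistic"`: percentile parameterizations. Under the
#'   default `mode = "adverse"`, the percentile is chosen per quantity from an
#'   orientation map so that the pessimistic parameterization always carries
#'   the *higher* probability of the adverse outcome: adverse-oriented
#'   quantities (e.g. probability of a bleaching-frequency increase, or of
#'   coral decline) take p75 when pessimistic and p25 when optimistic;
#'   beneficially-oriented quantities the reverse. `mode = "literal"` instead
#'   applies a single percentile to every quantity regardless of orientation
#'   (pessimistic = p25, optimistic = p75, the literal reading of
#'   percentile-labelled parameterizations); it is provided for sensitivity
#'   analysis and is not the default.
#'
#' @inheritParams pool_experts
#' @param label One of `"mean"`, `"pessimistic"`, `"optimistic"`.
#' @param orientation Named character vector mapping `quantity_id` to
#'   `"adverse"` or `"beneficial"`. Required (for every quantity) unless
#'   `label = "mean"` or `mode = "literal"`. See [default_orientation()] for
#'   the shipped network's map.
#' @param mode `"adverse"` (default) or `"literal"`; see Details.
#' @param required_quantities Optional character vector; if supplied, an error
#'   lists every required quantity with no responses.
#'
#' @return A tibble of class `reefbn_parameterization` with columns
#'   `quantity_id`, `value` and a `label` attribute.
#' @export
build_parameterization <- function(standardized,
                                   label = c("mean", "pessimistic", "optimistic"),
                                   orientation = NULL,
                                   mode = c("adverse", "literal"),
                                   required_quantities = NULL) {
  label <- match.arg(label)
  mode <- match.arg(mode)
  standardized <- tibble::as_tibble(standardized)
  assert_cols(standardized, c("quantity_id", "best"), "standardized responses")

  if (!is.null(required_quantities)) {
    absent <- setdiff(required_quantities, unique(standardized$quantity_id))
    if (length(absent) > 0) {
      abort(sprintf(
        "no responses for required quantit%s: %s",
        if (length(absent) > 1) "ies" else "y", paste(absent, collapse = ", ")
      ))
    }
  }

  quantity_stat <- function(qid) {
    if (label == "mean") return("mean")
    if (mode == "literal") {
      return(if (label == "pessimistic") "p25" else "p75")
    }
    side <- if (qid %in% names(orientation)) orientation[[qid]] else NA_character_
    if (is.na(side) || !side %in% c("adverse", "beneficial")) {
      abort(sprintf(
        "orientation (adverse/beneficial) missing for quantity '%s'", qid
      ))
    }
    if (label == "pessimistic") {
      if (side == "adverse") "p75" else "p25"
    } else {
      if (side == "adverse") "p25" else "p75"
    }
  }

  out <- standardized |>
    dplyr::group_by(.data$quantity_id) |>
    dplyr::summarise(
      value = pool_stat(.data$best, quantity_stat(dplyr::cur_group()$quantity_id)),
      .groups = "drop"
    )
  stopifnot(all(out$value >= 0 & out$value <= 1))
  new_parameterization(out, label)
}

new_parameterization <- function(tbl, label) {
  tbl <- tibble::as_tibble(tbl)[c("quantity_id", "value")]
  structure(tbl,
    label = label,
    class = c("reefbn_parameterization", class(tbl))
  )
}

#' @export
print.reefbn_parameterization <- function(x, ...) {
  cat(sprintf(
    "<reefbn parameterization: %s, %d quantities>\n",
    attr(x, "label"), nrow(x)
  ))
  NextMethod()
}

param_values <- function(param) {
  setNames(param$value, param$quantity_id)
}
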