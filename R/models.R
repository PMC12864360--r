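# Construction of the 12 preference models: six demand-related models derived
# from a participant's practice accuracy (DA/CS x all/low/high heuristics) and
# six fixed task-order models (one per permutation of the three tasks).

new_preference_model <- function(model_id, family, direction, heuristic,
                                 task_order, constraints, tie_flag = FALSE) {
  constraints <- as.data.frame(constraints, stringsAsFactors = FALSE)
  if (nrow(constraints) > 0L) {
    names(constraints) <- c("winner", "loser")
    assert_option(constraints$winner)
    assert_option(constraints$loser)
    key <- pair_key(constraints$winner, constraints$loser)
    if (anyDuplicated(key)) {
      stop("a pair appears more than once in the constraint set")
    }
    if (has_cycle(constraints)) {
      stop("constraint set is cyclic")
    }
  } else {
    constraints <- data.frame(winner = character(), loser = character(),
                              stringsAsFactors = FALSE)
  }
  structure(
    list(
      model_id = model_id,
      family = family,
      direction = direction,
      heuristic = heuristic,
      task_order = task_order,
      constraints = constraints,
      tie_flag = tie_flag
    ),
    class = "preference_model"
  )
}

# Kahn-style check on the winner -> loser relation over the 6 options.
has_cycle <- function(constraints) {
  nodes <- unique(c(constraints$winner, constraints$loser))
  edges <- constraints
  repeat {
    if (nrow(edges) == 0L || length(nodes) == 0L) return(FALSE)
    sources <- setdiff(nodes, edges$loser)
    if (length(sources) == 0L) return(TRUE)
    nodes <- setdiff(nodes, sources)
    edges <- edges[!(edges$winner %in% sources), , drop = FALSE]
  }
}

#' @export
print.preference_model <- function(x, ...) {
  cat(sprintf("Preference model %s (%s family, %d constraints%s)\n",
              x$model_id, x$family, nrow(x$constraints),
              if (isTRUE(x$tie_flag)) ", ties dropped" else ""))
  invisible(x)
}

#' Score the six options under a demand heuristic
#'
#' Demand-related models assume choices are driven by practice performance.
#' Under the `all` heuristic every option carries its own accuracy; under the
#' `low` (`high`) heuristic both options of a task carry that task's accuracy
#' at the low (high) demand level, i.e. one slice of performance generalises
#' to the whole task.
#'
#' @param profile a [performance_profile()].
#' @param heuristic one of `"all"`, `"low"`, `"high"`.
#' @return Named numeric vector of scores over [option_ids()].
#' @examples
#' acc <- c(memory_low = .837, memory_high = .709, motor_low = .883,
#'          motor_high = .757, hybrid_low = .842, hybrid_high = .625)
#' score_options(performance_profile("p1", acc), "high")
#' @export
score_options <- function(profile, heuristic = c("all", "low", "high")) {
  profile <- as_profile(profile)
  heuristic <- match.arg(heuristic)
  ids <- option_ids()
  if (heuristic == "all") {
    return(profile$accuracy[ids])
  }
  ref <- paste(option_task(ids), heuristic, sep = "_")
  stats::setNames(profile$accuracy[ref], ids)
}

#' Build one demand-related preference model
#'
#' Ranks the six options by their heuristic scores: the demand-avoidant (`DA`)
#' family prefers options with higher scores (better performance, lower
#' subjective demand), the challenge-seeking (`CS`) family prefers lower
#' scores. Under the `low`/`high` heuristics the two options of a task are
#' tied by construction and are ordered low-before-high for `DA` and
#' high-before-low for `CS`. Exact cross-task score ties yield no constraint
#' for the affected pairs and set the model's `tie_flag`.
#'
#' @inheritParams score_options
#' @param direction `"DA"` (demand avoidant) or `"CS"` (challenge seeking).
#' @return A `preference_model` whose constraints list every ordered pair
#'   (winner, loser) implied by the (partial) order.
#' @examples
#' acc <- c(memory_low = .837, memory_high = .709, motor_low = .883,
#'          motor_high = .757, hybrid_low = .842, hybrid_high = .625)
#' rank_options(performance_profile("p1", acc), "all", "DA")
#' @export
rank_options <- function(profile, heuristic = c("all", "low", "high"),
                         direction = c("DA", "CS")) {
  heuristic <- match.arg(heuristic)
  direction <- match.arg(direction)
  scores <- score_options(profile, heuristic)
  prs <- option_pairs()
  winners <- losers <- character(0)
  tie_flag <- FALSE
  for (i in seq_len(nrow(prs))) {
    a <- prs$option1[i]
    b <- prs$option2[i]
    same_task <- option_task(a) == option_task(b)
    if (same_task && heuristic != "all") {
      # tied by construction; resolved by the family's motivation
      low <- if (option_level(a) == "low") a else b
      high <- if (option_level(a) == "low") b else a
      w <- if (direction == "DA") low else high
    } else if (scores[[a]] == scores[[b]]) {
      tie_flag <- TRUE
      next
    } else {
      better <- if (scores[[a]] > scores[[b]]) a else b
      worse <- if (scores[[a]] > scores[[b]]) b else a
      w <- if (direction == "DA") better else worse
    }
    winners <- c(winners, w)
    losers <- c(losers, if (w == a) b else a)
  }
  new_preference_model(
    model_id = paste(direction, heuristic, sep = "-"),
    family = "demand",
    direction = direction,
    heuristic = heuristic,
    task_order = NA_character_,
    constraints = data.frame(winner = winners, loser = losers,
                             stringsAsFactors = FALSE),
    tie_flag = tie_flag
  )
}

#' Build the six demand-related models for a participant
#'
#' The Cartesian product of direction (`DA`, `CS`) and heuristic
#' (`all`, `low`, `high`), each via [rank_options()]. Model ids are
#' `DA-all`, `DA-low`, `DA-high`, `CS-all`, `CS-low`, `CS-high`.
#'
#' @inheritParams score_options
#' @return A named list of six `preference_model` objects.
#' @export
build_demand_models <- function(profile) {
  profile <- as_profile(profile)
  grid <- expand.grid(direction = c("DA", "CS"),
                      heuristic = c("all", "low", "high"),
                      stringsAsFactors = FALSE)
  models <- lapply(seq_len(nrow(grid)), function(i) {
    rank_options(profile, grid$heuristic[i], grid$direction[i])
  })
  names(models) <- vapply(models, `[[`, "", "model_id")
  models[c("DA-all", "DA-low", "DA-high", "CS-all", "CS-low", "CS-high")]
}

#' Build the six fixed task-order models
#'
#' One model per permutation of the three tasks. A task ranked above another
#' contributes a constraint from each of its two options to each of the lower
#' task's two options (12 inter-task constraints); the three within-task
#' pairs stay unconstrained, since a pure task preference says nothing about
#' demand levels. Task models do not depend on the participant.
#'
#' @return A named list of six `preference_model` objects with ids of the
#'   form `TASK-memory-motor-hybrid`.
#' @examples
#' names(build_task_models())
#' @export
build_task_models <- function() {
  perms <- list(
    c("memory", "motor", "hybrid"), c("memory", "hybrid", "motor"),
    c("motor", "memory", "hybrid"), c("motor", "hybrid", "memory"),
    c("hybrid", "memory", "motor"), c("hybrid", "motor", "memory")
  )
  models <- lapply(perms, function(ord) {
    winners <- losers <- character(0)
    for (i in 1:2) {
      for (j in (i + 1L):3L) {
        for (lw in .LEVELS) {
          for (ll in .LEVELS) {
            winners <- c(winners, paste(ord[i], lw, sep = "_"))
            losers <- c(losers, paste(ord[j], ll, sep = "_"))
          }
        }
      }
    }
    new_preference_model(
      model_id = paste(c("TASK", ord), collapse = "-"),
      family = "task",
      direction = NA_character_,
      heuristic = NA_character_,
      task_order = paste(ord, collapse = "-"),
      constraints = data.frame(winner = winners, loser = losers,
                               stringsAsFactors = FALSE)
    )
  })
  names(models) <- vapply(models, `[[`, "", "model_id")
  models
}

#' Build the full battery of 12 preference models
#'
#' @inheritParams score_options
#' @return Named list of the six demand-related models for `profile` followed
#'   by the six task-order models.
#' @export
build_model_battery <- function(profile) {
  c(build_demand_models(profile), build_task_models())
}

#' Serialize preference models to JSON
#'
#' @param models a single `preference_model` or a list of them.
#' @return A JSON string with one record per model:
#'   `{model_id, family, constraints: [[winner, loser], ...]}`.
#' @export
models_to_json <- function(models) {
  if (inherits(models, "preference_model")) models <- list(models)
  recs <- lapply(models, function(m) {
    list(
      model_id = m$model_id,
      family = m$family,
      constraints = unname(Map(c, m$constraints$winner, m$constraints$loser))
    )
  })
  jsonlite::toJSON(unname(recs), auto_unbox = TRUE, pretty = TRUE)
}
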