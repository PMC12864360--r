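# Adjusting-offer titration: the hybrid (primary) task is offered at a fixed
# incentive while the secondary task's offer moves toward the participant's
# indifference point. The reward phase trades francs (experimental currency),
# the demand phase trades squares (task elements).

#' Titration phase configuration
#'
#' Defaults encode the experimental design. Reward phase: both options open
#' at 200 francs; after each decision the secondary offer moves by the next
#' step of the diminishing sequence 50, 25, 13, 8, 4, 1 (up if the hybrid
#' task was chosen, down if the secondary was) and resets to 200 francs at
#' each new six-decision set. Demand phase: the secondary task opens at 7
#' squares against a fixed 4-square hybrid (both displayed as "level 6"),
#' moves by one square per decision (up if secondary chosen, down if hybrid),
#' is clamped to `[1, 12]` squares, and carries across sets. Each phase runs
#' three sets of six decisions.
#'
#' @param phase `"reward"` or `"demand"`.
#' @param initial_secondary_offer opening secondary offer (francs / squares).
#' @param hybrid_offer fixed hybrid offer.
#' @param adjustments reward-phase offer steps, one per decision in a set.
#' @param set_length decisions per set.
#' @param n_sets number of sets.
#' @param demand_floor,demand_ceiling square bounds for the demand phase.
#' @return A list of class `titration_config`.
#' @examples
#' titration_config("reward")
#' titration_config("demand")
#' @export
titration_config <- function(phase = c("reward", "demand"),
                             initial_secondary_offer = NULL,
                             hybrid_offer = NULL,
                             adjustments = c(50, 25, 13, 8, 4, 1),
                             set_length = 6L,
                             n_sets = 3L,
                             demand_floor = 1L,
                             demand_ceiling = 12L) {
  phase <- match.arg(phase)
  if (is.null(initial_secondary_offer)) {
    initial_secondary_offer <- if (phase == "reward") 200 else 7
  }
  if (is.null(hybrid_offer)) {
    hybrid_offer <- if (phase == "reward") 200 else 4
  }
  if (phase == "reward" && length(adjustments) != set_length) {
    stop("adjustments must have one entry per decision in a set")
  }
  if (phase == "demand" &&
      !(demand_floor < initial_secondary_offer &&
        initial_secondary_offer <= demand_ceiling)) {
    stop("require demand_floor < initial offer <= demand_ceiling")
  }
  structure(
    list(phase = phase,
         initial_secondary_offer = initial_secondary_offer,
         hybrid_offer = hybrid_offer,
         adjustments = adjustments,
         set_length = as.integer(set_length),
         n_sets = as.integer(n_sets),
         demand_floor = demand_floor,
         demand_ceiling = demand_ceiling),
    class = "titration_config"
  )
}

#' Next secondary-task offer after a decision
#'
#' Reward phase: the offer moves by `adjustments[decision_index]`, up when
#' the hybrid task is chosen and down when the secondary is. Demand phase:
#' the square count moves by one (up when the secondary is chosen, down when
#' the hybrid is) and is clamped to the configured floor/ceiling.
#'
#' @param config a [titration_config()].
#' @param current_offer the secondary offer presented at this decision.
#' @param decision_index position within the set (1-based).
#' @param choice `"hybrid"` or `"secondary"`.
#' @return The secondary offer to present at the next decision.
#' @examples
#' next_secondary_offer(titration_config("reward"), 200, 1, "secondary")  # 150
#' next_secondary_offer(titration_config("demand"), 1, 3, "hybrid")       # 1
#' @export
next_secondary_offer <- function(config, current_offer, decision_index, choice) {
  if (decision_index < 1L || decision_index > config$set_length) {
    stop(errorCondition(
      sprintf("decision_index %d outside 1..%d", decision_index, config$set_length),
      class = c("effortbf_domain_error", "error", "condition")
    ))
  }
  choice <- match.arg(choice, c("hybrid", "secondary"))
  if (config$phase == "reward") {
    step <- config$adjustments[decision_index]
    current_offer + if (choice == "hybrid") step else -step
  } else {
    step <- if (choice == "secondary") 1 else -1
    min(max(current_offer + step, config$demand_floor), config$demand_ceiling)
  }
}

#' Run one titration phase under a choice policy
#'
#' Simulates the full phase: `n_sets` sets of `set_length` decisions. At each
#' decision the policy sees the current state (phase, set, decision index,
#' both offers and the record history) and returns `"hybrid"` or
#' `"secondary"`; the secondary offer is then updated via
#' [next_secondary_offer()]. Reward offers reset to the initial 200 francs at
#' each new set; demand squares carry across sets. Within each set, three to
#' five randomly chosen decisions are flagged as performed (the participant
#' actually runs ten trials of the chosen task); the flags are reproducible
#' from `seed` and do not affect offers or scores.
#'
#' @param policy function of one argument (the state list) returning
#'   `"hybrid"` or `"secondary"`.
#' @param config a [titration_config()].
#' @param seed integer seed (drives the performed flags and any randomness in
#'   the policy).
#' @param participant,condition identifiers stored in the trace.
#' @return A data frame of class `titration_trace` with columns
#'   `participant`, `condition`, `phase`, `set`, `decision`,
#'   `secondary_offer` (the offer presented), `choice`, `performed`;
#'   the configuration is attached as attribute `"config"`.
#' @examples
#' run_phase(function(state) "secondary", titration_config("reward"), seed = 1)
#' @export
run_phase <- function(policy, config, seed = 1L,
                      participant = "sim", condition = "motor") {
  set.seed(seed)
  n <- config$n_sets * config$set_length
  rec <- data.frame(
    participant = rep(as.character(participant), n),
    condition = rep(condition, n),
    phase = rep(config$phase, n),
    set = rep(seq_len(config$n_sets), each = config$set_length),
    decision = rep(seq_len(config$set_length), config$n_sets),
    secondary_offer = numeric(n),
    choice = character(n),
    performed = logical(n),
    stringsAsFactors = FALSE
  )
  offer <- config$initial_secondary_offer
  row <- 0L
  for (s in seq_len(config$n_sets)) {
    if (config$phase == "reward" && s > 1L) {
      offer <- config$initial_secondary_offer
    }
    performed_at <- sample(seq_len(config$set_length), sample(3:5, 1L))
    for (d in seq_len(config$set_length)) {
      row <- row + 1L
      state <- list(phase = config$phase, set = s, decision = d,
                    secondary_offer = offer,
                    hybrid_offer = config$hybrid_offer,
                    history = rec[seq_len(row - 1L), , drop = FALSE])
      choice <- match.arg(policy(state), c("hybrid", "secondary"))
      rec$secondary_offer[row] <- offer
      rec$choice[row] <- choice
      rec$performed[row] <- d %in% performed_at
      offer <- next_secondary_offer(config, offer, d, choice)
    }
  }
  structure(rec, class = c("titration_trace", "data.frame"), config = config)
}

trace_config <- function(trace) {
  cfg <- attr(trace, "config")
  if (is.null(cfg)) stop("trace carries no titration_config attribute")
  cfg
}

#' Total francs earned over a reward-phase trace
#'
#' Sums, over all decisions, the offer of the option actually chosen (the
#' fixed hybrid offer when the hybrid task was chosen, the presented
#' secondary offer otherwise). All decisions count, performed or not.
#'
#' @param trace a reward-phase `titration_trace`.
#' @return Total francs (0 for an empty trace).
#' @examples
#' tr <- run_phase(function(state) "hybrid", titration_config("reward"))
#' total_francs(tr)  # 18 x 200
#' @export
total_francs <- function(trace) {
  if (nrow(trace) == 0L) return(0)
  cfg <- trace_config(trace)
  if (cfg$phase != "reward") {
    stop(errorCondition(
      "total_francs applies to reward-phase traces only",
      class = c("effortbf_wrong_phase", "effortbf_validation_error", "error", "condition")
    ))
  }
  sum(ifelse(trace$choice == "hybrid", cfg$hybrid_offer, trace$secondary_offer))
}

#' Map a franc total to its bonus payment
#'
#' Five payment categories: $1 up to 2,500 francs; $2 for 2,501–3,200;
#' $3 for 3,201–3,900; $4 for 3,901–4,600; $5 above 4,600.
#'
#' @param francs non-negative franc total.
#' @return Dollar amount (1–5). Vectorised.
#' @examples
#' payment_category(c(2400, 2500, 3600, 4601))
#' @export
payment_category <- function(francs) {
  if (any(francs < 0)) {
    stop(errorCondition(
      "franc totals must be non-negative",
      class = c("effortbf_domain_error", "error", "condition")
    ))
  }
  ifelse(francs <= 2500, 1,
         ifelse(francs <= 3200, 2,
                ifelse(francs <= 3900, 3,
                       ifelse(francs <= 4600, 4, 5))))
}

#' Average final offering of a titration phase
#'
#' The participant's phase score: the mean, over sets, of the secondary offer
#' *presented* at the last decision of each set (before its post-choice
#' adjustment). Invariant to the performed flags.
#'
#' @param trace a `titration_trace`.
#' @return The mean final offer.
#' @examples
#' tr <- run_phase(function(state) "secondary", titration_config("reward"))
#' final_offer_average(tr)  # 100
#' @export
final_offer_average <- function(trace) {
  cfg <- trace_config(trace)
  finals <- numeric(cfg$n_sets)
  for (s in seq_len(cfg$n_sets)) {
    row <- trace$set == s & trace$decision == cfg$set_length
    if (sum(row) != 1L) {
      stop(errorCondition(
        sprintf("set %d has no decision %d", s, cfg$set_length),
        class = c("effortbf_incomplete_trace", "effortbf_validation_error", "error", "condition")
      ))
    }
    finals[s] <- trace$secondary_offer[row]
  }
  mean(finals)
}
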