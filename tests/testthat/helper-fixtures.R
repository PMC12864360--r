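# Shared fixtures, built in code.

# Group-mean accuracy profile from the published practice-phase results.
group_mean_profile <- function(participant = "gm") {
  performance_profile(participant, c(
    memory_low = .837, memory_high = .709,
    motor_low = .883, motor_high = .757,
    hybrid_low = .842, hybrid_high = .625
  ))
}

# Choice data perfectly consistent with a model: k = n in the winner's
# direction on constrained pairs, an even split elsewhere.
perfect_choices <- function(model, n = 6L, participant = "ideal") {
  prs <- option_pairs()
  prs$n <- n
  prs$k <- as.integer(n / 2)
  ckey <- pair_key(model$constraints$winner, model$constraints$loser)
  idx <- match(pair_key(prs$option1, prs$option2), ckey)
  hit <- !is.na(idx)
  winner_first <- model$constraints$winner[idx[hit]] == prs$option1[hit]
  prs$k[hit] <- ifelse(winner_first, n, 0L)
  pairwise_choices(participant, prs)
}

# Choice data with explicit per-pair counts (named by "option1|option2").
choices_from_counts <- function(k_by_pair, n = 6L, participant = "manual") {
  prs <- option_pairs()
  prs$n <- n
  key <- pair_key(prs$option1, prs$option2)
  prs$k <- as.integer(ifelse(key %in% names(k_by_pair),
                             k_by_pair[key], n / 2))
  pairwise_choices(participant, prs)
}

# Independent hand-stepping oracle for one reward-phase set: given a
# length-6 choice vector, return the presented offers and the francs earned,
# using nothing from the titration module.
step_reward_set <- function(choices, initial = 200, hybrid = 200,
                            adjustments = c(50, 25, 13, 8, 4, 1)) {
  offers <- numeric(6)
  earned <- numeric(6)
  offer <- initial
  for (d in 1:6) {
    offers[d] <- offer
    earned[d] <- if (choices[d] == "hybrid") hybrid else offer
    offer <- offer + if (choices[d] == "hybrid") adjustments[d] else -adjustments[d]
  }
  list(offers = offers, francs = sum(earned))
}

is_inter_task_pair_vec <- function(a, b) {
  option_task(a) != option_task(b)
}

pair_in_constraints <- function(model, a, b) {
  (model$constraints$winner == a & model$constraints$loser == b) |
    (model$constraints$winner == b & model$constraints$loser == a)
}

# Independent acyclicity check: repeatedly peel vertices with no incoming
# edge (Kahn's algorithm, written from scratch for the test).
acyclic_by_toposort <- function(constraints) {
  nodes <- unique(c(constraints$winner, constraints$loser))
  edges <- constraints
  while (length(nodes) > 0L) {
    free <- nodes[!nodes %in% edges$loser]
    if (length(free) == 0L) return(FALSE)
    nodes <- setdiff(nodes, free)
    edges <- edges[!edges$winner %in% free, , drop = FALSE]
  }
  TRUE
}

# A profile whose accuracies group perfectly by task (memory > motor >
# hybrid, low > high within task): its DA-all, DA-low and DA-high orders all
# coincide with each other and with the memory-motor-hybrid task grouping.
task_grouped_profile <- function(participant = "grouped") {
  performance_profile(participant, c(
    memory_low = .95, memory_high = .90,
    motor_low = .80, motor_high = .75,
    hybrid_low = .60, hybrid_high = .55
  ))
}
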