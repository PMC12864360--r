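# Synthetic agents with known decision policies. The generator deliberately
# injects only ordinal structure: ranked agents follow their model's pairwise
# constraints with probability 1 - lapse and are at chance on unconstrained
# pairs, so the fitter sees exactly the information class its models encode.

#' Specify a synthetic agent
#'
#' @param policy one of `"demand_ranked"`, `"task_ranked"`,
#'   `"single_task_bias"`, `"random"`, `"titration_value"`,
#'   `"titration_loyal"`, or `"model"` (choices driven by an explicit
#'   `preference_model`).
#' @param direction,heuristic generating demand model (for `demand_ranked`).
#' @param task_order character vector of the three tasks, most preferred
#'   first (for `task_ranked`).
#' @param biased_task,bias_direction task-level bias (for
#'   `single_task_bias`); `bias_direction` is `"for"` or `"against"`.
#' @param model an explicit `preference_model` (for `policy = "model"`).
#' @param lapse lapse rate in `[0, 0.5)`: probability of choosing against
#'   the agent's own preference on a constrained pair.
#' @param tau reward-phase indifference margin in francs: a value-based
#'   titration agent takes the secondary task when its offer beats the hybrid
#'   offer by at least `tau`.
#' @param lambda demand-phase indifference level in squares: the agent takes
#'   the secondary task while its level is below `lambda`.
#' @param loyal_target `"hybrid"` or `"secondary"` (for `titration_loyal`).
#' @return A list of class `agent_spec`.
#' @examples
#' agent_spec("demand_ranked", direction = "DA", heuristic = "all")
#' agent_spec("titration_loyal", loyal_target = "hybrid")
#' @export
agent_spec <- function(policy = c("demand_ranked", "task_ranked",
                                  "single_task_bias", "random",
                                  "titration_value", "titration_loyal",
                                  "model"),
                       direction = NULL, heuristic = NULL, task_order = NULL,
                       biased_task = NULL, bias_direction = "for",
                       model = NULL, lapse = 0.05,
                       tau = 0, lambda = 7, loyal_target = NULL) {
  policy <- match.arg(policy)
  if (lapse < 0 || lapse >= 0.5) stop("lapse must lie in [0, 0.5)")
  if (policy == "demand_ranked" && (is.null(direction) || is.null(heuristic))) {
    stop("demand_ranked agents need a direction and a heuristic")
  }
  if (policy == "task_ranked") {
    if (is.null(task_order) || !setequal(task_order, tasks())) {
      stop("task_ranked agents need a permutation of the three tasks")
    }
  }
  if (policy == "single_task_bias" && is.null(biased_task)) {
    stop("single_task_bias agents need a biased_task")
  }
  if (policy == "titration_loyal" &&
      (is.null(loyal_target) || !loyal_target %in% c("hybrid", "secondary"))) {
    stop("titration_loyal agents need loyal_target 'hybrid' or 'secondary'")
  }
  if (policy == "model" && !inherits(model, "preference_model")) {
    stop("policy 'model' needs a preference_model")
  }
  structure(
    list(policy = policy, direction = direction, heuristic = heuristic,
         task_order = task_order, biased_task = biased_task,
         bias_direction = match.arg(bias_direction, c("for", "against")),
         model = model, lapse = lapse, tau = tau, lambda = lambda,
         loyal_target = loyal_target),
    class = "agent_spec"
  )
}

# Generating preference model of a ranked agent, if any.
agent_model <- function(agent, profile = NULL) {
  switch(agent$policy,
         demand_ranked = rank_options(profile, agent$heuristic, agent$direction),
         task_ranked = build_task_models()[[paste(c("TASK", agent$task_order),
                                                  collapse = "-")]],
         model = agent$model,
         NULL)
}

#' Generate a synthetic performance profile
#'
#' Per-option accuracies are drawn from beta distributions centred on the
#' pilot targets (mean .80 for low-demand options, .60 for high-demand) with
#' a common concentration, then discretised to the k/15 grid of 15 practice
#' trials. An infinite concentration pins each accuracy at its target.
#'
#' @param participant identifier.
#' @param seed integer seed.
#' @param mean_low,mean_high target mean accuracy per demand level.
#' @param concentration beta concentration (shape1 + shape2); `Inf` for
#'   degenerate draws at the mean.
#' @param n_trials practice trials per option (grid resolution).
#' @return A [performance_profile()].
#' @examples
#' gen_profile("p1", seed = 42)
#' @export
gen_profile <- function(participant = "sim", seed = 1L,
                        mean_low = 0.80, mean_high = 0.60,
                        concentration = 30, n_trials = 15L) {
  set.seed(seed)
  ids <- option_ids()
  mu <- ifelse(option_level(ids) == "low", mean_low, mean_high)
  raw <- if (is.infinite(concentration)) {
    mu
  } else {
    stats::rbeta(6L, mu * concentration, (1 - mu) * concentration)
  }
  acc <- round(raw * n_trials) / n_trials
  performance_profile(participant, stats::setNames(acc, ids), n_trials)
}

#' Generate pairwise choice data from an agent
#'
#' Each of the 15 pairs is presented `n_per_pair` times (default 6, i.e. 90
#' choices). Ranked agents choose the winner of each constrained pair with
#' probability `1 - lapse` and are at chance on unconstrained pairs; a
#' single-task-bias agent favours (or avoids) its task's options with
#' probability `1 - lapse` on the eight inter-task pairs involving that task
#' and is at chance elsewhere; a random agent is at chance everywhere.
#'
#' @param agent an [agent_spec()].
#' @param profile a [performance_profile()] (needed by `demand_ranked`).
#' @param seed integer seed.
#' @param n_per_pair presentations per pair.
#' @param participant identifier recorded in the output (defaults to the
#'   profile's, else `"sim"`).
#' @return A [pairwise_choices()] object.
#' @examples
#' agent <- agent_spec("task_ranked", task_order = c("hybrid", "motor", "memory"))
#' gen_choice_data(agent, seed = 1)
#' @export
gen_choice_data <- function(agent, profile = NULL, seed = 1L,
                            n_per_pair = 6L, participant = NULL) {
  if (!inherits(agent, "agent_spec")) stop("expected an 'agent_spec'")
  if (is.null(participant)) {
    participant <- if (!is.null(profile)) as_profile(profile)$participant else "sim"
  }
  prs <- option_pairs()
  p1 <- rep(0.5, nrow(prs))  # probability option1 is chosen
  if (agent$policy %in% c("demand_ranked", "task_ranked", "model")) {
    mod <- agent_model(agent, profile)
    cons <- mod$constraints
    ckey <- pair_key(cons$winner, cons$loser)
    idx <- match(pair_key(prs$option1, prs$option2), ckey)
    hit <- !is.na(idx)
    winner_first <- cons$winner[idx[hit]] == prs$option1[hit]
    p1[hit] <- ifelse(winner_first, 1 - agent$lapse, agent$lapse)
  } else if (agent$policy == "single_task_bias") {
    t1 <- option_task(prs$option1) == agent$biased_task
    t2 <- option_task(prs$option2) == agent$biased_task
    inter <- xor(t1, t2)
    pref <- if (agent$bias_direction == "for") 1 - agent$lapse else agent$lapse
    p1[inter & t1] <- pref
    p1[inter & t2] <- 1 - pref
  }
  set.seed(seed)
  prs$n <- as.integer(n_per_pair)
  prs$k <- stats::rbinom(nrow(prs), n_per_pair, p1)
  pairwise_choices(participant, prs)
}

#' Build a titration choice policy from an agent
#'
#' `titration_value` agents track an indifference point: in the reward phase
#' they take the secondary task whenever its offer beats the fixed hybrid
#' offer by at least `tau` francs (ties at `tau = 0` go to the secondary
#' task); in the demand phase they take the secondary task while its level is
#' below `lambda` squares. `titration_loyal` agents always choose their
#' target task. Both lapse (choose the opposite) with probability `lapse`.
#'
#' @param agent an [agent_spec()] with a titration policy.
#' @return A function usable as the `policy` argument of [run_phase()].
#' @examples
#' pol <- gen_titration_policy(agent_spec("titration_loyal",
#'                                        loyal_target = "hybrid", lapse = 0))
#' run_phase(pol, titration_config("reward"))
#' @export
gen_titration_policy <- function(agent) {
  if (!inherits(agent, "agent_spec")) stop("expected an 'agent_spec'")
  if (!agent$policy %in% c("titration_value", "titration_loyal")) {
    stop("agent is not a titration policy")
  }
  force(agent)
  function(state) {
    base <- if (agent$policy == "titration_loyal") {
      agent$loyal_target
    } else if (state$phase == "reward") {
      if (state$secondary_offer - state$hybrid_offer >= agent$tau)
        "secondary" else "hybrid"
    } else {
      if (state$secondary_offer < agent$lambda) "secondary" else "hybrid"
    }
    if (agent$lapse > 0 && stats::runif(1) < agent$lapse) {
      if (base == "hybrid") "secondary" else "hybrid"
    } else {
      base
    }
  }
}

#' Generate a full synthetic cohort
#'
#' Creates participants for each requested policy with known ground-truth
#' labels: a performance profile for everyone, pairwise choice data for the
#' choice-phase policies, and reward + demand titration traces for the
#' titration policies. Ranked agents can be screened for identifiability:
#' every other model of the 12-model battery must either conflict with the
#' generating model or be a dominated nested submodel (see
#' [model_identifiable()]), otherwise the participant's generating order is
#' redrawn (demand agents redraw their profile, task agents their task
#' order).
#'
#' @param config a [cohort_config()].
#' @return A list of class `cohort`: `profiles` (named list),
#'   `choices` (named list), `traces` (named list of
#'   `list(reward =, demand =)`), `truth` (data frame with one row per
#'   participant: `participant`, `policy`, `label` and policy parameters),
#'   and `config`.
#' @examples
#' coh <- gen_cohort(cohort_config(n_per_policy = c(random = 2), seed = 1))
#' coh$truth
#' @export
gen_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("expected a 'cohort_config'")
  set.seed(config$seed)
  npp <- config$n_per_policy
  total <- sum(npp)
  seeds <- matrix(sample.int(.Machine$integer.max, total * 4L), ncol = 4L)
  profiles <- list()
  choices <- list()
  traces <- list()
  truth <- NULL
  directions <- c("DA", "CS")
  heuristics <- c("all", "low", "high")
  orders <- list(
    c("memory", "motor", "hybrid"), c("memory", "hybrid", "motor"),
    c("motor", "memory", "hybrid"), c("motor", "hybrid", "memory"),
    c("hybrid", "memory", "motor"), c("hybrid", "motor", "memory")
  )
  i <- 0L
  for (policy in names(npp)) {
    for (r in seq_len(npp[[policy]])) {
      i <- i + 1L
      id <- sprintf("%s_%03d", policy, r)
      prof <- gen_profile(id, seed = seeds[i, 1L],
                          mean_low = config$mean_low,
                          mean_high = config$mean_high,
                          concentration = config$concentration)
      row <- data.frame(participant = id, policy = policy,
                        label = NA_character_, param = NA_character_,
                        stringsAsFactors = FALSE)
      agent <- NULL
      if (policy == "demand_ranked") {
        dir <- sample(directions, 1L)
        heu <- sample(heuristics, 1L)
        if (config$identifiable_only) {
          tries <- 0L
          while (!model_identifiable(rank_options(prof, heu, dir),
                                     build_model_battery(prof)) &&
                 tries < 100L) {
            tries <- tries + 1L
            prof <- gen_profile(id, seed = seeds[i, 1L] %% 100000L + tries,
                                mean_low = config$mean_low,
                                mean_high = config$mean_high,
                                concentration = config$concentration)
          }
        }
        agent <- agent_spec("demand_ranked", direction = dir, heuristic = heu,
                            lapse = config$lapse)
        row$label <- "demand_related"
        row$param <- paste(dir, heu, sep = "-")
      } else if (policy == "task_ranked") {
        ord <- orders[[sample.int(6L, 1L)]]
        if (config$identifiable_only) {
          tries <- 0L
          while (!model_identifiable(
                   agent_model(agent_spec("task_ranked", task_order = ord)),
                   build_model_battery(prof)) && tries < 20L) {
            tries <- tries + 1L
            ord <- orders[[sample.int(6L, 1L)]]
          }
        }
        agent <- agent_spec("task_ranked", task_order = ord,
                            lapse = config$lapse)
        row$label <- "task_driven"
        row$param <- paste(ord, collapse = "-")
      } else if (policy == "single_task_bias") {
        tk <- sample(tasks(), 1L)
        dirn <- sample(c("for", "against"), 1L)
        agent <- agent_spec("single_task_bias", biased_task = tk,
                            bias_direction = dirn, lapse = config$lapse)
        row$label <- "no_best_fit"
        row$param <- paste(dirn, tk)
      } else if (policy == "random") {
        agent <- agent_spec("random", lapse = config$lapse)
        row$label <- "no_best_fit"
      } else if (policy == "titration_value") {
        tau <- stats::rnorm(1L, 0, config$tau_sd)
        lambda <- sample(3:11, 1L)
        agent <- agent_spec("titration_value", tau = tau, lambda = lambda,
                            lapse = config$lapse)
        row$param <- sprintf("tau=%.0f;lambda=%d", tau, lambda)
      } else if (policy == "titration_loyal") {
        tgt <- if (r %% 2L == 1L) "hybrid" else "secondary"
        agent <- agent_spec("titration_loyal", loyal_target = tgt,
                            lapse = config$lapse)
        row$param <- tgt
      } else {
        stop("unknown policy in cohort config: ", policy)
      }
      profiles[[id]] <- prof
      if (agent$policy %in% c("demand_ranked", "task_ranked",
                              "single_task_bias", "random")) {
        choices[[id]] <- gen_choice_data(agent, prof, seed = seeds[i, 2L])
      }
      if (agent$policy %in% c("titration_value", "titration_loyal")) {
        pol <- gen_titration_policy(agent)
        cond <- if (i %% 2L == 0L) "memory" else "motor"
        traces[[id]] <- list(
          reward = run_phase(pol, titration_config("reward"),
                             seed = seeds[i, 3L], participant = id,
                             condition = cond),
          demand = run_phase(pol, titration_config("demand"),
                             seed = seeds[i, 4L], participant = id,
                             condition = cond)
        )
      }
      truth <- rbind(truth, row)
    }
  }
  structure(
    list(profiles = profiles, choices = choices, traces = traces,
         truth = truth, config = config),
    class = "cohort"
  )
}

#' Cohort simulation settings
#'
#' @param n_per_policy named integer vector: how many participants to
#'   generate per policy (names from the [agent_spec()] policy enum).
#' @param mean_low,mean_high generating mean accuracies (pilot targets .80
#'   low-demand, .60 high-demand).
#' @param concentration beta concentration of the accuracy draws.
#' @param lapse agent lapse rate.
#' @param tau_sd SD of value agents' franc indifference margins.
#' @param identifiable_only screen ranked agents' generating orders for
#'   identifiability (see [gen_cohort()]).
#' @param seed master seed (mandatory).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_policy = c(demand_ranked = 10, task_ranked = 10,
                                           single_task_bias = 5, random = 5,
                                           titration_value = 10,
                                           titration_loyal = 10),
                          mean_low = 0.80, mean_high = 0.60,
                          concentration = 30, lapse = 0.05, tau_sd = 40,
                          identifiable_only = TRUE, seed) {
  if (missing(seed)) stop("a master seed is mandatory")
  if (mean_low <= 0 || mean_low >= 1 || mean_high <= 0 || mean_high >= 1) {
    stop("generating means must lie in (0, 1)")
  }
  structure(
    list(n_per_policy = n_per_policy, mean_low = mean_low,
         mean_high = mean_high, concentration = concentration,
         lapse = lapse, tau_sd = tau_sd,
         identifiable_only = isTRUE(identifiable_only),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Is a generating model identifiable within a battery?
#'
#' A competitor can be separated from the generating model by the
#' best/second-best ratio criterion in one of two ways. Either it constrains
#' at least one pair in the opposite direction — data following the
#' generating model then crush the competitor on that pair — or it is a
#' nested submodel whose constraints are a strict subset of the generating
#' model's, at least `min_nested_margin` constraints smaller: each missing
#' constraint costs the submodel a factor of about 2 on consistent data, so a
#' margin of 3 puts the expected ratio near 8, comfortably past a 3.12
#' threshold. (The margin matters: a submodel only one constraint smaller
#' can never be out-voted by more than a factor of 2.) A competitor that is
#' neither conflicting nor deeply nested — for example a task model agreeing
#' with a demand model on every inter-task pair — is observationally
#' equivalent on the generating model's data, and the ratio criterion cannot
#' separate the two: a real identifiability limit of a purely ordinal
#' design. Low/high-heuristic demand models always group options by task, so
#' they always carry one task model as a nested (margin-3) submodel; they
#' remain identifiable unless score ties prune them below the margin.
#'
#' @param model the generating `preference_model`.
#' @param battery list of `preference_model` objects to compare against.
#' @param min_nested_margin minimum constraint-count deficit for a nested
#'   submodel to count as dominated.
#' @return `TRUE` if identifiable.
#' @export
model_identifiable <- function(model, battery, min_nested_margin = 3L) {
  okey <- function(m) paste(m$constraints$winner, m$constraints$loser, sep = ">")
  rkey <- function(m) paste(m$constraints$loser, m$constraints$winner, sep = ">")
  mkeys <- okey(model)
  rkeys <- rkey(model)
  for (other in battery) {
    if (identical(other$model_id, model$model_id)) next
    ok <- okey(other)
    if (any(ok %in% rkeys)) next
    if (all(ok %in% mkeys) &&
        length(mkeys) - length(ok) >= min_nested_margin) next
    return(FALSE)
  }
  TRUE
}
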