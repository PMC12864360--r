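test_that("gen_profile hits the pilot targets and the k/15 grid", {
  exact <- gen_profile("p", seed = 1, concentration = Inf)
  expect_equal(unname(exact$accuracy[option_level(option_ids()) == "low"]),
               rep(12 / 15, 3))
  expect_equal(unname(exact$accuracy[option_level(option_ids()) == "high"]),
               rep(9 / 15, 3))

  p1 <- gen_profile("p", seed = 33)
  p2 <- gen_profile("p", seed = 33)
  expect_identical(p1, p2)
  expect_true(all(abs(p1$accuracy * 15 - round(p1$accuracy * 15)) < 1e-9))

  accs <- vapply(1:500, function(i) {
    mean(gen_profile("x", seed = i)$accuracy[c("memory_low", "motor_low",
                                               "hybrid_low")])
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.80), 3 * se + 0.01)
})

test_that("noiseless ranked agents follow their constraints exactly", {
  prof <- group_mean_profile()
  agent <- agent_spec("demand_ranked", direction = "DA", heuristic = "all",
                      lapse = 0)
  dat <- gen_choice_data(agent, prof, seed = 2)
  model <- rank_options(prof, "all", "DA")
  for (i in seq_len(nrow(model$constraints))) {
    w <- model$constraints$winner[i]
    l <- model$constraints$loser[i]
    counts <- effortbf:::pair_counts_for(dat, w, l)
    expect_equal(unname(counts[["k"]]), 6L)
  }
})

test_that("random agents sit at chance on every pair", {
  ks <- replicate(400, {
    dat <- gen_choice_data(agent_spec("random"), seed = sample.int(1e6, 1))
    mean(dat$counts$k)
  })
  expect_lt(abs(mean(ks) - 3), 3 * sd(ks) / sqrt(length(ks)))
})

test_that("task-ranked agents are at chance within tasks", {
  agent <- agent_spec("task_ranked",
                      task_order = c("hybrid", "motor", "memory"), lapse = 0)
  within_k <- replicate(200, {
    dat <- gen_choice_data(agent, seed = sample.int(1e6, 1))
    within <- option_task(dat$counts$option1) == option_task(dat$counts$option2)
    mean(dat$counts$k[within])
  })
  se <- sd(within_k) / sqrt(length(within_k))
  expect_lt(abs(mean(within_k) - 3), 3 * se)
  # and deterministic on inter-task pairs
  dat <- gen_choice_data(agent, seed = 1)
  inter <- dat$counts[option_task(dat$counts$option1) !=
                        option_task(dat$counts$option2), ]
  rank_of <- c(hybrid = 1, motor = 2, memory = 3)
  wins_first <- rank_of[option_task(inter$option1)] <
    rank_of[option_task(inter$option2)]
  expect_equal(inter$k, unname(ifelse(wins_first, 6L, 0L)))
})

test_that("single-task-bias agents load only the inter-task pairs of their task", {
  agent <- agent_spec("single_task_bias", biased_task = "hybrid", lapse = 0)
  dat <- gen_choice_data(agent, seed = 9)
  counts <- dat$counts
  t1 <- option_task(counts$option1) == "hybrid"
  t2 <- option_task(counts$option2) == "hybrid"
  inter <- xor(t1, t2)
  expect_equal(counts$k[inter & t1], rep(6L, sum(inter & t1)))
  expect_equal(counts$k[inter & t2], rep(0L, sum(inter & t2)))

  avert <- agent_spec("single_task_bias", biased_task = "hybrid",
                      bias_direction = "against", lapse = 0)
  dat2 <- gen_choice_data(avert, seed = 9)
  expect_equal(dat2$counts$k[inter & t1], rep(0L, sum(inter & t1)))
})

test_that("titration value agents track the indifference point", {
  agent <- agent_spec("titration_value", tau = 0, lapse = 0)
  pol <- gen_titration_policy(agent)
  tr <- run_phase(pol, titration_config("reward"), seed = 1)
  # decision 1: 200 vs 200, tie resolved toward the secondary task
  expect_equal(tr$choice[1], "secondary")
  # hand-stepped: sec,hyb alternate as the offer crosses 200
  oracle_choices <- character(6)
  offer <- 200
  cfg <- titration_config("reward")
  for (d in 1:6) {
    oracle_choices[d] <- if (offer - 200 >= 0) "secondary" else "hybrid"
    offer <- next_secondary_offer(cfg, offer, d, oracle_choices[d])
  }
  expect_equal(tr$choice[1:6], oracle_choices)
  # the final offer lands near the hybrid's 200 francs
  expect_lt(abs(final_offer_average(tr) - 200), 25)
})

test_that("loyal titration agents pin the extremes", {
  loyal_h <- gen_titration_policy(
    agent_spec("titration_loyal", loyal_target = "hybrid", lapse = 0))
  tr <- run_phase(loyal_h, titration_config("reward"), seed = 1)
  expect_equal(tr$secondary_offer[tr$decision == 6], c(300, 300, 300))

  loyal_s <- gen_titration_policy(
    agent_spec("titration_loyal", loyal_target = "secondary", lapse = 0))
  trd <- run_phase(loyal_s, titration_config("demand"), seed = 1)
  expect_equal(max(trd$secondary_offer), 12)
  # ceiling reached after five increments and held thereafter
  expect_true(all(trd$secondary_offer[6:18] == 12))
})

test_that("gen_cohort is referentially intact and byte-reproducible", {
  cfg <- cohort_config(n_per_policy = c(demand_ranked = 2, task_ranked = 2,
                                        single_task_bias = 2, random = 2,
                                        titration_value = 2,
                                        titration_loyal = 2),
                       seed = 77)
  coh <- gen_cohort(cfg)
  expect_equal(nrow(coh$truth), 12L)
  expect_setequal(names(coh$profiles), coh$truth$participant)
  expect_true(all(names(coh$choices) %in% coh$truth$participant))
  expect_true(all(names(coh$traces) %in% coh$truth$participant))
  expect_setequal(unique(coh$truth$policy),
                  c("demand_ranked", "task_ranked", "single_task_bias",
                    "random", "titration_value", "titration_loyal"))

  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  write_cohort(gen_cohort(cfg), d1)
  write_cohort(gen_cohort(cfg), d2)
  for (f in c("performance.csv", "choices.csv", "titration.csv", "truth.csv",
              "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("observationally equivalent orders are a real identifiability limit", {
  # a task-grouped profile makes all three DA heuristics produce the same
  # total order, which also nests a task model: the ratio criterion cannot
  # pick a winner even from noiseless data
  prof <- task_grouped_profile()
  battery <- build_model_battery(prof)
  da <- battery[["DA-all"]]
  expect_identical(da$constraints, battery[["DA-low"]]$constraints)
  expect_false(model_identifiable(da, battery))

  dat <- gen_choice_data(agent_spec("model", model = da, lapse = 0),
                         seed = 13)
  fit <- fit_preferences(dat, prof)
  expect_equal(fit$classification$category, "no_best_fit")

  # while an identifiable generating order is recovered from the same amount
  # of noiseless data
  prof2 <- group_mean_profile()
  expect_true(model_identifiable(rank_options(prof2, "all", "DA"),
                                 build_model_battery(prof2)))
})
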