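test_that("score_options maps accuracies according to the heuristic", {
  prof <- group_mean_profile()
  expect_equal(score_options(prof, "all"), prof$accuracy)
  hi <- score_options(prof, "high")
  expect_equal(unname(hi[c("motor_low", "motor_high")]), c(.757, .757))
  expect_equal(unname(hi[c("memory_low", "memory_high")]), c(.709, .709))
  expect_equal(unname(hi[c("hybrid_low", "hybrid_high")]), c(.625, .625))
  lo <- score_options(prof, "low")
  expect_equal(unname(lo["hybrid_high"]), .842)

  uniform <- performance_profile("u", setNames(rep(.5, 6), option_ids()))
  for (h in c("all", "low", "high")) {
    expect_true(all(score_options(uniform, h) == .5))
  }
})

test_that("an incomplete profile raises a structured error naming the option", {
  acc <- setNames(rep(.7, 5), option_ids()[1:5])
  err <- expect_error(performance_profile("p", acc),
                      class = "effortbf_incomplete_profile")
  expect_match(conditionMessage(err), "hybrid_high")
})

test_that("rank_options recovers the sort order of the group means", {
  prof <- group_mean_profile()
  da <- rank_options(prof, "all", "DA")
  expect_equal(nrow(da$constraints), 15L)
  expect_false(da$tie_flag)
  # independent oracle: sort accuracies, enumerate implied pairs
  expected_order <- names(sort(prof$accuracy, decreasing = TRUE))
  expect_equal(expected_order,
               c("motor_low", "hybrid_low", "memory_low",
                 "motor_high", "memory_high", "hybrid_high"))
  for (i in 1:5) {
    for (j in (i + 1):6) {
      hit <- da$constraints$winner == expected_order[i] &
        da$constraints$loser == expected_order[j]
      expect_equal(sum(hit), 1L)
    }
  }
  # CS is the exact reversal
  cs <- rank_options(prof, "all", "CS")
  expect_equal(
    cs$constraints[order(cs$constraints$winner, cs$constraints$loser), ],
    setNames(da$constraints[order(da$constraints$loser, da$constraints$winner),
                            c("loser", "winner")],
             c("winner", "loser")),
    ignore_attr = TRUE
  )
})

test_that("an all-tied profile yields no constraints and a tie flag", {
  uniform <- performance_profile("u", setNames(rep(.5, 6), option_ids()))
  m <- rank_options(uniform, "all", "DA")
  expect_equal(nrow(m$constraints), 0L)
  expect_true(m$tie_flag)
  # under low/high heuristics the within-task pairs stay constrained by the
  # family rule even though every score ties
  mlow <- rank_options(uniform, "low", "DA")
  expect_equal(nrow(mlow$constraints), 3L)
  expect_true(all(option_task(mlow$constraints$winner) ==
                    option_task(mlow$constraints$loser)))
  expect_true(all(option_level(mlow$constraints$winner) == "low"))
  mlow_cs <- rank_options(uniform, "low", "CS")
  expect_true(all(option_level(mlow_cs$constraints$winner) == "high"))
})

test_that("build_demand_models returns the six named models", {
  models <- build_demand_models(group_mean_profile())
  expect_named(models, c("DA-all", "DA-low", "DA-high",
                         "CS-all", "CS-low", "CS-high"))
  expect_true(all(vapply(models, function(m) m$family, "") == "demand"))
})

test_that("the published worked example drives CS-high as expected", {
  # high-demand accuracies: hybrid 45% < motor 68% < memory 73%, so a
  # challenge seeker under the high heuristic prefers hybrid > motor > memory
  prof <- performance_profile("ex", c(
    memory_low = .80, memory_high = .73,
    motor_low = .80, motor_high = .68,
    hybrid_low = .80, hybrid_high = .45
  ))
  cs <- build_demand_models(prof)[["CS-high"]]
  for (h in c("hybrid_low", "hybrid_high")) {
    for (l in c("motor_low", "motor_high", "memory_low", "memory_high")) {
      expect_true(any(cs$constraints$winner == h & cs$constraints$loser == l))
    }
  }
  for (m_ in c("motor_low", "motor_high")) {
    for (l in c("memory_low", "memory_high")) {
      expect_true(any(cs$constraints$winner == m_ & cs$constraints$loser == l))
    }
  }
})

test_that("task models are fixed, twelve-constraint, and profile-free", {
  tm1 <- build_task_models()
  tm2 <- build_task_models()
  expect_length(tm1, 6L)
  expect_identical(tm1, tm2)
  for (m in tm1) {
    expect_equal(nrow(m$constraints), 12L)
    expect_true(all(is_inter_task_pair_vec(m$constraints$winner,
                                           m$constraints$loser)))
  }
  mmh <- tm1[["TASK-memory-motor-hybrid"]]
  expect_true(any(mmh$constraints$winner == "memory_low" &
                    mmh$constraints$loser == "hybrid_high"))
  expect_false(any(pair_in_constraints(mmh, "memory_low", "memory_high")))
})

test_that("the battery always holds 12 models with acyclic constraints", {
  set.seed(11)
  for (rep in 1:10) {
    prof <- gen_profile(paste0("r", rep), seed = rep)
    battery <- build_model_battery(prof)
    expect_length(battery, 12L)
    for (m in battery) {
      expect_true(acyclic_by_toposort(m$constraints))
    }
    # DA/CS reversal per heuristic when no ties were dropped
    for (h in c("all", "low", "high")) {
      da <- battery[[paste0("DA-", h)]]
      cs <- battery[[paste0("CS-", h)]]
      if (!da$tie_flag && !cs$tie_flag) {
        expect_setequal(paste(da$constraints$winner, da$constraints$loser),
                        paste(cs$constraints$loser, cs$constraints$winner))
      }
    }
  }
})

test_that("models serialize to the documented JSON shape", {
  js <- jsonlite::fromJSON(models_to_json(build_task_models()[1:2]),
                           simplifyVector = FALSE)
  expect_length(js, 2L)
  expect_named(js[[1]], c("model_id", "family", "constraints"))
  expect_length(js[[1]]$constraints[[1]], 2L)
})
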