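test_that("training schedule balances goals under the chaining constraint", {
  g <- fx_graph()
  sched <- make_training_schedule(g, start_room = 4, seed = 11)
  expect_equal(nrow(sched), 75L)
  expect_equal(as.integer(table(sched$goal_room)), rep(5L, 15))
  # chained starts, goal never in the start wing
  expect_equal(sched$start_room[-1], sched$goal_room[-75])
  expect_true(all(wing_of(g, sched$goal_room) != wing_of(g, sched$start_room)))
  # reproducible from seed, and the balance report is attached
  sched2 <- make_training_schedule(g, start_room = 4, seed = 11)
  expect_identical(sched, sched2)
  expect_s3_class(sched, "tbl_df")
  expect_false(is.null(attr(sched, "distance_balance")))
  expect_error(make_training_schedule(g, 1, n_miniblocks = 40L), "multiple")
})

test_that("testing goals are uniform over the 10 rooms outside the wing", {
  g <- fx_graph()
  set.seed(3)
  draws <- replicate(1e4, sample_testing_goal(g, 7))
  expect_equal(sort(unique(draws)), setdiff(1:15, 6:10))
  expect_gt(stats::chisq.test(table(draws))$p.value, 0.001)
})

test_that("environment steps land on the action's two outcomes equally often", {
  m <- fx_mapping()
  set.seed(5)
  draws <- replicate(1e4, step_environment(m, 1, "A1"))
  expect_setequal(unique(draws), m$outcomes[1, 1, ])
  bt <- stats::binom.test(sum(draws == m$outcomes[1, 1, 1]), 1e4, 0.5)
  expect_gt(bt$p.value, 0.001)
  expect_true(all(draws %in% room_neighbors(fx_graph(), 1)))
  set.seed(9); a <- replicate(20, step_environment(m, 3, 2))
  set.seed(9); b <- replicate(20, step_environment(m, 3, 2))
  expect_identical(a, b)
})

test_that("sessions chain miniblocks, respect the budget, and mark rests", {
  log <- fx_random_session()
  cfg <- msr_config(testing_budget = 800)
  # continuous walk: each miniblock starts at the previous goal
  starts <- log |>
    dplyr::group_by(.data$phase, .data$miniblock) |>
    dplyr::summarise(start = dplyr::first(.data$room),
                     goal = dplyr::first(.data$goal), .groups = "drop")
  tr <- starts[starts$phase == "training", ]
  te <- starts[starts$phase == "testing", ]
  expect_equal(tr$start[-1], tr$goal[-nrow(tr)])
  expect_equal(te$start[-1], te$goal[-nrow(te)])
  expect_equal(te$start[1], tr$goal[nrow(tr)])
  # budget conservation: testing moves == initial budget - final budget
  n_moves <- sum(log$phase == "testing" & log$event == "move" &
                   log$key %in% c("z", "m"))
  trace <- attr(log, "budget_trace")
  expect_equal(n_moves, cfg$testing_budget - trace[length(trace)])
  # the session ends at the first miniblock boundary below 0
  expect_lt(trace[length(trace)], 0)
  expect_true(all(trace[-length(trace)] >= 0))
  expect_gte(n_moves, cfg$testing_budget)
  # rests after training miniblocks 25, 50 and once the budget dips under 500
  rests <- attr(log, "rest_after")
  expect_true(all(c(25, 50) %in% rests))
  first_low <- which(trace < cfg$rest_budget_testing)[1]
  expect_true((75 + first_low) %in% rests)
})

test_that("participant exclusions catch key-perseveration and goal failures", {
  g <- fx_graph(); m <- fx_mapping()
  cfg <- msr_config(testing_budget = 120)
  perseverator <- run_session(msr_agent("random"), g, m, seed = 31,
                              config = cfg, participant = "stuck")
  # overwrite 95% of movement keys with one response: pure key bookkeeping
  zm <- which(perseverator$key %in% c("z", "m"))
  perseverator$key[zm[seq_along(zm) %% 20 != 0]] <- "m"
  sloppy <- run_session(
    msr_agent("random", lapse_goal = 0.8),                      # misses most goals
    g, m, seed = 32, config = cfg, participant = "sloppy")
  fine <- run_session(msr_agent("random"), g, m, seed = 33, config = cfg,
                      participant = "fine")
  res <- apply_participant_exclusions(dplyr::bind_rows(perseverator, sloppy, fine))
  expect_setequal(res$report$participant[res$report$excluded], c("stuck", "sloppy"))
  expect_setequal(unique(res$retained$participant), "fine")
  expect_gt(res$report$same_action_share[res$report$participant == "stuck"], 0.9)
  expect_gt(res$report$bad_miniblock_share[res$report$participant == "sloppy"], 0.5)
})

test_that("miniblock exclusions drop offending miniblocks and the start step", {
  log <- fx_random_session()
  kept <- apply_miniblock_exclusions(log)
  moves <- log[log$phase == "testing" & log$event == "move" &
                 log$key %in% c("z", "m"), ]
  bad <- unique(log$miniblock[log$phase == "testing" &
                                log$event %in% c("goal_miss", "wrong_goal")])
  clean_counts <- table(moves$miniblock[!(moves$miniblock %in% bad)])
  # every clean miniblock of k moves contributes k - 1 analyzable trials
  expect_equal(nrow(kept), sum(pmax(clean_counts - 1, 0)))
  expect_false(any(kept$miniblock %in% bad))
  # exclusions never span miniblock boundaries: other miniblocks keep trials
  expect_setequal(unique(kept$miniblock),
                  as.integer(names(clean_counts)[clean_counts > 1]))
})

test_that("long-run room occupancy of a random session is uniform", {
  g <- fx_graph(); m <- fx_mapping()
  log <- run_session(msr_agent("random", lapse_goal = 0, lapse_space = 0),
                     g, m, seed = 77,
                     config = msr_config(testing_budget = 30000))
  rooms <- log$room[log$event == "move" & log$key %in% c("z", "m")]
  # thin the walk to weaken Markov autocorrelation, which inflates the
  # chi-square statistic relative to its multinomial reference
  rooms <- rooms[seq(1, length(rooms), by = 5)]
  expect_gt(stats::chisq.test(table(rooms))$p.value, 0.01)
})

test_that("non-terminating agents hit the hard step cap with an error", {
  g <- fx_graph(); m <- fx_mapping()
  expect_error(
    run_session(msr_agent("random"), g, m, seed = 1,
                config = msr_config(step_cap = 3L)),
    "step cap")
})
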