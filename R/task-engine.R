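# Miniblock scheduling, environment stepping and session simulation.
# A session is one continuous walk: the start room of each miniblock is the
# goal room of the previous one, goals always lie outside the current wing.

#' Experiment configuration
#'
#' Defaults reproduce the published design constants: 75 training
#' miniblocks with a rest every 25, a testing budget of 1000 room
#' transitions with a rest once the budget drops below 500, rewards of
#' 0.10/0.15 currency units per goal (training/testing) and a 0.02 penalty
#' for wrong-goal and goal-miss presses.
#'
#' @param training_miniblocks number of training miniblocks
#' @param testing_budget steps available in the testing phase
#' @param rest_every_training rest interval (miniblocks) during training
#' @param rest_budget_testing budget threshold triggering the testing rest
#' @param reward_training,reward_testing,penalty payoff constants
#' @param step_cap hard per-miniblock step cap guarding non-terminating
#'   agents
#' @param sampler_profile `"test"` (scaled-down draws) or `"paper"`
#' @return a list of class `msr_config`
#' @export
msr_config <- function(training_miniblocks = 75L, testing_budget = 1000L,
                       rest_every_training = 25L, rest_budget_testing = 500L,
                       reward_training = 0.10, reward_testing = 0.15,
                       penalty = 0.02, step_cap = 1000L,
                       sampler_profile = c("test", "paper")) {
  structure(list(
    training_miniblocks = as.integer(training_miniblocks),
    testing_budget = as.integer(testing_budget),
    rest_every_training = as.integer(rest_every_training),
    rest_budget_testing = as.integer(rest_budget_testing),
    reward_training = reward_training, reward_testing = reward_testing,
    penalty = penalty, step_cap = as.integer(step_cap),
    sampler_profile = match.arg(sampler_profile)
  ), class = "msr_config")
}

#' Balanced training schedule
#'
#' Builds 75 chained miniblock specifications: every room serves as goal
#' exactly 5 times, the goal is never in the wing of the start room (which
#' is the previous goal), and start-goal shortest-path distance classes are
#' balanced as evenly as the chaining and goal-count constraints allow. The
#' achieved distance-class counts are attached as the `"distance_balance"`
#' attribute so the scheduling compromise is auditable.
#'
#' @param graph an `msr_graph`
#' @param start_room room where the session starts
#' @param seed integer seed (schedule is exactly reproducible from it)
#' @param n_miniblocks schedule length; the room-count balance requires a
#'   multiple of 15
#' @return tibble with `miniblock`, `start_room`, `goal_room`, `distance`
#' @export
make_training_schedule <- function(graph, start_room, seed = 1L,
                                   n_miniblocks = 75L) {
  if (n_miniblocks %% graph$n_rooms != 0L)
    stop("n_miniblocks must be a multiple of ", graph$n_rooms,
         " for exact goal balance")
  D <- room_distances(graph)
  per_room <- n_miniblocks %/% graph$n_rooms
  classes <- sort(unique(D[cbind(rep(1:15, each = 15), rep(1:15, 15))]))
  classes <- setdiff(classes, 0)
  withr_seed(seed, {
    for (attempt in 1:200) {
      remaining <- rep(per_room, graph$n_rooms)
      cur <- start_room
      goals <- integer(n_miniblocks)
      class_count <- stats::setNames(rep(0, length(classes)), classes)
      ok <- TRUE
      for (i in seq_len(n_miniblocks)) {
        cand <- which(remaining > 0L & graph$wing != wing_of(graph, cur))
        if (!length(cand)) { ok <- FALSE; break }
        # prefer candidates whose distance class is currently rarest
        dc <- as.character(D[cur, cand])
        score <- class_count[dc] + stats::runif(length(cand)) * 1e-6
        g <- cand[which.min(score)]
        goals[i] <- g
        class_count[as.character(D[cur, g])] <- class_count[as.character(D[cur, g])] + 1
        remaining[g] <- remaining[g] - 1L
        cur <- g
      }
      if (ok) break
    }
    if (!ok) stop("could not build a chained schedule satisfying goal balance; ",
                  "remaining quota: ", paste(remaining, collapse = ","))
    sched <- tibble::tibble(
      miniblock = seq_len(n_miniblocks),
      start_room = c(start_room, goals[-n_miniblocks]),
      goal_room = goals
    )
    sched$distance <- D[cbind(sched$start_room, sched$goal_room)]
    attr(sched, "distance_balance") <- table(sched$distance)
    sched
  })
}

# evaluate expr with a local RNG stream, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Shortest-path distances between all room pairs
#' @param graph an `msr_graph`
#' @return 15 x 15 integer matrix
#' @export
room_distances <- function(graph) {
  n <- graph$n_rooms
  A <- matrix(FALSE, n, n)
  A[graph$edges] <- TRUE
  A[graph$edges[, 2:1]] <- TRUE
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in 1:n) {
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- setdiff(which(apply(A[frontier, , drop = FALSE], 2, any)),
                     which(is.finite(D[s, ])))
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  storage.mode(D) <- "integer"
  D
}

#' Sample a testing-phase goal
#'
#' Uniform over the 10 rooms outside the wing of the current room.
#' @param graph an `msr_graph`
#' @param current_room current room id
#' @return a room id
#' @export
sample_testing_goal <- function(graph, current_room) {
  cand <- which(graph$wing != wing_of(graph, current_room))
  cand[sample.int(length(cand), 1L)]
}

#' Step the stochastic environment
#'
#' @param mapping an `msr_mapping`
#' @param room current room
#' @param action `"A1"` or `"A2"` (or 1/2)
#' @return outcome room (each of the action's two outcomes with
#'   probability 1/2)
#' @export
step_environment <- function(mapping, room, action) {
  a <- if (is.character(action)) match(action, c("A1", "A2")) else as.integer(action)
  stopifnot(a %in% 1:2)
  unname(mapping$outcomes[room, a, sample.int(2L, 1L)])
}

#' Run one agent through a full session
#'
#' Executes the 75-miniblock training phase followed by testing miniblocks
#' until the step budget drops below zero at a miniblock boundary. Each row
#' of the returned log is one key press: the initiating `space` press of a
#' miniblock (step 1), `z`/`m` moves, occasional erroneous `space` presses
#' (`wrong_goal`), and the final press in the goal room (`goal_reached`
#' for a correct `space`, `goal_miss` otherwise). If the agent carries
#' generative response-time parameters, RTs are attached afterwards from
#' the agent's own regressor model.
#'
#' @param agent an [msr_agent()]
#' @param graph an `msr_graph`
#' @param mapping an `msr_mapping`
#' @param seed session seed
#' @param config an [msr_config()]
#' @param participant participant identifier stored in the log
#' @return a `SessionLog` tibble with attributes `budget_trace`,
#'   `rest_after`, `truth` (agent parameters), `mapping_seed`
#' @export
run_session <- function(agent, graph, mapping, seed = 1L,
                        config = msr_config(), participant = "p1") {
  withr_seed(seed, {
    state <- agent_init(agent, mapping)
    sched <- make_training_schedule(graph, start_room = sample.int(15L, 1L),
                                    seed = seed + 104729L,
                                    n_miniblocks = config$training_miniblocks)
    rows <- list()
    rest_after <- integer(0)
    run_mb <- function(phase, mb, start, goal, budget) {
      out <- list()
      room <- start
      step <- 1L
      out[[step]] <- list(phase = phase, miniblock = mb, step = step,
                          room = room, key = "space", action = NA_character_,
                          outcome = room, goal = goal, event = "move")
      n_moves <- 0L
      while (room != goal) {
        if (n_moves >= config$step_cap)
          stop("miniblock exceeded the hard step cap (non-terminating agent?)")
        step <- step + 1L
        if (stats::runif(1) < agent$lapse_space) {
          out[[step]] <- list(phase = phase, miniblock = mb, step = step,
                              room = room, key = "space", action = NA_character_,
                              outcome = room, goal = goal, event = "wrong_goal")
          next
        }
        a <- agent_act(agent, state, room, goal, mapping)
        nxt <- step_environment(mapping, room, a)
        agent_learn(agent, state, room, a, nxt)
        out[[step]] <- list(phase = phase, miniblock = mb, step = step,
                            room = room, key = mapping$key_of[[a]], action = a,
                            outcome = nxt, goal = goal, event = "move")
        room <- nxt
        n_moves <- n_moves + 1L
        budget <- budget - 1L
      }
      step <- step + 1L
      if (stats::runif(1) < agent$lapse_goal) {
        k <- sample(c("A1", "A2"), 1L)
        out[[step]] <- list(phase = phase, miniblock = mb, step = step,
                            room = room, key = mapping$key_of[[k]], action = k,
                            outcome = room, goal = goal, event = "goal_miss")
      } else {
        out[[step]] <- list(phase = phase, miniblock = mb, step = step,
                            room = room, key = "space", action = NA_character_,
                            outcome = room, goal = goal, event = "goal_reached")
      }
      list(rows = out, room = room, budget = budget)
    }

    for (i in seq_len(nrow(sched))) {
      res <- run_mb("training", i, sched$start_room[i], sched$goal_room[i], NA_integer_)
      rows <- c(rows, res$rows)
      if (i %% config$rest_every_training == 0L && i < nrow(sched))
        rest_after <- c(rest_after, i)
    }
    room <- sched$goal_room[nrow(sched)]
    budget <- config$testing_budget
    budget_trace <- integer(0)
    mb <- 0L
    rested <- FALSE
    while (budget >= 0L) {
      mb <- mb + 1L
      goal <- sample_testing_goal(graph, room)
      res <- run_mb("testing", mb, room, goal, budget)
      rows <- c(rows, res$rows)
      room <- res$room
      budget <- res$budget
      budget_trace <- c(budget_trace, budget)
      if (!rested && budget < config$rest_budget_testing && budget >= 0L) {
        rest_after <- c(rest_after, config$training_miniblocks + mb)
        rested <- TRUE
      }
    }
    log <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
    log <- tibble::add_column(log, participant = participant, .before = 1)
    log$rt <- NA_real_
    if (!is.null(agent$rt)) log <- attach_generative_rt(log, agent, mapping)
    attr(log, "budget_trace") <- budget_trace
    attr(log, "rest_after") <- rest_after
    attr(log, "truth") <- agent_truth(agent)
    attr(log, "session_seed") <- seed
    log
  })
}

#' Apply the standard participant-level exclusions
#'
#' Drops participants who chose the same action on more than 90% of move
#' trials, or who produced a wrong-goal or goal-miss event on more than
#' half of their miniblocks.
#'
#' @param logs a session-log tibble covering one or more participants
#' @return list with `retained` (filtered log) and `report` (per-participant
#'   exclusion statistics)
#' @export
apply_participant_exclusions <- function(logs) {
  report <- logs |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      same_action_share = {
        k <- .data$key[.data$key %in% c("z", "m")]
        max(table(factor(k, levels = c("z", "m")))) / max(length(k), 1L)
      },
      bad_miniblock_share = {
        mb <- paste(.data$phase, .data$miniblock)
        bad <- unique(mb[.data$event %in% c("goal_miss", "wrong_goal")])
        length(bad) / length(unique(mb))
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(excluded = .data$same_action_share > 0.9 |
                    .data$bad_miniblock_share > 0.5)
  keep <- report$participant[!report$excluded]
  list(retained = dplyr::filter(logs, .data$participant %in% keep),
       report = report)
}

#' Trials entering the model likelihoods
#'
#' Testing-phase `z`/`m` move trials, excluding (i) all trials of
#' miniblocks containing a goal-miss or wrong-goal event and (ii) the first
#' move of every miniblock (the anticipated start state).
#'
#' @param log a single-participant session log
#' @param phase phase whose trials are analyzed
#' @return the filtered tibble of analyzable move trials
#' @export
apply_miniblock_exclusions <- function(log, phase = "testing") {
  log |>
    dplyr::filter(.data$phase %in% !!phase) |>
    dplyr::group_by(.data$miniblock) |>
    dplyr::filter(!any(.data$event %in% c("goal_miss", "wrong_goal"))) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$event == "move", .data$key %in% c("z", "m")) |>
    dplyr::group_by(.data$miniblock) |>
    dplyr::slice(-1) |>
    dplyr::ungroup()
}
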