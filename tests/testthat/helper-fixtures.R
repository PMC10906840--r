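# Shared fixtures, memoized so expensive simulations run once per suite.

fixture_env <- new.env(parent = emptyenv())

fx_graph <- function() {
  if (is.null(fixture_env$graph)) fixture_env$graph <- build_task_graph()
  fixture_env$graph
}

fx_mapping <- function(seed = 1L) {
  key <- paste0("map_", seed)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- build_action_mapping(fx_graph(), seed = seed)
  fixture_env[[key]]
}

# a mid-sized random-policy session (training + 800 testing moves)
fx_random_session <- function() {
  if (is.null(fixture_env$random_session)) {
    fixture_env$random_session <- run_session(
      msr_agent("random"), fx_graph(), fx_mapping(), seed = 101,
      config = msr_config(testing_budget = 800))
  }
  fixture_env$random_session
}

# an SR-family session with generative response times (the published
# population-mean slopes as ground truth)
fx_sr_session <- function() {
  if (is.null(fixture_env$sr_session)) {
    ag <- msr_agent("successor", choice_beta = 8, gamma = 0.9,
                    rt_beta = c(spe = 0.015, ev = 0.033, rpe = -0.023,
                                logrecency = 0.032, response_switch = 0.036))
    fixture_env$sr_session <- run_session(
      ag, fx_graph(), fx_mapping(), seed = 202,
      config = msr_config(testing_budget = 500))
  }
  fixture_env$sr_session
}

# independent brute-force value iteration over explicit transition lists,
# used as an oracle for the package implementation
oracle_vi <- function(trans, rewards, goal, gamma, n_states, tol = 1e-12) {
  V <- rep(0, n_states); V[goal] <- 1
  repeat {
    Q <- matrix(-Inf, n_states, 2)
    for (s in seq_len(n_states)) for (a in 1:2) {
      out <- trans[[s]][[a]]
      Q[s, a] <- rewards[s] + gamma * mean(V[out])
    }
    Q[goal, ] <- 1
    Vn <- pmax(Q[, 1], Q[, 2]); Vn[goal] <- 1
    if (max(abs(Vn - V)) < tol) return(list(V = Vn, Q = Q))
    V <- Vn
  }
}

# transition lists of the museum mapping in oracle_vi's format
mapping_to_trans <- function(mapping) {
  lapply(1:15, function(s) lapply(1:2, function(a) mapping$outcomes[s, a, ]))
}
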