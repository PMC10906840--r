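# Synthetic participants. Choices follow a response-coded logistic policy on
# the family's decision variable (key <m> coded 1); response times are drawn
# from a shifted lognormal whose mean is a linear function of the family's
# own (orthogonalized, standardized) regressors -- exactly the structure the
# fitting side assumes, so recovery is well-posed.

#' Create a synthetic agent
#'
#' @param family `"random"`, `"rotation"`, `"model_based"` or `"successor"`
#' @param choice_alpha,choice_beta intercept and slope of the response-coded
#'   choice policy (inverse-logit of `alpha + beta * x`, with `x` the
#'   family's decision variable for key `m`: the effect-coded rotation
#'   indicator, or the expected-value difference of the two keys)
#' @param rt_alpha,rt_beta,rt_sigma,rt_ndt generative shifted-lognormal RT
#'   parameters (log-ms intercept near 6, named slope vector over the
#'   family's regressor columns, lognormal sd, non-decision time in ms).
#'   Leave `rt_beta = NULL` for an agent without generative RTs.
#' @param gamma,lambda successor/model-based discount factor and SR learning
#'   rate
#' @param lapse_goal probability of pressing a movement key in the goal room
#'   (a "goal miss")
#' @param lapse_space per-step probability of an erroneous `space` press (a
#'   "wrong goal")
#' @return an object of class `msr_agent`
#' @export
msr_agent <- function(family = c("random", "rotation", "model_based", "successor"),
                      choice_alpha = 0, choice_beta = 0,
                      rt_alpha = 6, rt_beta = NULL, rt_sigma = 0.25,
                      rt_ndt = 200, gamma = 0.9, lambda = 0.1,
                      lapse_goal = 0.02, lapse_space = 0.004) {
  family <- match.arg(family)
  stopifnot(rt_sigma > 0, rt_ndt >= 0, gamma >= 0, gamma <= 1,
            lambda >= 0, lambda <= 1)
  rt <- if (is.null(rt_beta)) NULL else
    list(alpha = rt_alpha, beta = rt_beta, sigma = rt_sigma, ndt = rt_ndt)
  structure(list(
    family = family,
    choice = list(alpha = choice_alpha, beta = choice_beta),
    rt = rt, gamma = gamma, lambda = lambda,
    lapse_goal = lapse_goal, lapse_space = lapse_space
  ), class = "msr_agent")
}

agent_truth <- function(agent) {
  tibble::tibble(
    family = agent$family,
    choice_alpha = agent$choice$alpha, choice_beta = agent$choice$beta,
    gamma = agent$gamma, lambda = agent$lambda,
    rt_alpha = if (is.null(agent$rt)) NA_real_ else agent$rt$alpha,
    rt_sigma = if (is.null(agent$rt)) NA_real_ else agent$rt$sigma,
    rt_ndt = if (is.null(agent$rt)) NA_real_ else agent$rt$ndt,
    rt_beta = list(if (is.null(agent$rt)) NULL else agent$rt$beta)
  )
}

# mutable per-session agent state
agent_init <- function(agent, mapping) {
  e <- new.env(parent = emptyenv())
  e$prev_sa <- NA_integer_
  if (agent$family == "successor") e$M <- diag(30)
  if (agent$family == "model_based")
    e$Q <- precompute_mb_values(mapping, agent$gamma)
  e
}

sa_index <- function(room, action) (room - 1L) * 2L + action

#' Choice probability of a synthetic agent
#'
#' Probability that the agent presses key `m` in `room` given `goal`.
#' Random agents always return 0.5; rotation agents apply the logistic
#' policy to the effect-coded rotation indicator; model-based and successor
#' agents apply it to the expected-value difference of the two keys.
#' Inside the goal wing (where the choice models are silent) model-based
#' and successor agents act greedily on their values and the other families
#' choose at random.
#'
#' @param agent an `msr_agent`
#' @param state agent state from a running session (or `NULL` for a fresh
#'   one)
#' @param room,goal current and goal room
#' @param mapping an `msr_mapping`
#' @return probability of pressing key `m`
#' @export
act_prob <- function(agent, state, room, goal, mapping) {
  if (is.null(state)) state <- agent_init(agent, mapping)
  g <- mapping$graph
  in_goal_wing <- wing_of(g, room) == wing_of(g, goal)
  a_m <- if (mapping$key_of[["A1"]] == "m") 1L else 2L
  a_z <- 3L - a_m
  if (agent$family == "random") return(0.5)
  if (agent$family == "rotation") {
    if (in_goal_wing) return(0.5)
    rot <- correct_rotation(mapping, wing_of(g, room), wing_of(g, goal))
    x <- if (mapping$key_of[[rot]] == "m") 0.5 else -0.5
    return(stats::plogis(agent$choice$alpha + agent$choice$beta * x))
  }
  v <- agent_key_values(agent, state, room, goal, a_m, a_z)
  if (in_goal_wing) {
    d <- v[["m"]] - v[["z"]]
    if (abs(d) < 1e-12) return(0.5)
    return(as.numeric(d > 0))
  }
  stats::plogis(agent$choice$alpha + agent$choice$beta * (v[["m"]] - v[["z"]]))
}

agent_key_values <- function(agent, state, room, goal, a_m, a_z) {
  if (agent$family == "model_based") {
    Q <- state$Q[[goal]]
    return(c(m = Q[room, a_m], z = Q[room, a_z]))
  }
  r <- rep(-0.08, 30)
  r[sa_index(goal, 1L):sa_index(goal, 2L)] <- 1
  c(m = sum(state$M[sa_index(room, a_m), ] * r),
    z = sum(state$M[sa_index(room, a_z), ] * r))
}

agent_act <- function(agent, state, room, goal, mapping) {
  p_m <- act_prob(agent, state, room, goal, mapping)
  key <- if (stats::runif(1) < p_m) "m" else "z"
  names(mapping$key_of)[match(key, mapping$key_of)]
}

# SARSA update of the successor matrix once the next conjunction is chosen
agent_learn <- function(agent, state, room, action, outcome) {
  a <- match(action, c("A1", "A2"))
  sa <- sa_index(room, a)
  if (agent$family == "successor" && !is.na(state$prev_sa)) {
    i <- state$prev_sa
    delta <- agent$gamma * state$M[sa, ] - state$M[i, ]
    delta[i] <- delta[i] + 1
    state$M[i, ] <- state$M[i, ] + agent$lambda * delta
  }
  state$prev_sa <- sa
  invisible(NULL)
}

#' Draw a shifted-lognormal response time
#'
#' @param agent an `msr_agent` with generative RT parameters
#' @param regressor_row numeric vector of (standardized) regressor values,
#'   named like `agent$rt$beta`
#' @return response time in ms (`ndt + LogNormal(alpha + beta.x, sigma)`)
#' @export
generate_rt <- function(agent, regressor_row) {
  stopifnot(!is.null(agent$rt))
  b <- agent$rt$beta
  x <- if (length(b)) sum(b * regressor_row[names(b)]) else 0
  agent$rt$ndt + stats::rlnorm(1, meanlog = agent$rt$alpha + x,
                               sdlog = agent$rt$sigma)
}

# attach RTs to a completed walk from the agent's own regressor model
attach_generative_rt <- function(log, agent, mapping) {
  model <- switch(agent$family, successor = "sr", model_based = "mb",
                  rotation = "explicit", random = "null")
  reg <- build_regressors(log, mapping, model = model, gamma = agent$gamma,
                          lambda = agent$lambda)
  X <- attr(reg, "X")
  b <- agent$rt$beta
  miss <- setdiff(names(b), colnames(X))
  if (length(miss)) stop("rt_beta names not among regressors: ",
                         paste(miss, collapse = ", "))
  mu_fit <- agent$rt$alpha + as.vector(X[, names(b), drop = FALSE] %*% b)
  n <- nrow(log)
  mu <- rep(agent$rt$alpha, n)
  mu[reg$log_row] <- mu_fit
  log$rt <- agent$rt$ndt + stats::rlnorm(n, meanlog = mu, sdlog = agent$rt$sigma)
  log
}

#' Simulate a cohort of synthetic participants
#'
#' Runs `n` full sessions of one generating family, drawing per-participant
#' parameters from `parameter_distribution` (a function `(i) -> msr_agent`)
#' or using a shared default agent, and collects the ground truth.
#'
#' @param n number of participants
#' @param generating_family family passed to the default agent builder
#' @param parameter_distribution optional function `function(i)` returning
#'   the `msr_agent` for participant `i` (called with the cohort RNG
#'   active, so draws are reproducible from `seed`)
#' @param seed cohort master seed; participant sessions use derived child
#'   seeds
#' @param config an [msr_config()]
#' @return an `msr_cohort`: list with `logs` (named list of session logs),
#'   `truth` (ground-truth tibble), `graph`, `mappings`
#' @export
simulate_cohort <- function(n, generating_family = "successor",
                            parameter_distribution = NULL, seed = 1L,
                            config = msr_config()) {
  stopifnot(n >= 1)
  graph <- build_task_graph()
  logs <- list()
  mappings <- list()
  truths <- list()
  for (i in seq_len(n)) {
    id <- sprintf("p%02d", i)
    agent <- withr_seed(seed + 7919L * i, {
      if (is.null(parameter_distribution)) msr_agent(generating_family)
      else parameter_distribution(i)
    })
    mapping <- build_action_mapping(graph, seed = seed + 31L * i)
    logs[[id]] <- run_session(agent, graph, mapping, seed = seed + 1009L * i,
                              config = config, participant = id)
    mappings[[id]] <- mapping
    truths[[id]] <- tibble::add_column(agent_truth(agent), participant = id,
                                       .before = 1)
  }
  structure(list(logs = logs, truth = dplyr::bind_rows(truths),
                 graph = graph, mappings = mappings, seed = seed),
            class = "msr_cohort")
}

#' @export
print.msr_cohort <- function(x, ...) {
  cat("<msr_cohort> ", length(x$logs), " participants, families: ",
      paste(unique(x$truth$family), collapse = ", "), "\n", sep = "")
  invisible(x)
}
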