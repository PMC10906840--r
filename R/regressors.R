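# Model-derived trial regressors. All learning replays run over the full
# session's move sequence (training included) in exact presentation order;
# exclusions restrict only which trials enter a likelihood, never what the
# learner experiences.

#' Angular distance between two vectors
#'
#' `acos(cosine similarity) / pi`, a formal distance in `[0, 1]` insensitive
#' to vector magnitude; the cosine is clipped into `[-1, 1]` before `acos`.
#'
#' @param v1,v2 nonzero numeric vectors of equal length
#' @return scalar in `[0, 1]`
#' @export
angular_distance <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("angular distance undefined for a zero vector")
  acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))) / pi
}

#' One SARSA update of the successor matrix
#'
#' `M[sa_t, ] <- M[sa_t, ] + lambda * (onehot(sa_t) + gamma * M[sa_next, ] -
#' M[sa_t, ])`; all other rows are untouched.
#'
#' @param M successor matrix (rows index state-action conjunctions)
#' @param sa_t,sa_next 1-based conjunction indices of the transition
#' @param lambda learning rate
#' @param gamma discount factor
#' @return the updated matrix
#' @export
sr_update <- function(M, sa_t, sa_next, lambda, gamma) {
  stopifnot(sa_t >= 1, sa_t <= nrow(M), sa_next >= 1, sa_next <= nrow(M))
  cpp_sr_update(M, as.integer(sa_t), as.integer(sa_next), lambda, gamma)
}

#' Goal-conditional state-action values by value iteration
#'
#' Dynamic programming on the true one-step model: the goal room is
#' absorbing with terminal value 1, every other room carries the step cost,
#' and `Q(s, a) = r(s) + gamma * mean(V(outcomes))` with
#' `V(s) = max_a Q(s, a)`.
#'
#' @param graph an `msr_graph` (used only for validation)
#' @param mapping an `msr_mapping`
#' @param goal goal room
#' @param gamma discount factor in `[0, 1]`
#' @param cost per-room step cost (any negative value yields collinear
#'   regressors; the conventional value is -0.08)
#' @param tol sup-norm convergence tolerance
#' @param max_iter iteration cap (an error if exceeded)
#' @return 15 x 2 matrix of action values (rows rooms, goal rows fixed at 1)
#' @export
value_iteration <- function(graph, mapping, goal, gamma, cost = -0.08,
                            tol = 1e-10, max_iter = 1e4) {
  stopifnot(gamma >= 0, gamma <= 1, goal %in% 1:15)
  out <- mapping$outcomes
  V <- rep(0, 15); V[goal] <- 1
  r <- rep(cost, 15); r[goal] <- 1
  Q <- matrix(0, 15, 2)
  for (it in seq_len(max_iter)) {
    EVnext <- matrix(0, 15, 2)
    for (a in 1:2)
      EVnext[, a] <- 0.5 * (V[out[, a, 1]] + V[out[, a, 2]])
    Q <- r + gamma * EVnext
    Q[goal, ] <- 1
    Vnew <- pmax(Q[, 1], Q[, 2])
    Vnew[goal] <- 1
    if (max(abs(Vnew - V)) < tol) {
      colnames(Q) <- c("A1", "A2")
      return(Q)
    }
    V <- Vnew
  }
  stop("value iteration did not converge within ", max_iter, " sweeps")
}

# value iteration for all 15 goals simultaneously (V is states x goals)
precompute_mb_values <- function(mapping, gamma, cost = -0.08, tol = 1e-10,
                                 max_iter = 1e4) {
  out <- mapping$outcomes
  goal_idx <- cbind(1:15, 1:15)
  V <- matrix(0, 15, 15); V[goal_idx] <- 1
  r <- matrix(cost, 15, 15); r[goal_idx] <- 1
  Q1 <- Q2 <- matrix(0, 15, 15)
  for (it in seq_len(max_iter)) {
    Q1 <- r + gamma * 0.5 * (V[out[, 1, 1], ] + V[out[, 1, 2], ])
    Q2 <- r + gamma * 0.5 * (V[out[, 2, 1], ] + V[out[, 2, 2], ])
    Q1[goal_idx] <- 1; Q2[goal_idx] <- 1
    Vnew <- pmax(Q1, Q2)
    Vnew[goal_idx] <- 1
    if (max(abs(Vnew - V)) < tol) break
    V <- Vnew
    if (it == max_iter) stop("value iteration did not converge")
  }
  lapply(1:15, function(g) {
    Q <- cbind(A1 = Q1[, g], A2 = Q2[, g])
    Q[g, ] <- 1
    Q
  })
}

# ---- session move sequence ------------------------------------------------

# One row per z/m key press, in session order, with analysis flags.
session_moves <- function(log, mapping) {
  g <- mapping$graph
  moves <- log |>
    dplyr::mutate(log_row = dplyr::row_number()) |>
    dplyr::filter(.data$key %in% c("z", "m"))
  moves$action_id <- match(moves$action, c("A1", "A2"))
  moves$sa <- sa_index(moves$room, moves$action_id)
  moves$move_idx <- seq_len(nrow(moves))
  mb_id <- paste(moves$phase, moves$miniblock)
  bad_rows <- log$event %in% c("goal_miss", "wrong_goal")
  bad_mb <- unique(paste(log$phase, log$miniblock)[bad_rows])
  first_move <- !duplicated(mb_id)
  moves$analyzable <- moves$phase == "testing" & moves$event == "move" &
    !(mb_id %in% bad_mb) & !first_move & !is.na(moves$rt)
  # RTs may be absent for agents without a generative RT model
  if (all(is.na(moves$rt)))
    moves$analyzable <- moves$phase == "testing" & moves$event == "move" &
      !(mb_id %in% bad_mb) & !first_move
  moves$choice_analyzable <- moves$analyzable &
    wing_of(g, moves$room) != wing_of(g, moves$goal)
  moves
}

# raw nuisance columns over the full move sequence
nuisance_columns <- function(moves, mapping) {
  n <- nrow(moves)
  mb_id <- paste(moves$phase, moves$miniblock)
  step_in_mb <- stats::ave(rep(1, n), mb_id, FUN = cumsum)
  logsteps <- log(step_in_mb)
  logrecency <- numeric(n)
  last_seen <- rep(0L, 15)
  for (t in seq_len(n)) {
    r <- moves$room[t]
    logrecency[t] <- log(t - last_seen[r])
    last_seen[r] <- t
  }
  response_switch <- c(NA, as.numeric(moves$key[-1] != moves$key[-n]))
  prev_room <- c(NA_integer_, moves$room[-n])
  preferred <- wide_trans <- numeric(n)
  wide_node <- as.numeric(moves$room %in% mapping$graph$wide)
  for (t in 2:n) {
    lab <- mechanical_label(mapping, prev_room[t], moves$room[t])
    preferred[t] <- as.numeric(lab == "preferred")
    wide_trans[t] <- as.numeric(prev_room[t] %in% mapping$graph$wide)
  }
  cbind(logsteps = logsteps, logrecency = logrecency,
        response_switch = response_switch, preferred = preferred,
        wide_node = wide_node, wide_trans = wide_trans)
}

explicit_columns <- function(moves, mapping) {
  g <- mapping$graph
  n <- nrow(moves)
  prev_room <- c(NA_integer_, moves$room[-n])
  cbind(
    in_goal_wing = as.numeric(wing_of(g, moves$room) == wing_of(g, moves$goal)),
    between_wing = c(NA, as.numeric(wing_of(g, prev_room[-1]) !=
                                      wing_of(g, moves$room[-1]))),
    boundary_room = as.numeric(moves$room %in% g$boundary)
  )
}

# successor-representation readouts for a vector of discount factors
sr_outputs <- function(moves, gammas, lambda = 0.1,
                       variant = c("state_action", "state_state")) {
  variant <- match.arg(variant)
  if (variant == "state_action") {
    state <- moves$sa
    a1 <- sa_index(moves$room, 1L); a2 <- sa_index(moves$room, 2L)
    lo <- sa_index(moves$goal, 1L); hi <- sa_index(moves$goal, 2L)
    S <- 30L
  } else {
    state <- moves$room
    a1 <- a2 <- moves$room
    lo <- hi <- moves$goal
    S <- 15L
  }
  cpp_sr_replay(as.integer(state), as.integer(a1), as.integer(a2),
                as.integer(lo), as.integer(hi), as.numeric(gammas),
                lambda, -0.08, S, want_M = FALSE)
}

.msr_cache <- new.env(parent = emptyenv())

# goal-conditional Q values depend only on gamma (the contingency pattern is
# shared across key assignments), so they are memoized per session
mb_values_cached <- function(mapping, gamma, cost = -0.08) {
  key <- sprintf("mbq_%.10f_%.5f", gamma, cost)
  if (is.null(.msr_cache[[key]]))
    .msr_cache[[key]] <- precompute_mb_values(mapping, gamma, cost)
  .msr_cache[[key]]
}

mb_outputs <- function(moves, mapping, gammas) {
  n <- nrow(moves); G <- length(gammas)
  EV <- EV1 <- EV2 <- matrix(NA_real_, n, G)
  i_ev <- cbind(moves$room, moves$action_id, moves$goal)
  i_a1 <- cbind(moves$room, 1L, moves$goal)
  i_a2 <- cbind(moves$room, 2L, moves$goal)
  for (g in seq_len(G)) {
    Qs <- mb_values_cached(mapping, gammas[g])
    Qarr <- array(unlist(Qs), dim = c(15L, 2L, 15L))
    EV[, g] <- Qarr[i_ev]
    EV1[, g] <- Qarr[i_a1]
    EV2[, g] <- Qarr[i_a2]
  }
  list(SPE = NULL, EV = EV, EV1 = EV1, EV2 = EV2)
}

#' Successive Gram-Schmidt orthogonalization of the value regressors
#'
#' Leaves `EV` intact, removes the `EV` projection from `RPE`, then removes
#' the `EV` and orthogonalized-`RPE` projections from `EV_diff`. A column
#' whose residual has (numerically) zero variance is flagged in the
#' `"degenerate"` attribute rather than silently standardized.
#'
#' @param EV,RPE,EV_diff numeric vectors over the fitted trials
#' @return 3-column matrix of orthogonalized columns with attribute
#'   `"degenerate"`
#' @export
gram_schmidt_orthogonalize <- function(EV, RPE, EV_diff) {
  stopifnot(length(EV) == length(RPE), length(EV) == length(EV_diff))
  if (sum(EV^2) == 0) stop("EV column is identically zero")
  proj <- function(v, onto) {
    d <- sum(onto^2)
    if (d < 1e-24) return(v)
    v - sum(onto * v) / d * onto
  }
  rpe_o <- proj(RPE, EV)
  diff_o <- proj(proj(EV_diff, EV), rpe_o)
  out <- cbind(ev = EV, rpe = rpe_o, conflict = diff_o)
  degen <- apply(out, 2, function(x) stats::sd(x) < 1e-12)
  attr(out, "degenerate") <- names(which(degen))
  out
}

standardize_columns <- function(X) {
  flagged <- character(0)
  for (j in seq_len(ncol(X))) {
    s <- stats::sd(X[, j])
    if (is.na(s) || s < 1e-12) {
      X[, j] <- 0
      flagged <- c(flagged, colnames(X)[j])
    } else {
      X[, j] <- (X[, j] - mean(X[, j])) / s
    }
  }
  attr(X, "flagged_constant") <- flagged
  X
}

model_columns <- function(model) {
  nuis <- c("logsteps", "logrecency", "response_switch", "preferred",
            "wide_node", "wide_trans")
  switch(model,
    null = nuis,
    mb = c(nuis, "ev", "rpe", "conflict"),
    sr = c(nuis, "spe", "ev", "rpe", "conflict"),
    explicit = c(nuis, "in_goal_wing", "between_wing", "boundary_room"),
    stop("unknown model: ", model))
}

# assemble the raw (pre-orthogonalization) columns for one gamma slice
assemble_raw <- function(moves, mapping, model, outs, slice, extra_abs_rpe,
                         base = NULL) {
  n <- nrow(moves)
  if (is.null(base)) base <- nuisance_columns(moves, mapping)
  if (model == "explicit") return(cbind(base, explicit_columns(moves, mapping)))
  if (model == "null") return(base)
  EV <- outs$EV[, slice]
  RPE <- c(NA, diff(EV))
  conflict <- abs(outs$EV1[, slice] - outs$EV2[, slice])
  out <- cbind(base, ev = EV, rpe = RPE, conflict = conflict)
  if (model == "sr") out <- cbind(out, spe = outs$SPE[, slice])
  if (extra_abs_rpe) out <- cbind(out, abs_rpe = abs(RPE))
  out
}

finalize_columns <- function(raw, model, fit_rows, extra_abs_rpe = FALSE) {
  cols <- model_columns(model)
  if (extra_abs_rpe && model %in% c("mb", "sr")) cols <- c(cols, "abs_rpe")
  X <- raw[fit_rows, cols, drop = FALSE]
  if (model %in% c("mb", "sr")) {
    gs <- gram_schmidt_orthogonalize(X[, "ev"], X[, "rpe"], X[, "conflict"])
    X[, c("ev", "rpe", "conflict")] <- gs
  }
  standardize_columns(X)
}

#' Build the per-trial regressor matrix for one response-time model
#'
#' Replays the session (training plus testing) in presentation order,
#' computes the model's regressors, restricts them to the analyzable
#' testing trials, successively orthogonalizes EV / RPE / conflict
#' (Gram-Schmidt, EV first) and standardizes every column within
#' participant over exactly the fitted trials.
#'
#' @param log a single-participant session log
#' @param mapping the participant's `msr_mapping`
#' @param model `"null"`, `"mb"`, `"sr"` or `"explicit"`
#' @param gamma discount factor (mb/sr only)
#' @param lambda SR learning rate (fixed at 0.1 in the published fits)
#' @param variant `"state_action"` (30 conjunctions) or `"state_state"`
#'   (15 rooms; SR only)
#' @param abs_rpe also include the absolute (unsigned) RPE column used by
#'   the exploratory control model
#' @return tibble of analyzable trials (`log_row`, `miniblock`, `room`,
#'   `rt`, ...) with the standardized design matrix in attribute `"X"` and
#'   bookkeeping in attributes `"model"`, `"gamma"`, `"orthogonalized"`,
#'   `"standardized"`
#' @export
build_regressors <- function(log, mapping, model = c("sr", "mb", "explicit", "null"),
                             gamma = NULL, lambda = 0.1,
                             variant = c("state_action", "state_state"),
                             abs_rpe = FALSE) {
  model <- match.arg(model)
  variant <- match.arg(variant)
  if (model %in% c("mb", "sr")) {
    if (is.null(gamma)) stop("gamma is required for the ", model, " model")
    if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  }
  moves <- session_moves(log, mapping)
  outs <- switch(model,
    sr = sr_outputs(moves, gamma, lambda, variant),
    mb = mb_outputs(moves, mapping, gamma),
    NULL)
  raw <- assemble_raw(moves, mapping, model, outs, 1L, abs_rpe)
  fit_rows <- which(moves$analyzable)
  X <- finalize_columns(raw, model, fit_rows, abs_rpe)
  out <- moves[fit_rows, c("log_row", "phase", "miniblock", "step", "room",
                           "key", "action", "outcome", "goal", "rt")]
  for (j in colnames(X)) out[[j]] <- X[, j]
  attr(out, "X") <- X
  attr(out, "model") <- model
  attr(out, "gamma") <- gamma
  attr(out, "lambda") <- lambda
  attr(out, "variant") <- variant
  attr(out, "orthogonalized") <- model %in% c("mb", "sr")
  attr(out, "standardized") <- TRUE
  out
}

# gamma-grid cache of design matrices for the sampler (mb/sr models)
regressor_grid <- function(log, mapping, model, gammas = seq(0, 1, length.out = 101),
                           lambda = 0.1, variant = "state_action",
                           abs_rpe = FALSE) {
  moves <- session_moves(log, mapping)
  fit_rows <- which(moves$analyzable)
  choice_rows <- which(moves$choice_analyzable)
  if (model %in% c("null", "explicit")) {
    raw <- assemble_raw(moves, mapping, model, NULL, 1L, FALSE)
    X <- finalize_columns(raw, model, fit_rows)
    return(list(model = model, gammas = NULL,
                X = array(X, dim = c(dim(X), 1L),
                          dimnames = list(NULL, colnames(X), NULL)),
                y = moves$rt[fit_rows], moves = moves, fit_rows = fit_rows,
                choice_rows = choice_rows))
  }
  # evaluate the gamma = 0 boundary slice just inside the interior: at the
  # exact limit the value readouts are constant, get zeroed, and would
  # hand that grid cell a spurious marginal-likelihood bonus (the Occam
  # penalty of the dropped columns), i.e. an artifactual posterior mode
  gs_eval <- pmax(gammas, 1e-4)
  outs <- switch(model, sr = sr_outputs(moves, gs_eval, lambda, variant),
                 mb = mb_outputs(moves, mapping, gs_eval))
  base <- nuisance_columns(moves, mapping)
  p <- length(model_columns(model)) + as.integer(abs_rpe)
  Xg <- array(NA_real_, dim = c(length(fit_rows), p, length(gammas)))
  dvg <- matrix(NA_real_, length(choice_rows), length(gammas))
  a_m <- if (mapping$key_of[["A1"]] == "m") 1L else 2L
  for (g in seq_along(gammas)) {
    raw <- assemble_raw(moves, mapping, model, outs, g, abs_rpe, base = base)
    X <- finalize_columns(raw, model, fit_rows, abs_rpe)
    if (g == 1L) dimnames(Xg)[[2]] <- colnames(X)
    Xg[, , g] <- X
    # choice decision variable: EV(key m) - EV(key z), standardized
    dv <- (if (a_m == 1L) outs$EV1 - outs$EV2 else outs$EV2 - outs$EV1)[choice_rows, g]
    s <- stats::sd(dv)
    dvg[, g] <- if (is.na(s) || s < 1e-12) 0 else (dv - mean(dv)) / s
  }
  list(model = model, gammas = gammas, X = Xg, y = moves$rt[fit_rows],
       dv = dvg, moves = moves, fit_rows = fit_rows, choice_rows = choice_rows)
}
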