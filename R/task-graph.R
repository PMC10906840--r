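# Museum topology: a ring of three 5-cliques ("wings"), each wing a K5 minus
# the edge between its two boundary rooms, wings joined in a ring by single
# inter-wing edges. Rooms are 1-15; wing w owns rooms (5(w-1)+1):(5w); local
# positions 1..5 with 1 and 5 the boundary rooms (1 exits counterclockwise,
# 5 exits clockwise).

#' Build the 15-room museum graph
#'
#' Constructs the ring-of-cliques museum: 3 wings of 5 rooms, every room of
#' degree 4. Each wing is a 5-clique minus the single edge between its two
#' boundary rooms; the three wings are joined in a ring by one inter-wing
#' edge per wing pair, so the two boundary rooms of a wing are never
#' adjacent to each other.
#'
#' @return An object of class `msr_graph` with fields `n_rooms`, `wing`
#'   (integer vector, wing of each room), `edges` (two-column matrix of
#'   undirected room pairs), `boundary` (3 x 2 matrix; column 1 the
#'   counterclockwise boundary room of each wing, column 2 the clockwise
#'   one) and `wide` (the wing's "wide" room, defined by the action-outcome
#'   mapping but constant under the canonical contingency).
#' @export
build_task_graph <- function() {
  n_rooms <- 15L
  wing <- rep(1:3, each = 5L)
  edges <- NULL
  for (w in 1:3) {
    rooms <- (5L * (w - 1L) + 1L):(5L * w)
    pairs <- t(utils::combn(rooms, 2L))
    # boundary rooms are local positions 1 and 5; drop their edge
    drop <- pairs[, 1] == rooms[1] & pairs[, 2] == rooms[5]
    edges <- rbind(edges, pairs[!drop, , drop = FALSE])
  }
  for (w in 1:3) {
    nxt <- w %% 3L + 1L
    edges <- rbind(edges, cbind(5L * w, 5L * (nxt - 1L) + 1L))
  }
  g <- structure(
    list(
      n_rooms = n_rooms,
      wing = wing,
      edges = edges,
      boundary = cbind(ccw = c(1L, 6L, 11L), cw = c(5L, 10L, 15L)),
      wide = c(3L, 8L, 13L)
    ),
    class = "msr_graph"
  )
  stopifnot(all(room_degree(g) == 4L))
  g
}

#' @export
print.msr_graph <- function(x, ...) {
  cat("<msr_graph> 15 rooms, 3 wings of 5, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

room_degree <- function(graph) {
  tabulate(c(graph$edges[, 1], graph$edges[, 2]), nbins = graph$n_rooms)
}

#' Neighbors of a room
#' @param graph an `msr_graph`
#' @param room room id (1-15)
#' @return integer vector of adjacent rooms
#' @export
room_neighbors <- function(graph, room) {
  e <- graph$edges
  sort(c(e[e[, 1] == room, 2], e[e[, 2] == room, 1]))
}

#' Wing of one or more rooms
#' @param graph an `msr_graph`
#' @param room integer vector of room ids
#' @return integer vector of wings (1-3)
#' @export
wing_of <- function(graph, room) graph$wing[room]

local_pos <- function(room) (room - 1L) %% 5L + 1L

# Canonical wing contingency (within-wing local coordinates; 0 stands for the
# external room reached through the wing's inter-wing edge).  A1 is the
# clockwise-rotating action (its exit at local room 5 crosses to the next
# wing), A2 the counterclockwise one (exit at local room 1).  Found by
# exhaustive search over the constraint set: every outcome a neighbor,
# per-action indegree multiplicity 2 for every room (uniform occupancy under
# constant-key and random policies), 4 preferred transitions and exactly one
# wide room per wing, and a unique antirotation room per goal direction.
.wing_pattern <- list(
  A1 = list(c(2L, 3L), c(1L, 3L), c(4L, 5L), c(2L, 5L), c(4L, 0L)),
  A2 = list(c(2L, 0L), c(1L, 4L), c(1L, 2L), c(3L, 5L), c(3L, 4L))
)

#' Build the balanced probabilistic action-outcome mapping
#'
#' Every room offers two actions; each action leads to one of two outcome
#' rooms with probability 1/2. The contingencies are engineered so that (i)
#' each action consistently rotates through the wings in one direction
#' (pressing the same key repeatedly always first crosses into the same
#' neighboring wing), (ii) per wing there are exactly 4 "preferred"
#' transitions (an outcome shared by both actions of its source room), one
#' "wide" room with 4 distinct outcomes and 3 distinct outcomes everywhere
#' else, and (iii) room occupancy is uniform (1/15) in the long run under a
#' random policy and under either constant-key policy.  Only the assignment
#' of physical keys (`z`/`m`) to the two abstract actions is random, as it
#' was per participant in the experiment.
#'
#' @param graph an `msr_graph`
#' @param seed integer; controls only the key-to-action assignment
#' @return An `msr_mapping` with `outcomes` (15 x 2 x 2 array of outcome
#'   rooms), `key_of` (named character: physical key of A1 and A2),
#'   `rotation_direction` (named: +1 for A1, -1 for A2) and the parent graph.
#' @export
build_action_mapping <- function(graph, seed = 1L) {
  outcomes <- array(NA_integer_, dim = c(15L, 2L, 2L),
                    dimnames = list(NULL, c("A1", "A2"), NULL))
  for (w in 1:3) {
    base <- 5L * (w - 1L)
    ext <- c(A1 = 5L * (w %% 3L) + 1L,               # clockwise exit target
             A2 = 5L * ((w - 2L) %% 3L + 1L))        # counterclockwise exit target
    for (k in 1:5) {
      for (a in 1:2) {
        o <- .wing_pattern[[a]][[k]]
        o <- ifelse(o == 0L, ext[[a]], base + o)
        outcomes[base + k, a, ] <- o
      }
    }
  }
  keys <- if (stat_runif1(seed) < 0.5) c(A1 = "z", A2 = "m") else c(A1 = "m", A2 = "z")
  mapping <- structure(
    list(
      graph = graph,
      outcomes = outcomes,
      key_of = keys,
      rotation_direction = c(A1 = 1L, A2 = -1L)
    ),
    class = "msr_mapping"
  )
  validate_mapping(mapping)
  mapping
}

# one uniform draw from an isolated RNG stream; leaves the global RNG alone
stat_runif1 <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stats::runif(1)
}

#' @export
print.msr_mapping <- function(x, ...) {
  cat("<msr_mapping> balanced 2-key contingency; key of A1 (clockwise): <",
      x$key_of[["A1"]], ">\n", sep = "")
  invisible(x)
}

#' Distinct outcome rooms of a room (either action)
#' @param mapping an `msr_mapping`
#' @param room room id
#' @return sorted integer vector of reachable rooms
#' @export
room_outcomes <- function(mapping, room) {
  sort(unique(c(mapping$outcomes[room, , ])))
}

shared_outcome <- function(mapping, room) {
  s <- intersect(mapping$outcomes[room, 1, ], mapping$outcomes[room, 2, ])
  if (length(s)) s else NA_integer_
}

# Construction-time invariant checks; fails loudly on violation.
validate_mapping <- function(mapping) {
  g <- mapping$graph
  out <- mapping$outcomes
  for (r in 1:15) {
    nb <- room_neighbors(g, r)
    if (!all(out[r, , ] %in% nb)) stop("outcome not a graph neighbor for room ", r)
    if (anyDuplicated(out[r, 1, ]) || anyDuplicated(out[r, 2, ]))
      stop("duplicate outcome within an action for room ", r)
  }
  for (w in 1:3) {
    rooms <- (5L * (w - 1L) + 1L):(5L * w)
    shared <- vapply(rooms, function(r) shared_outcome(mapping, r), integer(1))
    if (sum(!is.na(shared)) != 4L) stop("wing ", w, ": preferred count != 4")
    n_out <- vapply(rooms, function(r) length(room_outcomes(mapping, r)), integer(1))
    if (sum(n_out == 4L) != 1L || !all(n_out[n_out != 4L] == 3L))
      stop("wing ", w, ": wide-room structure violated")
    for (r in rooms) {
      crossing <- c(any(wing_of(g, out[r, 1, ]) != w), any(wing_of(g, out[r, 2, ]) != w))
      if (all(crossing)) stop("room ", r, ": both actions can exit the wing")
    }
  }
  # rotation closure: repeating one action, the first inter-wing crossing
  # always enters the wing in that action's rotation direction
  for (a in 1:2) {
    dir <- mapping$rotation_direction[[a]]
    for (w in 1:3) {
      tgt <- (w - 1L + dir) %% 3L + 1L
      oc <- out[(5L * (w - 1L) + 1L):(5L * w), a, ]
      crossed <- wing_of(g, oc)[wing_of(g, oc) != w]
      if (length(crossed) == 0L || any(crossed != tgt))
        stop("rotation closure violated for action ", a, " wing ", w)
    }
  }
  # uniform stationary occupancy under random and both constant-key policies
  for (pol in list(matrix(0.5, 15, 2), cbind(rep(1, 15), 0), cbind(rep(0, 15), 1))) {
    pi_hat <- stationary_distribution(mapping, pol)
    if (max(abs(pi_hat - 1 / 15)) > 1e-10)
      stop("stationary room occupancy not uniform")
  }
  # a unique antirotation room per (wing, goal direction)
  for (w in 1:3) for (gw in setdiff(1:3, w)) antirotation_room(mapping, w, gw)
  invisible(mapping)
}

transition_matrix <- function(mapping, policy) {
  stopifnot(is.matrix(policy), nrow(policy) == 15L, ncol(policy) == 2L,
            all(policy >= 0), all(abs(rowSums(policy) - 1) < 1e-12))
  T_ <- matrix(0, 15, 15)
  for (r in 1:15) for (a in 1:2) for (s in 1:2) {
    T_[r, mapping$outcomes[r, a, s]] <- T_[r, mapping$outcomes[r, a, s]] + policy[r, a] * 0.5
  }
  T_
}

#' Stationary room-occupancy distribution under a policy
#'
#' Left eigenvector (eigenvalue 1) of the room-occupancy Markov chain
#' induced by `policy`, normalized to sum to one. Errors when the induced
#' chain is reducible (occupancy then depends on the start room).
#'
#' @param mapping an `msr_mapping`
#' @param policy 15 x 2 matrix of per-room action probabilities (rows sum
#'   to 1)
#' @return numeric vector of length 15 summing to 1
#' @export
stationary_distribution <- function(mapping, policy) {
  T_ <- transition_matrix(mapping, policy)
  reach <- (T_ > 0) + diag(15)
  for (i in 1:4) reach <- reach %*% reach
  if (any(reach == 0)) stop("induced room chain is reducible")
  A <- rbind(t(diag(15) - T_), rep(1, 15))
  b <- c(rep(0, 15), 1)
  pi_hat <- qr.solve(A, b)
  pi_hat / sum(pi_hat)
}

#' Action that rotates toward a goal wing
#'
#' With three wings arranged in a ring, exactly one action reaches any
#' non-current wing in a single wing-step; this is the hierarchically
#' "correct rotation".
#'
#' @param mapping an `msr_mapping`
#' @param current_wing,goal_wing wings (1-3), must differ
#' @return `"A1"` or `"A2"`
#' @export
correct_rotation <- function(mapping, current_wing, goal_wing) {
  if (current_wing == goal_wing) stop("current wing equals goal wing")
  if ((current_wing %% 3L + 1L) == goal_wing) "A1" else "A2"
}

#' The antirotation room of a wing for a given goal wing
#'
#' The unique room where the action opposite to the correct rotation
#' stochastically dominates: its outcome set holds the preferred transition
#' toward the goal wing plus a room that retains a goal-ward transition,
#' whereas the rotational action risks a room whose goal-ward transition was
#' removed.
#'
#' @inheritParams correct_rotation
#' @param wing wing containing the room
#' @return a room id
#' @export
antirotation_room <- function(mapping, wing, goal_wing) {
  if (wing == goal_wing) stop("wing equals goal wing")
  g <- mapping$graph
  rot <- correct_rotation(mapping, wing, goal_wing)
  a_rot <- if (rot == "A1") 1L else 2L
  a_anti <- 3L - a_rot
  # boundary room whose inter-wing exit leads toward the goal wing
  b <- if (rot == "A1") g$boundary[wing, "cw"] else g$boundary[wing, "ccw"]
  rooms <- setdiff((5L * (wing - 1L) + 1L):(5L * wing), b)
  hits <- integer(0)
  for (r in rooms) {
    sh <- shared_outcome(mapping, r)
    if (is.na(sh) || sh != b) next
    y <- setdiff(mapping$outcomes[r, a_rot, ], sh)
    z <- setdiff(mapping$outcomes[r, a_anti, ], sh)
    if (length(y) != 1L || length(z) != 1L) next
    y_removed <- (b %in% room_neighbors(g, y)) && !(b %in% room_outcomes(mapping, y))
    z_keeps <- (z == b) || (b %in% room_outcomes(mapping, z))
    if (y_removed && z_keeps) hits <- c(hits, r)
  }
  if (length(hits) != 1L)
    stop("expected exactly one antirotation room, found ", length(hits))
  hits
}

#' Label a transition under the mechanical and goal-relative taxonomies
#'
#' @param mapping an `msr_mapping`
#' @param room_from,room_to a realizable transition (an error otherwise)
#' @param goal goal room of the miniblock
#' @return a one-row tibble with columns `mechanical` (preferred, wide_node,
#'   wide_trans, within_plain, between), `goal_relative_transition`
#'   (outside, between, into, outof, inside) and `goal_relative_room`
#'   (outside, away, toward, within, outof; the class of `room_to`).
#' @export
label_transition <- function(mapping, room_from, room_to, goal) {
  if (!(room_to %in% room_outcomes(mapping, room_from)))
    stop("transition ", room_from, " -> ", room_to, " is not realizable")
  g <- mapping$graph
  tibble::tibble(
    mechanical = mechanical_label(mapping, room_from, room_to),
    goal_relative_transition = goal_transition_label(g, room_from, room_to, goal),
    goal_relative_room = goal_room_label(mapping, room_to, goal)
  )
}

mechanical_label <- function(mapping, room_from, room_to) {
  g <- mapping$graph
  if (wing_of(g, room_from) != wing_of(g, room_to)) return("between")
  sh <- shared_outcome(mapping, room_from)
  if (!is.na(sh) && sh == room_to) return("preferred")
  if (room_to %in% g$wide) return("wide_node")
  if (room_from %in% g$wide) return("wide_trans")
  "within_plain"
}

goal_transition_label <- function(g, room_from, room_to, goal) {
  wf <- wing_of(g, room_from); wt <- wing_of(g, room_to); wg <- wing_of(g, goal)
  if (wf == wg && wt == wg) return("inside")
  if (wf == wg) return("outof")
  if (wt == wg) return("into")
  if (wf == wt) return("outside")
  "between"
}

goal_room_label <- function(mapping, room, goal) {
  g <- mapping$graph
  w <- wing_of(g, room); wg <- wing_of(g, goal)
  is_boundary <- room %in% g$boundary
  if (w == wg) return(if (is_boundary) "outof" else "within")
  if (!is_boundary) return("outside")
  # boundary room outside the goal wing: where does its exit lead?
  dir <- if (room == g$boundary[w, "cw"]) 1L else -1L
  exit_wing <- (w - 1L + dir) %% 3L + 1L
  if (exit_wing == wg) "toward" else "away"
}

#' Enumerate all realizable directed room transitions with mechanical labels
#' @param mapping an `msr_mapping`
#' @return tibble with `from`, `to`, `mechanical`
#' @export
enumerate_transitions <- function(mapping) {
  purrr::map_dfr(1:15, function(r) {
    tibble::tibble(from = r, to = room_outcomes(mapping, r))
  }) |>
    dplyr::mutate(mechanical = purrr::map2_chr(.data$from, .data$to,
                                               ~ mechanical_label(mapping, .x, .y)))
}
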