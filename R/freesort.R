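# Free-sort post test: participants reconstruct the museum by placing the
# 15 paintings on a grid; the analysis works on standardized pairwise
# Euclidean distances labeled by their structural relationship.

#' Pairwise free-sort distances
#'
#' Computes all 105 unordered painting-pair Euclidean distances from grid
#' placements, standardizes them within participant, and labels each pair:
#' `community_connected` (same wing, connected), `community_boundary` (the
#' same-wing boundary pair, not connected), `bridge` (connected across
#' wings) or `unrelated`.
#'
#' @param grid_positions tibble with columns `participant`, `painting`
#'   (room id 1-15), `x`, `y`
#' @param graph an `msr_graph`
#' @return a FreesortTable tibble: `participant`, `room_i`, `room_j`,
#'   `distance` (standardized), `pair_type`
#' @export
pairwise_distances <- function(grid_positions, graph = build_task_graph()) {
  A <- matrix(FALSE, 15, 15)
  A[graph$edges] <- TRUE; A[graph$edges[, 2:1]] <- TRUE
  grid_positions |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) != 15L || anyDuplicated(df$painting) ||
          !setequal(df$painting, 1:15))
        stop("participant ", key$participant,
             ": expected exactly one placement for each of the 15 paintings")
      xy <- as.matrix(df[order(df$painting), c("x", "y")])
      pairs <- t(utils::combn(15L, 2L))
      d <- sqrt(rowSums((xy[pairs[, 1], ] - xy[pairs[, 2], ])^2))
      s <- stats::sd(d)
      if (s < 1e-12) stop("degenerate placements: zero distance variance")
      same_wing <- graph$wing[pairs[, 1]] == graph$wing[pairs[, 2]]
      connected <- A[pairs]
      tibble::tibble(
        room_i = pairs[, 1], room_j = pairs[, 2],
        distance = (d - mean(d)) / s,
        pair_type = dplyr::case_when(
          same_wing & connected ~ "community_connected",
          same_wing & !connected ~ "community_boundary",
          !same_wing & connected ~ "bridge",
          TRUE ~ "unrelated"
        )
      )
    }) |>
    dplyr::ungroup()
}

#' Regression design over free-sort distances
#'
#' `"full"`: dummies `community` (same wing, including the boundary pair),
#' `bridge` and `boundary`, with unrelated pairs as the reference.
#' `"indirect"`: only pairs with a shortest path of exactly one
#' intermediate room, with a single `community` dummy (these same-wing
#' pairs are precisely the two boundary paintings of each wing).
#'
#' @param table a FreesortTable from [pairwise_distances()]
#' @param variant `"full"` or `"indirect"`
#' @param graph an `msr_graph`
#' @return design tibble (`participant`, `distance`, regressors) ready for
#'   [fit_hier_linear()]
#' @export
build_freesort_design <- function(table, variant = c("full", "indirect"),
                                  graph = build_task_graph()) {
  variant <- match.arg(variant)
  if (variant == "full") {
    return(tibble::tibble(
      participant = table$participant,
      distance = table$distance,
      community = as.numeric(table$pair_type %in%
                               c("community_connected", "community_boundary")),
      bridge = as.numeric(table$pair_type == "bridge"),
      boundary = as.numeric(table$pair_type == "community_boundary")
    ))
  }
  D <- room_distances(graph)
  keep <- D[cbind(table$room_i, table$room_j)] == 2L
  tibble::tibble(
    participant = table$participant[keep],
    distance = table$distance[keep],
    community = as.numeric(table$pair_type[keep] == "community_boundary")
  )
}

#' Generate synthetic free-sort placements
#'
#' Blends a structured embedding (wings clustered around three centers)
#' with uniform random placement: `position = bias * structured +
#' (1 - bias) * random + noise`, rounded to an integer lattice. At
#' `structure_bias = 0` placements carry no community information; at 1
#' same-wing paintings are strongly compressed.
#'
#' @param n participants
#' @param structure_bias blend weight in `[0, 1]`
#' @param noise Gaussian jitter sd (grid units)
#' @param seed RNG seed
#' @param graph an `msr_graph`
#' @return tibble `participant`, `painting`, `x`, `y`
#' @export
generate_synthetic_sorts <- function(n, structure_bias = 0.8, noise = 1,
                                     seed = 1L, graph = build_task_graph()) {
  centers <- 8 * cbind(cos(2 * pi * (0:2) / 3), sin(2 * pi * (0:2) / 3))
  within <- 2.5 * cbind(cos(2 * pi * (0:4) / 5), sin(2 * pi * (0:4) / 5))
  structured <- centers[graph$wing, ] + within[local_pos(1:15), ]
  withr_seed(seed, {
    purrr::map_dfr(seq_len(n), function(i) {
      rnd <- matrix(stats::runif(30, -12, 12), 15, 2)
      pos <- structure_bias * structured + (1 - structure_bias) * rnd +
        matrix(stats::rnorm(30, 0, noise), 15, 2)
      tibble::tibble(participant = sprintf("p%02d", i), painting = 1:15,
                     x = round(pos[, 1]), y = round(pos[, 2]))
    })
  })
}
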