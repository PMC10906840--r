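# Community sensitivity of a learned successor representation. The
# modularity of a successor matrix is the ratio of the mean angular-distance
# state prediction error over all possible between-wing transitions to the
# mean over the designated non-preferred within-wing transitions (the one
# within-wing edge per wing that neither is preferred nor touches the wide
# room) -- classes that are topologically identical apart from the
# community boundary.

# enumerate the (prev conjunction, next conjunction) pairs of a mechanical
# transition class
class_pairs <- function(mapping, class, variant = "state_action") {
  key <- paste0("pairs_", class, "_", variant)
  if (!is.null(.msr_cache[[key]])) return(.msr_cache[[key]])
  .msr_cache[[key]] <- class_pairs_build(mapping, class, variant)
  .msr_cache[[key]]
}

class_pairs_build <- function(mapping, class, variant = "state_action") {
  tr <- enumerate_transitions(mapping)
  tr <- tr[tr$mechanical == class, ]
  if (!nrow(tr)) stop("empty transition class: ", class)
  if (variant == "state_state") return(cbind(tr$from, tr$to))
  out <- NULL
  for (i in seq_len(nrow(tr))) {
    for (a in 1:2) {
      if (!(tr$to[i] %in% mapping$outcomes[tr$from[i], a, ])) next
      for (a2 in 1:2) {
        out <- rbind(out, c(sa_index(tr$from[i], a), sa_index(tr$to[i], a2)))
      }
    }
  }
  out
}

#' Modularity of a successor matrix
#'
#' @param M successor matrix (30 x 30 state-action, or 15 x 15 state-state)
#' @param mapping an `msr_mapping`
#' @return scalar ratio; 1 means between- and within-wing transitions are
#'   equally surprising, values above 1 indicate community structure
#' @export
modularity <- function(M, mapping) {
  variant <- if (nrow(M) == 30L) "state_action" else "state_state"
  pb <- class_pairs(mapping, "between", variant)
  pw <- class_pairs(mapping, "within_plain", variant)
  spe <- function(pairs) mean(apply(pairs, 1, function(p)
    angular_distance(M[p[2], ], M[p[1], ])))
  spe(pb) / spe(pw)
}

# final successor matrices after replaying a session, for several gammas
replay_final_M <- function(log, mapping, gammas, lambda = 0.1,
                           variant = "state_action") {
  moves <- session_moves(log, mapping)
  if (variant == "state_action") {
    state <- moves$sa; S <- 30L
    a1 <- sa_index(moves$room, 1L); a2 <- sa_index(moves$room, 2L)
    lo <- sa_index(moves$goal, 1L); hi <- sa_index(moves$goal, 2L)
  } else {
    state <- moves$room; S <- 15L
    a1 <- a2 <- moves$room; lo <- hi <- moves$goal
  }
  res <- cpp_sr_replay(as.integer(state), as.integer(a1), as.integer(a2),
                       as.integer(lo), as.integer(hi), as.numeric(gammas),
                       lambda, -0.08, S, want_M = TRUE)
  array(res$M, dim = c(S, S, length(gammas)))
}

#' Modularity as a function of the discount factor
#'
#' Replays one participant's experienced sequence for a grid of discount
#' factors and evaluates the modularity of each final successor matrix
#' (the per-participant modularity curve).
#'
#' @param log a session log
#' @param mapping the participant's mapping
#' @param gammas discount grid
#' @param lambda SR learning rate
#' @return tibble `gamma`, `modularity`
#' @export
modularity_curve <- function(log, mapping, gammas = seq(0, 0.99, by = 0.03),
                             lambda = 0.1) {
  Ms <- replay_final_M(log, mapping, gammas, lambda)
  tibble::tibble(
    gamma = gammas,
    modularity = vapply(seq_along(gammas), function(i)
      modularity(Ms[, , i], mapping), numeric(1))
  )
}

#' Expected modularity under a set of discount-factor draws
#'
#' For each draw the experienced sequence is replayed to its final
#' successor matrix and the modularity evaluated; the expectation is the
#' mean over draws. Draws beyond `max_draws` are thinned to an
#' order-invariant (sorted, evenly spaced) subset.
#'
#' @param gamma_draws posterior draws of the discount factor
#' @param log,mapping the participant's session and mapping
#' @param lambda SR learning rate
#' @param max_draws replay budget
#' @return scalar expected modularity
#' @export
expected_modularity <- function(gamma_draws, log, mapping, lambda = 0.1,
                                max_draws = 200L) {
  g <- sort(gamma_draws)
  if (length(g) > max_draws)
    g <- g[round(seq(1, length(g), length.out = max_draws))]
  Ms <- replay_final_M(log, mapping, g, lambda)
  mean(vapply(seq_along(g), function(i) modularity(Ms[, , i], mapping),
              numeric(1)))
}

#' Expected modularity under the uniform prior on the discount factor
#'
#' The per-participant null: Beta(1, 1) draws of the discount factor
#' replayed over the same experienced sequence.
#'
#' @inheritParams expected_modularity
#' @param n_draws Monte-Carlo draws from the prior
#' @param seed RNG seed
#' @return scalar null modularity
#' @export
null_modularity <- function(log, mapping, n_draws = 200L, seed = 1L,
                            lambda = 0.1) {
  g <- withr_seed(seed, stats::rbeta(n_draws, 1, 1))
  expected_modularity(g, log, mapping, lambda = lambda, max_draws = n_draws)
}

#' Between-community response-time slowing
#'
#' Difference in mean response times between trials following a transition
#' between two non-goal wings ("between") and trials following a
#' within-wing transition outside the goal wing ("outside"); positive
#' values mean slower responding after community boundaries.
#'
#' @param log a session log with response times
#' @param mapping the participant's mapping
#' @return difference in ms
#' @export
rt_slowing <- function(log, mapping) {
  lab <- trial_transition_labels(log, mapping)
  m <- tapply(lab$rt, lab$transition_type, mean)
  if (is.na(m["between"]) || is.na(m["outside"]))
    stop("empty transition class for the slowing contrast")
  unname(m["between"] - m["outside"])
}

trial_transition_labels <- function(log, mapping) {
  moves <- session_moves(log, mapping)
  rows <- which(moves$analyzable)
  prev_room <- c(NA_integer_, moves$room[-nrow(moves)])
  tibble::tibble(
    rt = moves$rt[rows],
    room = moves$room[rows],
    transition_type = vapply(rows, function(i)
      goal_transition_label(mapping$graph, prev_room[i], moves$room[i],
                            moves$goal[i]), character(1)),
    room_type = vapply(rows, function(i)
      goal_room_label(mapping, moves$room[i], moves$goal[i]), character(1)),
    prev_between = wing_of(mapping$graph, prev_room[rows]) !=
      wing_of(mapping$graph, moves$room[rows])
  )
}

#' Paired within-community response-time contrasts
#'
#' Per-participant mean response times by goal-relative room class (trials
#' following a between-community transition excluded), compared by paired
#' t-tests: boundary rooms between non-goal wings vs plain non-goal rooms
#' ("away" vs "outside"), goal-ward boundary vs away boundary ("toward" vs
#' "away") and goal-wing boundary vs plain goal-wing rooms ("outof" vs
#' "within"); Holm-adjusted.
#'
#' @param cohort an `msr_cohort` with response times
#' @return tibble of contrasts with `estimate`, `t`, `df`, `p`, `p_holm`
#' @export
within_wing_contrasts <- function(cohort) {
  per <- purrr::imap_dfr(cohort$logs, function(lg, id) {
    lab <- trial_transition_labels(lg, cohort$mappings[[id]])
    lab <- lab[!lab$prev_between, ]
    out <- tapply(lab$rt, lab$room_type, mean)
    tibble::tibble(participant = id,
                   outside = out["outside"], away = out["away"],
                   toward = out["toward"], within = out["within"],
                   outof = out["outof"])
  })
  contrasts <- list(away_vs_outside = c("away", "outside"),
                    toward_vs_away = c("toward", "away"),
                    outof_vs_within = c("outof", "within"))
  res <- purrr::imap_dfr(contrasts, function(cc, nm) {
    d <- per[[cc[1]]] - per[[cc[2]]]
    d <- d[stats::complete.cases(d)]
    tt <- stats::t.test(d)
    tibble::tibble(contrast = nm, estimate = mean(d),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
  })
  res$p_holm <- holm_bonferroni(res$p)
  res
}

#' Two-step (hierarchical) regression of an outcome on slowing and
#' modularity
#'
#' Step 1 regresses the outcome on between-community response-time slowing
#' alone; step 2 adds the successor-representation modularity. The delta-F
#' statistic (1, n - 3 df) tests whether modularity explains variance
#' beyond slowing.
#'
#' @param y outcome vector (one value per participant)
#' @param slowing between-community RT slowing per participant
#' @param modularity expected modularity per participant
#' @return one-row tibble with step-1/step-2 F and R-squared, the
#'   modularity slope, `delta_F` and its p-value
#' @export
two_step_regression <- function(y, slowing, modularity) {
  ok <- stats::complete.cases(y, slowing, modularity)
  y <- y[ok]; slowing <- slowing[ok]; modularity <- modularity[ok]
  n <- length(y)
  if (n < 4) stop("need at least 4 complete cases")
  f1 <- stats::lm(y ~ slowing)
  f2 <- stats::lm(y ~ slowing + modularity)
  if (any(is.na(stats::coef(f2)))) stop("rank-deficient two-step design")
  s1 <- summary(f1); s2 <- summary(f2)
  rss1 <- sum(stats::residuals(f1)^2); rss2 <- sum(stats::residuals(f2)^2)
  dF <- (rss1 - rss2) / (rss2 / (n - 3))
  tibble::tibble(
    n = n,
    F1 = unname(s1$fstatistic[1]), R2_1 = s1$r.squared,
    F2 = unname(s2$fstatistic[1]), R2_2 = s2$r.squared,
    slope_modularity = unname(stats::coef(f2)["modularity"]),
    delta_F = dF,
    p = stats::pf(dF, 1, n - 3, lower.tail = FALSE)
  )
}

#' Accumulated reward of a session
#'
#' Goal rewards (training/testing rates) minus wrong-goal and goal-miss
#' penalties, in the task's currency units.
#'
#' @param log a session log
#' @param config an [msr_config()]
#' @return scalar reward
#' @export
accumulated_reward <- function(log, config = msr_config()) {
  hit_tr <- sum(log$event == "goal_reached" & log$phase == "training")
  hit_te <- sum(log$event == "goal_reached" & log$phase == "testing")
  pen <- sum(log$event %in% c("goal_miss", "wrong_goal"))
  hit_tr * config$reward_training + hit_te * config$reward_testing -
    pen * config$penalty
}

#' Individual-difference regression suite
#'
#' Applies the two-step slowing/modularity regression to every outcome
#' column and Holm-adjusts the delta-F p-values across the suite, mirroring
#' the exploratory 15-regression family; the confirmatory simple
#' regressions of modularity on the successor-model posterior probability
#' and on reward can be added by including those outcomes.
#'
#' @param data tibble with one row per participant, columns `slowing`,
#'   `modularity` and the outcome columns
#' @param outcomes character vector of outcome column names
#' @return tibble of two-step results with `p_holm`
#' @export
modularity_suite <- function(data, outcomes) {
  res <- purrr::map_dfr(outcomes, function(oc) {
    tibble::add_column(two_step_regression(data[[oc]], data$slowing,
                                           data$modularity),
                       outcome = oc, .before = 1)
  })
  res$p_holm <- holm_bonferroni(res$p)
  res
}
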