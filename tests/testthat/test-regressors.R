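test_that("SARSA successor updates match the closed-form hand computation", {
  M <- diag(30)
  expect_identical(sr_update(M, 3, 7, lambda = 0, gamma = 0.9), M)
  M0 <- sr_update(M, 3, 7, lambda = 0.1, gamma = 0)
  expect_equal(M0, M)  # row already one-hot at gamma = 0
  M1 <- sr_update(M, 3, 7, lambda = 0.1, gamma = 0.5)
  expect_equal(M1[3, 7], 0.05)
  expect_equal(M1[3, 3], 1)
  expect_equal(M1[-3, ], M[-3, ])
  # nonnegativity is preserved over random update sequences
  set.seed(2)
  Mx <- diag(30)
  seq_sa <- sample.int(30, 400, replace = TRUE)
  for (t in 2:400) Mx <- sr_update(Mx, seq_sa[t - 1], seq_sa[t],
                                   lambda = 0.3, gamma = 0.95)
  expect_true(all(Mx >= 0))
})

test_that("angular distance identities hold", {
  v <- c(0.2, 1.4, -0.3)
  expect_equal(angular_distance(v, v), 0)
  expect_equal(angular_distance(c(1, 0, 0), c(0, 1, 0)), 0.5)
  expect_equal(angular_distance(c(1, 1), c(1, 0)), 0.25)
  expect_equal(angular_distance(v, 3 * v), 0)        # magnitude-invariant
  expect_error(angular_distance(c(0, 0), c(1, 0)), "zero vector")
})

test_that("Gram-Schmidt orthogonalization leaves exact residuals", {
  set.seed(4)
  EV <- rnorm(200); RPE <- 0.6 * EV + rnorm(200); EVd <- rnorm(200) + 0.3 * RPE
  gs <- gram_schmidt_orthogonalize(EV, RPE, EVd)
  expect_equal(gs[, "ev"], EV)
  expect_lt(abs(sum(gs[, "ev"] * gs[, "rpe"])), 1e-10)
  expect_lt(abs(sum(gs[, "ev"] * gs[, "conflict"])), 1e-10)
  expect_lt(abs(sum(gs[, "rpe"] * gs[, "conflict"])), 1e-10)
  # an already-orthogonal column is unchanged
  o <- rnorm(200); o <- o - sum(o * EV) / sum(EV^2) * EV
  gs2 <- gram_schmidt_orthogonalize(EV, o, EVd)
  expect_equal(gs2[, "rpe"], o, tolerance = 1e-12)
  # a collinear column collapses to zero and is flagged
  gs3 <- gram_schmidt_orthogonalize(EV, 2 * EV, EVd)
  expect_true(all(abs(gs3[, "rpe"]) < 1e-10))
  expect_true("rpe" %in% attr(gs3, "degenerate"))
})

test_that("SR readouts have the stated limits on a long random walk", {
  m <- fx_mapping()
  log <- fx_random_session()
  moves <- museumsr:::session_moves(log, m)
  outs <- museumsr:::sr_outputs(moves, c(0.001, 0.9))
  # near gamma = 0 rows converge to one-hots: every transition's surprise
  # approaches the orthogonal-one-hot value of 0.5
  late <- seq(nrow(moves) - 400, nrow(moves))
  expect_lt(max(abs(outs$SPE[late, 1] - 0.5)), 0.01)
  # at gamma = 0.9, crossing a wing is more surprising than staying inside
  prev_room <- c(NA, moves$room[-nrow(moves)])
  between <- wing_of(m$graph, prev_room[late]) != wing_of(m$graph, moves$room[late])
  expect_gt(mean(outs$SPE[late, 2][between]),
            mean(outs$SPE[late, 2][!between]))
})

test_that("regressor matrices are standardized over exactly the fitted trials", {
  m <- fx_mapping()
  log <- fx_sr_session()
  reg <- build_regressors(log, m, "sr", gamma = 0.9)
  X <- attr(reg, "X")
  expect_true(attr(reg, "orthogonalized"))
  expect_true(attr(reg, "standardized"))
  ok <- setdiff(colnames(X), attr(X, "flagged_constant"))
  expect_equal(unname(colMeans(X[, ok])), rep(0, length(ok)), tolerance = 1e-10)
  expect_equal(unname(apply(X[, ok], 2, stats::sd)), rep(1, length(ok)),
               tolerance = 1e-10)
  # entering the goal wing is rewarded: positive RPE on average (checked on
  # the raw, pre-orthogonalization readouts)
  moves <- museumsr:::session_moves(log, m)
  outs <- museumsr:::sr_outputs(moves, 0.9)
  rpe <- c(NA, diff(outs$EV[, 1]))
  prev_room <- c(NA, moves$room[-nrow(moves)])
  into <- which(!is.na(prev_room) &
                  wing_of(m$graph, prev_room) != wing_of(m$graph, moves$goal) &
                  wing_of(m$graph, moves$room) == wing_of(m$graph, moves$goal))
  expect_gt(mean(rpe[into], na.rm = TRUE), 0)
})

test_that("nuisance regressors match their definitions row by row", {
  m <- fx_mapping()
  log <- fx_random_session()
  moves <- museumsr:::session_moves(log, m)
  nc <- museumsr:::nuisance_columns(moves, m)
  n <- nrow(moves)
  # independent recomputation with plain loops
  for (t in sort(sample(2:n, 25))) {
    mb <- paste(moves$phase, moves$miniblock)
    step_in_mb <- sum(mb[1:t] == mb[t])
    expect_equal(unname(nc[t, "logsteps"]), log(step_in_mb))
    prev_visits <- which(moves$room[seq_len(t - 1)] == moves$room[t])
    expected_rec <- if (length(prev_visits)) t - max(prev_visits) else t
    expect_equal(unname(nc[t, "logrecency"]), log(expected_rec))
    expect_equal(unname(nc[t, "response_switch"]),
                 as.numeric(moves$key[t] != moves$key[t - 1]))
    sh <- museumsr:::shared_outcome(m, moves$room[t - 1])
    expect_equal(unname(nc[t, "preferred"]),
                 as.numeric(!is.na(sh) && sh == moves$room[t] &&
                              wing_of(m$graph, moves$room[t - 1]) ==
                              wing_of(m$graph, moves$room[t])))
    expect_equal(unname(nc[t, "wide_node"]), as.numeric(moves$room[t] %in% m$graph$wide))
    expect_equal(unname(nc[t, "wide_trans"]), as.numeric(moves$room[t - 1] %in% m$graph$wide))
  }
})

test_that("trial order matters for SR regressors but not MB or explicit ones", {
  m <- fx_mapping()
  log <- fx_sr_session()
  moves <- museumsr:::session_moves(log, m)
  set.seed(8)
  perm <- sample(nrow(moves))
  shuffled <- moves[perm, ]
  sr_a <- museumsr:::sr_outputs(moves, 0.8)$SPE
  sr_b <- museumsr:::sr_outputs(shuffled, 0.8)$SPE
  expect_false(isTRUE(all.equal(sort(sr_a[-1]), sort(sr_b[-1]))))
  mb_a <- museumsr:::mb_outputs(moves, m, 0.8)$EV
  mb_b <- museumsr:::mb_outputs(shuffled, m, 0.8)$EV
  expect_equal(mb_a[perm], mb_b[, 1])  # MB values are trial-local
})

test_that("the state-state variant predicts boundary surprise the state-action one hides", {
  m <- fx_mapping()
  log <- fx_random_session()
  moves <- museumsr:::session_moves(log, m)
  sa <- museumsr:::sr_outputs(moves, 0.9, variant = "state_action")$SPE[, 1]
  ss <- museumsr:::sr_outputs(moves, 0.9, variant = "state_state")$SPE[, 1]
  late <- seq(max(2, nrow(moves) - 500), nrow(moves))
  lab <- vapply(late, function(i)
    museumsr:::goal_room_label(m, moves$room[i], moves$goal[i]), character(1))
  contrast <- function(spe) mean(spe[late][lab == "away"], na.rm = TRUE) -
    mean(spe[late][lab == "outside"], na.rm = TRUE)
  # relative surprise at "away" boundary rooms is larger under the
  # state-state formulation
  expect_gt(contrast(ss) / mean(ss[late], na.rm = TRUE),
            contrast(sa) / mean(sa[late], na.rm = TRUE))
})

test_that("regressor tables round-trip through CSV with their header", {
  m <- fx_mapping()
  reg <- build_regressors(fx_sr_session(), m, "sr", gamma = 0.85)
  path <- tempfile(fileext = ".csv")
  write_regressors_csv(reg, path)
  back <- read_regressors_csv(path)
  expect_equal(attr(back, "gamma"), 0.85)
  expect_equal(attr(back, "model"), "sr")
  expect_equal(back$spe, reg$spe, tolerance = 1e-12)
  unlink(c(path, paste0(path, ".json")))
})
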