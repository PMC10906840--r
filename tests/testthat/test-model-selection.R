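# Exact leave-one-out oracle for the conjugate normal-mean model with known
# observation sd: p(y_i | y_-i) is Student-like only through the Gaussian
# posterior predictive, available in closed form.
exact_loo_normal <- function(y, prior_mean = 0, prior_sd = 2, obs_sd = 1) {
  vapply(seq_along(y), function(i) {
    yi <- y[-i]
    post_prec <- 1 / prior_sd^2 + length(yi) / obs_sd^2
    post_mean <- (prior_mean / prior_sd^2 + sum(yi) / obs_sd^2) / post_prec
    stats::dnorm(y[i], post_mean, sqrt(1 / post_prec + obs_sd^2), log = TRUE)
  }, numeric(1))
}

draw_normal_posterior <- function(y, S, prior_mean = 0, prior_sd = 2,
                                  obs_sd = 1, seed = 1) {
  post_prec <- 1 / prior_sd^2 + length(y) / obs_sd^2
  post_mean <- (prior_mean / prior_sd^2 + sum(y) / obs_sd^2) / post_prec
  withr_seed(seed, stats::rnorm(S, post_mean, sqrt(1 / post_prec)))
}

test_that("PSIS-LOO agrees with exact leave-one-out on a small conjugate model", {
  set.seed(21)
  y <- rnorm(8, 0.4, 1)
  mu_draws <- draw_normal_posterior(y, 4000, seed = 22)
  ll <- sapply(y, function(yi) stats::dnorm(yi, mu_draws, 1, log = TRUE))
  res <- psis_loo(ll)
  exact <- sum(exact_loo_normal(y))
  expect_lt(abs(res$elpd_loo - exact), 2 * res$se)
  expect_length(res$pointwise, 8)
})

test_that("PSIS-LOO is additive in constants and rejects degenerate draws", {
  set.seed(23)
  ll <- matrix(rnorm(2000 * 12, -1, 0.3), 2000, 12)
  a <- psis_loo(ll)
  b <- psis_loo(ll + 0.7)
  expect_equal(b$elpd_loo, a$elpd_loo + 12 * 0.7, tolerance = 1e-6)
  expect_equal(psis_loo(ll)$elpd_loo, a$elpd_loo)  # deterministic, duplicate model
  expect_error(psis_loo(matrix(-1, 100, 4)), "degenerate")
})

test_that("pseudo-BMA+ weights form a simplex and regularize noisy ties", {
  set.seed(25)
  N <- 60
  p1 <- rnorm(N, -1, 0.2)
  ev <- tibble::tibble(
    participant = "p1",
    model = c("a", "b"),
    elpd_loo = c(sum(p1), sum(p1)),
    se = c(1, 1),
    pointwise = list(p1, p1),
    pareto_k = list(rep(0.1, N), rep(0.1, N))
  )
  w <- pseudo_bma_plus(ev, n_boot = 400, seed = 3)
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  expect_equal(w$weight, c(0.5, 0.5), tolerance = 0.02)  # identical models
  # strong dominance: winner weight approaches 1
  p2 <- p1 - 0.8
  ev$pointwise[[2]] <- p2
  ev$elpd_loo[2] <- sum(p2)
  w2 <- pseudo_bma_plus(ev, n_boot = 400, seed = 3)
  expect_gt(w2$weight[w2$model == "a"], 0.99)
  # a noisy small difference: bootstrap weights are less extreme than the
  # raw exp(elpd) weights
  set.seed(26)
  p3 <- p1 + rnorm(N, 0.05, 0.8)
  ev$pointwise[[2]] <- p3
  ev$elpd_loo[2] <- sum(p3)
  raw <- exp(ev$elpd_loo - max(ev$elpd_loo))
  raw <- raw / sum(raw)
  w3 <- pseudo_bma_plus(ev, n_boot = 800, seed = 4)
  expect_lt(max(w3$weight), max(raw))
})

test_that("group BMS: exchangeable evidences give flat pxp and a high omnibus risk", {
  L <- matrix(-100, 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  b <- group_bms(L, seed = 5)
  expect_equal(unname(b$pxp), rep(1 / 3, 3), tolerance = 0.01)
  expect_gt(b$bor, 0.5)
  expect_equal(sum(b$pxp), 1, tolerance = 1e-9)
  expect_equal(unname(rowSums(b$model_prob)), rep(1, 12), tolerance = 1e-12)
  expect_error(group_bms(L[, 1, drop = FALSE]), "at least 2")
})

test_that("group BMS detects a dominant model in a 20-participant cohort", {
  set.seed(6)
  n <- 20
  L <- cbind(win = rnorm(n, -95, 2), lose1 = rnorm(n, -102, 2),
             lose2 = rnorm(n, -103, 2))
  b <- group_bms(L, seed = 7)
  expect_gt(b$pxp[["win"]], 0.95)
  expect_lt(b$bor, 0.05)
  expect_gt(b$freq[["win"]], 0.6)
})

test_that("pairwise BMS applies the Holm multiplier and respects symmetry", {
  ev <- tibble::tibble(
    participant = rep(paste0("p", 1:12), each = 2),
    model = rep(c("a", "b"), 12),
    elpd_loo = rep(-50, 24),
    se = 1,
    pointwise = replicate(24, rep(-5, 10), simplify = FALSE),
    pareto_k = replicate(24, rep(0.1, 10), simplify = FALSE)
  )
  pb <- pairwise_bms(ev, "a", "b", m_comparisons = 3)
  expect_gte(pb$bor_adjusted, pb$bor_raw)
  expect_equal(unname(pb$bms$pxp), c(0.5, 0.5), tolerance = 1e-6)
  # dominant pair
  ev2 <- ev
  ev2$elpd_loo[ev2$model == "b"] <- -80
  ev2$pointwise[ev2$model == "b"] <- replicate(12, rep(-8, 10), simplify = FALSE)
  pb2 <- pairwise_bms(ev2, "a", "b")
  expect_gt(pb2$bms$pxp[["a"]], 0.95)
})

test_that("the generalized-Pareto tail fit recovers known shapes", {
  set.seed(8)
  for (k_true in c(0.2, 0.7)) {
    x <- (runif(3000)^(-k_true) - 1) / k_true   # GPD(sigma = 1, k_true)
    fit <- museumsr:::gpd_fit(x)
    expect_equal(fit$k, k_true, tolerance = 0.12)
    expect_equal(fit$sigma, 1, tolerance = 0.15)
  }
})

test_that("response-time model comparison recovers the successor generator", {
  # slopes drawn from the fitting prior (the generator default), which
  # makes the surprise channel clearly expressed in the data
  rt_cols <- c("spe", "ev", "rpe", "conflict", "logsteps", "logrecency",
               "response_switch", "preferred", "wide_node", "wide_trans")
  coh <- simulate_cohort(4, "successor", function(i)
    msr_agent("successor", choice_beta = 8, gamma = 0.9,
              rt_beta = stats::setNames(stats::rnorm(10, 0, 0.1), rt_cols)),
    seed = 909, config = msr_config(testing_budget = 400))
  models <- c("null", "explicit", "mb", "sr")
  fits <- purrr::imap(coh$logs, function(lg, id) {
    i <- match(id, names(coh$logs))
    stats::setNames(lapply(seq_along(models), function(j)
      fit_rt_model(lg, coh$mappings[[id]], models[j],
                   seed = 500 + 10 * i + j)), models)
  })
  cmp <- compare_models(fits, seed = 2)
  expect_equal(names(which.max(cmp$bms$pxp)), "sr")
  w <- cmp$weights |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(w = mean(.data$weight))
  expect_gt(w$w[w$model == "sr"], 0.9)
})
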