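test_that("pointwise likelihood matches the closed-form shifted lognormal", {
  m <- fx_mapping()
  log <- fx_sr_session()
  grid <- museumsr:::regressor_grid(log, m, "null")
  fit <- fit_rt_model(log, m, "null", seed = 3, grid = grid)
  d <- fit$draws
  flat <- matrix(d, nrow = prod(dim(d)[1:2]), ncol = dim(d)[3])
  colnames(flat) <- dimnames(d)[[3]]
  y <- grid$y
  X <- grid$X[, , 1]
  set.seed(1)
  for (s in sample(nrow(flat), 5)) {
    mu <- flat[s, "alpha"] + drop(X %*% flat[s, grep("^b_", colnames(flat))])
    sig <- flat[s, "sigma"]; ndt <- flat[s, "ndt"]
    manual <- -log((y - ndt) * sig * sqrt(2 * pi)) -
      (log(y - ndt) - mu)^2 / (2 * sig^2)
    expect_equal(fit$loglik[s, ], manual, tolerance = 1e-12)
  }
  # non-decision time never exceeds the fastest response
  expect_true(all(extract_draws(fit, "ndt") < min(y)))
  expect_true(check_convergence(fit))
})

test_that("slope posteriors cover zero for null data and sharpen with more trials", {
  g <- fx_graph(); m <- fx_mapping()
  ag <- msr_agent("random", rt_beta = c(logsteps = 0), rt_sigma = 0.25,
                  rt_ndt = 200)   # RTs carry no regressor signal
  short <- run_session(ag, g, m, seed = 41, config = msr_config(testing_budget = 150))
  long <- run_session(ag, g, m, seed = 42, config = msr_config(testing_budget = 700))
  f_s <- fit_rt_model(short, m, "null", seed = 5)
  f_l <- fit_rt_model(long, m, "null", seed = 6)
  width <- function(f, p) diff(unname(hdi(extract_draws(f, p))))
  covered <- vapply(grep("^b_", dimnames(f_l$draws)[[3]], value = TRUE),
                    function(p) {
                      h <- hdi(extract_draws(f_l, p)); h[1] <= 0 && 0 <= h[2]
                    }, logical(1))
  expect_gt(mean(covered), 0.75)
  expect_lt(width(f_l, "b_preferred"), width(f_s, "b_preferred"))
  expect_lt(width(f_l, "b_logrecency"), width(f_s, "b_logrecency"))
})

test_that("the sampler is calibrated: rank statistics of truths are uniform", {
  # simulation-based calibration at reduced scale on the lognormal
  # regression with the non-decision time fixed (its empirical-Bayes bound
  # makes the data-dependent prior unsuitable for exact SBC)
  set.seed(99)
  n <- 40
  X <- array(cbind(scale(rnorm(n)), scale(rnorm(n))), c(n, 2, 1),
             dimnames = list(NULL, c("x1", "x2"), NULL))
  n_rep <- 60
  bins <- 8
  ranks <- matrix(NA_real_, n_rep, 3)
  for (r in seq_len(n_rep)) {
    alpha <- rnorm(1, 6, 1.5); beta <- rnorm(2, 0, 0.1)
    sigma <- abs(rnorm(1, 0, 1)) + 1e-3
    y <- 100 + exp(rnorm(n, alpha + drop(X[, , 1] %*% beta), sigma))
    grid <- list(model = "null", gammas = NULL, X = X, y = y,
                 moves = NULL, fit_rows = seq_len(n), choice_rows = integer(0))
    fit <- fit_rt_model(log = tibble::tibble(participant = "sbc"),
                        mapping = fx_mapping(), model = "null", seed = 1000 + r,
                        grid = grid, ndt_fixed = 100, n_draws = 1200L)
    for (j in 1:3) {
      par <- c("alpha", "b_x1", "sigma")[j]
      truth <- c(alpha, beta[1], sigma)[j]
      dr <- extract_draws(fit, par)
      ranks[r, j] <- (sum(dr < truth) + 0.5) / (length(dr) + 1)
    }
  }
  for (j in 1:3) {
    counts <- table(cut(ranks[, j], breaks = seq(0, 1, length.out = bins + 1)))
    expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  }
})

test_that("choice models recover rotation behavior and stay flat for random agents", {
  g <- fx_graph(); m <- fx_mapping()
  cfg <- msr_config(testing_budget = 500)
  rot_log <- run_session(msr_agent("rotation", choice_alpha = 0.3,
                                   choice_beta = 1.2), g, m, seed = 51,
                         config = cfg)
  fit_rot <- fit_choice_model(rot_log, m, "explicit", seed = 7)
  h <- hdi(extract_draws(fit_rot, "beta"))
  expect_true(h[1] <= 1.2 && 1.2 <= h[2])
  expect_gt(mean(extract_draws(fit_rot, "beta")), 0.5)
  rnd_log <- run_session(msr_agent("random"), g, m, seed = 52, config = cfg)
  fit_rnd <- fit_choice_model(rnd_log, m, "explicit", seed = 8)
  h0 <- hdi(extract_draws(fit_rnd, "beta"))
  expect_true(h0[1] <= 0 && 0 <= h0[2])
})

test_that("population model shrinks, recovers, and widens with noisier inputs", {
  set.seed(12)
  n <- 15
  truth_mu <- 0.03
  beta_i <- rnorm(n, truth_mu, 0.02)
  bh <- cbind(eff = beta_i + rnorm(n, 0, 0.01))
  eps <- cbind(eff = rep(0.01, n))
  fit <- fit_population_summary(bh, eps, seed = 31)
  h <- hdi(extract_draws(fit, "mu_eff"))
  expect_true(h[1] <= truth_mu && truth_mu <= h[2])
  # shrinkage: participant effects lie between their input and the mean
  pe <- fit$meta$participant_effects[, "eff"]
  mu_hat <- mean(extract_draws(fit, "mu_eff"))
  between <- (pe >= pmin(bh[, 1], mu_hat) - 1e-6) &
    (pe <= pmax(bh[, 1], mu_hat) + 1e-6)
  expect_gt(mean(between), 0.9)
  # tight zero inputs concentrate the population mean at zero
  fit0 <- fit_population_summary(cbind(e = rep(0, 10)), cbind(e = rep(0.001, 10)),
                                 seed = 32)
  expect_lt(diff(unname(hdi(extract_draws(fit0, "mu_e")))), 0.02)
  # inflating the measurement noise widens the population posterior
  fit_w <- fit_population_summary(bh, eps * 20, seed = 33)
  expect_gt(diff(unname(hdi(extract_draws(fit_w, "mu_eff")))),
            diff(unname(hdi(extract_draws(fit, "mu_eff")))))
  expect_error(fit_population_summary(bh[1, , drop = FALSE],
                                      eps[1, , drop = FALSE]), "2 participants")
})

test_that("hierarchical logistic designs and fits behave on targeted agents", {
  cfg <- msr_config(testing_budget = 350)
  coh <- simulate_cohort(4, "rotation", function(i)
    msr_agent("rotation", choice_alpha = 0.3, choice_beta = 1.5), seed = 61,
    config = cfg)
  sw <- build_switch_design(coh$logs[[1]], coh$mappings[[1]])
  expect_true(all(sw$switch %in% 0:1))
  expect_true(all(sw$entry %in% 0:1) && all(sw$leave %in% 0:1))
  expect_lt(abs(mean(sw$logrep)), 1e-8)  # standardized within participant
  rot <- build_rotation_design(coh$logs[[1]], coh$mappings[[1]])
  expect_setequal(unique(rot$node_type), c(-0.5, 0.5))
  expect_setequal(unique(abs(rot$interaction)), 0.25)
  # a strongly rotating agent almost never switches keys after entering the
  # goal wing relative to leaving it; fit the switch design end to end
  fit <- fit_hier_logistic(coh, "switch", seed = 62)
  expect_true(all(c("mu_entry", "mu_leave", "mu_logrep") %in%
                    dimnames(fit$draws)[[3]]))
  expect_gt(mean(extract_draws(fit, "mu_leave")),
            mean(extract_draws(fit, "mu_entry")))
})

test_that("HDI, evidence ratios and Holm adjustment match hand arithmetic", {
  set.seed(44)
  z <- rnorm(4e4)
  h <- hdi(z, 0.95)
  expect_equal(unname(h), c(-1.96, 1.96), tolerance = 0.05)
  draws <- c(rep(1, 975), rep(-1, 25))
  expect_equal(evidence_ratio(draws, "+"), 39)
  expect_equal(evidence_ratio(rep(2, 100), "+"), Inf)
  expect_equal(evidence_ratio(c(-1, 1), "+"), 1)
  expect_equal(evidence_ratio(draws, "-"), 1 / 39)
  expect_equal(holm_bonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_bonferroni(0.03), 0.03)
  p <- holm_bonferroni(c(0.04, 0.001, 0.02, 0.5))
  expect_true(all(diff(p[order(c(0.04, 0.001, 0.02, 0.5))]) >= 0))
  expect_true(all(p <= 1))
})

test_that("posterior predictions stay above ndt and track transition types", {
  m <- fx_mapping()
  log <- fx_sr_session()
  fit <- fit_rt_model(log, m, "sr", seed = 71)
  pp <- posterior_predict_rt(fit, log, m)
  expect_true(all(pp$predictive > min(extract_draws(fit, "ndt"))))
  expect_true(all(c("observed_mean", "predicted_mean") %in% names(pp$by_type)))
  # self-consistency: predictive means track observed means by type
  expect_gt(stats::cor(pp$by_type$observed_mean, pp$by_type$predicted_mean), 0.5)
})
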