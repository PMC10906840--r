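# Two-stage population inference. Participant-level posteriors are
# summarized by Gaussian density estimation (posterior mean and sd per
# slope) and combined in a hierarchical Gaussian model by Gibbs sampling:
#   beta_hat_i ~ N(beta_i, diag(eps_i));  beta_i ~ N(mu, diag(tau^2))
# with mu ~ N(0, 0.1) and tau ~ halfN(0, 0.1) for the two-stage regression
# of model slopes, or a Student-t(3, 0, 2.5) population prior (expressed as
# a scale mixture of normals) for the hierarchical GLM designs. The
# covariance is diagonal (see the methods vignette for the rationale).

#' Two-stage population model over participant posterior summaries
#'
#' @param beta_hat matrix (participants x effects) of participant posterior
#'   means, with column names
#' @param epsilon matrix of matching posterior standard deviations
#' @param prior `"two_stage"` (mu ~ N(0, 0.1), tau ~ halfN(0, 0.1)) or
#'   `"glm"` (mu ~ Student-t(3, 0, 2.5), tau ~ half-t(3, 0, 2.5))
#' @param profile sampler profile
#' @param seed sampler seed
#' @return an `msr_draws` over `mu_*` and `tau_*` with the shrunken
#'   participant effects (posterior means of `beta_i`) in
#'   `meta$participant_effects`
#' @export
fit_population_summary <- function(beta_hat, epsilon,
                                   prior = c("two_stage", "glm"),
                                   profile = c("test", "paper"), seed = 1L) {
  prior <- match.arg(prior)
  profile <- match.arg(profile)
  beta_hat <- as.matrix(beta_hat); epsilon <- as.matrix(epsilon)
  if (!identical(dim(beta_hat), dim(epsilon)))
    stop("beta_hat and epsilon dimensions disagree")
  n <- nrow(beta_hat); d <- ncol(beta_hat)
  if (n < 2) stop("population model needs at least 2 participants")
  effects <- colnames(beta_hat)
  if (is.null(effects)) effects <- paste0("x", seq_len(d))
  s <- sampler_settings(profile, "population")
  kept <- floor(s$iter / s$thin)
  draws <- array(NA_real_, c(kept, s$chains, 2L * d),
                 dimnames = list(NULL, NULL, c(paste0("mu_", effects),
                                               paste0("tau_", effects))))
  eff_acc <- matrix(0, n, d)
  mu_sd0 <- if (prior == "two_stage") 0.1 else NULL  # glm prior handled below
  tau_scale <- if (prior == "two_stage") 0.1 else 2.5
  withr_seed(seed, {
    for (ch in seq_len(s$chains)) {
      mu <- stats::rnorm(d, 0, 0.05)
      tau <- abs(stats::rnorm(d, 0, 0.05)) + 0.02
      beta <- beta_hat
      omega <- rep(1, d)   # t-prior mixture scales (glm prior only)
      k <- 0L
      for (i in seq_len(s$warmup + s$iter)) {
        prec_b <- 1 / epsilon^2 + matrix(1 / tau^2, n, d, byrow = TRUE)
        mean_b <- (beta_hat / epsilon^2 +
                     matrix(mu / tau^2, n, d, byrow = TRUE)) / prec_b
        beta <- mean_b + matrix(stats::rnorm(n * d), n, d) / sqrt(prec_b)
        if (prior == "glm") {
          omega <- stats::rgamma(d, shape = 2, rate = (3 + (mu / 2.5)^2) / 2)
          mu_var0 <- 2.5^2 / omega
        } else mu_var0 <- rep(mu_sd0^2, d)
        prec_mu <- n / tau^2 + 1 / mu_var0
        mean_mu <- colSums(beta) / tau^2 / prec_mu
        mu <- stats::rnorm(d, mean_mu, 1 / sqrt(prec_mu))
        # metropolis-within-gibbs on log tau
        for (o in seq_len(d)) {
          lt <- log(tau[o]); lt_p <- lt + stats::rnorm(1, 0, 0.3)
          lp <- function(l) {
            t_ <- exp(l)
            ll <- sum(stats::dnorm(beta[, o], mu[o], t_, log = TRUE))
            pr <- if (prior == "two_stage")
              stats::dnorm(t_, 0, tau_scale, log = TRUE)
            else stats::dt(t_ / tau_scale, df = 3, log = TRUE) - log(tau_scale)
            ll + pr + l   # jacobian of exp
          }
          if (log(stats::runif(1)) < lp(lt_p) - lp(lt)) tau[o] <- exp(lt_p)
        }
        if (i > s$warmup && (i - s$warmup) %% s$thin == 0L) {
          k <- k + 1L
          draws[k, ch, ] <- c(mu, tau)
          eff_acc <- eff_acc + beta / (kept * s$chains)
        }
      }
    }
  })
  colnames(eff_acc) <- effects
  msr_draws(draws, model = paste0("population_", prior),
            meta = list(kind = "population", effects = effects,
                        beta_hat = beta_hat, epsilon = epsilon,
                        participant_effects = eff_acc))
}

#' Summarize participant-level slope posteriors for the population stage
#'
#' @param fits list of `msr_draws` (one per participant)
#' @param parameters parameter names to extract (default: all `b_*` slopes
#'   of the first fit)
#' @return list with `beta_hat` and `epsilon` matrices
#' @export
summarize_for_population <- function(fits, parameters = NULL) {
  if (is.null(parameters)) {
    pn <- dimnames(fits[[1]]$draws)[[3]]
    parameters <- grep("^b_", pn, value = TRUE)
  }
  beta_hat <- t(vapply(fits, function(f)
    vapply(parameters, function(p) mean(extract_draws(f, p)), numeric(1)),
    numeric(length(parameters))))
  epsilon <- t(vapply(fits, function(f)
    vapply(parameters, function(p) stats::sd(extract_draws(f, p)), numeric(1)),
    numeric(length(parameters))))
  colnames(beta_hat) <- colnames(epsilon) <- sub("^b_", "", parameters)
  list(beta_hat = beta_hat, epsilon = epsilon)
}

# ---- hierarchical GLM designs --------------------------------------------

#' Response-switch design
#'
#' One row per testing move trial with a within-miniblock predecessor:
#' outcome `switch` (key differs from the previous trial), dummies for the
#' trial immediately after entering / leaving the goal wing, and the
#' log-transformed successive repetition count of the previous key
#' (standardized within participant).
#'
#' @param log a single-participant session log
#' @param mapping the participant's mapping
#' @return design tibble
#' @export
build_switch_design <- function(log, mapping) {
  g <- mapping$graph
  moves <- session_moves(log, mapping)
  moves <- moves[moves$phase == "testing" & moves$event == "move", ]
  n <- nrow(moves)
  prev_same_mb <- c(FALSE, moves$miniblock[-1] == moves$miniblock[-n])
  prev_room <- c(NA_integer_, moves$room[-n])
  prev_key <- c(NA_character_, moves$key[-n])
  in_gw <- wing_of(g, moves$room) == wing_of(g, moves$goal)
  prev_in_gw <- c(NA, wing_of(g, prev_room[-1]) == wing_of(g, moves$goal[-1]))
  run_len <- numeric(n); run_len[1] <- 1
  for (t in 2:n) run_len[t] <-
    if (!is.na(prev_key[t]) && moves$key[t] == prev_key[t]) run_len[t - 1] + 1 else 1
  prev_run <- c(NA, run_len[-n])
  out <- tibble::tibble(
    participant = moves$participant,
    switch = as.numeric(moves$key != prev_key),
    entry = as.numeric(!prev_in_gw & in_gw),
    leave = as.numeric(prev_in_gw & !in_gw),
    logrep = log(prev_run)
  )[prev_same_mb, ]
  out$logrep <- as.vector(scale(out$logrep))
  out
}

#' Rotation / antirotation design
#'
#' Trials in the two structurally matched rooms per (wing, goal) pair: the
#' room where the correct rotation is also value-optimal and the room where
#' the antirotation dominates. Outcome: the correct rotation was selected.
#' Regressors: which key the rotation is (`z` -0.5, `m` +0.5), node type
#' (rotation-optimal +0.5, antirotation-optimal -0.5), and their
#' interaction.
#'
#' @inheritParams build_switch_design
#' @return design tibble
#' @export
build_rotation_design <- function(log, mapping) {
  g <- mapping$graph
  moves <- session_moves(log, mapping)
  rows <- which(moves$choice_analyzable)
  recs <- list()
  for (i in rows) {
    w <- wing_of(g, moves$room[i]); wg <- wing_of(g, moves$goal[i])
    other <- setdiff(1:3, c(w, wg))
    orange <- antirotation_room(mapping, w, wg)
    blue <- antirotation_room(mapping, w, other)
    if (!(moves$room[i] %in% c(orange, blue))) next
    rot <- correct_rotation(mapping, w, wg)
    recs[[length(recs) + 1L]] <- tibble::tibble(
      participant = moves$participant[i],
      chose_rotation = as.numeric(moves$action[i] == rot),
      rotation_key = if (mapping$key_of[[rot]] == "m") 0.5 else -0.5,
      node_type = if (moves$room[i] == blue) 0.5 else -0.5
    )
  }
  out <- dplyr::bind_rows(recs)
  out$interaction <- out$rotation_key * out$node_type
  out
}

# stage-1 logistic posterior via the adaptive sampler (weak N(0, 2) priors)
logistic_stage1 <- function(y, X, profile = "test", seed = 1L) {
  p <- ncol(X)
  log_post <- function(theta) {
    eta <- drop(X %*% theta)
    sum(stats::dbinom(y, 1, stats::plogis(eta), log = TRUE)) +
      sum(stats::dnorm(theta, 0, 2, log = TRUE))
  }
  init <- function(ch) stats::rnorm(p, 0, 0.3)
  s <- sampler_settings(profile, "participant")
  run <- withr_seed(seed, run_adaptive_mh(log_post, init, n_chains = 2L,
                                          warmup = s$warmup, iter = s$iter,
                                          thin = s$thin))
  flat <- matrix(run$draws, ncol = p)
  list(mean = colMeans(flat), sd = apply(flat, 2, stats::sd))
}

#' Hierarchical Bayesian logistic regression (two-stage)
#'
#' Fits the response-switch or rotation/antirotation design: per-participant
#' logistic posteriors (weakly-informative N(0, 2) priors) are combined by
#' the population model with the Student-t(3, 0, 2.5) population prior.
#'
#' @param data an `msr_cohort`, or a prebuilt design tibble with columns
#'   `participant`, an outcome column, and regressors
#' @param design `"switch"` or `"rotation"` (ignored for a prebuilt tibble
#'   whose outcome column is then taken to be the first non-participant
#'   column)
#' @param profile,seed sampler controls
#' @return an `msr_draws` over population effects (`mu_*`, `tau_*`)
#' @export
fit_hier_logistic <- function(data, design = c("switch", "rotation"),
                              profile = c("test", "paper"), seed = 1L) {
  design <- match.arg(design)
  profile <- match.arg(profile)
  if (inherits(data, "msr_cohort")) {
    builder <- if (design == "switch") build_switch_design else build_rotation_design
    tabs <- purrr::imap(data$logs, function(lg, id)
      builder(lg, data$mappings[[id]]))
    tab <- dplyr::bind_rows(tabs)
  } else tab <- data
  ycol <- setdiff(names(tab), "participant")[1]
  xcols <- setdiff(names(tab), c("participant", ycol))
  ids <- unique(tab$participant)
  bh <- eps <- matrix(NA_real_, length(ids), 1L + length(xcols),
                      dimnames = list(ids, c("intercept", xcols)))
  for (j in seq_along(ids)) {
    sub <- tab[tab$participant == ids[j], ]
    X <- cbind(intercept = 1, as.matrix(sub[, xcols]))
    st <- logistic_stage1(sub[[ycol]], X, profile = profile, seed = seed + j)
    bh[j, ] <- st$mean; eps[j, ] <- st$sd
  }
  fit <- fit_population_summary(bh, eps, prior = "glm", profile = profile,
                                seed = seed + 101L)
  fit$meta$design <- design
  fit
}

#' Hierarchical Bayesian linear regression (two-stage)
#'
#' Used for the free-sort distance designs: per-participant OLS summaries
#' (coefficient and standard error) are combined by the population model
#' with the Student-t population prior.
#'
#' @param data design tibble with columns `participant`, an outcome column
#'   (first non-participant column) and regressors
#' @param profile,seed sampler controls
#' @return an `msr_draws` over population effects
#' @export
fit_hier_linear <- function(data, profile = c("test", "paper"), seed = 1L) {
  profile <- match.arg(profile)
  ycol <- setdiff(names(data), "participant")[1]
  xcols <- setdiff(names(data), c("participant", ycol))
  ids <- unique(data$participant)
  bh <- eps <- matrix(NA_real_, length(ids), 1L + length(xcols),
                      dimnames = list(ids, c("intercept", xcols)))
  for (j in seq_along(ids)) {
    sub <- data[data$participant == ids[j], ]
    f <- stats::lm(stats::reformulate(xcols, response = ycol), data = sub)
    sm <- summary(f)$coefficients
    if (nrow(sm) != 1L + length(xcols)) stop("rank-deficient design for ", ids[j])
    bh[j, ] <- sm[, 1]; eps[j, ] <- sm[, 2]
  }
  fit <- fit_population_summary(bh, eps, prior = "glm", profile = profile,
                                seed = seed + 211L)
  fit$meta$outcome <- ycol
  fit
}

#' Draw-wise contrast between two population effects
#'
#' @param fit an `msr_draws` from a population model
#' @param a,b effect names (without the `mu_` prefix)
#' @return numeric vector of contrast draws `mu_a - mu_b`
#' @export
contrast_draws <- function(fit, a, b) {
  extract_draws(fit, paste0("mu_", a)) - extract_draws(fit, paste0("mu_", b))
}
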